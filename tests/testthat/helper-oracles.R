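# Independent oracles the tests check the implementation against.
# These deliberately share no code with the package: the motif oracle is
# a naive all-offsets character comparison, the alignment oracle a plain
# Gotoh dynamic program.

# All (offset, motif) matches by direct character comparison.
oracle_scan <- function(sequences, motifs) {
  rows <- list()
  for (sid in names(sequences)) {
    chars <- strsplit(sequences[[sid]], "")[[1]]
    L <- length(chars)
    if (L < 9L) next
    starts <- 0:(L - 9L)
    for (m in motifs) {
      off <- as.integer(names(m$required))
      res <- unname(m$required)
      ok <- rep(TRUE, length(starts))
      for (k in seq_along(off)) {
        ok <- ok & chars[starts + off[k] + 1L] == res[k]
      }
      if (any(ok)) {
        st <- starts[ok]
        rows[[length(rows) + 1L]] <- data.frame(
          sequence_id = sid, motif_id = m$motif_id, start = st,
          matched_9mer = substring(sequences[[sid]], st + 1L, st + 9L),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(sequence_id = character(), motif_id = character(),
                      start = integer(), matched_9mer = character(),
                      stringsAsFactors = FALSE)
  }
  out <- out[order(out$sequence_id, out$start, out$motif_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Smith-Waterman score by Gotoh DP; a gap of length L costs
# gap_open + L * gap_extend. Score floored at zero.
oracle_sw_score <- function(query, subject, mat, gap_open = 11,
                            gap_extend = 1) {
  q <- strsplit(query, "")[[1]]
  s <- strsplit(subject, "")[[1]]
  n <- length(q); m <- length(s)
  H <- matrix(0, n + 1L, m + 1L)
  E <- matrix(-Inf, n + 1L, m + 1L)   # gap in query (along subject)
  F_ <- matrix(-Inf, n + 1L, m + 1L)  # gap in subject
  best <- 0
  for (i in 2:(n + 1L)) {
    for (j in 2:(m + 1L)) {
      E[i, j] <- max(H[i, j - 1L] - (gap_open + gap_extend),
                     E[i, j - 1L] - gap_extend)
      F_[i, j] <- max(H[i - 1L, j] - (gap_open + gap_extend),
                      F_[i - 1L, j] - gap_extend)
      H[i, j] <- max(0,
                     H[i - 1L, j - 1L] + mat[q[i - 1L], s[j - 1L]],
                     E[i, j], F_[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

blosum62 <- local({
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  get("BLOSUM62", envir = env)
})

random_protein <- function(L, freqs = NULL) {
  paste(sample(aa_alphabet(), L, replace = TRUE, prob = freqs),
        collapse = "")
}

canonical_match_frame <- function(x) {
  x <- x[order(x$sequence_id, x$start, x$motif_id), , drop = FALSE]
  rownames(x) <- NULL
  x
}

mog21 <- "MEVGWYRSPFSRVVHLYRNGK"
p3_21 <- "TTLSFYRPPFLRVRRPFYIIF"
scrambled21 <- "KGNRYLHVVRSFPSRYWGVEM"
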