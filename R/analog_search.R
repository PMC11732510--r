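# Local-alignment search of the query epitope against a protein collection.
# Plays the role of a BLASTp pass: Smith-Waterman scores under BLOSUM62 with
# affine gaps, converted to e-values with Karlin-Altschul statistics.

#' Construct an epitope query with its MHC/TCR footprint
#'
#' The footprint maps 0-based offsets within the epitope to required
#' residues: the MHC-anchor tyrosine plus the TCR-contact residues whose
#' conservation at fixed spacing defines a mimic.
#'
#' @param name epitope label.
#' @param sequence amino-acid string.
#' @param footprint named character vector; names are 0-based offsets,
#'   values single residues. Must agree with \code{sequence}.
#' @param mhc_anchor_offset offset of the MHC-anchor residue (must be a
#'   footprint position).
#' @return An object of class \code{epitope_query}.
#' @export
epitope_query <- function(name, sequence, footprint, mhc_anchor_offset) {
  sequence <- toupper(sequence)
  off <- as.integer(names(footprint))
  if (is.unsorted(off, strictly = TRUE)) {
    stop("footprint offsets must be strictly increasing")
  }
  if (any(off < 0L | off >= nchar(sequence))) {
    stop("footprint offsets outside the epitope")
  }
  got <- substring(sequence, off + 1L, off + 1L)
  if (!all(got == unname(footprint))) {
    stop("epitope sequence disagrees with footprint at offset(s): ",
         paste(off[got != unname(footprint)], collapse = ", "))
  }
  if (!mhc_anchor_offset %in% off) {
    stop("mhc_anchor_offset must be one of the footprint offsets")
  }
  structure(list(name = name, sequence = sequence,
                 footprint = footprint,
                 mhc_anchor_offset = as.integer(mhc_anchor_offset)),
            class = "epitope_query")
}

#' @export
print.epitope_query <- function(x, ...) {
  cat("Epitope query:", x$name, "\n  ", x$sequence, "\n  footprint:",
      paste0(unname(x$footprint), "@", names(x$footprint), collapse = " "),
      "(MHC anchor @", x$mhc_anchor_offset, ")\n")
  invisible(x)
}

#' The MOG 35-55 epitope query
#'
#' Mouse MOG 35-55 (MEVGWYRSPFSRVVHLYRNGK) or its human variant (proline at
#' position 42), with the annotated footprint: tyrosine 40 as the dominant
#' MHC II anchor and R41, F44, R46, V47 as the major TCR contacts —
#' 0-based epitope offsets 5, 6, 9, 11, 12.
#'
#' @param variant \code{"mouse"} or \code{"human"}.
#' @return An \code{\link{epitope_query}}.
#' @export
mog_epitope <- function(variant = c("mouse", "human")) {
  variant <- match.arg(variant)
  seqs <- c(mouse = "MEVGWYRSPFSRVVHLYRNGK",
            human = "MEVGWYRPPFSRVVHLYRNGK")
  epitope_query(name = paste0(variant, "_MOG35-55"),
                sequence = seqs[[variant]],
                footprint = c(`5` = "Y", `6` = "R", `9` = "F",
                              `11` = "R", `12` = "V"),
                mhc_anchor_offset = 5L)
}

#' Smith-Waterman local alignment of two protein sequences
#'
#' Maximal local alignment under a substitution matrix with affine gap
#' penalties (a gap of length L costs \code{gap_open + L * gap_extend},
#' the BLAST convention). Scores are floored at zero: when no residue pair
#' scores positively the result is score 0 with empty spans.
#'
#' @param query,subject amino-acid strings.
#' @param matrix substitution matrix name (a matrix shipped with
#'   Biostrings, e.g. \code{"BLOSUM62"}).
#' @param gap_open,gap_extend affine gap parameters.
#' @return list with \code{score} and 0-based half-open \code{query_span}
#'   and \code{subject_span} (integer length-2 vectors).
#' @export
local_align <- function(query, subject, matrix = "BLOSUM62",
                        gap_open = 11, gap_extend = 1) {
  stopifnot(nzchar(query), nzchar(subject))
  mat <- get_substitution_matrix(matrix)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(subject), Biostrings::AAString(query),
    substitutionMatrix = mat, gapOpening = gap_open,
    gapExtension = gap_extend, type = "local")
  s <- Biostrings::score(pa)
  if (s <= 0) {
    return(list(score = 0, query_span = c(0L, 0L), subject_span = c(0L, 0L)))
  }
  sr <- pa@pattern@range   # subject was the pattern
  qr <- pa@subject@range
  list(score = s,
       query_span = c(BiocGenerics::start(qr) - 1L, BiocGenerics::end(qr)),
       subject_span = c(BiocGenerics::start(sr) - 1L, BiocGenerics::end(sr)))
}

get_substitution_matrix <- function(name) {
  env <- new.env()
  ok <- tryCatch({
    utils::data(list = name, package = "Biostrings", envir = env)
    TRUE
  }, warning = function(w) FALSE, error = function(e) FALSE)
  if (!ok || !exists(name, envir = env)) {
    stop("unknown substitution matrix: ", name)
  }
  get(name, envir = env)
}

#' Karlin-Altschul e-value from a raw local-alignment score
#'
#' E = K * m * n * exp(-lambda * S), the expected number of alignments with
#' score at least S between a query of length m and a database of n
#' residues.
#'
#' @param score raw alignment score.
#' @param m query length (residues).
#' @param n database length (total residues searched).
#' @param K,lam Karlin-Altschul parameters; must be positive.
#' @return The e-value.
#' @export
evalue_from_score <- function(score, m, n, K = 0.041, lam = 0.267) {
  if (K <= 0 || lam <= 0) stop("K and lam must be positive")
  stopifnot(m >= 1, n >= 1)
  K * m * n * exp(-lam * score)
}

#' Search a proteome for epitope analogs
#'
#' Aligns the epitope locally against every subject, converts the best
#' per-subject score to an e-value with the database length set to the
#' total residue count of the proteome, and retains subjects at or below
#' the threshold. One hit is reported per subject (the best-scoring local
#' alignment); the matched subject subsequence is carried for downstream
#' motif scanning.
#'
#' @param query an \code{\link{epitope_query}}.
#' @param proteome data.frame of protein records
#'   (\code{\link{read_fasta}}).
#' @param evalue_threshold inclusive e-value cutoff (the screen used
#'   0.001).
#' @param matrix,gap_open,gap_extend alignment parameters.
#' @param K,lam Karlin-Altschul parameters.
#' @return data.frame of analog hits: subject_id, score, bitscore, evalue,
#'   s_start0, s_end0 (0-based half-open), subject_subsequence.
#' @export
search_analogs <- function(query, proteome, evalue_threshold = 1e-3,
                           matrix = "BLOSUM62", gap_open = 11,
                           gap_extend = 1, K = 0.041, lam = 0.267) {
  empty <- data.frame(subject_id = character(), score = numeric(),
                      bitscore = numeric(), evalue = numeric(),
                      s_start0 = integer(), s_end0 = integer(),
                      subject_subsequence = character(),
                      stringsAsFactors = FALSE)
  if (nrow(proteome) == 0L) {
    warning("empty proteome; no analog hits")
    return(empty)
  }
  mat <- get_substitution_matrix(matrix)
  n_db <- sum(nchar(proteome$sequence))
  m <- nchar(query$sequence)
  subjects <- Biostrings::AAStringSet(proteome$sequence)
  names(subjects) <- proteome$id
  pa <- Biostrings::pairwiseAlignment(
    subjects, Biostrings::AAString(query$sequence),
    substitutionMatrix = mat, gapOpening = gap_open,
    gapExtension = gap_extend, type = "local")
  sc <- Biostrings::score(pa)
  ev <- evalue_from_score(pmax(sc, 0), m, n_db, K, lam)
  # bit score under the same statistics
  bits <- (lam * pmax(sc, 0) - log(K)) / log(2)
  keep <- which(sc > 0 & ev <= evalue_threshold)
  if (length(keep) == 0L) return(empty)
  sr <- pa@pattern@range[keep]
  st0 <- BiocGenerics::start(sr) - 1L
  en0 <- BiocGenerics::end(sr)
  out <- data.frame(
    subject_id = proteome$id[keep],
    score = sc[keep], bitscore = round(bits[keep], 1), evalue = ev[keep],
    s_start0 = st0, s_end0 = en0,
    subject_subsequence = substring(proteome$sequence[keep], st0 + 1L, en0),
    stringsAsFactors = FALSE)
  out[order(out$evalue, out$subject_id), , drop = FALSE]
}

#' Export analog hits in the 12-column tabular dialect
#'
#' Produces rows interchangeable with externally computed alignment hits,
#' so the downstream stages accept either source.
#'
#' @param hits result of \code{\link{search_analogs}}.
#' @param query the \code{\link{epitope_query}} searched.
#' @param proteome the searched proteome (for identity bookkeeping).
#' @return data.frame in the dialect of
#'   \code{\link{ingest_alignment_hits}}.
#' @export
analog_hits_as_table <- function(hits, query, proteome) {
  if (nrow(hits) == 0L) {
    out <- stats::setNames(
      data.frame(matrix(nrow = 0, ncol = 12)), alignment_hit_columns())
    return(out)
  }
  qlen <- nchar(query$sequence)
  alen <- hits$s_end0 - hits$s_start0
  qseq <- query$sequence
  ident <- mapply(function(sub_seq, n) {
    k <- min(nchar(sub_seq), qlen)
    mean(strsplit(substr(sub_seq, 1, k), "")[[1]] ==
           strsplit(substr(qseq, 1, k), "")[[1]]) * 100
  }, hits$subject_subsequence, alen)
  data.frame(query_id = query$name, subject_id = hits$subject_id,
             pct_identity = round(ident, 2), aln_len = alen,
             mismatches = NA_integer_, gap_opens = NA_integer_,
             q_start = 1L, q_end = qlen,
             s_start = hits$s_start0 + 1L, s_end = hits$s_end0,
             evalue = hits$evalue, bitscore = hits$bitscore,
             stringsAsFactors = FALSE)
}
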