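# The discriminating stage of the screen: compile degenerate fixed-spacing
# motifs from the epitope footprint, scan sequences, truncate ~21-residue
# ligand windows around each match, collapse to nonredundant ligands, and
# chop ligands into 11-mer windows carrying 9-mer binding cores.

#' Compile the footprint motif set from an epitope
#'
#' The footprint residues, re-indexed relative to the MHC anchor, give a
#' 9-position degenerate pattern: Y at core offset 0 (the anchor), with
#' TCR contacts R, F, R, V at offsets 1, 4, 6, 7 for the MOG epitope. The
#' default set contains the full pattern plus the four variants that relax
#' exactly one TCR contact; the anchor is never relaxed. This yields the
#' pattern family YR..F.RV., YR..F.R.., YR..F..V., YR....RV. and
#' Y...F.RV. in display form.
#'
#' @param epitope an \code{\link{epitope_query}}.
#' @return list of motifs (class \code{footprint_motif_set}); each motif
#'   has \code{motif_id}, \code{required} (named residue vector, names are
#'   0-based core offsets), \code{length} and \code{pattern}.
#' @export
build_motifs <- function(epitope) {
  stopifnot(inherits(epitope, "epitope_query"))
  off <- as.integer(names(epitope$footprint))
  anchor <- epitope$mhc_anchor_offset
  if (!anchor %in% off) stop("footprint is missing the MHC anchor")
  core_off <- off - anchor
  if (any(core_off < 0L)) stop("MHC anchor must be the first footprint residue")
  res <- unname(epitope$footprint)
  motif_len <- 9L
  if (any(core_off >= motif_len)) stop("footprint spans more than 9 positions")
  required_full <- stats::setNames(res, core_off)
  relaxable <- core_off[core_off != 0L]
  make <- function(required, id) {
    structure(list(motif_id = id, length = motif_len,
                   required = required,
                   pattern = motif_pattern(required, motif_len)),
              class = "footprint_motif")
  }
  motifs <- c(
    list(make(required_full, "full")),
    lapply(relaxable, function(drop_off) {
      keep <- required_full[names(required_full) != as.character(drop_off)]
      id <- paste0("relax_", required_full[[as.character(drop_off)]], drop_off)
      make(keep, id)
    }))
  names(motifs) <- vapply(motifs, `[[`, character(1), "motif_id")
  structure(motifs, class = "footprint_motif_set")
}

motif_pattern <- function(required, len) {
  p <- rep(".", len)
  p[as.integer(names(required)) + 1L] <- unname(required)
  paste(p, collapse = "")
}

#' @export
print.footprint_motif_set <- function(x, ...) {
  cat("Footprint motif set (", length(x), " motifs):\n", sep = "")
  for (m in x) cat(sprintf("  %-10s [%s]\n", m$motif_id, m$pattern))
  invisible(x)
}

#' Scan sequences for footprint motif matches
#'
#' Every (offset, motif) pair where all required residues match exactly is
#' reported; a 9-mer satisfying several motifs yields one row per motif.
#' Overlapping matches are found. X never satisfies a required position
#' (required positions are exact-residue tests); wildcard positions accept
#' any alphabet letter including X.
#'
#' @param sequences named character vector of sequences, or a protein
#'   record data.frame with \code{id} and \code{sequence}.
#' @param motifs a \code{footprint_motif_set} from
#'   \code{\link{build_motifs}}.
#' @return data.frame with \code{sequence_id}, \code{motif_id},
#'   \code{start} (0-based offset of the motif anchor) and
#'   \code{matched_9mer}.
#' @export
scan_motifs <- function(sequences, motifs) {
  if (is.data.frame(sequences)) {
    sequences <- stats::setNames(sequences$sequence, sequences$id)
  }
  if (is.null(names(sequences))) {
    names(sequences) <- paste0("seq", seq_along(sequences))
  }
  out <- vector("list", length(motifs))
  for (k in seq_along(motifs)) {
    m <- motifs[[k]]
    rx <- motif_regex(m)
    hits <- gregexpr(rx, sequences, perl = TRUE)
    rows <- lapply(seq_along(sequences), function(i) {
      st <- hits[[i]]
      if (st[1] == -1L) return(NULL)
      data.frame(sequence_id = names(sequences)[i], motif_id = m$motif_id,
                 start = as.integer(st) - 1L,
                 matched_9mer = substring(sequences[[i]], st, st + m$length - 1L),
                 stringsAsFactors = FALSE)
    })
    out[[k]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(sequence_id = character(), motif_id = character(),
                      start = integer(), matched_9mer = character(),
                      stringsAsFactors = FALSE)
  }
  res <- res[order(res$sequence_id, res$start, res$motif_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Build the lookahead regex: required positions are literal residues,
# wildcards any canonical letter or X.
motif_regex <- function(m) {
  chars <- strsplit(m$pattern, "")[[1]]
  body <- vapply(chars, function(ch) {
    if (ch == ".") paste0("[", paste(aa_alphabet(TRUE), collapse = ""), "]")
    else ch
  }, character(1))
  paste0("(?=", paste(body, collapse = ""), ")")
}

#' Truncate a ligand window around a motif match
#'
#' Extracts the ~21-residue region containing the binding pattern: the
#' window starts five residues upstream of the motif anchor (clamped at
#' the protein's N-terminus) and extends to 21 residues (clipped at the
#' C-terminus). With five upstream residues available the anchor sits at
#' window index 5, reproducing the register of the printed MOG and P3
#' peptides.
#'
#' @param matches data.frame from \code{\link{scan_motifs}}.
#' @param proteins protein record data.frame (\code{id}, \code{sequence},
#'   optionally \code{source_genome}).
#' @param window_len window length (default 21).
#' @param anchor_offset target index of the motif anchor in the window
#'   (default 5).
#' @return data.frame of ligand windows: \code{sequence},
#'   \code{parent_id}, \code{parent_start} (0-based), \code{motif_id},
#'   \code{anchor_index}, \code{genome_id}.
#' @export
truncate_windows <- function(matches, proteins, window_len = 21L,
                             anchor_offset = 5L) {
  idx <- match(matches$sequence_id, proteins$id)
  if (anyNA(idx)) {
    stop("match sequence_id not found in proteins: ",
         paste(unique(matches$sequence_id[is.na(idx)]), collapse = ", "))
  }
  parent_seq <- proteins$sequence[idx]
  plen <- nchar(parent_seq)
  w_start <- pmax(0L, matches$start - anchor_offset)
  w_end <- pmin(plen, w_start + window_len)     # 0-based half-open
  genome <- if ("source_genome" %in% names(proteins)) {
    proteins$source_genome[idx]
  } else NA_character_
  data.frame(
    sequence = substring(parent_seq, w_start + 1L, w_end),
    parent_id = matches$sequence_id,
    parent_start = w_start,
    motif_id = matches$motif_id,
    anchor_index = matches$start - w_start,
    genome_id = genome,
    stringsAsFactors = FALSE)
}

#' Collapse ligand windows to a nonredundant set
#'
#' One representative per distinct window sequence, by global
#' case-sensitive string identity across the whole corpus; the
#' representative is the first window encountered in input order.
#' Multiplicity and the source parent/genome/motif lists are retained.
#' Idempotent: deduplicating a deduplicated set changes nothing.
#'
#' @param windows data.frame from \code{\link{truncate_windows}}.
#' @return data.frame of nonredundant ligands with \code{ligand_id},
#'   \code{sequence}, \code{n_sources}, semicolon-joined \code{parent_ids},
#'   \code{genome_ids}, \code{motif_ids}, and the representative's
#'   \code{parent_id}, \code{parent_start}, \code{motif_id},
#'   \code{anchor_index}, \code{genome_id}.
#' @export
dedup_ligands <- function(windows) {
  if (nrow(windows) == 0L) {
    return(data.frame(ligand_id = character(), sequence = character(),
                      n_sources = integer(), parent_ids = character(),
                      genome_ids = character(), motif_ids = character(),
                      parent_id = character(), parent_start = integer(),
                      motif_id = character(), anchor_index = integer(),
                      genome_id = character(), stringsAsFactors = FALSE))
  }
  # first-encounter order of distinct sequences
  first <- !duplicated(windows$sequence)
  reps <- windows[first, , drop = FALSE]
  key <- match(windows$sequence, reps$sequence)
  agg <- function(x) vapply(split(x, key), function(v)
    paste(unique(v[!is.na(v)]), collapse = ";"), character(1))
  out <- data.frame(
    ligand_id = sprintf("L%05d", seq_len(nrow(reps))),
    sequence = reps$sequence,
    n_sources = as.integer(tabulate(key, nbins = nrow(reps))),
    parent_ids = unname(agg(windows$parent_id)),
    genome_ids = unname(agg(windows$genome_id)),
    motif_ids = unname(agg(windows$motif_id)),
    parent_id = reps$parent_id, parent_start = reps$parent_start,
    motif_id = reps$motif_id, anchor_index = reps$anchor_index,
    genome_id = reps$genome_id,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Enumerate 11-mer windows with 9-mer binding cores along ligands
#'
#' Each ligand of length L yields the L - 10 consecutive 11-residue
#' windows (stride 1); the central nine residues of a window are the
#' putative MHC II binding core, the outer two its immediate flanks.
#' Duplicate 11-mers within one ligand are collapsed (candidates are
#' unique per ligand); windows containing X are excluded. Candidate ids
#' are derived from the 11-mer itself, so the same peptide carries the
#' same id wherever it occurs — score tables keyed on candidate_id join
#' stably across runs.
#'
#' @param ligands data.frame with \code{ligand_id} and \code{sequence}
#'   (from \code{\link{dedup_ligands}}).
#' @return data.frame of core candidates: \code{candidate_id},
#'   \code{ligand_id}, \code{start_in_ligand} (0-based), \code{window11},
#'   \code{core9}.
#' @export
enumerate_cores <- function(ligands) {
  empty <- data.frame(candidate_id = character(), ligand_id = character(),
                      start_in_ligand = integer(), window11 = character(),
                      core9 = character(), stringsAsFactors = FALSE)
  if (nrow(ligands) == 0L) return(empty)
  short <- nchar(ligands$sequence) < 11L
  if (any(short)) {
    warning(sum(short), " ligand(s) shorter than 11 residues yield no cores")
  }
  rows <- lapply(which(!short), function(i) {
    sq <- ligands$sequence[i]
    L <- nchar(sq)
    st <- 0:(L - 11L)
    w11 <- substring(sq, st + 1L, st + 11L)
    keep <- !duplicated(w11) & !grepl("X", w11, fixed = TRUE)
    st <- st[keep]; w11 <- w11[keep]
    if (!length(st)) return(NULL)
    data.frame(candidate_id = paste0("c_", w11),
               ligand_id = ligands$ligand_id[i],
               start_in_ligand = st, window11 = w11,
               core9 = substring(w11, 2L, 10L),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty)
  rownames(out) <- NULL
  out
}
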