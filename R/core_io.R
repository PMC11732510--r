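# Readers and writers for the external formats the screen touches:
# protein FASTA, GTDB-style taxonomy tables, 12-column tabular alignment
# hits, and the two structure-prediction confidence tables.

#' Canonical amino-acid alphabet
#'
#' The twenty canonical residues, optionally with the ambiguity letter X.
#'
#' @param with_x include the mask character X.
#' @return A character vector of single letters.
#' @export
aa_alphabet <- function(with_x = FALSE) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  if (with_x) c(aa, "X") else aa
}

#' MHC and TCR structural template identifiers
#'
#' Fixed template sets carried as metadata on confidence records: three
#' peptide-MHC II templates and four TCR:pMHC II complex templates.
#'
#' @return Character vector of PDB-style identifiers.
#' @export
mhc_templates <- function() c("4p23", "6mng", "1muj")

#' @rdname mhc_templates
#' @export
tcr_templates <- function() c("3c60", "3rdt", "3c5z", "6mnn")

#' Read a protein FASTA file
#'
#' Sequences are upper-cased and checked against the canonical alphabet
#' (twenty residues plus X). The genome of origin is taken from the header
#' token when it has the form \code{<genome>|<protein>}, which is the
#' convention the synthetic generator writes; otherwise it is NA and can be
#' supplied through a separate mapping.
#'
#' @param path FASTA file.
#' @param on_invalid \code{"error"} rejects sequences containing letters
#'   outside the alphabet, naming them; \code{"mask"} replaces such letters
#'   with X (windows containing X are excluded from core enumeration
#'   downstream).
#' @return data.frame with columns \code{id}, \code{sequence},
#'   \code{source_genome}.
#' @export
read_fasta <- function(path, on_invalid = c("error", "mask")) {
  on_invalid <- match.arg(on_invalid)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) == 0L) {
    warning("empty FASTA file: ", path)
    return(data.frame(id = character(), sequence = character(),
                      source_genome = character(), stringsAsFactors = FALSE))
  }
  if (!startsWith(trimws(lines[nonempty[1]]), ">")) {
    stop("malformed FASTA: line ", nonempty[1], " is not a header line")
  }
  # validate residue letters on the raw text: the parser silently drops
  # unknown one-letter codes, which would mask corrupt inputs
  seq_lines <- !startsWith(trimws(lines), ">")
  raw <- toupper(gsub("\\s", "", paste(lines[seq_lines], collapse = "")))
  bad_chars <- setdiff(strsplit(raw, "")[[1]], aa_alphabet(TRUE))
  src <- path
  if (length(bad_chars)) {
    if (on_invalid == "error") {
      stop("invalid residue letters in ", path, ": ",
           paste(sort(bad_chars), collapse = ", "))
    }
    rx <- paste0("[^>", paste(aa_alphabet(TRUE), collapse = ""), "]")
    lines[seq_lines] <- gsub(rx, "X", toupper(lines[seq_lines]))
    src <- tempfile(fileext = ".fasta")
    on.exit(unlink(src), add = TRUE)
    writeLines(lines, src)
  }
  seqs <- Biostrings::readAAStringSet(src)
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  sq <- toupper(as.character(seqs))
  if (any(!nzchar(sq))) stop("empty sequence for id: ",
                             paste(ids[!nzchar(sq)], collapse = ", "))
  data.frame(id = ids, sequence = unname(sq),
             source_genome = ifelse(grepl("|", ids, fixed = TRUE),
                                    sub("\\|.*$", "", ids), NA_character_),
             stringsAsFactors = FALSE)
}

#' Write protein records to FASTA
#'
#' @param records data.frame with \code{id} and \code{sequence} columns.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(is.data.frame(records), all(c("id", "sequence") %in% names(records)))
  x <- Biostrings::AAStringSet(records$sequence)
  names(x) <- records$id
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

#' Parse the phylum rank from a GTDB lineage string
#'
#' @param lineage semicolon-delimited GTDB rank string
#'   (\code{d__...;p__...;...}).
#' @return Phylum name, or \code{"UNCLASSIFIED"} when the p__ rank is absent
#'   or empty.
#' @export
parse_phylum <- function(lineage) {
  m <- regmatches(lineage, regexpr("p__[^;]*", lineage))
  out <- rep("UNCLASSIFIED", length(lineage))
  hit <- grepl("p__[^;]*", lineage)
  val <- trimws(sub("^p__", "", m))
  out[hit] <- ifelse(nzchar(val), val, "UNCLASSIFIED")
  out
}

#' Read a genome taxonomy table
#'
#' A TSV with columns \code{genome_id} and \code{lineage}; the phylum is
#' parsed from the \code{p__} token of the lineage.
#'
#' @param path TSV file.
#' @return data.frame with \code{genome_id}, \code{lineage}, \code{phylum}.
#' @export
read_taxonomy_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("genome_id", "lineage")
  if (!all(need %in% names(tab))) {
    stop("taxonomy table must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(tab$genome_id)) {
    stop("duplicate genome_id in taxonomy table: ",
         paste(unique(tab$genome_id[duplicated(tab$genome_id)]), collapse = ", "))
  }
  tab$phylum <- parse_phylum(tab$lineage)
  tab[, c("genome_id", "lineage", "phylum")]
}

#' Column names of the 12-column tabular alignment dialect
#' @keywords internal
alignment_hit_columns <- function() {
  c("query_id", "subject_id", "pct_identity", "aln_len", "mismatches",
    "gap_opens", "q_start", "q_end", "s_start", "s_end", "evalue", "bitscore")
}

#' Ingest tabular alignment hits
#'
#' Reads the 12-column tab-separated alignment dialect (BLAST outfmt-6
#' style), retains rows at or below the e-value threshold, and normalizes
#' subject coordinates: 1-based inclusive columns are kept as read, and
#' 0-based half-open \code{s_start0}/\code{s_end0} are added for internal
#' use (reversed subject coordinates are swapped first).
#'
#' @param path tabular hits file (no header).
#' @param evalue_threshold inclusive e-value cutoff; rows above it are
#'   dropped and the dropped count reported.
#' @return data.frame of retained hits.
#' @export
ingest_alignment_hits <- function(path, evalue_threshold = 1e-3) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) != 12L) {
    stop("expected 12 tab-separated columns, found ", ncol(tab))
  }
  names(tab) <- alignment_hit_columns()
  ev <- suppressWarnings(as.numeric(tab$evalue))
  if (anyNA(ev)) {
    stop("non-numeric evalue at row(s): ",
         paste(which(is.na(ev)), collapse = ", "))
  }
  tab$evalue <- ev
  if (any(ev < 0)) stop("negative evalue at row(s): ",
                        paste(which(ev < 0), collapse = ", "))
  rev_rows <- tab$s_start > tab$s_end
  if (any(rev_rows)) {
    tmp <- tab$s_start[rev_rows]
    tab$s_start[rev_rows] <- tab$s_end[rev_rows]
    tab$s_end[rev_rows] <- tmp
  }
  keep <- tab$evalue <= evalue_threshold
  if (any(!keep)) {
    message(sum(!keep), " hit(s) dropped above e-value threshold ",
            format(evalue_threshold))
  }
  out <- tab[keep, , drop = FALSE]
  out$s_start0 <- out$s_start - 1L
  out$s_end0 <- out$s_end
  rownames(out) <- NULL
  out
}

#' Write alignment hits in the tabular dialect read by
#' \code{\link{ingest_alignment_hits}}
#'
#' @param hits data.frame with the 12 dialect columns.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_alignment_hits <- function(hits, path) {
  cols <- alignment_hit_columns()
  stopifnot(all(cols %in% names(hits)))
  utils::write.table(hits[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

validate_confidence_records <- function(tab) {
  need <- c("candidate_id", "mhc_template", "peptide_plddt", "inter_pae")
  if (!all(need %in% names(tab))) {
    stop("MHC score table must have columns: ", paste(need, collapse = ", "))
  }
  if (any(tab$peptide_plddt < 0 | tab$peptide_plddt > 100)) {
    stop("peptide_plddt outside [0,100] for candidate(s): ",
         paste(tab$candidate_id[tab$peptide_plddt < 0 | tab$peptide_plddt > 100],
               collapse = ", "))
  }
  if (any(tab$inter_pae < 0)) stop("negative inter_pae")
  tab
}

validate_tcrdock_records <- function(tab) {
  need <- c("candidate_id", "tcr_template", "run_index", "pae_tcr_pmhc",
            "peptide_plddt")
  if (!all(need %in% names(tab))) {
    stop("TCR score table must have columns: ", paste(need, collapse = ", "))
  }
  bad <- setdiff(unique(tab$tcr_template), tcr_templates())
  if (length(bad)) {
    stop("unknown tcr_template value(s): ", paste(bad, collapse = ", "),
         " (expected ", paste(tcr_templates(), collapse = "/"), ")")
  }
  if (!all(tab$run_index %in% 1:3)) stop("run_index must be in {1,2,3}")
  if (any(tab$peptide_plddt < 0 | tab$peptide_plddt > 100)) {
    stop("peptide_plddt outside [0,100]")
  }
  if (any(tab$pae_tcr_pmhc < 0)) stop("negative pae_tcr_pmhc")
  n_runs <- stats::aggregate(run_index ~ candidate_id + tcr_template,
                             tab, length)
  incomplete <- n_runs[n_runs$run_index != 3L, , drop = FALSE]
  if (nrow(incomplete)) {
    warning(nrow(incomplete), " (candidate, template) set(s) without ",
            "exactly 3 runs; flagged incomplete")
    attr(tab, "incomplete") <- incomplete[, c("candidate_id", "tcr_template")]
  }
  tab
}

#' Read the two structure-prediction confidence tables
#'
#' The peptide-MHC II table carries one scalar pair per candidate and MHC
#' template (mean peptide pLDDT and mean inter-chain lowest PAE); the
#' TCR-docking table carries three runs per candidate and TCR template.
#' Record invariants are enforced on read; (candidate, template) groups
#' without exactly three runs are flagged via an \code{"incomplete"}
#' attribute and a warning.
#'
#' @param path_mhc TSV with columns candidate_id, mhc_template,
#'   peptide_plddt, inter_pae.
#' @param path_tcr TSV with columns candidate_id, tcr_template, run_index,
#'   pae_tcr_pmhc, peptide_plddt.
#' @return list with elements \code{mhc} and \code{tcr}.
#' @export
read_score_tables <- function(path_mhc, path_tcr) {
  mhc <- utils::read.delim(path_mhc, stringsAsFactors = FALSE)
  tcr <- utils::read.delim(path_tcr, stringsAsFactors = FALSE)
  list(mhc = validate_confidence_records(mhc),
       tcr = validate_tcrdock_records(tcr))
}

#' Write a data.frame as TSV (column names, no quoting)
#' @keywords internal
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
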