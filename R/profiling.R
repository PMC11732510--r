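# Downstream profiling: per-genome-normalized taxonomic distribution of
# motif analogs, position-frequency matrices over the 11-mer binder
# windows, start-residue logo grouping, and the four-criterion candidate
# prioritization.

#' Phylum-level motif analog profile, normalized per genome
#'
#' Counts motif matches per (phylum, motif) and normalizes by the number
#' of genomes the taxonomy table assigns to that phylum (all genomes, not
#' only motif-bearing ones). Phyla represented by fewer than
#' \code{min_genomes} genomes, and unclassified genomes/contigs, are
#' pooled into "Others" before rates are computed; pooling sums both
#' analog and genome counts, so totals are conserved.
#'
#' @param matches motif matches carrying a \code{genome_id} column (e.g.
#'   ligand windows or \code{\link{scan_motifs}} output joined to
#'   genomes); needs \code{motif_id} and \code{genome_id}.
#' @param taxonomy data.frame from \code{\link{read_taxonomy_table}}.
#' @param min_genomes minimum genomes for a phylum to stand alone
#'   (default 10).
#' @return data.frame with phylum, motif_id, analog_count, genome_count,
#'   rate (analogs per genome).
#' @export
phylum_profile <- function(matches, taxonomy, min_genomes = 10L) {
  stopifnot(all(c("motif_id", "genome_id") %in% names(matches)))
  phy_of <- stats::setNames(taxonomy$phylum, taxonomy$genome_id)
  phylum <- unname(phy_of[matches$genome_id])
  phylum[is.na(phylum)] <- "UNCLASSIFIED"

  genome_counts <- table(taxonomy$phylum)
  small <- names(genome_counts)[genome_counts < min_genomes]
  pool <- function(p) ifelse(p %in% small | p == "UNCLASSIFIED", "Others", p)

  phylum <- pool(phylum)
  tax_phy <- pool(taxonomy$phylum)
  genome_by_pooled <- table(tax_phy)

  motif_ids <- sort(unique(matches$motif_id))
  phyla <- sort(unique(c(phylum, names(genome_by_pooled))))
  counts <- table(factor(phylum, levels = phyla),
                  factor(matches$motif_id, levels = motif_ids))
  out <- as.data.frame(counts, stringsAsFactors = FALSE)
  names(out) <- c("phylum", "motif_id", "analog_count")
  out$genome_count <- as.integer(genome_by_pooled[out$phylum])
  out$genome_count[is.na(out$genome_count)] <- 0L
  out$rate <- ifelse(out$genome_count > 0,
                     out$analog_count / out$genome_count, 0)
  out <- out[order(out$phylum, out$motif_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Position frequency matrix over 11-mer binder windows
#'
#' Empirical residue frequencies at each window position. Columns are
#' labeled loc_0 to loc_10 (0-indexed): loc_1 to loc_9 are the binding
#' core seated in the MHC II groove, loc_0 and loc_10 the flanking
#' residues outside it. Every column sums to one.
#'
#' @param window11 character vector of 11-mer windows (e.g.
#'   \code{window11} of binder candidates).
#' @return 20 x 11 numeric matrix (rows the canonical residues, columns
#'   loc_0..loc_10) with attribute \code{n_sequences}.
#' @export
position_frequency_matrix <- function(window11) {
  if (length(window11) == 0L) stop("no windows; cannot build a matrix")
  if (any(nchar(window11) != 11L)) stop("all windows must be 11-mers")
  if (any(grepl("X", window11, fixed = TRUE))) {
    stop("windows containing X are not admissible in the frequency matrix")
  }
  aa <- aa_alphabet()
  mat <- vapply(1:11, function(j) {
    col <- substring(window11, j, j)
    as.vector(table(factor(col, levels = aa))) / length(window11)
  }, numeric(20))
  dimnames(mat) <- list(aa, paste0("loc_", 0:10))
  attr(mat, "n_sequences") <- length(window11)
  mat
}

#' Group binder windows by core start residue
#'
#' Partitions 11-mer windows by the residue at loc_1 (the first position
#' of the 9-mer binding core) and builds one position frequency matrix
#' per group — the per-start-residue sequence logos. Groups cover the
#' input exactly once, and their size-weighted average equals the global
#' matrix.
#'
#' @param window11 character vector of 11-mer windows.
#' @return named list of matrices from
#'   \code{\link{position_frequency_matrix}}, names the start residues.
#' @export
group_logos_by_start <- function(window11) {
  if (length(window11) == 0L) return(stats::setNames(list(), character()))
  start_res <- substring(window11, 2L, 2L)
  groups <- split(window11, start_res)
  lapply(groups, position_frequency_matrix)
}

#' Prioritize ligands by the four selection criteria
#'
#' Scores each nonredundant ligand on the four binary criteria used to
#' shortlist peptides for synthesis: (1) the ligand contains the full
#' canonical motif (all five footprint residues; relaxed variants do not
#' qualify); (2) the ligand was detected in the metagenome cohort; (3)
#' the ligand's source taxon is among the disease-associated species; (4)
#' the ligand carries a binder core starting with a noncanonical F or L.
#'
#' @param ligands nonredundant ligand data.frame
#'   (\code{\link{dedup_ligands}}); \code{motif_ids} and
#'   \code{genome_ids} are consulted.
#' @param binder_cores data.frame mapping ligands to binder cores:
#'   columns \code{ligand_id} and \code{core9} (binder candidates only).
#' @param cohort_ids character vector of ligand sequences (or ids)
#'   detected in the metagenome cohort.
#' @param flagged_species character vector of disease-associated taxa;
#'   matched against the taxa in \code{species_of} when supplied,
#'   otherwise against \code{genome_ids}.
#' @param species_of optional named vector genome_id -> species label.
#' @param noncanonical_starts residues defining criterion 4 (default F
#'   and L).
#' @return data.frame with the four flags and \code{n_criteria}, sorted
#'   by descending n_criteria then ligand_id.
#' @export
prioritize <- function(ligands, binder_cores, cohort_ids = character(),
                       flagged_species = character(), species_of = NULL,
                       noncanonical_starts = c("F", "L")) {
  if (length(cohort_ids) == 0L) {
    warning("empty cohort set; cohort criterion false for all ligands")
  }
  if (length(flagged_species) == 0L) {
    warning("empty flagged-species set; species criterion false for all ligands")
  }
  motif_lists <- strsplit(ligands$motif_ids, ";", fixed = TRUE)
  has_full <- vapply(motif_lists, function(m) "full" %in% m, logical(1))
  in_cohort <- ligands$sequence %in% cohort_ids |
    ligands$ligand_id %in% cohort_ids
  genome_lists <- strsplit(ligands$genome_ids, ";", fixed = TRUE)
  species_flag <- vapply(genome_lists, function(g) {
    taxa <- if (is.null(species_of)) g else unname(species_of[g])
    any(taxa %in% flagged_species, na.rm = TRUE)
  }, logical(1))
  starts <- split(substring(binder_cores$core9, 1L, 1L),
                  binder_cores$ligand_id)
  noncanon <- vapply(ligands$ligand_id, function(id) {
    any(starts[[id]] %in% noncanonical_starts)
  }, logical(1))
  out <- data.frame(
    ligand_id = ligands$ligand_id, sequence = ligands$sequence,
    has_canonical_motif = has_full, in_metagenome_cohort = in_cohort,
    species_flagged = species_flag, noncanonical_start = unname(noncanon),
    stringsAsFactors = FALSE)
  out$n_criteria <- rowSums(out[, c("has_canonical_motif",
                                    "in_metagenome_cohort",
                                    "species_flagged",
                                    "noncanonical_start")])
  out <- out[order(-out$n_criteria, out$ligand_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
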