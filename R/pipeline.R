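# End-to-end orchestration of the screen: analog search (optional),
# motif filtering, window truncation, dedup, core enumeration, binder
# triage, profiling and prioritization, with every stage's table
# materialized and a run manifest summarizing the funnel.

#' Default run configuration
#'
#' Returns the configuration list \code{\link{run_pipeline}} consumes,
#' with the screen's default thresholds (e-value 0.001, pLDDT >= 90,
#' inter-PAE <= 4.34, confidence pLDDT >= 70) and a small synthetic
#' corpus. Any YAML file with the same structure can be used instead.
#'
#' @param output_dir where stage tables are written.
#' @param seed master seed for the synthetic generators.
#' @return Nested configuration list.
#' @export
default_config <- function(output_dir = tempfile("mimicrun"), seed = 1L) {
  list(
    epitope = list(variant = "mouse"),
    inputs = list(fasta = NULL, taxonomy = NULL,
                  mhc_scores = NULL, tcr_scores = NULL),
    synthetic = list(
      enabled = TRUE,
      phylum_spec = c(Verrucomicrobiota = 15, Bacteroidota = 30,
                      Firmicutes_A = 40, Actinobacteriota = 12,
                      Proteobacteria = 8, UNCLASSIFIED = 3),
      proteins_per_genome = 20, length_mean = 300, length_sd = 60,
      n_plants = 50, binder_fraction = 0.3, nonconfident_fraction = 0),
    alignment = list(bypass = FALSE, evalue = 1e-3, matrix = "BLOSUM62",
                     gap_open = 11, gap_extend = 1, K = 0.041, lam = 0.267),
    thresholds = list(plddt_min = 90, inter_pae_max = 4.34,
                      confident_plddt_min = 70),
    profiling = list(min_genomes = 10),
    prioritize = list(cohort_ids = character(), flagged_species = character()),
    output = list(dir = output_dir),
    seed = as.integer(seed))
}

read_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  base <- default_config()
  modifyList(base, config)
}

resolve_epitope <- function(spec) {
  if (!is.null(spec$variant)) return(mog_epitope(spec$variant))
  epitope_query(spec$name, spec$sequence,
                stats::setNames(unlist(spec$footprint),
                                names(spec$footprint)),
                spec$mhc_anchor_offset)
}

#' Run the full mimicry screen
#'
#' Executes the stages in order — input acquisition (files or synthetic
#' generation), analog search (or bypass), motif filtering, window
#' truncation, nonredundant collapse, core enumeration, binder triage
#' with best-model selection, phylum profiling, position-frequency
#' matrices, and prioritization — writing every stage's table as TSV
#' under the output directory plus a JSON manifest with per-stage
#' counters.
#'
#' @param config a configuration list (see \code{\link{default_config}})
#'   or the path of a YAML file with the same structure.
#' @return The run manifest (list), invisibly; its \code{counts} element
#'   holds the stage funnel, \code{tables} the in-memory stage tables.
#' @export
run_pipeline <- function(config = default_config()) {
  cfg <- read_config(config)
  dir.create(cfg$output$dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(cfg$output$dir, f)
  log_lines <- character(0)
  note <- function(...) {
    msg <- paste0(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  epitope <- resolve_epitope(cfg$epitope)
  motifs <- build_motifs(epitope)

  # --- inputs ---------------------------------------------------------
  truth <- NULL
  if (isTRUE(cfg$synthetic$enabled)) {
    sy <- cfg$synthetic
    corp <- generate_proteome(
      phylum_spec = unlist(sy$phylum_spec),
      proteins_per_genome = sy$proteins_per_genome,
      length_mean = sy$length_mean, length_sd = sy$length_sd,
      seed = cfg$seed)
    corp <- plant_mimics(corp, motifs, n_plants = sy$n_plants,
                         seed = cfg$seed + 1L)
    proteins <- corp$proteins
    taxonomy <- corp$taxonomy
    truth <- corp$truth
    write_fasta(proteins, out("proteome.faa"))
    write_tsv(taxonomy[, c("genome_id", "lineage")], out("taxonomy.tsv"))
    write_tsv(truth$planted_windows, out("truth_planted.tsv"))
    note("synthetic corpus: ", nrow(taxonomy), " genomes, ",
         nrow(proteins), " proteins, ", nrow(truth$planted_windows),
         " planted windows")
  } else {
    proteins <- read_fasta(cfg$inputs$fasta)
    taxonomy <- read_taxonomy_table(cfg$inputs$taxonomy)
    note("inputs: ", nrow(proteins), " proteins, ", nrow(taxonomy),
         " genomes")
  }

  # --- analog search (optional) --------------------------------------
  if (isTRUE(cfg$alignment$bypass)) {
    scan_set <- proteins
    n_analogs <- nrow(proteins)
    note("alignment bypassed: motif-scanning all ", n_analogs, " proteins")
  } else {
    al <- cfg$alignment
    hits <- search_analogs(epitope, proteins, evalue_threshold = al$evalue,
                           matrix = al$matrix, gap_open = al$gap_open,
                           gap_extend = al$gap_extend, K = al$K,
                           lam = al$lam)
    write_tsv(analog_hits_as_table(hits, epitope, proteins),
              out("analog_hits.tsv"))
    scan_set <- proteins[proteins$id %in% hits$subject_id, , drop = FALSE]
    n_analogs <- nrow(hits)
    note("analog search: ", n_analogs, " subjects at e-value <= ",
         format(al$evalue))
  }

  # --- motif filter and windows --------------------------------------
  matches <- scan_motifs(scan_set, motifs)
  write_tsv(matches, out("motif_matches.tsv"))
  note("motif filter: ", nrow(matches), " matches in ",
       length(unique(matches$sequence_id)), " proteins")
  windows <- truncate_windows(matches, proteins)
  write_tsv(windows, out("ligand_windows.tsv"))
  ligands <- dedup_ligands(windows)
  write_tsv(ligands, out("ligands_nonredundant.tsv"))
  note("windows: ", nrow(windows), " -> ", nrow(ligands), " nonredundant")
  candidates <- enumerate_cores(ligands)
  write_tsv(candidates, out("core_candidates.tsv"))
  note("core candidates: ", nrow(candidates))

  # --- binder triage --------------------------------------------------
  th <- triage_thresholds(cfg$thresholds$plddt_min,
                          cfg$thresholds$inter_pae_max,
                          cfg$thresholds$confident_plddt_min)
  score_truth <- NULL
  if (!is.null(cfg$inputs$mhc_scores)) {
    st <- read_score_tables(cfg$inputs$mhc_scores, cfg$inputs$tcr_scores)
    mhc <- st$mhc; tcr <- st$tcr
    unknown <- setdiff(mhc$candidate_id, candidates$candidate_id)
    if (length(unknown)) {
      warning(length(unknown), " scored candidate(s) not enumerated in ",
              "this run; dropped")
      mhc <- mhc[mhc$candidate_id %in% candidates$candidate_id, ,
                 drop = FALSE]
      tcr <- tcr[tcr$candidate_id %in% candidates$candidate_id, ,
                 drop = FALSE]
    }
  } else {
    st <- generate_score_tables(
      candidates, binder_fraction = cfg$synthetic$binder_fraction,
      nonconfident_fraction = cfg$synthetic$nonconfident_fraction,
      seed = cfg$seed + 2L)
    mhc <- st$mhc; tcr <- st$tcr; score_truth <- st$truth
    write_tsv(mhc, out("mhc_scores.tsv"))
    write_tsv(tcr, out("tcr_scores.tsv"))
  }
  if (nrow(mhc) > 0L) {
    calls <- classify_binders(mhc, th)
    best <- if (nrow(tcr) > 0L) select_best_models(tcr, th) else
      data.frame(candidate_id = character(), tcr_template = character(),
                 chosen_run = integer(), pae_tcr_pmhc = numeric(),
                 peptide_plddt = numeric(), confident = logical())
    mf <- if (any(calls$is_binder) && nrow(best) > 0L) {
      modeled_fraction(calls, best)
    } else NaN
  } else {
    calls <- data.frame(candidate_id = character(),
                        peptide_plddt = numeric(), inter_pae = numeric(),
                        is_binder = logical())
    best <- data.frame()
    mf <- NaN
  }
  write_tsv(calls, out("binder_calls.tsv"))
  write_tsv(best, out("best_models.tsv"))
  n_binders <- sum(calls$is_binder)
  note("triage: ", n_binders, " binders of ", nrow(calls),
       " candidates; modeled fraction ", format(mf, digits = 4))

  # --- profiling ------------------------------------------------------
  profile <- phylum_profile(windows, taxonomy,
                            min_genomes = cfg$profiling$min_genomes)
  write_tsv(profile, out("phylum_profile.tsv"))
  binder_cand <- candidates[candidates$candidate_id %in%
                              calls$candidate_id[calls$is_binder], ,
                            drop = FALSE]
  if (nrow(binder_cand) > 0L) {
    pfm <- position_frequency_matrix(binder_cand$window11)
    write_tsv(cbind(residue = rownames(pfm), as.data.frame(pfm)),
              out("pfm_binders.tsv"))
    logos <- group_logos_by_start(binder_cand$window11)
    logo_summary <- data.frame(
      start_residue = names(logos),
      n_sequences = vapply(logos, attr, integer(1), "n_sequences"))
    write_tsv(logo_summary, out("logo_groups.tsv"))
  } else {
    pfm <- NULL; logos <- list()
    note("no binders; frequency matrices skipped")
  }
  prio <- prioritize(ligands,
                     binder_cores = binder_cand[, c("ligand_id", "core9")],
                     cohort_ids = cfg$prioritize$cohort_ids,
                     flagged_species = cfg$prioritize$flagged_species)
  write_tsv(prio, out("prioritization.tsv"))

  # --- manifest -------------------------------------------------------
  counts <- list(
    n_proteins = nrow(proteins), n_genomes = nrow(taxonomy),
    n_analogs = n_analogs, n_motif_matches = nrow(matches),
    n_windows = nrow(windows), n_ligands_nonredundant = nrow(ligands),
    n_core_candidates = nrow(candidates), n_binders = n_binders,
    modeled_fraction = mf)
  stopifnot(counts$n_ligands_nonredundant <= counts$n_windows,
            counts$n_binders <= counts$n_core_candidates)
  manifest <- list(
    seed = cfg$seed, counts = counts,
    thresholds = cfg$thresholds,
    output_dir = cfg$output$dir,
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest[c("seed", "counts", "thresholds",
                                  "output_dir", "timestamp")],
                       out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  writeLines(log_lines, out("run_log.txt"))
  manifest$tables <- list(
    proteins = proteins, taxonomy = taxonomy, matches = matches,
    windows = windows, ligands = ligands, candidates = candidates,
    mhc = mhc, tcr = tcr, binder_calls = calls, best_models = best,
    profile = profile, pfm = pfm, logos = logos, prioritization = prio)
  manifest$truth <- list(planted = truth, scores = score_truth)
  invisible(manifest)
}
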