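# Synthetic study inputs with known ground truth: background proteomes
# with controlled residue frequencies and taxonomy, planted motif-bearing
# 21-mers at recorded loci, and confidence-score tables whose binder and
# best-run labels straddle the triage thresholds by construction.

seed_rng <- function(seed) {
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
}

#' Generate a synthetic background proteome with taxonomy
#'
#' Proteins are i.i.d. residue strings under the supplied frequency
#' vector (uniform over the twenty canonical residues by default), with
#' lengths drawn from a normal distribution floored at a minimum.
#' Genomes carry well-formed GTDB-style lineages; a phylum named
#' \code{"UNCLASSIFIED"} in the spec produces genomes whose lineage lacks
#' the p__ rank (emulating unclassified contigs). Fully reproducible for
#' a fixed seed.
#'
#' @param phylum_spec named integer vector: genomes per phylum.
#' @param proteins_per_genome proteins generated for each genome.
#' @param length_mean,length_sd protein length distribution (residues);
#'   lengths are floored at 30.
#' @param residue_freqs named 20-vector of residue probabilities summing
#'   to one; NULL for uniform.
#' @param seed integer seed.
#' @return list with \code{proteins} (id, sequence, source_genome),
#'   \code{taxonomy} (genome_id, lineage, phylum) and an empty
#'   \code{truth}.
#' @export
generate_proteome <- function(phylum_spec, proteins_per_genome = 20L,
                              length_mean = 300, length_sd = 60,
                              residue_freqs = NULL, seed = 1L) {
  stopifnot(length(phylum_spec) >= 1L, all(phylum_spec >= 1L),
            proteins_per_genome >= 1L)
  residue_freqs <- check_residue_freqs(residue_freqs)
  seed_rng(seed)
  phyla <- rep(names(phylum_spec), as.integer(phylum_spec))
  n_gen <- length(phyla)
  genome_id <- sprintf("g%04d", seq_len(n_gen))
  lineage <- ifelse(
    phyla == "UNCLASSIFIED",
    "d__Bacteria",
    paste0("d__Bacteria;p__", phyla, ";c__Clostridia;o__Oscillospirales;",
           "f__F", seq_len(n_gen), ";g__G", seq_len(n_gen),
           ";s__G", seq_len(n_gen), " sp", seq_len(n_gen)))
  taxonomy <- data.frame(genome_id = genome_id, lineage = lineage,
                         phylum = parse_phylum(lineage),
                         stringsAsFactors = FALSE)
  aa <- aa_alphabet()
  n_prot <- n_gen * proteins_per_genome
  lens <- pmax(30L, as.integer(round(stats::rnorm(n_prot, length_mean,
                                                  length_sd))))
  seqs <- vapply(lens, function(L)
    paste(sample(aa, L, replace = TRUE, prob = residue_freqs),
          collapse = ""), character(1))
  prot_genome <- rep(genome_id, each = proteins_per_genome)
  proteins <- data.frame(
    id = paste0(prot_genome, "|p",
                sprintf("%03d", rep(seq_len(proteins_per_genome), n_gen))),
    sequence = seqs, source_genome = prot_genome,
    stringsAsFactors = FALSE)
  list(proteins = proteins, taxonomy = taxonomy,
       truth = list(planted_windows = empty_truth_windows(), seed = seed))
}

check_residue_freqs <- function(residue_freqs) {
  aa <- aa_alphabet()
  if (is.null(residue_freqs)) {
    return(stats::setNames(rep(1 / 20, 20), aa))
  }
  if (is.null(names(residue_freqs)) || !setequal(names(residue_freqs), aa)) {
    stop("residue_freqs must be named by the 20 canonical residues")
  }
  residue_freqs <- residue_freqs[aa]
  if (any(residue_freqs < 0) || abs(sum(residue_freqs) - 1) > 1e-8) {
    stop("residue_freqs must be nonnegative and sum to 1")
  }
  residue_freqs
}

empty_truth_windows <- function() {
  data.frame(genome_id = character(), protein_id = character(),
             window_start = integer(), anchor_start = integer(),
             planted_21mer = character(), motif_id = character(),
             stringsAsFactors = FALSE)
}

#' Plant motif-bearing 21-mers into a proteome
#'
#' Overwrites (never inserts, so coordinates are preserved) a 21-residue
#' stretch of randomly chosen host proteins with a window carrying the
#' assigned motif: required residues at the anchor register (anchor at
#' window index 5), wildcard positions drawn from the residue
#' frequencies. Windows are rejection-sampled so that (a) within the
#' planted 21-mer no motif matches anywhere except the intended anchor
#' offset and (b) all planted windows are mutually distinct; the truth
#' table records the exact loci.
#'
#' @param proteome list from \code{\link{generate_proteome}}.
#' @param motifs \code{footprint_motif_set} from
#'   \code{\link{build_motifs}}.
#' @param n_plants number of windows to plant (motifs are cycled so each
#'   is represented when n_plants >= length(motifs)).
#' @param residue_freqs wildcard residue distribution (NULL = uniform).
#' @param seed integer seed.
#' @return the proteome list with modified proteins and populated
#'   \code{truth$planted_windows}.
#' @export
plant_mimics <- function(proteome, motifs, n_plants, residue_freqs = NULL,
                         seed = 1L) {
  residue_freqs <- check_residue_freqs(residue_freqs)
  seed_rng(seed)
  proteins <- proteome$proteins
  eligible <- which(nchar(proteins$sequence) >= 21L + 10L)
  if (length(eligible) < n_plants) {
    stop("not enough proteins long enough to host ", n_plants, " plants")
  }
  hosts <- sample(eligible, n_plants)
  motif_ids <- rep_len(names(motifs), n_plants)
  planted <- character(0)
  rows <- vector("list", n_plants)
  for (i in seq_len(n_plants)) {
    m <- motifs[[motif_ids[i]]]
    w <- sample_planted_window(m, motifs, residue_freqs, planted)
    planted <- c(planted, w)
    L <- nchar(proteins$sequence[hosts[i]])
    # anchor at window index 5; keep the whole 21-mer inside the protein
    ws <- sample(0:(L - 21L), 1L)
    seq0 <- proteins$sequence[hosts[i]]
    proteins$sequence[hosts[i]] <- paste0(
      substr(seq0, 1L, ws), w, substr(seq0, ws + 22L, L))
    rows[[i]] <- data.frame(
      genome_id = proteins$source_genome[hosts[i]],
      protein_id = proteins$id[hosts[i]],
      window_start = ws, anchor_start = ws + 5L,
      planted_21mer = w, motif_id = motif_ids[i],
      stringsAsFactors = FALSE)
  }
  proteome$proteins <- proteins
  proteome$truth$planted_windows <- do.call(rbind, rows)
  proteome
}

# Draw one 21-mer carrying `m` at anchor index 5, rejecting windows where
# any motif matches off-anchor or that duplicate an earlier plant.
sample_planted_window <- function(m, motifs, residue_freqs, forbidden,
                                  max_tries = 10000L) {
  aa <- aa_alphabet()
  req_at <- as.integer(names(m$required)) + 6L   # 1-based window positions
  for (try in seq_len(max_tries)) {
    chars <- sample(aa, 21L, replace = TRUE, prob = residue_freqs)
    chars[req_at] <- unname(m$required)
    w <- paste(chars, collapse = "")
    if (w %in% forbidden) next
    hits <- scan_motifs(stats::setNames(w, "w"), motifs)
    if (all(hits$start == 5L) && nrow(hits) >= 1L) return(w)
  }
  stop("could not sample an unambiguous planted window")
}

#' Generate confidence-score tables with planted binder labels
#'
#' A designated fraction of candidates are labeled binders and receive
#' peptide pLDDT ~ U(92, 98) and inter-chain PAE ~ U(2.0, 4.0);
#' non-binders fail at least one arm, with pLDDT ~ U(60, 88) and/or PAE
#' ~ U(4.5, 12). No generated value falls within 0.5 pLDDT or 0.1 PAE of
#' a classification threshold, so recovery is float-robust. Binders get
#' three TCR-docking runs for each of the four templates with a
#' designated strict-minimum-PAE run; a fraction of binders can be made
#' non-confident (chosen-run pLDDT below 70 on one template) to exercise
#' the modeled-fraction denominator.
#'
#' @param candidates core candidate data.frame
#'   (\code{\link{enumerate_cores}}); only \code{candidate_id} is used.
#' @param binder_fraction fraction of candidates labeled binders.
#' @param nonconfident_fraction fraction of binders whose chosen model is
#'   not confident on one template (default 0).
#' @param seed integer seed.
#' @return list with \code{mhc} and \code{tcr} score tables and
#'   \code{truth} (binder_labels, best_run_labels, modeled_labels).
#' @export
generate_score_tables <- function(candidates, binder_fraction,
                                  nonconfident_fraction = 0, seed = 1L) {
  stopifnot(binder_fraction >= 0, binder_fraction <= 1,
            nonconfident_fraction >= 0, nonconfident_fraction <= 1)
  ids <- unique(candidates$candidate_id)
  n <- length(ids)
  if (n == 0L) {
    return(list(mhc = data.frame(), tcr = data.frame(),
                truth = list(binder_labels = data.frame(),
                             best_run_labels = data.frame(),
                             modeled_labels = data.frame())))
  }
  seed_rng(seed)
  n_bind <- round(binder_fraction * n)
  binder_idx <- sort(sample(n, n_bind))
  is_binder <- seq_len(n) %in% binder_idx

  plddt <- numeric(n); pae <- numeric(n)
  plddt[is_binder] <- stats::runif(n_bind, 92, 98)
  pae[is_binder] <- stats::runif(n_bind, 2.0, 4.0)
  if (n - n_bind > 0) {
    mode <- sample(c("low_plddt", "high_pae", "both"), n - n_bind,
                   replace = TRUE)
    nb_plddt <- ifelse(mode == "high_pae",
                       stats::runif(n - n_bind, 92, 98),
                       stats::runif(n - n_bind, 60, 88))
    nb_pae <- ifelse(mode == "low_plddt",
                     runif_excluding(n - n_bind, 2, 12, 4.24, 4.44),
                     stats::runif(n - n_bind, 4.5, 12))
    plddt[!is_binder] <- nb_plddt
    pae[!is_binder] <- nb_pae
  }
  mhc <- data.frame(
    candidate_id = ids,
    mhc_template = sample(mhc_templates(), n, replace = TRUE),
    peptide_plddt = round(plddt, 2), inter_pae = round(pae, 3),
    stringsAsFactors = FALSE)

  binders <- ids[is_binder]
  n_nonconf <- round(nonconfident_fraction * length(binders))
  nonconf <- if (n_nonconf > 0) sample(binders, n_nonconf) else character(0)
  tmpl <- tcr_templates()
  tcr_rows <- vector("list", length(binders) * length(tmpl))
  best_rows <- tcr_rows
  k <- 0L
  for (cid in binders) {
    weak_tmpl <- if (cid %in% nonconf) sample(tmpl, 1L) else NA_character_
    for (tt in tmpl) {
      k <- k + 1L
      best_run <- sample(3L, 1L)
      pae3 <- stats::runif(3, 5, 10)
      pae3[best_run] <- stats::runif(1, 3, 4.8)
      pl3 <- stats::runif(3, 75, 95)
      if (!is.na(weak_tmpl) && tt == weak_tmpl) {
        pl3[best_run] <- stats::runif(1, 40, 65)
      }
      tcr_rows[[k]] <- data.frame(
        candidate_id = cid, tcr_template = tt, run_index = 1:3,
        pae_tcr_pmhc = round(pae3, 3), peptide_plddt = round(pl3, 2),
        stringsAsFactors = FALSE)
      best_rows[[k]] <- data.frame(
        candidate_id = cid, tcr_template = tt, run_index = best_run,
        stringsAsFactors = FALSE)
    }
  }
  tcr <- if (k > 0) do.call(rbind, tcr_rows) else data.frame(
    candidate_id = character(), tcr_template = character(),
    run_index = integer(), pae_tcr_pmhc = numeric(),
    peptide_plddt = numeric(), stringsAsFactors = FALSE)
  list(
    mhc = mhc, tcr = tcr,
    truth = list(
      binder_labels = data.frame(candidate_id = ids, is_binder = is_binder,
                                 stringsAsFactors = FALSE),
      best_run_labels = if (k > 0) do.call(rbind, best_rows) else
        data.frame(candidate_id = character(), tcr_template = character(),
                   run_index = integer(), stringsAsFactors = FALSE),
      modeled_labels = data.frame(candidate_id = binders,
                                  modeled = !(binders %in% nonconf),
                                  stringsAsFactors = FALSE)))
}

#' Expected count of distinct background match sites
#'
#' Like \code{\link{expected_background_matches}} but counting distinct
#' (protein, offset) sites: a site matching several motifs at once counts
#' once, mirroring how matches collapse into one ligand window. The union
#' probability over motifs is computed by inclusion-exclusion on the
#' required-residue constraint sets.
#'
#' @inheritParams expected_background_matches
#' @return Expected number of distinct matched offsets.
#' @export
expected_background_sites <- function(proteins, motifs,
                                      residue_freqs = NULL) {
  residue_freqs <- check_residue_freqs(residue_freqs)
  n_offsets <- sum(pmax(0L, nchar(proteins$sequence) - 8L))
  reqs <- lapply(motifs, `[[`, "required")
  k <- length(reqs)
  p_union <- 0
  for (mask in seq_len(2^k - 1L)) {
    members <- which(bitwAnd(mask, 2^(seq_len(k) - 1L)) > 0L)
    merged <- list()
    ok <- TRUE
    for (i in members) {
      for (off in names(reqs[[i]])) {
        if (!is.null(merged[[off]]) && merged[[off]] != reqs[[i]][[off]]) {
          ok <- FALSE; break
        }
        merged[[off]] <- reqs[[i]][[off]]
      }
      if (!ok) break
    }
    p_int <- if (ok) prod(residue_freqs[unlist(merged)]) else 0
    p_union <- p_union + (-1)^(length(members) + 1L) * p_int
  }
  n_offsets * p_union
}

# Uniform draw on [lo, hi] avoiding the open interval (xlo, xhi).
runif_excluding <- function(n, lo, hi, xlo, xhi) {
  x <- stats::runif(n, lo, hi)
  bad <- x > xlo & x < xhi
  while (any(bad)) {
    x[bad] <- stats::runif(sum(bad), lo, hi)
    bad <- x > xlo & x < xhi
  }
  x
}

#' Expected background motif-match count in a random proteome
#'
#' Closed-form expectation of chance motif matches: for each scanable
#' offset (sum over proteins of length minus 8) and each motif, the
#' product over required positions of that residue's background
#' frequency. Used to calibrate planted-recovery precision: background
#' match counts should fall in the Poisson interval around this value.
#'
#' @param proteins protein record data.frame.
#' @param motifs \code{footprint_motif_set}.
#' @param residue_freqs background residue frequencies (NULL = uniform).
#' @return Expected total match count (all motifs).
#' @export
expected_background_matches <- function(proteins, motifs,
                                        residue_freqs = NULL) {
  residue_freqs <- check_residue_freqs(residue_freqs)
  n_offsets <- sum(pmax(0L, nchar(proteins$sequence) - 8L))
  p_per_offset <- sum(vapply(motifs, function(m)
    prod(residue_freqs[unname(m$required)]), numeric(1)))
  n_offsets * p_per_offset
}
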