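# Threshold-based triage of structure-prediction confidence scalars:
# MHC II binder classification (peptide pLDDT and inter-chain PAE) and
# best-of-three TCR docking model selection.

#' Triage thresholds for binder classification
#'
#' A candidate is called an MHC II binder when its peptide pLDDT is at
#' least \code{plddt_min} AND its mean inter-chain lowest PAE is at most
#' \code{inter_pae_max}; both boundaries are inclusive. A model is
#' "confident" when the peptide pLDDT of the chosen run is at least
#' \code{confident_plddt_min}.
#'
#' @param plddt_min minimum peptide pLDDT for a binder (default 90).
#' @param inter_pae_max maximum peptide-MHC inter-chain PAE (default
#'   4.34).
#' @param confident_plddt_min pLDDT bound for a confidently modeled
#'   complex (default 70).
#' @return list of class \code{triage_thresholds}.
#' @export
triage_thresholds <- function(plddt_min = 90, inter_pae_max = 4.34,
                              confident_plddt_min = 70) {
  stopifnot(confident_plddt_min >= 0, confident_plddt_min <= plddt_min,
            plddt_min <= 100, inter_pae_max > 0)
  structure(list(plddt_min = plddt_min, inter_pae_max = inter_pae_max,
                 confident_plddt_min = confident_plddt_min),
            class = "triage_thresholds")
}

#' Classify MHC II binders from confidence records
#'
#' Pure elementwise rule: binder iff
#' \code{peptide_plddt >= plddt_min & inter_pae <= inter_pae_max}.
#'
#' @param records data.frame with \code{candidate_id},
#'   \code{peptide_plddt}, \code{inter_pae} (the \code{mhc} element of
#'   \code{\link{read_score_tables}}).
#' @param thresholds a \code{\link{triage_thresholds}} object.
#' @return data.frame of binder calls: candidate_id, peptide_plddt,
#'   inter_pae, is_binder.
#' @export
classify_binders <- function(records, thresholds = triage_thresholds()) {
  records <- validate_confidence_records(records)
  data.frame(
    candidate_id = records$candidate_id,
    peptide_plddt = records$peptide_plddt,
    inter_pae = records$inter_pae,
    is_binder = records$peptide_plddt >= thresholds$plddt_min &
      records$inter_pae <= thresholds$inter_pae_max,
    stringsAsFactors = FALSE)
}

#' Select the best TCR docking model per (candidate, template)
#'
#' Three simulations are run per candidate and TCR template; the chosen
#' model is the one with the lowest PAE between the TCR and the pMHC,
#' ties broken by the lowest run index. The chosen run is flagged
#' confident when its peptide pLDDT reaches the confidence bound.
#'
#' @param runs TcrDock record data.frame (\code{candidate_id},
#'   \code{tcr_template}, \code{run_index}, \code{pae_tcr_pmhc},
#'   \code{peptide_plddt}).
#' @param thresholds a \code{\link{triage_thresholds}}.
#' @param allow_incomplete when TRUE, groups with fewer than 3 runs are
#'   resolved best-of-available with a warning instead of an error.
#' @return data.frame of best models: candidate_id, tcr_template,
#'   chosen_run, pae_tcr_pmhc, peptide_plddt, confident.
#' @export
select_best_models <- function(runs, thresholds = triage_thresholds(),
                               allow_incomplete = FALSE) {
  runs <- suppressWarnings(validate_tcrdock_records(runs))
  key <- paste(runs$candidate_id, runs$tcr_template, sep = "\r")
  sizes <- table(key)
  if (any(sizes != 3L)) {
    msg <- paste0(sum(sizes != 3L),
                  " (candidate, template) group(s) without exactly 3 runs")
    if (allow_incomplete) warning(msg, "; using best of available")
    else stop(msg)
  }
  ord <- order(key, runs$pae_tcr_pmhc, runs$run_index)
  sorted <- runs[ord, , drop = FALSE]
  best <- sorted[!duplicated(key[ord]), , drop = FALSE]
  out <- data.frame(
    candidate_id = best$candidate_id, tcr_template = best$tcr_template,
    chosen_run = best$run_index, pae_tcr_pmhc = best$pae_tcr_pmhc,
    peptide_plddt = best$peptide_plddt,
    confident = best$peptide_plddt >= thresholds$confident_plddt_min,
    stringsAsFactors = FALSE)
  out <- out[order(out$candidate_id, out$tcr_template), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fraction of binders confidently modeled against all TCR templates
#'
#' A binder counts as successfully modeled when its chosen model is
#' confident for every one of the TCR templates; the denominator is all
#' binders.
#'
#' @param binder_calls result of \code{\link{classify_binders}}.
#' @param best_models result of \code{\link{select_best_models}}.
#' @param templates the required template set (default the four TCR:pMHC
#'   templates).
#' @return Fraction in [0, 1]; NaN with a warning when there are no
#'   binders.
#' @export
modeled_fraction <- function(binder_calls, best_models,
                             templates = tcr_templates()) {
  binders <- unique(binder_calls$candidate_id[binder_calls$is_binder])
  if (length(binders) == 0L) {
    warning("no binders; modeled fraction undefined")
    return(NaN)
  }
  conf <- best_models[best_models$confident, , drop = FALSE]
  ok <- vapply(binders, function(cid) {
    all(templates %in% conf$tcr_template[conf$candidate_id == cid])
  }, logical(1))
  sum(ok) / length(binders)
}
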