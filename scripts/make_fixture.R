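#!/usr/bin/env Rscript
# Regenerates the tiny packaged fixture under inst/extdata/: a synthetic
# 3-genome, 30-protein corpus with 5 planted mimic windows (two of them
# the MOG 35-55 and P3 21-mers verbatim), its taxonomy and truth tables,
# and matching synthetic confidence-score tables. All files are small
# plain text; rerunning reproduces them byte-identically.
suppressMessages(library(mimicscreen))

dest <- file.path("inst", "extdata")
dir.create(dest, recursive = TRUE, showWarnings = FALSE)

motifs <- build_motifs(mog_epitope())
corp <- generate_proteome(
  phylum_spec = c(Verrucomicrobiota = 1, Bacteroidota = 1, Firmicutes_A = 1),
  proteins_per_genome = 10, length_mean = 120, length_sd = 15, seed = 2024)
corp <- plant_mimics(corp, motifs, n_plants = 3, seed = 2025)

# embed the two printed peptides verbatim as additional plants
embed <- function(corp, protein_id, start0, window, motif_id) {
  i <- match(protein_id, corp$proteins$id)
  s <- corp$proteins$sequence[i]
  corp$proteins$sequence[i] <- paste0(
    substr(s, 1, start0), window, substr(s, start0 + 22L, nchar(s)))
  corp$truth$planted_windows <- rbind(
    corp$truth$planted_windows,
    data.frame(genome_id = corp$proteins$source_genome[i],
               protein_id = protein_id, window_start = start0,
               anchor_start = start0 + 5L, planted_21mer = window,
               motif_id = motif_id, stringsAsFactors = FALSE))
  corp
}
mog21 <- mog_epitope("mouse")$sequence
p3 <- "TTLSFYRPPFLRVRRPFYIIF"
used <- corp$truth$planted_windows$protein_id
free <- setdiff(corp$proteins$id[nchar(corp$proteins$sequence) >= 60], used)
corp <- embed(corp, free[1], 20L, mog21, "full")
corp <- embed(corp, free[2], 30L, p3, "full")

write_fasta(corp$proteins, file.path(dest, "fixture_synthetic_proteome.faa"))
utils::write.table(corp$taxonomy[, c("genome_id", "lineage")],
                   file.path(dest, "fixture_synthetic_taxonomy.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(corp$truth$planted_windows,
                   file.path(dest, "fixture_synthetic_truth.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

# run the deterministic screen stages to get candidates, then scores
matches <- scan_motifs(corp$proteins, motifs)
windows <- truncate_windows(matches, corp$proteins)
ligands <- dedup_ligands(windows)
cands <- enumerate_cores(ligands)
st <- generate_score_tables(cands, binder_fraction = 0.4, seed = 2026)
utils::write.table(st$mhc, file.path(dest, "fixture_synthetic_mhc_scores.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(st$tcr, file.path(dest, "fixture_synthetic_tcr_scores.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("fixture written:", nrow(corp$proteins), "proteins,",
    nrow(corp$truth$planted_windows), "plants,", nrow(cands),
    "candidates\n")
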