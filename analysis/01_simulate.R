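#!/usr/bin/env Rscript
# Stage 1 — build the synthetic study corpus.
#
# Generates a background proteome spanning several phyla with known
# residue frequencies, plants 50 mimic windows (each carrying one of the
# five footprint motifs at the anchor register) at recorded loci, and
# writes the corpus in the exact formats the screen ingests. Everything
# downstream treats these files as it would real genome-catalog inputs.

suppressMessages(library(mimicscreen))
seed <- 20260101L
outdir <- "results/sim"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

motifs <- build_motifs(mog_epitope("mouse"))
corpus <- generate_proteome(
  phylum_spec = c(Verrucomicrobiota = 15, Bacteroidota = 30,
                  Firmicutes_A = 40, Actinobacteriota = 12,
                  Proteobacteria = 8, UNCLASSIFIED = 3),
  proteins_per_genome = 20, length_mean = 300, length_sd = 60,
  seed = seed)
corpus <- plant_mimics(corpus, motifs, n_plants = 50, seed = seed + 1L)

write_fasta(corpus$proteins, file.path(outdir, "proteome.faa"))
write.table(corpus$taxonomy[, c("genome_id", "lineage")],
            file.path(outdir, "taxonomy.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(corpus$truth$planted_windows,
            file.path(outdir, "truth_planted.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

tr <- corpus$truth$planted_windows
cat("Corpus:", nrow(corpus$taxonomy), "genomes across",
    length(unique(corpus$taxonomy$phylum)), "phyla;",
    nrow(corpus$proteins), "proteins;",
    sum(nchar(corpus$proteins$sequence)), "residues.\n")
cat("Planted:", nrow(tr), "mimic windows (",
    paste(names(table(tr$motif_id)), table(tr$motif_id), collapse = ", "),
    ") — truth recorded in", file.path(outdir, "truth_planted.tsv"), "\n")
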