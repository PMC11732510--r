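test_that("proteome generation is deterministic and respects the spec", {
  spec <- c(A = 12, B = 5)
  a <- generate_proteome(spec, proteins_per_genome = 5, seed = 42)
  b <- generate_proteome(spec, proteins_per_genome = 5, seed = 42)
  expect_identical(a$proteins, b$proteins)
  expect_identical(a$taxonomy, b$taxonomy)
  c_ <- generate_proteome(spec, proteins_per_genome = 5, seed = 43)
  expect_false(identical(a$proteins$sequence, c_$proteins$sequence))

  expect_equal(nrow(a$taxonomy), 17L)
  expect_equal(table(a$taxonomy$phylum)[["A"]], 12L)
  expect_equal(nrow(a$proteins), 17L * 5L)
  expect_true(all(a$proteins$source_genome %in% a$taxonomy$genome_id))
  # lineages are well-formed GTDB strings
  expect_true(all(grepl("^d__Bacteria", a$taxonomy$lineage)))
  expect_equal(parse_phylum(a$taxonomy$lineage), a$taxonomy$phylum)

  # written FASTA/taxonomy are byte-identical across same-seed runs
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_fasta(a$proteins, f1); write_fasta(b$proteins, f2)
  expect_identical(readLines(f1), readLines(f2))

  expect_error(generate_proteome(spec, residue_freqs = c(A = 1)), "20")
})

test_that("empirical residue frequencies match the generator's target", {
  corp <- generate_proteome(c(A = 10), proteins_per_genome = 40,
                            length_mean = 260, length_sd = 10, seed = 3)
  chars <- strsplit(paste(corp$proteins$sequence, collapse = ""), "")[[1]]
  n <- length(chars)
  expect_gt(n, 1e5)
  freq <- table(factor(chars, levels = aa_alphabet())) / n
  # each residue within 3 binomial standard errors of 0.05
  se <- sqrt(0.05 * 0.95 / n)
  expect_true(all(abs(freq - 0.05) < 3.5 * se))
})

test_that("planted windows carry their motif at anchor index 5", {
  motifs <- build_motifs(mog_epitope())
  corp <- generate_proteome(c(A = 10, B = 10), proteins_per_genome = 10,
                            seed = 2)
  corp <- plant_mimics(corp, motifs, n_plants = 25, seed = 12)
  tr <- corp$truth$planted_windows
  expect_equal(nrow(tr), 25L)
  expect_equal(length(unique(tr$planted_21mer)), 25L)
  expect_setequal(unique(tr$motif_id), names(motifs))
  for (i in seq_len(nrow(tr))) {
    # the recorded window is verbatim in the host protein
    seqs <- corp$proteins$sequence[corp$proteins$id == tr$protein_id[i]]
    expect_equal(substr(seqs, tr$window_start[i] + 1L,
                        tr$window_start[i] + 21L), tr$planted_21mer[i])
    # rescanning finds the planted motif at anchor 5 and nowhere else
    hits <- scan_motifs(stats::setNames(tr$planted_21mer[i], "w"), motifs)
    expect_true(tr$motif_id[i] %in% hits$motif_id)
    expect_true(all(hits$start == 5L))
  }
  # planting overwrites: lengths unchanged
  fresh <- generate_proteome(c(A = 10, B = 10), proteins_per_genome = 10,
                             seed = 2)
  expect_equal(nchar(corp$proteins$sequence),
               nchar(fresh$proteins$sequence))
  expect_error(plant_mimics(corp, motifs, n_plants = 1e6, seed = 1),
               "not enough")
})

test_that("background match rate matches the closed-form expectation", {
  motifs <- build_motifs(mog_epitope())
  # aggregate over seeds for a stable Poisson check at modest corpus size
  total <- 0; expected <- 0
  for (s in 101:103) {
    corp <- generate_proteome(c(A = 40), proteins_per_genome = 20,
                              length_mean = 300, length_sd = 30, seed = s)
    mm <- scan_motifs(corp$proteins, motifs)
    total <- total + nrow(unique(mm[, c("sequence_id", "start")]))
    expected <- expected + expected_background_sites(corp$proteins, motifs)
  }
  ci <- qpois(c(0.005, 0.995), expected)
  expect_gte(total, ci[1])
  expect_lte(total, ci[2])
  # per-motif expectation: uniform background gives (1/20)^k per offset
  full_only <- expected_background_matches(
    corp$proteins, motifs["full"])
  n_off <- sum(nchar(corp$proteins$sequence) - 8L)
  expect_equal(full_only, n_off * (1 / 20)^5)
})

test_that("score-table generation straddles the thresholds by a margin", {
  cand <- data.frame(candidate_id = sprintf("c%04d", 1:400))
  st <- generate_score_tables(cand, binder_fraction = 0.25, seed = 9)
  mhc <- st$mhc
  lab <- st$truth$binder_labels$is_binder
  expect_equal(sum(lab), 100L)
  # no value within the guard band of either threshold
  expect_true(all(abs(mhc$peptide_plddt - 90) >= 0.5))
  expect_true(all(mhc$inter_pae <= 4.24 | mhc$inter_pae >= 4.44))
  # binders satisfy both arms, non-binders fail at least one
  expect_true(all(mhc$peptide_plddt[lab] >= 90 & mhc$inter_pae[lab] <= 4.34))
  expect_true(all(mhc$peptide_plddt[!lab] < 90 | mhc$inter_pae[!lab] > 4.34))
  # 3 runs x 4 templates per binder
  expect_equal(nrow(st$tcr), 100L * 4L * 3L)
  expect_identical(generate_score_tables(cand, 0.25, seed = 9)$mhc, mhc)

  none <- generate_score_tables(cand, binder_fraction = 0, seed = 9)
  expect_equal(sum(none$truth$binder_labels$is_binder), 0L)
  expect_equal(nrow(none$tcr), 0L)

  # mixed confidence: modeled fraction equals the planted proportion
  st2 <- generate_score_tables(cand, binder_fraction = 0.25,
                               nonconfident_fraction = 0.2, seed = 11)
  calls <- classify_binders(st2$mhc)
  bm <- select_best_models(st2$tcr)
  expect_equal(modeled_fraction(calls, bm),
               mean(st2$truth$modeled_labels$modeled))
  expect_equal(mean(st2$truth$modeled_labels$modeled), 0.8)
})
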