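motifs <- build_motifs(mog_epitope())

test_that("the epitope footprint compiles to the five-motif family", {
  expect_length(motifs, 5L)
  expect_setequal(
    vapply(motifs, `[[`, character(1), "pattern"),
    c("YR..F.RV.", "Y...F.RV.", "YR....RV.", "YR..F..V.", "YR..F.R.."))
  expect_equal(motifs$full$pattern, "YR..F.RV.")
  # relaxing F at core offset 4 keeps Y0, R1, R6, V7
  expect_equal(motifs$relax_F4$required,
               c(`0` = "Y", `1` = "R", `6` = "R", `7` = "V"))
  # the anchor is required by every motif
  expect_true(all(vapply(motifs, function(m) m$required[["0"]] == "Y",
                         logical(1))))
  # a footprint without the anchor is rejected
  ep_noY <- epitope_query("x", "MEVGWARSPFSRVVHLYRNGK",
                          c(`5` = "A", `6` = "R", `9` = "F",
                            `11` = "R", `12` = "V"),
                          mhc_anchor_offset = 5)
  expect_silent(build_motifs(ep_noY))  # anchor A is still at offset 0
  expect_error(epitope_query("x", mog21, c(`6` = "R", `9` = "F"),
                             mhc_anchor_offset = 5), "anchor")
})

test_that("scanning reproduces the printed peptides and the oracle", {
  seqs <- c(MOG = mog21, P3 = p3_21, SCR = scrambled21)
  res <- scan_motifs(seqs, motifs)
  full <- res[res$motif_id == "full", ]
  expect_equal(full$sequence_id, c("MOG", "P3"))
  expect_equal(full$start, c(5L, 5L))
  expect_equal(full$matched_9mer, c("YRSPFSRVV", "YRPPFLRVR"))
  expect_equal(sum(res$sequence_id == "SCR"), 0L)
  expect_equal(res, oracle_scan(seqs, motifs))
})

test_that("motif engine equals the brute-force oracle on random sequences", {
  withr::local_seed(11)
  n <- 400
  seqs <- stats::setNames(
    vapply(sample(9:60, n, replace = TRUE),
           function(L) random_protein(L, freqs = c(
             stats::setNames(rep(0.02, 15), setdiff(aa_alphabet(), c("Y", "R", "F", "V", "S"))),
             Y = 0.2, R = 0.2, F = 0.1, V = 0.1, S = 0.1)[aa_alphabet()]),
           character(1)),
    paste0("s", seq_len(n)))
  expect_equal(scan_motifs(seqs, motifs), oracle_scan(seqs, motifs))
})

test_that("X satisfies wildcards but never a required position", {
  res <- scan_motifs(c(x1 = "YRXXFXRVX"), motifs)
  expect_true("full" %in% res$motif_id)     # X at wildcard positions is fine
  res2 <- scan_motifs(c(x2 = "XRSPFSRVV"), motifs)
  expect_equal(nrow(res2), 0L)              # X cannot stand for the anchor Y
})

test_that("window truncation places the anchor at index 5 with clamping", {
  parent <- data.frame(id = "prot", source_genome = "g1",
                       sequence = paste0("AAAAA", mog21, "AAAAA"))
  m <- scan_motifs(stats::setNames(parent$sequence, parent$id), motifs)
  m <- m[m$motif_id == "full", ]
  expect_equal(m$start, 10L)
  w <- truncate_windows(m, parent)
  expect_equal(w$sequence, mog21)
  expect_equal(w$anchor_index, 5L)
  expect_equal(w$parent_start, 5L)
  expect_equal(w$genome_id, "g1")

  # left clamp: match anchor at offset 2 leaves only 2 upstream residues
  parent2 <- data.frame(id = "p2", sequence = paste0("GA", "YRSPFSRVV",
                                                     strrep("A", 15)))
  m2 <- scan_motifs(stats::setNames(parent2$sequence, parent2$id), motifs)
  m2 <- m2[m2$motif_id == "full", ]
  w2 <- truncate_windows(m2, parent2)
  expect_equal(w2$parent_start, 0L)
  expect_equal(w2$anchor_index, 2L)
  expect_equal(nchar(w2$sequence), 21L)

  # a 21-residue parent with the match at 5 returns the whole parent
  parent3 <- data.frame(id = "p3", sequence = p3_21)
  m3 <- scan_motifs(stats::setNames(parent3$sequence, parent3$id), motifs)
  m3 <- m3[m3$motif_id == "full", ]
  w3 <- truncate_windows(m3, parent3)
  expect_equal(w3$sequence, p3_21)
  expect_equal(w3$anchor_index, 5L)

  # truncation then rescanning finds the motif at the anchor index
  rescan <- scan_motifs(stats::setNames(w$sequence, "w"), motifs)
  expect_true(any(rescan$start == w$anchor_index))
})

test_that("dedup collapses by global string identity and is idempotent", {
  win <- data.frame(
    sequence = c(mog21, mog21, p3_21),
    parent_id = c("a", "b", "c"), parent_start = c(0L, 3L, 0L),
    motif_id = c("full", "relax_F4", "full"),
    anchor_index = 5L, genome_id = c("g1", "g2", "g1"),
    stringsAsFactors = FALSE)
  nr <- dedup_ligands(win)
  expect_equal(nrow(nr), 2L)
  expect_equal(nr$n_sources, c(2L, 1L))
  expect_equal(nr$genome_ids[1], "g1;g2")
  expect_equal(nr$motif_ids[1], "full;relax_F4")
  # representative is the first encountered
  expect_equal(nr$parent_id, c("a", "c"))

  # set-cardinality oracle on synthetic duplicates
  withr::local_seed(5)
  pool <- vapply(1:40, function(i) random_protein(21), character(1))
  many <- win[rep(1, 0), ]
  picks <- sample(pool, 500, replace = TRUE)
  many <- data.frame(sequence = picks, parent_id = paste0("p", 1:500),
                     parent_start = 0L, motif_id = "full",
                     anchor_index = 5L, genome_id = "g1")
  nr2 <- dedup_ligands(many)
  expect_equal(nrow(nr2), length(unique(picks)))

  # idempotence: dedup(dedup(X)) = dedup(X)
  again <- dedup_ligands(nr2[, names(many)])
  expect_equal(again$sequence, nr2$sequence)
  expect_equal(nrow(again), nrow(nr2))
})

test_that("core enumeration follows the L - 10 formula with stride 1", {
  lig <- function(s) data.frame(ligand_id = "L1", sequence = s)
  cand <- enumerate_cores(lig("ABCDEFGHIJKLMNOPQRSTU"))
  expect_equal(nrow(cand), 11L)
  expect_equal(cand$window11[1], "ABCDEFGHIJK")
  expect_equal(cand$core9[1], "BCDEFGHIJ")
  expect_equal(cand$start_in_ligand, 0:10)
  # each window is a verbatim ligand substring with its core centered
  expect_true(all(substring("ABCDEFGHIJKLMNOPQRSTU",
                            cand$start_in_ligand + 1L,
                            cand$start_in_ligand + 11L) == cand$window11))
  expect_true(all(substring(cand$window11, 2, 10) == cand$core9))

  expect_equal(nrow(enumerate_cores(lig("ABCDEFGHIJK"))), 1L)
  expect_warning(none <- enumerate_cores(lig("ABCDEFGHIJ")), "shorter")
  expect_equal(nrow(none), 0L)

  # property: count is L - 10 for L in 11..30 (distinct random residues
  # make intra-ligand dedup a no-op)
  withr::local_seed(31)
  for (L in 11:30) {
    s <- random_protein(L)
    n_expect <- length(unique(substring(s, 1:(L - 10), 11:L)))
    expect_equal(nrow(enumerate_cores(lig(s))), n_expect)
  }

  # duplicate 11-mers within one ligand collapse
  dup <- paste0("ABCDEFGHIJK", "ABCDEFGHIJK")
  expect_lt(nrow(enumerate_cores(lig(dup))), nchar(dup) - 10L)

  # windows containing X are excluded
  cx <- enumerate_cores(lig("ABCDEXGHIJKLMNOPQRSTU"))
  expect_false(any(grepl("X", cx$window11)))
  expect_equal(nrow(cx), 5L)  # only windows starting after the X
})
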