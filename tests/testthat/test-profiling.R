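make_taxonomy <- function(spec) {
  # spec: named vector phylum -> n genomes ("UNCLASSIFIED" = no p__ rank)
  phyla <- rep(names(spec), spec)
  data.frame(
    genome_id = sprintf("g%03d", seq_along(phyla)),
    lineage = ifelse(phyla == "UNCLASSIFIED", "d__Bacteria",
                     paste0("d__Bacteria;p__", phyla)),
    phylum = ifelse(phyla == "UNCLASSIFIED", "UNCLASSIFIED", phyla),
    stringsAsFactors = FALSE)
}

test_that("phylum profile normalizes by all genomes of the phylum", {
  tax <- make_taxonomy(c(Verrucomicrobiota = 4))
  matches <- data.frame(motif_id = "full",
                        genome_id = c("g001", "g002"))
  prof <- phylum_profile(matches, tax, min_genomes = 1)
  expect_equal(prof$analog_count, 2L)
  expect_equal(prof$genome_count, 4L)
  expect_equal(prof$rate, 0.5)
})

test_that("small phyla and unclassified genomes pool into Others", {
  tax <- make_taxonomy(c(Bacteroidota = 12, Firmicutes = 9,
                         UNCLASSIFIED = 3))
  matches <- data.frame(
    motif_id = c("full", "full", "relax_F4", "full"),
    genome_id = c("g001", "g013", "g014", "g022"))  # B, F, F, UNCLASS
  prof <- phylum_profile(matches, tax, min_genomes = 10)
  expect_setequal(unique(prof$phylum), c("Bacteroidota", "Others"))
  others_full <- prof$analog_count[prof$phylum == "Others" &
                                     prof$motif_id == "full"]
  expect_equal(others_full, 2L)  # one Firmicutes + one unclassified
  # Others genome count sums the pooled phyla
  expect_equal(unique(prof$genome_count[prof$phylum == "Others"]), 12L)

  # conservation: analog counts sum to total matches, genomes to table size
  expect_equal(sum(prof$analog_count), nrow(matches))
  per_phylum <- tapply(prof$genome_count, prof$phylum, unique)
  expect_equal(sum(unlist(per_phylum)), nrow(tax))
  # rate recomputation is exact
  expect_equal(prof$analog_count, prof$rate * prof$genome_count)

  # a genome id missing from the taxonomy counts as unclassified
  prof2 <- phylum_profile(data.frame(motif_id = "full",
                                     genome_id = "missing"), tax)
  expect_equal(sum(prof2$analog_count[prof2$phylum == "Others"]), 1L)
})

test_that("position frequency matrices count residues per location", {
  # hand-counted example: core one-hot, flanks split between A and G
  pfm <- position_frequency_matrix(c("AYRSPFSRVVA", "GYRSPFSRVVG"))
  expect_equal(unname(pfm["A", "loc_0"]), 0.5)
  expect_equal(unname(pfm["G", "loc_0"]), 0.5)
  core <- strsplit("YRSPFSRVV", "")[[1]]
  for (j in 1:9) {
    expect_equal(unname(pfm[core[j], paste0("loc_", j)]), 1.0)
  }
  expect_equal(unname(colSums(pfm)), rep(1, 11))
  expect_equal(attr(pfm, "n_sequences"), 2L)

  # duplicated input gives one-hot columns everywhere
  pfm2 <- position_frequency_matrix(rep("WYRPPFSRVVH", 2))
  expect_true(all(apply(pfm2, 2, max) == 1))

  expect_error(position_frequency_matrix(character(0)), "no windows")
  expect_error(position_frequency_matrix("TOOSHORT"), "11-mers")
  expect_error(position_frequency_matrix("AXRSPFSRVVA"), "X")
})

test_that("logo groups partition the windows and average to the global PFM", {
  withr::local_seed(23)
  wins <- vapply(1:60, function(i)
    paste0(random_protein(1), sample(c("YRSPFSRVV", "LRSPFSRVV",
                                       "FRPPFLRVR"), 1),
           random_protein(1)), character(1))
  groups <- group_logos_by_start(wins)
  expect_setequal(names(groups), unique(substring(wins, 2, 2)))
  sizes <- vapply(groups, attr, integer(1), "n_sequences")
  expect_equal(sum(sizes), length(wins))
  # size-weighted mean of group matrices equals the global matrix
  global <- position_frequency_matrix(wins)
  weighted <- Reduce(`+`, Map(function(g, n) g * n, groups, sizes)) /
    length(wins)
  expect_equal(weighted, global, ignore_attr = TRUE, tolerance = 1e-12)

  # grouping is order-invariant
  expect_equal(group_logos_by_start(c("AYRSPFSRVVA", "ALRSPFSRVVA")),
               group_logos_by_start(c("ALRSPFSRVVA", "AYRSPFSRVVA")),
               ignore_attr = TRUE)
})

test_that("prioritization scores the four selection criteria", {
  ligands <- data.frame(
    ligand_id = c("L1", "L2", "L3"),
    sequence = c(p3_21, "AAAAAYAAAFARVAAAAAAAA", mog21),
    motif_ids = c("full;relax_V7", "relax_R1", "full"),
    genome_ids = c("akk1", "g002", "g003"),
    stringsAsFactors = FALSE)
  cores <- data.frame(ligand_id = c("L1", "L3"),
                      core9 = c("LSFYRPPFL", "YRSPFSRVV"))
  res <- suppressWarnings(prioritize(
    ligands, cores,
    cohort_ids = mog21,
    flagged_species = "Akkermansia muciniphila",
    species_of = c(akk1 = "Akkermansia muciniphila")))
  r <- function(id) res[res$ligand_id == id, ]
  # canonical motif means the full pattern; relaxed variants do not count
  expect_true(r("L1")$has_canonical_motif)
  expect_false(r("L2")$has_canonical_motif)
  expect_true(r("L1")$species_flagged)
  expect_false(r("L3")$species_flagged)
  expect_true(r("L3")$in_metagenome_cohort)
  # L1's binder core starts with L (noncanonical start)
  expect_true(r("L1")$noncanonical_start)
  expect_false(r("L3")$noncanonical_start)
  expect_equal(res$n_criteria,
               rowSums(res[, c("has_canonical_motif", "in_metagenome_cohort",
                               "species_flagged", "noncanonical_start")]))
  # sorted by criteria count, ties by ligand id; deterministic
  expect_true(all(diff(res$n_criteria) <= 0))
  res2 <- suppressWarnings(prioritize(
    ligands, cores, cohort_ids = mog21,
    flagged_species = "Akkermansia muciniphila",
    species_of = c(akk1 = "Akkermansia muciniphila")))
  expect_identical(res, res2)

  w <- testthat::capture_warnings(prioritize(ligands, cores))
  expect_match(w, "cohort", all = FALSE)
  expect_match(w, "species", all = FALSE)
})
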