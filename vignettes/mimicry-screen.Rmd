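---
title: "Screening microbial proteomes for MHC II-TCR mimics of a self-epitope"
author: "mimicscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening microbial proteomes for MHC II-TCR mimics of a self-epitope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Molecular mimicry proposes that a microbial peptide resembling a
self-antigen at the residues contacted by the immune receptors can
activate self-reactive T cells. For an MHC class II-restricted epitope,
"resemblance" is surprisingly narrow: cross-recognition can be driven by
a handful of residues at fixed spacing — one dominant anchor seated in
the MHC groove plus a few solvent-exposed TCR contacts — while the rest
of the peptide varies freely. `mimicscreen` operationalizes this
hotspot view of mimicry as a sequence screen: given a self-epitope with
an annotated MHC-anchor/TCR-contact footprint, it searches microbial
protein collections for peptides that conserve the footprint at the
correct spacing, and then triages the candidates with
structure-prediction confidence scores.

The reference epitope built in is MOG 35-55
(`MEVGWYRSPFSRVVHLYRNGK`, mouse; the human variant carries a proline at
position 42), the encephalitogenic myelin peptide used to induce EAE in
C57BL/6J mice. Its footprint is the tyrosine at position 40 (the
dominant MHC II anchor) and R41, F44, R46, V47 (the major TCR
contacts): 0-based epitope offsets 5, 6, 9, 11, 12. Any epitope with an
analogous annotation can be supplied through `epitope_query()`.

## The screen, stage by stage

**Motif compilation.** `build_motifs()` re-indexes the footprint
relative to the anchor, giving a 9-position degenerate pattern
(`YR..F.RV.` for MOG). The default family is this full pattern plus the
four variants relaxing exactly one TCR contact — the anchor is never
relaxed. The relaxation ladder reflects the biology: losing one TCR
contact may weaken but not abolish cross-recognition, while losing the
MHC anchor abolishes presentation in this register. Published versions
of such pattern families are often typeset inconsistently (8- versus
9-position strings); we canonicalize all members to 9-position patterns
over core offsets {0, 1, 4, 6, 7}, which keeps every variant the same
length and the anchor at offset 0.

**Analog prefilter (optional).** `search_analogs()` plays the role of a
BLASTp pass: Smith-Waterman local alignment of the epitope against
every subject (via `Biostrings::pairwiseAlignment`), BLOSUM62, affine
gaps 11/1 (a gap of length L costs 11 + L), raw scores converted to
e-values with the Karlin-Altschul form E = K m n exp(-lambda S) using
K = 0.041, lambda = 0.267 and n the total residue count of the
collection. The e-value boundary is inclusive (a hit at exactly the
threshold is retained), matching the convention of the common search
tools. The scoring parameters are standard protein-search defaults and
configurable; word size, compositional adjustment and other heuristics
of a production search engine are deliberately out of scope, because in
this screen the motif filter — not the alignment — is the discriminating
stage. For that reason the pipeline can also bypass alignment entirely
(`alignment$bypass`) and scan every protein; on planted exact mimics
the two routes recover the same ligands, and the bypass route is the
one the validation suite leans on because it admits exact expected
counts.

**Motif scan and window truncation.** `scan_motifs()` reports every
(offset, motif) pair whose required residues match exactly; overlapping
matches are found, and a 9-mer satisfying several motifs yields one row
per motif. `truncate_windows()` cuts the ~21-residue ligand region
around each match — a fixed-window surrogate for proteolytic processing
before MHC II loading — placing the anchor at window index 5 and
clamping at protein termini ("21 where available, shorter at the
ends"). Index 5 is not arbitrary: both printed reference peptides (the
MOG 21-mer and the validated mimic P3, `TTLSFYRPPFLRVRRPFYIIF`) carry
the motif anchor at exactly that index, so this convention reproduces
them verbatim.

**Nonredundant collapse.** `dedup_ligands()` collapses windows by
global, case-sensitive string identity of the full window (the
21-mer), keeping the first representative and the multiplicity and
source lists. Keying the collapse on the 21-mer rather than the 11-mer
or the core is a choice; it matches the "nonredundant ligand" unit the
downstream bookkeeping is phrased in. The collapse is idempotent.

**Core enumeration.** `enumerate_cores()` chops each ligand into its
L - 10 consecutive 11-mers (stride 1); the central nine residues are
the putative MHC II binding core, the outer two the immediate flanks.
Duplicate 11-mers within a ligand are collapsed, so a repetitive
ligand can yield fewer than L - 10 candidates. Candidate ids are
derived from the 11-mer string itself, so the same peptide carries the
same id wherever it occurs and externally produced score tables join
stably across runs. Windows containing the mask character X are
excluded: motif positions are exact-residue tests and a masked flank
would poison the frequency matrices downstream.

**Binder triage.** The structure-prediction step itself (fine-tuned
AlphaFold for peptide-MHC II, TCR-docking for the ternary complex) is
outside this package; its scalar confidence outputs are the contract.
`classify_binders()` calls a candidate an MHC II binder when peptide
pLDDT >= 90 AND mean inter-chain lowest PAE <= 4.34, both boundaries
inclusive exactly as written. The pLDDT scalar is understood as the
mean per-residue pLDDT over the 11-mer; the reduction from per-residue
values lives in whoever produces the table and is documented rather
than enforced. `select_best_models()` implements best-of-three run
selection per (candidate, TCR template): the run with the lowest
TCR:pMHC PAE wins, ties broken by the lowest run index — deterministic
and order-invariant. A chosen model is "confident" at pLDDT >= 70, and
`modeled_fraction()` reports the fraction of binders confident on all
four TCR templates (3c60, 3rdt, 3c5z, 6mnn — carried as metadata). The
precise denominator behind a "successfully modeled" percentage is a
modeling-team convention; the definition here (all four templates
confident, over all binders) is the package's documented reading and
is validated only against synthetic labels.

**Profiling and prioritization.** `phylum_profile()` counts motif
analogs per (phylum, motif) and normalizes by the number of genomes the
taxonomy table assigns to the phylum — all genomes, not only
motif-bearing ones, since the question is "analogs per genome".
Phyla with fewer than 10 genomes and unclassified genomes pool into
"Others" before rates are computed, so counts are conserved. All
(redundant) matches are counted, which is configurable by passing the
deduplicated tables instead. `position_frequency_matrix()` gives the
residue frequencies at window positions loc_0..loc_10 (0-indexed; core
at loc_1..loc_9), and `group_logos_by_start()` partitions binder
windows by the core's first residue — the grouping used to display
canonical (Y-anchored) versus noncanonical (F-, L-started) binding
modes. `prioritize()` scores each nonredundant ligand on four binary
criteria: carries the full canonical motif; detected in the metagenome
cohort (supplied as a sequence set — reproducing metagenome detection
is out of scope); derived from a disease-associated taxon (supplied
list); and has a binder core starting with F or L.

## The synthetic-data module

`generate_proteome()`, `plant_mimics()` and `generate_score_tables()`
produce every input the screen consumes, with recorded ground truth.
They define the validation conditions of the package:

* Background proteins are i.i.d. residue strings, uniform over the 20
  canonical residues by default, lengths ~ Normal(300, 60) floored at
  30 — a deliberately featureless null in which chance motif matches
  have a closed-form expectation (`expected_background_sites()`; for a
  motif with k required positions, each scanable offset matches with
  probability (1/20)^k under the uniform background, combined across
  the family by inclusion-exclusion).
* The default corpus spans 108 genomes in six phyla (15/30/40/12/8
  genomes plus 3 unclassified), 20 proteins each — large enough that
  the <10-genome pooling rule, per-phylum normalization and Poisson
  background calibration are all exercised, small enough that the full
  pipeline runs in seconds.
* 50 mimic windows are planted by overwriting (never inserting, so
  coordinates stay fixed) 21 contiguous residues: required residues at
  the anchor register, wildcards drawn from the background.
  Rejection sampling guarantees no off-anchor motif match within the
  planted 21-mer and mutual distinctness of the planted windows.
* Score tables straddle the triage thresholds with a guard band (no
  value within 0.5 pLDDT or 0.1 PAE of a threshold), so label recovery
  is float-robust; binders get 3 runs x 4 templates with a designated
  strict-minimum run.

What the generator does **not** emulate: real proteome composition
(domain structure, low-complexity regions, codon- or GC-driven residue
bias), homology between genomes, partial or frame-shifted mimics, and
realistic correlation structure in structure-prediction confidence.
Passing the planted-recovery suite therefore demonstrates that the
screen's bookkeeping is exact — every planted mimic recovered, chance
matches at their analytic rate — not that the footprint-mimicry
hypothesis holds in real data, which is a wet-lab question.

## Numerical and edge-case conventions

* Local alignment scores are floored at zero (no positive-scoring
  pair means "no alignment"); alignment ties resolve deterministically
  inside the alignment engine.
* Windows shorter than 11 residues (possible only at protein termini)
  yield no core candidates, with a warning.
* An empty binder set is legal: frequency matrices are skipped, the
  modeled fraction is NaN with a warning, and prioritization criterion
  4 is false everywhere.
* Incomplete TCR run triplets are an error by default,
  best-of-available behind an explicit flag.
* Stage tables are always materialized as TSV; rerunning with the same
  configuration and seed reproduces them byte-identically (the
  generators use R's integer-state Mersenne-Twister with fixed normal
  and sample kinds).
* A 21-mer ligand yields 11 stride-1 windows by the L - 10 formula;
  intra-ligand duplicate windows (repetitive sequence) collapse, so a
  particular peptide can legitimately yield fewer unique candidates
  than L - 10.

## Validation sizes

The test suite checks the motif engine against a brute-force
all-offsets oracle on 10,000 random sequences (length <= 60) and the
aligner against a hand-written Gotoh dynamic program on 500 random
pairs (length <= 40); planted recovery runs on the 108-genome corpus
with 50 plants; triage recovery on 500 candidates. These sizes were
chosen to give the oracles real coverage (the motif oracle sees every
match class, the Poisson band is a few counts wide) while keeping the
suite interactive.

## Known limitations

The screen inherits the hotspot-mimicry assumption wholesale: peptides
that mimic through conformation rather than identical footprint
residues are invisible to it. The fixed 21-residue truncation is a
surrogate for antigen processing, not a protease model. Strain-level
attribution is outside the taxonomy contract (phylum is the unit of
profiling). And the binder classifier is a threshold rule on upstream
confidence scalars — it is exactly as good as the structure predictions
feeding it.
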