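---
title: "Models and methods behind mitocomp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mitocomp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`mitocomp` implements a comparative-mitogenomics workflow for insect
mitochondrial genomes: composition and strand skew, per-gene and
per-codon-position substitution rates, structure discovery in the AT-rich
(control) region, rate–GC regression, and a simulator with planted ground
truth. This vignette explains the models, the tunable parameters, the
numerical choices, and what the synthetic tests do and do not establish.

## Genome model and coordinates

A genome is a circular J-strand sequence with typed features (PCG, tRNA,
rRNA, region) in 1-based inclusive coordinates; a feature wrapping the
origin is stored with `end < start`. Gene names are canonicalized through
an explicit synonym table (COI/COX1 → cox1, ND4L → nad4l, 16S → rrnL, ...);
unknown names fail loudly rather than guess. The leucine and serine tRNA
duplicates are split by anticodon or codon-family tag. The AT-rich region is
defined operationally as the non-coding stretch between the rrnS end and
the trnI start; the GenBank reader adds it when no control-region feature is
annotated and the stretch is at least 50 bp. Ambiguity codes other than N
are rejected on read; N sites are excluded from all counts and deleted
pairwise in distance calculations.

## Composition

All percentages are computed on the non-N length. AT-skew = (A−T)/(A+T) and
GC-skew = (G−C)/(G+C); a skew with zero denominator is reported missing.
Codon-position composition pools nucleotide counts over all PCGs of a
strand group (length-weighted pooling, not genome-weighted averaging), with
terminal stop codons excluded. Translation uses the invertebrate
mitochondrial code (NCBI table 5) throughout — the taxa, the ATA = Met
reading and the ATN/GTG/TTG start-codon inventory all require it.
Fourfold-degenerate families are derived from the code at run time rather
than hard-coded.

While implementing the desk checks we found that three GC-skew values in
the source composition table contradict the base percentages printed in the
same rows (two sign flips and one value that instead matches the other
table's whole-genome average of −0.249). The bundled TSVs reproduce the
printed values; the acceptance test asserts the self-consistent
recomputation for those three rows and the printed skews everywhere else.

## Alignment

Pairwise global alignment (Needleman–Wunsch with affine gaps) is delegated
to `Biostrings::pairwiseAlignment`; a gap of length L costs open + L·extend.
Constants are fixed for reproducibility: nucleotides match +1 / mismatch −1,
gap open 2 / extend 1; proteins PAM120, gap open 10 / extend 1. More than
two sequences are merged center-star ("once a gap, always a gap") around
the sequence with the greatest total pairwise score. Codon alignment is
protein-guided: each CDS is translated (incomplete terminal codon and
terminal stop dropped), the proteins aligned, and the alignment
back-translated, so gaps are whole triplets and the reading frame is
preserved in every row. When all trimmed CDSs have equal length — the
simulator's default, which plants no indels — the pipeline pairs sites
directly, which is exact. Center-star is a standard approximation for small
taxon sets; guide-tree MSA is deliberately out of scope.

## Distances

* **K2p**: K = −½·ln((1−2P−Q)·√(1−2Q)). Saturation (non-positive log
  argument) raises an explicit error; it is never silently truncated.
  When P = Q/2 the formula collapses to the Jukes–Cantor distance, which
  the tests assert numerically.
* **Ti/Tv** is the raw observed transition/transversion ratio.
* **PAM distance**: the Dayhoff rate matrix (exchangeabilities and
  equilibrium frequencies, the same constants distributed with phangorn and
  PAML) is normalized to one expected substitution per site per unit
  distance and eigen-decomposed; expected identity at distance d is
  Σᵢ πᵢ Pᵢᵢ(d), a strictly decreasing curve from 1 to ~0.06. The reported
  distance is the d whose expected identity equals the observed identity
  (monotone root-finding), i.e. t/100 for the matching PAM-t power.
  Identity below the PAM-2000 expectation is a saturation error.
* **Ka/Ks**: original Nei–Gojobori. Per codon, each position contributes
  the fraction of its three possible changes that are synonymous; changes
  to stop codons are skipped while the per-codon site total stays 3 (the
  common implementation convention). Differences average over all orderings
  of the changed positions with equal weight, discarding paths through
  stops (all paths kept if none is valid). pS and pN are Jukes–Cantor
  corrected; pS or pN ≥ 0.75 is a saturation error, and a single-codon
  synonymous difference is therefore saturated by construction — the tests
  pad such cases. The ratio is reported missing when Ks = 0.
* **Group rows**: "Total" rows concatenate gene alignments (sites pooled
  before the distance transform), then average over the n(n−1)/2 pairs;
  saturated pairs are excluded from means and flagged. Pooling before the
  K2p transform matters: because K2p is convex, the pooled total of a
  rate-heterogeneous gene (cox1: position rates 0.076/0.011/0.355) is lower
  than the mean of its positional distances, which is exactly why cox1
  ranks below nad4 on totals while being higher on the positional mean.

## AT-rich structure discovery

* **Tandem repeats** (defaults: unit ≥ 20 bp, ≥ 2.0 copies, identity ≥
  0.85): for each candidate period p the sequence is compared to itself at
  lag p; intervals whose full-period windows pass the threshold are then
  boundary-refined with a short (≤24 bp) rolling window, because a
  full-period window that straddles the repeat edge can pass while 20–30 bp
  of flank leak in. The interval identity is re-checked after refinement;
  the period is canonicalized to its smallest divisor still meeting the
  threshold; copy number is interval length / unit length, reported to one
  decimal (fractional copies are expected).
* **Conserved segments** (defaults: seed k = 10, length ≥ 12, column
  identity ≥ 0.90): exact k-mer seeds are taken from every taxon in turn; a
  seed must match exactly in a majority of taxa, and the remaining taxa are
  placed at their best approximate occurrence (≤2 mismatches, preferring
  positions near the median of the exact matches — homologous control
  regions are roughly collinear). Anchors extend while a local
  rolling-window column consensus stays above the threshold, then ragged
  ends are trimmed. Candidates must pass whole-segment column identity, be
  corroborated by at least two seeds, keep every taxon's agreement with the
  consensus outside the anchor above 0.70 (this kills chimeras where one
  taxon's anchor landed on a non-homologous near-copy), keep the spread of
  relative start positions below 0.35, and survive an all-taxa overlap
  dedup (one locus belongs to at most one segment). Detected tandem-repeat
  intervals can be excluded: repeats are homologous DNA whose internal
  conservation is annotated by the repeat report, not as segments. The
  literal design sketch — exact k-mers shared by all taxa — had ~75%
  per-block sensitivity at 95% cross-taxon identity and was replaced by the
  majority-exact + rescue scheme; measured performance is 0.98–1.00
  sensitivity with zero false segments across 3 × 50 seeded replicates.
* **Poly(N) runs** are maximal single-base runs of a minimum length
  (default 5), any base.
* **Hairpins**: all outward-maximal inverted-repeat pairings with
  Watson–Crick and G·U pairs, stem ≥ 4, loop 3–30, scored by paired-base
  count with best-first non-overlapping selection. This is a combinatorial
  pair counter, not a thermodynamic folder: the source study's mFold free
  energy (−8.76 kcal/mol for its most stable conserved-segment fold) is
  acknowledged but not reproduced.

## Rate synthesis

The per-gene table carries strand, pooled per-position GC content,
group-average K2p (total and per position), PAM distance and Ka/Ks.
The GC–rate relation is ordinary least squares of group-average
per-position K2p on pooled per-position GC content across genes, unweighted
(the study shows simple trend lines); per-gene group averages rather than
per-pair points are the regression units. Rankings sort by pooled total
K2p, ties alphabetical.

## The simulator and its stated world

The generator's defaults are the published study values, planted once:

* architecture: 37 genes in the ancestral insect order, 23 J / 14 N,
  gene lengths typical for spittlebug mitogenomes (~15.5 kb total),
  7-nt PCG–PCG overlaps at atp8/atp6, nad4/nad4l and nad6/cytb sharing the
  ATGATAA motif in coding space, six start-codon kinds (ATN, GTG, TTG),
  complete TAA stops except cox1 (T) and cox2 (TA);
* composition: the published per-position, per-strand base percentages as
  stationary frequencies (J1/J2/J3, N1/N2/N3, tRNA, rRNA, AT-rich);
* rates (per branch on a star tree; pairwise distance = 2 × branch):
  positions 0.060 / 0.0285 / 0.165 (pairwise 0.120 / 0.057 / 0.330),
  J-tRNA 0.037, N-tRNA 0.0675, rRNA 0.045, control region 0.45 (pairwise
  0.90 on the mutable background, landing the whole-region estimate in the
  published 0.3–0.6 band), conserved elements 0.02; κ = 3;
* per-gene positional multipliers: the published per-gene per-position
  K2p values divided by the all-PCG value at that position — so atp8 is
  fastest and cox1 slowest by construction, with the real second-position
  spread (0.011–0.141);
* control region: a 144-bp unit tiled to ~3.6 copies, four conserved
  segments (25/40/35/20 bp; segment 2 carries a planted 8-bp-stem hairpin),
  poly(N) runs of 9/7/6/5 between segments 3 and 4, in an AT-rich
  background totalling ~800 bp;
* GC–rate coupling 0.25: genes fast at positions 1–2 get proportionally
  less GC there and slightly more at position 3, planting the published
  negative/negative/positive slope signs. A stronger coupling (0.5) was
  rejected because, combined with the real positional rate spread, it
  distorted the amino-acid spectrum away from the published top five
  (Leu, Ile, Ser, Phe, Met).

Design choices worth recording:

* **HKY, not literal K2p.** A substitution kernel with equal base
  frequencies drifts an AT-biased ancestor toward uniform composition
  (third-position A+T would fall from ~86% toward ~77% at the planted
  rates), destroying the composition tables the package exists to produce.
  The simulator therefore combines the K2p transition/transversion
  structure with the planted stationary frequencies — an HKY process whose
  expected substitutions per site equal the branch length. Where a property
  requires the estimator's own generating model (the <2% recovery bound),
  pairs are simulated under strict equal-frequency K2p.
* **Analytic truth.** Because K2p applied to AT-biased HKY data is a
  biased estimator of the process distance at high divergence, the truth
  object stores, besides the planted distance 2b, the closed-form
  expectation of the K2p statistic (expected transition/transversion
  proportions from the realized ancestral composition through the HKY
  transition matrix, two branches, plugged into the K2p formula).
  End-to-end recovery tests compare to that expectation — they verify the
  pipeline (extraction, orientation, masks, counting), not the estimator's
  model mismatch, which is characterized separately.
* **No internal stops.** Ancestral codons are sampled excluding stops, and
  a codon that evolves into TAA/TAG is re-evolved from its ancestral state
  (rejection), which keeps realized rates unbiased to first order; start
  codons, stop tails and overlap motifs are clamped (shared across taxa),
  a ~1% dilution accounted for in the recovery tolerances.
* **Concerted repeat evolution.** Evolving every repeat copy independently
  at the control-region rate would erase within-genome copy identity and no
  descendant would show a detectable repeat, contradicting the published
  repeat table; real control-region repeats homogenize by replication
  slippage. The unit evolves at the full rate and is re-tiled per taxon.
* **Poly(N) runs are structural, not columnar, homologs**: offsets and
  lengths are fixed but the run bases are permuted per taxon, otherwise the
  zone itself would be (wrongly) reported as a fifth conserved segment.
* **Purifying selection** for the Ka/Ks property is modelled in
  `simulate_codon_pair` as proposal rejection (nonsynonymous proposals
  accepted with probability 0.1), keeping the truth analytically checkable;
  in whole genomes the position-specific rates already encode the
  selective constraint, so Ka/Ks < 1 emerges without a codon model.
* **Indels** are off by default (site-wise alignment is then exact); an
  option deletes whole codons in one taxon to exercise the
  protein-guided aligner.

## What a green test establishes — and what it does not

The synthetic world reproduces the published architecture, composition,
rate structure and control-region anatomy, and every analytic stage is
verified against planted truth, closed forms, or independent brute-force
oracles (alignment scores by exhaustive recursion at ≤8 residues, hairpins
by exhaustive enumeration at ≤40 bp, Nei–Gojobori counts by hand-enumerated
path averaging, the Dayhoff identity curve by a series matrix exponential).
The generator does not emulate: sequencing or annotation error, gene
rearrangement, length variation of the control region between taxa
(629–1040 bp in the study), heteroplasmy, slippage-generated copy-number
variation, or non-stationary composition. Accession-based checks therefore
run against this stand-in world, not the deposited records — offline
environments cannot fetch them — and agreement with the printed tables is
by construction of the defaults plus estimation, not an independent
re-measurement of the original data. Quantities the study's own software
choices leave underdetermined (the exact Ka/Ks variant, the AT-rich
alignment protocol) are reproduced only qualitatively.

One stochastic caveat: atp8 spans 51 codons, so its estimated total rate
carries a large standard error and the realized fastest gene can flip to
nad2 on a minority of seeds; the acceptance check asserts the ranking on
the analytic expectations and requires strong rank concordance (Spearman)
of the estimates instead of an exact realized order.

## Numerical and degenerate-input conventions

Pairwise deletion of gaps/N everywhere; saturation always raises, and group
averages flag and exclude saturated pairs; skews with zero denominators are
missing, not zero; DP tie-breaks and fixture bytes are deterministic under a
fixed seed (the GenBank writer stamps a constant date); report tables are
tab-separated UTF-8 with ASCII minus signs; empty results are zero-row
tables, never NULL surprises in exported functions.
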