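---
title: "Quantifying chromatin-protection shifts from fragment-length-resolved MNase data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying chromatin-protection shifts from fragment-length-resolved MNase data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mnassp)
```

## The measurement model

MNase digests DNA that is not protein-bound; what survives digestion and
enters a single-stranded library is a census of protections: nucleosomes
(~147 bp), hexasomes that have lost one H2A-H2B dimer (~102–112 bp, or
83–93 bp), tetrasomes (~61–71 bp), and short non-nucleosomal footprints
(<60 bp) concentrated in promoter nucleosome-depleted regions (NDRs). The
package treats a sequencing library as a multiset of genomic intervals
("fragments", BED, 0-based half-open) and every analysis as a function of
fragment **length** and fragment **midpoint** relative to annotated
nucleosome dyads.

Three assumptions underlie the analyses:

1. *Dyad positions are inputs.* Nucleosome dyads (+1…+10 per gene, plus
   −1) come from an external annotation; the package never re-estimates
   them from the data.
2. *Fragment length is protection length.* BED lengths are taken as true
   protected lengths; the read-level rules (truncate at 140 bp, discard
   <35 bp) are applied upstream of alignment and are housed in
   `preprocess_reads()` for completeness.
3. *Rotational positioning is discrete.* Alternative nucleosome
   placements occur at ~10 bp steps around the annotated dyad, so
   occupancy within ±50 bp is summarized at the eleven positions
   −50, −40, …, +50 bp.

## Coverage and normalization

Coverage is computed at 1 bp windows, either whole-fragment (each
fragment adds weight over every bp it overlaps) or midpoint (weight at
`floor((start+end)/2)` only). The per-library weight is
`N = 139,712,364 / total mapped reads`; the constant is arbitrary and only
fixes the scale, and it is exposed as a parameter. Length bins are
inclusive on both ends (142–152 keeps 142 and 152). The midpoint of an
even-length fragment has no centre bp; we round down uniformly, which
cancels in every relative comparison.

Cross-sample comparisons are confounded by digestion extent, so
`match_length_distributions()` equalizes length histograms first. We
implement the strongest reproducible reading of "similar distributions":
for every length L each sample keeps exactly the minimum across samples of
the count at L, drawn without replacement under one seed. After matching,
histograms are identical, not merely similar; whether coarser strata would
suffice is data-dependent and we prefer the exact invariant.

## V-plots, metagenes, difference matrices

A V-plot is the 2-D histogram of (strand-oriented midpoint offset from a
dyad) × (fragment length). Offsets are oriented so downstream of the gene
is positive for both strands. Counting is anchor-centric: a fragment near
two closely spaced dyads contributes once per dyad, the metagene
convention; totals therefore equal (fragment, anchor) pairs, not
fragments. Default extents are ±500 bp for V-plots and ±1000 bp for
metagene profiles, both configurable.

Metagene profiles average coverage across anchors (equal anchor
weighting) rather than pooling fragments; with equal per-gene weighting
the two differ only when libraries are very unevenly distributed across
genes, and averaging keeps a single deep locus from dominating. Occupancy
heatmaps carry one row per gene, anchored at the +1 dyad, ranked by
descending gene length (ties broken by gene id), and difference heatmaps
are elementwise mutant − wild type: loss upstream of a dyad paired with
gain downstream is the signature of a downstream positioning shift.

## The rotational-position shift statistic

For each (gene, nucleosome index) the eleven rotational-position
occupancies are collected from midpoint coverage with a ±2 bp window per
position — wide enough to tolerate end-nibbling jitter, narrow enough that
adjacent 10 bp positions never overlap. Each row is standardized to Z
scores with the *population* standard deviation (the row is the entire
population of positions for that dyad); rows with zero variance map to
all zeros rather than NaN. Z rows are invariant to adding a constant or
positively rescaling occupancy, which removes per-gene depth.

For a mutant vs wild-type comparison, the per-gene difference
ΔZ = Z_mut − Z_wt is the effect size, summarized by its median across
genes at each (index, position) cell. Significance uses the two-sided
Wilcoxon rank-sum test between the mutant and wild-type Z values across
genes at that cell — not a signed-rank on ΔZ, so pairing noise in either
condition inflates neither tail. P-values are Benjamini–Hochberg adjusted
across all cells of one comparison and called at adjusted p < 0.05; both
raw and adjusted values are reported so either convention for starring
cells can be applied. Genes contribute to index k only if they have a +k
dyad, and any index with fewer than `min_genes` (default 10) eligible
genes is skipped with a warning — long-gene quartiles therefore test more
indices than short-gene quartiles, which is a property of the genome, not
of the test. Quartile stratification ranks genes by length (or by an
expression score: summed per-bp nascent-transcription counts over the
oriented window TSS+100…TSS+200) and cuts into contiguous groups of equal
size ±1, ties broken by gene id so the assignment is order-free.

Gene-group × quartile enrichment is
`log2((|G∩Q|/|G|)/(|Q|/|U|))` with hypergeometric one-sided tails (upper
for over-enrichment, lower for depletion; both reported, the tail
matching the sign selected) and BH correction across the table. The
background universe defaults to the stratified genes and can be supplied
explicitly; an empty overlap reports −Inf enrichment with the exact
depletion p.

## What the simulator emulates — and what it does not

`generate_genome()` lays out genes on one synthetic chromosome with
log-normal lengths (median ~1.5 kb, clipped to 0.5–8 kb so length
quartiles are non-degenerate), alternating strands, a +1 dyad 60 bp past
the TSS, 165 bp dyad spacing (the canonical yeast repeat), up to ten
gene-body dyads as gene length allows, and an NDR (default 140 bp)
between the −1 and +1 nucleosome cores holding 1–3 short protein
footprints.

`simulate_digestion()` draws fragments from a mixture over protection
classes (defaults 0.55/0.15/0.08/0.07/0.15 for
nucleosome/hexasome/tetrasome/NDR-short/background — chosen so
nucleosome-length fragments dominate, as in real libraries, while every
class is well sampled). Rotational occupancy decays away from the dyad
with weights (0.04, 0.12, 0.30, 1, 0.30, 0.12, 0.04) over offsets −30…+30
bp; real relative amplitudes are not known precisely, so this profile is
a stand-in and is exposed as a parameter. Hexasome/tetrasome midpoints
are displaced by ±(147−len)/2 with equal probability of proximal or
distal dimer loss — dimer loss moves the protection midpoint, and the
exact magnitude is a modeling choice consistent with the geometry.
End-nibbling is modeled as independent geometric trims at both fragment
ends whose *difference* jitters the midpoint (mean 0.7 bp per end at high
dose, 1.4 at low dose); the drawn per-class length is the observed
post-digestion length. The enzymological 25:1 linker:nucleosomal
cleavage-rate ratio is modeled explicitly in `simulate_cuts()`, which
draws cut events in proportion to per-bp class rates and from which
`estimate_cut_rate_ratio()` recovers the ratio — keeping the digestion
model testable independently of the fragment mixture.

Mutant phenotypes are injected as presets: `"K192N"` drops NDR-footprint
survival to 0.1 at high dose (survival rises to ~0.95 under gentle
digestion, reproducing dose-dependent fragility; digested-away footprints
re-emit as background so totals are conserved) and redistributes
rotational occupancy one 10 bp step downstream at indices ≥ +3 with
magnitude growing along the gene; `"141-305"` keeps the NDR intact but
shifts more strongly and includes +1/+2. Shift probability is
magnitude/10 × a per-length-quartile coupling (0.4/0.8/1.2/1.6), making
power in the shift test length-coupled by construction. Dose is two
discrete levels (low ↔ 32 U, high ↔ 128 U); the contrasts of interest
need no continuous dose model. Randomness runs through per-class
substreams derived from one master seed, so identical inputs give
byte-identical fragments and one class's draw count never perturbs
another's.

The simulator does **not** emulate sequence: no FASTA/FASTQ, no AT bias
of MNase, no mappability structure, no replicate-to-replicate biological
variability, and dyad annotations are exact rather than inferred. Passing
tests on synthetic data therefore demonstrate that the statistics recover
known injected structure at realistic coverage — not that real libraries
are free of the biases above.

## Numerical choices and degenerate inputs

* Midpoint ties round down; bin ends are inclusive; coordinates are
  0-based half-open throughout, with 1-based dyad inputs converted on
  read.
* Zero-variance occupancy rows → all-zero Z rows (no NaN propagation).
* Wilcoxon tests use the normal approximation (`exact = FALSE`); Z values
  are continuous so ties are rare and exact enumeration buys nothing at
  n ≥ 10.
* Dyads within 52 bp of a chromosome edge are dropped (with a message)
  rather than padded.
* `validate_config()` treats unknown keys as warnings and structural
  problems (missing files, min > max bins) as errors.
* bedGraph output is run-length merged at 6 significant digits; reading a
  written track reproduces per-bp values to formatting precision.

## Problem sizes

The test suite and the reproduction script run on 200–400-gene genomes
with 0.3–1.2 million fragments per condition and one million cut events —
sizes at which the V-plot argmax, the 10 bp periodicity, the 25:1 rate
ratio, the NDR dose contrast, null calibration of the shift test
(fraction of raw p < 0.05 within binomial bounds of 0.05) and
quartile-monotone power are all stable across seeds, while a full suite
completes in well under a minute of compute.

## Limitations

Real MNase data carry sequence bias, replicate variability and imperfect
dyad maps that the simulator omits; the shift statistic conditions on the
dyad annotation, so systematic annotation error translates into apparent
shifts; and anchor-centric counting means V-plot totals depend on anchor
density. For real libraries, fragment inputs arrive as BED (one record
per sequenced fragment) and drop into the same pipeline unchanged.
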