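---
title: "Models and methods behind tridram"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tridram}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

tridram analyses assays in which the same fixed nuclei are GpC-methylated
(M.CviPI marks open chromatin in GpC context), DpnII-digested,
proximity-ligated and bisulfite-sequenced. Each sequenced molecule then
reports three things at once: a chromatin contact (which two loci were
ligated), the accessibility of both loci on that single molecule (GCH
calls), and endogenous CpG methylation (HCG calls). This vignette
documents the models, conventions and numerical choices; the package
README shows the corresponding code.

## Read processing

**Junction splitting.** Proximity ligation of two DpnII sticky ends,
followed by fill-in, creates the 8-mer `GATCGATC` at the junction.
After bisulfite conversion the unmethylated C can read as T, so
chimeric reads are scanned for `GATTGATT` and `GATTGATC` (forward) and
`AATCAATC` and `GATCAATC` (reverse); the motif list is a parameter, so
unconverted or other-enzyme junctions can be handled. Reads are cut at
the 8-mer midpoint so each product keeps one 4 bp half-site — the two
half-sites genuinely belong to the two partner fragments, and the
midpoint is the only placement that preserves every base exactly once.
Products shorter than 20 bp (the usual adapter-trimming floor) are
dropped. Overlapping motif hits are all honoured; cut points are
deduplicated.

**Fends.** Contact coordinates are projected onto restriction fragment
ends: a + strand read maps to the nearest cut site at or downstream of
its position, a − strand read to the nearest at or upstream. Cut site
*j* of a chromosome carries fends 2*j*−1 (upstream side) and 2*j*
(downstream side); positions beyond the terminal sites go to
chromosome-terminal pseudo-fends (0 and 2*n*+1). Deduplication keeps
the first pair per unordered fend key — two read pairs landing on the
same fend pair are, at the assay's resolution, copies of one ligation
product.

**NOMe contexts.** Each cytosine is classified by its flanks on its own
strand: `HCG` (preceding base not G, following base G) is the
endogenous-CpG channel; `GCH` (preceding G, following not G) is the
M.CviPI accessibility channel; `GCG` is ambiguous — both enzymes can
have produced the mark — and is excluded from both channels; `HCH`
carries no signal. Minus-strand cytosines are evaluated on the reverse
complement; a missing flank at a chromosome edge counts as non-G.

## Bulk tracks

Pileups keep positions with at least `minCov` calls (5 for a single
replicate, 10 for merged replicates, both parameters). Metaprofile bins
with no covered cytosine are missing rather than zero — a zero would be
a biological claim that absence of coverage cannot support — and
per-bin means weight features equally rather than by call count, so
deeply covered features cannot dominate the profile shape.

Conversion QC uses two spike-in classes. On unmethylated lambda DNA
every methylated CpG call is a conversion failure, so the conversion
efficiency is the unmethylated percentage of lambda HCG calls. Fully
methylated controls (pUC19; in-situ-GpC-methylated lambda) measure the
detection (false-negative) rate as their methylated percentage. Missing
lambda calls are an error; missing methylated controls yield an NA
detection rate with a warning, since conversion-only QC is routine.

## The single-molecule co-accessibility model

The assay's core question: are the accessibility states of the two loci
joined by one ligation product dependent, or does each locus open and
close independently? For filter-interval sets A and B (e.g. convergent
CTCF motifs under ChIP-seq peaks):

1. each methylation call is assigned to its nearest interval midpoint
   (binary search; ties toward the lower coordinate) and retained if it
   lies within `window/2` of it ("100 bp window" = midpoint ± 50 bp);
2. reads retaining no call are discarded; a read landing in several
   windows keeps its best-covered anchor;
3. mate 1 is anchored to A and mate 2 to B, the symmetric assignment is
   pooled, and mates are merged on the full read name, so only pairs
   spanning both sets survive. Separation between anchor midpoints must
   lie within `[minSep, maxSep]`; an orientation rule can require
   convergent motifs (+ at the lower coordinate). Presets follow the
   long-range analyses: CTCF pairs ≥ 1 kb convergent; CRE–TSS ≥ 5 kb;
   adjacent TF motif pairs use a 50 bp window and 100–300 bp
   separation;
4. per mate, the mean over retained GCH calls estimates the molecule's
   accessibility at that anchor; the (meanA, meanB) matrix is clustered
   with seeded k-means (k = 4, 10 restarts) and clusters relabelled by
   descending grand mean, so cluster 1 is open/open;
5. mates are binarized (open iff mean ≥ 0.5, at least 1 call; both
   parameters) and tested with the two-sided Fisher exact test. The
   reported odds ratio is the sample cross-product, with the
   Haldane–Anscombe 0.5 correction when a cell is empty; a zero margin
   leaves it undefined with p = 1. Because the binarization rule and
   the "co-accessible fraction" are not uniquely determined by the
   field's practice, the fraction is reported both threshold-derived
   (open/open share) and cluster-derived (top-cluster share).

A read pair qualifying in both mate-to-set assignments keeps one
observation, selected by swap-invariant keys (total call support, then
anchor coordinates, then sorted means). This makes exchanging the roles
of A and B exactly transpose the contingency table — a symmetry the
analysis should have, and which a "first assignment wins" rule silently
breaks.

The randomized control re-runs the statistics on read pairs where
exactly one mate overlaps a filter interval; the free mate's calls are
taken around the midpoint of its own call span, and the control is
subsampled (seeded) to the observed-set size. This isolates the
contribution of feature anchoring itself: under a uniform open
probability *p* both the anchored and the control open/open fractions
converge to 100·p².

**Co-methylation** runs the identical machinery on HCG calls; "open"
then reads "methylated", and cluster ordering is unchanged (cluster 1 =
most methylated).

## The simulator

`simConfig()` fixes the study conditions: a 2 Mb test chromosome,
DpnII-like cut sites every ~300 bp, GpCs every ~15 bp and CpGs every
~75 bp (matching mammalian dinucleotide densities to within the
factor-of-two that matters here), distance decay `P(s) ∝ s^(−α)` with
α = 1 above a 1 kb floor, four TAD boundaries with a 3× within-TAD
contact boost, a 250 kb compartment checkerboard with a 2× same-label
boost, 100 bp reads, GCH emission probabilities 0.85 (open molecule)
and 0.05 (closed), a 0.7 CpG methylation baseline and a 2% conversion
failure rate ε applied symmetrically (unmethylated→methylated:
conversion failure; methylated→unmethylated: detection failure). Where
the source conditions leave a value open these defaults were chosen
once as field-realistic and are not tuned.

Anchored read pairs draw a latent (open_A, open_B) per molecule from
the joint Bernoulli law solved by `solveJointBernoulli()`: given
marginals p₁, p₂ and odds ratio θ, p₁₁ is the admissible root of
(θ−1)x² − ((θ−1)(p₁+p₂)+1)x + θp₁p₂ = 0 (the product of the marginals
at θ = 1). Latent accessibility is per molecule, not per locus — the
single-molecule framing under test — so locus-level persistent states
are deliberately out of scope. One master seed drives fixed per-stage
substreams, so adding a stage never perturbs earlier draws and all
outputs are byte-reproducible.

What the simulator does *not* model: sequencing error beyond ε,
footprint shape around bound factors (emission probabilities are flat
within the window), trans contacts, copy-number or mappability
structure, and locus-to-locus variation in GpC density. Passing
recovery tests therefore demonstrates correctness of the estimators
under the stated generative model, not robustness to every artefact of
real libraries.

## Contact statistics

**Expected model.** All observed/expected statistics share one
distance-only expected model: the per-diagonal mean contact count,
constrained to decay monotonically by an isotonic
(pool-adjacent-violators) fit. PAVA pools exactly those sparse
long-range diagonals whose sample means invert the decay, while leaving
any monotone input unchanged — so an obs = exp map scores identically
zero everywhere, a calibration property the tests rely on. (An earlier
log-binned smoother left ±0.06 log2 residue on pure power-law maps and
was dropped for this reason.) This transparent model deliberately
stands in for kNN-based normalization engines, which are external
tools; it normalizes distance, not local coverage.

**Insulation and boundaries.** For each 1 kb bin the contacts crossing
it are summed over the upstream-flank × downstream-flank rectangle
(±250 kb default) and compared with the expected-model sum over the
same cells: score = −log2((obs+1)/(exp+1)), sign-flipped so boundaries
are maxima. The expected rectangle sum is position-independent, so it is
computed once. Boundaries are bins above the genome-wide 90% quantile
that are maximal within ±2 kb, plateau ties resolving to the lowest
coordinate. Edge bins within one flank are NaN.

**Rescaled TAD pileups** extend each TAD of length L by L on both
sides and sample the 3L region onto a 100×100 grid of log2 obs/exp
(nearest-bin sampling), averaging across TADs; a companion per-grid-bin
track profile (methylation or accessibility) uses the same coordinates.

**Compartments.** The eigenvector is the leading eigenvector of the
correlation matrix of the obs/exp map at 250 kb bins, zero-coverage
bins masked; the sign is oriented by an external track (A = more
accessible) when given, else the first entry is made positive. A
constant map has no defined correlations and is flagged unreliable.
Compartment strength is (AA+BB)/(AB+BA) over cis bin pairs ≥ 10 Mb
apart, computed on count-normalized obs/exp sums (i.e. a ratio of
means). The normalization is a deliberate choice: a ratio of raw sums
confounds contact preference with the number of same- versus
cross-label pairs — a structureless uniform map would not score 1 —
whereas the ratio of means is exactly 1 there and exactly the planted
contrast on two-level constructions.

**Aggregate pair enrichment** stacks log2((obs+1)/(exp+1)) submatrices
centred on anchor pairs. The centre statistic is the mean over the
central nine bins; each corner is a 3×3 block; the centre/corner ratio
is formed on the linear enrichment scale, corners averaged together
(per-corner ratios are also emitted). Per-pair scores are the mean
log2 enrichment in a 10 kb window around each pair separately —
a distance-normalized stand-in for kNN-smoothed per-pair scores —
suitable for Wilcoxon rank-sum comparisons between pair classes.

**Peak-to-gene association.** Features within ±5 kb of a TSS go to the
nearest TSS. Distal features go to the same-TAD TSS with the highest
contact score among candidates 5 kb–2 Mb away, ties to the nearest;
features outside any TAD stay unassigned. With the default promoter
window the sub-5 kb floor is unreachable in the distal branch (any such
TSS would have triggered the promoter rule); it becomes active whenever
the promoter window is configured tighter, and is kept for that reason.

## Numerical choices and degenerate inputs

* Pseudocount ψ = 1 count in every log ratio (configurable).
* Coordinates are 0-based half-open internally; BED/bedGraph writers
  keep 0-based starts, the `.pairs` and call-TSV writers emit 1-based
  positions as those formats conventionally do.
* k-means uses 10 restarts under a fixed seed; degenerate duplicate
  observations are handled by base `kmeans`.
* `dedup(dedup(x)) = dedup(x)`; junction-free reads are fixed points of
  splitting; empty inputs return empty tables rather than errors
  (except where a result is undefined, e.g. decay with no qualifying
  pairs).
* Fisher p-values come from `stats::fisher.test`; the odds ratio
  reported is the cross-product estimate, not the conditional-MLE value
  that `fisher.test` prints — the two differ noticeably in small
  tables, and the cross-product form matches the 2×2 definition used
  throughout.

## Problem sizes

The shipped tests and the acceptance script use a 2 Mb single-chromosome
genome, 20,000–50,000 contact pairs, 500-bin insulation maps and
100-bin compartment maps — sizes at which every planted parameter is
recovered comfortably within its tolerance while the whole suite runs
in a few minutes on one core. These sizes are the package's chosen
validation conditions; all of them are config parameters.

## Known limitations

* The expected model normalizes distance only; locus-specific coverage
  biases (mappability, GC, copy number) are untouched — real-data
  compartment strengths will differ from kNN-normalized published
  values.
* The randomized-control construction (span-midpoint window for the
  free mate, seeded size matching) is one reasonable reading of a
  control that published analyses do not fully specify.
* Whether a "co-accessible fraction" should be threshold- or
  cluster-derived is genuinely ambiguous; both are reported.
* Junction splitting assumes exact motif matches; one sequencing error
  in the 8-mer hides a junction. Downstream mapping tolerates this (the
  chimeric read simply stays unmapped), but junction yield is a slight
  undercount.
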