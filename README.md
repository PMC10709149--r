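# tridram

Analysis toolkit for multi-omic assays that read out the **3D genome**,
**chromatin accessibility** and **DNA methylation** from the *same*
proximity-ligated, bisulfite-converted molecules. In such assays nuclei
are treated with the GpC methyltransferase M.CviPI (which marks open
chromatin in GpC context, the NOMe-seq principle), digested with DpnII,
proximity-ligated, and bisulfite-sequenced: each read pair therefore
carries Hi-C contact information *and* per-molecule GpC accessibility
(GCH) and endogenous CpG methylation (HCG) calls.

The package covers the computational path from raw reads to statistics:

* **Read processing** — splitting chimeric reads at bisulfite-converted
  DpnII ligation junctions (`GATTGATT`, `GATTGATC`, `AATCAATC`,
  `GATCAATC`), restriction fragment-end (fend) assignment, contact
  deduplication on unordered fend keys, and NOMe cytosine-context
  classification (HCG / GCH / GCG-ambiguous).
* **Bulk tracks** — coverage-filtered per-cytosine pileups (5× / 10×
  floors), spike-in bisulfite conversion QC, strand-aware
  feature-centred metaprofiles.
* **Single-molecule co-accessibility** — the core assay: for read pairs
  whose two mates anchor to two genomic features (e.g. convergent CTCF
  motifs ≥ 1 kb apart), per-mate mean GpC accessibility is computed from
  calls within a 100 bp window around each feature midpoint, clustered
  (k-means, k = 4), binarized, and tested for dependence with the
  two-sided Fisher exact test. For mates called open (`o`) / closed
  (`c`) the report contains the contingency table
  `[[n_oo, n_oc], [n_co, n_cc]]`, the cross-product odds ratio
  `(n_oo·n_cc)/(n_oc·n_co)`, the co-accessible fraction `100·n_oo/N`,
  and a randomized control in which only one mate must overlap a
  feature. The same machinery runs on the HCG channel
  (co-methylation).
* **Contact statistics** — distance-decay curves `P(s) ∝ s^(−α)`,
  insulation scores (1 kb bins, ±250 kb flank, sign-flipped so TAD
  boundaries are maxima), boundary calling (local 2 kb maxima above the
  genome-wide 90% quantile), rescaled 100×100 TAD pileups, A/B
  compartment eigenvectors (250 kb bins) and compartment strength
  `(AA+BB)/(AB+BA)` over ≥ 10 Mb pairs, APA-style aggregate pair
  enrichment (central nine bins vs corner blocks), per-pair contact
  scores, and the promoter/distal peak-to-gene association rule
  (±5 kb promoter; otherwise best-scoring same-TAD TSS at 5 kb–2 Mb).
* **A seeded synthetic-data generator** with planted ground truth —
  power-law contact decay, TAD blocks, compartment checkerboards, and
  anchored read pairs whose per-molecule open/open states follow a
  joint Bernoulli law with configurable marginals and odds ratio — so
  every stage is testable without sequencing data.

## Worked example

Simulate 5,000 anchored read pairs whose latent open/open states have
marginal open probability 0.3 at both anchors and odds ratio 3, emit
noisy GpC calls, and run the full single-molecule path:

```r
library(tridram)

cfg <- simConfig(nPairs = 0L, nAnchoredPairs = 5000L,
                 p1 = 0.3, p2 = 0.3, oddsRatio = 3, seed = 42L)
sim   <- simulateContactPairs(cfg)
calls <- simulateReadMethCalls(cfg, sim$pairs, sim$truth)

af <- cfg@anchorFeatures
anchors <- GenomicRanges::GRanges(af$chrom,
             IRanges::IRanges(af$pos + 1, width = 1),
             strand = af$strand, label = af$label)
res <- coAccessibility(calls,
                       anchors[grepl("^A", af$label)],
                       anchors[grepl("^B", af$label)],
                       window = 100, minSep = 1000, k = 4, seed = 7,
                       control = FALSE)
res
#> CoAccessibilityResult: 5000 read-pair observations
#>   odds ratio 2.815, Fisher p 2.01e-57
#>   co-accessible: 14.4% (threshold), 14.4% (top cluster)
contingencyTable(res)
#>         B
#> A        open closed
#>   open    722    827
#>   closed  817   2634
```

The estimated odds ratio 2.82 recovers the planted value 3 (the joint
law at θ = 3, p₁ = p₂ = 0.3 gives p₁₁ = 0.141, i.e. ~14% open/open
molecules, matching the reported co-accessible fraction), and the
Fisher test rejects independence decisively.

A complete end-to-end demonstration — simulation, junction/fend
processing, pileups, QC, single-molecule statistics, insulation/TAD
boundaries, compartments, decay — runs with:

```r
runPipeline("demo_run", seed = 1)
```

and writes every intermediate in plain-text formats (FASTA, 4DN-style
`.pairs`, call TSV, BED, bedGraph, JSON) plus a checksummed manifest;
reruns with the same seed are byte-identical. A thin command-line
wrapper with the same stages is installed at
`system.file("scripts/tridram", package = "tridram")`.

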