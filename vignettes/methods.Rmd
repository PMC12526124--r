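---
title: "Methods: enhancer landscapes, TF co-binding and core regulatory circuits"
author: "regcircuit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: enhancer landscapes, TF co-binding and core regulatory circuits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`regcircuit` implements a multi-omic integration for a two-condition
chromatin design: a condition in which a chromatin-remodeler subunit is
absent and one in which it has been restored. The pipeline links
condition-specific (gained) enhancers, lineage-specific transcription-factor
(TF) binding, and transcription into a hub-centred core regulatory circuit
(CRC):

1. **Enhancer calling.** H3K27ac constituent peaks are stitched when within
   12.5 kb of each other; each stitched region is scored by the summed
   per-bp ChIP signal minus the summed per-bp input signal, floored at zero.
   With both axes of the ascending rank/signal curve min-max scaled to
   [0, 1], super-enhancers (SEs) are the regions whose scaled signal lies
   strictly above the first point, scanning from low signal, at which the
   curve's discrete slope (central differences, one-sided at the ends)
   exceeds 1. The cutoff is reported on the original signal scale. Gained
   constituent enhancers are the restored-condition H3K27ac peaks with zero
   base-pair overlap with any absent-condition peak (whole-peak
   subtraction; a base-pair residual mode is also available).
2. **Chromatin states.** Each TF peak receives exactly one of five labels by
   a precedence rule: H3K4me3 overlap makes an *active promoter*; otherwise
   H3K4me1 plus absent-condition H3K27ac makes a *remodeler-independent
   active enhancer*; otherwise H3K4me1 plus restored-condition H3K27ac makes
   a *remodeler-dependent active enhancer*; otherwise H3K4me1 alone makes a
   *poised enhancer*; anything else is *unclassified*. The fifth label is an
   explicit design addition: four states do not cover all mark
   combinations, and the catch-all keeps the partition exhaustive and
   auditable. Peaks carrying H3K27ac in both conditions at H3K4me1+ loci
   are labelled independent (the absent-condition branch is tested first):
   activity that survives without the subunit is not evidence of
   dependence.
3. **Co-binding.** TF peaks are extended 150 bp bilaterally from their
   centers (slightly more than one nucleosomal unit) and tabulated over a
   fixed-width genomic-bin universe (default 1 kb) into a 2×2 table per TF
   pair; significance is the two-sided Fisher exact probability (sum of
   hypergeometric masses no greater than the observed table's, at fixed
   margins), with Benjamini–Hochberg adjustment across pairs. The binned
   universe is a design choice: a Fisher test needs a well-defined universe
   of units, and fixed-width bins make one; the bin width is exposed and
   reported with every result.
4. **Transcriptional regulatory networks (TRNs).** Gained enhancers are
   assigned to genes either by the single-nearest TSS of the enhancer
   center (ties to the lexicographically smaller gene id) or by ≥ 1 bp
   overlap with a curated element-to-gene interaction table
   (many-to-many). The TRN keeps links whose target genes show increased
   expression: FDR < 0.05 and log2 fold change strictly > 0, both
   config-exposed. Genes absent from the DE table are non-significant by
   definition.
5. **Enrichment.** Over-representation is upper-tail hypergeometric with BH
   adjustment across terms. Preranked enrichment is the running-sum
   statistic: hits increment by |score|^w normalised over hits (w = 1
   default, w = 0 classic), misses decrement by 1/(N − n_hits); ES is the
   maximum deviation. Significance is by gene-label permutation, one-sided
   toward the observed ES sign and conditional on same-signed permutation
   statistics, with the (1 + b)/(n_same_sign + 1) correction. The
   sign-conditional comparison is deliberate: the ES of a ranked list is a
   signed max-deviation statistic, and comparing an observed positive ES
   against the pooled two-signed permutation distribution double-counts the
   sign selection, deflating null p-values; conditioning restores null
   uniformity (verified by a KS check in the test suite).
6. **Network and CRC.** TRN genes are projected onto a protein-protein
   interaction (PPI) graph. Edge enrichment uses a transparent binomial
   null: with background density ρ = E / C(V, 2), the observed edge count m
   among n selected nodes is compared to Binomial(C(n, 2), ρ) via
   P(X ≥ m). *Integration* of a node is its within-subgraph degree (direct
   interactions with other network members); ties rank lexicographically.
   The CRC is an explicitly chosen hub plus its direct neighbours within
   the subgraph. Hub choice is manual by design — no defensible automatic
   rule exists for preferring, say, the second-most-integrated node — but
   the integration table makes any such statement checkable. Circuit
   conservation between models is upper-tail hypergeometric on the member
   overlap.

# Coordinate and overlap conventions

Coordinates are 0-based half-open (BED convention) everywhere; GTF-style
inputs are converted on read. Overlap means ≥ 1 shared bp throughout.
Center extension uses center = floor((start + end)/2); a 0-flank extension
returns the 1-bp interval [center, center + 1) since zero-width intervals
are not representable. Interval arithmetic is delegated to
GenomicRanges/IRanges internally; the test suite checks every operation
against independent per-bp boolean-array oracles.

# Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `stitch_gap` | 12,500 | bp | published ROSE default |
| `tss_exclusion_window` | 0 (off) | bp | ROSE's exclusion flag status is unknown for the source analysis; off, configurable |
| `extend` | 150 | bp | just over one nucleosomal unit, for co-binding detection |
| `bin_width` | 1,000 | bp | co-binding universe resolution |
| `fdr_max`, `lfc_min` | 0.05, 0 | — | "increased expression" rule (exclusive bounds) |
| `promoter_window` | 2,000 | bp | active promoter = H3K4me3 peak center within ±2 kb of a TSS |
| `n_perm` | 1,000 | — | permutation resolution vs cost |

Signal units are arbitrary (no depth normalisation); cross-condition SE
comparisons therefore require same-library-size tracks, which the
synthetic generator enforces by construction. Whether ranked-enhancer
curves use summed or per-bp mean signal is a free choice; summed is the
default, `stat = "mean"` is available.

# The synthetic study design

`generate_synthetic_data()` emulates the two-condition design end to end
with planted ground truth, so that every stage can be tested closed-loop
without any external download. Defaults (all config-exposed, chosen once):

* 2 chromosomes × 1 Mb with 200 genes on a regular TSS lattice
  (spacing ≈ 9.9 kb). Planted distal elements occupy alternate gene slots
  and sit 2.4–4.7 kb downstream of their gene's TSS — inside half the gene
  spacing, so nearest-TSS assignment provably recovers the planted target,
  and far enough apart that 12.5 kb stitching never bridges neighbouring
  genes' elements.
* 40 restored-only enhancers (6 of them three-peak SE clusters), 30 shared
  enhancers, 10 poised regions, 4 absent-condition promoter-anchored SE
  clusters.
* Piecewise-constant signal tracks: background 1.0, enhancer peaks 5×,
  SE peaks 25×, input flat at 1.0. The ~10× separation between the top
  regular region and the SE cluster scores makes the tangent-cutoff
  behaviour analyzable: the slope-1 crossing lands at the last regular
  region, and exactly the planted clusters end up strictly above it.
* Three TFs bind each planted enhancer with probability 0.8 in the
  restored condition and are promoter-localised with probability 0.8 in
  the absent condition; 30% of promoters also carry restored-condition TF
  peaks, plus a handful of unmarked background sites, so all five states
  occur.
* The DE table is generated directly (gene, log2FC, FDR) rather than from
  simulated counts — differential testing is upstream of this pipeline.
  Planted targets draw log2FC ~ N(2, 0.25) with FDR < 0.05; all other
  genes draw log2FC ~ N(0, 0.25) with FDR ≥ 0.05.
* The PPI background is Erdős–Rényi over the 200-gene universe at density
  0.03; the hub (an SE-bearing planted target) is wired to every planted
  upregulated target. Ground truth for the CRC is recorded from the
  emitted edge list itself, so the closed loop tests the whole
  file-write/read/graph path.

All randomness flows from one seeded generator: identical (config, seed)
produce byte-identical files, which the determinism tests assert via
checksums.

**What the generator does not emulate:** read-level noise, peak-caller
false positives/negatives, irregular gene density, mappability artefacts,
depth differences between libraries, or correlated DE noise. Passing the
closed-loop tests therefore demonstrates correctness of the integration
logic under clean planted structure — not robustness of the statistics to
the failure modes of real ChIP-seq, which are upstream of this pipeline's
contract.

# Numerical choices and degenerate inputs

* Tangent cutoff: ties resolve toward fewer super-enhancers (strictly
  above the cutoff); a curve whose slope never exceeds 1 (e.g. perfectly
  linear) yields no SEs; identical signals yield none, with a warning. The
  call is invariant under positive affine rescaling of all signals.
* Fisher: degenerate margins (an empty row or column) give p = 1 and an
  undefined odds ratio; the sample odds ratio is reported, Inf when the
  denominator is zero with a nonzero numerator.
* Nearest-TSS ties break lexicographically by gene id; intervals on
  chromosomes absent from the annotation are flagged NA (dropped with a
  warning at link assignment).
* Enrichment with a gene set saturating the ranking returns ES = 1;
  an empty intersection is an error.
* Binomial edge enrichment with ρ = 0 and observed edges flags an
  inconsistent background.

# Calibration test design

Two acceptance properties assert frequentist calibration under a null, and
both use designs chosen for adequate resolution of the discrete test
statistics: the co-binding null places 100 point peaks on a 1.5 Mb
chromosome tiled into 2 kb bins (point peaks extended to 300 bp occupy
essentially one bin each, so bins are near-independent; wide peaks spanning
several bins would inflate type-I error through spatial autocorrelation,
which is a property of the simulation design, not of the test), and the
edge-enrichment null selects 20 of 40 nodes at background density 0.3,
where the exact rejection probability of the binomial tail at α = 0.05 is
0.0499. Both empirical rates are required to fall inside the binomial 95%
CI around 0.05 over 500 seeded replicates.

# Problem sizes

The test suite and the acceptance script run everything at the toy scale
above: the full six-stage pipeline completes in roughly two seconds, the
complete suite in a few minutes. The hub-ranking replication (100 seeded
generator replicates) uses a half-scale design (2 chromosomes × 0.5 Mb,
100 genes, 25 gained enhancers) purely to keep the replicate loop brisk;
the planted-hub property it checks is scale-free.

# Known limitations

* The Fisher universe is binned genome, not a peak-count permutation
  null; absolute p-values depend on the bin width (always reported).
* The binomial edge-enrichment null ignores degree heterogeneity; a
  degree-corrected null would be stricter for hub-heavy selections.
* "Integration" is plain degree; betweenness is available as a secondary
  metric but never the default.
* The curated interaction mode treats the supplied element-to-gene table
  as authoritative; no re-scoring of interaction confidence is attempted.
* No BAM/FASTQ handling, no peak calling, no count-level DE, no motif
  analysis, no GO DAG propagation, no network visualisation — all upstream
  or out of scope.
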