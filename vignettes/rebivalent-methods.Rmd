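---
title: "Methods: sequential-ChIP analysis of bivalent chromatin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequential-ChIP analysis of bivalent chromatin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rebivalent)
```

## The problem

Bivalent chromatin is the co-occurrence of the activating H3K4me3 and the
repressive H3K27me3 mark on opposite tails of the same nucleosome, a state
characteristic of poised developmental promoters in embryonic stem cells.
Calling a region bivalent from two *independent* single-mark ChIP-seq
experiments ("in-silico overlap") cannot distinguish true co-occurrence from
two confounders:

* **allelic heterogeneity** — one allele carries H3K4me3, the other
  H3K27me3, in every cell;
* **cellular heterogeneity** — one subpopulation of cells carries H3K4me3,
  another H3K27me3.

Sequential ChIP (reChIP) resolves this: chromatin is immunoprecipitated with
the first antibody, eluted, and re-immunoprecipitated with the second, so
only fragments carrying *both* marks survive both rounds. This package
implements the complete analysis for such experiments — peak calling,
reciprocal bivalent-region calling, confidence stratification, promoter
classification, QC metrics, and differential bivalency — together with a
generative simulator of the assay so every stage is testable without
sequencing data.

## The simulator

`sim_config()` / `build_truth()` / `simulate_sample()` implement a
population-of-cells model:

* Nucleosomes sit on a fixed spacing grid (default 200 bp; no positional
  jitter, which keeps truth intervals exact — jitter would add nothing the
  downstream pipeline tests). Each of `n_cells` cells (default 2,000) is
  diploid, so a position carries `2 * n_cells` independent nucleosome units.
* Designated regions (placed uniformly at random, non-overlapping, at least
  two fragment lengths apart) carry a state: `K4_ONLY`, `K27_ONLY`,
  `BIVALENT`, `ALLELIC_HET` (allele 0 gets H3K4me3, allele 1 H3K27me3) or
  `CELLULAR_HET` (a fraction `het_fraction` of cells gets H3K4me3, the rest
  H3K27me3). The designated mark is present with probability `mark_prob`
  (default 0.8); everywhere else — including the non-designated mark inside a
  region, where the model is deliberately conservative — marks appear at the
  background rate `background_mark_prob` (default 0.001).
* An immunoprecipitation round captures a fragment with probability
  `capture_specific` (default 0.3) when the fragment carries the antibody's
  target mark, else `capture_nonspecific` (default 0.003; also the IgG
  capture rate). Between rounds a captured fragment survives elution with
  probability `elution_efficiency` (default 0.8); the second round
  additionally retains any first-round fragment with the mark-independent
  carry-over probability `carryover` (default 0.002). Both histone-tail
  marks travel with the fragment — this is the mechanism that makes the
  two-round assay specific for bona fide bivalency.
* The surviving pool is subsampled without replacement to `depth` fragments
  (default 500,000); if fewer survive, all survivors are emitted with a
  warning rather than resampled.

Identically distributed (cell, allele) units at a position are aggregated
and each round is drawn as binomial thinning per mark combination; because a
thinned Bernoulli chain is a Bernoulli with the product probability, this is
distributionally identical to simulating every unit, at a small fraction of
the cost.

The default capture/carry-over values are not measured quantities — no
quantitative estimates of antibody efficiency or carry-over magnitude exist
for this assay — they were chosen once so that the simulated assay
reproduces the qualitative behaviour of the real protocol's controls
(IgG–IgG FRiP well below 0.1, strong reChIP enrichment, IgG-as-second-IP
mirroring) and are exposed in the configuration, not asserted as claims.

What the simulator deliberately omits: PCR duplication, sequencing error,
mappability structure, antibody cross-reactivity with H3K4me2, and
MNase-vs-sonication fragment-length differences. Passing tests therefore
demonstrate the pipeline's logic under a clean generative model, not its
robustness to every artefact of real libraries.

Three perturbation modes mirror the assay's control experiments:

* `TAZ` erases all H3K27me3 after mark assignment (emulating Ezh2
  inhibition). The second round then captures only nonspecifically, so the
  reChIP yield collapses in both orientations. Note what does *not* happen:
  within the residual sample, fragment proportions still mirror the first
  IP's enrichment, exactly as with IgG as a second antibody — a failed
  second round subsamples the first. The depletion is therefore measured as
  absolute bivalent-region yield relative to the unperturbed assay (about
  1–2% residual at defaults), which is what the qPCR-style readout of the
  real control measures.
* `DKO` treats a seeded fraction (default 10%) of bivalent regions as having
  lost both marks, emulating knockout of a priming factor that maintains
  bivalency at a subset of promoters.

## Peak calling

`call_islands()` is a Poisson island caller for diffuse histone marks,
equivalent in structure to the classical bin-and-chain approach: the genome
is tiled into 100-bp bins; fragments are assigned to bins by midpoint (exact
count conservation, which the Poisson model needs); a bin is *eligible* when
its count exceeds the control-derived expectation at upper-tail probability
`window_p0` (default 0.2, the classical default; the study protocol fixes
only the FDR cutoff); eligible bins are chained into islands bridging at
most `gaps_allowed` (default 1) consecutive ineligible bins; islands are
scored by the Poisson upper tail of their summed count against their summed
expectation and filtered by Benjamini–Hochberg FDR (default 0.05).

The per-bin expectation is `max(control * T/C, T * bin / genome)`: the floor
prevents zero-control bins from being free enrichment, a case the classical
tools handle internally without documenting how. The fold-change uses a 0.5
pseudocount, the smallest symmetric stabiliser. Post-filters retain peaks
with `log2FC > 2` and `FDR < 0.05` and remove blacklist overlaps. This
caller is not a bit-compatible clone of any named tool; it is validated by
its statistical properties (null identity, null FDR control, recovery of
constructed enrichments) and cross-checked against brute-force oracles.

An effective-genome-fraction correction is omitted: simulated genomes are
fully mappable. The pipeline performs no duplicate removal.

## Bivalency calling and classification

Replicate peak sets are reduced to consensus by iterated intersection
(overlap segments, merged). A region is *reciprocally bivalent* when a
K4-K27 consensus peak overlaps (>= 1 bp) at least one K27-K4 consensus peak;
the K4-K27 interval represents the region and the supporting peaks are
recorded, so the one-sided choice of representative is auditable. Each
bivalent peak is then stratified against the total single-ChIP peak sets
into `HC` (both totals), `K4B` (total H3K4me3 only), `K27B` (total H3K27me3
only) or `LC` (neither); the four classes partition the set and
`classify_peaks()` asserts it.

`in_silico_comparison()` quantifies the heterogeneity confounder: the merged
intersection of the two total peak sets is the putative in-silico bivalent
set; members with no reciprocal reChIP support are its false positives. On
simulated data the heterogeneous regions are flagged almost unanimously by
the in-silico overlap yet essentially never by the reciprocal call — the
package's central demonstration.

Promoters are windows of TSS ± 1.5 kb (strand-aware, clipped at chromosome
ends; duplicate gene names keep the first record). A promoter inherits the
highest-priority class among its overlapping bivalent peaks under
`HC > K4B > K27B > LC`; the assignment is independent of peak order.

## QC metrics

* `log2_cpm_per_bp()`: fragment count per region, normalised to counts per
  million and per bp of region width, floored at `2^-10` before the log so
  empty regions are finite (the floor is configuration-exposed; the choice
  of clamp follows the min-value convention of interactive genomics
  browsers).
* `frip()`: fraction of a library's fragments overlapping at least one peak,
  each fragment counted once even when it spans several peaks — this is what
  bounds the score in [0, 1].
* `profile_matrix()`: regions recentred to centre ± 5 kb, 100 equal bins,
  mean CPM/bp per bin, 99th-percentile masking, global max scaling to
  [0, 1]; column means give the average profile with every region weighted
  equally.
* `downsampling_curve()`: seeded subsampling of every library at a grid of
  fractions with an arbitrary pipeline closure re-run per fraction. Note
  that raw peak *count* is not monotone in depth under sparse background
  (islands split at intermediate coverage); region recovery is the monotone
  quantity and is what the package's tests assert.

## Differential bivalency

Counts are taken at consensus reChIP peaks; normalisation factors come from
trimmed-mean-of-M-values (TMM) over genome-wide 10-kb bin counts (all-zero
bins dropped), with the classical trims (30% of M, 5% of A), the
upper-quartile reference-selection rule and precision weights of the
method's original description, rescaled to geometric mean one. The
normalisation corrects compositional bias; sequencing depth enters through
the library sizes themselves.

The two-group test is a negative-binomial likelihood-ratio test authored in
this package: per-region method-of-moments dispersion with a leverage
correction for the two fitted group means, shrunk toward the pooled common
dispersion with `prior_weight` (default 20) pseudo-observations; NB rates
fitted by Newton iterations with effective library sizes as offsets; a 1-df
chi-square LRT; BH correction across regions. It is equivalent in spirit —
not numerically identical — to quasi-likelihood GLM pipelines; an installed
independent implementation is used in the test suite purely as a
directional cross-check. The test's empirical size on null simulations
(dispersion 0.1, two vs two samples) is close to nominal, which the
acceptance suite asserts at 50 seeds.

A region is *differentially bivalent* only when significant
(`|log2FC| > 1`, `FDR < 0.05`) **with the same sign** in both reChIP
orientations; requiring concordant sign (the stricter reading of joint
significance) is a deliberate choice and is what makes knockout simulations
produce losses only. Promoter-level calls follow by overlap.

## Sequence features

`gc_metrics()` computes GC fraction (C+G over informative, non-N length) and
CpG dinucleotide frequency (CG count over `length - 1` dinucleotide
positions — the denominator choice is documented here because both
conventions exist). `matched_random_regions()` draws width-preserving
candidate regions avoiding the query and selects nearest-neighbour GC
matches without replacement — a concrete algorithm standing in for
covariate-matching frameworks. Simulator genomes carry no sequence, so
`synth_genome()` generates a synthetic one (i.i.d. bases at a background GC
level, elevated inside designated regions) to exercise these metrics; the
test suite uses it to reproduce, directionally, the CpG-rich character of
bivalent regions.

## Orchestration, determinism and problem sizes

`run_all()` executes peaks → consensus → reciprocal bivalency →
classification → promoters → QC → (two conditions) differential from a
sample sheet, using IgG–IgG as the peak-calling control when present (input
otherwise), and writes a JSON summary holding every count. All randomness
derives from explicit integer seeds; per-sample seeds are the master seed
plus a stable string hash of the sample id, so studies regenerate
byte-identically.

The test and acceptance runs use two 5-Mb chromosomes, 2,000 cells and
500,000-fragment target depth (the generator defaults), with smaller
single-chromosome studies in unit tests; these sizes keep every stage
exercised at full algorithmic generality while each simulation completes in
seconds. Statistical calibration suites use 20 seeds (island null FDR) and
50 seeds (NB test size), with thresholds fixed from the analyses described
above.

## Known limitations

* The simulator's clean background makes peak calling much easier than on
  real libraries; FRiP values near 0.9 are a property of the model, not a
  promise about experiments.
* The NB test supports exactly two conditions with replicates; no batch
  covariates or robust hyperparameter estimation.
* BAM/CRAM input, bigWig output, chromatin-state HMMs, motif and
  gene-ontology enrichment are out of scope; fragment BED files and bedGraph
  stand in for binary formats.
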