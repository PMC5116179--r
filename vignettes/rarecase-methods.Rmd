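---
title: "Methods: family-based genomic workup of a rare tumor case"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: family-based genomic workup of a rare tumor case}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rarecase)
```

`rarecase` packages the analysis pattern used in single-patient genomic case
studies of rare tumors: a tumor sample plus the germline trio (patient
leukocyte, mother, father) analysed jointly, so that every variant can be
assigned an inheritance mode; copy-number profiling on two platforms with a
concordance check; delimitation of a tumor-defining translocation breakpoint
from mate-pair sequencing; and a droplet-digital-PCR (ddPCR) assay on the
junction for monitoring circulating tumor DNA (ctDNA) in plasma. This
vignette documents the models behind each stage, the tunable parameters and
their defaults, the design choices that were genuinely open, and what the
synthetic-data generator does and does not emulate.

## Trio variant classification

The classifier consumes a *wide trio table*: one row per biallelic site with
per-role depth (`*_dp`), alt-read count (`*_alt`), variant allele fraction
(VAF, `*_vaf`) and optional genotype class (`*_gt`), plus gene symbol,
functional consequence and population minor allele frequency (MAF). It
applies four rules, all vectorised and all with machine-readable failure
reasons:

* **Somatic** — tumor and patient-leukocyte depth ≥ `min_depth` (10×),
  tumor VAF ≥ `somatic_min_tumor_vaf` (20%), and leukocyte VAF ≤
  `max_normal_vaf`.
* **De novo** — all three leukocyte depths ≥ 10×, patient VAF ≥
  `denovo_min_vaf` (30%), both parents free of the alternate allele.
* **Rare homozygous** — patient homozygous-alt, both parents heterozygous,
  all at depth, MAF ≤ `rare_maf_max` (10%).
* **Compound heterozygous** — per gene, at least one maternal-only and one
  paternal-only heterozygous variant, each heterozygous in the patient, at
  depth, and rare. "Maternal-only" requires the father to carry no
  alternate allele, and vice versa.

All stated thresholds are inclusive: a tumor VAF of exactly 20% at exactly
10× passes. A rule whose required samples lack a call returns `NA`
(indeterminate), which is deliberately distinct from `FALSE`; a
tumor-normal-only case therefore yields indeterminate rather than negative
germline calls, and `run_case()` marks those stages skipped.

Three parameters deserve comment because the underlying filtering
conventions rarely state them explicitly:

* `max_normal_vaf` (default 0): the alternate support tolerated in a sample
  required to be negative. Zero demands strict absence, which is the
  behaviour implied by counting a variant "in the tumor only"; it is exposed
  because deep leukocyte sequencing with sequencing error would need a small
  positive tolerance.
* Genotype bounds `het_low = 0.15`, `hom_min = 0.80`: when no genotype
  string is available, a call is het on VAF `[0.15, 0.80)` and hom-alt at
  `≥ 0.80`. These bounds are chosen so that observed fractions like 83.3%
  class as homozygous and 17.9% as heterozygous, matching how such tables
  are read in practice; they are a documented convention, not a community
  standard.
* Missing MAF counts as rare (`maf_missing_rare = TRUE`): a variant never
  observed in population databases is the strongest candidate of all, and
  real case tables include alleles with no database frequency. When several
  databases disagree upstream, the caller expects the *maximum* reported
  MAF in the `maf` column (conservative; the package does not arbitrate
  between databases itself).

A variant heterozygous in both parents has ambiguous phase; it is ineligible
as a compound-het member but does not disqualify its gene. Genes with more
than two eligible variants report every maternal × paternal pair.

## Copy-number segmentation

Probe-level log2 ratios are segmented by recursive binary splitting: each
interval is split at the point maximising the two-sample *t* statistic
between flanking means (computed in O(n) from cumulative sums), a split is
accepted when its p-value clears `alpha` (default 1e-8), and the halves are
segmented recursively — a circular-binary-segmentation-style mean-shift
model. The commercial HMM-based segmentation used on the original array
platform is proprietary, so this package substitutes an open change-point
algorithm while preserving the published operating settings: at least five
consecutive probes per non-neutral call, significance 1e-8, and log2
thresholds 0.33 / −0.3 for gains/losses and 1.2 / −1.1 for high-copy gains
and homozygous losses (all inclusive).

Segments always partition each chromosome — classification is a pure
function of the segment mean, and sub-threshold ("low-level mosaic")
segments are not discarded but remain in the output with call `neutral` and
their mean log2 available for an advisory review. Non-neutral calls with
fewer than `min_probes` probes are demoted to neutral.

Read-depth (exome) copy-number calls reuse the same segmentation: per-region
log2(tumor/normal) ratios, regions with normal depth < 10 excluded, then
*median-centering* before segmentation. Median-centering absorbs library
size but assumes the majority of the genome is diploid; in a genome where
aberrant segments cover close to half of all regions the centre shifts and
absolute thresholds lose meaning. That caveat shapes the test genomes (bulk
diploid background) and should be kept in mind for heavily rearranged
samples.

Cross-platform concordance calls an array event *validated* when a
read-depth event of the same sign (gain-like vs loss-like) overlaps it; the
default rule is any-overlap (≥ 1 bp) with a reciprocal-overlap fraction
available as an option, since published concordance percentages rarely
define their overlap criterion. Events falling in regions absent from the
exome footprint are exactly the ones that fail validation, which is how a
concordance below 1 decomposes in the tests.

The case's reported event spectrum ships as `build_cna_truth()`: gains of
chromosomes 5 and 18, losses of 11p, 13q and 22q, and one focal homozygous
deletion of ~1.3 Mb on 9p. Only the focal deletion has printed base-pair
coordinates (chr9:17,106,384–18,449,088); the arm boundaries are approximate
centromere positions, and the text's 9p22.2 band label disagrees with the
9p24.1 label used elsewhere in the source report — the coordinates are taken
as authoritative.

## Translocation breakpoint delimitation

Mate-pair libraries circularise ~2 kb fragments, so a pair whose reads map
to different chromosomes — or to the same chromosome at a separation outside
`insert_mean ± 3·insert_sd` — is discordant. Interchromosomal discordant
pairs are grouped per chromosome pair and clustered by single linkage with
window `insert_mean + 3·insert_sd` on both coordinates; single linkage was
chosen for determinism (ties broken by leftmost coordinate, output invariant
under permutation of input order). Clusters with `min_support ≥ 3` pairs
become breakpoint calls.

The junction interval on each side spans one maximal insert from the
innermost read start, directed by strand: plus-strand reads face the
junction down-coordinate, minus-strand reads up-coordinate. Interval width
is therefore bounded by `insert_mean + 3·insert_sd`, and the interval
contains the true junction whenever the supporting pairs straddle it — the
property tested over 100 simulated libraries. Orientation classes are
reported but never used to filter, since a junction validated by PCR does
not need orientation logic. Split-read base-pair refinement is out of scope;
`assay_region()` instead extracts ~400 bp flanks (the amplicon size used for
confirmation PCR) and builds a synthetic fused contig for assay design.

## ddPCR quantification and ctDNA monitoring

With template partitioned into `n` droplets at mean `λ` copies per droplet,
a droplet is positive with probability `1 − e^{−λ}`; inverting the observed
positive fraction gives `λ̂ = −ln(1 − p̂)`. The 95% interval is the exact
binomial (Clopper–Pearson) interval of `p̂` pushed through the same
transform. Replicate wells are pooled before estimation. A saturated well
returns an infinite point estimate with a finite lower bound. Concentration
is reported per microliter of partitioned volume using a droplet volume of
0.85 nL (QX200-class instruments; configurable, as vendors do not always
publish it).

A sample's detection call is three-valued: `invalid` when the wild-type
channel shows no signal (no amplifiable cell-free DNA) or when any negative
control has fusion signal at `min_positive` droplets or more; `negative`
when valid and the fusion channel is below `min_positive` (default 2 — a
single positive droplet is treated as inconclusive rather than as disease);
`positive` otherwise. The fusion fraction is the ratio of fusion to total
concentration with a conservative CI from crossing the two channels' bounds.

`lod_simulation()` characterises the limit of detection over the assay's
validation grid — input masses from 60 ng down five tenfold dilutions to
6 pg, and tumor fractions including the 1.0% and 0.1% spike-ins — converting
mass to genome equivalents at 3.3 pg per haploid genome. Detection
probability per condition is the fraction of simulated wells with at least
one positive droplet, alongside the closed form `1 − e^{−copies}`. At 6 pg
(1–2 genome copies) detection is possible but not guaranteed, which is the
expected single-molecule regime. Monotonicity of detection probability in
mass and fraction holds in expectation; empirical estimates from a finite
number of replicate wells are checked as monotone within three binomial
standard errors, which is the correct statistical reading of a Monte Carlo
estimate rather than a loosened claim.

## The synthetic-data generator

Every stage is testable without external data because the generator plants
known truth:

* **Trios** (`simulate_trio()`): per-sample depth is Poisson around
  `depth_mean` (only a 10× floor is implied by the filters; Poisson is the
  standard coverage model) and alt counts are Binomial(depth, true VAF).
  Inheritance classes fix the true VAFs per role (e.g. somatic: tumor 0.4,
  all leukocytes 0; rare homozygous: patient 1.0, parents 0.5). Background
  variants are common polymorphisms drawn under Hardy–Weinberg in the
  parents and transmitted Mendelianly, so they stress every filter without
  belonging to any class.
* **Copy number** (`simulate_cna_profile()`): probes on a regular grid with
  mean `log2(copy/2)` inside truth segments (floored at −3 where the signal
  saturates for homozygous losses) plus Gaussian noise.
* **Mate pairs** (`simulate_matepairs()`): concordant pairs genome-wide plus
  junction-spanning pairs whose insert is split at the junction.
* **Droplets** (`simulate_droplets()`): the positive count is drawn as
  Binomial(n, 1 − e^{−λ}) — exactly the per-droplet Bernoulli model,
  vectorised.

The generator is deterministic under a fixed seed. It does **not** emulate
read-level sequences (no FASTQ), sequencing error, mapping artefacts, GC or
capture bias, contamination, or tumor subclonality. Passing recovery tests
therefore demonstrate that the *rules and estimators* are implemented
correctly and are well calibrated at the stated depths and noise levels —
not that the thresholds are optimal for any particular real instrument.

The default study conditions mirror the case workup: mean depth 30× for the
recovery suite (20 planted variants per class, 1,000 background variants,
pooled over 10 seeds — sensitivity ≥ 0.95 and FDR ≤ 0.05 per class), probe
spacing 15 kb with noise sd 0.15 for the copy-number spectrum (a 180K-array
scale genome of the six involved chromosomes, ~47,000 probes), 50
junction-supporting pairs among 10,000 concordant pairs for breakpoint
recovery, and 20,000-droplet wells. Pooling recovery counts over seeds is
the intended reading of a multi-seed criterion: per-class sensitivity at 30×
is intrinsically ~98–99% (a true 50% VAF can sample below a 30% cutoff), so
single-seed counts of 20 would make the 0.95 bound a coin-flip on the tail
rather than a property of the method.

## Degenerate inputs and numerical conventions

Zero-depth samples class as `missing`; malformed AD fields flag that
sample's call missing without dropping the record; duplicate planted
positions, overlapping truth segments, unsorted probe series, disjoint
region sets and out-of-bounds flanks are errors. Coordinates are 1-based
closed on all user-facing tables (BEDPE I/O converts to/from 0-based
half-open). Fixture values that the source tables do not print are synthetic
and documented as such (parental calls absent in the somatic table, depth 50
where coverage is unprinted, sequential placeholder positions where only
gene and cDNA change are given).

## Known limitations

Multi-allelic sites are out of scope (records are assumed biallelic after
upstream normalisation); genotype-likelihood models, pathogenicity
prediction, allele-specific copy number, purity/ploidy estimation, general
SV typing and fluorescence-amplitude droplet thresholding are deliberately
not implemented. The somatic rule with `max_normal_vaf = 0` is exact-absence
filtering and will over-filter at very high leukocyte depths on real,
error-bearing data; raise the tolerance accordingly.
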