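---
title: "Characterizing a segregating chromosomal inversion with invkaryo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing a segregating chromosomal inversion with invkaryo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(invkaryo)
```

## The problem

A polymorphic chromosomal inversion suppresses recombination between its two
orientations in heterozygous carriers. At the population level this leaves a
distinctive footprint in genotype data: a multi-megabase block of loci in
strong mutual linkage disequilibrium (LD), three clusters of samples
corresponding to the two homokaryotypes and the heterokaryotype, elevated
divergence (per-SNP F~ST~) between the homokaryotype groups across the block,
and — because the two arrangements stopped exchanging material when the
inversion arose — a per-gene sequence divergence between arrangements that
can be converted into an age with a molecular clock.

`invkaryo` packages that whole chain of analysis for diploid genotype
matrices (VCF or dosage input): localize the inversion from LD, select
karyotype-diagnostic loci, call per-sample karyotypes and summarize their
frequencies along a latitudinal gradient, contrast the diversity of the two
homokaryotype groups (site frequency spectra, Watterson's
$\hat\theta_W = S/a_1$, nucleotide diversity $\pi$, Tajima's $D$, sliding
windows, Weir–Cockerham $\hat\theta$ per SNP, per-sample heterozygosity,
Welch and one-way ANOVA tests), date the split of the two arrangements from
duplicated ortholog families with a calibrated strict clock, and test
functional-term enrichment of the genes inside the inversion with Fisher's
exact test under Benjamini–Hochberg FDR control.

Every stage can be exercised against coalescent-based simulators that
produce truth-labelled cohorts, ortholog families and annotation tables, so
the package's claims about itself are tested end to end.

## The simulators and what they emulate

`simulate_inversion_cohort()` builds a diploid cohort on one chromosome:

* Each diploid draws two haplotype-class labels (ancestral or inverted) by
  Hardy–Weinberg sampling from its population's inverted-haplotype
  frequency. The default cohort is five populations of ten diploids along a
  33–49° latitude gradient with inverted-haplotype frequencies
  (0.2, 0.5, 0.8, 1, 1): a cline in which the ancestral arrangement is
  common in the south and absent in the north, the configuration under
  which karyotype frequencies are scientifically interesting.
* Inside the inversion, sites arise on clean-split two-deme coalescent
  genealogies: the two classes diverged `t_div_ci` (default 4, in units of
  2N generations) ago with no exchange since. The inversion interior is
  split into `n_ci_blocks` (default 16) sub-blocks that share the one class
  assignment per chromosome but have independent within-class genealogies.
  This reflects real inversion genetics: recombination between orientations
  is suppressed along the entire inversion (so class-tagging variation is
  fully linked across it), while homokaryotypes recombine freely within
  their own class (so within-class haplotype structure decays with
  distance). Simulating the interior as a single frozen genealogy would
  instead freeze within-class haplotypes chromosome-wide, creating
  artifactual within-class long-range LD as strong as the karyotype signal
  itself — and would make any long non-recombining segment indistinguishable
  from an inversion even at divergence zero.
* Outside the inversion, `n_background_blocks` (default 40) independent
  neutral Kingman-coalescent blocks occupy contiguous intervals, so
  background LD stays short-range, as free recombination would make it.
* `theta_per_site` (population-scaled mutation rate, default 3e-6/bp) gives
  a few hundred SNPs on a 30-Mb chromosome — the marker density of a
  reduced-representation survey, which is the data type this analysis is
  designed for.

The simulator does **not** model demographic history (growth, migration,
bottlenecks), selection, gene flux between arrangements, indels, genotyping
error or missingness. Passing tests therefore demonstrate correctness of the
statistical machinery and recoverability of inversions under the assumed
sampling design, not robustness to demographic confounding in real data.

`simulate_ortholog_families()` evolves equal-length alignments by
single-rate JC69 substitution along a fixed species tree containing two
esociform outgroups and two homeolog clades created by a whole-genome
duplication; the focal clade carries two trout sequences that split
`t_inv` million years ago. Default node ages (112 root, 85 esociform split,
95 duplication, 51.8 crown of each homeolog clade, 35 whitefish–grayling,
27.3 Salmo–Oncorhynchus, 1.0 inversion) are strictly nested and mirror the
fossil and molecular calibrations commonly used for this clade.

`simulate_annotation()` plants enrichment: every gene receives each term by
an independent Bernoulli draw at a baseline probability (default 0.02), but
genes inside the inversion receive the enriched terms at a multiplied
probability (default: 3 of 20 terms at multiplier 8, with 300 inversion
genes against 30,000 background genes).

All three simulators are deterministic given their seed: one seeded
generator per top-level call, child streams derived deterministically.

## Localizing the inversion

`compute_r2()` estimates LD as the squared Pearson correlation of dosage
vectors (composite, phase-free LD), pairwise-complete over non-missing
samples, after a minor-allele-frequency filter (default 0.05); only pairs
with $r^2 \ge$ 0.8 (default) and at least 10 jointly non-missing samples
are kept.

`detect_inversion_region()` then builds a graph on sites joined by pairs at
least `min_distance` (default 1 Mb) apart. The distance gate matters at this
marker density: ordinary background LD is short-range, so long-range
high-LD edges are the inversion's signature. Suppressed recombination
produces *several* mutually unlinked high-LD site sets that span the same
interval — the karyotype-tagging sites, plus haplotype clusters segregating
within each karyotype class — so every connected component supported by at
least `min_pairs` (default 50) qualifying pairs is kept and components with
overlapping genomic spans are merged, starting from the best-supported one.
Taking only the single best component is not safe: in cohorts where one
karyotype class is rare, a within-class cluster can carry more qualifying
pairs than the karyotype cluster while the karyotype cluster still spans
the full block. No qualifying component is a valid negative result.

### Diagnostic loci and the sample score

`select_diagnostic_loci()` clusters samples into at most three karyotype
groups and keeps loci whose genotypes match the implied 0/1/2 pattern in at
least `concordance_min` (default 0.95) of samples, in their better allele
orientation. Three numerical choices deserve explanation:

* **The score is PC1 of centered, unscaled dosages** over all polymorphic
  sites in the region span. A plain mean of standardized dosages cancels,
  because the derived allele tags opposite classes at different sites; PC1
  aligns the signs. Covariance (rather than correlation) weighting makes
  each site contribute in proportion to its dosage variance, which is
  maximal for the intermediate-frequency, perfectly correlated sites that
  tag the karyotype and small for low-frequency within-class variants —
  so the karyotype axis dominates even when a within-class axis involves
  more sites.
* **K-means centres are initialized at the score minimum, midpoint and
  maximum** (deterministic; ties broken by sample order). The three
  genotype clusters are equally spaced on a dosage axis, and extreme-based
  centres are robust to heavily skewed karyotype frequencies — with an
  84%-inverted cohort, quantile-based centres would start two centres
  inside the same cluster and merge the other two classes.
* **One refinement pass**: loci that already fit the provisional clusters
  in ≥ 80% of samples re-score every sample as a mean oriented dosage, and
  samples are re-assigned to the nearest karyotype group on that axis.
  Residual within-class variance blurs the k-means boundaries in a minority
  of cohorts; the refined, dosage-scaled axis separates the three groups
  cleanly before the final concordance filter is applied.

Orientation of the "inverted" label cannot be read from genotypes alone
(that requires cross-species synteny). Supply `ancestral_samples` if known;
otherwise the globally commoner haplotype class is labelled inverted, which
matches the empirical predominance in the motivating system. The choice is
recorded in the output's `orientation` attribute.

## Karyotype calls and frequencies

`call_karyotypes()` averages each sample's oriented dosage (2 = two copies
of the inverted-tagged allele) over non-missing diagnostic loci and calls
`ANC_HOM` below 0.5, `HET` in [0.75, 1.25], `INV_HOM` above 1.5, otherwise
`UNRESOLVED`; samples missing more than half the loci are `UNRESOLVED`. The
dead zones guard against mosaic or error-ridden samples; the thresholds are
configurable because no principled universal value exists. Population
summaries report counts, frequencies, percentages (one decimal) and the
allele-counting ancestral frequency $(2\,n_{anc} + n_{het})/(2n)$;
`latitude_cline()` orders populations by latitude, and
`single_locus_frequency()` gives the amplicon-panel analogue with a Wilson
95% interval.

## Diversity contrasts

Windows are half-open `[start, start + window)`, starting at `1 + k·step`,
fully contained in the chromosome — the tiling is exact and edge handling
unambiguous. Defaults: 50-kb windows sliding by 10 kb, with a
`passes_filter` flag at ≥ 100 segregating sites; windows overlapping a
region mask can be kept exclusively or excluded, matching analyses
restricted to (or purged of) the inversion. $\pi$ is computed from the SFS
as $\sum_i i(n-i)\,\xi_i / \binom{n}{2}$ and reported both per window and
per bp, because conventions differ between studies and the two are not
interchangeable when windows are filtered.

Sites with missing genotypes are down-projected to a common chromosome
count by the expected hypergeometric projection; sites with fewer complete
chromosomes than 80% of 2n are dropped. (An explicit rule is needed here
because genotype-likelihood pipelines hide this choice inside their SFS
machinery.)

Weir–Cockerham $\hat\theta$ uses the two-population variance components
(a, b, c) from allele frequencies, diploid sample sizes and observed
heterozygote proportions; negative estimates are reported as computed, with
a flag, never clamped. Welch's t (Satterthwaite df, two-tailed) and classic
one-way ANOVA are both provided because group contrasts of this kind are
reported with either; degenerate inputs (both variances zero) return
t = 0, p = 1 when means agree and are an error otherwise.

A note on Tajima's $D$ under neutrality: $D$ is only approximately
standardized, and its exact null mean is slightly negative at any finite
sample size (about −0.12 at 30 chromosomes, −0.03 to −0.05 at 6, measured
here and confirmed against an independent coalescent simulator). The
package's neutral-calibration checks therefore use small samples (6
chromosomes) with a moderate per-block mutation supply, where the bias is
well inside the Monte-Carlo band of 1,000 replicates — a property of the
statistic, not of the implementation.

## Dating the inversion

The dating stage reduces gene-tree inference and Bayesian relaxed-clock
machinery to the smallest estimator that preserves the scientific
operation — a calibrated TMRCA of the two arrangements, summarized over
ortholog families:

1. `jc69_distance()` computes $d = -\frac{3}{4}\ln(1 - \frac{4}{3}p)$ over
   comparable sites (N/- excluded; at least 100 required; $p \ge 0.75$ is a
   saturation error).
2. `nj_tree()` builds the neighbor-joining gene tree, and
   `check_ortholog_topology()` roots it on the esociform pair and verifies,
   as monophyly statements: both homeolog clades intact; Atlantic salmon
   and trout sisters within each clade; the two trout arrangement sequences
   sisters; and the pair not identical (an invariant pair carries no dating
   signal). `filter_families()` tallies rejections by the first violated
   criterion.
3. `estimate_tmrca()` anchors the local substitution rate on the
   Salmo–Oncorhynchus split (default 27.3 MY, configurable): the rate is
   $\bar d(\text{trout}, \text{atlantic}) / (2 \times 27.3)$ using the mean
   of the two trout-to-salmon distances — which trout copy "is" the
   calibration lineage is not identifiable, so both are averaged — and the
   age is $d(\text{anc}, \text{inv})/(2 \cdot \text{rate})$. Ages are
   exactly linear in the calibration age, and estimates are invariant to
   swapping the arrangement labels.
4. `summarize_ages()` reports the median and mean over passing, variant
   families. Per-family ages are Poisson-noisy (an expected ~20 differences
   per pair at the default simulation settings), so the median is the
   headline number; the mean is reported alongside because right-skew makes
   the two differ in practice.

A strict clock on a single calibration is a deliberate simplification:
rate variation across lineages, fossil-prior uncertainty and posterior
intervals are out of scope, and per-family ages should be read as a
distribution, not as per-gene truths.

## Enrichment

`term_enrichment()` tests each term once with a 2×2 Fisher's exact test
(inversion genes with/without the term against background genes
with/without), using the two-sided point-probability convention — the sum
of hypergeometric probabilities no larger than the observed table's, the
dominant convention among statistical software. The reported odds ratio is
the sample cross-product $(ad)/(bc)$ with zero cells flagged as 0/Inf.
Benjamini–Hochberg q-values are step-up adjusted, capped at one,
order-preserving. The gene universe is all annotated genes; terms are
tested exactly as annotated, with no ontology-graph propagation (no
parent-term inheritance), because annotation pipelines differ on this and
silently propagating would change the test's meaning.

## The pipeline and reproducibility

`run_pipeline()` executes simulate → ldscan → karyotype → popgen →
(dating, enrich) from one configuration (R list or JSON), writes every
output under one directory, and emits a manifest with MD5 checksums, the
resolved configuration, stage timings and the seed. Reruns with the same
configuration and seed produce identical checksums for all deterministic
outputs. A failing stage aborts with the stage named and leaves a
`.partial` marker. A thin command-line dispatcher over the same functions
ships in `inst/cli/invkaryo.R`.

## Problem sizes used in validation

The package's own test suite and the acceptance script use: 20 cohorts of
50 diploids (five populations, ~500–700 SNPs each) for detection and
karyotyping recovery; 1,000 neutral blocks of 6 chromosomes for Tajima's D
calibration; 10,000 replicates each for Welch and Fisher type-I error;
~10,500 pooled near-independent sites for the SFS shape check; 200
ortholog families of 10 kb for dating recovery; and 100 planted-enrichment
replicates (30,300 genes, 20 terms) for power and FDR. Boundary accuracy
of the detected inversion is assessed as a bracket: the detected interval
must cover the realized span of fixed inter-class differences and must not
extend beyond the span of detectably differentiated sites (inter-class
F~ST~ ≥ 0.8), each to within one median inter-SNP spacing of the filtered
marker set. The latent simulation boundaries themselves are recoverable
only up to the outermost segregating site, so the bracket — not the latent
parameter — is the meaningful accuracy target at realistic marker density.

## Known limitations

* Composite (dosage-correlation) LD, not haplotype-EM LD; the two converge
  for the strong-LD signals used here, but weak-LD values differ.
* One inversion per chromosome; nested or adjacent inversions will be
  merged into one block by design.
* Karyotype thresholds and the 1-Mb distance gate are tuned for
  multi-megabase inversions at reduced-representation marker density;
  small inversions or dense WGS data warrant different settings.
* The dating estimator assumes a strict clock and equal-rate JC69
  substitution; systematic rate variation between the arrangement lineages
  biases ages in proportion.
* Enrichment treats annotations as flat labels; GO-graph structure is the
  user's responsibility.
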