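---
title: "Methods: spike-in calibrated RRBS analysis for caste and colony designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spike-in calibrated RRBS analysis for caste and colony designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind each stage of the
pipeline, the assumptions it makes, the tunable parameters and their
defaults, what the synthetic-data generator does and does not emulate, and
the design decisions taken where more than one defensible choice existed.

## The measurement model

RRBS reports, for each CpG in each sample, how many reads carry a
non-converted (putatively methylated) cytosine and how many a converted one.
Two error processes sit between the truth and those counts:

* **Non-conversion.** A fraction *e* of truly unmethylated cytosines escapes
  bisulfite conversion and masquerades as methylation. *e* is estimated per
  sample from an unmethylated spike-in control as
  `spikein_meth / (spikein_meth + spikein_unmeth)`. Samples with *e* ≥ 5%
  fail QC (`estimate_nonconversion()`, `qc_threshold = 0.05`); a stricter
  2% flag (`strict_threshold`) marks the quality tier that well-converted
  libraries reach. If a site has true methylation *p*, its reads are
  methylated with probability `p + (1 − p)·e`.
* **Sampling depth.** Counts are binomial in the read coverage, so shallow
  sites are uninformative. Sites below `min_coverage = 5` reads are treated
  as *unsequenced* — absent, not unmethylated — and all cross-sample
  analyses run on the intersection of CpGs sequenced in every sample, the
  largest common ground of the design (`build_matrix()`).

**Methylation calling** (`call_methylation()`) asks whether the observed
methylated count exceeds what non-conversion alone explains: the p-value is
the one-sided upper binomial tail `P(X ≥ m | n, e)`. The test is one-sided
because genuine methylation can only inflate the non-converted count above
the error floor; a deficit of non-converted reads has no biological reading
here. P-values are Benjamini–Hochberg adjusted *within each sample* across
its tested sites and flagged at `q < alpha` (default 0.05). The per-sample
family is a choice: the correction could also be applied across all samples
jointly; per-sample is the natural unit because each sample has its own
error rate and its own set of sequenced sites, and it keeps a sample's calls
invariant to which other samples are co-analysed.

CpGs are kept **per strand**; the two cytosines of a CpG dyad are never
merged. Merging assumes symmetric methylation and halves positional
resolution; per-strand is the conservative reading of coverage-file input,
and a dyad-merging step could always be added upstream.

Coverage files are read in the 1-based Bismark `.cov` dialect by default;
`zero_based = TRUE` switches to the 0-based bedGraph dialect. The two differ
by exactly one base and silent mixups are the classic off-by-one bug in this
file family, hence an explicit flag rather than guessing.

## Genomic annotation

`build_feature_index()` derives, per gene, the merged exon union over
transcripts, introns as inter-exon gaps, and 10 kb flanks attached to the
gene span and oriented by strand. Flanks are measured from the gene span
(first to last exon), not per-transcript TSSs, because the merged exon model
is the unit of annotation. Element ranks count 5'→3' on the coding strand
(rank 1 = 5'-most), so gradients read in transcription order.

`annotate_sites()` gives every CpG exactly one class with precedence
**exon > intron > flank > repeat > intergenic**, and removes a site as
*ambiguous* when two different genes imply conflicting genic classes (exon
of one, intron of another) or when 5'- and 3'-flanks of different genes both
cover it. Rationale: within-gene classes are unambiguous by construction;
between-gene conflicts have no principled resolution, so those sites are
excluded from region-level statements. A repeat under a genic or flank class
yields the genic/flank class — repeat methylation is interpreted as
transposon signal *outside* genes. Flank bins are
`ceiling(distance / 1000)`, 1 kb steps counted outward from the gene
boundary (10 bins per flank at the default 10 kb flank; the meta-profile
reports 5'-bins as −10..−1 and 3'-bins as +1..+10, i.e. 20 one-kilobase bins
across both flanks).

## Descriptive statistics

Region-level tests (`region_summary()`) are computed on **per-CpG
cross-sample means** — one observation per CpG — then Kruskal–Wallis across
classes and pairwise two-sided Wilcoxon with BH adjustment. Using per-site
means avoids pseudo-replication: the 12 samples' values at one CpG are not
independent draws of that region's methylation.

The meta-gene profile (`metagene_profile()`) averages per sample over exon
rank, intron rank and flank bin. Ranks above `rank_cap = 10` pool into a
terminal "last" category: deep-rank categories are rare and noisy, and the
biological claim of interest (a 3'-rising gradient) concerns the ordered
low ranks.

The robustness census (`robustness_census()`) counts, per CpG, the number of
samples in which it is called methylated; genes containing at least one CpG
methylated in *all* samples form the robustly methylated gene list used in
the DEG-association test (`robust_deg_test()`).

## Differential methylation

`test_differential()` filters to sites with ≥ `min_cov = 10` reads in every
one of the six samples of a pairwise comparison, then applies a
likelihood-ratio test of a two-proportion versus one-proportion binomial
model on the replicate counts. With group as the only covariate, the group
totals are sufficient statistics, so this is exactly the likelihood-ratio
statistic of a logistic regression of methylation on group — implemented in
closed form and vectorised over sites rather than via per-site model fits,
which is what makes the 1000-iteration bootstrap affordable. A site is a
DMS when the pooled-proportion difference is at least `diff_threshold =
0.25` (25 percentage points, on the pooled difference, not a mean of
per-replicate differences) *and* the BH-adjusted p within the comparison is
below `q_threshold = 0.05`. The raw binomial likelihood carries no
overdispersion correction by default; `correction = "williams"` provides a
Williams-type tempering for users who want it. Under overdispersion the raw
test is anti-conservative, but the 25-point effect threshold is the binding
constraint in practice and the bootstrap null (below) is run with identical
settings, so the null comparison is like for like.

`classify_dms()` counts a site once however many comparisons flag it; in a
comparison A-vs-B a site hypermethylated in A is simultaneously
hypomethylated in B, and per-phenotype hyper/hypo sets collect directions
over comparisons. DMGs are genes with ≥ 1 DMS in the gene body (exon or
intron). `region_enrichment()` tests each phenotype × direction × region
cell as a 2×2 chi-square without continuity correction against all
annotated matrix CpGs, switching to Fisher's exact test when an expected
cell is below 1 (recorded in the output), with BH across cells.

`bootstrap_null()` draws two groups of three samples and re-runs the
identical test, 1000 times by default. The default draws **six distinct
samples split 3/3 (without replacement)**; a `with_replacement` mode allows
the two groups to share individuals. Both readings are defensible for a
randomized-grouping null and both are supported; disjoint groups are the
default because they mirror the observed comparisons, in which no individual
appears on both sides. Percentile intervals at 95% and 99% are reported and
observed per-pair counts are flagged above the 95th/99th or below the 5th
percentile of the null.

## Methylation–expression models

`aggregate_gene_region()` averages methylation per gene × feature type ×
sample (each site weighted equally) and keeps the summed coverage as a
weight. `fit_methylation_glm()` then fits

```
cbind(successes, failures) ~ log10(expression + 0.001) * variable * region + sample
```

with `successes = round(mean_level × total_reads)` — the rounding error is
at most half a read against weights in the hundreds. The `0.001` offset
keeps zero-expression genes finite on the log scale. Samples enter as
absorbed fixed intercepts by default (`method = "fixed"`); a
`lme4::glmer` random intercept is available (`method = "glmer"`). The two
agree closely on the contrasts of interest, and the fixed-intercept fit is
fast and free of convergence fragility, which matters inside simulation
loops.

Two inference choices are deliberate and recorded in the fit metadata:

* **Quasi-likelihood dispersion** (`family = "quasibinomial"`, default).
  Gene-region counts aggregated over CpGs are overdispersed relative to
  binomial; the Pearson-residual dispersion estimate rescales the Wald
  statistics accordingly. `family = "binomial"` gives the raw fit.
* **Cluster-robust contrasts** (`glm_variable_contrast(se = "cluster")`,
  default for the fixed fit). A gene contributes up to 4 regions × 12
  samples of correlated rows; treating genes as clusters in a sandwich
  covariance keeps type-I error near nominal when gene-level heterogeneity
  (baseline differences, shared random effects) is present. With model-based
  standard errors the same contrast is visibly anti-conservative on
  overdispersed data.

`glm_variable_contrast()` reports the variable's effect within a region at a
chosen expression percentile on the logit scale (delta-method CI);
`predict_methylation_grid()` returns response-scale predictions over
expression percentiles averaged across sample intercepts, for effect
displays.

`pca_top_variable()` ranks sites by across-sample variance, keeps the top
1000 and runs `prcomp` centred per site and unscaled — levels share a scale,
so rescaling would up-weight near-constant sites. `variance_partition()`
tests colony, phenotype and region on the long site × sample levels of the
10 000 most variable sites by Kruskal–Wallis and reports the rank
epsilon-squared-style effect size `η²_H = (H − k + 1)/(n − k)`. A
"generalized eta squared" is defined for ANOVA decompositions, not for
rank tests; `η²_H` is the standard rank analogue and is used here for all
factors uniformly.

## The synthetic-study generator

`simulate_study()` produces a fully specified study under a 4-phenotype ×
3-colony design with known truth. Defaults are the study conditions the
pipeline targets, chosen once:

| parameter | default | why |
|---|---|---|
| region baselines | exon 0.10, intron 0.04, flank 0.025, repeat 0.022, intergenic 0.017 | the coding ≫ intron > repeat/flank > intergenic ordering typical of termite methylomes |
| `gradient_slope` | 0.015 per rank | reproduces a 3'-rising gene-body gradient of realistic size |
| `flank_size` | 10 000 bp | matches the 10 kb flank convention of the annotation |
| `coverage_mean`, `coverage_dispersion` | NB(12, 5) | RRBS-like shallow, overdispersed coverage |
| `nonconversion_rate` | 0.01 | within the <2% band that passing libraries show |
| `colony_sd`, `phenotype_sd` | 0.5, 0.1 (logit) | site-specific effects shared within colony/phenotype; colony-dominant, as replicated designs observe |
| `colony_mean_sd`, `phenotype_mean_sd` | 0.15, 0.05 (logit) | small genome-wide offsets per colony/phenotype: real colonies also differ in overall methylation, which is what marginal (rank-based) variance partitioning sees |
| `beta_dispersion` | 0.02 | beta-binomial per-site counts, because real RRBS is overdispersed and downstream FDR behaviour should be tested under overdispersion |
| `n_planted_dms` | 0 | null design by default; experiments plant effects explicitly |
| `dms_effect` | 0.40 | a percentage-point shift comfortably above the 25-point call threshold |
| `de_fraction_up`, `de_fraction_down` | 0.106, 0.158 | genome-wide DEG proportions of the emulated design |

Mechanics worth knowing:

* Effects combine on the **logit scale**
  (`plogis(qlogis(baseline) + colony + phenotype + offsets)`); planted DMS
  shift one phenotype of one pair by `dms_effect` on the probability scale,
  clamped to [0.001, 0.999], shifting upward unless the clamp forbids it
  (a downward shift from a 2% baseline would be invisible). Planted sites
  are guaranteed coverage ≥ 1 in every sample so truth and files stay
  consistent.
* Colony/phenotype effects are site-specific draws shared by the samples of
  that colony/phenotype — this, not a global shift alone, is what makes
  samples cluster by colony in PCA.
* Genes are laid out without overlap and with padding beyond the flanks, so
  generated sites have unambiguous classes and the annotation truth is
  exact; the *classifier* is separately tested on deliberately conflicting
  toy genomes.
* When `coupling = TRUE`, genes in the coupling target (all DE genes, or
  genes over-expressed in mature vs virgin queens) have exon baselines
  shifted by `coupling_exon_shift` (−0.05) and 3'-flank baselines by
  `coupling_flank3_shift` (+0.01), planting a methylation–expression
  association for the GLM to recover.
* Everything is a deterministic function of `seed`; written studies are
  byte-identical across runs.

What the generator does **not** emulate: read-level artefacts (mapping
bias, duplicates, strand asymmetries), sequence composition and true
CpG-island structure, the strongly bimodal per-site methylation of real
insect methylomes (levels here are unimodal around each baseline), linkage
between neighbouring CpGs, and library-size differences. Passing tests
therefore demonstrate statistical correctness of the pipeline under a
realistic dispersion and effect structure — not robustness to every
artefact of real libraries.

## Numerical choices and degenerate inputs

* Binomial tails use `pbinom(m − 1, n, e, lower.tail = FALSE)`; `m = 0`
  gives p = 1 exactly. The LR statistic uses the `0·log 0 = 0` convention
  and is clamped at 0 against floating-point negatives.
* BH is `p.adjust(method = "BH")`; tests verify it against a literal
  step-up implementation.
* Empty intersections, single-level factors (all genes non-DE), one-sample
  inputs, genes without introns, and classes with fewer than two sites
  all either degrade gracefully (documented reduced models, absent rows)
  or fail loudly with a named reason — never silently.
* Ties in flank assignment (a site equidistant from two genes' same-class
  flanks) resolve to the nearest, then lexicographically first, gene —
  deterministic across platforms.

## Problem sizes used by the test-suite experiments

Simulation-backed checks run at desk scale, chosen to keep the full suite
in a few minutes while leaving each check well-powered: 6 000–16 000 CpGs
and 60–250 genes per simulated study, 50 000 CpGs for the caller-calibration
and DMS-recovery experiments, 200 randomized groupings × 20 seeds for the
bootstrap-coverage experiment, and 10 seeds for the calibration-rate
checks. The same experiments, at the same sizes, are re-run from scratch by
`scripts/acceptance.R`.

## Known limitations

* The DMS test ignores replicate-level overdispersion unless the Williams
  flag is set; its FDR is honest relative to the bootstrap null but nominal
  q-values on strongly overdispersed data are optimistic.
* Dyad strands are never merged; studies that merge them will report about
  half as many distinct "sites".
* The GLM treats expression as fixed and error-free and its aggregation
  discards within-gene site heterogeneity beyond the read-count weight.
* `η²_H` is not numerically comparable to ANOVA-based generalized eta
  squared; only the ordering of factors should be compared across methods.
* Region enrichment conditions on the annotated background; it inherits any
  bias in which CpGs are sequenceable by RRBS.
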