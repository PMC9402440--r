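---
title: "Methods: somatic mutation analysis for clonal lymphocyte colonies"
author: "lymphmut authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: somatic mutation analysis for clonal lymphocyte colonies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lymphmut)
```

# The problem

Whole-genome sequencing of colonies grown from single flow-sorted
lymphocytes gives clonal genomes in which every true somatic mutation of
the founder cell is present at a variant allele fraction (VAF) near 0.5.
Because the colonies of one donor are sequenced without a matched
normal, each candidate call is a mixture of three populations: germline
heterozygous variants (VAF ~0.5 in *every* colony), clonal somatic
mutations (VAF ~0.5 in the carrier colonies, absent elsewhere) and
library or mapping artefacts (low VAF, scattered independently across
colonies). `lymphmut` implements the statistical machinery that turns
these read counts into per-cell mutation burdens, signature exposures,
genomic-distribution regressions, structural-variant mechanism calls and
mutation-timing inferences, together with a synthetic-data generator
that emulates the whole data structure with known ground truth.

# Variant filtering

The filtering cascade in `filter_variants()` applies, per donor:

1. **Mean-VAF screen.** Variants with mean VAF strictly above 40% across
   the donor's colonies are germline (`mean_vaf_screen()`).
2. **Pooled exact binomial test.** For each variant the alternate and
   total reads are summed over colonies and tested one-sided against the
   heterozygous proportion (0.5 on autosomes, 0.95 on male sex
   chromosomes). p-values are Benjamini–Hochberg adjusted within the
   donor and a variant is called germline on *failure* to reject at
   q ≥ 1e-6 (`aggregate_binomial_test()`, `classify_germline()`). The
   unusual direction — germline is the null — makes the germline set a
   high-confidence truth set for sensitivity estimation.
3. **Beta-binomial overdispersion.** True clonal mutations are strongly
   overdispersed across colonies; artefacts with a site-specific error
   rate are not. `betabinom_overdispersion()` fits a beta-binomial with
   shared mean by maximum likelihood over a fixed overdispersion grid
   (rho from 1e-4 to 0.999, 61 log-spaced points) and forms a
   likelihood-ratio statistic against the binomial. The statistic is
   mapped to a score, −log10 of the chi-square(1) tail probability
   halved at the boundary. The score distribution over variants is
   bimodal, and the per-donor cutoff is placed at the deepest
   kernel-density valley between the two major modes
   (`valley_threshold()`, Silverman bandwidth; modes below 10% of the
   tallest peak are treated as density wiggles; ties break to the
   smallest score; unimodal distributions fall back to a configurable
   cutoff and are flagged).

Per-colony sensitivity is the recall of the germline set under the
genotyping rule — present iff at least 2 alternate reads *and*
VAF ≥ 20% (`call_genotype()`, `germline_recall_sensitivity()`). At 20×
depth this rule detects a heterozygous variant with probability
`1 - pbinom(3, 20, 0.5)` ≈ 0.9987. Because the alt-read threshold
`ceiling(0.2 * depth)` steps up with depth, sensitivity is not strictly
monotone point-by-point in depth; it increases across any doubling of
depth, which is the property we test.

An external subclonality caller and artefact blacklists integrate
through pass-through arguments (`subclonal`, `blacklist`): they are
AND-ed with, or applied ahead of, the overdispersion pass, and are not
reimplemented here.

# Burden modelling

Observed burden rises with sequencing depth and saturates. We fit
`y = b0 + b1 (1 − exp(−exp(lrc) · x))` by Levenberg–Marquardt least
squares with `stats::NLSstAsymptotic()` starting values
(`fit_depth_response()`), and rescale each colony's burden by the
fitted-curve ratio `f(30)/f(depth)` (`adjust_to_reference_depth()`);
the multiplicative form preserves zero burdens and is exactly the
identity at the 30× reference. The reference fit is intended to be run
on HSPC colonies (naive cells for tonsil donors), excluding colonies
deeper than 50×.

`fit_burden_age_model()` fits burden ~ age × cell type by maximum
likelihood with a donor-by-cell-type random intercept and a separate
residual variance per cell type (`nlme::lme` with `varIdent` weights).
We read "weighted by cell type" as heteroscedastic residual variances —
the interpretation under which the reported per-compartment standard
deviations (tens of SNVs for stem cells, hundreds for memory cells) are
model parameters. Two numerical choices matter:

* **Interval construction.** Age slopes and cell-type offsets are
  donor-level contrasts: with 7 donors they carry roughly
  `n_donors − 2` degrees of freedom, and ML variance components are
  biased low at that sample size. Wald intervals therefore use standard
  errors from an REML refit and a t quantile with `n_donors − 2`
  degrees of freedom. In simulation at the default scale this gives
  ~95% empirical coverage, where naive ±1.96 × ML standard errors give
  75–85%.
* **Degenerate data.** Noise-free tables (all variance components zero)
  are detected and solved exactly by ordinary least squares.

The age × cell-type interaction is tested by a likelihood-ratio test of
the ML fits with and without the interaction; variance heterogeneity by
an LRT of the heteroscedastic against the homoscedastic model,
chi-square with (number of cell types − 1) degrees of freedom
(`variance_heterogeneity_test()`). Note that clamping simulated burdens
at zero truncates low-mean compartments and genuinely breaks
homoscedasticity — null calibration checks must use configurations whose
burdens stay positive.

# Signature attribution

Exposures are maximum-likelihood mixing proportions under
counts ~ Multinomial(n, Σ_s w_s S_s), found by EM on the simplex
(`fit_exposures()`). Uncertainty is a seeded multinomial bootstrap: the
catalogue is resampled, refitted, and the 5th/95th percentiles form a
90% interval. We chose the bootstrap over an MCMC posterior because it
is deterministic given the seed and adds no sampler dependency; the
1%-lower-bound display rule is applied to the bootstrap interval.
`exclude_and_refit()` implements the two-pass rule: signatures below
10% exposure in every sample are dropped and all samples refitted on
the reduced catalogue.

Per-variant attribution is the posterior
`P(s | c) = w_s S_s[c] / Σ_t w_t S_t[c]` (`per_variant_attribution()`).
`window_attribution()` refines coarse-window exposures to 10-kb bins:
each mutation contributes its posterior to its bin, so per-bin signature
counts sum exactly to the raw bin count, and a bin enters the regression
for a signature only when its mean attribution exceeds 0.5 — without
this rule, high-burden bins acquire spuriously large counts from
trivially small attributions.

The shipped catalogue (`synthetic_signature_catalog()`,
`inst/extdata/signatures_96_synthetic.tsv`) is a synthetic stand-in:
eight 96-channel vectors with the characteristic concentrations of the
blood clock signature, CpG deamination, ultraviolet damage, SBS8, the
germinal-centre TpW signature (SBS9), SBS17b, SBS18 and on-target
somatic hypermutation. It is not the published reference catalogue;
substitute one via `read_signature_catalog()` for real data.

# Genomic feature regression

The published analysis used a lasso-penalised generalised additive
model. Here each feature is expanded in a natural-spline basis of fixed
dimension 10 and the concatenated basis is lasso-fitted with `glmnet`
(`fit_penalized_additive()`): the penalty is chosen by seeded 5-fold
cross-validation on a two-thirds training split under the
one-standard-error rule, a feature counts as selected when any of its
basis coefficients is non-zero, and R² is reported on the full table —
the training/held-out ambiguity in the published overall R² is resolved
in favour of the full-table value, and documented here. Individual
effect sizes are R² values of single-feature penalised smooths
(`mgcv::gam`, basis dimension 10, `individual_feature_r2()`). Counts are
modelled as Gaussian to match the published R² semantics.
`assemble_regression_table()` appends a seeded random sample of
zero-mutation bins sized to 10% of the final table, and
`preprocess_replication_timing()` removes regions with sum signal below
95 before the replication-timing track is used.

# Structural-variant motif analysis

RSS (recombination signal sequence) scanning uses position weight
matrices built from the consensus heptamer CACAGTG and nonamer
ACAAAAACC with probability 0.85 on the consensus base and 0.05
elsewhere — the published scanner's matrices are not recoverable, so a
reproducible consensus PWM is the declared substitute. A scanned
position is a hit when its log-odds score has exact-enumeration
p < 1e-4 under a uniform background (`pwm_score_cutoff()`,
`pwm_tail_prob()`; the score distribution is convolved exactly, and at
this threshold both motifs require a perfect consensus match). A full
RSS additionally requires the nonamer at a 12 or 23 bp spacer ± 1 bp.
Windows are 50 bp either side of either breakpoint for RSS and 1,000 bp
for CSR switch-motif clusters (≥ 2 exact AGCT/TGCA occurrences with
gaps ≤ 100 bp). Positions are signed interior-positive for deletions.

The genomic background is the median per-set hit proportion over 100
random control sets drawn from the callable mask
(`genomic_background()`), and the mechanism-attributable fraction is
the observed proportion minus that background, clamped at zero
(`rag_attributable_fraction()`). Note that under a uniform random
genome the CSR cluster definition fires frequently (AGCT occurs every
~256 bp), so CSR conclusions lean entirely on the background
correction; real genomes and the published cluster scanner are less
permissive.

# Mutation timing by epigenome matching

`attribute_and_bin()` assigns each mutation to its argmax signature
(ties to the lexicographically first name, flagged) and aggregates into
1-Mb windows; signatures averaging under one mutation per window are
flagged ineligible. `epigenome_match()` regresses the window profile on
each candidate epigenome's histone-mark features with a random forest
(`ranger`, 500 trees, seeded, single-threaded) in 10-fold
cross-validation, scoring held-out folds by the LogCosh distance — the
mean of `log(cosh(observed − predicted))`, quadratic for small residuals
and linear for large ones. The best epigenome has the smallest mean
distance; epigenomes are compared by paired two-sided Wilcoxon tests on
the 10 fold values. Multiple marks per epigenome enter as stacked
feature columns (the `groups` argument), the declared resolution of the
combine-marks ambiguity. `matched_count_control()` equalises mutation
numbers between two profiles by seeded multivariate-hypergeometric
subsampling before comparing their matches with an unpaired Wilcoxon
test.

# Germinal-centre summaries and selection

`gc_summary()` combines the on-target somatic hypermutation rate
(IGHV variants / gene length, capped at 1), the genome-wide SBS9 count
(exposure × burden) and per-bp rate (over a callable genome of 3.1 Gb
minus 383 kb), the on/off-target density fold and the off-target ratio;
the identity `density_fold × sbs9_rate = shm_rate` holds to floating
precision. The productive IGHV gene length is a per-sample input — no
universal constant exists. `linear_association()` is ordinary least
squares with a two-sided slope test. `driver_fraction()` converts a
dN/dS ratio ω into the excess fraction (ω − 1)/ω of non-synonymous
mutations under positive selection, clamped at zero, and
`apply_ig_mask()` removes variants inside the three GRCh37
immunoglobulin loci where hypermutation breaks the selection model's
rate assumptions.

# The synthetic-data generator

`sim_config()` holds the generative quantities; its defaults are the
study conditions: seven donors (a neonate, two 4-year-olds, four adults
aged 27–81), five compartments with age slopes 16/15/17/22/25 SNVs per
cell per year, differentiation offsets 0/110/1034/59/277 SNVs, residual
standard deviations 70/150/820/150/592 SNVs, donor standard deviation
60 SNVs, and 20× depth. The naive-compartment residual standard
deviations are not published; 150 SNVs — intermediate between stem and
memory cells, matching the reported confidence-interval widths — was
chosen once and is not revisited. Depth is Poisson around the colony
mean truncated at 1; artefact sites draw a site-specific error
probability once from Uniform(0.01, 0.05) and then binomial counts per
colony, which produces low-VAF noise that is *not* overdispersed — the
exact population the beta-binomial filter must reject; somatic variants
are private to one colony with probability 0.8 and otherwise shared by
a random clade of up to a third of colonies (the true shared fraction
is unknown; 0.8 is a declared free parameter), which guarantees
overdispersion without simulating a full phylogeny. Negative simulated
burdens are clamped to zero with a warning, since burdens are counts.

The generator emulates the *statistical* structure — it does not
simulate reads, base qualities, mapping error, a coalescent phylogeny,
real genomic sequence composition or real epigenomes. Passing tests
therefore demonstrate that the estimators recover their generating
quantities under the modelled noise, not that the pipeline is robust to
artefact classes the generator does not produce.

# Problem sizes and determinism

The test-suite and acceptance runs use: 10,000 sites × 30 colonies for
the filtering confusion matrix; 100 simulated cohorts of 1,400 colonies
for mixed-model coverage; 50,000-mutation catalogues for exposure
recovery; 200 structural variants on an 800-kb synthetic genome; 1,000–
2,000 windows × 4 tracks for epigenome matching; and 25,000 bins for
the single-feature R² calibration. Every stochastic step is seeded;
`run_pipeline()` fans a single global seed out to per-stage seeds by
fixed offsets, so a rerun with the same configuration is byte-identical.

# Known limitations

* The catalogue is synthetic; exposure estimates on real data require a
  real signature catalogue.
* The beta-binomial statistic fed to valley-finding, the consensus PWMs
  and the CSR cluster rule are declared reconstructions — the published
  tools' internals are not recoverable from the text.
* Sex-chromosome handling is limited to the configurable null
  proportion (0.95) of the pooled binomial test.
* dN/dS estimation itself, structural-variant calling, immunoglobulin
  rearrangement reconstruction and telomere-length estimation are
  consumed as inputs, not reimplemented.
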