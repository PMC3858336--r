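---
title: "Models and methods behind hematrio"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hematrio}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hematrio)
```

## The question the package answers

When heterozygous mutations in interacting genes are individually silent
but jointly produce a phenotype, the genes are said to show a complex
haploinsufficiency interaction. hematrio implements this test for a
four-genotype mouse design combining a *c-Myb* null allele with KIX-domain
point mutations in the coactivators CBP and p300, read out as complete
blood counts, plus the companion expression analyses that ask whether
c-Myb-dependent transcription requires the KIX domain.

## The epistasis model

Blood-cell counts are strictly positive, roughly lognormal quantities, so
all modelling happens on the natural-log scale, where a multiplicative
model of allele effects becomes additive. With genotype roles

* `WT0` — wild type,
* `CM1` — *c-Myb*^+/-^,
* `CP2` — *CBP*^+/KIX^;*p300*^+/KIX^,
* `TH3` — the triple heterozygote,

the no-interaction (purely multiplicative) expectation is that the
extreme genotypes jointly equal the intermediates, `WT0 * TH3 =
CM1 * CP2` on the count scale. On the log scale the deviation from that
expectation is the epistasis statistic

$$E = (\mu_{WT0} + \mu_{TH3}) - (\mu_{CM1} + \mu_{CP2}),$$

with $E = 0$ meaning no interaction, $E > 0$ a higher-than-expected
triple-heterozygote phenotype (positive epistasis) and $E < 0$ a
lower-than-expected one. Because counts come from independent
experiments run months apart on a drifting analyser, the per-genotype
means are estimated by a linear mixed model

$$\log y_{ij} = \mu_{g(i)} + b_{j} + \varepsilon_{ij}, \qquad
b_j \sim N(0, \sigma_b^2), \ \varepsilon_{ij} \sim N(0, \sigma_e^2),$$

with an experiment random intercept $b_j$, fitted by REML
(`fit_genotype_model()`, via lme4). $E$ is the contrast
$c^\top\hat\mu$ with $c = (+1, -1, -1, +1)$, its standard error
$\sqrt{c^\top \hat V c}$ from the covariance of the fixed effects, and
the default interval $\hat E \pm z_{0.975}\,\mathrm{SE}$. The sign call
is read off the interval: positive iff the lower limit exceeds 0,
negative iff the upper limit is below 0, otherwise none. Panels over
several cell types are deliberately **not** adjusted for multiplicity;
each interval is per-phenotype.

Numerical and design choices worth knowing:

* **Log base.** Natural logs throughout, recorded in the output
  metadata. $E$ rescales linearly with the base, so magnitudes are only
  comparable between analyses using the same base; the sign and the
  z-statistic are base-invariant.
* **Interval quantile.** The z quantile is the default.
  `df_method = "residual"` switches to a t interval on the residual
  degrees of freedom; in the calibration simulations below both sit
  inside the acceptance band (the t interval is very slightly wider and
  marginally better calibrated at these sample sizes).
* **Boundary fits.** A batch variance estimated at zero is reported as a
  fixed-effects-equivalent fit with a warning, not an error; with a
  single experiment, or `batch_as_random = FALSE`, the model reduces to
  per-group means with pooled residual variance. For balanced
  single-experiment data the mixed contrast equals the plain group
  log-mean contrast to numerical precision, which the tests assert.
* **Degenerate data.** Zero-variance data give SE 0 and a degenerate
  interval equal to the point estimate.
* **Covariates.** Strain and age columns are carried in the data model
  but excluded from the default fit (they carried no detectable effect
  in the motivating study); `covariates =` adds them as fixed effects.
* **Supporting comparisons.** `anova_tukey()` wraps the one-way ANOVA +
  Tukey HSD pairwise test used alongside the interaction analysis, with
  star codes at 0.05/0.01/0.001.

## The blood-count simulator

`simulate_blood_counts()` draws data from exactly the model above: one
random intercept per experiment, one residual per animal, genotype
log-means built as baseline + additive allele effects + an interaction
term `true_E`, so that `true_E` is by construction the quantity the
estimator targets. Counts are returned on the natural scale and are
lognormal — there is no count discretisation, since analyser counts in
K/µL are quasi-continuous. Genotypes are allocated to experiments in
balance by default (remainders round-robin), with an unbalanced mode
that assigns experiments at random for robustness checks. Two calls with
the same seed are identical.

Default study conditions are those of the motivating design: 15 animals
per genotype over 5 experiments, batch sd 0.1 and residual sd 0.2 on the
log scale. The per-genotype raw means of the original animals are not
published, so the baselines in `analysis/01_simulate.R` (platelets
1000 K/µL, hematocrit 45%, lymphocyte subsets 0.8–2 K/µL, neutrophils
1.5 K/µL, monocytes 0.3 K/µL) are ordinary values for healthy young
laboratory mice, chosen once for plausibility, and the planted
interaction terms are the published point estimates, used as simulation
truths rather than reproduction targets. One visible consequence: with a
common residual sd of 0.2, a planted hematocrit interaction of −0.11 is
under-powered at n = 15 and is often (correctly, given the interval)
called "none" — the real study's hematocrit interval was narrower than
its lymphoid ones, implying phenotype-specific noise the simulator does
not model.

What passing the simulation tests shows, and what it does not: the
estimator is consistent, unbiased and calibrated **under its own
generative model** (lognormal noise, shared residual variance, random
batch intercepts). Real blood counts can violate all three assumptions
(heavier tails, phenotype-specific and genotype-specific variance,
batch-by-genotype interactions); the tests say nothing about those
regimes beyond the balanced-design invariances asserted explicitly.

## Expression analyses

`simulate_expression()` emulates a two-genotype (wild type vs KIX
mutant) × two-treatment (control vs c-Myb-expressing) array experiment
on the log2 scale: planted activated genes gain `activation_log2fc`
under treatment, repressed genes lose `|repression_log2fc|`, and a
chosen fraction of each class is KIX-sensitive, meaning the treatment
effect is zero in the mutant. A fraction of unregulated genes sits below
the detection floor in all conditions. Truth labels travel with the
matrix.

The classification pipeline mirrors the figure-level filters of the
motivating analysis:

* replicates are averaged arithmetically on the log2 scale (the scale of
  the published scatter axes); a linear-scale averaging mode exists for
  sensitivity analysis;
* presence = mean log2 signal ≥ 3.4 ("twice background") in **every**
  named condition — the original Affymetrix present/absent detection
  calls cannot be re-derived from signal matrices, so a signal floor
  stands in for them;
* activated = treated/control ratio ≥ 2, repressed = ratio ≤ 0.5,
  KIX-sensitive = response blunted ≥ 1.5-fold in the mutant (reversed
  comparison for repressed genes). All thresholds are inclusive,
  reading "at least twofold" literally. The twofold criterion is applied
  to averaged signals by default; a replicate-wise mode
  (`replicate_t_filter()` for the p < 0.05 variant) is available because
  the published wording is ambiguous between the two;
* probe→gene collapsing keeps the probe with the highest mean signal,
  ties broken lexicographically — the original collapsing rule is
  unstated;
* `direction_concordance()` performs the cross-dataset
  same-direction-of-regulation count used for ChIP-overlap comparisons.

At `noise_sd = 0` the classifier recovers planted truth exactly (the
thresholds are strictly inside the planted effect sizes); recovery
degrades continuously with noise, which the tests check at three noise
levels.

## Gene set enrichment

The enrichment stage is a from-scratch implementation of the standard
weighted Kolmogorov–Smirnov procedure. Genes are ranked by signal-to-noise
$(\bar x_A - \bar x_B)/(s_A + s_B)$ with each class sd floored at
$0.2\,|\bar x|$ (absolute floor 0.2 when mean and sd are both zero) so
near-constant genes cannot dominate. Walking the ranked list, a gene in
the set adds $|r_i|^{p}/\sum_{hits}|r_j|^{p}$ and a miss subtracts
$1/(N - N_{hits})$; the enrichment score is the signed maximum deviation
of the walk, which ends exactly at zero. Defaults $p = 1$, phenotype
permutation, 1000 permutations, set sizes 15–500 follow the published
procedure's defaults, since the motivating paper states none. Ties in
the metric keep stable original gene order.

Significance: class labels are permuted (all distinct assignments are
enumerated when there are at most `n_permutations` of them — with 4
samples per class that is $\binom{8}{4} = 70$, and note the identity
assignment is then always part of the null, so the attainable p floor is
$1/35$ per sign); the nominal p uses the same-signed tail of the set's
own null, NES divides ES by the mean magnitude of same-signed null
scores, FDR q compares the observed NES tail with the pooled normalized
null over all sets (capped at 1), and FWER p uses the distribution of
the per-permutation extreme NES. A tail count of zero is displayed as
`<1/n` alongside the 0, matching the field's reporting convention.
Under a null comparison the nominal p is uniform, which the acceptance
tests check with a Kolmogorov–Smirnov test over 200 independent
two-class matrices.

## Problem sizes used in the checks

The calibration and recovery checks run at the study's own scale —
1000 replicates of 60 animals for coverage and centering, 500 replicates
for recovery of a planted 0.41 platelet interaction, 200 × 500
permutations for null uniformity, 100 random instances for each
enumeration oracle — sizes at which the Monte-Carlo error of each check
is comfortably below its acceptance band.

## Known limitations

* The estimator's interval ignores uncertainty in the variance
  components (no Kenward–Roger/Satterthwaite correction); at 60 animals
  this costs about half a coverage point under the z default.
* The simulators share one residual sd across phenotypes and plant no
  batch-by-genotype or strain effects; they are calibration instruments,
  not generative fits to real animals.
* Presence filtering by signal floor approximates, but is not, the
  original detection-call filter; published probe-set counts are
  therefore not reproducible from signal matrices alone, and the package
  does not attempt them.
* FDR behaviour depends on the composition of the analysed set
  collection; with few sets the pooled-null estimate is coarse.
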