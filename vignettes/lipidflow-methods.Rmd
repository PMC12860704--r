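---
title: "Methods: targeted lipidomics analysis with lipidflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: targeted lipidomics analysis with lipidflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidflow)
```

# Scope and model

`lipidflow` implements the complete computational analysis of a two-group
targeted-lipidomics study design: a disease group (here labelled CKD, for a
chronic-kidney-disease mouse model) against controls (CTL/sham), with lipid
panels measured in plasma and peritoneal macrophages, an acylcarnitine
panel, a deuterated-water labelling arm for de novo lipogenesis, and qPCR
expression measurements. Every stage is an ordinary tidyverse verb on a
tibble, so the pipeline is a pipe chain, and every result has `tidy()` /
`glance()` / `autoplot()` methods.

## Quantification and normalization

Targeted LC-MS/MS panels report one peak area per lipid per sample plus a
spiked internal standard per lipid class. Concentration is the area ratio
times the standard's known concentration:

$$c_{ij} = \frac{a_{ij}}{a^{IS}_{k(i),j}} \cdot c^{IS}_{k(i)}$$

for lipid $i$ in class $k(i)$, sample $j$. Vendors do not publish the
class-to-standard assignment, so `quantify_areas()` requires it as an
explicit mapping and validates completeness. Cell-pellet samples are then
normalized to total protein mass, plasma to sampled volume (canonically
50 µl). Missing peaks stay missing here; imputation is a later, declared
step.

## Preprocessing chain

The chain is: missingness filter → k-nearest-neighbour imputation → TAG
isotopomer collapse → class-wise sum normalization → logit transform →
per-feature z-score. Choices that needed fixing:

* **Missingness** ("below 50%" retained) is read strictly: a feature missing
  in exactly half the samples of any tissue is dropped. Fractions are
  computed within tissue because detected panels differ between plasma and
  macrophages.
* **KNN imputation** is feature-space: the $k = 10$ nearest features by
  root-mean-square Euclidean distance on standardized, pairwise-complete
  profiles donate their mean value in the target sample. Only features
  observed in that sample are candidates; a feature with no co-observed
  partner falls back to its own median (warned). Observed cells are never
  altered.
* **TAG collapse**: vendor panels report each triacylglycerol once per
  named constituent acyl chain; all features sharing a total
  carbon:double-bond composition are summed into one species (445 panel
  features → 95 compositions under the default panel). Per-sample class
  totals are conserved exactly. The collapse key (total composition) is an
  inference from the panel arithmetic; sn-resolved isomers are out of
  scope.
* **Logit clamp**: class fractions are clamped into $[\varepsilon,
  1-\varepsilon]$ before $\log(p/(1-p))$, with $\varepsilon$ = half the
  smallest nonzero fraction, floored at $10^{-6}$. Data-adaptive, monotone,
  and keeps singleton classes finite. A singleton class is constant 1 after
  clamping and is dropped at the z-score stage (zero variance), with a
  warning.
* **z-score** uses the $n-1$ standard deviation, so tests can assert exact
  closed forms.

## Differential abundance

Feature-level comparisons are Welch t-tests on the z-score scale, tallied
at raw $p < 0.01$ (the counting rule used for cross-tissue accounting) with
BH-adjusted values alongside. Class/subclass effects pool all feature
observations of a stratum (class × saturation by default) into a linear
mixed model

$$z_{fs} = \beta_0 + \beta_1\,\text{group}_s + u_f + \epsilon_{fs}, \qquad
u_f \sim N(0, \sigma^2_u)$$

with a random intercept per lipid species, respecting within-class
correlation. `lme4` supplies the fit; the group-effect p-value is the Wald
normal approximation on the t-statistic (no Satterthwaite machinery is
available in this dependency set, and at the pooled sample sizes involved
the approximation error is small — the null-calibration test bounds it). A
single-feature stratum degenerates to the plain t-test. BH adjustment runs
across all strata tested. The mixed model is the default because the more
specific description of the published analysis names mixed models; a plain
fixed-effect model is a config option.

For published tables that report only n, mean ± SD per group,
`ttest_from_summary()` reproduces pooled-variance (default) or Welch
t-tests from the summary statistics alone. Pooled variance reproduces the
printed p-values of the worked examples used in the acceptance tests; one
published row (16-week body weight) reproduces under neither variant and
is deliberately not asserted.

## Correlation networks

**Marginal networks** score every feature pair with Pearson r, test via
Fisher Z ($z = \operatorname{atanh} r$, SE $1/\sqrt{n-3}$), BH-adjust
across pairs, and call an edge significant only when both $q < 0.05$ and
$|r| > 0.7$ — the conjunctive reporting rule.

**DSPC** (debiased sparse partial correlation) is authored in-package as
the desparsified nodewise lasso: each node is lasso-regressed on all
others (penalty chosen per node by 10-fold cross-validation), the relaxed
inverse-covariance estimate $\hat\Theta$ is assembled from the nodewise
coefficients with $\hat\tau_j^2 = \|X_j - X_{-j}\hat\gamma_j\|_2^2/n +
\lambda_j\|\hat\gamma_j\|_1$, and the de-biased estimator

$$\hat T = \hat\Theta + \hat\Theta^\top - \hat\Theta^\top \hat\Sigma \hat\Theta$$

restores asymptotically normal entries with variance $(\hat T_{ii}\hat
T_{jj} + \hat T_{ij}^2)/n$, giving per-edge p-values even when features
outnumber samples. Edges with $p < 0.1$ are flagged, the conventional
liberal threshold for exploratory network contrasts. Known limitation: in
the very-small-n regime (a dozen samples per group) the CV-tuned penalty
overfits, $\hat\tau^2$ shrinks, and the p-values are anti-conservative —
the null-calibration test is run at moderate n where the asymptotics hold.

Between-group comparison builds a 2×2 table of significant versus
non-significant edges over a shared universe (by default all pairs
incident to the chosen FFA stratum and present in both networks, making
the denominators identical) and applies a two-sided Fisher exact test —
sidedness is not specified by the published analysis, and two-sided is the
conservative default.

## Fatty-acid metabolism metrics

* **β-oxidation proxy**: ratio of summed long-chain (C16–C20) to summed
  intermediate-chain (C5–C14) acylcarnitine abundance, per sample, on raw
  within-sample sums (a ratio of standardized values is not
  scale-meaningful). Species outside both windows are excluded;
  unsaturated species count in their carbon window.
* **De novo lipogenesis**: total palmitate deuterium enrichment $E_1 +
  2E_2 + 3E_3 + 4E_4$ over the fractional mass-isotopomer distribution,
  averaged over (nominally triplicate) replicates. Natural-abundance
  correction is not applied — the measure is relative, and the published
  protocol describes none; this is flagged as a limitation.
* **Expression**: ΔΔCt with a per-gene reference-group mean baseline, so
  the reference group's geometric-mean fold change is exactly 1.

# The synthetic-data generator

`generate_study()` emulates the study so the full pipeline is testable
without any data download. Its defaults are a stated world, not tuning
knobs:

* 12 animals per group per tissue (the published design used 10–12).
* The targeted panel's class sizes (TAG as 445 isotopomer features over 95
  compositions, FFA 16, PC 65, PE 47, PE-O 19, PE-P 41, PG 24, SM 27, AC
  29, …). Published class sizes do not sum to the published grand total
  (one class is listed twice); the registry stores each class once and the
  sizes are generator defaults, not validation constraints.
* Log-normal concentrations with class baselines spanning ~3 decades and
  per-feature biological SD σ = 0.4 on the log scale (≈ 40% CV, typical
  for targeted lipidomics of biological replicates).
* Group shifts of ±0.8 SD on the log scale, by class × saturation stratum,
  with directions mirroring the published phenotype (saturated FFA, PG,
  PE, saturated ether-PE up in macrophages; unsaturated FFA, TAG, DAG,
  PC, SM down; opposing directions in plasma).
* Abundance-dependent missingness: logistic in mean log concentration
  (limit-of-detection censoring), calibrated so the overall missing rate
  hits the target (default 5%).
* One latent-factor block (loading 0.9) linking unsaturated FFA and
  unsaturated TAG in the control group only — the mechanism that emulates
  a loss of lipid-lipid interactions in disease.
* Acylcarnitine long-chain abundances multiplied by 0.7 in disease (a 30%
  ratio reduction, consistent with a reported borderline effect at n =
  11/group); equal-by-group deuterium enrichment (plasma 0.15, macrophage
  0.10, liver 0.25 — chosen as realistic relative enrichments after ~72 h
  of 5% heavy water); Acsl1 5-fold and cytokines 2-fold up in disease in
  the qPCR arm.

Peak areas are back-computed through the internal-standard relation, so
quantification inverts the generator to machine precision — an end-to-end
identity the tests assert.

**What a green test does not establish.** The generator draws independent
log-normal features apart from the programmed blocks; real panels have
pervasive correlation, batch structure, and drift that are not emulated
(pooled-QC drift checks are wet-lab QC, out of scope). Compositional
effects matter: class-sum normalization exactly cancels a uniform
multiplicative shift of an entire class, so whole-class programmed shifts
attenuate after preprocessing, and the parameter-recovery tests therefore
assert the saturation-contrast strata (saturated vs unsaturated within a
class), where the contrast survives composition. Similarly, per-sample
protein normalization introduces a shared factor across all features that
sum normalization removes again — correlation-block tests standardize log
concentrations directly so the programmed block is measured where it acts.

# Numerical choices and degenerate inputs

* Correlations are clamped to $|r| \le 1 - 10^{-12}$ before
  $\operatorname{atanh}$; p-values are floored at $10^{-300}$ so BH input
  stays in $(0, 1]$.
* Constant features are dropped (z-score stage, networks) with warnings,
  never silently.
* Stage tags (`raw` → `concentration` → `normalized` → `class_fraction` →
  `logit` → `zscore`) travel as a tibble attribute and out-of-order stage
  application is an error; a table freshly assembled by the user (no tag)
  is accepted and tagged.
* All randomness flows from the config seed; identical configs produce
  byte-identical study bundles (asserted via file digests).

# Worked example

```{r example, eval = FALSE}
library(lipidflow)

study <- generate_study(study_config(seed = 1))
z <- study$peak_areas$PM |>
  quantify_areas(study$standards, study$is_map) |>
  normalize_samples(study$samples) |>
  preprocess_abundance(samples = study$samples)

fit <- fit_class_effects(z, study$samples, stratify_by = "saturation")
tidy(fit)
autoplot(fit)

ratios <- acylcarnitine_ratio(study$ac_profiles)
```

# Known limitations

* No batch/drift correction, no covariate adjustment, no natural-abundance
  isotope correction, no sn-resolved isomer handling — all deliberately
  out of scope.
* Mixed-model p-values use the Wald normal approximation; at very small
  per-stratum sizes they are mildly anti-conservative.
* DSPC inference is asymptotic; with a dozen samples per group its edge
  p-values are exploratory, which is why the edge-contingency comparison,
  not any single edge, is the reported contrast.
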