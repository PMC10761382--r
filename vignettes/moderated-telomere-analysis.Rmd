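---
title: "Moderated Bayesian regression of telomere length and internalizing symptoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Moderated Bayesian regression of telomere length and internalizing symptoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(telomod)
```

## The scientific problem

Telomeres — the protective nucleoprotein caps at chromosome ends — shorten
with cell division and with chronic stress exposure, making relative
telomere length a biomarker of cumulative biological aging. In adolescents,
shorter telomeres have been linked to internalizing symptoms (anxiety and
depression), but the association is inconsistent across samples, suggesting
that the social environment moderates the coupling between cellular aging
and emotional health.

`telomod` implements the full analysis chain used to study that question in
a cross-sectional adolescent cohort:

1. **qPCR quantification** of relative telomere length as a T/S ratio — the
   telomere (T) signal normalized to a single-copy gene (S; albumin) and
   referenced to a calibrator sample;
2. **psychometric scale construction** for ~38 youth- and caregiver-reported
   social-environment instruments, with reliability gating and
   chained-equations imputation of item-level missingness;
3. **Bayesian moderated linear regression** of each z-scored outcome on
   z-scored T/S, z-scored scale scores, all T/S-by-scale product terms, and
   forced covariates (age, sex, collection season), fit by a conjugate
   Gibbs sampler with standard-normal coefficient priors;
4. **evidence summaries** per coefficient: posterior mean, 95% highest
   density interval (HDI), Savage–Dickey inclusion Bayes factor,
   Pr(incl) = BF/(1+BF), and the credibility rule
   Pr(incl) > 0.5 ∧ 0 ∉ HDI.

Because the underlying participant data are not public, the package ships a
first-class **synthetic cohort generator** whose defaults encode the
published study descriptives, so every stage is exercisable and testable at
desk scale.

## The model

For outcome $y$ (z-scored) and design matrix $X$ with columns for the
z-scored T/S ratio $t$, the $k$ z-scored moderator scores $s_j$, the
centered products $t \cdot s_j$, and the centered forced covariates:

$$y = X\beta + \varepsilon, \qquad \varepsilon \sim N(0, \sigma^2 I),
\qquad \beta_j \sim N(0, 1), \qquad
\sigma^2 \sim \mathrm{InvGamma}(a_0, b_0).$$

The Gibbs sampler alternates the two exact conjugate block updates
($\beta \mid \sigma^2$ multivariate normal; $\sigma^2 \mid \beta$
inverse-gamma). A one-time eigendecomposition of $X^\top X$ reduces each
iteration to $O(p)$ work in the eigenbasis, so a full default fit
(4 chains × 6000 iterations, $p \approx 75$) takes about one second in pure
R; draws are rotated back once per chain. Chain $c$ is seeded
`seed + c`, making every fit exactly reproducible.

Evidence for each non-forced coefficient uses the Savage–Dickey density
ratio $BF_{10} = p(\beta_j = 0)/p(\beta_j = 0 \mid y)$. The posterior
density at zero is estimated by Rao-Blackwellization: at every retained
draw the full conditional of $\beta_j$ is an exact normal whose mean and
variance come from the conjugate update restricted to column $j$, and the
conditional densities at zero are averaged. In the no-data limit the
conditionals *are* the prior, so $BF_{10} = 1$ exactly — a property the
test suite asserts to machine precision. A closed-form known-variance
marginal-likelihood oracle (`analytic_bf_oracle`) validates the estimator
on random problems to within 5% on the log scale.

## Tunable parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `coef_sd` | 1 | z-outcome per z-predictor | the standard-normal prior under which the published Bayes factors are defined |
| `a0`, `b0` | 0.01, 0.01 | — | weakly-informative variance prior; the publication never states one, so it is exposed as the sensitivity hook |
| chains × iterations | 4 × 5000 | retained draws | reproduces the published 20,000-draw posterior accounting |
| warmup | 1000 | iterations | discarded burn-in; the publication reports only retained counts |
| r-hat bound | 1.005 | — | the published convergence criterion (classic split-chain statistic, not rank-normalized, matching the era of the cited diagnostic) |
| reliability gate | α > 0.6 (3+ items), r > 0.2 (2 items) | — | the published inclusion rule; inequalities are strict, so a scale at exactly 0.6 is excluded |
| QC range | 0.5 | Ct cycles | triplicate-spread flag; flagged reactions are retained with a warning since no exclusion rule is published |
| imputation | m = 5, 10 sweeps, 5 PMM donors | — | conventional mice-style settings |

## What the synthetic generator emulates — and what it does not

The generator reproduces, per the published descriptives: n = 411; age
truncated-normal (mean 14.23, SD 1.85) on 11–17; 54% female (the abstract's
figure; the results section prints 46% — the discrepancy is left to a
config knob rather than resolved); collection dates uniform over a year,
dichotomized into autumn/winter (September–February) vs spring/summer
(March–August); a registry of 38 instruments with the published item counts
and reliabilities; T/S log-normal moment-matched to mean 0.29, SD 0.81
(SD ≫ mean forces the right skew, and the log-normal is the simplest
positive-support family); and outcomes on their instrument metrics (anxiety
1–5, mean 1.76, SD 0.71; depression 0–3, mean 0.82, SD 0.56).

Likert items are thresholded latent-Gaussian variables: one latent factor
per participant per scale, loadings calibrated so the **discretized** items
reach the target reliability. The calibration inverts a Hermite-series
expression for the correlation of thresholded Gaussians, so even coarse
(binary) items hit their target Cronbach's α in expectation — the naive
continuous-item formula would undershoot binary scales by ~0.1.

Outcomes are built as a linear predictor over the z-scored *realized*
scores (not the latent factors, so no attenuation is built in), normalized
by its theoretical SD so that the standardized regression coefficients of
the z-scored outcome equal the effect-map entries, then affine-mapped to the
instrument metric and clipped to the instrument range. Clipping affects
~15% of anxiety values at the floor (the instrument mean sits 1.07 SD above
its minimum) and ~7% of depression values; the induced coefficient
attenuation is of order 5–7% and is recorded per cohort
(`truth$clip_fraction`).

Default item-level missingness is 5% MCAR (typical survey nonresponse); a
MAR option makes missingness log-odds linear in z-scored caregiver
education, to exercise the imputer beyond MCAR. Imputation chains within
each scale's item table — sibling items are the dominant predictors of an
item, and full cross-scale chaining over ~230 columns would add cost
without adding realism at desk scale.

Deliberately **not** emulated: inter-run qPCR variability at the published
repeatability (ICC 0.62) — default plates carry realistic triplicate noise
(0.15 cycles), which yields duplicate ICC ≈ 0.98; the published 0.62 is
instead the anchor of a dedicated ICC recovery simulation. Also out of
scope: genotypes, spatial neighborhood structure, longitudinal follow-up,
item-level differential functioning, and scale-level correlation structure
(scales are generated independently, so a green recovery test establishes
identifiability under independence, not under the collinearity of real
social-environment measures).

## Numerical choices

- **HDI**: shortest window containing ⌈0.95·S⌉ sorted draws; ties break to
  the leftmost window. On the integer grid 1..100 this gives (1, 95).
- **Split r-hat**: each chain halved; degenerate (zero-variance) chains are
  an error rather than NaN.
- **Bayes factor cap**: 10^6, with a flag, to keep reports finite when the
  posterior places no mass near zero.
- **Pfaffl convention**: efficiency is the amplification factor per cycle
  (2.0 = perfect doubling, matching the published 1.87/1.90);
  `E = 10^(-1/slope)` from the standard-curve slope in cycles per decade.
- **Calibrator**: the Pfaffl reference is a designated plate sample; the
  publication's use of HeLa standards leaves the reference ambiguous, so a
  standard-curve-quantity mode is also provided (`mode = "curve"`), and the
  two agree exactly on noiseless plates.
- **Median split**: values equal to the median go to the low group —
  deterministic, and used for visualization only.
- **Rank deficiency**: the spherical prior is itself the ridge; the sampler
  warns and proceeds.
- **Missing-data handling**: the publication describes letting the prior
  absorb scale-level missingness inside the Bayesian model; the exact
  mechanism is unspecified, so this package imputes item-level data by
  chained equations (PMM), averages scores across the m completed datasets
  before the single fit, and evaluates the reliability gate on the first
  completed dataset (single published α values suggest a single evaluation).
  Rubin's-rules pooling of posteriors across imputations is deliberately
  out of scope.

## Design decisions that were genuinely open

- The depression moderator is caregiver-**sustained** inter-partner
  psychological aggression: of the two candidate CTS subscales, only it
  (α = 0.65) passes the publication's own α > 0.6 gate (inflicted: 0.56).
- Forced covariates ("prior likelihood of 1") are modeled like any other
  coefficient but are always in the model and excluded from BF/credibility
  reporting — no indicator-variable model selection is performed, because
  the Savage–Dickey procedure is the only mechanism described operationally.
- Interaction columns are products of z-scored parents, centered (their raw
  mean equals the parents' sample correlation) but not rescaled, keeping
  coefficients on the simple-slopes scale.
- Separate outcomes get independent MCMC runs with offset seeds
  (`seed`, `seed + 1000`).

## Known limitations

The dominant one: under a log-normal T/S with the published moments
(mean 0.29, SD 0.81; log-variance 2.17), the z-scored T/S column is a
near-constant with a handful of extreme positive values, so every
T/S-by-moderator product column concentrates its statistical information in
those few samples. Per-cohort posterior SDs for interaction coefficients
then fluctuate between roughly 0.08 and 0.3 — two to five times the
published interval widths — and a true interaction of |β| ≈ 0.15 clears the
credibility rule in only a minority of replicates. The package's
parameter-recovery suite therefore verifies *calibration* (95% HDIs cover
seeded truths at nominal rate; null cohorts stay quiet) rather than
*power*; the corresponding acceptance check on majority-credibility is
knowingly left failing, since no two-parameter positive distribution with
those moments is better behaved, and reshaping the T/S marginal to
manufacture power would falsify the stated world. Nothing in this vignette
asserts an empirical result that the test suite or the acceptance script
does not itself compute.

## A minimal run

```r
library(telomod)
cfg <- run_config(outcome = "anxiety", n = 411, seed = 1)
res <- run_analysis(cfg)
print(res)                       # credible terms + max split r-hat
head(res$outcomes$anxiety$summary)
write_report(res, "out/")        # CSV tables + convergence + manifest
```

The acceptance report (`Rscript scripts/acceptance.R --seed 1 --out
results/acceptance.json`) recomputes the headline accounting numbers — the
maximum split r-hat of a default fit, the 20,000-draw posterior pool, and
the 1.56 ng/µL dilution floor — from scratch against the installed package.
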