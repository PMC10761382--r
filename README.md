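# telomod

Bayesian moderated regression of relative telomere length (qPCR T/S ratio)
against adolescent anxiety and depressive symptoms, with social-environment
moderators — plus everything needed to exercise the analysis end to end
when the raw cohort data are unavailable: a synthetic cohort generator,
synthetic qPCR plates, T/S quantification, psychometric scale building with
imputation, and a from-scratch conjugate Gibbs sampler with Savage–Dickey
inclusion Bayes factors.

**Who it is for**: biostatisticians and developmental/psychiatric
epidemiologists who want a tested, reproducible implementation of the
moderated telomere–internalizing analysis chain, or who need a calibrated
synthetic cohort to study the statistical behavior of such designs.

## The model

Relative telomere length is quantified from qPCR cycle thresholds via the
efficiency-corrected ratio against a calibrator sample

    T/S = E_tel^(Ct_cal,TEL − Ct_s,TEL) / E_alb^(Ct_cal,ALB − Ct_s,ALB),

with per-target amplification efficiencies `E = 10^(−1/slope)` from a
5-point two-fold standard dilution series (25 → 1.56 ng/µL). For each
outcome (anxiety, depression) the model is a Bayesian linear regression

    y = Xβ + ε,   ε ~ N(0, σ²I),   β_j ~ N(0,1),   σ² ~ InvGamma(a₀, b₀)

where X holds the z-scored T/S ratio, ~38 z-scored social-environment scale
scores, all T/S × scale product terms, and forced covariates (age, sex,
collection season). Inference is by a blocked conjugate Gibbs sampler
(default 4 chains × 5000 retained draws = 20,000 per parameter), with
split-chain R̂ (< 1.005), 95% highest-density intervals, Savage–Dickey
Bayes factors (prior-to-posterior density ratio at β = 0, Rao-Blackwellized)
and Pr(incl) = BF/(1+BF). A coefficient is *credible* when
Pr(incl) > 0.5 and its HDI excludes zero.

## Worked example

```r
library(telomod)
cfg <- run_config(outcome = "anxiety", n = 411, seed = 3)
res <- run_analysis(cfg)
print(res)
```

```
anxiety: max Rhat 1.0003; credible terms: loneliness, family_support,
  cg_perceived_stress, family_environment:ts, school_belongingness:ts
```

The cohort was simulated with the default effect map, which seeds the
published credible effects (e.g. perceived stress → anxiety at +0.28, the
T/S × school belongingness interaction at −0.16). Inspecting the summary:

```r
s <- res$outcomes$anxiety$summary
s[s$name %in% c("cg_perceived_stress", "school_belongingness:ts"), ]
```

```
                                           name        role    mean hdi_low hdi_high   bf10 pr_incl credible
cg_perceived_stress         cg_perceived_stress      direct  0.2232  0.1067   0.3303 131.10  0.9924     TRUE
school_belongingness:ts school_belongingness:ts interaction -0.3317 -0.5460  -0.1203  11.18  0.9179     TRUE
```

Read: the direct perceived-stress coefficient is recovered near its seeded
+0.28 with overwhelming inclusion evidence; the seeded −0.16 interaction is
inside its (wide) HDI and flagged credible in this replicate — as is one
null-seeded interaction (`family_environment:ts`), a reminder that ~75
terms are tested without multiplicity adjustment. Interaction HDIs are wide
by construction — the heavily right-skewed T/S marginal (mean 0.29,
SD 0.81) concentrates interaction information in a few tail samples; see
the methods vignette, "Known limitations".

Quantification alone:

```r
ch <- generate_cohort(n = 50, seed = 1)
plate <- generate_qpcr_plate(ch$truth$true_ts, noise_sd = 0, seed = 2)
q <- quantify_plate(plate)
q$curves$TEL$efficiency   # 1.87 — recovered exactly from noiseless standards
```

Command-line entry points live in `inst/scripts/` (`quantify.R`,
`moderated-bayes.R`, YAML-configured).

## Layout

- `R/` — cohort generator (`generate_cohort`, `generate_qpcr_plate`),
  quantification (`fit_standard_curve`, `compute_ts_ratio`, `compute_icc`),
  scales (`cronbach_alpha`, `score_scale`, `impute_items`,
  `build_design_matrix`), inference (`gibbs_fit`, `compute_rhat`,
  `compute_hdi`, `savage_dickey_bf`, `analytic_bf_oracle`), pipeline
  (`run_analysis`, `classify_credible`, `median_split_export`,
  `write_report`).
- `vignettes/moderated-telomere-analysis.Rmd` — the methods vignette:
  model, generator assumptions, numerical choices, limitations.
- `tests/testthat/` — unit + property tests per module and
  `test-acceptance.R` (the acceptance criteria at their stated tolerances;
  one recovery clause is knowingly red — see the vignette).
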