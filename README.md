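# mrdflow

Functional clustering and risk stratification of minimal residual
disease (MRD) trajectories.

## What it is for

Clinical trials in hematologic malignancies measure MRD — the molecular
tumor burden, a log-scale tumor-cell ratio from quantitative PCR —
repeatedly at protocol restaging points in bone marrow (BM) and
peripheral blood (PB). The resulting series are short (3–9 points),
irregularly sampled, and censored at the assay limits (positive not
quantifiable, PNQ ≈ 10⁻⁶; negative, NEG). mrdflow is for
biostatisticians and translational researchers who want to turn those
series into a prognostic stratification:

1. **Pre-processing** — encode QUANT/PNQ/NEG results onto one log10
   axis, map protocol labels to months, apply minimum-time-point
   inclusion rules (`read_cohort()`, `encode_mrd_value()`,
   `filter_cohort()`).
2. **Predictive model definition** — fit a Gaussian mixed-effects
   mixture over spline-represented latent curves by EM
   (`fit_fcm()`), with cross-validation and a functional
   Davies–Bouldin index to choose the free parameters
   (`select_model()`, `fdb_index()`), posterior memberships,
   reconstructed continuous curves (`predict_curve()`) and discriminant
   time-importance functions (`discriminant_functions()`).
3. **Model abstraction** — classify never-before-seen trajectories
   against the frozen model with a Shannon-entropy uncertainty gate:
   a patient is UNCLASSIFIED only if the best membership probability is
   below 0.6 **and** the entropy exceeds 1 bit (`classify()`,
   `shannon_entropy()`).
4. **Post-processing** — merge clusters into favorable/unfavorable
   kinetic groups, Kaplan–Meier curves with below-0.5 medians, log-rank
   tests, univariate Cox hazard ratios, landmark analyses that use only
   pre-landmark data, and cross-tissue concordance
   (`km_estimate()`, `logrank_test()`, `cox_hr()`,
   `landmark_analysis()`, `concordance_table()`).

The model, for subject *i* with values *y&#7522;* at times *t&#7522;* and spline
basis matrix *S&#7522;*:

    y_i = S_i (λ0 + Λ α_k + γ_i) + ε_i ,   γ_i ~ N(0, Γ),  ε_i ~ N(0, σ² I)

with cluster *k* drawn with prior π&#8342;; marginally
*y&#7522;* ~ N(*S&#7522;*μ&#8342;, *S&#7522;*Γ*S&#7522;*ᵀ + σ²I), μ&#8342; = λ0 + Λα&#8342;. Estimation is a
generalized EM with a provably non-decreasing observed log-likelihood;
see the methods vignette (`vignettes/mrd-kinetics.Rmd`) for the
half-step structure, identifiability constraints and numerical floors.

A synthetic-cohort generator (`simulate_mrd_study()`) emulating
protocol-scheduled sampling with detection-limit censoring and
cluster-linked relapse hazards makes the whole pipeline testable without
any patient data.

## Worked example

```r
library(mrdflow)

sim <- simulate_mrd_study(config = simulation_config(n_subjects = 120, seed = 42))
cohort <- filter_cohort(sim$cohort, min_timepoints = 3)
fit <- fit_fcm(cohort, G = 4, p = 5, n_starts = 10, seed = 42)
fit
#> Functional clustering fit: G = 4 | p = 5 | h = 3
#> log-likelihood: -459.2949 | converged: FALSE ( 502 iterations )
#> assignment
#>  A  B  C  D
#> 52 27 22 19

## classify a new 6-point series against the frozen model
new_tr <- mrd_trajectory("NEW1", "BM", c(0, 3, 6, 12, 18, 24),
                         c(-2.5, -4, -6.2, -7, -7, -7))
classify(fit$model, new_tr)
#> Patient NEW1 -> B (max p = 1.000, entropy = 0.000 bits, 6 time points)

## favorable (A+B) vs unfavorable (C+D) time to progression
groups <- setNames(merge_groups(fit$assignments), fit$patient_id)
rec <- survival_records(cohort$clinical, groups)
cox_hr(rec, reference = "FAVORABLE")[c("hr", "ci_lower", "ci_upper")]
#> $hr
#> [1] 5.12234
#> $ci_lower
#> [1] 3.066892
#> $ci_upper
#> [1] 8.555362
```

The four recovered clusters are the generator's archetypes
(stable-negative, late-negativization, fluctuating,
transient-negativization), relabeled A–D in order of increasing MRD
burden; the estimated unfavorable-vs-favorable hazard ratio of 5.1
(CI 3.1–8.6) covers the injected value of 4. The `converged: FALSE`
flag only means the variance components were still creeping at the
tight 1e-6 tolerance when the iteration cap was reached; the
memberships are stable (raise `max_iter` to silence it).
A command-line front end over the same functions is installed at
`inst/cli/mrdflow` (subcommands `simulate`, `fit`, `classify`,
`survival`, `landmark`, `run`), and `run_workflow()` drives all four
phases from one YAML config into a static report bundle.

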