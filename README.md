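# thyropls

Paired biomarker analysis and two-block PLS for selenium-supplementation
cohorts in autoimmune thyroiditis.

## The problem

Selenium-supplementation studies in Hashimoto's thyroiditis follow a
within-subjects design: each patient is measured before ("I") and after
("F") supplementation across thyroid-function markers (TSH, fT4, T3,
anti-TPO), selenium-status markers (Se, SELENOP, GPX3), cytokine panels
(IFN-γ, TNF-α, CXCL10, IL-4, IL-1β, IL-17, TGF-β, CRP), metabolic and
anthropometric covariates, and urinary iodine at three timepoints. The
analysis has three stages, each implemented here as tested, reusable
code for anyone running or re-analysing such a study:

1. **Paired univariate comparisons** with distribution-based test
   routing — Shapiro–Wilk, Lilliefors and Levene screening decides
   between the paired Student t-test and the Wilcoxon signed-rank test
   (exact, tie-aware p-values up to 25 pairs) — and the dual summary
   convention: mean ± SD, or for skewed biomarkers the back-transformed
   log-scale mean with a log-scale interval (the `#` convention).

2. **Two-block PLS (NIPALS)** relating a predictor block (thyroid,
   selenium, metabolic, anthropometric, iodine) to an immunological
   response block through mutually orthogonal latent components
   (`w = X'u/|X'u|`, `t = Xw`, `c = Y't/t't`, `u = Yc/c'c`, deflation
   `X − tp'`, `Y − b·tc'`), with per-component cross-validation
   `Q² = 1 − PRESS/SS` (limit 0.05, 7 prediction groups), sequential
   component retention, and iterative pruning of parameters whose
   weights stay below 0.3 on both of the first two components.

3. **Correlation weights**: for each eligible pair of parameters in the
   two-component weight plane (both |weights| > 0.3 along a shared
   axis), the signed statistic `cw(a,b) = ‖a‖·‖b‖·cos θ = a·b`, ranked
   by absolute value into a top-25 table and cross-checked with
   tie-corrected Spearman rank correlations (`N.S.` at p ≥ 0.05).

Because the original patient-level data were never deposited, the
package also ships a **synthetic cohort generator**
(`default_study_spec()` + `generate_cohort()`) that reproduces the
published design: n = 29 paired observations, every published marginal
(including the planted IFN-γ decrease 6.25 → 4.47 pg/mL and the Se
75.0 → 87.7 µg/L shift), lognormal marginals for the skewed biomarkers,
and a latent-factor correlation backbone calibrated in closed form so
the implied Spearman correlations match the published significant pairs
(e.g. GPX3–TGF-β 0.632, age–BMI 0.601) and each biomarker's pre/post
values correlate 0.5 within patient.

## Worked example

```r
library(thyropls)

spec   <- default_study_spec()          # the study conditions
cohort <- generate_cohort(spec, seed = 57)
out    <- run_full_analysis(cohort)     # univariate + two PLS models
out
#> <ht_analysis>
#>   univariate: 21 paired biomarkers; significant: INFg, IL1b, Se, SELENOP
#>   initial model: 8 predictors, 6 responses, 2 component(s) kept
#>   final model: 8 predictors, 6 responses, 3 component(s) kept
```

The univariate table routes each biomarker and applies the summary
convention (`#` marks log-scale summaries):

```r
summarize_cohort(cohort) |>
  dplyr::filter(parameter %in% c("INFg", "TNFa", "IL1b", "Se")) |>
  dplyr::select(parameter, initial, final, test_used, p_value)
#>   parameter               initial                final test_used p_value
#> 1      INFg           7.41 ± 6.11 4.19 (1.60; 10.99) #  wilcoxon 0.01289
#> 2      TNFa 10.21 (1.81; 57.64) # 8.96 (2.39; 33.50) #  wilcoxon 0.33053
#> 3      IL1b          10.28 ± 5.74         13.19 ± 4.58  paired_t 0.00484
#> 4        Se         75.36 ± 13.76         86.75 ± 5.16  wilcoxon 0.00003
```

The planted IFN-γ decrease and IL-1β increase are detected, as are the
selenium-status shifts. The post-supplementation PLS model keeps three
cross-validated components and its ranked correlation-weight table
recovers the planted GPX3–TGF-β association with its Spearman
cross-check:

```r
head(out$models$final$correlations, 4)
#>   param_a param_b     cw spearman_rho spearman_p ns_flag
#> 1  energy  TGFb_F  0.455        0.833   2.06e-08   FALSE
#> 2    T3_F  TGFb_F -0.442       -0.815   7.44e-08   FALSE
#> 3  GPX3_F  TGFb_F  0.389        0.729   7.42e-06   FALSE
#> 4  INFg_F   IL4_F  0.376        0.486   7.49e-03   FALSE

explained_variance(out$models$final$fit)
#>   component   r2x   r2y eigenvalue cum_r2x cum_r2y
#> 1         1 0.397 0.319       3.17   0.397   0.319
#> 2         2 0.358 0.146       2.86   0.754   0.465
```

`cw` is the correlation weight (dot product in the weight plane);
`eigenvalue` uses the convention `λ_a = K_x · r²x_a`, under which the
eigenvalue sum over the predictor count equals the explained X-variance
exactly. `autoplot(out$models$final$fit)` draws the weight plot (dots =
predictors, triangles = responses, dashed lines at ±0.3);
`write_analysis(out, "results/")` emits the summary table, weight
coordinates, correlation tables (CSV) and model reports (JSON).

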