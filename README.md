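# irscore

Predicting post-prostatectomy biochemical recurrence from FT-IR
spectroscopic imaging of the tumor microenvironment.

## The problem and who this is for

Clinical tools for predicting prostate cancer recurrence after radical
prostatectomy (CAPRA-S, Cox-model nomograms) perform worst exactly where
precision is most needed: the mid-grade, organ-confined majority. In a
nested case-control design — each recurrent case matched to a
non-recurrent control on age, race, Gleason score and pathologic stage —
those tools are near chance by construction. FT-IR spectroscopic imaging
records an infrared absorption spectrum per tissue pixel, a label-free
chemical fingerprint, and the tumor-adjacent (reactive) stroma carries
recurrence signal that clinical variables do not.

`irscore` is for computational pathology / biospectroscopy researchers who
want that pipeline as reusable, tested components: per-pixel spectral
metrics, pattern mining, ranking models, clinical baselines and the
matched-design evaluation statistics.

## The method

1. Per-pixel spectra are reduced to *k* spectral metrics (peak
   absorbance, peak ratio, band area, band center of gravity), then each
   metric is discretized into 20 equal-width bins, so pixel *i* becomes a
   vector *d_i* of bin indices.
2. FP-growth mines, per outcome class, every **pattern**
   φ = ((j₁, φ_{j₁}), (j₂, φ_{j₂}), …) — an assignment of bins to a subset
   of metrics — whose support is ≥ θ|D| (θ = 0.02). A two-stage
   rank-sum screen keeps the m = 100 patterns whose per-subject
   frequencies differ between classes and shift toward their source
   class.
3. Per-core pattern frequencies are features for a linear **Ranking-SVM**
   trained on within-pair ordering constraints f(case core) > f(control
   core), after maximal-relevance/minimal-redundancy selection.
4. For patients p₁, p₂ with core sets S₁, S₂ the pooled core scores are
   ranked and

   Preference(p₁; p₂) = Σ_{s ∈ S₁} rank(s)^d,  d ≥ 1,

   normalized by its attainable extremes to **nPreference** ∈ [0, 1]
   (at d = 1 this is the normalized Mann–Whitney U). A query patient is
   matched to the most clinically similar recurrent and non-recurrent
   training patients; a logistic model on the two nPreference covariates
   yields the **IR Score**, the predicted probability of recurrence.
5. Evaluation: nested pair cross-validation with an exact binomial test,
   K-fold query cross-validation, empirical + binormal-smoothed ROC/AUC
   with 2000-rep bootstrap confidence intervals, Kolmogorov–Smirnov score
   comparisons, quartile odds ratios with Wald tests, a full CAPRA-S
   scorer (0–12 points; low/intermediate/high at 0–2/3–5/≥6), a pluggable
   Kattan-nomogram interface, and the weighted combination
   C = (1 − x)·IR + x·E.

Because the original TMA cohorts are not publicly deposited, the package
includes a synthetic matched-cohort generator with planted, analytically
known pattern signal; all shipped checks run on it.

## Worked example

Generate a 20-pair matched cohort with one planted stromal pattern
(3 items, 30% of case stromal pixels vs 5% of control), fit the pipeline,
and evaluate both study designs:

```r
library(irscore)

cfg <- cohort_config(
  n_pairs = 20,
  planted_patterns = list(planted_pattern(metrics = c(2, 5, 7),
                                          bins = c(15, 4, 17),
                                          enrich_case = 0.30,
                                          enrich_control = 0.05)),
  seed = 42)
cohort <- generate_cohort(cfg)
cohort
#> <ir_cohort> 40 patients (20 pairs), 119 cores, 23585 pixels, 12 metrics

fit <- fit_ir_pipeline(cohort$pixels, cohort$clinical, pipeline_config())
fit
#> <ir_pipeline> 1092 union patterns -> 100 retained -> 30 selected features;
#>   training pairwise accuracy 1.000

nested <- nested_cv_pair_accuracy(cohort, pipeline_config(),
                                  cv_config(k = 5, seed = 1))
nested
#> <ir_nested_cv> 20/20 pairs correct (accuracy 1.000), binomial p = 9.54e-07

q <- kfold_query_cv(cohort, pipeline_config(), cv_config(k = 5, seed = 2))
head(q, 4)
#> # A tibble: 4 x 6
#>   patient_id recurrence  fold npref_recurrent npref_nonrecurrent   ir_score
#>   <chr>      <lgl>      <int>           <dbl>              <dbl>      <dbl>
#> 1 P004       FALSE          1             0                0.875 0.00526
#> 2 P014       FALSE          1             0                0.667 0.00000273
#> 3 P019       TRUE           1             0.5              1     1.000
#> 4 P022       FALSE          1             0                0.667 0.00000273

roc_auc_smoothed(q, score = "ir_score")
#> <ir_roc> empirical AUC 1.000, smoothed (binormal) AUC 1.000
#>   (20 cases / 20 controls)

ks_compare(q, score = "ir_score")
#> # A tibble: 1 x 4
#>   statistic  p_value n_case n_control
#>       <dbl>    <dbl>  <int>     <int>
#> 1         1 1.45e-11     20        20
```

Reading the output: every held-out pair is ordered correctly (exact
binomial tail 9.5e-07), and held-out query IR Scores separate cases from
controls completely — expected here, since the planted 30%-vs-5%
enrichment over hundreds of pixels per core is a very strong signal. On
null cohorts (`generate_null_cohort()`) the same machinery returns
chance-level accuracy and AUC ≈ 0.5; that calibration is part of the test
suite. `autoplot(roc_auc_smoothed(...))` and `plot_score_distributions(q,
"ir_score")` draw the corresponding figures, and `tidy()`/`glance()`
methods expose model internals as tibbles.

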