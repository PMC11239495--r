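# glucotrack

Analysis tools for asking *what temporal feature of blood glucose a neural
population encodes*: the current concentration (proportional tracking) or
its rate of change (derivative tracking). The package reimplements, as a
tested R pipeline, the analysis workflow used to study hypothalamic
hypocretin/orexin neurons (HONs) recorded simultaneously with blood
glucose telemetry, indirect calorimetry, body temperature and wheel
running in behaving mice — driven by a synthetic session generator with
ground-truth labels so every stage can be validated by parameter
recovery.

## What it computes

- **Photometry conditioning.** A raw fluorescence trace is detrended by
  fitting a non-negative triple exponential
  `f(t) = a₁e^(−t/τ₁) + a₂e^(−t/τ₂) + a₃e^(−t/τ₃) + c` through the lower
  convex hull of the trace (its local-minima envelope), forming
  `(F − f)/f`, then z-scoring against the 20-min pre-infusion baseline.
- **Temporal analyses.** Finite-difference derivatives (units/min),
  lagged cross-correlation, simple linear fits (R², slope p-value),
  glucose-transient detection, 50-point hysteresis loops with signed
  shoelace area, canonical epoch means (baseline −11…−2, high-derivative
  2…11, high-absolute 11…20 min), locomotion bouts (super-threshold runs
  ≥ 1 s separated by > 2 s), Weir energy expenditure
  `3.94·VO₂ + 1.1·VCO₂` and the respiratory exchange ratio `VCO₂/VO₂`.
- **Encoding model.** Activity is regressed on ten predictors (running,
  glucose, temperature, VO₂, VCO₂ and their derivatives, each 1-min
  binned, Savitzky–Golay filtered and z-scored) with a chunked bootstrap:
  contiguous quarter-duration chunks are randomly assigned 70/30 to
  train/validation; each predictor's contribution is the validation
  ΔR² = R²(full) − R²(without it), clipped at zero, median-aggregated and
  normalized to percent.
- **Single-cell classification.** Four templates built from a held-out
  glucose trace — smoothed glucose (G), its re-smoothed derivative (dG)
  and their inversions (iG, idG) — over the first 20 min post-infusion.
  Each cell takes the class of its maximum Pearson correlation unless no
  template reaches p < 0.001/4 (Bonferroni), in which case it is
  no-response (N/A). Running coupling is classified by whole-session
  Spearman correlation (positive: p < 0.05, ρ > 0.01; negative:
  p < 0.05, ρ < −0.01), cross-tabulated with the glucose classes into a
  multiplexing table, and the population response is reconstructed as
  Σ prevalence × amplitude × template.
- **ROI identity matching.** Two ROIs are the same cell when they sit on
  neighbouring imaging planes, their 3-pixel-dilated masks overlap by
  more than 5%, their traces correlate above 0.90 at a lag under 2 s,
  and the pairing recurs in at least two sessions; joined pairs merge by
  connected components.

## Worked example

```r
library(glucotrack)

sim    <- simulate_session(sim_config(seed = 42, n_cells = 200))
report <- run_pipeline(sim, encode_iterations = 200)
print(report)
```

```
<analysis_report>
  cross-correlation peak: r = -0.52 at lag -529 s
  R^2 activity ~ glucose: 0.008; ~ d[glucose]/dt: 0.921
  top encoding predictor: d_glucose (99.9% of explained variance)
  cell classes: G 22%, dG 7%, iG 28%, idG 41%, N/A 2%
  multiplexed (glucose x running): 37%
```

Reading the output: the cross-correlation peak at a *negative* lag means
population activity changes minutes before blood glucose does; activity
is barely explained by the glucose concentration itself (R² ≈ 0.01) but
almost entirely by its rate of change (R² ≈ 0.92); the encoding model
attributes the explained variance to the glucose derivative; and the
single-cell classifier recovers the simulated mixture of proportional
(G/iG) and derivative (dG/idG) trackers, with 2% of cells failing every
template. Fitted objects follow broom conventions:

```r
head(tidy(report$encoding), 3)
#> # A tibble: 3 × 5
#>   predictor delta_r2_median delta_r2_mean contribution_pct  rank
#>   <chr>               <dbl>         <dbl>            <dbl> <int>
#> 1 d_glucose        34.2           261.             99.9        1
#> 2 vo2               0.0138          0.121           0.0404     2
#> 3 running           0.00504         0.157           0.0147     3
```

and every result type has a ggplot2 `autoplot()` method
(cross-correlograms, hysteresis loops, contribution rankings, templates,
session channels).

## Package layout

| Area | Files |
|---|---|
| Synthetic sessions | `R/simulate.R`, `R/session.R` |
| Fluorescence conditioning | `R/preprocess.R` |
| Temporal analyses | `R/temporal.R` |
| Encoding model | `R/encoding.R` |
| Cell classification | `R/classify.R` |
| ROI matching | `R/roi.R` |
| Orchestration, tidiers, plots | `R/pipeline.R`, `R/tidiers.R`, `R/plots.R` |

The methods vignette (`vignettes/glucose-tracking.Rmd`) documents the
models, parameter choices and known limitations.
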