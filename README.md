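# g1dist

Single-cell G1 length distributions, sister-cell asymmetry, and a
WNT-linked shifted-Poisson model.

## What it is for

Human pluripotent stem cell populations are heterogeneous in the absolute
length of G1, and the shape of the single-cell G1 length distribution — not
the fraction of cells in G1 — predicts the population's differentiation bias.
`g1dist` implements that analysis for FUCCI time-lapse data:

* parse per-cell FUCCI color-event tables and derive absolute phase lengths
  (G1 = red-on to green-on; S/G2/M = red-off to green-off; 10-min frames by
  default, censoring at the movie boundary);
* summarize and compare G1 distributions (CV, cutoff splits, two-sample
  Kolmogorov-Smirnov and Mann-Whitney U with exact tie handling);
* quantify sister-cell G1 asymmetry via ΔG1/⟨G1⟩ at fixed and sliding
  cutoffs, and sister-sister correlation;
* fit the core model: shift G1 by the pooled minimum, G1\* = G1 − c, so that
  var(G1\*) ≈ mean(G1\*), then regress the per-condition mean of G1\* on the
  population AXIN2 level (the WNT readout) with a log link,

  μ\* = exp(β₀ + β₁·AXIN2),   P(G1\*) = μ^{G1\*} e^{−μ} / Γ(G1\* + 1),

  giving the predicted single-cell distribution and its CV,
  CV(G1) = √μ\* / (μ\* + c), plus q-q, Box-Cox and dispersion diagnostics;
* score CG-normalized 5-hmC density per transcript and gene (gene body
  ± 1 kb, isoform ratios summed per gene) and compare gene sets by ECDF and
  U tests;
* generate synthetic lineage-resolved track tables and 5-hmC fixtures with
  the statistical structure the analysis assumes, and orchestrate everything
  through `run_pipeline()` with a reproducible manifest.

## Worked example

```r
library(g1dist)

cfg   <- sim_config(seed = 42)          # study conditions, published panel sizes
study <- simulate_study(cfg)
rec   <- derive_phase_lengths(study$tracks)

low  <- rec[rec$condition == "mtesr1" & !rec$g1_censored, ]  # low WNT
high <- rec[rec$condition == "e8" & !rec$g1_censored, ]      # high WNT

summarize_lengths(low$g1_hours)
#> Phase-length summary: n = 114
#>   mean 6.481 h, sd 1.535 h, range [4.17, 13.33] h
#>   CV 23.7%

ks_two_sample(high$g1_hours, low$g1_hours)
#> KS: statistic = 0.751566, p = < 2.2e-16 (n1 = 112, n2 = 114, asymptotic)

pairs <- pair_and_score(low)
classify_pairs(pairs, cutoff = 0.2)$fraction_asymmetric   # 0.12
sister_correlation(pairs)$r                               # 0.60

ds    <- simulate_dose_series(sim_config(seed = 42))      # WNT3A 0/10/20/100 ng/ml
drec  <- subset(derive_phase_lengths(ds$tracks), !g1_censored)
ax    <- setNames(ds$conditions$axin2_level, ds$conditions$label)
cells <- data.frame(condition = drec$condition, axin2 = ax[drec$condition],
                    g1_hours = drec$g1_hours)
model <- fit_wnt_g1_glm(cells, pooled_shift(cells$g1_hours))
model
#> Shifted-Poisson G1 model: mu* = exp(beta0 + beta1 * AXIN2)
#>   c_shift = 4.000 h, beta0 = 3.495, beta1 = -6945.32
#>   adj R^2 = 0.988, dispersion var/mean = 1.506, quadratic-term p = 0.385

predicted_cv(predict_mu(model, 3.6e-4), model$c_shift)    # 0.245
```

Reading the output: the low-WNT population has long, variable G1 (mean
6.5 h, CV 24%) while the high-WNT population is short and narrow, and the
two distributions separate completely (KS D = 0.75, p below the 2.2e-16
reporting floor). Most sister pairs share G1 length (r = 0.60) but a
minority are asymmetric, which maintains the population's spread. The fitted
coefficients recover the generating exponential link (β₀ = 3.2,
β₁ = −6380 up to one series' sampling error), and the model converts any
AXIN2 level into a predicted mean, distribution and CV of G1.

The methods vignette (`vignettes/g1-length-distributions.Rmd`) documents the
model, its assumptions, the generator's calibration, and known limitations.

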