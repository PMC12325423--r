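# bileEEM

Characterisation of the fluorescence fingerprint of fish bile from
excitation–emission matrix (EEM) dilution series. Bile concentrates
fluorescent metabolites, which makes its EEM a candidate biomarker of
pollutant exposure — but only once the intrinsic bile fluorescence baseline
is resolved into its fluorophore components and separated from measurement
artifacts. `bileEEM` provides that workflow for chemometricians and
ecotoxicologists:

* **Preprocessing** — solvent-blank subtraction, excision of the four
  Rayleigh/Raman scattering bands (defaults +20/−10, +20/−15, +5/−15,
  +10/−15 nm around each line) and interpolation over the gaps.
* **Dilution-series handling** — dilution factors
  `DF = V0 / (V0 + Vsolvent)` (labels "1:N" read as DF = 1/N),
  inner-filter-effect detection on dilution curves, and thin-limit sample
  selection (`DF ≤ 0.0025` by default, with logged overrides).
* **Decomposition** — non-negativity-constrained PARAFAC
  `X[i,j,k] = Σ_f a_if b_jf c_kf + e_ijk` fitted by multi-start alternating
  least squares (compiled NNLS sub-solves), with residual sum of squares,
  core consistency (CORCONDIA) and a factor-count selection rule.
* **Diagnostics** — ±10% moving-window bias/SD/RMSE discrepancy maps,
  reduced major axis regression of modeled on observed surfaces,
  per-sample RMSE-to-mean ratios, score–dilution curves with monotonicity
  checks, and equal-score concentration-ratio estimation between sources.
* **Synthetic studies** — a generator of EEM dilution studies with known
  ground truth (Gaussian fluorophores, blank, scatter ridges, inner-filter
  attenuation, noise), so the full pipeline is testable without
  instrument data.

## Worked example

```r
library(bileEEM)

study  <- make_study(default_scenario(seed = 42))        # 7 sources x 7 dilutions
pre    <- lapply(study$eems, preprocess_eem, blank = study$blank)
sel    <- select_thin_limit(study$manifest)              # keeps DF <= 0.0025
tensor <- stack_eems(pre[sel$included$sample_id], sel$included)

sweep  <- model_sweep(tensor, 1:4, fit_options(n_starts = 10, seed = 42))
sweep
#>  F core_consistency         rss converged n_iter
#>  1        100.00000 39672555258      TRUE      8
#>  2         99.98132 10872551674      TRUE     11
#>  3         96.31462 10446458018      TRUE     12
#>  4         69.46001 10236411635      TRUE     35

best <- sweep$models[[as.character(choose_factor_count(sweep$table))]]
best
#> <parafac_model> F = 3, RSS = 1.04465e+10, core consistency = 96.3%, 12 iteration(s), converged
peak_location(best, 1)
#>  ex  em
#> 225 365
```

Reading the output: a one-factor model always has core consistency 100, so
the sweep is judged by where the statistic collapses — here it holds in the
90s up to F = 3 (the number of planted fluorophores) and drops sharply at
F = 4, so `choose_factor_count()` selects three factors. The dominant
factor's loading peaks at excitation 225 nm / emission 365 nm, recovering
the planted tryptophan-like family (Ex 225 / Em 360) to within one 5 nm
grid step on this noisy fit. Scores (`best$A`) are concentration proxies:
regressed against the generator's truth they are proportional within 2% in
the thin limit.

The `analysis/` directory holds the narrative drivers
(`01_simulate.R` → `04_diagnostics.R`); run them in order from the
repository root to produce the study, preprocessed surfaces, factor sweeps
and diagnostics tables under `results/`.

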