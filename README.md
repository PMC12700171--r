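# photoyield

Linking the excited-state kinetics of organic photosensitizers (OPSs) to
their photocatalytic activity. Given the five first-order rate constants of
the three-state (S0, S1, T1) kinetic scheme —

- `k_r(S1→S0)` radiative decay,
- `k_ic(S1→S0)` internal conversion,
- `k_isc(S1→T1)` intersystem crossing,
- `k_risc(T1→S1)` reverse intersystem crossing,
- `k_isc(T1→S0)` non-radiative triplet decay

— the package builds descriptor sets from them, predicts product yields of
photocatalytic reactions with gradient-boosted trees, and decomposes every
prediction into per-descriptor Shapley attributions. It is aimed at
photochemists and cheminformaticians who have (computed or measured) rate
constants for a sensitizer library plus screening yields, and want to know
*which* excited-state processes drive catalytic activity.

## What it computes

**Photophysics.** The S1/T1 populations obey the linear system

    d[S1]/dt = -(k_r + k_ic + k_isc)[S1] + k_risc[T1]
    d[T1]/dt = k_isc[S1] - (k_risc + k_isc,T1S0)[T1]

whose two negative eigenvalues give the prompt and delayed emission
lifetimes (τ_p, τ_d); the emission quantum yield is
Φ = k_r ∫[S1]dt, split into prompt/delayed shares by eigenmode.
`decay_eigenmodes()` evaluates this in closed form, `integrate_populations()`
is the numerical ODE oracle, `invert_observables()` recovers rate constants
from measured (τ_p, τ_d, Φ_p, Φ_d), and `detailed_balance_risc()` is the
thermally activated up-conversion surrogate
k_risc = k_isc · exp(−ΔE_ST / k_B T).

**Descriptors.** `scale_rates()` forms the branching-ratio descriptor set
s_RC (each rate divided by the sum of all five, so components sum to 1);
`assemble_features()` joins a base rate set (s_RC, or log10 raw rates RC),
any subset of seven electronic descriptors (E_HOMO, E_LUMO, E_S1, E_T1,
ΔE_ST, f_S1, ΔDM) and a one-hot reaction encoding into the model matrix.

**Modelling.** `train_model()` fits a histogram-binned gradient-boosted
regressor (xgboost, `tree_method = "hist"`); `evaluate_repeated()` reports
test-set R² and RMSE averaged over repeated random splits with fixed seeds;
`subset_search()` scores every non-empty auxiliary-descriptor subset
(2^7 − 1 = 127 combinations for the full pool) with paired splits.

**Attribution.** `explain_model()` computes exact interventional
tree-Shapley attributions (additive: base value + Σφ = prediction);
`exact_shapley()` is the brute-force coalition-enumeration oracle;
`summarize_attributions()` / `waterfall_table()` produce the bar, scatter
and waterfall data; `pairwise_attribution()` decomposes the predicted-yield
difference between two sensitizers into per-descriptor contributions.

**Synthetic data.** `generate_sensitizers()` / `generate_yields()` create a
population with the statistical structure the analysis assumes (rate
constants spanning many decades, 0.86-correlated frontier orbitals, yields
driven by triplet-channel branching ratios, an orbital-energy window and
the singlet–triplet gap), so the whole pipeline is testable without
quantum-chemistry calculations.

## Worked example

```r
library(photoyield)

# OPS1 (4CzIPN) with its experimentally determined rate constants
ops1 <- rate_constant_set(k_r_S1S0 = 1.7e7, k_isc_S1T1 = 5.1e7,
                          k_risc_T1S1 = 2.7e6)
decay_eigenmodes(ops1)
#> <photophysics_observables>
#>   tau_prompt  1.428e-08 s
#>   tau_delayed 1.526e-06 s
#>   phi_prompt  0.2356 | phi_delayed 0.7644 | phi_total 1

config <- generator_config(seed = 1)          # 60 OPSs x 5 reactions
sens   <- generate_sensitizers(config)
yields <- generate_yields(sens, config)
dm <- assemble_features(yields, sens,
        feature_spec("s_RC", auxiliary = c("E_HOMO", "f_S1", "dEST", "dDM")))
evaluate_repeated(dm, n_runs = 10)
#> <evaluation_result> s_RC + E_HOMO + f_S1 + dEST + dDM
#>   R2 0.831 (0.048)  RMSE 12.86 (1.89)  [10 runs]

model <- train_model(dm)
expl  <- explain_model(model)
head(summarize_attributions(expl)$bar, 3)
#> 1 s_k_risc_T1S1        13.5
#> 2 s_k_isc_T1S0          6.50
#> 3 reaction_CO-a         6.37
```

The prompt lifetime of OPS1 (14.28 ns) matches its measured 14.2 ns within
1%; on the default synthetic dataset the model explains ~0.83 of held-out
yield variance (RMSE ~13 yield points), and the attribution ranking
recovers the triplet-channel branching ratios that generate the yields.

The same sequence, at full scale and with all tables written under
`results/`, is scripted in `analysis/01_simulate.R` …
`analysis/05_shap.R`; `run_pipeline()` executes it from a single YAML
config.

## Package layout

- `R/`, `src/` — implementation (the tree-Shapley kernel is compiled);
- `analysis/` — numbered narrative scripts reproducing the full analysis;
- `tests/testthat/` — unit, property and acceptance tests, including the
  ODE and coalition-enumeration oracles;
- `vignettes/methods.Rmd` — models, assumptions, parameter choices and
  limitations.
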