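---
title: "Methods: excited-state kinetics, yield models and Shapley attribution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: excited-state kinetics, yield models and Shapley attribution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models implemented in `photoyield`, the
assumptions behind them, the parameters a user may want to change, the
numerical choices made where the design was genuinely open, and the known
limitations. Nothing here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The three-state kinetic model

An organic photosensitizer (OPS) is modelled with three electronic states:
the ground state S0, the first excited singlet S1 and the first triplet T1.
Five first-order rate constants (all in 1/s) connect them: radiative decay
`k_r_S1S0`, internal conversion `k_ic_S1S0`, intersystem crossing
`k_isc_S1T1`, reverse intersystem crossing `k_risc_T1S1` and non-radiative
triplet decay `k_isc_T1S0`. The radiative T1→S0 channel (phosphorescence)
is omitted: in purely organic sensitizers it is far slower than the
competing channels and does not shape the kinetics. After an excitation
pulse ([S1](0) = 1) the populations follow a linear two-compartment system;
its rate matrix has two real negative eigenvalues whose inverses are the
prompt and delayed emission lifetimes — the familiar biexponential decay of
thermally activated delayed fluorescence (TADF). The emission quantum yield
is `k_r` times the time-integral of [S1].

Assumptions worth stating explicitly:

* first-order kinetics throughout — no annihilation, no excimer formation,
  no substrate quenching term;
* a single emitting state (S1); T1 contributes to emission only through
  reverse ISC;
* time-independent rate constants (fixed temperature and solvent).

**Prompt/delayed yield split.** Measured quantum-yield pairs are usually
reported without a definition of the split. Here the split is defined by
the eigenmode decomposition of the [S1] integral: the fast mode's share of
`k_r ∫[S1]dt` is the prompt yield. This is an explicit package convention,
chosen because it is unambiguous, additive and reproducible.

**Degenerate inputs.** If the triplet has no decay channel at all
(`k_risc = k_isc_T1S0 = 0`), the delayed lifetime is reported as `NA` and
the delayed yield as 0. If the two eigenvalues coincide within a relative
1e-12, a single lifetime is reported for both components. A system whose
S1/T1 cycle has no loss channel does not decay and is rejected with an
error. When both non-emissive channels are exactly zero the quantum yield
is set to exactly 1 rather than evaluated through the cancelling ratio.

**Inversion.** `invert_observables()` recovers rate constants from
(τ_prompt, τ_delayed, Φ_prompt, Φ_delayed). Five unknowns face at most four
independent observables, so at least one rate must be fixed; the default
convention fixes `k_ic_S1S0 = 0` and attributes any sub-unity total yield
to the triplet loss channel. When all four observables are present the
inverse has a closed form (the amplitude split of the biexponential pins
the total S1 depopulation rate and `k_r`; the eigenvalue sum and product
then give the triplet rates), which is used as the optimizer's starting
point; a bounded least-squares polish in log10-rate space (bounds
1e-2–1e12 1/s, because rates span more than ten decades) plus a small
deterministic multi-start ladder handles partial observable sets. The
round-trip property (forward model → inversion recovers the free rates to
1e-4 relative) is enforced in the test suite over random rate sets spanning
1e4–1e9 1/s.

**Detailed-balance surrogate.** The synthetic generator couples reverse to
forward ISC through the thermal activation picture
`k_risc = k_isc · exp(−ΔE_ST / k_B T)` (k_B = 8.617333e-5 eV/K, default
T = 298 K, configurable). This is a deliberate simplification of the real
vibronically mediated process — adequate for generating populations whose
small singlet–triplet gaps co-occur with fast up-conversion, not for
quantitative rate prediction.

## Descriptors

The branching-ratio set **s_RC** divides each rate constant by the sum of
all five, so the components are dimensionless, lie in [0, 1], sum to 1 and
are invariant under an overall rescaling of the kinetics. The raw set
**RC** is log10-transformed by default: tree models are scale-robust, but
logs make attribution scatter plots over ten-decade rates readable; the raw
mode remains available via `rate_transform = "raw"`. Rates are floored at
1e-12 1/s before taking logs because computed reverse-ISC rates can
underflow to ~1e-5 1/s and below for large gaps. Reaction identity is
one-hot encoded with *all* levels kept (no reference level dropped) so that
every reaction's contribution is visible in attribution plots. No
centering or standardization is applied anywhere: gradient-boosted trees
are invariant to monotone feature scaling, and untouched values keep the
attribution axes physical.

## Yield model and evaluation

The regressor is a histogram-binned gradient-boosted tree ensemble
(xgboost, `tree_method = "hist"`). Defaults: 100 rounds, learning rate 0.1,
depth 4, `min_child_weight = 2`, no row/column subsampling — the last
choice makes every fit bit-reproducible regardless of seed. All
hyperparameters are exposed through `train_model()` and the pipeline
config; no tuning machinery is included, because the package's purpose is
descriptor comparison and attribution at a fixed, adequate model class.

Evaluation uses repeated uniform random row splits (default 20% test,
seeds 0…n_runs−1) and reports the mean and sample SD of test-set R² and
RMSE. R² is computed against the test-fold mean. Fixed split seeds make
subset comparisons *paired*: every descriptor subset is scored on the
identical sequence of splits, so ranking differences are not split noise.
Row-level splitting means the same sensitizer can appear in train and test
under different reactions — the evaluation is interpolative by design (the
question is "how well do these descriptors carry over across this library
and reaction panel", not extrapolation to unseen chemistry). Grouped
splitting by sensitizer would be the natural extension and is a known
limitation.

The exhaustive search enumerates all 2^d − 1 non-empty subsets of the
auxiliary pool (guarded at d ≤ 15), ranks by mean R² (ties: mean RMSE, then
subset label) and is deterministic end to end.

## Shapley attribution

`explain_model()` implements **interventional** tree-Shapley attribution:
the value of a feature coalition S for row x is the expected model output
when features outside S are replaced by values from a background row,
averaged over a background set (default: the full training data,
optionally a seed-fixed subsample). For a tree ensemble this expectation is
computed exactly, leaf by leaf: for one (row, background-row) pair each
leaf's path constraints split the path features into a set A that only x
satisfies and a set B that only the background row satisfies, and the
Shapley value of the resulting indicator game has the closed form
`+v·(a−1)!·b!/(a+b)!` for members of A and `−v·a!·(b−1)!/(a+b)!` for
members of B. Summing over leaves, trees and background rows gives
attributions that satisfy additivity (base value + Σφ = prediction)
exactly. The interventional variant was chosen over path-dependent
weighting because it has a model-agnostic definition — the classic Shapley
formula over coalitions with background replacement — and can therefore be
verified against an independent brute-force oracle (`exact_shapley()`,
feasible up to ~15 features); the test suite checks agreement to 1e-8 and
per-row additivity to 1e-6.

One numerical subtlety: xgboost routes rows by float32 comparison and
accumulates leaf values in float32. The attribution kernel reproduces the
float32 *routing* exactly (otherwise rows lying on histogram cut points are
misattributed) but sums leaf values in double precision; predictions
reported alongside attributions use the same double-precision path
(`predict(..., precise = TRUE)`), which differs from the booster's native
output by less than 1e-4 yield points.

Pairwise decomposition compares two explanations from the same model and
background: base values cancel, so the difference of predictions equals the
sum of per-feature attribution differences, and the share of any named
feature subset is reported both as signed yield points and as a fraction of
the total gap. A zero total gap with a nonzero subset contribution is
flagged as undefined rather than divided through.

## The synthetic generator

The generator stands in for quantum-chemistry pipelines and screening
campaigns; its defaults describe the study design the analysis assumes
(60 sensitizers × 5 reactions = 300 rows, one mechanistic family). What it
emulates:

* rate constants spanning many decades: log-uniform draws over
  k_r 10^6–10^7.7, k_ic 10^4–10^8, k_isc(S1→T1) 10^5–10^9,
  k_isc(T1→S0) 10^2–10^6 1/s, with k_risc derived from the
  detailed-balance surrogate times truncated lognormal scatter
  (SD 0.5 decades, cut at ±3 SD) — so k_risc is physically tied to the
  forward rate and the gap;
* strongly correlated frontier orbitals: (E_HOMO, E_LUMO) bivariate normal
  with correlation 0.86, means −5.9/−1.8 eV, SDs 0.35 eV;
* excitation energies: E_S1 ~ N(2.9, 0.25) eV (truncated at 1.5 eV),
  ΔE_ST lognormal with median 0.15 eV (capped at 0.8 eV),
  E_T1 = E_S1 − ΔE_ST;
* yields driven by a latent mechanism score (logit units): band-pass
  windows on the log branching ratios of the two triplet channels
  ("a favourable range", reflecting that both too-slow and too-fast
  triplet processing hurt sensitization), a linear penalty in the
  internal-conversion branching ratio, a band-pass window on E_HOMO for
  energy-transfer reactions or on E_LUMO for redox reactions, a decreasing
  term in ΔE_ST, and a reaction-specific intercept; the score is mapped
  through `100·plogis(·)` and Gaussian noise (default SD 8 yield points)
  is added before clipping to [0, 100].

The window/weight constants were calibrated once, at design time, so that
the default population spans the full yield range with a realistic spread
and the mechanism is learnable at the default noise level; they live in
`generator_config()` and the tests pin them. Band-pass (non-monotone)
windows were chosen deliberately: tree models and attribution methods are
exactly the tools one reaches for when effects are non-monotone, and a
purely monotone generator would not exercise that.

What the generator does **not** emulate: real chemistry. Descriptors are
drawn from smooth parametric distributions rather than a discrete chemical
series; the yield mechanism is a designed function, not nature; there are
no systematic errors of the kind a quantum-chemistry method introduces
(e.g. gap-dependent bias in ISC rates), no inter-descriptor structure
beyond the HOMO/LUMO copula and the detailed-balance coupling, and no
reaction-specific chemistry beyond an intercept and the orbital-window
switch. Passing tests on synthetic data therefore demonstrate that the
*pipeline* is correct and that the attribution recovers known drivers under
realistic noise — they do not validate the photochemical conclusions on any
real dataset.

Pure-noise decoy descriptors (`n_decoys`) can be appended for
importance-recovery checks; they are off by default.

## Problem sizes and tolerances used by the checks

The test suite runs the full design (300 rows) for accuracy, noise-ladder
and attribution checks; 10 repeated splits for the headline accuracy, 5 per
noise level on the ladder {4, 8, 16, 32}; the exhaustive 127-subset search
at 3 runs per subset; 1000 random rate sets for the kinetics-vs-ODE oracle
(solver tolerances rtol 1e-11 / atol 1e-15, trajectory agreement 1e-6
relative where [S1] > 1e-8); 100 round-trip inversions at 1e-4 relative;
and coalition-enumeration cross-checks up to 6 features × 16 background
rows at 1e-8. A zero-noise, exactly tree-realizable target is used for the
near-perfect-fit sanity check, since the generator's smooth mechanism
itself caps achievable held-out R² below 1 even without noise.

## Known limitations

* The kinetic model has three states and five channels; sensitizers with
  ultrafast higher-state chemistry, strong phosphorescence (metal
  complexes) or emissive charge-transfer intermediates fall outside it.
* The inversion's identifiability analysis counts observables naively; it
  will refuse under-determined problems but cannot detect practically weak
  identifiability (e.g. a delayed component with vanishing amplitude).
* Row-level evaluation splits are interpolative, as discussed above.
* Attribution explains the *model*, not the mechanism: correlated
  descriptors (E_HOMO/E_LUMO at 0.86) share credit in ways that depend on
  the fitted trees, which is visible in the synthetic benchmarks where the
  driver's correlated partner can rank above the driver itself.
* The exhaustive search is limited to 15 auxiliary descriptors; no
  heuristic mode is provided.
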