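# ricestor

Pesticide residue kinetics, next-step forecasting and quality grading for
rice under controlled storage.

Residues of common pesticides (imidacloprid, carbaryl, fenitrothion,
chlorpyrifos-methyl, deltamethrin) dissipate in stored grain at rates that
depend on temperature and relative humidity, and regulators grade grain by
where its residue level falls. `ricestor` packages that whole workflow for
storage scientists:

* **Synthetic storage study.** `generate_study_dataset()` simulates the
  standard two-arm design — temperatures 25/30/35/40 °C at 65 % RH and
  humidities 65/70/75/80 % at 25 °C, five pesticides, 30 daily samples, 1200
  records — as bi-exponential decay
  `C(t) = C0 [f e^(−k_f t) + (1−f) e^(−k_slow t)]` with a unimodal
  (Gaussian) response of the fast rate `k_f(T, H)` peaking at a critical
  temperature and humidity.
* **Rotation-attention forecaster.** `quatformer()` trains a from-scratch
  encoder–decoder attention model whose queries and keys are rotated by
  learned per-position frequencies ω ∈ [0, 0.5] and phases θ ∈ (−π, π)
  (score `exp(⟨R_m q, R_n k⟩/√d_h)`), with trend normalization in place of
  layer normalization, a length-`c` global memory that makes attention cost
  `Nc + cL` instead of `NL`, and the loss
  `L = L_pred + λ₁·L_ω + λ₂·L_θ` combining mean squared error with
  frequency-smoothness and phase-sparsity regularizers. A persistence
  (last-value) baseline and the MSE/RMSE/MAE/MAPE/SMAPE report are built in.
* **Quality grading.** `grade_model()` clusters the index
  `M = [d_current, d_predicted]` (measured residue paired with its
  forecast) per pesticide using hand-rolled Lloyd K-means with k-means++
  seeding, selects the number of grades by mean silhouette over K = 3..7,
  and emits grade intervals `(0, b₁) / [b₁, b₂] / (b₂, +∞)` ordered from
  High (lowest residue) to Low.
* **Storage statistics.** `fit_first_order()` (log-linear kinetics,
  `t½ = ln 2 / k`), `duncan_mrt()` (Duncan's multiple range test with
  compact letter display), and `response_surface_fit()` (full quadratic on
  coded factors A = (T−35)/5, B = (H−75)/5).
* **Pipeline.** `run_pipeline()` chains simulate → train → forecast →
  index → grade → statistics and writes delimited-text artifacts plus a
  deterministic run manifest; `inst/cli/ricestor.R` is a thin command-line
  wrapper over the same functions.

## A worked example

```r
library(ricestor)

## simulate one pesticide under the temperature arm, noise-free
prof <- default_profiles(noise_sd = 0)$imidacloprid
series <- lapply(c(25, 30, 35, 40), function(tc)
  simulate_series(prof, storage_condition(tc, 65), days = 30, seed = 1))

## first-order kinetics at 25 degC / 65 % RH
fit_first_order(series[[1]])
#> <kinetic_fit> k = 0.05745 /day, t1/2 = 12.06 days, C0 = 2.054 mg/kg, R^2 = 0.7113 (n = 30)

## the early dissipation phase is much faster than the full-series fit
fit_first_order(series[[1]], max_day = 7)
#> <kinetic_fit> k = 0.2238 /day, t1/2 = 3.097 days, C0 = 4.575 mg/kg, R^2 = 0.9860 (n = 8)

## grade quality from measured/predicted residue pairs
m <- generate_tiered_m_samples(c(0.4, 1.2, 2.0), tier_sd = 0.06,
                               n_per_tier = 40, seed = 1)
gm <- grade_model(build_m_index(m$d_current, m$d_predicted, "imidacloprid"),
                  k_range = 3:5, seed = 1)
gm
#> <grade_model> imidacloprid K=3, silhouette=0.8935
#>    grade d_current d_predicted  n        interval
#>     High 0.4055216    0.374269 40     (0, 0.7937)
#>   Medium 1.2066476    1.113170 40 [0.7937, 1.615]
#>      Low 1.9813765    1.847052 40   (1.615, +Inf)
#> silhouette by K:  3=0.894, 4=0.756, 5=0.634
```

The kinetic fit shows the hallmark of bi-phasic dissipation: the full-series
log-linear half-life (12.1 days, R² 0.71) mixes the fast first week with the
late plateau, while the initial-phase fit (days 0–7) recovers the fast
dissipation (t½ ≈ 3.1 days, R² 0.99). The grade model recovers the three
planted residue tiers and converts them into High/Medium/Low concentration
intervals with the silhouette confirming K = 3.

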