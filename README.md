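# phistress

Modelling photosynthetic quantum efficiency of sugarcane under light,
temperature and drought stress, from pulse-amplitude-modulated (PAM)
chlorophyll-fluorescence measurements.

Seasonal drought is a leading cause of sugarcane yield loss, and cultivars
differ sharply in how their photosystems respond to a drying substrate.
`phistress` provides, for ecophysiologists and crop modellers, a complete
and tested pipeline for the quantum-efficiency approach to drought
diagnosis: deriving quenching parameters from raw fluorescence signals,
fitting a photothermal response model of the effective PSII quantum yield
Φ, extending it with a drought-stress index driven by the relative
substrate water content (rSWC), classifying drought severity, and
summarizing how absorbed light energy is partitioned between photochemistry
(Φ), regulated heat dissipation (NPQ) and non-regulated losses (Φ_NO) as a
drying cycle progresses.

## The model

From each PAM record (steady and maximal light-adapted fluorescence F_s,
F_m′; dark-adapted F_o, F_m) the package derives

- Φ = (F_m′ − F_s)/F_m′, F_v/F_m = (F_m − F_o)/F_m, NPQ = F_m/F_m′ − 1,
- F_o′ = F_o / (F_v/F_m + F_o/F_m′),
  q_L = (F_o′/F_s)(F_m′ − F_s)/(F_m′ − F_o′),
- Φ_NO = 1 / (NPQ + 1 + q_L(F_m/F_o − 1)), and rSWC = VWC/VWC_s.

Under well-watered conditions Φ responds to temperature T and irradiance
PAR through a piecewise-sinusoidal interpolation between three exponential
PAR envelopes anchored at the cardinal temperatures (T_min/T_o/T_max =
15/30/40 °C for sugarcane):

    Φ(T, PAR) = Φ_bL + (Φ_To − Φ_bL) · sin(π/2 · (T − T_min)/(T_o − T_min)),  T ≤ T_o
    Φ(T, PAR) = Φ_bH + (Φ_To − Φ_bH) · sin(π/2 · (T_max − T)/(T_max − T_o)),  T ≥ T_o

with Φ_bL = a_L e^(−b_L·PAR), Φ_bH = a_H e^(−b_H·PAR) and
Φ_To = (F_v/F_m) e^(−ε·PAR). Drought enters through a stress index ε_D (on
the ×10⁴ scale of ε) that stays at the baseline above a critical water
content rSWC_c and rises exponentially below it,

    ε_D(rSWC) = ε_s + c · e^(−d·rSWC)   for rSWC ≤ rSWC_c,

attenuating every envelope by e^(−(ε_D−ε_s)·10⁻⁴·PAR). Severity bands at
ε_D = 7 / 9 / 13 separate well-watered, slight, moderate and severe
drought. `fit_photothermal()` estimates (a_L, b_L, a_H, b_H, ε) by
Levenberg–Marquardt least squares; `fit_drought()` inverts observed yields
to per-record ε_D values and recovers (c, d, rSWC_c) by a weighted
changepoint-profile search.

Because the underlying field data are not publicly deposited, the package
ships a synthetic-experiment generator (`simulate_photothermal()`,
`simulate_drought()`) whose two built-in cultivar archetypes — the
drought-resistant 'ROC22' and drought-susceptible 'ROC16' — carry the
published coefficient sets and drying curves, so every stage of the
pipeline is testable end-to-end against known ground truth.

## Worked example

```r
library(phistress)

arch    <- cultivar_archetype("roc22")
cal     <- simulate_photothermal(arch, seed = 11)  # 3 PAR x 10 T calibration
dry     <- simulate_drought(arch, seed = 12)       # diurnal ramps, days 1-9
records <- rbind(cal$records, dry$records)

res <- run_pipeline(records)
res$photothermal
res$drought$roc22
res$stages
res$validation$roc22
```

```
Photothermal quantum-yield model fit (joint)
  n = 24, SSE = 0.004726, residual sigma = 0.01577
Photothermal quantum-yield parameters
  Phi_bL(PAR) = 0.6595 * exp(-0.0006554 * PAR)
  Phi_bH(PAR) = 0.6919 * exp(-0.0005609 * PAR)
  Phi_To(PAR) = 0.769 * exp(-0.0005958 * PAR)   (eps scaled: 5.958)
  cardinal temperatures: 15 / 30 / 40 degC
Drought-stress model fit (changepoint profile)
  rswc_c = 0.4001, c = 41.43, d = 10.22
  n = 100 (excluded low-PAR: 20, clamped at baseline: 26)
  SSE = 44.94, index jump at changepoint = 0.6948
  cultivar day_after_drought     eps_d        stage
1    roc22                 1  5.957886 well_watered
2    roc22                 3  5.957886 well_watered
3    roc22                 5  6.661067 well_watered
4    roc22                 7  8.627494       slight
5    roc22                 9 12.661665     moderate
Validation report
  n = 100, mean observed = 0.4563
  r2 = 0.9771, rRMSE = 0.04488
```

Reading the output: the calibration recovers the generating envelopes (the
archetype's truth is a_L = 0.688, b_L = 6.77e-4, a_H = 0.676,
b_H = 5.16e-4, ε = 5.91e-4) from 24 usable noisy records; the drought fit
places the critical water content at rSWC_c ≈ 0.40 — 'ROC22' pots dried to
40% of saturation before the photosystem registered stress — with index
coefficients c ≈ 41, d ≈ 10 (truth 39.63, 10.01). The per-day stages show
the cycle crossing into slight stress at day 7 and moderate stress at day
9, and the validation report compares observed yields with the fitted
model's predictions on the drought records.

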