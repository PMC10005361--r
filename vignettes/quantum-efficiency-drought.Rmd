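---
title: "Modelling PSII quantum efficiency under photothermal and drought stress"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling PSII quantum efficiency under photothermal and drought stress}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(phistress)
```

# The measurement layer

Pulse-amplitude-modulated (PAM) fluorometry yields four basic signals per
measurement: steady (`F_s`) and maximal (`F_m'`) fluorescence of the
light-adapted leaf, and minimal (`F_o`) and maximal (`F_m`) fluorescence
after 30 minutes of dark adaptation at the same leaf position. `chlf_params()`
turns a table of such quartets into the quenching parameters of the lake
model: the effective PSII quantum efficiency `Phi`, the dark-adapted maximum
`F_v/F_m`, nonphotochemical quenching `NPQ`, the open-centre fraction `q_L`
(via the `F_o'` estimate `F_o / (F_v/F_m + F_o/F_m')`), and the yield of
non-regulated energy losses `Phi_NO`. All derived quantities are ratios, so
they are invariant under uniform rescaling of the signals — a property the
test suite asserts on random quartets.

One algebraic fact shapes several design choices below: with the `F_o'`
estimate above, `Phi_NO` simplifies *identically* to

$$\Phi_{NO} \;=\; \frac{F_s}{F_m} \;=\; \frac{1-\Phi}{1+NPQ}.$$

`Phi_NO` is therefore not an independent degree of freedom of a quartet:
prescribing `Phi` and `NPQ` fixes it. The package still computes it through
the full lake-model formula (the two routes agree to machine precision,
which is itself a useful internal consistency check), but the synthetic-data
generator must — and does — respect the identity.

# The photothermal model

Under well-watered conditions the quantum yield responds to air temperature
`T` and irradiance `PAR` through a piecewise sinusoidal interpolation
between three exponential PAR envelopes pinned at the cardinal temperatures
(15, 30, 40 degC for sugarcane; treated as known constants, not fitted):

- `Phi_bL(PAR) = a_L exp(-b_L PAR)` — the base yield at `T_min`,
- `Phi_bH(PAR) = a_H exp(-b_H PAR)` — the base yield at `T_max`,
- `Phi_To(PAR) = (F_v/F_m) exp(-eps PAR)` — the optimum yield at `T_o`.

Both branches meet at `T_o`, the surface is continuous and unimodal in
temperature, and `b_L > b_H` reproduces the stronger cold sensitivity of a
C4 crop (cold-labile PEPC/PPDK limitation): the low-temperature envelope
decays faster with light than the high-temperature one.

A note on the scale of `eps`: the stored parameter is the *effective*
per-PAR exponent (around `5.91e-4` for the built-in archetypes). Its
`x 1e4` scaled representation (around 5.91) is used as the baseline of the
drought index so that index values land on the conventional 7/9/13
severity bands; parameter documents serialize both (`eps_effective`,
`eps_scaled`) to keep the convention explicit.

## Fitting

`fit_photothermal()` estimates `(a_L, b_L, a_H, b_H, eps)` with `F_v/F_m`
supplied by the user (experimentally it is measured directly; the pipeline
uses the mean of the well-watered records). Two strategies are provided:

- **joint** (default): one 5-coefficient Levenberg–Marquardt least-squares
  problem over all records, with bounds `[0,1]` on amplitudes and
  `[0, 0.1]` on decay rates, relative tolerance `1e-10`, initialized from
  the two-stage estimates;
- **two_stage**: per-PAR-level fits of the temperature response — which is
  *linear* in `(Phi_bL, Phi_bH, Phi_To)` once the sine weights are formed,
  so ordinary least squares suffices — followed by log-linear fits of the
  three envelopes across PAR levels.

On noise-free data the two agree exactly (tested); on the small 30-point
calibration design the joint fit is more stable, which is why it is the
default. Records outside the cardinal range are excluded with a warning;
designs that cannot identify the coefficients (one PAR level, one
temperature branch, fewer than five distinct design points) raise
underdetermined-design errors rather than returning garbage.

# The drought extension

Drought enters through a stress index `eps_D` on the scaled-`eps` axis:
at relative substrate water content (`rSWC = VWC/VWC_s`, a fraction) above
a critical value `rswc_c` the index equals the well-watered baseline
`eps_s`; at or below it,

$$\varepsilon_D(rSWC) = \varepsilon_s + c\,e^{-d \cdot rSWC}.$$

`rSWC` enters as a fraction: with decay rates of order 10–22 per unit
fractional `rSWC` (the magnitudes of the built-in archetypes), a percent
scale would make the exponential numerically degenerate. The index is
deliberately discontinuous at the changepoint, as defined; the jump size
`c exp(-d rswc_c)` is reported as a fit diagnostic rather than forced to
zero.

The drought-modified yield multiplies **all three** envelopes by the ratio
attenuation `exp(-(eps_D - eps_s) 1e-4 PAR)`. This form makes
`Phi_To` under drought exactly `(F_v/F_m) exp(-eps_D 1e-4 PAR)` and — more
importantly — reduces the model *exactly* to the well-watered one at
`eps_D = eps_s`, so the yield surface is continuous at drought onset. A
literal variant that applies `exp(-eps_D 1e-4 PAR)` directly to the base
envelopes (which does not reduce to the well-watered model) is kept behind
`attenuation = "literal"` for comparison; it is not the default precisely
because of that discontinuity.

## Inverting observed yields

`invert_epsilon_d()` maps an observed yield back to the index by bisecting
the monotone forward model on `[eps_s, 200]` to `1e-8`; the test suite
checks it against an exhaustive million-point forward scan. Two guards
matter in practice:

- **low irradiance**: as `PAR -> 0` the attenuation factor tends to 1 for
  *any* index value, so the index is unidentifiable; records below
  `par_min` (default 50 umol photons m-2 s-1) are refused, and the fitting
  routine excludes them with a logged count;
- **observations above the well-watered prediction**: these carry no
  stress signal. Within `noise_tol` (default 0.02, matching a plausible
  yield noise SD) they clamp to the baseline with a warning; beyond it
  they raise an inversion error.

## Changepoint fitting

`fit_drought()` recovers `(c, d, rswc_c)` by profiling candidate
changepoints over a grid (every observed `rSWC` plus a 0.01-step lattice on
`[0.05, 0.95]`): records at or below a candidate are fitted with the
exponential rise (for fixed `d` the amplitude is a closed-form weighted
projection, so only `d` needs a 1-D search), records above it are scored
against the baseline. Four numerical choices deserve explanation, all
adopted after explicit bias experiments on generator output with known
truth:

1. **Signed elevations.** The regression uses the signed closed-form
   elevation `-1e4 log(Phi_obs/Phi_ww)/PAR`, letting unstressed records
   scatter *below* zero. Clamping them at the baseline first (as the
   reporting convention does) censors the error distribution and biases
   `(c, d)` downward by over 10% at realistic noise.
2. **Inverse-variance weights from predicted yields.** The delta method
   gives `sd(eps_D,i) ~ 1e4 sigma_Phi / (PAR_i Phi_i)`: a fixed yield
   noise is magnified enormously on the index scale at low irradiance or
   collapsed yield. Weighting by `(PAR x Phi)^2` with `Phi` the *model
   prediction* (well-watered on a first pass, the fitted model on one IRLS
   refinement) restores efficiency without the bias that observed-yield
   weights introduce (weights correlated with noise systematically
   underweight upward-fluctuating records).
3. **Group-mean regressors.** When `group` is supplied (the pipeline uses
   the measurement day), records of a group share one substrate water
   status and the regression uses the group-mean `rSWC`. This mirrors the
   measurement protocol — water content is read once per pot each morning
   while many leaves are measured — and removes the regression-dilution
   bias that per-record observation noise in the regressor otherwise
   causes (measured at roughly -5% on `d` at a 0.01 observation SD).
4. **Left-edge selection.** Above the true changepoint the SSE profile is
   nearly flat (the fitted exponential passes close to zero there, so
   unstressed records fit almost equally well on either side of the
   candidate), while below it the profile rises sharply. The reported
   changepoint is therefore the smallest candidate within a 5% relative
   band of the profile minimum — the left edge of the flat region — which
   reduces to exact recovery (up to grid resolution) on noise-free data.

When no candidate shows a detectable index elevation (data entirely above
the changepoint, or pure noise), a changepoint-unidentifiable error is
raised instead of a spurious estimate.

## Severity classification

`drought_stage()` maps index values onto the conventional bands — below 7
well-watered, 7–9 slight, 9–13 moderate, above 13 severe. The band
definitions leave the boundary points unassigned; here boundaries belong to
the more severe stage, the conservative choice for stress diagnosis. The
bands are global constants by default and overridable per call.

# Validation metrics

`validation_metrics()` reports the squared Pearson correlation (`r2`
computed literally as squared correlation, *not* as `1 - SSE/SST`; the two
differ for biased predictions) and the relative root mean-squared error
`rRMSE = RMSE / mean(obs)`, whose denominator is always the mean of the
*observed* values. `r2` is affine-invariant (association), `rRMSE` is not
(agreement); the pair is reported together deliberately. On synthetic
validation sets `rRMSE` converges to the noise-to-signal ratio
`sigma_Phi / mean(Phi)`, asserted at `n = 500` in the tests.

# Energy-distribution summaries

`energy_curves()` bins derived records per cultivar x day x 100-unit PAR
bin (means, SDs, counts; single-record bins keep the value with a missing
SD). `phino_turning_point()` flags, per cultivar, the earliest day whose
all-PAR mean `Phi_NO` exceeds the day-1 baseline by a relative threshold.
The 10% default is this package's operationalization of a "sustained rise"
— no numeric rule exists in the literature the model derives from — and is
exposed as a parameter; day-level means (record-weighted) are compared
rather than per-bin tests, because the per-day average is the quantity the
turning point is defined on.

# The synthetic-experiment generator

The generator exists because the underlying field data are available only
on request: every stage of the pipeline is instead exercised against
simulated experiments with known truth. Two archetypes mirror the studied
cultivars:

- **'ROC22'** (drought-resistant): drought coefficients
  `c = 39.63, d = 10.01, rswc_c = 0.40`; drying anchors reaching 40% of
  saturation at day 5 and about 18% by day 9; a strong NPQ response whose
  saturating light curve approaches 1.6 at 1200 umol photons m-2 s-1 from
  day 5 on.
- **'ROC16'** (drought-susceptible): `c = 286.78, d = 21.53,
  rswc_c = 0.29`; faster early drying (56% at day 3, 29% at day 5); a weak
  NPQ response staying below 1.3 throughout; a pronounced `Phi_NO` rise
  from day 3.

Both share the photothermal set `a_L = 0.688, b_L = 6.77e-4, a_H = 0.676,
b_H = 5.16e-4, F_v/F_m = 0.769, eps = 5.91e-4`.

Design choices, fixed once:

- **Designs.** Calibration: 3 PAR levels (285/625/1150) x 10 temperatures
  spanning 11.8–42.7 degC — 30 records, of which the 2 temperatures
  outside the cardinal range are emitted flagged so range filtering is
  exercised. Drought: diurnal ramps of 6 PAR steps (0 to 1200 by 240, one
  per hour from 06:00, emulating a 20%-per-hour phytotron protocol) x 4
  replicate leaves on days 1, 3, 5, 7, 9, at temperatures uniform in
  29 +/- 1.5 degC.
- **Noise.** Additive Gaussian noise with SD `sigma_phi = 0.02` on the
  yield scale, propagated into `F_s` (the model's error structure is
  defined on the yield, which keeps recovery tolerances interpretable);
  water-content observations get SD `sigma_rswc = 0.01` on the fraction
  scale, consistent with replicated probe readings.
- **Drying curves.** Anchored at the observed day-5 values (and day 3 for
  'ROC16'); unanchored days interpolate log-linearly (exponential drying,
  the standard kinetics for a free-draining pot), extrapolating the last
  log-slope beyond the final anchor. Values for days the study did not
  report numerically (1, 7, 9) are package choices on that drying curve
  and are overridable per archetype. The drying contrast between the
  cultivars is configurable rather than hard-coded, since the direction of
  that contrast is not settled.
- **Quenching dynamics.** Because of the `Phi_NO` identity, the per-day
  `Phi_NO` trajectory (baseline + step at a cultivar-specific day + slope)
  acts as a *floor*: the emitted NPQ is `min(cap, (1-Phi)/Phi_NO_floor - 1)`
  with `cap` the day's saturating NPQ light curve and a lower bound of 0.
  Where a bound binds (always at `PAR = 0`, where `Phi_NO` is forced to
  `1-Phi`), the emitted `Phi_NO` deviates from the floor and the truth
  record counts it. One consequence is accepted openly: with the published
  coefficient sets, the identity makes a *simultaneous* strong NPQ
  response and early `Phi_NO` rise impossible, so the resistant archetype
  shows no early turning point (its `Phi_NO` dips mid-cycle as quenching
  strengthens) — the susceptible archetype's day-3 turning point, which is
  the diagnostic contrast, is reproduced robustly.
- **Determinism.** Each generator takes a `seed`; equal seed and
  configuration give byte-identical output (R's default Mersenne-Twister),
  asserted in the tests.

## What passing tests do and do not show

Parameter recovery on generator output demonstrates that the estimation
machinery is consistent under the model's own assumptions at realistic
noise and the study's design sizes — 30-point calibrations recover the
photothermal coefficients (median `eps` within a few permil, amplitudes
within 1%), and 120-record drying cycles recover `(c, d, rswc_c)` with
median errors of a few percent over 50 replicates. It does *not*
demonstrate robustness to what real leaves add: non-Gaussian and
drift-like measurement error, leaf-to-leaf parameter heterogeneity,
diurnal physiology beyond the modelled PAR/T response, or drought x
temperature interactions (the attenuation is assumed temperature-neutral).
Published validation statistics on the original field data cannot be
reproduced here because those data are not deposited; the package
deliberately reports its own synthetic-recovery results instead of
imitating numbers it cannot compute.

# Problem sizes and runtime

The default test and acceptance runs use the study-scale designs (30
calibration points; 120 drought records per cycle), 50 replicate fits for
recovery medians and 100 replicates for turning-point detection; the full
suite completes in about half a minute and the acceptance script in under
a minute on one CPU.

# Known limitations

- Cardinal temperatures are fixed constants; no uncertainty is propagated
  from them.
- The changepoint's sampling uncertainty is not quantified (no profile
  confidence interval); the SSE profile is returned so users can inspect
  identifiability.
- `c` and `d` are partially confounded along the profile (a steeper decay
  can be traded against a larger amplitude over the observed `rSWC`
  range); median recovery is accurate, but single-experiment estimates of
  `c` for strongly curved index trajectories carry wide spread.
- The severity bands are treated as cultivar-independent constants.
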