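---
title: "Head impact kinematics, strain reduction and model comparison: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Head impact kinematics, strain reduction and model comparison: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(headkin)
```

# Scientific problem

Helmeted head impact experiments instrument a headform with accelerometers,
reconstruct the six-degree-of-freedom rigid-body motion of the head, reduce
that motion to a handful of scalar kinematic metrics, and ask which of those
metrics best predicts the brain strain that a finite-element head model
computes for the same motion. Two strain measures are standard:

- **CSDM-15** (cumulative strain damage measure): the volume fraction of
  brain elements whose maximum principal strain reaches or exceeds 0.15 at
  any time during the simulation, and
- **MPS** (maximum principal strain): the single largest strain attained by
  any element at any time.

`headkin` implements the full laboratory-to-statistics chain, together with a
synthetic data generator so the chain can be exercised, validated, and
studied end to end without access to the original (undeposited) impact
recordings.

# Rigid-body sensing: the 3-2-2-2 nine-accelerometer array

The headform carries nine single-axis accelerometers: a triaxial cluster at
the reference point (centre of mass), plus three two-accelerometer arms at
distances $\rho_x, \rho_y, \rho_z$ along the body axes. A sensor at position
$\mathbf r$ with sensing axis $\hat{\mathbf n}$ on a rigid body reads

$$ a = \left( \mathbf a_{cm} + \boldsymbol\alpha \times \mathbf r
      + \boldsymbol\omega \times (\boldsymbol\omega \times \mathbf r) \right)
      \cdot \hat{\mathbf n}. $$

The classical arm-difference combination cancels the quadratic
$\boldsymbol\omega$ products *exactly*, leaving a purely algebraic estimate
of angular acceleration, e.g.

$$ \alpha_x = \tfrac12 \left[ \frac{a_{z}^{(y\,\text{arm})} - a_{z}^{(0)}}{\rho_y}
            - \frac{a_{y}^{(z\,\text{arm})} - a_{y}^{(0)}}{\rho_z} \right] $$

and cyclic permutations. This is why the array needs exactly this 3-2-2-2
layout: each arm contributes the two tangential channels that pair up in the
differences. `nap_geometry()` builds the layout (default arm length 5 cm),
`simulate_array()` applies the forward model above, and `nap_transform()`
inverts it. The exact cancellation is tested directly: a constant-spin
motion produces non-zero (centripetal) channel readings yet transforms to
zero angular acceleration to machine precision.

```{r}
geom <- nap_geometry()
geom$sensors[, c("label", "arm", "axis")]
```

# Signal processing

**Filtering.** Channels are low-pass filtered to channel frequency class
(CFC) 1000 as specified for head accelerations in crash-test practice: a
two-pole Butterworth with per-pass $-3$ dB point at $1.65 \times$ CFC
$= 1650$ Hz, applied forward and backward (`cfc_filter()`). The double pass
gives zero net phase shift — essential because peak *timing* feeds the
metrics — and a combined attenuation of $0.5$ at the per-pass corner, which
the test-suite verifies. Edge transients are controlled by odd-reflection
padding before filtering.

**Integration.** Angular velocity is the running trapezoidal integral of
filtered angular acceleration (`integrate_velocity()`), starting from rest
at the processing-window origin. At the 100 kHz sampling rate of the
generator the quadrature error for pulse-like signals is orders of
magnitude below the measurement noise (verified at $10^{-4}$ relative on
closed-form pulses).

**Windowing.** `process_recording()` triggers on the 5 g resultant linear
acceleration, retains 5 ms of pre-trigger, and removes the channel bias
estimated from the samples before that window.

# Kinematic metrics

`extract_metrics()` reduces each processed recording to thirteen scalars:

| name | definition |
|---|---|
| `peak_g` | peak resultant linear acceleration / 9.80665 |
| `v_i` | impact speed |
| `dv_r` | resultant of the per-axis linear-velocity excursions (max − min) |
| `v_r` | peak resultant velocity including the initial condition |
| `alpha_r` | peak resultant angular acceleration |
| `dw_x, dw_y, dw_z` | per-axis angular-velocity excursions |
| `dw_r` | resultant (norm) of the three excursions |
| `w_x, w_y, w_z` | per-axis peak absolute angular velocity |
| `w_r` | peak resultant angular velocity |

Excursion means max minus min over the window, irrespective of timing; the
"Δ-resultant" convention (norm of per-axis excursions rather than excursion
of the norm) follows the laboratory practice this package mirrors. Peak g
also feeds a three-bin severity classification (< 45 g, 45–80 g, > 80 g)
and the angular-velocity excursion feeds a diffuse-axonal-injury flag
(strictly above 46.5 rad/s).

# Strain reduction

A strain history is a time-by-element matrix of maximum principal strain
with element volumes and region labels. `csdm()` applies the running-max
definition (an element that ever reaches the threshold stays counted);
`mps()` returns the global maximum with deterministic tie-breaking
(earliest time, then lowest element id). `stable_max_check()` verifies the
80 ms simulation window was long enough: the running maximum must have
plateaued (final 10 % of the window flat to within $10^{-9}$). Both
reducers are tested against brute-force double-loop oracles for exact
agreement.

# The synthetic study generator

Because the original 267-impact dataset is not public, the package ships a
generative model whose *defaults are the study conditions*:

- **Design**: 267 impacts split 105 front / 88 back / 74 side; impact
  speeds 1.2–5.8 m/s; sampling at 100 kHz; severity-bin probabilities per
  location matching the reported count table (drawn, not forced).
- **Pulses**: haversine ($\sin^2$) acceleration pulses of 4–12 ms duration.
  The closed-form integral ($A\,T/2$ for peak $A$, duration $T$) gives every
  record exact ground-truth metrics without numerical processing, so the
  signal chain can be validated against truth. Angular pulses include a
  rebound of opposite sign (restitution-like ratio 1.05–1.6) so that the
  excursion Δω genuinely exceeds the peak ω — without it the two would be
  identical and several candidate regression models would be exactly
  collinear.
- **Coupling**: peak g and Δω$_R$ are correlated per location (strongest
  for back impacts), reflecting how oblique helmet loading converts linear
  to rotational motion.
- **Strain surrogates**: CSDM-15 follows a logistic link in Δω$_R$
  (midpoint 30 rad/s, scale 6 rad/s) and MPS a linear link
  ($0.05 + 0.005\,\Delta\omega_R$), each with Gaussian noise. These links
  encode the headline empirical finding — rotational velocity change is the
  dominant strain predictor — as the generative truth, which the
  model-comparison machinery must then *recover*.
- **Seeding**: one master seed; every record draws from an independent
  derived stream (`derive_seed()`), so any single impact can be regenerated
  in isolation and identical configuration reproduces byte-identical
  studies.

`generate_strain_history()` additionally constructs full element-level
histories that reduce *exactly* to requested CSDM/MPS targets (targets are
quantized to the element-volume granularity and checked for mutual
consistency), giving the reducers a non-trivial round-trip test.

```{r}
study <- generate_study(synth_config(n = 267, seed = 1))
summarize_severity(study$impacts)
```

# Regression model comparison

`fit_ols()` is QR-based ordinary least squares reporting
$R^2 = 1 - SSE/SST$, adjusted
$R^2 = 1 - (1 - R^2)(n-1)/(n-k-1)$, the model-vs-intercept
$F = (R^2/k)\,/\,((1-R^2)/(n-k-1))$, and two-sided coefficient p-values on
$n-k-1$ degrees of freedom. Coefficients stay on raw predictor scales and
significance is judged at $p < 0.05$ with no multiple-testing correction,
matching the practice being mirrored. The implementation is validated
against `stats::lm()` to $10^{-8}$ on random datasets.

Model enumeration supports two modes: `all_subsets` up to a size cap, and
`canonical37` — the fixed comparison set of 37 predictor subsets (7 single-
predictor, 13 two-, 8 three-, 8 four-, 1 five-variable) used in the
laboratory study's comparison tables, shipped as a version-controlled
fixture together with the originally reported adjusted $R^2$ and $F$ values.
The fixture is a best-effort transcription from the published table
structure; the anchor rows used in selection summaries are confirmed
against the published text. Selection criteria are maximum $F$, maximum
adjusted $R^2$, and best two-variable model, with deterministic
tie-breaking (fewer predictors, then lexicographic names).

```{r}
led <- fit_ledger(study$impacts, enumerate_models("csdm15", "canonical37"))
select_best(led, "max_f")
```

# Numerical and design choices

- All heavy numerics reuse established implementations (Butterworth design
  from `signal`, cumulative trapezoids from `pracma`, QR from base R); the
  package's own code is the domain logic.
- Exactness over iteration: the array transform, strain reducers, and the
  haversine integrals all have closed forms, and the tests hold them to
  machine-precision or near-machine-precision tolerances.
- Determinism everywhere: seeded streams, no reliance on global RNG state
  (`with_seed()` restores it), and pipeline outputs carry an MD5 manifest
  so byte-identical reproduction is checkable.

# Limitations

- The strain surrogates are statistical links, not finite-element
  mechanics; they reproduce the predictor-to-strain *relationships*, not
  actual strain fields.
- The generator draws severity bins from the reported distribution, so
  per-bin counts match the study only in expectation.
- The canonical model table is a transcription of a published comparison
  set; its reported values are used for desk arithmetic, not re-fit.
- Single rigid-body motion only: no neck compliance, no headform-helmet
  relative motion, sensor noise is white and Gaussian.
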