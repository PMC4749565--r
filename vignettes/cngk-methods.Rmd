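---
title: "Models and methods behind cngk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cngk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cngk)
```

`cngk` implements the analysis chain used to characterise a pH-gated,
K⁺-selective sperm channel (the CNGK family): swimming-path kinematics
from dark-field video, voltage-clamp IV analysis, Hill and pH
dose–response fitting with the NH₄Cl → pHᵢ calibration, stopped-flow
fluorescence normalization, and free-ion calculation for
chelator-buffered pipette solutions. This vignette explains the models,
the tunable parameters, the numerical choices, and what the synthetic
data generator does and does not emulate.

## 1. Trajectory kinematics

### Model

Sperm head positions $(x_i, y_i)$ tracked at frame rate $f$ (30 Hz for
the dark-field movies this package targets) are smoothed into the
*average swimming path* (ASP) with a second-degree Savitzky–Golay filter
over a 200 ms span. The filter fits a local quadratic by least squares
in each window; the smoothed position and the first and second time
derivatives are all read off the same local polynomial — one consistent
estimator, rather than finite differences of already-smoothed points.
Signed path curvature is then

$$\kappa = \frac{\dot x\,\ddot y - \dot y\,\ddot x}
                {(\dot x^2 + \dot y^2)^{3/2}},$$

whose magnitude for a circle of radius $r$ is $1/r$, and the
averaged-path velocity (VAP) is the time-average of
$\sqrt{\dot x^2 + \dot y^2}$.

### Parameters

* `span_ms` (default 200 ms): filter span. The window in frames is
  `span_ms * fps / 1000` rounded to the nearest odd integer, ties
  upward — 7 frames at 30 Hz. Savitzky–Golay windows must be odd; the
  rounding convention is ours, since only the span in milliseconds is
  standard.
* `poly_order` (default 2): degree of the local fit. Order 2
  reproduces quadratic paths exactly, including at the edges, where we
  evaluate the first/last full-window polynomial off-centre rather than
  shrinking the window.
* `min_speed` (default 1 µm/s): samples slower than this are masked
  (`NA`) in the curvature output, because the formula divides by speed
  cubed. Masking is deliberate — silently returning zero would bias
  window averages.
* Boundary samples (half a window at each end) are flagged and excluded
  from all summaries; SG estimates there have higher bias and variance.

### Accuracy regime and estimator choice

The quadratic SG filter tracks an arc faithfully only while the path
turns little within one window. With turn rate $\omega = v\kappa$
(rad/s) at 30 Hz and a 7-frame window, the curvature bias is about
0.2 % at $\omega = 1$, 0.7 % at 2, 3 % at 4 and ~19 % at 10 rad/s.
Closed-form tests therefore use turn rates of ≲2 rad/s; recovering a
programmed ten-fold curvature step within 10 % works up to ~5 rad/s
post-flash. This is a property of the standard 200 ms/order-2 recipe
itself, not of this implementation.

For a constant-curvature ground truth the pipeline test compares the
*signed* mean curvature, which is nearly unbiased under localisation
noise; the mean of $|\kappa|$ (the convention used for biological
summaries, where turn direction varies between cells) acquires a
positive noise floor of a few percent at SNR 10.

### Detection and linking

`detect_spots()` thresholds at median + `threshold_sd` × MAD, labels
8-connected components, and returns intensity-weighted centroids
(sub-pixel; pixel centres at half-integer coordinates), converted to µm
at this point and never later. `link_tracks()` performs greedy
nearest-neighbour assignment per frame: candidate links sorted by
distance (ties by detection index), accepted while both ends are free
and the displacement is within `max_disp`; gaps terminate tracks, and
tracks shorter than 5 frames are dropped. This is the simplest linker
that is exact for the non-crossing, well-separated cells the synthetic
movies produce; it makes no attempt at gap closing or crossing
resolution.

## 2. Voltage-clamp analysis

Steady-state currents are averaged over the trailing `window_fraction`
(default 25 %) of each voltage step; the window must exclude the first
10 ms, where capacitive transients would sit. The reversal potential is
the linear interpolation between the two IV points bracketing zero
current — the estimator closest to reading the crossing off the plotted
IV, robust to rectification away from the crossing. Without a sign
change the two points nearest zero are extrapolated and the result is
flagged rather than trusted.

Closed forms: the Nernst potential $(RT/zF)\ln([X]_o/[X]_i)$ and the
GHK voltage equation for monovalent ions, with anions entering with
sides swapped. At the default 293.15 K (room temperature; recordings in
this field rarely state it) the Nernstian slope is 58.17 mV per decade
of $[K^+]_o$, and 5.4 mM out / 130 mM in gives −80.36 mV.

Normalized IV relations divide by $|I(-115\,\mathrm{mV})|$ with the
sign convention that the value at −115 mV is exactly −1, so curves from
cells with different maximal conductance superimpose. The
rectification index $|I(+25)|/|I(-115)|$ is scale-free and identical on
raw and normalized curves.

Intracellular Na⁺ block is modelled as single-site Woodhull block: the
blocker senses a fraction $\delta$ of the membrane field, so
$K_d(V) = K_{d0}\,e^{-\delta z F V / RT}$ and the unblocked fraction is
$1/(1 + [\mathrm{Na}]_i/K_d(V))$. No equation for this block is
published for the sperm channel; the functional form is our design
choice, exposed through its two parameters and validated only by the
qualitative ordering it must produce (deeper block with depolarization
and with $[\mathrm{Na}]_i$, hence a falling rectification index).

All voltages are liquid-junction-corrected by contract;
`correct_junction()` applies an explicit offset exactly once and
refuses a second application.

## 3. Dose–response fitting

`fit_hill()` fits
$\,R(c) = \mathrm{floor} + \mathrm{ceiling}\cdot f(c;K,h)$ with
$f = 1/(1+(K/c)^h)$ for activation or $1/(1+(c/K)^h)$ for block, by
`nls` (port algorithm). $K$ is fitted as $\log K$ for conditioning;
start values come from the dose where the range-scaled response crosses
one half on the log-dose axis. The floor is bounded below at 0 (or at
the data minimum if the data go lower): a blocked-current magnitude
cannot be negative, and without this bound the 4-parameter fit is badly
conditioned on single noisy curves. Standard errors for $K$ use the
delta method from the $\log K$ covariance.

Fits are unweighted by default; when replicate SDs are available,
$1/\mathrm{SD}^2$ weights should be passed — under the multiplicative
noise that current measurements show, unweighted least squares
over-weights the large-response points and roughly doubles the error in
$K$. The parameter-recovery tests simulate the realistic design (three
applications per dose per cell, weighted fit), which brings the median
$K$ error under 10 % at 10 % noise; single unweighted 7-point curves
sit nearer 17 % even at the *global* least-squares optimum (verified
against an exhaustive grid search), an identifiability limit of the
model, not an optimizer failure.

The pH dependence is fitted directly in pH (log-proton) space,
$I = I_{max}/(1 + 10^{s\,(\mathrm{pH}_{1/2} - \mathrm{pH})})$, which is
the Hill equation in $[\mathrm{H}^+]$ but numerically far
better-conditioned.

### NH₄Cl → pHᵢ calibration

Weak-base alkalization and direct pipette-pH titration probe the same
proton gate, so equating the two fractional activations maps an NH₄Cl
dose to the intracellular pH it produces:
$\mathrm{pH}_i(c) = \mathrm{ph}^{-1}(\mathrm{nh4cl}(c))$, clipped below
at the resting pH 6.4. The default NH₄Cl curve has Hill coefficient 1
and half-max 1.5 mM — the unique $(h, K)$ pair consistent with both
published anchors (≈40 % activation at 1 mM; half-maximal response at
1.5 mM, the dose that raises pHᵢ from 6.4 to the half-activation pH
7.08). With $h = 1$, $K = 1.5$ mM the curve predicts 87 % activation at
10 mM, slightly short of the reported "maximal" response there; the
shape beyond 1.5 mM is not tabulated anywhere, so we note the tension
and keep the anchored parameters. Fractions outside the invertible
range of the pH curve are flagged (`boundary` attribute), not silently
extrapolated.

```{r calibration}
cal <- calibrate_nh4cl()
predict(cal, c(0, 1, 1.5, 10))
```

## 4. Stopped-flow photometry

Traces are normalized to the mean of the first `n_baseline` samples
(default 8, the middle of the conventional 5–10) before the mix time:
$\Delta F/F = (F - F_0)/F_0$, with no background subtraction, matching
the acquisition convention. The mix time comes from instrument
metadata and is never inferred from the trace. Dual-emission
(BCECF-style) recordings are reduced to a ratio first; both
orientations occur in published figure legends and methods sections, so
`compute_ratio()` records the orientation used (`ch1_over_ch2`, i.e.
F494/F549, by default) in the output metadata instead of guessing.
Repeats (3–6 recordings by convention) are averaged pointwise after
linear resampling onto the first trace's time base.

## 5. Chelator equilibria

`solve_equilibrium()` solves the coupled mass balances for Ca²⁺, Mg²⁺,
EGTA and ATP at fixed pH. Each metal–ligand pair is collapsed to an
effective association constant per *metal-free* ligand pool,

$$K_{\mathrm{eff}} = \frac{\beta_{ML} + \beta_{MHL} K_{H1} [H^+]}
  {1 + K_{H1}[H^+] + K_{H1}K_{H2}[H^+]^2 + \dots},$$

whose reciprocal is the familiar apparent (proton-corrected) $K_d$; the
protonated complex MHL is included by default. The two-metal ×
two-ligand system is then iterated by damped successive substitution in
log space until every mass balance closes to $10^{-12}$ relative — a
handful of milliseconds for physiological recipes.

Constants are critical-stability association constants (Martell–Smith)
referenced at $I = 0.1$ M, 20 °C, the set used by the Maxchelator
family of calculators; they are moved to the working ionic strength
with a Davies activity correction ($\Delta z^2$ per association step),
and the pH-meter reading is treated as proton *activity* and converted
to concentration with $\gamma_H$ from the same Davies model. Both
corrections matter: at the pipette recipe's ionic strength (0.172 M,
computed from the composition at nominal charges) they raise the
apparent Ca–EGTA $K_d$ at pH 7.4 from ~35 nM to ~88 nM, which is what
published calculator outputs reflect. Temperature enters through the
Debye–Hückel $A(T)$ parameter only; binding enthalpies are not applied,
so constants are most accurate near the 20 °C reference — the default
`temperature` — and results at other temperatures shift only the
activity correction. Aspartate is treated as a non-chelating background
electrolyte, matching common calculator practice.

```{r chelator}
pipette_free_ca(6.4) * 1e9    # nM
pipette_free_ca(7.4) * 1e12   # pM
```

The published calculation for this recipe (7.7 nM and 91 pM) is
reproduced within ~0.05 log₁₀ units; the stated comparison tolerance is
0.15 log₁₀ units because the exact constant set, temperature and ionic
strength behind any given calculator run are rarely recorded.

## 6. The synthetic-data generator

The generator exists so that every analysis stage can be validated
against known ground truth:

* **Trajectories** — constant speed, heading integrating
  $\dot\theta = v\,\kappa(t)$ plus optional white heading noise;
  positions advance along exact circular arcs between samples, so
  noise-free schedule segments are exact arcs (the basis of the
  closed-form tests). Localisation noise is additive Gaussian on the
  output.
* **Video** — one Gaussian spot per frame on a constant background with
  Poisson shot noise plus Gaussian read noise, the standard EMCCD
  model. `snr` is peak amplitude over background noise SD.
* **Sweeps** — current = gate(pHᵢ) × unblocked(V) × $g_{max}$ ×
  (V − V_rev) + leak + noise, with V_rev from the Nernst/GHK closed
  forms, an ohmic driving force, and capacitive transients omitted by
  default (steady-state windows are all the analysis uses; an optional
  exponential spike is available).
* **Dose–response** — Hill curves with multiplicative Gaussian noise of
  stated CV.
* **Stopped flow** — mono-exponential rise after a dead time; the
  dual-channel variant puts the rise in channel 1 against a flat
  reference channel, so the ratio encodes alkalization.

What it deliberately does **not** emulate: flagellar waveforms and
their beat-frequency wobble (the ASP filter's raison d'être is removing
it, but the tests feed smooth paths plus noise instead), wall
interactions and the "spinning" behaviour near chamber walls, 3-D
swimming, crossing trajectories, series-resistance and capacitance
artefacts, channel gating kinetics (steps are instantaneous),
photobleaching, and indicator calibration to absolute concentrations.
A green pipeline test therefore establishes that the estimators are
correct for clean planar paths and ohmic steady-state currents at the
stated noise levels — not that tracking would survive dense fields or
that IV analysis would survive poor compensation.

All generators take explicit `seed` arguments, give bit-identical
output for a fixed seed, and leave the caller's RNG state untouched.

## 7. Known limitations

* Curvature and VAP degrade predictably above ~5 rad/s turn rate at
  30 Hz (see §1); faster spinning cells need higher frame rates, which
  the filter handles but the tests do not certify.
* The measured reversal potentials of real sperm (−77 mV at 5.4 mM
  $[K^+]_o$) sit below the Nernst prediction, and the published
  51 mV/decade slope is sub-Nernstian; these reflect finite selectivity
  and junction offsets that are not reconstructable from published
  numbers, so the package validates its electrophysiology against
  closed forms, not against those measurements.
* The chelator module covers EGTA and ATP with Ca²⁺/Mg²⁺/H⁺; other
  buffers (BAPTA, HEDTA) would need their constant rows added.
* Hill-fit standard errors are asymptotic (from the `nls` covariance);
  for the 7-point curves typical of these experiments they are rough
  guides, and replicate spread is the better uncertainty estimate.
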