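---
title: "Superposition-eye pupillometry: models, parameters and design choices"
author: "PupilKinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Superposition-eye pupillometry: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PupilKinetics)
```

## The measurement and its model

A dark-adapted superposition compound eye reflects incident light from its
tapetum as a bright central spot, the superposition pupil. Screening
pigments migrating across the clear zone attenuate this reflection, so eye
brightness under near-infrared illumination is a proxy for the eye's
light-adaptation state. The pipeline quantifies three phenomena:

* **Induced closing** under a bright stimulus (brightness falls),
* **induced opening** in darkness (brightness rises, after an initial
  transient), and
* **intrinsic rhythm**: spontaneous alternation between open and closed
  states under constant darkness, driven by the circadian clock.

The measured quantity per frame is the *integrated density* over a
circular region of interest: ROI area times mean grey value, equivalently
the sum of member-pixel grey values. Pixel membership uses the
pixel-centre-within-radius rule with 0-based pixel-centre coordinates;
this is deterministic and reproducible, unlike interactive ROI tools.

### Camera linearization

Consumer cameras compress luminance nonlinearly. We model the transfer
function as a gamma curve,

$$Y_{out} = A \, Y_{in}^{\gamma},$$

fitted to chart pairs by nonlinear least squares in the original response
space (Levenberg–Marquardt, initialized from the log–log linear
regression, which is exact up to noise and leaves the optimizer little to
do). The inverse, $Y_{corr} = (Y_{meas}/A)^{1/\gamma}$, linearizes all
measurements before any kinetic analysis. The fitting space is a genuine
choice — log–log least squares weights relative errors, original-space
least squares weights absolute errors; we fit in original space because
measurement noise on grey values is closer to additive. Values above the
fitted amplitude are corrected by extrapolation (result > 1) and flagged
with a message rather than clipped.

### Kinetic model

Each corrected curve is min–max normalized to $[0,1]$ (extremes taken over
the full series, times re-zeroed) and fitted with the two-parameter
log-logistic sigmoid

$$f(x) = \frac{1}{1 + \exp\!\big(b(\log x - \log t_{50})\big)},$$

the time-domain equivalent of the classical Lipetz response–intensity
relation. $t_{50}$ (seconds) is the time at half brightness —
$f(t_{50}) = 0.5$ holds identically — and $b$ is the slope of the linear
part of the sigmoid; it is dimensionless in the sense that rescaling time
rescales $t_{50}$ but leaves $b$ unchanged (the slope lives in log-time).
Two sign conventions circulate for such curves; we adopt **closing:
$b > 0$ ($f$ decreasing), opening: $b < 0$ ($f$ increasing)**, which
matches the function's algebra, and fits warn when the recovered sign
contradicts the declared direction.

The model deliberately has **no offset or amplitude parameters**: the
asymptotes are pinned at 0 and 1. This is the "forced through the origin"
constraint — for an opening curve $f(0^+) = 0$ holds automatically; for a
closing curve the constraint pins the asymptotes rather than the literal
point $(0,0)$, since $f(0^+) = 1$ there. Whether one fits brightness or
$1 - $ brightness changes only the sign of $b$, not $|b|$ or $t_{50}$.

### The opening transient ("bump")

Dark re-opening recordings begin with the eye transiently brightened; the
signal decays to a "minimum low" within the first 5–15 minutes before the
sigmoid rise. The transient is modelled in the generator as an additive
pulse held at `peakHeight` from the recording start until `peakTime`, then
decaying exponentially with constant `decayTau`. We chose the held-peak
form (rather than a ramp from zero) because the recording starts *at* the
sudden brightness increase: with a ramp the composite curve's global
minimum would sit at $t \approx 0$ instead of at the post-transient dip,
which is not what such recordings look like.

Detection mirrors this shape: on the smoothed curve (centered moving
average, width 5 samples) the first local maximum inside the search window
(default 20 min, covering the observed transient span) marks the peak —
the first sample qualifies when the curve starts elevated — and the bump
end is the windowed minimum after the peak. A minimum prominence of 0.02
normalized units guards against flat starts and noise ripples. Samples
before the bump end are removed, time is re-zeroed there, and the retained
span is re-normalized; the pipeline therefore normalizes, trims, then
re-normalizes, an order that keeps the fitted rise anchored at 0.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| camera `A`, `gamma` | 16.71, 0.58 | grey, — | transfer function of the recording camera used as the simulator default |
| noise `sigma` | 0.03 | normalized brightness | realistic frame-to-frame scatter for a consumer NIR setup |
| closing sampling | 1 frame/s, 900 s | — | induced closing completes in ~15 min |
| opening sampling | 1 frame/min, 5400 s | — | dark opening completes in ~90 min |
| intrinsic sampling | 1 frame/5 min, 36 h | — | circadian recording length before preparations deteriorate |
| `periodH` | 12 | h | open/closed alternation after 12:12 entrainment |
| `transitionB` | 8 | — | sharp but smooth state transitions |
| hysteresis `low`, `high` | 0.3, 0.7 | normalized | transitions are full-amplitude; thresholds sit well outside noise |
| refractory interval | 2 | h | far below the period, above transition duration |
| bump window | 1200 | s | covers the 5–15 min transient span |
| smoothing width | 5 (curves), 3 (rhythm) | samples | below the kinetic/transition timescale |
| selection `alpha` | 0.05 | — | conventional level, matches the Tukey display |

Temperature enters the generator as a Q10-style multiplicative factor on
$t_{50}$ (default: factor 2 per 7 °C below the 22 °C reference), a
minimal way to express "colder is slower" without asserting a kinetic
law.

## The synthetic-data generator

The generator produces, under a single seeded RNG contract (identical
seeds give bit-identical output, and the caller's RNG state is restored):

* calibration pairs $Y_{out} = A Y_{in}^\gamma + \varepsilon$,
* induced series: normalized ground truth $g(t) = f(t; b, t_{50})$ plus
  the optional bump, pushed through the camera forward model,
* intrinsic series: alternating plateaus with log-logistic-shaped
  transitions whose 0.5-crossings fall exactly on the switch times
  ($k \cdot$ `periodH` + `phaseOffsetH`), plus a linear brightness drift
  (negative drift emulates the irreversible closure of deteriorating
  small preparations), and
* rendered 8-bit frame stacks (noisy background, dim eye disc, central
  pupil disc carrying the series value), so the imaging module can be
  tested end to end against known truth.

Noise is additive Gaussian expressed in normalized-brightness units and
applied on the camera's output scale (SD $= \sigma A$), after which grey
values are clipped at zero; drift is linear because the observed closure
is gradual and no functional form is established. Every simulated object
carries its generating truth (`groundTruth()`), which is what
parameter-recovery tests compare against.

What the generator does **not** emulate — and what passing tests therefore
do not establish about real data: specimen motion (a single fixed ROI is
assumed), slow illumination or focus drift within a recording, the
bimodal/inflected closing shape seen in some species (no mixture
component is fitted), photochemical after-effects of strong stimuli, and
any dependence of noise on brightness. Recovery results on synthetic data
bound what the pipeline can do under its own assumptions, not under all
field conditions.

## Numerical choices

* **Log-logistic fitting** runs on $(b, \log t_{50})$ with
  Levenberg–Marquardt least squares, tolerance $10^{-10}$ on the sum of
  squares, at most 500 iterations. Initialization: $t_{50}^{(0)}$ from the
  linearly interpolated 0.5-crossing; $b^{(0)} = 4/(\log t_{0.25} -
  \log t_{0.75})$ from the quartile crossings (sign falls out
  automatically). When crossings are absent, a grid over slopes
  $\pm\{0.5, 1, 2, 4, 8\}$ and quartile $t_{50}$ candidates is scored,
  polished by Nelder–Mead, then refitted; if even that fails the fit is
  returned with `converged = FALSE` and diagnostics.
* **The $t = 0$ sample** cannot enter a log-time loss; it is shifted
  forward by half the sampling interval (configurable). This touches one
  sample out of hundreds and is documented rather than silently dropped.
* **Degenerate inputs** are rejected with specific errors: constant
  series cannot be normalized, trims leaving fewer than 5 samples are
  refused, collinear points admit no circle, ROIs must lie fully inside
  the frame.
* **Switch detection** demands full-amplitude transitions: a 0.5-crossing
  counts only if the signal was beyond the outer threshold since the last
  accepted switch and reaches the opposite threshold before the next
  crossing. Detrending (subtracting the open-plateau drift line when
  estimable) precedes detection so that slow closure does not masquerade
  as extra switches. Drift itself is the least-squares slope through the
  per-cycle open-plateau medians, computed over each plateau's central
  half to stay clear of transitions.
* **Model selection** walks $n = 0 \ldots 3$ and accepts an order only
  when its sequential F-test $p < \alpha$ *and* its AIC beats the last
  accepted model's. `stats::AIC` counts the Gaussian dispersion parameter,
  so the intercept-only model has $k = 2$; the offset is constant across
  the hierarchy and cancels in comparisons. Note the walk takes up to
  three 5%-level tests, so under a global null the family-wise probability
  of leaving $n = 0$ is about $1 - 0.95^3 \approx 0.14$ before the AIC
  condition damps it — "kept the simple model" should be read against
  that rate, not against 5%.
* **Compact letter display**: emmeans supplies the marginal means and
  Tukey-adjusted pairwise $p$-values; letters are then assigned by a
  greedy merge on the mean-ordered levels — every maximal run of
  consecutive levels that are pairwise non-significant receives one
  letter, runs contained in an earlier run are skipped, ties broken by
  mean order. For the 2–3-level factors of this design this reproduces
  the standard display.
* **Circle fitting** uses the Kåsa algebraic formulation (linear least
  squares on $x^2 + y^2 = 2ax + 2by + c$): exact on noiseless circles,
  no initialization, translation- and rotation-equivariant. Its known
  small-arc bias is irrelevant for near-complete eye outlines.

## Known limitations

* **Min–max normalization couples the estimates to the recording
  window.** Because the extremes are taken over raw noisy samples, the
  normalized curve is compressed by extreme-value noise, and a window
  that truncates the sigmoid's tail shifts the apparent half-time.
  Through the full pipeline this biases closing-curve estimates
  noticeably low at realistic noise (the test suite freezes the measured
  bounds), while fitting the model samples directly is unbiased as noise
  vanishes. Comparisons *between* groups recorded under the same protocol
  are unaffected to first order, which is how the statistics module uses
  the parameters; absolute values of $b$ and $t_{50}$ should be quoted
  with the protocol.
* The intrinsic-rhythm module reports entrained 12-h switching and a
  plateau drift; it is not a general circadian toolbox (no periodogram,
  no free-running-period estimation), and a possible interaction between
  drift and switch amplitude is not modelled.
* Specimens are treated as independent records in the GLM hierarchy; no
  mixed-effects structure is fitted.
* The optional mid-curve inflection of closing curves in some species is
  not modelled; a two-component mixture would need parameters no current
  recording constrains.

## Problem sizes used by the test and acceptance suites

Monte-Carlo checks use 50 seeded replicates for curve-fit quality
($R^2$ floors of 0.87 for closing and 0.90 for opening through the full
camera–correction–normalization–fit pipeline) and for the intrinsic
period (mean within $\pm 0.5$ h of 12 h); calibration round-trip
properties run 1000 randomized cameras at $10^{-9}$ tolerance; model
selection calibration and power use 200 seeded specimen tables with 10
(null) and 20 (effect) specimens per cell. These sizes were chosen so the
binomial/Monte-Carlo error of each checked rate is several times smaller
than the margin being asserted.

```{r example}
cam <- fitGamma(generateCalibrationPairs(CameraCalibration(16.71, 0.58),
                                         (1:24) / 24))
s <- simulateInducedSeries(KineticTruth(b = 2.5, t50 = 300),
                           durationS = 900, dtS = 1,
                           noise = NoiseModel(sigma = 0.03, seed = 42))
fitInducedCurve(s, cam, direction = "closing")$fit
```
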