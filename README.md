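# PupilKinetics

Analysis pipeline for **superposition-eye pupillometry**: quantifying how
the "pupil" of an insect superposition compound eye opens and closes, from
near-infrared (NIR) eye-reflection recordings.

In a dark-adapted superposition eye the tapetal reflection appears as a
bright spot — the superposition pupil — whose brightness tracks the
position of the screening pigments and hence the eye's light-adaptation
state. Recording that brightness under NIR illumination (which does not
trigger phototransduction) gives a non-invasive readout of pupil kinetics:
light-induced closing, dark re-opening, and the intrinsic circadian
open/closed rhythm under constant darkness. The package is aimed at visual
ecologists and insect physiologists who record such series with simple
USB-microscope setups and want a reproducible route from image stacks to
comparable kinetic parameters.

## What it computes

1. **Reflectance extraction** — per-frame integrated density (ROI area x
   mean grey value) over a circular region of interest on a grayscale
   image stack.
2. **Camera linearization** — the camera's transfer function
   `Y_out = A * Y_in^gamma` is fitted to calibration-chart pairs by
   nonlinear least squares, and its inverse
   `Y_corr = (Y_meas / A)^(1/gamma)` corrects all measurements.
3. **Kinetic fitting** — each corrected curve is min-max normalized to
   [0, 1] and fitted with the two-parameter log-logistic (Lipetz-type)
   sigmoid

   ```
   f(x) = 1 / (1 + exp(b * (log x - log t50)))
   ```

   where `b` is the slope of the linear part of the sigmoid and `t50` the
   time at half brightness (`f(t50) = 0.5` by construction; closing curves
   have `b > 0`, opening curves `b < 0`). Dark re-opening recordings begin
   with a transient "bump" that is detected and excluded before fitting.
4. **Circadian rhythm** — hysteresis switch detection, mean switching
   period and open-plateau drift on 36-h constant-darkness series.
5. **Group comparison** — hierarchical Gaussian GLM selection over
   `~ (sex + species + temperature)^n`, n = 0..3, by sequential ANOVA +
   AIC, followed by Tukey-adjusted estimated-marginal-mean contrasts with
   a compact letter display.
6. **Morphometry utilities** — interommatidial angle (180° / arc count),
   algebraic (Kåsa) circle fitting for eye outlines, and a packaged
   reference table of eye measurements for the stereo-vs-CT cross-check.

A seeded synthetic-data generator emulates every recording type (induced
closing at 1 frame/s, dark opening at 1 frame/min, 36-h intrinsic series
at 1 frame/5 min, rendered 8-bit frame stacks), pushing known ground truth
through the same camera model, so the whole pipeline is testable without
any raw recordings.

## Worked example

```r
library(PupilKinetics)

## camera calibration from (synthetic) chart pairs
cam <- fitGamma(generateCalibrationPairs(CameraCalibration(16.71, 0.58),
                                         (1:24) / 24))
cam
#> CameraCalibration: Y_out = A * Y_in^gamma
#>   A = 16.71, gamma = 0.58 (rss = 0)

## a UV-induced closing recording (1 frame/s, 15 min), fitted end to end
s <- simulateInducedSeries(KineticTruth(b = 2.5, t50 = 300),
                           durationS = 900, dtS = 1,
                           noise = NoiseModel(sigma = 0.03, seed = 42))
res <- fitInducedCurve(s, cam, direction = "closing")
res$fit
#> LogLogisticFit (closing)
#>   b = 2.27243, t50 = 250.923 s, R^2 = 0.9736

## intrinsic rhythm in a 36-h constant-darkness recording
si <- simulateIntrinsicSeries(IntrinsicParams(), durationH = 36, dtMin = 5,
                              noise = NoiseModel(sigma = 0.05, seed = 42))
analyzeRhythm(normalizeCurve(correctSeries(si, cam)))
#> RhythmResult: 2 switches, start state open
#>   switch times (h): 11.98, 24.03
#>   mean period: 12 h (sd NA), drift: -0.000607 /h

## group comparison on a synthetic specimen table
rec <- simulateSpecimenTable(nPerCell = 10,
                             speciesEffect = list(t50_s = c(GM = 120)),
                             seed = 42)
h <- fitGlmHierarchy(rec, "t50_s")
n <- selectModel(h)          # -> order 1 (main effects)
emmPairwise(attr(n, "model"), "species")
#> ContrastTable for 'species' (Tukey-adjusted, alpha = 0.05)
#>  species   emmean       SE  df lower.CL upper.CL .group
#>       CP 295.9738 5.715862 115 284.6518 307.2959      a
#>       GM 414.4249 5.715862 115 403.1029 425.7469      b
#>       LB 296.7753 5.715862 115 285.4532 308.0973      a
```

The fitted `b` and `t50` are the two dependent variables of the kinetic
analysis: `t50` measures how fast the pupil reaches half adaptation, `b`
how abrupt the transition is around that point. In the contrast table,
levels sharing no letter differ significantly — here the species whose
half-time was shifted (GM) is separated from the other two.

The camera-correction fit above reproduces the generating parameters
exactly because the pairs are noiseless; on noisy recordings the fit
quality is reported via the residual sum of squares and the per-curve
`R^2`.

## Package layout

- `R/` — S4 classes (`ReflectanceSeries`, `CameraCalibration`,
  `NormalizedCurve`, `LogLogisticFit`, `RhythmResult`, ...), generators,
  and one file per pipeline stage.
- `inst/extdata/table1_morphometry.csv` — packaged eye-morphometry
  reference table.
- `vignettes/pupillometry-pipeline.Rmd` — the methods vignette: model
  assumptions, parameter choices, numerical details and limitations.
- `tests/testthat/` — unit, property and acceptance suites.
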