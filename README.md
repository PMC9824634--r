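# msaccid

Person identification from fixational microsaccades.

Even during steady fixation the eye keeps moving: microsaccades (fast
~12 arcmin jerks), drift (slow wander, 0–40 Hz, ~4 arcmin/s) and tremor
(70–103 Hz oscillation). `msaccid` treats the microsaccades recorded during
a 15 s point fixation as a behavioural biometric and asks whether a
held-out fixation can be attributed to the person who produced it. The
package is aimed at eye-movement and biometrics researchers who want a
complete, reproducible implementation of that pipeline together with a
simulator for controlled validation.

## The method

1. **Preprocessing.** A 1 kHz monocular gaze trace (degrees) is denoised by
   zeroing DFT amplitudes above 104 Hz plus 50/100 Hz mains notches (a
   constant-velocity Kalman filter is available as an alternative).
   Microsaccades are detected with a velocity-ellipse test
   ((vx/ηx)² + (vy/ηy)² > 1, η = 6 × robust SD) or a chi-square(10) change
   detector on 11-sample windows; the residual splits exactly into drift
   (0–40 Hz) and tremor (70–103 Hz) bands.
2. **Features.** Each event Z = z₁…zₙ yields 13 features: duration (n−1 ms),
   height H (max distance to the endpoint chord), area S (shoelace /
   Green's formula, self-crossing trajectories decomposed at their crossing
   points), sharpness H/S, base length, the double-microsaccade ratio
   (base/duration, threshold 0.01) and flag, average speed, windowed
   maximal speeds (11 and 21 speeds), mean pseudo-acceleration, top-10
   acceleration magnitude mean, and maximal diameter.
3. **Metric learning.** The quasilinear distance
   ρ(A,B) = Σᵢ wᵢ ΔPᵢ² + Σᵢ<ⱼ wᵢⱼ ΔPᵢ ΔPⱼ carries 91 nonnegative weights
   (13 singles + 78 cross terms). Segments (all events of one fixation) are
   compared through trimmed mass centers (d3; d1/d2 variants included).
   Weights minimize Err(w) = Σ within-person segment distances / Σ
   between-person segment distances — scale-invariant, so the search runs
   on the unit sphere in the nonnegative orthant by projected steepest
   descent (finite-difference gradients, projection = clip negatives +
   renormalize) from 30 random restarts.
4. **Identification.** Leave-one-fixation-out: per person, 4 fixations
   train the feature scales and weights, the 5th is test data. A table of
   summed train-segment distances (rows = test segments, columns = persons)
   is assigned greedily: global minimum first, then L1 row renormalization
   before each subsequent pick.

A seeded simulator (`synth_cohort()`) generates fixational traces —
microsaccade trains with bell-shaped speed profiles, band-limited drift and
tremor, Gaussian sensor noise — with ground-truth event intervals, and is
the basis of all end-to-end validation.

## Worked example

```r
library(msaccid)

co  <- synth_cohort(n_persons = 4, n_fixations = 5, seed = 7)  # 20 x 15 s traces
fco <- cohort_features(co)         # detect + featurize: ~15-30 events/segment

ev <- fco$P1[[1]][1, ]             # one microsaccade's 13 features
round(ev, 4)
#>     duration       height         area    sharpness  base_length double_ratio
#>      24.0000       0.0250       0.0025      10.1524       0.2245       0.0094
#>  double_flag         v_av      v_max11      v_max21     accel_av  accel_max10
#>       1.0000       0.0111       0.0166       0.0123      -0.0001       0.0029
#> max_diameter
#>       0.2301

res <- loo_evaluate(fco, holdout = 5, n_starts = 5, base_seed = 7,
                    max_iter = 15, tol = 1e-5)
round(res$table, 4)                # test segments (rows) vs persons (columns)
#>        P1     P2     P3     P4
#> P1 0.0002 0.0013 0.0048 0.0017
#> P2 0.0034 0.0002 0.0006 0.0061
#> P3 0.0063 0.0008 0.0002 0.0096
#> P4 0.0012 0.0055 0.0107 0.0000
res$assignment
#>   test person
#> 1   P4     P4
#> 2   P1     P1
#> 3   P2     P2
#> 4   P3     P3
#> accuracy: 4/4
```

The first event lasted 24 ms, covered 0.22°, and its base/duration ratio
(0.0094 < 0.01) classifies it as a double (out-and-back) microsaccade. In
the distance table every test segment is closest to its own person's
training segments — the greedy assignment recovers all four identities
(here from 5 optimizer restarts; the full protocol uses 30).

A thin CLI covering simulate / preprocess / extract / train / identify /
evaluate lives at `inst/cli/msaccid.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/msaccid.R", package="msaccid"))')" \
  evaluate --persons 4 --fixations 5 --seed 7 --starts 5 --out report.json
```

## Package layout

- `R/synth.R` — seeded trace/cohort simulator with ground truth
- `R/preprocess.R` — spectral/Kalman denoising, detectors, band splitting
- `R/features.R` — the 13 trajectory features and normalization
- `R/metric.R` — quasilinear distance, segment/person distances, error ratio
- `R/optimize.R` — projected steepest descent, multi-start
- `R/identify.R` — distance table, greedy assignment, leave-one-fixation-out
- `R/io.R` — CSV/JSON/BED-like readers and writers
- `vignettes/microsaccade-biometrics.Rmd` — models, assumptions, design
  choices and limitations
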