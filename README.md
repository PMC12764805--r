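# benthtrack

Movement analysis for slow benthic animals tracked with acoustic telemetry
in small receiver arrays — built around the tracking design used for the
Japanese sea cucumber (*Apostichopus japonicus*) released in a rectangular
fishing port: ultrasonic tags emitting at random 90–150 s intervals, five
seabed receivers with independent millisecond clocks, and a fixed
synchronization tag co-located with one receiver.

The package covers the full chain from raw detections to behavioural
statistics:

1. **Positioning.** Receiver clocks are aligned against the sync tag, the
   detections of each emission are grouped, and the planar position is the
   hyperbolic time-difference-of-arrival (TDOA) solution: each receiver
   pair constrains the tag to a hyperbola, and a damped Gauss–Newton least
   squares on range-difference residuals finds the intersection.
2. **Trajectory estimation.** Position fixes *y<sub>t</sub>* are
   assimilated with a linear-Gaussian state-space model

   x_t = F x_{t−1} + G v_t,  v_t ~ N(0, σ²I)
   y_t = H x_t + w_t,     w_t ~ N(0, τ²I)

   either a planar random walk (F = G = H = I₂) or a position–velocity
   model with state (x, y, u, v)ᵀ and a first-order Δt step. The Kalman
   filter skips the update at detection gaps, a fixed-interval (RTS)
   smoother refines every estimate with the full record, and (σ, τ) — the
   per-step movement magnitude and the positioning-noise level — are
   estimated by maximum likelihood (L-BFGS-B on the prediction-error
   decomposition).
3. **Movement complexity.** Higuchi's coarse-grained length ⟨L(k)⟩ of the
   hourly trajectory gives the fractal dimension D = −slope of
   (log₂k, log₂⟨L(k)⟩): D = 1 for directed motion, D → 2 when positioning
   noise dominates. A regression-parallelism F-test compares dimensions
   between trajectories, and a breakpoint scan over k = 1..30 finds the
   coarsening scale at which the slope changes.
4. **Displacement statistics.** Hourly displacement dt₁ is compared across
   seasons and boulder strata (Wilcoxon rank-sum) and modelled with a
   gamma GLM, log E[dt₁] = β₀ + β₁·temperature + β₂·boulder + β₃·daytime,
   fitted by IRLS with a VIF collinearity check.

A first-class synthetic-data module simulates the entire measurement
system (array geometry, clock offsets and drift, 1-ms quantization,
random emission intervals, dropout), so every stage is testable against
known ground truth without any field data.

## Worked example

```r
library(benthtrack)

# a growing-stage individual in the default 80 m port, 6 tracked days
man <- run_pipeline(list(seed = 1, fixtures = c("sync_tag", "growing_D"),
                         duration_days = 6))
man
#> Pipeline run (benthtrack 0.1.0 )
#>
#> Fixture sync_tag:
#>   emissions 4320 -> detections 20482 -> sets 3318 -> fixes 3318
#>   sigma = 8.87e-07 m/step, tau = 0.343 m
#>   fractal D (x1 windows): 2.01
#>   sync-tag error: raw 0.308 m, smoothed 0.022 m
```

The stationary sync tag behaves as the method expects: its estimated
system noise σ is orders of magnitude below the observation noise τ (a
fixed transmitter "moves" only through measurement error), its fractal
dimension is near 2 (pure noise), and Kalman smoothing shrinks its raw
hyperbolic localization error by an order of magnitude.

Fitting a single trajectory directly:

```r
fx  <- locate_fixes(sets, geometry)        # TDOA fixes from arrival sets
obs <- resample_series(fx, "native")       # 120-s grid with gap flags
fit <- track_ssm(obs, model = "rw")        # ML (sigma, tau) + smoother
coef(fit)                                  # sigma and tau, metres
fitted(fit)                                # smoothed trajectory + covariances
displacement_series(fit, "hourly")         # dt1 for the behavioural models
```

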