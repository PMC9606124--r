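# ligaseflux

Quantifying ubiquitin-ligase activity from fluorescent degron reporters.

A degron reporter expressed from a constitutive promoter reaches a level
set by the balance of synthesis and ligase-driven degradation:

    dR/dt = s − k(t) · R

where `R` is the nuclear reporter intensity (a.u.), `s` the synthesis
rate (a.u./h) and `k` the first-order degradation constant (1/h) imposed
by the ligase. Two drug arms identify the parameters separately: a
neddylation inhibitor (MLN-4924) sets `k → 0`, so the trace slope reads
out `s`; cycloheximide sets `s → 0`, so the decay reads out `k` as a
half-life `t½ = ln 2 / k`. With `s` in hand, the *degradation flux*

    A(t) = s − dR/dt

is the ligase activity at every frame of an unperturbed movie.

`ligaseflux` implements this whole route as composable, pipe-friendly
functions, for people analysing single-cell reporter time-lapse data or
luminescent reporter screens:

* **synthetic ground truth** — phase schedules, piecewise-analytic
  reporter traces with a mitotic intensity artifact and drug
  perturbations, rendered two-channel nuclear image series, 1536-well
  screening plates, paired live/fixed single-cell datasets;
* **image quantification** — illumination-bias estimation from
  background pixels, flat-fielding and global background subtraction,
  nuclear segmentation (EBImage primitives), mutual-nearest-neighbour
  tracking with division detection, median-nuclear-intensity trace
  extraction;
* **kinetic inference** — Geminin-based phase annotation, mitotic-frame
  masking, synthesis-rate estimation, activity computation, half-life
  fitting, mitosis alignment;
* **screen analytics** — percent-activity normalization against neutral
  and negative control medians, strict >50% hit calling, 11-point 1:3
  titration four-parameter logistic IC50 fits, reporter-selectivity
  counter-screen filtering;
* **population statistics** — live-to-fixed cell matching,
  activity-versus-protein correlation with bootstrap CIs, fold
  differences in median activity, IC50 fold shifts.

## Worked example

Simulate a cycloheximide chase at G1-phase kinetics and recover the
half-life:

```r
library(ligaseflux)

traces <- simulate_chx_chase(200, k = 0.2521, duration = 8, R0 = 1000,
                             noise_cv = 0.05, seed = 1)
fits <- estimate_half_life(traces)
median(fits$t_half)
#> [1] 2.745138
```

The generating constant `k = 0.2521 / h` corresponds to `t½ = 2.75 h`;
the log-linear estimator recovers it from 200 noisy single-cell decays.

Infer activity in an unperturbed movie, using a separate inhibited arm
to measure the synthesis rate:

```r
sched <- simulate_phase_schedule(50, duration = 30, seed = 2)
pars  <- kinetic_params(s = 10, noise_cv = 0.05)
movie <- simulate_reporter_trace(sched, pars, seed = 2)

mln <- simulate_reporter_trace(
  sched, pars, perturbations = perturbation("MLN4924", t_on = 0),
  seed = 3)
s_hat <- estimate_synthesis_rate(mln, window_h = c(0.5, 6))$s

activity <- movie |>
  mask_mitotic_frames() |>
  compute_activity(s = s_hat)

align_to_mitosis(activity, value = "A") |> autoplot()
```

`activity$A` is the degradation flux in a.u./h (positive = active
degradation); `activity$k_specific = A / R` is the level-normalized
rate. Screen analytics chain the same way:

```r
plate <- simulate_screen_plate(plate_layout_1536(), seed = 4)
hits <- plate |> normalize_plate() |> call_hits(threshold = 50)
```

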