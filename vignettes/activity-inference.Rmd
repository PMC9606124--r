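---
title: "From reporter traces to ligase activity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From reporter traces to ligase activity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ligaseflux)
library(dplyr)
```

## The model

A fluorescent degron reporter transcribed from a constitutive promoter
and degraded by a ubiquitin ligase obeys a first-order balance

$$\frac{dR}{dt} = s - k(t)\,R,$$

with a constant synthesis rate $s$ (a.u./h) and a degradation constant
$k$ (1/h) that carries all of the biology: it changes with cell-cycle
phase, quiescence, and drug treatment. Two consequences drive every
method in this package:

1. **Identifiability by perturbation.** Inhibiting degradation
   (neddylation inhibitor, $k \to 0$) makes the trace rise linearly at
   slope $s$; inhibiting synthesis (cycloheximide, $s \to 0$) makes it
   decay exponentially at rate $k$, so $t_{1/2} = \ln 2 / k$.
2. **Frame-wise activity.** Once $s$ is known, the degradation flux
   $A(t) = s - dR/dt$ is measurable at every frame of an *unperturbed*
   movie. At any instant $A = kR$, so the flux depends on the reporter
   level; the specific rate $k_\mathrm{specific} = A/R$ is exposed
   alongside it. The flux is the default summary because it is what the
   derivative recipe yields directly; the normalized rate is preferable
   when comparing cells at very different reporter levels. Both
   conventions are provided since the choice is genuinely open.

## What the simulator emulates — and what it does not

`simulate_phase_schedule()` cycles G1 → S → G2 → M with lognormal phase
durations (defaults 8, 6, 5, 0.6 h, a ~20 h cycle; M capped well under
an hour). `simulate_reporter_trace()` integrates the balance equation
*analytically* on each segment of constant coefficients — phase
intervals split at perturbation onsets — so the latent ground truth
carries no solver error at all; tests compare it against `deSolve` at
tight tolerance. The measurement layer adds:

* a **mitotic spike**: measured intensity is multiplied by 1.8 on M
  frames, emulating the apparent brightening when a rounding cell
  concentrates its fluorophores during nuclear envelope breakdown. The
  literature describes this artifact qualitatively; the amplitude and
  the 0.6 h M duration are free parameters here, configurable and fixed
  once at values that make the artifact unmistakable without dwarfing
  the signal;
* **multiplicative lognormal noise** with a CV parameter (default 5%),
  since fluorescence measurement error scales with signal;
* frame cadence of 0.2 h (12-minute imaging interval), configurable.

Drug semantics (`perturbation()`): MLN-4924 scales $k$ by 0 (complete
inhibition — justified by the inhibited reporter reaching the level of
a degron-mutant reporter); cycloheximide sets $s = 0$; sunitinib
triples $k$ after a 1 h onset lag; mitogen withdrawal/stimulation
switch the phase to/from G0, where the default $k$ is the highest of
any phase. Division conserves concentration (daughter latent level
equals the mother's), and the tracker follows one daughter per
division, chosen deterministically by label order.

The default decay constants are $k_{G1} = 0.2521$/h and
$k_{S/G2} = 0.0770$/h — half-lives of 2.75 h and 9 h — with synthesis
at 10 a.u./h and the initial level at the G1 steady state $s/k$.

What the simulator deliberately does *not* model: photobleaching,
camera shot/read noise physics, cell motility beyond static nuclei,
out-of-focus light, and any mechanism of SCF complex assembly or
downstream signaling. Passing tests therefore demonstrate that the
*inference* is correct under the stated generative model, not that the
model captures every property of real movies; in particular real data
add tracking errors from motile, touching cells that the rendered
fixtures only probe mildly.

## Image quantification choices

* **Illumination bias** is fit as a 2nd-order 2D polynomial to pixels
  below the 10th intensity percentile of each sampled frame. Background
  light is spatially flat before the optics, so those pixels trace the
  bias up to a constant; the field is normalized to unit mean, and the
  low polynomial order keeps the surface from absorbing cellular
  signal.
* **Global background** after flattening is the 5th percentile of the
  frame — robust when cells are sparse. Corrected frames may contain
  small negatives; they are intentionally not clipped.
* **Segmentation** is Gaussian smoothing (σ = 2 px), Otsu thresholding,
  a 40–2500 px² area filter, and distance-transform watershed splitting
  of touching nuclei. No algorithm is canonical for this step; these
  are the standard primitives, and the suite validates them against
  rendered ground truth (≥ stated detection and ≤ 2% round-trip error)
  rather than against a reference implementation.
* **Tracking** links mutual nearest centroids greedily under a
  displacement cap. A division is declared when a mother disappears
  and two unlinked objects appear within 1.5× the cap — or when a
  linked mother has one extra orphan appear beside its link, which is
  how a real mitosis usually presents to a greedy linker. The heuristic
  is configurable and deliberately simple; it is validated on simulated
  lineages, not tuned to any particular dataset.

## Inference choices

* **Derivative**: centered local linear fit over 5 frames (1 h at
  12-min cadence). This suppresses frame-to-frame noise while keeping
  drug-onset transients sharp; the suite verifies $A = kR$ within 1%
  discretization error on noiseless traces for $k \le 0.5$/h.
* **Mitotic masking**: mitotic frames ±2 frames (24 min) are excluded
  from derivatives and fits; the spike otherwise injects large spurious
  activity excursions of both signs.
* **Synthesis rate**: per-cell least-squares slope over a post-MLN
  window, summarized by the population median (robust to outlier
  cells); the median is applied population-wide by default. Incomplete
  inhibition bends the rise and is flagged when the late-half slope
  falls below 0.9× the early-half slope.
* **Half-life**: ordinary least squares of $\ln R$ on $t$. Under
  multiplicative noise the log transform is variance-stabilizing, so
  this is preferred over nonlinear fitting of the exponential.
  Non-positive intensities are dropped (erroring beyond a 20%
  fraction); a non-positive decay estimate is reported as a `no_decay`
  flag with $t_{1/2} = \infty$, never silently.
* **Phase annotation**: S entry is called at the first frame where the
  Geminin signal exceeds baseline + 0.2× its dynamic range and keeps
  rising for 3 frames. The threshold fraction and persistence are free
  parameters (no published value exists); 0.2/3 rejects isolated noise
  crossings at 5% CV.
* **Activity is not clipped at zero** — negative values diagnose noise
  or unmodeled synthesis changes.

## Screen analytics choices

Percent activity is anchored per plate:
$PA = 100\,(\mathrm{lum} - \mathrm{med}_n) / (\mathrm{med}_n -
\mathrm{med}_{neg})$, so the neutral-control median scores 0 and the
media-only median −100. Positive PA (more luminescence than neutral)
means the reporter accumulated, i.e. ligase *inhibition*; this sign
convention follows the behaviour of the two control drugs (MLN-4924
up, cycloheximide down). Per-plate medians make the normalization
robust to plate-to-plate gain drift, and the suite checks exact
affine invariance. Hit thresholds are strict inequalities at 50% in
both directions.

Dose–response uses the 4-parameter logistic
$r = b + (t - b)/(1 + (d/\mathrm{IC}_{50})^h)$ fit by
Levenberg–Marquardt from a grid of starts (IC50 spread geometrically
over the dose range, Hill slopes of both signs), keeping the best
converged start. Degenerate outcomes map to a small class taxonomy —
`converged`, `flat`, `incomplete` (IC50 beyond 10× the dose range),
`non-converged` — and a non-converged fit is reported as such, never
replaced by a default. The titration defaults to 11 points at 1:3 from
13 µM, the primary-screen concentration.

Correlation between single-cell activity and protein level defaults to
Spearman (robust to staining nonlinearity; Pearson available — the
coefficient behind a published ρ is often unstated, so both are
exposed). "Activity" for a fixed-cell comparison is summarized as the
median flux over the final 2 h of imaging before fixation, a window
that has no canonical definition and is configurable at the call site.
Bootstrap CIs use 2000 percentile resamples, seeded.

## Numerical and degenerate-input conventions

Pixel coordinates are 1-based (row, col); intensities are arbitrary
units. Identical seeds reproduce every generator bit-for-bit. Empty
frames segment to empty label maps; empty movies track to empty
graphs; traces without mitoses are excluded (and counted) by the
aligner; degenerate controls (equal neutral and negative medians) and
zero-variance correlation inputs are errors, not NaNs.

## Problem sizes

The validation suite runs cohorts of 50–200 cells, 128–160 px frames
over ≤ 50 frames, ten 1536-well plates, and 20-replicate titrations —
sizes at which every recovery criterion (half-life within 5%,
synthesis within 2%, activity fold within 15%, IC50 fold within 10%)
is comfortably resolved while the whole suite completes in well under
a minute per file.

## Known limitations

Division detection assumes daughters appear within one frame and
within 1.5× the displacement cap; slow imaging cadences will miss
divisions. The bias estimator requires genuine background area — a
confluent field violates its premise and errors. The activity
derivative inherits a one-window lag around sharp transitions. The 4PL
residual-resampling CI for IC50 fold shifts understates uncertainty
for titrations with fewer than ~8 informative doses.
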