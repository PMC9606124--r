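# Synthetic single-cell reporter traces ---------------------------------
#
# The generative model is a synthesis-degradation balance for a degron
# reporter R driven by a constitutive promoter:
#
#     dR/dt = s - k(t) * R
#
# with a constant synthesis rate s (a.u./h) and a first-order degradation
# constant k that depends on cell-cycle phase and on drug perturbations.
# The coefficients are piecewise constant, so the trajectory is integrated
# analytically segment by segment; no numerical solver error enters the
# ground truth.

#' Kinetic parameters of the reporter synthesis-degradation model
#'
#' Bundles the parameters of the ordinary differential equation
#' \eqn{dR/dt = s - k \cdot R} used by the trace simulator, together with
#' the measurement-layer parameters (mitotic intensity artifact and
#' multiplicative noise).
#'
#' Default decay constants follow first-order half-lives of 2.75 h in G1
#' and 9 h in S/G2 (\eqn{k = \ln 2 / t_{1/2}}), with quiescent (G0) cells
#' degrading the reporter faster than any cycling phase.
#'
#' @param s Synthesis rate in a.u./h; must be >= 0.
#' @param k_by_phase Named vector of decay constants (1/h) with entries for
#'   G0, G1, S, G2 and M; all >= 0.
#' @param mitotic_spike Multiplicative intensity artifact applied to
#'   measured (not latent) intensity on mitotic frames, caused by cell
#'   rounding and nuclear envelope breakdown; >= 1.
#' @param noise_cv Coefficient of variation of multiplicative lognormal
#'   measurement noise; >= 0.
#' @param R0 Initial reporter level (a.u.). Defaults to the G1 steady state
#'   `s / k_G1` when that is defined, otherwise 100.
#' @return A list of class `kinetic_params`.
#' @export
#' @examples
#' kinetic_params(s = 10, noise_cv = 0)
kinetic_params <- function(s = 10,
                           k_by_phase = c(G0 = 0.5, G1 = 0.2521,
                                          S = 0.0770, G2 = 0.0770,
                                          M = 0.2521),
                           mitotic_spike = 1.8,
                           noise_cv = 0.05,
                           R0 = NULL) {
  if (!is.numeric(s) || length(s) != 1L || s < 0)
    abort("`s` must be a single non-negative number.")
  req <- c("G0", "G1", "S", "G2", "M")
  if (is.null(names(k_by_phase)) || !all(req %in% names(k_by_phase)))
    abort("`k_by_phase` must be named with entries G0, G1, S, G2, M.")
  if (any(k_by_phase < 0)) abort("all decay constants must be >= 0.")
  if (mitotic_spike < 1) abort("`mitotic_spike` must be >= 1.")
  if (noise_cv < 0) abort("`noise_cv` must be >= 0.")
  if (is.null(R0)) {
    kG1 <- k_by_phase[["G1"]]
    R0 <- if (s > 0 && kG1 > 0) s / kG1 else 100
  }
  if (R0 < 0) abort("`R0` must be >= 0.")
  structure(list(s = s, k_by_phase = k_by_phase[req],
                 mitotic_spike = mitotic_spike,
                 noise_cv = noise_cv, R0 = R0),
            class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("<kinetic_params> s =", x$s, "a.u./h, R0 =", signif(x$R0, 4), "\n")
  cat("  k (1/h):", paste(names(x$k_by_phase),
                          signif(x$k_by_phase, 4), sep = "=",
                          collapse = ", "), "\n")
  cat("  mitotic spike x", x$mitotic_spike,
      ", noise CV", x$noise_cv, "\n")
  invisible(x)
}

#' Describe a drug or mitogen perturbation
#'
#' A perturbation overrides the model coefficients from `t_on + lag_h`
#' onward: `s_factor` scales the synthesis rate, `k_factor` scales every
#' phase decay constant, and `phase_to` forces a phase (entry to or exit
#' from quiescence). Per-drug defaults:
#'
#' * `MLN4924` (neddylation inhibitor): `k_factor = 0` — degradation fully
#'   inhibited, the reporter accumulates at its synthesis rate.
#' * `CHX` (cycloheximide): `s_factor = 0` — synthesis stops, the decay
#'   reads out degradation.
#' * `SUNITINIB`: `k_factor = 3`, `lag_h = 1` — degradation accelerates
#'   within an hour of treatment.
#' * `MITOGEN_WITHDRAWAL`: `phase_to = "G0"`.
#' * `MITOGEN_STIM`: `phase_to = "G1"` (exit from quiescence).
#' * `SIRNA`: `k_factor = 0.3` (partial knockdown of the ligase).
#'
#' @param drug One of MLN4924, CHX, SUNITINIB, MITOGEN_WITHDRAWAL,
#'   MITOGEN_STIM, SIRNA.
#' @param t_on Treatment time in hours.
#' @param lag_h Onset delay in hours; drug-specific default.
#' @param s_factor,k_factor,phase_to Optional explicit overrides.
#' @return A one-row tibble; rows from several calls can be combined with
#'   [dplyr::bind_rows()].
#' @export
#' @examples
#' perturbation("CHX", t_on = 24)
perturbation <- function(drug = c("MLN4924", "CHX", "SUNITINIB",
                                  "MITOGEN_WITHDRAWAL", "MITOGEN_STIM",
                                  "SIRNA"),
                         t_on, lag_h = NULL, s_factor = NULL,
                         k_factor = NULL, phase_to = NULL) {
  drug <- match.arg(drug)
  defaults <- switch(drug,
    MLN4924            = list(lag = 0, s = 1,  k = 0,  ph = NA_character_),
    CHX                = list(lag = 0, s = 0,  k = 1,  ph = NA_character_),
    SUNITINIB          = list(lag = 1, s = 1,  k = 3,  ph = NA_character_),
    MITOGEN_WITHDRAWAL = list(lag = 0, s = 1,  k = 1,  ph = "G0"),
    MITOGEN_STIM       = list(lag = 0, s = 1,  k = 1,  ph = "G1"),
    SIRNA              = list(lag = 0, s = 1,  k = 0.3, ph = NA_character_))
  lag_h <- lag_h %||% defaults$lag
  s_factor <- s_factor %||% defaults$s
  k_factor <- k_factor %||% defaults$k
  phase_to <- phase_to %||% defaults$ph
  if (s_factor < 0 || k_factor < 0)
    abort("perturbation scale factors must be >= 0.")
  tibble(drug = drug, t_on = t_on, lag_h = lag_h,
         s_factor = s_factor, k_factor = k_factor, phase_to = phase_to)
}

#' Simulate cell-cycle phase schedules
#'
#' Generates, per cell, an ordered set of phase intervals tiling
#' `[0, duration]` by cycling G1 -> S -> G2 -> M with lognormally
#' distributed phase durations. Each completed M interval ends at a
#' mitosis. With `quiescent = TRUE` every cell is a single G0 interval.
#'
#' @param n_cells Number of cells.
#' @param cycle_params Named list `phase -> c(mean_h, cv)` for G1, S, G2
#'   and M. A CV of 0 gives deterministic durations. The defaults give a
#'   ~20 h cycle.
#' @param duration Total simulated time in hours (> 0).
#' @param seed Integer seed; identical seeds reproduce the schedule
#'   exactly.
#' @param quiescent If TRUE, cells stay in G0 for the whole window.
#' @return Tibble with columns `cell_id`, `start_h`, `end_h`, `phase`.
#' @seealso [schedule_mitoses()], [simulate_reporter_trace()]
#' @export
#' @examples
#' sched <- simulate_phase_schedule(2, duration = 40, seed = 1)
#' schedule_mitoses(sched)
simulate_phase_schedule <- function(n_cells,
                                    cycle_params = list(
                                      G1 = c(8, 0.15), S = c(6, 0.10),
                                      G2 = c(5, 0.10), M = c(0.6, 0)),
                                    duration = 48, seed = 1,
                                    quiescent = FALSE) {
  if (duration <= 0) abort("`duration` must be > 0.")
  if (!quiescent) {
    need <- c("G1", "S", "G2", "M")
    if (!all(need %in% names(cycle_params)))
      abort("`cycle_params` must name G1, S, G2 and M.")
    means <- vapply(cycle_params[need], `[`, numeric(1), 1L)
    if (any(means <= 0)) abort("phase duration means must be positive.")
  }
  set.seed(seed)
  draw <- function(phase) {
    p <- cycle_params[[phase]]
    m <- p[1]; cv <- p[2]
    if (cv <= 0) return(m)
    sdlog <- sqrt(log1p(cv^2))
    rlnorm(1, meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
  }
  one_cell <- function(i) {
    id <- sprintf("cell_%04d", i)
    if (quiescent)
      return(tibble(cell_id = id, start_h = 0, end_h = duration,
                    phase = "G0"))
    t0 <- 0
    rows <- list()
    order <- c("G1", "S", "G2", "M")
    j <- 0L
    while (t0 < duration) {
      ph <- order[(j %% 4L) + 1L]
      t1 <- min(t0 + draw(ph), duration)
      rows[[j + 1L]] <- tibble(cell_id = id, start_h = t0, end_h = t1,
                               phase = ph)
      t0 <- t1
      j <- j + 1L
    }
    list_rbind(rows)
  }
  list_rbind(map(seq_len(n_cells), one_cell))
}

#' Mitosis times implied by a phase schedule
#'
#' @param schedule Tibble from [simulate_phase_schedule()].
#' @return Tibble `cell_id`, `mitosis_h` (end of each M interval).
#' @export
schedule_mitoses <- function(schedule) {
  schedule |>
    filter(.data$phase == "M") |>
    transmute(cell_id = .data$cell_id, mitosis_h = .data$end_h)
}

# Exact solution of dR/dt = s - k R over an interval of length t with
# constant coefficients.
ode_step <- function(R0, s, k, t) {
  if (k > 0) s / k + (R0 - s / k) * exp(-k * t) else R0 + s * t
}

#' Simulate measured reporter traces from a phase schedule
#'
#' Integrates \eqn{dR/dt = s - k(t) R} analytically over each segment of
#' constant coefficients (phase intervals split at perturbation onsets),
#' samples the latent trajectory on a uniform frame grid, then applies the
#' measurement layer: a multiplicative mitotic intensity spike on M frames
#' and multiplicative lognormal noise with the configured CV.
#'
#' Perturbation semantics: from `t_on + lag_h` onward `s` is multiplied by
#' `s_factor`, every phase `k` by `k_factor`, and a non-NA `phase_to`
#' overrides the scheduled phase. Several active perturbations compose
#' multiplicatively; the most recent phase override wins.
#'
#' @param schedule Phase schedule tibble (may contain many cells).
#' @param params A [kinetic_params()] object.
#' @param perturbations Optional tibble of [perturbation()] rows, applied
#'   to every cell.
#' @param seed Integer seed for the measurement noise.
#' @param dt Frame interval in hours (default 0.2 h, i.e. 12 min).
#' @return Tibble with one row per cell and frame: `cell_id`, `frame`,
#'   `time_h`, `latent` (noiseless, artifact-free), `intensity`
#'   (measured), `phase`, `is_mitosis`.
#' @export
#' @examples
#' sched <- simulate_phase_schedule(1, duration = 20, seed = 1)
#' tr <- simulate_reporter_trace(sched, kinetic_params(noise_cv = 0))
#' head(tr)
simulate_reporter_trace <- function(schedule, params,
                                    perturbations = NULL, seed = 1,
                                    dt = 0.2) {
  stopifnot(inherits(params, "kinetic_params"))
  if (!is.null(perturbations)) {
    t_max <- max(schedule$end_h)
    if (any(perturbations$t_on < 0 | perturbations$t_on > t_max))
      abort("perturbation `t_on` outside the simulated window.")
  }
  set.seed(seed)
  cells <- split(schedule, schedule$cell_id)
  out <- map(cells, function(sc) {
    sc <- arrange(sc, .data$start_h)
    t_end <- max(sc$end_h)
    times <- seq(0, t_end, by = dt)
    n <- length(times)

    # phase per frame: interval with start <= t < end; last frame -> last
    idx <- findInterval(times, sc$start_h)
    idx[idx < 1L] <- 1L
    phase <- sc$phase[idx]

    # perturbation state per frame
    s_fac <- rep(1, n); k_fac <- rep(1, n)
    ph_override <- rep(NA_character_, n)
    if (!is.null(perturbations) && nrow(perturbations) > 0) {
      pt <- arrange(perturbations, .data$t_on + .data$lag_h)
      for (i in seq_len(nrow(pt))) {
        eff <- pt$t_on[i] + pt$lag_h[i]
        on <- times >= eff - 1e-9
        s_fac[on] <- s_fac[on] * pt$s_factor[i]
        k_fac[on] <- k_fac[on] * pt$k_factor[i]
        if (!is.na(pt$phase_to[i])) ph_override[on] <- pt$phase_to[i]
      }
    }
    phase_eff <- ifelse(is.na(ph_override), phase, ph_override)

    # piecewise-analytic propagation: coefficients are constant between
    # consecutive frames except where a switch falls off-grid, which we
    # handle by splitting the step at every segment boundary.
    bounds <- sort(unique(c(
      0, t_end, sc$start_h, sc$end_h,
      if (!is.null(perturbations) && nrow(perturbations) > 0)
        perturbations$t_on + perturbations$lag_h)))
    bounds <- bounds[bounds >= 0 & bounds <= t_end]
    coef_at <- function(t) {
      # evaluate effective (s, k) for the segment starting at t
      i <- findInterval(t + 1e-9, sc$start_h)
      i <- max(min(i, nrow(sc)), 1L)
      ph <- sc$phase[i]
      sf <- 1; kf <- 1; po <- NA_character_
      if (!is.null(perturbations) && nrow(perturbations) > 0) {
        act <- perturbations$t_on + perturbations$lag_h <= t + 1e-9
        if (any(act)) {
          sf <- prod(perturbations$s_factor[act])
          kf <- prod(perturbations$k_factor[act])
          ov <- perturbations$phase_to[act]
          ov <- ov[!is.na(ov)]
          if (length(ov)) po <- ov[length(ov)]
        }
      }
      if (!is.na(po)) ph <- po
      c(s = params$s * sf, k = params$k_by_phase[[ph]] * kf)
    }
    seg_R <- numeric(length(bounds))
    seg_R[1] <- params$R0
    for (i in seq_len(length(bounds) - 1L)) {
      ck <- coef_at(bounds[i])
      seg_R[i + 1L] <- ode_step(seg_R[i], ck[["s"]], ck[["k"]],
                                bounds[i + 1L] - bounds[i])
    }
    seg_idx <- findInterval(times + 1e-9, bounds)
    seg_idx <- pmin(seg_idx, length(bounds) - 1L)
    latent <- vapply(seq_len(n), function(j) {
      i <- seg_idx[j]
      ck <- coef_at(bounds[i])
      ode_step(seg_R[i], ck[["s"]], ck[["k"]], times[j] - bounds[i])
    }, numeric(1))

    is_m <- phase_eff == "M"
    meas <- latent * ifelse(is_m, params$mitotic_spike, 1)
    if (params$noise_cv > 0) {
      sdlog <- sqrt(log1p(params$noise_cv^2))
      meas <- meas * rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    }
    tibble(cell_id = sc$cell_id[1], frame = seq_len(n), time_h = times,
           latent = latent, intensity = meas, phase = phase_eff,
           is_mitosis = is_m)
  })
  list_rbind(out)
}

#' Simulate a cycloheximide-chase cohort
#'
#' Convenience wrapper for half-life experiments: cells sit in a single
#' phase with decay constant `k`, synthesis is shut off at `t = 0`
#' (cycloheximide), and the measured decay is sampled every `dt` hours for
#' `duration` hours with multiplicative noise.
#'
#' @param n_cells Number of cells.
#' @param k Decay constant (1/h) during the chase.
#' @param duration Chase length in hours.
#' @param R0 Reporter level at the start of the chase (a.u.).
#' @param noise_cv Measurement noise CV.
#' @param dt Frame interval (h).
#' @param seed Integer seed.
#' @return Trace tibble as from [simulate_reporter_trace()].
#' @export
simulate_chx_chase <- function(n_cells, k, duration = 8, R0 = 1000,
                               noise_cv = 0.05, dt = 0.2, seed = 1) {
  sched <- list_rbind(map(seq_len(n_cells), function(i)
    tibble(cell_id = sprintf("cell_%04d", i), start_h = 0,
           end_h = duration, phase = "G1")))
  pars <- kinetic_params(
    s = 10, k_by_phase = c(G0 = k, G1 = k, S = k, G2 = k, M = k),
    mitotic_spike = 1, noise_cv = noise_cv, R0 = R0)
  simulate_reporter_trace(sched, pars,
                          perturbations = perturbation("CHX", t_on = 0),
                          seed = seed, dt = dt)
}
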