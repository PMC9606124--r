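# Trace kinetics: from reporter intensity to degradation activity ------
#
# The central identity: with a constant synthesis rate s, the reporter
# obeys dR/dt = s - A(t) where A is the degradation flux driven by the
# ligase. Hence A = s - dR/dt, computable per frame once s has been
# measured in a neddylation-inhibitor (MLN-4924) arm where degradation is
# shut off and the trace slope equals s.

#' Annotate cell-cycle phases from the Geminin channel
#'
#' Mitotic frames come from tracking (`is_mitosis`). Between mitoses the
#' cell is G1 until Geminin onset and "S/G2" afterwards. Onset is the
#' first frame where Geminin exceeds
#' `baseline + onset_frac * (max - baseline)` (baseline and max taken
#' within the inter-mitotic segment) and keeps rising for at least
#' `persist` frames. Traces ending before onset stay G1 and are flagged
#' incomplete.
#'
#' @param traces Reporter trace tibble with `cell_id`, `frame`,
#'   `is_mitosis`.
#' @param geminin Geminin trace tibble on the same frame grid (`cell_id`,
#'   `frame`, `intensity`).
#' @param onset_frac Fraction of the Geminin dynamic range defining onset
#'   (default 0.2).
#' @param persist Number of consecutive rising frames required (default 3).
#' @return `traces` with columns `phase` (G1, S/G2 or M) and
#'   `phase_incomplete` (TRUE when no onset was observed before the trace
#'   or segment ended).
#' @export
annotate_phases <- function(traces, geminin, onset_frac = 0.2,
                            persist = 3) {
  gem <- select(geminin, "cell_id", "frame", gem = "intensity")
  joined <- left_join(traces, gem, by = c("cell_id", "frame"))
  if (anyNA(joined$gem))
    abort("geminin trace does not cover the reporter frame grid.")
  ann <- joined |>
    group_by(.data$cell_id) |>
    group_modify(function(df, key) {
      df <- arrange(df, .data$frame)
      n <- nrow(df)
      phase <- rep("G1", n)
      phase[df$is_mitosis] <- "M"
      incomplete <- rep(FALSE, n)
      # inter-mitotic segments: split on mitosis runs
      seg_id <- cumsum(df$is_mitosis &
                       !dplyr::lag(df$is_mitosis, default = FALSE))
      for (sid in unique(seg_id)) {
        in_seg <- seg_id == sid & !df$is_mitosis
        if (!any(in_seg)) next
        g <- df$gem[in_seg]
        rng <- max(g) - min(g)
        onset <- NA_integer_
        if (rng > 0) {
          thr <- min(g) + onset_frac * rng
          for (j in seq_along(g)) {
            if (g[j] > thr && j + persist - 1L <= length(g) &&
                all(diff(g[j:(j + persist - 1L)]) > 0)) {
              onset <- j; break
            }
          }
        }
        idx <- which(in_seg)
        if (is.na(onset)) {
          incomplete[idx] <- TRUE
        } else if (onset < length(idx)) {
          phase[idx[onset:length(idx)]] <- "S/G2"
        }
      }
      df$phase <- phase
      df$phase_incomplete <- incomplete
      df
    }) |>
    ungroup()
  select(ann, -"gem")
}

#' Mask mitotic frames and a guard margin around them
#'
#' The apparent intensity spike at mitosis is a geometric artifact of
#' cell rounding, not biochemistry; derivative-based inference must skip
#' it. Flags every mitotic frame plus `margin` frames on each side.
#'
#' @param traces Trace tibble with `cell_id`, `frame`, `is_mitosis`.
#' @param margin Frames masked on each side of a mitotic frame
#'   (default 2, i.e. 24 min at 12-min cadence).
#' @return `traces` with a logical `masked` column.
#' @export
mask_mitotic_frames <- function(traces, margin = 2) {
  traces |>
    group_by(.data$cell_id) |>
    group_modify(function(df, key) {
      df <- arrange(df, .data$frame)
      m <- which(df$is_mitosis)
      masked <- rep(FALSE, nrow(df))
      for (i in m)
        masked[max(1, i - margin):min(nrow(df), i + margin)] <- TRUE
      df$masked <- masked
      df
    }) |>
    ungroup()
}

#' Estimate the reporter synthesis rate from an MLN-4924 arm
#'
#' After complete degradation inhibition the trace rises linearly at the
#' synthesis rate. Fits a least-squares line per cell over the window and
#' reports the population synthesis rate as the median slope. Residual
#' degradation (incomplete inhibition) bends the rise; it is flagged when
#' the median late-half slope falls below `0.9 x` the early-half slope.
#'
#' @param traces Traces from cells treated with MLN-4924.
#' @param window_h `c(start, end)` of the fit window in hours (absolute
#'   trace time); should begin after the drug takes effect.
#' @param min_frames Minimum frames per cell (default 3).
#' @return Object of class `synthesis_fit`: `s` (median slope, a.u./h),
#'   `slopes` (per-cell tibble), `residual_k_flag`.
#' @export
estimate_synthesis_rate <- function(traces, window_h, min_frames = 3) {
  stopifnot(length(window_h) == 2, window_h[2] > window_h[1])
  if (!"masked" %in% names(traces)) traces$masked <- FALSE
  win <- filter(traces, .data$time_h >= window_h[1],
                .data$time_h <= window_h[2], !.data$masked)
  mid <- mean(window_h)
  per_cell <- win |>
    group_by(.data$cell_id) |>
    group_modify(function(df, key) {
      if (nrow(df) < min_frames)
        abort("fit window shorter than `min_frames` frames.")
      fit <- lm(intensity ~ time_h, data = df)
      early <- df[df$time_h <= mid, ]
      late <- df[df$time_h > mid, ]
      half_slope <- function(d)
        if (nrow(d) >= 2) unname(coef(lm(intensity ~ time_h, d))[2])
        else NA_real_
      tibble(slope = unname(coef(fit)[2]), n = nrow(df),
             slope_early = half_slope(early), slope_late = half_slope(late))
    }) |>
    ungroup()
  flag <- isTRUE(median(per_cell$slope_late, na.rm = TRUE) <
                 0.9 * median(per_cell$slope_early, na.rm = TRUE))
  structure(list(s = median(per_cell$slope), slopes = per_cell,
                 residual_k_flag = flag, window_h = window_h),
            class = "synthesis_fit")
}

#' @export
print.synthesis_fit <- function(x, ...) {
  cat("<synthesis_fit> s =", signif(x$s, 4), "a.u./h over",
      nrow(x$slopes), "cells",
      if (x$residual_k_flag) "(residual degradation flagged)" else "", "\n")
  invisible(x)
}

# Centered local linear slope over a window of `width` frames, skipping
# masked points; NA where fewer than 2 usable points.
local_slope <- function(t, y, masked, width) {
  n <- length(t)
  h <- (width - 1L) %/% 2L
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (masked[i]) next
    j <- max(1L, i - h):min(n, i + h)
    j <- j[!masked[j] & is.finite(y[j])]
    if (length(j) < 2L) next
    tt <- t[j] - mean(t[j])
    out[i] <- sum(tt * y[j]) / sum(tt^2)
  }
  out
}

#' Compute degradation activity as synthesis minus the trace derivative
#'
#' The first derivative of the reporter is estimated by a centered local
#' linear fit over `window` frames; the activity (degradation flux) is
#' `A = s - dR/dt`, positive when the ligase is actively degrading the
#' reporter. The specific rate `k_specific = A / R` is also reported,
#' since the flux depends on the reporter level. Masked frames propagate
#' as `NA`.
#'
#' @param traces Trace tibble (run [mask_mitotic_frames()] first when the
#'   data contain mitoses).
#' @param s Synthesis rate (a.u./h), e.g. from
#'   [estimate_synthesis_rate()].
#' @param window Derivative window in frames (odd; default 5, i.e. 1 h).
#' @param eps Reporter level below which `k_specific` is undefined.
#' @return `traces` with columns `dRdt`, `A`, `k_specific`, and `s_used`.
#' @export
compute_activity <- function(traces, s, window = 5, eps = 1e-8) {
  if (s < 0) abort("`s` must be >= 0.")
  if (!"masked" %in% names(traces)) traces$masked <- FALSE
  out <- traces |>
    group_by(.data$cell_id) |>
    group_modify(function(df, key) {
      df <- arrange(df, .data$frame)
      if (sum(!df$masked) < window)
        abort("fewer unmasked frames than the smoothing window.")
      df$dRdt <- local_slope(df$time_h, df$intensity, df$masked, window)
      df$A <- s - df$dRdt
      df$k_specific <- ifelse(df$intensity > eps, df$A / df$intensity,
                              NA_real_)
      df
    }) |>
    ungroup()
  out$s_used <- s
  out
}

#' Fit a first-order half-life to a cycloheximide chase
#'
#' Log-linear least squares of `ln R` against time over the window; with
#' multiplicative measurement noise the log transform is
#' variance-stabilising, so ordinary least squares on the log scale is
#' the natural estimator. `t_half = ln(2) / k_fit`. A non-positive decay
#' estimate is reported as `no_decay` with an infinite half-life rather
#' than an error.
#'
#' @param traces Trace tibble (one or many cells); masked frames are
#'   skipped when a `masked` column is present.
#' @param window_h Optional `c(start, end)` fit window in hours; default
#'   spans the whole trace.
#' @param min_frames Minimum usable frames per cell (default 5).
#' @param max_nonpos_frac Maximum tolerated fraction of non-positive
#'   intensities (dropped before fitting); beyond it the fit errors.
#' @return Tibble with one row per cell: `cell_id`, `k_fit` (1/h),
#'   `t_half` (h), `r_squared`, `n_frames`, `no_decay`.
#' @export
estimate_half_life <- function(traces, window_h = NULL, min_frames = 5,
                               max_nonpos_frac = 0.2) {
  if (!"masked" %in% names(traces)) traces$masked <- FALSE
  traces |>
    group_by(.data$cell_id) |>
    group_modify(function(df, key) {
      df <- arrange(df, .data$frame)
      if (!is.null(window_h))
        df <- filter(df, .data$time_h >= window_h[1],
                     .data$time_h <= window_h[2])
      df <- filter(df, !.data$masked)
      nonpos <- df$intensity <= 0
      if (mean(nonpos) > max_nonpos_frac)
        abort("too many non-positive intensities in the fit window.")
      df <- df[!nonpos, ]
      if (nrow(df) < min_frames)
        abort("fewer than `min_frames` usable frames.")
      fit <- lm(log(intensity) ~ time_h, data = df)
      k <- -unname(coef(fit)[2])
      tss <- sum((log(df$intensity) - mean(log(df$intensity)))^2)
      r2 <- if (tss > 0) 1 - sum(resid(fit)^2) / tss else 1
      if (k <= 0)
        tibble(k_fit = k, t_half = Inf, r_squared = r2,
               n_frames = nrow(df), no_decay = TRUE)
      else
        tibble(k_fit = k, t_half = log(2) / k, r_squared = r2,
               n_frames = nrow(df), no_decay = FALSE)
    }) |>
    ungroup()
}

#' Align traces to the time of mitosis
#'
#' Re-indexes each cell's trace so that its anchor mitosis sits at
#' relative time 0 and summarises the cohort by the per-timepoint median
#' where at least `min_count` cells contribute. Cells without a mitosis
#' are excluded (and counted in the result).
#'
#' @param traces Trace tibble with `is_mitosis`; any value column works.
#' @param value Name of the column to align (default "intensity").
#' @param anchor Which mitosis anchors each cell: "first" or "last".
#' @param window_h `c(-before, +after)` window in relative hours.
#' @param min_count Minimum cells per timepoint for the median.
#' @return Object of class `aligned_traces`: `data` (tibble `cell_id`,
#'   `rel_time_h`, `value`), `summary` (tibble `rel_time_h`, `median`,
#'   `n`), `n_cells`, `n_excluded`.
#' @export
align_to_mitosis <- function(traces, value = "intensity",
                             anchor = c("first", "last"),
                             window_h = c(-10, 10), min_count = 1) {
  anchor <- match.arg(anchor)
  if (!value %in% names(traces)) abort("`value` column not found.")
  cells <- split(traces, traces$cell_id)
  aligned <- list(); excluded <- 0L
  for (df in cells) {
    df <- arrange(df, .data$frame)
    m <- which(df$is_mitosis)
    if (!length(m)) { excluded <- excluded + 1L; next }
    # anchor at the first frame of the chosen mitosis run
    runs <- m[c(TRUE, diff(m) > 1)]
    a <- if (anchor == "first") runs[1] else runs[length(runs)]
    rel <- df$time_h - df$time_h[a]
    keep <- rel >= window_h[1] & rel <= window_h[2]
    aligned[[length(aligned) + 1L]] <- tibble(
      cell_id = df$cell_id[1], rel_time_h = round(rel[keep], 6),
      value = df[[value]][keep])
  }
  if (!length(aligned))
    abort("no traces carry a mitosis to align to.")
  data <- list_rbind(aligned)
  summary <- data |>
    summarise(median = median(.data$value, na.rm = TRUE),
              n = sum(!is.na(.data$value)), .by = "rel_time_h") |>
    arrange(.data$rel_time_h) |>
    mutate(median = ifelse(.data$n >= min_count, .data$median, NA_real_))
  structure(list(data = data, summary = summary,
                 n_cells = length(aligned), n_excluded = excluded),
            class = "aligned_traces")
}

#' @export
print.aligned_traces <- function(x, ...) {
  cat("<aligned_traces>", x$n_cells, "cells aligned,",
      x$n_excluded, "excluded (no mitosis)\n")
  invisible(x)
}
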