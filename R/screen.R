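# 1536-well luminescent screen analytics --------------------------------

#' Build a 1536-well plate layout with control columns
#'
#' 32 rows x 48 columns. Column 1 holds the neutral controls (cells +
#' DMSO), column 2 the negative controls (media only); the remaining
#' wells carry compounds at a single concentration.
#'
#' @param compounds Character vector of compound ids; recycled row-major
#'   over the available wells, `NA`-padded if shorter.
#' @param conc_uM Screening concentration (default 13).
#' @param n_neutral,n_negative Number of control wells (default 32 each).
#' @return Tibble `row`, `col`, `role`, `compound_id`, `conc_uM`.
#' @export
plate_layout_1536 <- function(compounds = NULL, conc_uM = 13,
                              n_neutral = 32, n_negative = 32) {
  grid <- tidyr::expand_grid(row = 1:32, col = 1:48)
  grid$role <- "compound"
  grid$role[grid$col == 1][seq_len(n_neutral)] <- "neutral"
  grid$role[grid$col == 2][seq_len(n_negative)] <- "negative"
  ncomp <- sum(grid$role == "compound")
  if (is.null(compounds)) compounds <- sprintf("C%04d", seq_len(ncomp))
  ids <- rep(NA_character_, ncomp)
  ids[seq_len(min(ncomp, length(compounds)))] <-
    compounds[seq_len(min(ncomp, length(compounds)))]
  grid$compound_id <- NA_character_
  grid$compound_id[grid$role == "compound"] <- ids
  grid$conc_uM <- ifelse(grid$role == "compound", conc_uM, NA_real_)
  grid
}

#' Simulate a luminescent reporter screening plate
#'
#' Each compound well's luminescence is the reporter level after
#' `read_time` hours of treatment under that compound's synthesis/decay
#' modifiers, obtained from the closed-form solution of
#' \eqn{dR/dt = s \cdot f_s - k \cdot f_k \cdot R} starting from the
#' untreated steady state \eqn{R_0 = s/k}. Wells are scaled by a gain
#' chosen so the neutral median is ~1000 a.u. over a baseline; negative
#' (media-only) wells emit baseline only. Noise is multiplicative
#' lognormal.
#'
#' @param layout Layout tibble from [plate_layout_1536()].
#' @param effect_table Tibble `compound_id`, `s_factor`, `k_factor`;
#'   compounds absent from it are effect-free. Must not reference unknown
#'   compounds.
#' @param read_time Hours between treatment and the read (default 6).
#' @param noise_cv Multiplicative noise CV.
#' @param s,k Baseline synthesis rate (a.u./h) and decay constant (1/h).
#' @param baseline Instrument baseline luminescence (a.u.).
#' @param target_neutral Noiseless neutral-well luminescence used to set
#'   the gain (default 1000).
#' @param plate_id Plate identifier.
#' @param seed Integer seed.
#' @return Tibble `plate_id`, `row`, `col`, `role`, `compound_id`,
#'   `conc_uM`, `lum`.
#' @export
simulate_screen_plate <- function(layout, effect_table = NULL,
                                  read_time = 6, noise_cv = 0.05,
                                  s = 10, k = 0.2521, baseline = 50,
                                  target_neutral = 1000,
                                  plate_id = "plate_01", seed = 1) {
  if (!any(layout$role == "neutral") || !any(layout$role == "negative"))
    abort("layout needs at least one neutral and one negative well.")
  if (!is.null(effect_table)) {
    unknown <- setdiff(effect_table$compound_id,
                       layout$compound_id[!is.na(layout$compound_id)])
    if (length(unknown))
      abort("effect table references compounds not on the plate.")
  }
  set.seed(seed)
  R0 <- s / k
  gain <- (target_neutral - baseline) / R0  # neutral R(read) = R0
  wells <- layout
  wells$s_factor <- 1; wells$k_factor <- 1
  if (!is.null(effect_table)) {
    m <- match(wells$compound_id, effect_table$compound_id)
    hit <- !is.na(m)
    wells$s_factor[hit] <- effect_table$s_factor[m[hit]]
    wells$k_factor[hit] <- effect_table$k_factor[m[hit]]
  }
  R_read <- mapply(function(sf, kf)
    ode_step(R0, s * sf, k * kf, read_time),
    wells$s_factor, wells$k_factor)
  lum <- ifelse(wells$role == "negative", baseline,
                gain * R_read + baseline)
  if (noise_cv > 0) {
    sdlog <- sqrt(log1p(noise_cv^2))
    lum <- lum * rlnorm(length(lum), -sdlog^2 / 2, sdlog)
  }
  tibble(plate_id = plate_id, row = wells$row, col = wells$col,
         role = wells$role, compound_id = wells$compound_id,
         conc_uM = wells$conc_uM, lum = lum)
}

#' Normalize plate luminescence to percent activity
#'
#' Per plate, with `med_n` the neutral-control median and `med_neg` the
#' negative-control median:
#' \deqn{PA = 100 (lum - med_n) / (med_n - med_{neg})}
#' so a well at the neutral median scores 0% and one at the negative
#' median scores -100%. Positive PA (luminescence above neutral) means
#' reporter accumulation, i.e. ligase inhibition; negative PA means
#' activation.
#'
#' @param plate Plate tibble with `plate_id`, `role`, `lum` (and compound
#'   annotation columns, carried through).
#' @return Tibble of compound wells with a `pa` column plus per-plate
#'   control medians.
#' @export
normalize_plate <- function(plate) {
  plate |>
    group_by(.data$plate_id) |>
    group_modify(function(df, key) {
      med_n <- median(df$lum[df$role == "neutral"])
      med_neg <- median(df$lum[df$role == "negative"])
      if (!is.finite(med_n) || !is.finite(med_neg))
        abort("control wells missing or non-finite.")
      if (med_n == med_neg)
        abort("degenerate controls: neutral and negative medians equal.")
      df |>
        filter(.data$role == "compound") |>
        mutate(pa = 100 * (.data$lum - med_n) / (med_n - med_neg),
               med_neutral = med_n, med_negative = med_neg)
    }) |>
    ungroup()
}

#' Call screening hits from percent activity
#'
#' Strictly-greater comparison against the threshold in both directions:
#' `pa > threshold` flags an inhibitor (reporter accumulated),
#' `pa < -threshold` an activator (reporter degraded).
#'
#' @param pa_table Output of [normalize_plate()].
#' @param threshold Percent-activity threshold (default 50).
#' @return `pa_table` with a `hit` column in {"inhibitor", "activator",
#'   "none"}.
#' @export
call_hits <- function(pa_table, threshold = 50) {
  if (!nrow(pa_table)) abort("empty percent-activity table.")
  mutate(pa_table, hit = case_when(
    .data$pa > threshold ~ "inhibitor",
    .data$pa < -threshold ~ "activator",
    TRUE ~ "none"))
}

#' Generate an 11-point 1:3 dilution series
#'
#' @param top_uM Top dose (default 13).
#' @param points Number of doses (default 11).
#' @param dilution Dilution factor (default 3).
#' @return Numeric vector, strictly decreasing.
#' @export
dose_series <- function(top_uM = 13, points = 11, dilution = 3) {
  top_uM / dilution^(seq_len(points) - 1)
}

fourpl <- function(dose, bottom, top, ic50, hill)
  bottom + (top - bottom) / (1 + (dose / ic50)^hill)

#' Fit a four-parameter logistic dose-response curve
#'
#' Model: `response = bottom + (top - bottom) / (1 + (dose/ic50)^hill)`.
#' Fitted by Levenberg-Marquardt nonlinear least squares
#' (minpack.lm) from a grid of starting values (IC50 spread
#' geometrically across the dose range, Hill slopes of both signs); the
#' best converged start wins. Non-convergence is reported, never silently
#' replaced by a default. Fit classes: `converged`, `flat` (no dose
#' dependence), `incomplete` (IC50 outside `[min dose/10, max dose*10]`),
#' `non-converged`.
#'
#' @param data Data frame with dose and response columns.
#' @param dose,response Column names (default "dose", "response").
#' @param min_doses Minimum distinct doses required (default 5).
#' @param flat_tol Response range (in response units) below which the
#'   curve is declared flat.
#' @return Object of class `dose_response_fit` with elements `bottom`,
#'   `top`, `ic50`, `hill`, `converged`, `fit_class`, `rss`, `data`,
#'   `fitted`, `residuals`.
#' @export
#' @examples
#' d <- data.frame(dose = dose_series(), response = NA)
#' d$response <- 100 / (1 + (d$dose / 1)^1)
#' fit_dose_response(d)
fit_dose_response <- function(data, dose = "dose", response = "response",
                              min_doses = 5, flat_tol = 1e-6) {
  doses <- data[[dose]]; resp <- data[[response]]
  ok <- is.finite(doses) & is.finite(resp) & doses > 0
  doses <- doses[ok]; resp <- resp[ok]
  if (length(unique(doses)) < min_doses)
    abort("need at least `min_doses` distinct positive doses.")
  out <- list(bottom = NA_real_, top = NA_real_, ic50 = NA_real_,
              hill = NA_real_, converged = FALSE, fit_class = "flat",
              rss = NA_real_,
              data = tibble(dose = doses, response = resp),
              fitted = rep(NA_real_, length(doses)),
              residuals = rep(NA_real_, length(doses)))
  rng <- diff(range(resp))
  if (rng <= max(flat_tol, 1e-9 * max(abs(resp), 1))) {
    return(structure(out, class = "dose_response_fit"))
  }
  ic50_grid <- exp(seq(log(min(doses)), log(max(doses)), length.out = 5))
  hill_grid <- c(-3, -1.5, -0.7, 0.7, 1.5, 3)
  best <- NULL
  df <- data.frame(dose = doses, response = resp)
  for (ic in ic50_grid) for (hl in hill_grid) {
    fit <- try(suppressWarnings(minpack.lm::nlsLM(
      response ~ bottom + (top - bottom) / (1 + (dose / ic50)^hill),
      data = df,
      start = list(bottom = min(resp), top = max(resp),
                   ic50 = ic, hill = hl),
      lower = c(-Inf, -Inf, min(doses) / 1e4, -20),
      upper = c(Inf, Inf, max(doses) * 1e4, 20),
      control = minpack.lm::nls.lm.control(maxiter = 200))),
      silent = TRUE)
    if (inherits(fit, "try-error")) next
    rss <- sum(resid(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) {
    out$fit_class <- "non-converged"
    return(structure(out, class = "dose_response_fit"))
  }
  cf <- coef(best$fit)
  out$bottom <- unname(cf["bottom"]); out$top <- unname(cf["top"])
  out$ic50 <- unname(cf["ic50"]); out$hill <- unname(cf["hill"])
  out$rss <- best$rss
  out$fitted <- fitted(best$fit)
  out$residuals <- resid(best$fit)
  out$converged <- TRUE
  out$fit_class <- if (out$ic50 < min(doses) / 10 ||
                       out$ic50 > max(doses) * 10) "incomplete"
                   else "converged"
  structure(out, class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat("<dose_response_fit>", x$fit_class, "\n")
  if (x$converged)
    cat("  IC50 =", signif(x$ic50, 4), "uM, hill =", signif(x$hill, 3),
        ", bottom =", signif(x$bottom, 3), ", top =", signif(x$top, 3),
        "\n")
  invisible(x)
}

#' Reporter-selectivity counter-screen filter
#'
#' A compound is selective when it moves the target reporter beyond the
#' hit threshold while leaving both counter-screen reporters (a
#' degron-mutant version of the target reporter and a related-ligase
#' reporter) within `margin` percent activity of zero (strict
#' comparisons). Pan-degradation compounds (all three reporters shifted,
#' cycloheximide-like) fail the filter.
#'
#' @param data Data frame with one row per compound.
#' @param target,mutant,offtarget Names of the percent-activity columns
#'   for the target reporter, the degron-mutant reporter and the
#'   related-ligase reporter.
#' @param threshold Hit threshold on the target reporter (default 50).
#' @param margin Counter-screen tolerance (default 20).
#' @return `data` with columns `selective` (logical, `NA` when a
#'   counter-screen value is missing) and `selectivity_status`.
#' @export
selectivity_filter <- function(data, target = "pa_target",
                               mutant = "pa_mutant",
                               offtarget = "pa_offtarget",
                               threshold = 50, margin = 20) {
  pt <- data[[target]]; pm <- data[[mutant]]; po <- data[[offtarget]]
  status <- dplyr::case_when(
    is.na(pm) | is.na(po) ~ "incomplete",
    !(abs(pt) > threshold) ~ "below-threshold",
    abs(pm) < margin & abs(po) < margin ~ "selective",
    TRUE ~ "non-selective")
  data$selective <- ifelse(status == "incomplete", NA,
                           status == "selective")
  data$selectivity_status <- status
  data
}
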