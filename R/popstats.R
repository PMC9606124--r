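# Population statistics: live/fixed matching, correlations, folds ------

#' Simulate paired live-imaging and fixed-staining single-cell data
#'
#' Draws per-cell (activity, protein) pairs from a bivariate normal
#' latent with correlation `rho_true`, places cells uniformly in a field,
#' and jitters the fixed-cell centroids to exercise live-to-fixed
#' matching.
#'
#' @param n_cells Number of cells (>= 3).
#' @param rho_true Target latent correlation, in [-1, 1].
#' @param activity_mean,activity_sd Marginal of inferred activity
#'   (a.u./h).
#' @param protein_mean,protein_sd Marginal of immunofluorescence protein
#'   level (a.u.).
#' @param jitter_px Maximum centroid displacement between live and fixed
#'   coordinates (pixels).
#' @param field_dim Field size `c(rows, cols)` in pixels.
#' @param seed Integer seed.
#' @return Tibble `cell_id`, `activity`, `protein_level`, `live_row`,
#'   `live_col`, `fixed_row`, `fixed_col`.
#' @export
simulate_live_fixed_pairs <- function(n_cells, rho_true = 0,
                                      activity_mean = 5,
                                      activity_sd = 1.5,
                                      protein_mean = 100,
                                      protein_sd = 20,
                                      jitter_px = 2,
                                      field_dim = c(2048, 2048),
                                      seed = 1) {
  if (abs(rho_true) > 1) abort("`rho_true` must lie in [-1, 1].")
  if (n_cells < 3) abort("need at least 3 cells.")
  set.seed(seed)
  z1 <- rnorm(n_cells); z2 <- rnorm(n_cells)
  act <- activity_mean + activity_sd * z1
  prot <- protein_mean + protein_sd *
    (rho_true * z1 + sqrt(1 - rho_true^2) * z2)
  r <- runif(n_cells, 1, field_dim[1])
  c <- runif(n_cells, 1, field_dim[2])
  ang <- runif(n_cells, 0, 2 * pi)
  rad <- runif(n_cells, 0, jitter_px)
  tibble(cell_id = sprintf("cell_%05d", seq_len(n_cells)),
         activity = act, protein_level = prot,
         live_row = r, live_col = c,
         fixed_row = r + rad * sin(ang), fixed_col = c + rad * cos(ang))
}

#' Match live-imaged cells to fixed-stained cells by position
#'
#' Globally greedy one-to-one matching: candidate (live, fixed) pairs are
#' accepted in order of increasing centroid distance, each cell used at
#' most once, pairs beyond `cap` pixels rejected.
#'
#' @param live Tibble with `row`, `col` and an id column (first column).
#' @param fixed Same structure for the fixed dataset.
#' @param cap Maximum match distance in pixels.
#' @return Tibble with one row per live cell: `live_id`, `fixed_id`
#'   (`NA` when unmatched), `match_distance`.
#' @export
match_live_to_fixed <- function(live, fixed, cap = 5) {
  if (!nrow(live)) abort("`live` centroid set is empty.")
  out <- tibble(live_id = live[[1]], fixed_id = NA_character_,
                match_distance = NA_real_)
  if (!nrow(fixed)) return(out)
  dmat <- sqrt(outer(live$row, fixed$row, "-")^2 +
               outer(live$col, fixed$col, "-")^2)
  used_l <- logical(nrow(live)); used_f <- logical(nrow(fixed))
  repeat {
    d2 <- dmat
    d2[used_l, ] <- Inf; d2[, used_f] <- Inf
    m <- which.min(d2)
    if (!length(m) || d2[m] > cap) break
    ij <- arrayInd(m, dim(d2))
    used_l[ij[1]] <- TRUE; used_f[ij[2]] <- TRUE
    out$fixed_id[ij[1]] <- as.character(fixed[[1]][ij[2]])
    out$match_distance[ij[1]] <- d2[m]
  }
  out
}

#' Correlate single-cell activity with protein level
#'
#' Spearman by default (robust to staining-intensity nonlinearity);
#' Pearson available. The 95% confidence interval comes from a seeded
#' percentile bootstrap over cells.
#'
#' @param pairs Data frame with `activity` and `protein_level` columns.
#' @param method "spearman" or "pearson".
#' @param n_boot Bootstrap resamples (default 2000).
#' @param conf Confidence level (default 0.95).
#' @param seed Integer seed for the bootstrap.
#' @return Object of class `correlation_result`: `rho`, `n`, `method`,
#'   `ci` (length-2), `pairs`.
#' @export
correlate_activity_protein <- function(pairs,
                                       method = c("spearman", "pearson"),
                                       n_boot = 2000, conf = 0.95,
                                       seed = 1) {
  method <- match.arg(method)
  x <- pairs$activity; y <- pairs$protein_level
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) abort("need at least 3 complete pairs.")
  if (sd(x) == 0 || sd(y) == 0)
    abort("zero-variance input: correlation undefined.")
  rho <- cor(x, y, method = method)
  set.seed(seed)
  boot <- vapply(seq_len(n_boot), function(i) {
    j <- sample.int(n, n, replace = TRUE)
    suppressWarnings(cor(x[j], y[j], method = method))
  }, numeric(1))
  alpha <- (1 - conf) / 2
  ci <- unname(quantile(boot, c(alpha, 1 - alpha), na.rm = TRUE))
  structure(list(rho = rho, n = n, method = method, ci = ci,
                 pairs = tibble(activity = x, protein_level = y)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat("<correlation_result>", x$method, "rho =", signif(x$rho, 3),
      sprintf("(95%% CI %.3f to %.3f), n = %d\n", x$ci[1], x$ci[2], x$n))
  invisible(x)
}

#' Fold difference in median activity between two populations
#'
#' @param group_a,group_b Numeric vectors of per-cell activities.
#' @param n_boot Bootstrap resamples for the CI (default 2000).
#' @param conf Confidence level.
#' @param seed Integer seed.
#' @return Object of class `fold_result`: `median_a`, `median_b`, `fold`
#'   (= median_a / median_b), `ci`.
#' @export
compare_activity_populations <- function(group_a, group_b,
                                         n_boot = 2000, conf = 0.95,
                                         seed = 1) {
  group_a <- group_a[is.finite(group_a)]
  group_b <- group_b[is.finite(group_b)]
  if (length(group_a) < 3 || length(group_b) < 3)
    abort("both groups need at least 3 cells.")
  mb <- median(group_b)
  if (mb <= 0) abort("median of `group_b` must be positive.")
  ma <- median(group_a)
  set.seed(seed)
  boot <- vapply(seq_len(n_boot), function(i) {
    median(sample(group_a, replace = TRUE)) /
      median(sample(group_b, replace = TRUE))
  }, numeric(1))
  alpha <- (1 - conf) / 2
  structure(list(median_a = ma, median_b = mb, fold = ma / mb,
                 ci = unname(quantile(boot, c(alpha, 1 - alpha)))),
            class = "fold_result")
}

#' @export
print.fold_result <- function(x, ...) {
  cat("<fold_result> fold =", signif(x$fold, 4),
      sprintf("(95%% CI %.3g to %.3g)\n", x$ci[1], x$ci[2]))
  invisible(x)
}

#' Fold shift between two fitted IC50s
#'
#' Ratio of the IC50s of two converged four-parameter logistic fits, with
#' a confidence interval from residual resampling: each curve is refit to
#' `fitted + resampled residuals` and the ratio recomputed.
#'
#' @param fit_a,fit_b Converged [fit_dose_response()] objects.
#' @param n_boot Resampling rounds (default 200).
#' @param conf Confidence level.
#' @param seed Integer seed.
#' @return Object of class `fold_result` with elements `fold`
#'   (= ic50_a / ic50_b), `ci`, `ic50_a`, `ic50_b`.
#' @export
ic50_fold_shift <- function(fit_a, fit_b, n_boot = 200, conf = 0.95,
                            seed = 1) {
  stopifnot(inherits(fit_a, "dose_response_fit"),
            inherits(fit_b, "dose_response_fit"))
  if (!fit_a$converged || !fit_b$converged)
    abort("both dose-response fits must have converged.")
  refit_ic50 <- function(fit) {
    d <- fit$data
    d$response <- fit$fitted + sample(fit$residuals, replace = TRUE)
    f <- try(fit_dose_response(d), silent = TRUE)
    if (inherits(f, "try-error") || !f$converged) NA_real_ else f$ic50
  }
  set.seed(seed)
  boot <- vapply(seq_len(n_boot), function(i)
    refit_ic50(fit_a) / refit_ic50(fit_b), numeric(1))
  alpha <- (1 - conf) / 2
  structure(list(fold = fit_a$ic50 / fit_b$ic50,
                 ic50_a = fit_a$ic50, ic50_b = fit_b$ic50,
                 median_a = fit_a$ic50, median_b = fit_b$ic50,
                 ci = unname(quantile(boot, c(alpha, 1 - alpha),
                                      na.rm = TRUE))),
            class = "fold_result")
}
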