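# phase annotation, activity inference, half-life fitting, alignment

# a trace with one mid-run mitosis (M from 4.0 to 4.6 h)
mitotic_trace <- function(noise_cv = 0, spike = 1.8, duration = 9,
                          k = 0.25, seed = 1) {
  sched <- tibble::tibble(cell_id = "c1",
                          start_h = c(0, 4, 4.6),
                          end_h = c(4, 4.6, duration),
                          phase = c("G1", "M", "G1"))
  simulate_reporter_trace(sched,
                          uniform_params(k = k, R0 = 40,
                                         noise_cv = noise_cv,
                                         spike = spike),
                          seed = seed)
}

test_that("flat geminin keeps every post-mitotic frame in G1", {
  tr <- mitotic_trace()
  gem <- dplyr::mutate(tr, intensity = 0)
  ann <- annotate_phases(tr, gem)
  expect_true(all(ann$phase[!ann$is_mitosis] == "G1"))
  expect_true(all(ann$phase_incomplete[!ann$is_mitosis]))
})

test_that("geminin onset matches a brute-force scan of the rule", {
  tr <- simulate_reporter_trace(flat_schedule(duration = 10),
                                uniform_params(R0 = 40))
  # synthetic geminin: flat baseline then a ramp from frame 26
  gem <- tr
  g <- rep(5, nrow(tr))
  ramp <- 26:nrow(tr)
  g[ramp] <- 5 + 2 * seq_along(ramp)
  gem$intensity <- g
  ann <- annotate_phases(tr, gem, onset_frac = 0.2, persist = 3)
  # oracle: scan the stated threshold rule directly
  thr <- min(g) + 0.2 * (max(g) - min(g))
  onset <- NA
  for (j in seq_along(g)) {
    if (g[j] > thr && j + 2 <= length(g) && all(diff(g[j:(j + 2)]) > 0)) {
      onset <- j
      break
    }
  }
  expect_false(is.na(onset))
  expect_equal(which(ann$phase == "S/G2")[1], onset)
  expect_true(all(ann$phase[seq_len(onset - 1)] == "G1"))
})

test_that("no masked frames without mitoses; margin arithmetic is exact", {
  tr <- simulate_reporter_trace(flat_schedule(duration = 10),
                                uniform_params(R0 = 40))
  expect_false(any(mask_mitotic_frames(tr)$masked))
  tr2 <- tr
  tr2$is_mitosis[40] <- TRUE
  m <- mask_mitotic_frames(tr2, margin = 2)
  expect_equal(which(m$masked), 38:42)
})

test_that("masking removes the mitotic-spike excursion from activity", {
  # steady-state trace: without the artifact, A = s identically
  tr <- mitotic_trace(noise_cv = 0, spike = 1.8)
  masked <- mask_mitotic_frames(tr, margin = 2)
  act <- compute_activity(masked, s = 10)
  a <- act$A[!act$masked & is.finite(act$A)]
  expect_lt(max(abs(a - 10)), 1e-6)
  # without masking the x1.8 spike injects large spurious excursions
  act0 <- compute_activity(tr, s = 10)
  expect_gt(max(abs(act0$A - 10), na.rm = TRUE), 10)
})

test_that("synthesis slope is exact on a noiseless inhibited trace", {
  tr <- simulate_reporter_trace(
    flat_schedule(duration = 8), uniform_params(s = 10, k = 0.25, R0 = 40),
    perturbation("MLN4924", t_on = 0))
  fit <- estimate_synthesis_rate(tr, window_h = c(0, 8))
  expect_equal(fit$s, 10, tolerance = 1e-9)
  expect_false(fit$residual_k_flag)
})

test_that("median synthesis slope is unbiased within 2% on noisy cells", {
  tr <- simulate_reporter_trace(
    flat_schedule(100, duration = 8),
    uniform_params(s = 10, k = 0.25, R0 = 40, noise_cv = 0.05),
    perturbation("MLN4924", t_on = 0), seed = 5)
  fit <- estimate_synthesis_rate(tr, window_h = c(0, 8))
  expect_equal(fit$s, 10, tolerance = 0.02)
})

test_that("residual degradation bends the rise and is flagged", {
  # incomplete inhibition: k scaled to 0.3 of baseline instead of 0
  tr <- simulate_reporter_trace(
    flat_schedule(duration = 12), uniform_params(s = 10, k = 0.5, R0 = 20),
    perturbation("MLN4924", t_on = 0, k_factor = 0.3))
  fit <- estimate_synthesis_rate(tr, window_h = c(0, 12))
  expect_lt(fit$s, 10)
  expect_true(fit$residual_k_flag)
})

test_that("activity equals s on a constant trace and 0 under full
          inhibition", {
  tr <- simulate_reporter_trace(flat_schedule(duration = 6),
                                uniform_params(s = 5, k = 0.125, R0 = 40))
  act <- compute_activity(tr, s = 5)
  expect_equal(act$A[is.finite(act$A)],
               rep(5, sum(is.finite(act$A))), tolerance = 1e-9)
  mln <- simulate_reporter_trace(
    flat_schedule(duration = 8), uniform_params(s = 10, k = 0.25, R0 = 40),
    perturbation("MLN4924", t_on = 0))
  a2 <- compute_activity(mln, s = 10)
  expect_lt(max(abs(a2$A), na.rm = TRUE), 1e-9)
})

test_that("activity obeys the identity A = k R within 1% discretization
          error", {
  for (k in c(0.077, 0.25, 0.5)) {
    tr <- simulate_reporter_trace(
      flat_schedule(duration = 20),
      uniform_params(s = 10, k = k, R0 = 20))
    act <- compute_activity(tr, s = 10)
    interior <- dplyr::filter(act, frame > 3, frame < dplyr::n() - 3,
                              is.finite(A))
    rel <- abs(interior$A - k * interior$latent) / (k * interior$latent)
    expect_lt(max(rel), 0.01)
  }
})

test_that("half-life fitting is exact on a clean exponential", {
  tr <- simulate_chx_chase(1, k = log(2) / 3, duration = 8, R0 = 1000,
                           noise_cv = 0)
  hl <- estimate_half_life(tr)
  expect_equal(hl$t_half, 3, tolerance = 1e-9)
  expect_equal(hl$r_squared, 1, tolerance = 1e-9)
  expect_false(hl$no_decay)
})

test_that("a constant trace is reported as no-decay", {
  tr <- simulate_reporter_trace(flat_schedule(duration = 6),
                                uniform_params(s = 10, k = 0.25, R0 = 40))
  hl <- estimate_half_life(tr)
  expect_true(hl$no_decay)
  expect_equal(hl$t_half, Inf)
})

test_that("half-life recovery holds within 5% across decay constants", {
  for (k in c(0.077, 0.25, 0.5)) {
    dur <- min(3 * log(2) / k, 24)
    tr <- simulate_chx_chase(50, k = k, duration = dur, R0 = 1000,
                             noise_cv = 0.05, seed = round(1000 * k))
    hl <- estimate_half_life(tr)
    expect_equal(median(hl$t_half), log(2) / k,
                 tolerance = 0.05 * log(2) / k)
  }
})

test_that("phase-dependent decay shows higher activity in G1 than S/G2", {
  sched <- purrr::map_dfr(1:100, function(i)
    tibble::tibble(cell_id = sprintf("c%03d", i),
                   start_h = c(0, 8), end_h = c(8, 20),
                   phase = c("G1", "S")))
  p <- kinetic_params(s = 10,
                      k_by_phase = c(G0 = 0.5, G1 = 0.2521, S = 0.077,
                                     G2 = 0.077, M = 0.2521),
                      mitotic_spike = 1, noise_cv = 0.05, R0 = 10 / 0.2521)
  tr <- simulate_reporter_trace(sched, p, seed = 9)
  act <- compute_activity(tr, s = 10)
  per_cell <- act |>
    dplyr::filter(is.finite(A)) |>
    dplyr::summarise(g1 = median(A[phase == "G1"]),
                     sg2 = median(A[phase == "S"]),
                     .by = cell_id)
  # sign test: G1 activity exceeds S/G2 activity in nearly every cell
  n_pos <- sum(per_cell$g1 > per_cell$sg2)
  pval <- binom.test(n_pos, nrow(per_cell), 0.5,
                     alternative = "greater")$p.value
  expect_lt(pval, 0.01)
})

test_that("post-inhibition activity settles at zero within noise", {
  tr <- simulate_reporter_trace(
    flat_schedule(50, duration = 10),
    uniform_params(s = 10, k = 0.25, R0 = 40, noise_cv = 0.05),
    perturbation("MLN4924", t_on = 2), seed = 21)
  act <- compute_activity(tr, s = 10)
  post <- dplyr::filter(act, time_h > 3, is.finite(A))
  expect_lt(abs(median(post$A)), 0.05 * 10)
})

test_that("alignment puts the anchor mitosis at relative time zero", {
  sched <- tibble::tibble(cell_id = "c1",
                          start_h = c(0, 10, 10.6), end_h = c(10, 10.6, 20),
                          phase = c("G1", "M", "G1"))
  tr <- simulate_reporter_trace(sched, uniform_params(R0 = 40))
  al <- align_to_mitosis(tr, window_h = c(-5, 5))
  row0 <- dplyr::filter(al$data, rel_time_h == 0)
  expect_equal(nrow(row0), 1)
  orig <- dplyr::filter(tr, time_h == 10)
  expect_equal(row0$value, orig$intensity)
})

test_that("cells without a mitosis are excluded and counted", {
  with_m <- mitotic_trace()
  no_m <- simulate_reporter_trace(flat_schedule(duration = 9,
                                                prefix = "flat"),
                                  uniform_params(R0 = 40))
  al <- align_to_mitosis(dplyr::bind_rows(with_m, no_m))
  expect_equal(al$n_cells, 1)
  expect_equal(al$n_excluded, 1)
  expect_error(align_to_mitosis(no_m), "no traces")
})

test_that("the aligned cohort median peaks at the mitotic artifact", {
  trs <- purrr::map_dfr(1:30, function(i) {
    tr <- mitotic_trace(noise_cv = 0.05, seed = i)
    tr$cell_id <- sprintf("c%03d", i)
    tr
  })
  al <- align_to_mitosis(trs, window_h = c(-3, 3))
  peak <- al$summary$rel_time_h[which.max(al$summary$median)]
  # the artifact spans the M frames at rel time 0, 0.2 and 0.4 h
  expect_gte(peak, -0.2 - 1e-9)
  expect_lte(peak, 0.4 + 1e-9)
})
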