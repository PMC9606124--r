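# rendering and the image-quantification chain

make_movie <- function(n = 10, duration = 4, dim = c(160, 160),
                       bias = NULL, noise_cv = 0, noise_sd = 0,
                       k = 0.25, R0 = 60, seed = 3) {
  lay <- nuclei_layout(n, dim = dim, radius = 7, min_sep = 30,
                       seed = seed)
  sched <- purrr::map_dfr(lay$cell_id, function(id)
    tibble::tibble(cell_id = id, start_h = 0, end_h = duration,
                   phase = "G1"))
  tr <- simulate_reporter_trace(sched,
                                uniform_params(k = k, R0 = R0,
                                               noise_cv = noise_cv),
                                seed = seed)
  list(movie = render_image_series(tr, lay, dim = dim, bias = bias,
                                   noise_sd = noise_sd, seed = seed),
       traces = tr, layout = lay)
}

test_that("identity render: nuclear median equals the trace value", {
  mk <- make_movie(n = 3, duration = 1)
  mv <- mk$movie
  for (f in c(1, 3)) {
    truth <- dplyr::filter(mv$truth, frame == f)
    for (i in seq_len(nrow(truth))) {
      msk <- ligaseflux:::ellipse_mask(
        dim(mv$reporter[[f]]), mk$layout$row[truth$label[i]],
        mk$layout$col[truth$label[i]], mk$layout$r_row[truth$label[i]],
        mk$layout$r_col[truth$label[i]])
      expect_equal(median(mv$reporter[[f]][msk]) - mv$bg_level,
                   truth$intensity[i], tolerance = 1e-12)
    }
  }
})

test_that("rendering is multiplicative in the bias field", {
  bias <- quadratic_bias(c(64, 64), 0.4)
  lay <- nuclei_layout(2, dim = c(64, 64), radius = 6, min_sep = 25,
                       seed = 1)
  tr <- simulate_reporter_trace(flat_schedule(2, duration = 0.2),
                                uniform_params(R0 = 50), seed = 1)
  tr$cell_id <- rep(lay$cell_id, each = 2)
  flat <- render_image_series(tr, lay, dim = c(64, 64), bias = NULL)
  biased <- render_image_series(tr, lay, dim = c(64, 64), bias = bias)
  expect_equal(biased$reporter[[1]], flat$reporter[[1]] * bias,
               tolerance = 1e-12)
})

test_that("ground truth has one row per rendered nucleus per frame", {
  mk <- make_movie(n = 10, duration = 2)
  counts <- dplyr::count(mk$movie$truth, frame)
  expect_true(all(counts$n == 10))
  expect_equal(nrow(counts), length(mk$movie$reporter))
})

test_that("nuclei outside the frame are a geometry error", {
  lay <- tibble::tibble(cell_id = "cell_0001", row = 2, col = 30,
                        r_row = 6, r_col = 6)
  tr <- simulate_reporter_trace(flat_schedule(duration = 0.2),
                                uniform_params(R0 = 50))
  expect_error(render_image_series(tr, lay, dim = c(64, 64)), "bounds")
})

test_that("flat background yields a near-unit bias field", {
  mk <- make_movie(n = 5, duration = 1)
  bf <- estimate_illumination_bias(mk$movie$nuclear)
  expect_lt(max(abs(bf$values - 1)), 0.01)
})

test_that("a known quadratic bias is recovered within 2% RMS", {
  bias <- quadratic_bias(c(160, 160), 0.3)
  mk <- make_movie(n = 8, duration = 2, bias = bias)
  bf <- estimate_illumination_bias(mk$movie$nuclear)
  expect_lt(sqrt(mean((bf$values - bias)^2)), 0.02)
})

test_that("disjoint frame samples give consistent bias estimates", {
  bias <- quadratic_bias(c(160, 160), 0.3)
  mk <- make_movie(n = 8, duration = 4, bias = bias, noise_sd = 1)
  frames <- mk$movie$nuclear
  half <- length(frames) %/% 2
  b1 <- estimate_illumination_bias(frames[seq_len(half)])
  b2 <- estimate_illumination_bias(frames[(half + 1):length(frames)])
  expect_lt(sqrt(mean((b1$values - b2$values)^2)), 0.01)
})

test_that("all-foreground frames fail bias estimation loudly", {
  expect_error(estimate_illumination_bias(list()), "at least one")
})

test_that("correct_frame inverts the multiplicative construction", {
  bias <- quadratic_bias(c(64, 64), 0.4)
  # pure background: frame = bias * c -> ~0 everywhere
  out <- correct_frame(bias * 37, bias)
  expect_lt(max(abs(out)), 1e-9)
  # background + signal: recovered up to the global background shift
  sig <- matrix(0, 64, 64); sig[20:30, 20:30] <- 120
  out2 <- correct_frame(bias * (37 + sig), bias)
  expect_equal(out2, sig, tolerance = 1e-9)
  # identity when bias is flat and background zero
  x <- matrix(runif(64^2), 64, 64)
  x[1] <- 0
  expect_equal(correct_frame(x, NULL, bg_quantile = 0), x,
               tolerance = 1e-12)
  expect_error(correct_frame(x, quadratic_bias(c(32, 32))), "dimensions")
})

test_that("segmentation finds well-separated nuclei at their centroids", {
  mk <- make_movie(n = 10, duration = 0.2)
  fr <- correct_frame(mk$movie$nuclear[[1]])
  lm <- segment_nuclei(fr)
  expect_equal(nrow(lm$props), 10)
  truth <- dplyr::filter(mk$movie$truth, frame == 1)
  d <- sapply(seq_len(nrow(truth)), function(i)
    min(sqrt((lm$props$row - truth$row[i])^2 +
             (lm$props$col - truth$col[i])^2)))
  expect_lt(max(d), 1)
})

test_that("blank frames segment to zero labels", {
  lm <- segment_nuclei(matrix(5, 64, 64))
  expect_equal(nrow(lm$props), 0)
  expect_true(all(lm$labels == 0))
})

test_that("two moderately overlapping nuclei are split into two labels", {
  lay <- tibble::tibble(cell_id = c("a", "b"),
                        row = c(32, 32), col = c(28, 28 + 1.6 * 8),
                        r_row = c(8, 8), r_col = c(8, 8))
  tr <- tibble::tibble(cell_id = c("a", "b"), frame = 1, time_h = 0,
                       latent = 50, intensity = 50, phase = "G1",
                       is_mitosis = FALSE)
  mv <- render_image_series(tr, lay, dim = c(64, 64))
  lm <- segment_nuclei(correct_frame(mv$nuclear[[1]]), min_area = 30)
  expect_equal(nrow(lm$props), 2)
})

test_that("a static nucleus tracks as one unbroken path", {
  lms <- replicate(5, square_label_map(rbind(c(30, 30))),
                   simplify = FALSE)
  tg <- track_nuclei(lms, max_disp = 5)
  expect_equal(nrow(tg$nodes), 5)
  expect_equal(length(unique(tg$nodes$track_id)), 1)
  expect_true(all(tg$edges$type == "link"))
})

test_that("a division produces exactly two children", {
  lms <- list(square_label_map(rbind(c(30, 30))),
              square_label_map(rbind(c(30, 30))),
              square_label_map(rbind(c(25, 28), c(35, 32))),
              square_label_map(rbind(c(24, 28), c(36, 32))))
  tg <- track_nuclei(lms, max_disp = 6)
  div <- dplyr::filter(tg$edges, type == "division")
  expect_equal(nrow(div), 2)
  expect_equal(unique(div$frame_from), 2L)
  expect_equal(unique(div$label_from), 1L)
  # structural invariants: each node has at most one parent, non-division
  # nodes at most one child
  child_keys <- paste(tg$edges$frame_to, tg$edges$label_to)
  expect_false(any(duplicated(child_keys)))
  per_parent <- dplyr::count(tg$edges, frame_from, label_from, type)
  expect_true(all(per_parent$n[per_parent$type == "link"] == 1))
  expect_true(all(per_parent$n[per_parent$type == "division"] == 2))
})

test_that("an empty movie yields an empty track graph", {
  lms <- replicate(3, segment_nuclei(matrix(0, 32, 32)),
                   simplify = FALSE)
  tg <- track_nuclei(lms, max_disp = 5)
  expect_equal(nrow(tg$nodes), 0)
  expect_equal(nrow(tg$edges), 0)
})

test_that("median extraction is robust to a saturated outlier pixel", {
  lm <- square_label_map(rbind(c(30, 30)))
  rep_frame <- matrix(10, 64, 64)
  rep_frame[lm$labels == 1] <- 55
  rep_frame[30, 30] <- 1e6
  tg <- track_nuclei(list(lm), max_disp = 5)
  tr <- extract_traces(list(rep_frame), list(lm), tg)
  expect_equal(tr$intensity, 55)
})

test_that("render -> correct -> segment -> track -> extract round trip
          recovers the generating traces", {
  bias <- quadratic_bias(c(160, 160), 0.3)
  mk <- make_movie(n = 10, duration = 4, bias = bias)
  mv <- mk$movie
  bf <- estimate_illumination_bias(mv$nuclear)
  lms <- lapply(seq_along(mv$nuclear), function(i)
    segment_nuclei(correct_frame(mv$nuclear[[i]], bf)))
  # detection: every well-separated ground-truth nucleus found once
  expect_true(all(vapply(lms, function(l) nrow(l$props), 1L) == 10))
  tg <- track_nuclei(lms, max_disp = 10)
  reps <- lapply(mv$reporter, correct_frame, bias = bf)
  ex <- extract_traces(reps, lms, tg, dt = 0.2)
  expect_equal(length(unique(ex$cell_id)), 10)
  # match extracted tracks to generating cells by centroid, compare values
  joined <- dplyr::inner_join(ex, mv$truth, by = "frame",
                              suffix = c("", ".t"),
                              relationship = "many-to-many") |>
    dplyr::mutate(d = sqrt((row - row.t)^2 + (col - col.t)^2)) |>
    dplyr::slice_min(d, n = 1, by = c(cell_id, frame))
  rel_err <- abs(joined$intensity - joined$intensity.t) /
    joined$intensity.t
  expect_lt(median(rel_err), 0.02)
})
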