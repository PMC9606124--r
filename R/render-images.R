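# Synthetic microscopy: render nuclear image series from traces --------

#' Lay out elliptical nuclei in a frame
#'
#' Places `n` nuclei uniformly at random, rejecting positions closer than
#' `min_sep` to an existing nucleus or to the frame border.
#'
#' @param n Number of nuclei.
#' @param dim Frame dimensions `c(rows, cols)` in pixels.
#' @param radius Mean nuclear semi-axis in pixels; per-axis radii are
#'   jittered +/-15% to make the nuclei elliptical.
#' @param min_sep Minimum centre-to-centre separation (pixels).
#' @param seed Integer seed.
#' @return Tibble `cell_id`, `row`, `col`, `r_row`, `r_col`.
#' @export
nuclei_layout <- function(n, dim = c(128, 128), radius = 8,
                          min_sep = 3 * radius, seed = 1) {
  set.seed(seed)
  rows <- numeric(0); cols <- numeric(0)
  pad <- radius * 1.5 + 1
  tries <- 0L
  while (length(rows) < n) {
    r <- runif(1, pad, dim[1] - pad)
    c <- runif(1, pad, dim[2] - pad)
    if (!length(rows) || all(sqrt((rows - r)^2 + (cols - c)^2) >= min_sep)) {
      rows <- c(rows, r); cols <- c(cols, c)
    }
    tries <- tries + 1L
    if (tries > 20000L)
      abort("could not place nuclei: frame too small for `n` at `min_sep`.")
  }
  tibble(cell_id = sprintf("cell_%04d", seq_len(n)),
         row = rows, col = cols,
         r_row = radius * runif(n, 0.85, 1.15),
         r_col = radius * runif(n, 0.85, 1.15))
}

#' Smooth quadratic illumination-bias surface
#'
#' A strictly positive, unit-mean 2D field rising towards the frame
#' corners, mimicking uneven illumination across a well.
#'
#' @param dim Frame dimensions `c(rows, cols)`.
#' @param strength Peak-to-centre relative amplitude before normalisation.
#' @return Matrix of dimension `dim` with mean 1.
#' @export
quadratic_bias <- function(dim = c(128, 128), strength = 0.25) {
  r <- (seq_len(dim[1]) - (dim[1] + 1) / 2) / dim[1]
  c <- (seq_len(dim[2]) - (dim[2] + 1) / 2) / dim[2]
  b <- 1 + strength * (outer(r^2, rep(1, dim[2])) +
                       outer(rep(1, dim[1]), c^2))
  b / mean(b)
}

ellipse_mask <- function(dim, row0, col0, r_row, r_col) {
  rr <- outer((seq_len(dim[1]) - row0) / r_row, rep(1, dim[2]))
  cc <- outer(rep(1, dim[1]), (seq_len(dim[2]) - col0) / r_col)
  rr^2 + cc^2 <= 1
}

#' Render a two-channel nuclear image series from reporter traces
#'
#' Produces, per frame, a nuclear-marker channel (constant intensity
#' inside each elliptical nucleus, standing in for H2B) and a reporter
#' channel whose value inside a nucleus equals that cell's measured trace
#' intensity at the frame. Both channels sit on a flat background level,
#' are multiplied by the illumination-bias field, and optionally receive
#' additive Gaussian camera noise. A ground-truth table records every
#' rendered nucleus.
#'
#' @param traces Trace tibble from [simulate_reporter_trace()]; every cell
#'   must appear in `layout`.
#' @param layout Nucleus layout from [nuclei_layout()] (static positions).
#' @param dim Frame dimensions `c(rows, cols)`.
#' @param bias Illumination field matrix (strictly positive); `NULL` for
#'   flat illumination.
#' @param bg_level Background intensity added to both channels (a.u.).
#' @param nuclear_level Nuclear-marker intensity inside nuclei (a.u.).
#' @param noise_sd Additive Gaussian noise SD (a.u.); 0 for none.
#' @param seed Integer seed for the camera noise.
#' @return List of class `reporter_movie`: `nuclear` and `reporter` (lists
#'   of matrices, one per frame), `truth` (tibble `frame`, `cell_id`,
#'   `label`, `row`, `col`, `intensity`), `bias`, `bg_level`, `dt`.
#' @export
render_image_series <- function(traces, layout, dim = c(128, 128),
                                bias = NULL, bg_level = 20,
                                nuclear_level = 500, noise_sd = 0,
                                seed = 1) {
  if (is.null(bias)) bias <- matrix(1, dim[1], dim[2])
  if (!all(dim(bias) == dim)) abort("`bias` dimensions must match `dim`.")
  if (any(bias <= 0)) abort("`bias` must be strictly positive.")
  bad <- layout$row - layout$r_row < 1 | layout$row + layout$r_row > dim[1] |
         layout$col - layout$r_col < 1 | layout$col + layout$r_col > dim[2]
  if (any(bad)) abort("nucleus outside frame bounds.")
  miss <- setdiff(unique(traces$cell_id), layout$cell_id)
  if (length(miss)) abort("traces contain cells missing from `layout`.")
  set.seed(seed)

  masks <- map(seq_len(nrow(layout)), function(i)
    ellipse_mask(dim, layout$row[i], layout$col[i],
                 layout$r_row[i], layout$r_col[i]))
  frames <- sort(unique(traces$frame))
  dt <- if (nrow(traces) > 1) diff(sort(unique(traces$time_h)))[1] else 0.2

  nuclear <- vector("list", length(frames))
  reporter <- vector("list", length(frames))
  truth <- vector("list", length(frames))
  for (fi in seq_along(frames)) {
    f <- frames[fi]
    tf <- traces[traces$frame == f, ]
    nuc <- matrix(bg_level, dim[1], dim[2])
    rep_ <- matrix(bg_level, dim[1], dim[2])
    rows <- list()
    for (i in seq_len(nrow(layout))) {
      val <- tf$intensity[match(layout$cell_id[i], tf$cell_id)]
      if (is.na(val)) next
      nuc[masks[[i]]] <- bg_level + nuclear_level
      rep_[masks[[i]]] <- bg_level + val
      rows[[length(rows) + 1L]] <- tibble(
        frame = f, cell_id = layout$cell_id[i], label = i,
        row = layout$row[i], col = layout$col[i], intensity = val)
    }
    nuc <- nuc * bias
    rep_ <- rep_ * bias
    if (noise_sd > 0) {
      nuc <- nuc + matrix(rnorm(prod(dim), 0, noise_sd), dim[1], dim[2])
      rep_ <- rep_ + matrix(rnorm(prod(dim), 0, noise_sd), dim[1], dim[2])
    }
    nuclear[[fi]] <- nuc
    reporter[[fi]] <- rep_
    truth[[fi]] <- list_rbind(rows)
  }
  structure(list(nuclear = nuclear, reporter = reporter,
                 truth = list_rbind(truth), bias = bias,
                 bg_level = bg_level, dt = dt),
            class = "reporter_movie")
}

#' @export
print.reporter_movie <- function(x, ...) {
  d <- dim(x$nuclear[[1]])
  cat("<reporter_movie>", length(x$nuclear), "frames,",
      d[1], "x", d[2], "px,",
      length(unique(x$truth$cell_id)), "nuclei\n")
  invisible(x)
}
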