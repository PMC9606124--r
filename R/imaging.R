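# Image quantification: bias correction, segmentation, tracking --------
#
# Pixel coordinates are 0-free: matrices are indexed [row, col] starting
# at 1, and centroids are reported on that grid.

#' Estimate the optical illumination bias from background pixels
#'
#' Samples background pixels (those below a per-frame intensity
#' percentile) across the supplied frames and fits a low-order 2D
#' polynomial surface to their intensities. Because background light is
#' spatially flat before the optics, the fitted surface estimates the
#' multiplicative illumination bias up to a constant, which is removed by
#' normalising the field to unit mean.
#'
#' @param frames List of image matrices sharing one dimension.
#' @param bg_quantile Per-frame quantile below which pixels count as
#'   background (default 0.10).
#' @param degree Polynomial surface order (default 2; low order so the
#'   surface cannot absorb cellular signal).
#' @return Object of class `bias_field`: `values` (unit-mean positive
#'   matrix), `fit_meta` (degree, n pixels sampled, residual SD).
#' @export
estimate_illumination_bias <- function(frames, bg_quantile = 0.10,
                                       degree = 2) {
  if (!length(frames)) abort("need at least one frame.")
  d <- dim(frames[[1]])
  samp <- list_rbind(map(frames, function(fr) {
    thr <- quantile(fr, bg_quantile)
    idx <- which(fr <= thr, arr.ind = TRUE)
    if (!nrow(idx)) return(NULL)
    tibble(row = idx[, 1], col = idx[, 2], value = fr[idx])
  }))
  if (is.null(samp) || !nrow(samp))
    abort("no background pixels found under the selector.")
  # centred coordinates keep the polynomial well conditioned
  samp <- mutate(samp, r = (.data$row - d[1] / 2) / d[1],
                 c = (.data$col - d[2] / 2) / d[2])
  fml <- if (degree >= 2)
    value ~ r + c + I(r^2) + I(c^2) + I(r * c) else value ~ r + c
  fit <- lm(fml, data = samp)
  grid <- expand.grid(row = seq_len(d[1]), col = seq_len(d[2]))
  grid$r <- (grid$row - d[1] / 2) / d[1]
  grid$c <- (grid$col - d[2] / 2) / d[2]
  vals <- matrix(predict(fit, grid), d[1], d[2])
  if (any(vals <= 0))
    abort("fitted bias surface is not strictly positive.")
  vals <- vals / mean(vals)
  structure(list(values = vals,
                 fit_meta = list(degree = degree, n_pixels = nrow(samp),
                                 residual_sd = sd(resid(fit)))),
            class = "bias_field")
}

#' @export
print.bias_field <- function(x, ...) {
  cat("<bias_field>", paste(dim(x$values), collapse = " x "),
      "px, range", paste(signif(range(x$values), 4), collapse = "-"), "\n")
  invisible(x)
}

#' Flatten a frame and subtract its global background
#'
#' Divides the frame by the illumination bias, then subtracts a robust
#' global background estimated as a low percentile of the flattened
#' frame. Small negative values are retained (not clipped) so that
#' downstream statistics stay unbiased.
#'
#' @param frame Image matrix.
#' @param bias A [estimate_illumination_bias()] result, a plain positive
#'   matrix, or `NULL` for flat illumination.
#' @param bg_quantile Percentile of the flattened frame used as the
#'   global background (default 0.05).
#' @return Corrected matrix, same dimension as `frame`.
#' @export
correct_frame <- function(frame, bias = NULL, bg_quantile = 0.05) {
  b <- if (is.null(bias)) 1
       else if (inherits(bias, "bias_field")) bias$values
       else bias
  if (is.matrix(b) && !all(dim(b) == dim(frame)))
    abort("`bias` dimensions do not match the frame.")
  flat <- frame / b
  flat - quantile(flat, bg_quantile)
}

#' Segment nuclei in a corrected nuclear-marker frame
#'
#' Gaussian smoothing, Otsu thresholding, size filtering and
#' distance-transform watershed splitting of touching nuclei
#' (via EBImage primitives).
#'
#' @param frame Corrected single-channel matrix.
#' @param min_area,max_area Label area bounds in pixels.
#' @param blur_sigma Gaussian smoothing SD in pixels.
#' @param split If TRUE, separate touching nuclei by watershed on the
#'   distance transform.
#' @return Object of class `label_map`: `labels` (integer matrix, 0 =
#'   background) and `props` (tibble `label`, `row`, `col`, `area`).
#' @export
segment_nuclei <- function(frame, min_area = 40, max_area = 2500,
                           blur_sigma = 2, split = TRUE) {
  empty <- function() structure(
    list(labels = matrix(0L, nrow(frame), ncol(frame)),
         props = tibble(label = integer(), row = numeric(),
                        col = numeric(), area = numeric())),
    class = "label_map")
  rng <- range(frame)
  if (diff(rng) <= 0) return(empty())
  img <- EBImage::Image((frame - rng[1]) / diff(rng))
  sm <- EBImage::gblur(img, sigma = blur_sigma)
  thr <- try(EBImage::otsu(sm), silent = TRUE)
  if (inherits(thr, "try-error")) return(empty())
  mask <- sm > thr
  if (split) {
    dm <- EBImage::distmap(mask)
    lab <- EBImage::watershed(dm, tolerance = 1, ext = 1)
  } else {
    lab <- EBImage::bwlabel(mask)
  }
  lab <- EBImage::imageData(lab)
  if (max(lab) == 0) return(empty())
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= min_area & areas <= max_area)
  if (!length(keep)) return(empty())
  relab <- integer(length(areas))
  relab[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(frame), ncol(frame))
  nz <- lab > 0
  out[nz] <- relab[lab[nz]]
  idx <- which(out > 0, arr.ind = TRUE)
  props <- tibble(label = out[idx], row = idx[, 1], col = idx[, 2]) |>
    summarise(row = mean(.data$row), col = mean(.data$col),
              area = dplyr::n(), .by = "label") |>
    arrange(.data$label)
  structure(list(labels = out, props = props), class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  cat("<label_map>", nrow(x$props), "labels\n")
  invisible(x)
}

#' Link nuclei across frames into tracks with division detection
#'
#' Greedy mutual-nearest-centroid linking between consecutive frames:
#' candidate pairs within `max_disp` pixels are accepted in order of
#' increasing distance, each object used at most once. An object that
#' disappears while two unlinked objects appear nearby in the next frame
#' (within `division_factor * max_disp`) becomes a division with exactly
#' two children.
#'
#' @param labelmaps List of `label_map`s, one per frame, in order.
#' @param max_disp Maximum frame-to-frame displacement in pixels.
#' @param division_factor Search-radius multiplier for daughter candidates.
#' @return Object of class `track_graph`: `nodes` (tibble `frame`,
#'   `label`, `row`, `col`, `area`, `track_id`) and `edges` (tibble
#'   `frame_from`, `label_from`, `frame_to`, `label_to`, `dist`, `type`
#'   in {"link", "division"}).
#' @export
track_nuclei <- function(labelmaps, max_disp = 15, division_factor = 1.5) {
  if (max_disp <= 0) abort("`max_disp` must be > 0.")
  nodes <- list_rbind(imap(labelmaps, function(lm, i)
    mutate(lm$props, frame = as.integer(i), .before = 1)))
  edges <- tibble(frame_from = integer(), label_from = integer(),
                  frame_to = integer(), label_to = integer(),
                  dist = numeric(), type = character())
  if (is.null(nodes) || !nrow(nodes)) {
    return(structure(list(nodes = tibble(frame = integer(),
                                         label = integer(), row = numeric(),
                                         col = numeric(), area = numeric(),
                                         track_id = integer()),
                          edges = edges), class = "track_graph"))
  }
  for (f in seq_len(length(labelmaps) - 1L)) {
    a <- filter(nodes, .data$frame == f)
    b <- filter(nodes, .data$frame == f + 1L)
    if (!nrow(a) || !nrow(b)) next
    dmat <- outer(a$row, b$row, "-")^2 + outer(a$col, b$col, "-")^2
    dmat <- sqrt(dmat)
    used_a <- logical(nrow(a)); used_b <- logical(nrow(b))
    links <- list()
    repeat {
      dmat2 <- dmat
      dmat2[used_a, ] <- Inf; dmat2[, used_b] <- Inf
      m <- which.min(dmat2)
      if (!length(m) || dmat2[m] > max_disp) break
      ij <- arrayInd(m, dim(dmat2))
      used_a[ij[1]] <- TRUE; used_b[ij[2]] <- TRUE
      links[[length(links) + 1L]] <- tibble(
        frame_from = f, label_from = a$label[ij[1]],
        frame_to = f + 1L, label_to = b$label[ij[2]],
        dist = dmat2[m], type = "link")
    }
    links <- if (length(links)) list_rbind(links) else NULL
    # division: a disappeared mother with >= 2 orphaned nearby children
    for (i in which(!used_a)) {
      cand <- which(!used_b & dmat[i, ] <= division_factor * max_disp)
      if (length(cand) >= 2L) {
        kids <- cand[order(dmat[i, cand])][1:2]
        used_b[kids] <- TRUE
        edges <- bind_rows(edges, tibble(
          frame_from = f, label_from = a$label[i],
          frame_to = f + 1L, label_to = b$label[kids],
          dist = dmat[i, kids], type = "division"))
      }
    }
    # a linked mother with one additional orphan daughter nearby is also
    # a division (the tracker grabbed the closer daughter as the link)
    if (!is.null(links)) {
      for (r in seq_len(nrow(links))) {
        i <- match(links$label_from[r], a$label)
        cand <- which(!used_b & dmat[i, ] <= division_factor * max_disp)
        if (length(cand) >= 1L) {
          kid <- cand[which.min(dmat[i, cand])]
          used_b[kid] <- TRUE
          links$type[r] <- "division"
          links <- bind_rows(links, tibble(
            frame_from = f, label_from = a$label[i],
            frame_to = f + 1L, label_to = b$label[kid],
            dist = dmat[i, kid], type = "division"))
        }
      }
      edges <- bind_rows(edges, links)
    }
  }
  # assign track ids: a new id at every unparented node and at each
  # division daughter
  nodes$track_id <- NA_integer_
  key <- function(fr, lb) paste(fr, lb)
  parent_of <- setNames(key(edges$frame_from, edges$label_from),
                        key(edges$frame_to, edges$label_to))
  type_of <- setNames(edges$type, key(edges$frame_to, edges$label_to))
  next_id <- 0L
  ids <- new.env()
  for (r in seq_len(nrow(nodes))) {
    k <- key(nodes$frame[r], nodes$label[r])
    p <- parent_of[k]
    if (is.na(p) || is.null(ids[[p]]) || type_of[[k]] == "division") {
      next_id <- next_id + 1L
      ids[[k]] <- next_id
    } else {
      ids[[k]] <- ids[[p]]
    }
    nodes$track_id[r] <- ids[[k]]
  }
  structure(list(nodes = nodes, edges = edges), class = "track_graph")
}

#' @export
print.track_graph <- function(x, ...) {
  ndiv <- sum(x$edges$type == "division") / 2
  cat("<track_graph>", nrow(x$nodes), "nodes,",
      length(unique(x$nodes$track_id)), "tracks,", ndiv, "divisions\n")
  invisible(x)
}

# Follow a root node forward; at a division take the daughter with the
# smaller label (deterministic choice).
walk_track <- function(tg, frame0, label0) {
  path <- list(c(frame0, label0))
  f <- frame0; l <- label0
  repeat {
    nxt <- filter(tg$edges, .data$frame_from == f, .data$label_from == l)
    if (!nrow(nxt)) break
    nxt <- arrange(nxt, .data$label_to)[1, ]
    f <- nxt$frame_to; l <- nxt$label_to
    path[[length(path) + 1L]] <- c(f, l, division = nxt$type == "division")
  }
  path
}

#' Extract median-intensity reporter traces along tracks
#'
#' For every root-to-leaf track path (one daughter followed per division,
#' chosen by label order) reports the median reporter intensity over the
#' pixels of the tracked nucleus at each frame. Frames where the label is
#' missing yield `NA` and are flagged.
#'
#' @param reporter_frames List of corrected reporter-channel matrices.
#' @param labelmaps List of `label_map`s matching the frames.
#' @param tracks A [track_nuclei()] result.
#' @param dt Frame interval in hours.
#' @return Trace tibble: `cell_id`, `frame`, `time_h`, `intensity`,
#'   `row`, `col`, `is_mitosis` (TRUE on the frame after a division),
#'   `gap` (TRUE where the label was missing).
#' @export
extract_traces <- function(reporter_frames, labelmaps, tracks, dt = 0.2) {
  roots <- anti_join(tracks$nodes,
                     transmute(tracks$edges, frame = .data$frame_to,
                               label = .data$label_to),
                     by = c("frame", "label")) |>
    # daughters of divisions restart track ids but are not roots of a
    # new lineage path; keep only truly unparented nodes
    arrange(.data$frame, .data$label)
  out <- list()
  for (r in seq_len(nrow(roots))) {
    path <- walk_track(tracks, roots$frame[r], roots$label[r])
    rows <- map(path, function(p) {
      f <- p[1]; l <- p[2]
      lm <- labelmaps[[f]]
      px <- reporter_frames[[f]][lm$labels == l]
      pr <- lm$props[lm$props$label == l, ]
      tibble(frame = as.integer(f),
             intensity = if (length(px)) median(px) else NA_real_,
             row = if (nrow(pr)) pr$row else NA_real_,
             col = if (nrow(pr)) pr$col else NA_real_,
             is_mitosis = length(p) >= 3 && p[3] == 1,
             gap = !length(px))
    })
    out[[r]] <- list_rbind(rows) |>
      mutate(cell_id = sprintf("track_%03d", r),
             time_h = (.data$frame - 1L) * dt,
             .before = 1)
  }
  list_rbind(out) |>
    select("cell_id", "frame", "time_h", "intensity", "row", "col",
           "is_mitosis", "gap")
}
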