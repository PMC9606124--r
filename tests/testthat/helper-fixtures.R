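# shared fixture builders ----------------------------------------------

# single-phase schedule for n cells, used when cycle structure is not
# under test
flat_schedule <- function(n = 1, duration = 10, phase = "G1",
                          prefix = "cell") {
  purrr::map_dfr(seq_len(n), function(i)
    tibble::tibble(cell_id = sprintf("%s_%04d", prefix, i),
                   start_h = 0, end_h = duration, phase = phase))
}

# kinetic params with one decay constant in every phase
uniform_params <- function(s = 10, k = 0.25, noise_cv = 0, R0 = NULL,
                           spike = 1) {
  kinetic_params(s = s,
                 k_by_phase = c(G0 = k, G1 = k, S = k, G2 = k, M = k),
                 mitotic_spike = spike, noise_cv = noise_cv, R0 = R0)
}

# hand-built label map: 3x3 square nuclei at the given (row, col) centers
square_label_map <- function(centers, dim = c(64, 64)) {
  m <- matrix(0L, dim[1], dim[2])
  for (i in seq_len(nrow(centers)))
    m[centers[i, 1] + (-1:1), centers[i, 2] + (-1:1)] <- i
  structure(list(labels = m,
                 props = tibble::tibble(
                   label = seq_len(nrow(centers)),
                   row = centers[, 1], col = centers[, 2], area = 9)),
            class = "label_map")
}

# exact 4PL responses on the standard titration
fourpl_responses <- function(doses, bottom = 0, top = 100, ic50 = 1,
                             hill = 1) {
  bottom + (top - bottom) / (1 + (doses / ic50)^hill)
}
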