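# Shared fixtures and independent oracles for the test suite.

# Map simulator ground-truth step states to pipeline segment classes.
truth_class_map <- c("pause" = "stationary",
                     "retro-run" = "retrograde",
                     "antero-run" = "anterograde")

# Boundary-free motility parameters: a very long axon so renewal-theory
# closed forms (which assume free runs) apply, and equal run speeds so the
# expected path length per moving step is v regardless of direction.
free_params <- function(v = 1, p_pause = 0.2, mean_pause = 3,
                        speed_cv = 0, p_switch = 0) {
  transport_params(v_retro = v, v_antero = v, p_pause = p_pause,
                   mean_pause = mean_pause, p_switch = p_switch,
                   speed_cv = speed_cv, axon_length = 1e5)
}

# Wrap a bare matrix as a kymograph (for tracer tests on hand-built data).
make_kymo <- function(m, row_scale = 1, col_scale = 0.16) {
  structure(list(matrix = m, row_scale = row_scale, col_scale = col_scale,
                 orientation = "soma_right", reducer = "max", width = 1),
            class = "kymograph")
}

# Hand-built kymograph with Gaussian ridges at given per-row centres.
ridge_matrix <- function(centres, n_cols, amplitude = 100, sigma = 1.3,
                         background = 0) {
  centres <- as.matrix(centres) # n_rows x n_ridges
  m <- matrix(background, nrow(centres), n_cols)
  for (f in seq_len(nrow(centres))) {
    for (r in seq_len(ncol(centres))) {
      m[f, ] <- m[f, ] + amplitude *
        exp(-((seq_len(n_cols) - centres[f, r])^2) / (2 * sigma^2))
    }
  }
  m
}

# Independent exhaustive permutation two-sided p for a two-sample t.
permutation_p <- function(a, b) {
  x <- c(a, b)
  n <- length(a)
  t_stat <- function(i) {
    g1 <- x[i]
    g2 <- x[-i]
    sp <- sqrt(((length(g1) - 1) * var(g1) + (length(g2) - 1) * var(g2)) /
                 (length(x) - 2))
    (mean(g1) - mean(g2)) / (sp * sqrt(1 / length(g1) + 1 / length(g2)))
  }
  obs <- abs(t_stat(seq_len(n)))
  splits <- utils::combn(length(x), n)
  stats <- apply(splits, 2, function(i) abs(t_stat(i)))
  mean(stats >= obs - 1e-12)
}
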