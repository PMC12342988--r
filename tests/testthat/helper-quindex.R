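# Shared fixtures and independent oracles, all built in code.

# brute-force type-7 quantile: sort + linear interpolation at 1 + (n-1)p,
# written independently of stats::quantile
quantile_oracle <- function(x, p) {
  xs <- sort(x)
  n <- length(xs)
  h <- 1 + (n - 1) * p
  lo <- floor(h)
  hi <- ceiling(h)
  xs[lo] + (h - lo) * (xs[hi] - xs[lo])
}

# tiny grouped_samples fixture from explicit vectors
tiny_grouped <- function(values_by_cluster_by_subject, marker = "m") {
  rows <- list()
  for (s in names(values_by_cluster_by_subject)) {
    cls <- values_by_cluster_by_subject[[s]]
    for (cl in names(cls)) {
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = s, cluster_id = cl, m = cls[[cl]],
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  names(df)[3] <- marker
  grouped_samples(df, marker)
}

# hand-constructed linear qi_fit with explicit basis coefficients; with
# theta = rep(c, m) the partition of unity makes beta(p) = c exactly
manual_linear_fit <- function(theta, grid = prob_grid(),
                              q_range = c(-10, 10), n_basis = length(theta)) {
  structure(list(
    family = "gaussian", kind = "linear",
    theta = theta, intercept = 0, coefficients = c(0, theta),
    offsets = rep(0, length(theta)),
    lambda = c(p = 1), basis = spline_basis(n_basis),
    grid = grid, q_range = q_range,
    edf = NA_real_, converged = TRUE, flags = character(),
    n = NA_integer_), class = "qi_fit")
}

# random nested dataset for property tests
random_grouped <- function(n_subjects, n_clusters, n_cells, seed) {
  set.seed(seed)
  rows <- do.call(rbind, lapply(seq_len(n_subjects), function(i) {
    do.call(rbind, lapply(seq_len(n_clusters), function(j) {
      data.frame(subject_id = sprintf("S%02d", i),
                 cluster_id = sprintf("C%02d", j),
                 m = rlnorm(n_cells, rnorm(1, 0, 0.4), 0.5),
                 stringsAsFactors = FALSE)
    }))
  }))
  grouped_samples(rows, "m")
}
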