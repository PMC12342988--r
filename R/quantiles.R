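#' Empirical quantiles on a probability grid
#'
#' Sample quantiles of a single cluster's intensities at every grid
#' probability, using the linear-interpolation order-statistic estimator
#' (position \eqn{1 + (n - 1)p} between sorted values; R's type-7 rule).
#' The output is non-decreasing and bounded by the sample range.
#'
#' @param values non-empty vector of finite intensities.
#' @param grid a [prob_grid()] (or a grid size / probability vector).
#' @return Numeric vector of length `grid$K`.
#' @examples
#' empirical_quantile(1:10, prob_grid(p = 0.5))  # 5.5
#' @export
empirical_quantile <- function(values, grid = prob_grid()) {
  grid <- as_prob_grid(grid)
  if (length(values) == 0L) stop("empty value vector")
  if (any(!is.finite(values))) stop("non-finite values in cluster")
  quantile(values, probs = grid$p, type = 7, names = FALSE)
}

#' Per-cluster quantile functions for each subject
#'
#' @param grouped a [grouped_samples()] object.
#' @param grid a [prob_grid()].
#' @return Named list (by subject) of matrices, one row per cluster.
#' @export
cluster_quantiles <- function(grouped, grid = prob_grid()) {
  stopifnot(inherits(grouped, "grouped_samples"))
  grid <- as_prob_grid(grid)
  lapply(grouped$data, function(cl) {
    m <- do.call(rbind, lapply(cl, empirical_quantile, grid = grid))
    rownames(m) <- names(cl)
    m
  })
}

#' Aggregate cluster quantile functions to subject level
#'
#' Step 1 of the quantile-index pipeline.  Each lowest-level cluster (ROI
#' or TMA core) is first converted to its empirical quantile function on
#' the shared grid; clusters of the same subject are then combined
#' point-wise — at each grid probability separately — by the chosen
#' aggregator.  Aggregation always happens on the quantile scale; cells
#' are never pooled across clusters.  For a subject with a single cluster
#' all four aggregators return that cluster's quantile vector unchanged.
#'
#' Point-wise min/mean/median/max of non-decreasing functions is
#' non-decreasing, so every row of the result is a valid quantile
#' function.
#'
#' @param grouped a [grouped_samples()] object.
#' @param grid a [prob_grid()]; defaults to 100 midpoint probabilities.
#' @param method point-wise aggregator: `"mean"` (default), `"median"`,
#'   `"min"` or `"max"`.
#' @return An object of class `quantile_matrix`: an n_subjects x K matrix
#'   with subject ids as row names and attributes `grid`, `method`,
#'   `marker`.
#' @export
aggregate_quantile <- function(grouped, grid = prob_grid(),
                               method = c("mean", "median", "min", "max")) {
  method <- match.arg(method)
  grid <- as_prob_grid(grid)
  cq <- cluster_quantiles(grouped, grid)
  agg <- switch(method,
                mean   = function(m) colMeans(m),
                median = function(m) apply(m, 2, median),
                min    = function(m) apply(m, 2, min),
                max    = function(m) apply(m, 2, max))
  Q <- do.call(rbind, lapply(cq, function(m) {
    if (nrow(m) == 1L) m[1, ] else agg(m)
  }))
  rownames(Q) <- names(cq)
  quantile_matrix(Q, grid, method = method, marker = grouped$marker)
}

#' Construct / validate a quantile matrix
#'
#' @param Q numeric matrix, one row per subject, one column per grid
#'   probability; rows must be non-decreasing and finite.
#' @param grid the [prob_grid()] the columns refer to.
#' @param method aggregation method that produced the rows.
#' @param marker marker name (optional bookkeeping).
#' @return `Q` with class `quantile_matrix` and grid attributes.
#' @export
quantile_matrix <- function(Q, grid, method = "none", marker = NULL) {
  grid <- as_prob_grid(grid)
  Q <- as.matrix(Q)
  if (ncol(Q) != grid$K) stop("ncol(Q) must equal the grid size K")
  if (any(!is.finite(Q))) stop("quantile matrix entries must be finite")
  viol <- apply(Q, 1, function(r) any(diff(r) < -1e-10))
  if (any(viol))
    stop("non-monotone quantile row(s): ",
         paste(head(rownames(Q)[viol], 3), collapse = ", "))
  if (is.null(rownames(Q))) rownames(Q) <- paste0("subj", seq_len(nrow(Q)))
  structure(Q, class = c("quantile_matrix", "matrix"),
            grid = grid, method = method, marker = marker)
}

#' @export
print.quantile_matrix <- function(x, ...) {
  g <- attr(x, "grid")
  cat(sprintf(
    "Quantile matrix: %d subjects x K = %d (aggregation: %s)\n",
    nrow(x), g$K, attr(x, "method")))
  invisible(x)
}

q_grid <- function(Q) attr(Q, "grid")

#' Write / read a quantile matrix as CSV
#'
#' Columns are `subject_id` followed by `q_<p>` for each grid probability.
#'
#' @param Q a `quantile_matrix`.
#' @param path output path.
#' @export
write_quantiles_csv <- function(Q, path) {
  g <- q_grid(Q)
  df <- data.frame(subject_id = rownames(Q), unclass(Q),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("subject_id", sprintf("q_%.12g", g$p))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_quantiles_csv
#' @param method aggregation label to attach on read.
#' @export
read_quantiles_csv <- function(path, method = "none") {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  qc <- grep("^q_", names(df), value = TRUE)
  if (length(qc) == 0L) stop("no q_<p> columns in ", path)
  p <- as.numeric(sub("^q_", "", qc))
  Q <- as.matrix(df[qc])
  rownames(Q) <- as.character(df$subject_id)
  colnames(Q) <- NULL
  quantile_matrix(Q, prob_grid(p = p), method = method)
}
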