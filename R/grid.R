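#' Probability grid for quantile functions
#'
#' Defines the shared grid of probabilities \eqn{0 < p_1 < \dots < p_K < 1}
#' on which all empirical quantile functions are evaluated, together with
#' the Riemann quadrature weights used to integrate along it.  The default
#' is the midpoint grid \eqn{p_k = (k - 0.5)/K}, which avoids the unstable
#' extreme order statistics at \eqn{p = 0} and \eqn{p = 1} and makes every
#' quadrature weight exactly \eqn{1/K}.
#'
#' For a user-supplied grid the weights are the widths of the cells obtained
#' by splitting \eqn{[0, 1]} at the midpoints between adjacent grid points,
#' which reduces to the midpoint rule on the default grid.
#'
#' @param K number of grid points (ignored when `p` is given).
#' @param p optional strictly increasing vector of probabilities in (0, 1).
#'
#' @return An object of class `prob_grid`: a list with elements `p`
#'   (probabilities), `K` (grid size) and `w` (quadrature weights summing
#'   to 1).
#' @examples
#' g <- prob_grid(100)
#' stopifnot(all.equal(sum(g$w), 1))
#' @export
prob_grid <- function(K = 100L, p = NULL) {
  if (is.null(p)) {
    K <- as.integer(K)
    if (K < 1L) stop("'K' must be a positive integer")
    p <- (seq_len(K) - 0.5) / K
  } else {
    p <- as.numeric(p)
    if (length(p) < 1L) stop("'p' must be non-empty")
    if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1))
      stop("'p' must lie strictly inside (0, 1)")
    if (is.unsorted(p, strictly = TRUE))
      stop("'p' must be strictly increasing")
    K <- length(p)
  }
  bounds <- c(0, (p[-K] + p[-1]) / 2, 1)
  structure(list(p = p, K = K, w = diff(bounds)), class = "prob_grid")
}

#' @export
print.prob_grid <- function(x, ...) {
  cat(sprintf("Probability grid: K = %d, p in [%.4g, %.4g]\n",
              x$K, x$p[1], x$p[x$K]))
  invisible(x)
}

as_prob_grid <- function(x) {
  if (inherits(x, "prob_grid")) return(x)
  if (is.numeric(x) && length(x) == 1L && x >= 1) return(prob_grid(K = x))
  if (is.numeric(x)) return(prob_grid(p = x))
  stop("cannot interpret 'grid'; supply a prob_grid(), a grid size K, ",
       "or a vector of probabilities")
}
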