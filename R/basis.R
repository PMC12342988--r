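#' B-spline basis for coefficient functions
#'
#' A univariate B-spline basis with equally spaced interior knots and a
#' difference penalty on the coefficients (the P-spline construction).
#' Cubic splines with a second-order difference penalty are the default:
#' the penalty null space then consists of functions affine in the
#' argument, so heavy smoothing shrinks the fitted coefficient function
#' towards a straight line rather than towards zero.
#'
#' @param n_basis number of basis functions (>= degree + 1).
#' @param degree polynomial degree (3 = cubic).
#' @param range domain endpoints.
#' @param penalty_order order of the difference penalty.
#' @return An object of class `spline_basis`.
#' @export
spline_basis <- function(n_basis = 10L, degree = 3L, range = c(0, 1),
                         penalty_order = 2L) {
  n_basis <- as.integer(n_basis); degree <- as.integer(degree)
  stopifnot(length(range) == 2L, range[2] > range[1],
            penalty_order >= 1L, penalty_order < n_basis)
  if (n_basis < degree + 1L)
    stop("n_basis must be at least degree + 1")
  ord <- degree + 1L
  n_int <- n_basis - ord
  interior <- if (n_int > 0L) {
    seq(range[1], range[2], length.out = n_int + 2L)[-c(1L, n_int + 2L)]
  } else numeric()
  knots <- c(rep(range[1], ord), interior, rep(range[2], ord))
  structure(list(n_basis = n_basis, degree = degree, range = range,
                 knots = knots, penalty_order = as.integer(penalty_order)),
            class = "spline_basis")
}

#' Evaluate a basis at a vector of points
#'
#' Points are clamped to the basis range before evaluation (range policy —
#' whether out-of-range values are an error or are clamped and flagged —
#' is enforced by the callers).
#'
#' @param basis a `spline_basis` or `tensor_basis`.
#' @param x evaluation points (for a tensor basis: see [eval_tensor()]).
#' @return Matrix `length(x)` x `n_basis`.
#' @export
eval_basis <- function(basis, x) {
  stopifnot(inherits(basis, "spline_basis"))
  x <- pmin(pmax(as.numeric(x), basis$range[1]), basis$range[2])
  splineDesign(basis$knots, x, ord = basis$degree + 1L)
}

#' Difference penalty matrix of a basis
#'
#' @param basis a `spline_basis`.
#' @return `n_basis` x `n_basis` positive semi-definite matrix
#'   \eqn{D^\top D} with `D` the `penalty_order`-th difference operator.
#' @export
penalty_matrix <- function(basis) {
  stopifnot(inherits(basis, "spline_basis"))
  D <- diff(diag(basis$n_basis), differences = basis$penalty_order)
  crossprod(D)
}

# Greville abscissae: coefficients at which the B-spline expansion
# reproduces the identity function exactly (degree >= 1).
greville <- function(basis) {
  k <- basis$knots; d <- basis$degree
  vapply(seq_len(basis$n_basis),
         function(j) mean(k[(j + 1):(j + d)]),
         numeric(1))
}

#' Tensor-product basis for bivariate integrand surfaces
#'
#' Marginal B-spline bases over the probability axis `p` and the quantile
#' axis `q`, combined by row-wise tensor product.  Coefficients are stored
#' with the `p` index varying fastest (column-major vec of the
#' `n_p` x `n_q` coefficient matrix).  Each margin carries its own
#' difference penalty; the full penalty is
#' \eqn{\lambda_p (I_q \otimes P_p) + \lambda_q (P_q \otimes I_p)}.
#'
#' @param basis_p marginal basis over \[0, 1\].
#' @param basis_q marginal basis over the observed quantile range.
#' @return An object of class `tensor_basis`.
#' @export
tensor_basis <- function(basis_p, basis_q) {
  stopifnot(inherits(basis_p, "spline_basis"),
            inherits(basis_q, "spline_basis"))
  structure(list(basis_p = basis_p, basis_q = basis_q,
                 n_basis = basis_p$n_basis * basis_q$n_basis),
            class = "tensor_basis")
}

#' @rdname tensor_basis
#' @param basis a `tensor_basis`.
#' @export
tensor_penalties <- function(basis) {
  stopifnot(inherits(basis, "tensor_basis"))
  mp <- basis$basis_p$n_basis; mq <- basis$basis_q$n_basis
  list(p = kronecker(diag(mq), penalty_matrix(basis$basis_p)),
       q = kronecker(penalty_matrix(basis$basis_q), diag(mp)))
}

#' Row-wise tensor evaluation
#'
#' Evaluates all `n_p * n_q` tensor basis functions at paired points
#' `(p[i], q[i])`.
#'
#' @param basis a `tensor_basis`.
#' @param p,q equal-length coordinate vectors.
#' @return Matrix `length(p)` x `n_basis`.
#' @export
eval_tensor <- function(basis, p, q) {
  stopifnot(inherits(basis, "tensor_basis"), length(p) == length(q))
  Bp <- eval_basis(basis$basis_p, p)
  Bq <- eval_basis(basis$basis_q, q)
  mp <- ncol(Bp); mq <- ncol(Bq)
  Bq[, rep(seq_len(mq), each = mp), drop = FALSE] *
    Bp[, rep(seq_len(mp), times = mq), drop = FALSE]
}

#' Default marginal q-basis covering a quantile matrix
#'
#' The q-range is the observed range of the training quantile matrix,
#' padded by a small relative margin so boundary evaluations stay inside
#' the knot span.
#'
#' @param Q a `quantile_matrix`.
#' @param n_basis marginal basis dimension.
#' @param degree,penalty_order passed to [spline_basis()].
#' @export
q_basis_for <- function(Q, n_basis = 8L, degree = 3L, penalty_order = 2L) {
  r <- range(Q)
  pad <- 1e-8 * max(diff(r), abs(r), 1)
  spline_basis(n_basis = n_basis, degree = degree,
               range = c(r[1] - pad, r[2] + pad),
               penalty_order = penalty_order)
}
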