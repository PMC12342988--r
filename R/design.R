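#' Functional design matrix for scalar-on-function regression
#'
#' Discretizes the functional term by the grid quadrature rule.  For the
#' linear model the columns are
#' \eqn{X_{ij} = \sum_k w_k B_j(p_k) Q_i(p_k)}, so that
#' \eqn{X \theta} approximates \eqn{\int_0^1 \beta(p) Q_i(p)\,dp} with
#' \eqn{\beta = \sum_j \theta_j B_j}.  For the nonlinear model the columns
#' are \eqn{X_{ij} = \sum_k w_k T_j(p_k, Q_i(p_k))} with \eqn{T_j} a
#' tensor basis function, approximating \eqn{\int_0^1 F(p, Q_i(p))\,dp}.
#' On the default midpoint grid the weights are exactly \eqn{1/K}
#' (midpoint rule).
#'
#' @param Q a [quantile_matrix()] (training data).
#' @param basis a [spline_basis()] over \[0, 1\] (linear kind) or a
#'   [tensor_basis()] (nonlinear kind).
#' @param kind `"linear"` or `"nonlinear"`; inferred from the basis class
#'   when omitted.
#' @return An object of class `functional_design`: list with the raw
#'   (uncentered) design matrix `X`, the basis, kind, grid and the
#'   training quantile range.
#' @export
functional_design <- function(Q, basis, kind = NULL) {
  stopifnot(inherits(Q, "quantile_matrix"))
  if (is.null(kind))
    kind <- if (inherits(basis, "tensor_basis")) "nonlinear" else "linear"
  kind <- match.arg(kind, c("linear", "nonlinear"))
  grid <- q_grid(Q)
  w <- grid$w
  if (kind == "linear") {
    stopifnot(inherits(basis, "spline_basis"))
    B <- eval_basis(basis, grid$p)          # K x m
    X <- unclass(Q) %*% (w * B)             # n x m
  } else {
    stopifnot(inherits(basis, "tensor_basis"))
    qr_ <- basis$basis_q$range
    out <- which(apply(Q, 1, function(r) any(r < qr_[1] | r > qr_[2])))
    if (length(out))
      stop("quantile values outside the tensor q-range for subject ",
           rownames(Q)[out[1]],
           "; enlarge the q-basis range (training data must be covered)")
    X <- t(vapply(seq_len(nrow(Q)), function(i) {
      Tm <- eval_tensor(basis, grid$p, Q[i, ])
      as.numeric(crossprod(Tm, w))
    }, numeric(basis$n_basis)))
  }
  rownames(X) <- rownames(Q)
  structure(list(X = X, basis = basis, kind = kind, grid = grid,
                 q_range = range(Q)),
            class = "functional_design")
}
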