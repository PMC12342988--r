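#' Penalized scalar-on-function GLM
#'
#' Fits the functional generalized linear model (linear kind) or
#' functional generalized additive model (nonlinear kind) by maximizing
#' the penalized log-likelihood
#' \deqn{\ell(\theta) - \tfrac12 \sum_r \lambda_r \theta^\top P_r \theta}
#' via iteratively reweighted penalized least squares.  Design columns are
#' centered and an explicit unpenalized intercept is included; the
#' centering offsets are stored on the fit and re-applied at prediction.
#' When `lambda` is not supplied it is selected by generalized
#' cross-validation, \eqn{n \cdot D / (n - \mathrm{edf})^2} with `D` the
#' deviance, over a logarithmic grid (a full 2-D grid for the tensor
#' smooth, one \eqn{\lambda} per penalty direction).
#'
#' Convergence: relative change of the penalized objective below `1e-8`,
#' at most 200 iterations; non-convergence and degenerate binomial
#' weights (quasi-separation) are flagged on the returned object, not
#' fatal.
#'
#' @param design a [functional_design()].
#' @param y numeric response; 0/1 for `family = "binomial"`.
#' @param family `"gaussian"` or `"binomial"`.
#' @param lambda optional fixed smoothing parameter(s): a scalar for the
#'   linear kind, length-2 (p- and q-direction) for the nonlinear kind.
#' @param lambda_grid optional vector of candidate values searched by GCV
#'   (used for each direction of a tensor smooth).
#' @return An object of class `qi_fit` holding coefficients, intercept,
#'   centering offsets, smoothing parameters, effective degrees of
#'   freedom, the GCV path, and convergence diagnostics.
#' @seealso [fit_penalized_cox()] for survival outcomes; [fit_qi_model()]
#'   for the high-level interface.
#' @export
fit_penalized_glm <- function(design, y, family = c("gaussian", "binomial"),
                              lambda = NULL, lambda_grid = NULL) {
  family <- match.arg(family)
  stopifnot(inherits(design, "functional_design"))
  X <- design$X
  n <- nrow(X)
  y <- as.numeric(y)
  if (length(y) != n) stop("length(y) does not match the design")
  if (n < 10L) stop("need at least 10 subjects to fit")
  if (family == "binomial" && !all(y %in% c(0, 1)))
    stop("binomial family requires a 0/1 response")
  Plist <- design_penalties(design)
  offsets <- colMeans(X)
  Xc <- sweep(X, 2, offsets)
  Xd <- cbind(`(Intercept)` = 1, Xc)

  if (is.null(lambda)) {
    grid <- lambda_combos(Plist, lambda_grid)
    # candidates where the penalized system is singular (tiny lambda with
    # a rank-deficient functional design) are skipped, not fatal
    fits <- lapply(grid, function(lam)
      tryCatch(glm_pirls(Xd, y, family, Plist, lam),
               error = function(e) NULL))
    ok <- !vapply(fits, is.null, logical(1))
    if (!any(ok))
      stop("singular penalized system for every candidate lambda; ",
           "reduce n_basis")
    grid <- grid[ok]; fits <- fits[ok]
    gcv <- vapply(fits, `[[`, numeric(1), "gcv")
    best <- which.min(gcv)
    fit <- fits[[best]]
    lambda <- grid[[best]]
    gcv_table <- data.frame(
      do.call(rbind, grid), gcv = gcv,
      edf = vapply(fits, `[[`, numeric(1), "edf"))
    names(gcv_table)[seq_along(Plist)] <- paste0("lambda_", names(Plist))
  } else {
    lambda <- rep_len(as.numeric(lambda), length(Plist))
    fit <- glm_pirls(Xd, y, family, Plist, lambda)
    gcv_table <- NULL
  }

  theta_full <- fit$theta
  structure(list(
    family = family, kind = design$kind,
    coefficients = theta_full,
    intercept = theta_full[1],
    theta = theta_full[-1],
    offsets = offsets,
    lambda = setNames(lambda, names(Plist)),
    basis = design$basis, grid = design$grid, q_range = design$q_range,
    edf = fit$edf, deviance = fit$deviance,
    converged = fit$converged, iterations = fit$iter,
    flags = fit$flags, gcv = fit$gcv, gcv_table = gcv_table,
    fitted_eta = as.numeric(Xd %*% theta_full),
    n = n), class = "qi_fit")
}

# penalty matrices of a design: one for the linear kind, two (p and q
# directions) for the tensor kind
design_penalties <- function(design) {
  if (design$kind == "linear") {
    list(p = penalty_matrix(design$basis))
  } else {
    tensor_penalties(design$basis)
  }
}

lambda_combos <- function(Plist, lambda_grid = NULL) {
  if (is.null(lambda_grid)) {
    lambda_grid <- if (length(Plist) == 1L) {
      10^seq(-8, 8, length.out = 25)
    } else {
      10^seq(-6, 6, length.out = 7)
    }
  }
  if (length(Plist) == 1L) {
    lapply(lambda_grid, function(l) l)
  } else {
    g <- expand.grid(lambda_grid, lambda_grid, KEEP.OUT.ATTRS = FALSE)
    lapply(seq_len(nrow(g)), function(i) as.numeric(g[i, ]))
  }
}

# bordered penalty: zero row/column for the unpenalized intercept
pen_full <- function(Plist, lambda) {
  P <- Reduce(`+`, Map(`*`, Plist, as.list(lambda)))
  rbind(0, cbind(0, P))
}

# Solve the penalized normal equations.  Directions that are flat in both
# the likelihood and the penalty (e.g. the p-only components of a tensor
# surface, whose integral is absorbed by the intercept) make the system
# exactly singular; they are resolved to the minimum-norm solution by an
# escalating, scale-relative ridge applied only when a plain solve fails.
solve_pen <- function(A, b) {
  sc <- mean(abs(diag(A)))
  if (!is.finite(sc) || sc <= 0) sc <- 1
  for (r in c(0, 1e-10, 1e-8, 1e-6)) {
    out <- tryCatch(solve(A + r * sc * diag(nrow(A)), b),
                    error = function(e) NULL)
    if (!is.null(out)) return(out)
  }
  stop("singular penalized system; increase lambda or reduce n_basis",
       call. = FALSE)
}

# penalized IRLS for gaussian / binomial; gaussian converges in one step
glm_pirls <- function(Xd, y, family, Plist, lambda,
                      tol = 1e-8, maxit = 200L) {
  n <- nrow(Xd)
  P <- pen_full(Plist, lambda)
  flags <- character()
  if (family == "gaussian") {
    A <- crossprod(Xd) + P
    theta <- solve_pen(A, crossprod(Xd, y))
    eta <- as.numeric(Xd %*% theta)
    rss <- sum((y - eta)^2)
    edf <- sum(diag(solve_pen(A, crossprod(Xd))))
    return(list(theta = as.numeric(theta), edf = edf, deviance = rss,
                gcv = n * rss / (n - edf)^2,
                converged = TRUE, iter = 1L, flags = flags))
  }
  # binomial
  theta <- numeric(ncol(Xd))
  theta[1] <- qlogis(min(max(mean(y), 1e-3), 1 - 1e-3))
  obj_old <- Inf
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- as.numeric(Xd %*% theta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    A <- crossprod(Xd, w * Xd) + P
    theta <- as.numeric(solve_pen(A, crossprod(Xd, w * z)))
    eta <- as.numeric(Xd %*% theta)
    mu <- plogis(eta)
    ll <- sum(y * log(pmax(mu, 1e-12)) + (1 - y) * log(pmax(1 - mu, 1e-12)))
    obj <- -ll + 0.5 * sum(theta * (P %*% theta))
    if (is.finite(obj_old) &&
        abs(obj_old - obj) < tol * (abs(obj) + tol)) {
      converged <- TRUE
      break
    }
    obj_old <- obj
  }
  if (!converged) flags <- c(flags, "not_converged")
  if (any(abs(eta) > 30)) flags <- c(flags, "quasi_separation")
  w <- pmax(mu * (1 - mu), 1e-10)
  A <- crossprod(Xd, w * Xd) + P
  edf <- sum(diag(solve_pen(A, crossprod(Xd, w * Xd))))
  dev <- -2 * sum(y * log(pmax(mu, 1e-12)) +
                  (1 - y) * log(pmax(1 - mu, 1e-12)))
  list(theta = theta, edf = edf, deviance = dev,
       gcv = n * dev / (n - edf)^2,
       converged = converged, iter = it, flags = flags)
}

#' @export
print.qi_fit <- function(x, ...) {
  cat(sprintf(
    "Penalized scalar-on-function fit (%s, %s kind)\n", x$family, x$kind))
  cat(sprintf("  n = %d, basis dim = %d, edf = %.2f\n",
              x$n, length(x$theta), x$edf))
  cat("  lambda:", paste(sprintf("%s = %.4g", names(x$lambda), x$lambda),
                         collapse = ", "), "\n")
  if (!x$converged) cat("  WARNING: not converged\n")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}
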