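#' Penalized linear / additive functional Cox model
#'
#' Maximizes the penalized Cox partial log-likelihood (Breslow handling of
#' tied event times) by Newton iterations with step halving.  There is no
#' intercept — it is absorbed by the baseline hazard — but design columns
#' are still centered for numerical stability, which leaves the partial
#' likelihood unchanged.  When `lambda` is not supplied it is chosen by
#' 5-fold cross-validated partial likelihood (the Verweij–van Houwelingen
#' criterion \eqn{\sum_k [\ell(\hat\theta_{-k}) - \ell_{-k}(\hat\theta_{-k})]})
#' over a logarithmic grid.  Fold membership is assigned deterministically
#' by rank of the survival time, so repeated fits are reproducible without
#' consuming random numbers.
#'
#' A monotone partial likelihood (coefficients diverging at `lambda = 0`)
#' is flagged and refitted with a small ridge-like floor on `lambda`.
#'
#' @param design a [functional_design()].
#' @param time strictly positive survival/censoring times.
#' @param event 0/1 event indicator; at least 5 events are required.
#' @param lambda optional fixed smoothing parameter(s), as in
#'   [fit_penalized_glm()].
#' @param lambda_grid optional candidate grid for cross-validation.
#' @param nfolds folds for the cross-validated partial likelihood.
#' @return A `qi_fit` object (with `intercept = 0`).
#' @export
fit_penalized_cox <- function(design, time, event, lambda = NULL,
                              lambda_grid = NULL, nfolds = 5L) {
  stopifnot(inherits(design, "functional_design"))
  X <- design$X
  n <- nrow(X)
  time <- as.numeric(time); event <- as.numeric(event)
  if (length(time) != n || length(event) != n)
    stop("time/event length does not match the design")
  if (any(time <= 0)) stop("survival times must be strictly positive")
  if (!all(event %in% c(0, 1))) stop("event indicator must be 0/1")
  if (sum(event) == 0) stop("no events: Cox model cannot be fitted")
  if (sum(event) < 5) stop("fewer than 5 events; fit would be unstable")
  Plist <- design_penalties(design)
  offsets <- colMeans(X)
  Xc <- sweep(X, 2, offsets)

  if (is.null(lambda)) {
    if (is.null(lambda_grid)) {
      lambda_grid <- if (length(Plist) == 1L) {
        10^seq(-6, 6, length.out = 13)
      } else {
        10^seq(-4, 4, length.out = 5)
      }
    }
    combos <- lambda_combos(Plist, lambda_grid)
    folds <- ((rank(time, ties.method = "first") - 1L) %% nfolds) + 1L
    cvpl <- vapply(combos, function(lam) {
      acc <- 0
      for (k in seq_len(nfolds)) {
        tr <- folds != k
        fit_k <- tryCatch(
          cox_newton(Xc[tr, , drop = FALSE], time[tr], event[tr],
                     Plist, lam),
          error = function(e) NULL)
        if (is.null(fit_k)) return(-Inf)   # singular at this lambda: skip
        full <- cox_pl(as.numeric(Xc %*% fit_k$theta), time, event)
        train <- cox_pl(as.numeric(Xc[tr, , drop = FALSE] %*% fit_k$theta),
                        time[tr], event[tr])
        acc <- acc + (full - train)
      }
      acc
    }, numeric(1))
    if (!any(is.finite(cvpl)))
      stop("singular penalized system for every candidate lambda; ",
           "reduce n_basis")
    best <- which.max(cvpl)
    lambda <- combos[[best]]
    cv_table <- data.frame(do.call(rbind, combos), cvpl = cvpl)
    names(cv_table)[seq_along(Plist)] <- paste0("lambda_", names(Plist))
  } else {
    lambda <- rep_len(as.numeric(lambda), length(Plist))
    cv_table <- NULL
  }

  fit <- cox_newton(Xc, time, event, Plist, lambda)
  flags <- fit$flags
  if (all(lambda == 0) &&
      (!fit$converged || "diverging_coefficients" %in% fit$flags)) {
    # monotone likelihood: apply a small lambda floor and refit
    lambda <- rep_len(1e-4, length(Plist))
    fit <- cox_newton(Xc, time, event, Plist, lambda)
    flags <- union(c(flags, "monotone_likelihood"), fit$flags)
  }

  structure(list(
    family = "cox", kind = design$kind,
    coefficients = fit$theta,
    intercept = 0,
    theta = fit$theta,
    offsets = offsets,
    lambda = setNames(lambda, names(Plist)),
    basis = design$basis, grid = design$grid, q_range = design$q_range,
    edf = fit$edf, deviance = -2 * fit$loglik,
    converged = fit$converged, iterations = fit$iter,
    flags = flags, gcv = NA_real_, gcv_table = cv_table,
    fitted_eta = as.numeric(Xc %*% fit$theta),
    n = n), class = "qi_fit")
}

# --- Breslow partial likelihood machinery ----------------------------------
# All functions sort internally by decreasing time so that risk sets are
# prefixes and cumulative sums give the risk-set aggregates S0, S1, S2.

cox_order <- function(time) order(time, decreasing = TRUE)

# positions (in decreasing-time order) of the last member of each tie
# group, the per-group event counts, and the event indicator rows
cox_groups <- function(time_o, event_o) {
  r <- rle(time_o)
  gend <- cumsum(r$lengths)
  d <- vapply(seq_along(gend), function(g) {
    from <- gend[g] - r$lengths[g] + 1L
    sum(event_o[from:gend[g]])
  }, numeric(1))
  keep <- d > 0
  list(gend = gend[keep], d = d[keep])
}

# Breslow partial log-likelihood at a linear predictor
cox_pl <- function(eta, time, event) {
  o <- cox_order(time)
  eta_o <- eta[o]; ev_o <- event[o]
  c_ <- max(eta_o)
  S0 <- cumsum(exp(eta_o - c_))
  g <- cox_groups(time[o], ev_o)
  sum(eta_o[ev_o == 1]) - sum(g$d * (log(S0[g$gend]) + c_))
}

# score and information of the (unpenalized) partial likelihood
cox_deriv <- function(X, time, event, theta) {
  o <- cox_order(time)
  Xo <- X[o, , drop = FALSE]
  ev_o <- event[o]
  eta_o <- as.numeric(Xo %*% theta)
  c_ <- max(eta_o)
  e <- exp(eta_o - c_)
  m <- ncol(X)
  S0 <- cumsum(e)
  S1 <- apply(Xo * e, 2, cumsum)
  if (length(S0) == 1L) S1 <- matrix(S1, nrow = 1L)
  iu <- which(upper.tri(diag(m), diag = TRUE), arr.ind = TRUE)
  Z <- Xo[, iu[, 1], drop = FALSE] * Xo[, iu[, 2], drop = FALSE] * e
  S2 <- apply(Z, 2, cumsum)
  if (nrow(Xo) == 1L) S2 <- matrix(S2, nrow = 1L)
  g <- cox_groups(time[o], ev_o)
  grad <- colSums(Xo[ev_o == 1, , drop = FALSE])
  info <- matrix(0, m, m)
  M <- matrix(0, m, m)
  for (j in seq_along(g$gend)) {
    i0 <- g$gend[j]; dg <- g$d[j]
    xbar <- S1[i0, ] / S0[i0]
    grad <- grad - dg * xbar
    M[cbind(iu[, 1], iu[, 2])] <- S2[i0, ]
    M[cbind(iu[, 2], iu[, 1])] <- S2[i0, ]
    info <- info + dg * (M / S0[i0] - tcrossprod(xbar))
  }
  ll <- sum(eta_o[ev_o == 1]) - sum(g$d * (log(S0[g$gend]) + c_))
  list(loglik = ll, grad = grad, info = info)
}

# penalized Newton iterations with step halving
cox_newton <- function(X, time, event, Plist, lambda,
                       tol = 1e-8, maxit = 200L) {
  m <- ncol(X)
  P <- Reduce(`+`, Map(`*`, Plist, as.list(lambda)))
  theta <- numeric(m)
  d0 <- cox_deriv(X, time, event, theta)
  obj <- d0$loglik - 0.5 * sum(theta * (P %*% theta))
  converged <- FALSE
  flags <- character()
  it <- 0L
  for (it in seq_len(maxit)) {
    d <- cox_deriv(X, time, event, theta)
    grad_pen <- d$grad - as.numeric(P %*% theta)
    H_pen <- d$info + P
    step <- solve_pen(H_pen, grad_pen)
    s <- 1
    repeat {
      theta_new <- theta + s * step
      d_new <- cox_pl(as.numeric(X %*% theta_new), time, event)
      obj_new <- d_new - 0.5 * sum(theta_new * (P %*% theta_new))
      if (is.finite(obj_new) && obj_new >= obj - 1e-12) break
      s <- s / 2
      if (s < 1e-10) { theta_new <- theta; obj_new <- obj; break }
    }
    done <- abs(obj_new - obj) < tol * (abs(obj_new) + tol)
    theta <- theta_new
    obj <- obj_new
    if (done) { converged <- TRUE; break }
  }
  if (!converged) flags <- c(flags, "not_converged")
  if (max(abs(theta)) > 50) flags <- c(flags, "diverging_coefficients")
  d <- cox_deriv(X, time, event, theta)
  H_pen <- d$info + P
  edf <- tryCatch(sum(diag(solve(H_pen, d$info))), error = function(e) NA_real_)
  list(theta = theta, loglik = d$loglik, edf = edf,
       converged = converged, iter = it, flags = flags)
}
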