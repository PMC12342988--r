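#' Integrand surface of a fitted quantile-index model
#'
#' The estimated integrand surface is
#' \deqn{\hat S(p, q) = \hat\beta(p)\,q \quad \textrm{(linear kind)}
#'   \qquad \hat S(p, q) = \hat F(p, q) \quad \textrm{(nonlinear kind)}}
#' defined for \eqn{p \in [0, 1]} and `q` in the training quantile range.
#' Integrating the sign-adjusted surface
#' \eqn{\hat S^*(p,q) = \hat c \cdot \hat S(p,q)} along a subject's
#' quantile path \eqn{(p, Q_i(p))} yields that subject's quantile index.
#' The sign factor is initialized to +1 (unadjusted); see [sign_adjust()].
#'
#' @param model a converged `qi_fit`.
#' @return An object of class `integrand_surface`.
#' @export
integrand_surface <- function(model) {
  stopifnot(inherits(model, "qi_fit"))
  structure(list(model = model, c_hat = 1L, p_tilde = NA_real_,
                 q_range = model$q_range),
            class = "integrand_surface")
}

#' @export
print.integrand_surface <- function(x, ...) {
  cat(sprintf(
    "Integrand surface (%s kind, %s family): sign %+d%s, q-range [%.4g, %.4g]\n",
    x$model$kind, x$model$family, x$c_hat,
    if (is.na(x$p_tilde)) " (unadjusted)"
    else sprintf(" at p~ = %.3g", x$p_tilde),
    x$q_range[1], x$q_range[2]))
  invisible(x)
}

#' Evaluate an integrand surface at paired points
#'
#' @param surface an `integrand_surface`.
#' @param p,q equal-length (or recyclable) coordinate vectors.
#' @param adjusted apply the sign factor (default).
#' @return Numeric vector of surface values.
#' @export
surface_eval <- function(surface, p, q, adjusted = TRUE) {
  stopifnot(inherits(surface, "integrand_surface"))
  n <- max(length(p), length(q))
  p <- rep_len(as.numeric(p), n); q <- rep_len(as.numeric(q), n)
  m <- surface$model
  s <- if (m$kind == "linear") {
    as.numeric(eval_basis(m$basis, p) %*% m$theta) * q
  } else {
    as.numeric(eval_tensor(m$basis, p, q) %*% m$theta)
  }
  if (adjusted) s * as.numeric(surface$c_hat) else s
}

#' Sign-adjust an integrand surface (optional part of Step 2)
#'
#' Sets the sign factor \eqn{\hat c = \mathrm{sign}\{\mathrm{corr}(Q_i(\tilde p),
#' \widehat{QI}_i)\}} so that the quantile indices correlate positively
#' with the quantile at a reference probability \eqn{\tilde p} (default
#' 0.5, the median), easing interpretation.  The correlation is Pearson's,
#' computed between the training subjects' unadjusted indices and their
#' quantiles at the grid point nearest \eqn{\tilde p}.  An exactly zero or
#' undefined correlation (constant \eqn{Q_i(\tilde p)}) keeps
#' \eqn{\hat c = +1}; the adjustment is therefore idempotent, and the sign
#' is fixed at training time and reused for test data.
#'
#' @param surface an `integrand_surface`.
#' @param Q_train the training [quantile_matrix()].
#' @param p_tilde reference probability in (0, 1); snapped to the nearest
#'   grid point.
#' @return The surface with `c_hat` and `p_tilde` set.
#' @export
sign_adjust <- function(surface, Q_train, p_tilde = 0.5) {
  stopifnot(inherits(surface, "integrand_surface"),
            inherits(Q_train, "quantile_matrix"),
            p_tilde > 0, p_tilde < 1)
  g <- q_grid(Q_train)
  k <- which.min(abs(g$p - p_tilde))
  base <- surface
  base$c_hat <- 1L
  qi0 <- compute_qi(base, Q_train)$qi
  r <- suppressWarnings(cor(Q_train[, k], qi0))
  if (!is.finite(r)) {
    warning("correlation with Q(p~) undefined (constant quantile); ",
            "keeping sign +1")
    c_hat <- 1L
  } else if (r == 0) {
    c_hat <- 1L
  } else {
    c_hat <- as.integer(sign(r))
  }
  surface$c_hat <- c_hat
  surface$p_tilde <- g$p[k]
  surface$sign_cor <- r  # unadjusted correlation, for diagnostics
  surface
}

#' Compute quantile indices along subject quantile paths (Step 3)
#'
#' For each subject the index is the quadrature sum
#' \eqn{\widehat{QI}_i = \sum_k w_k \hat S^*(p_k, Q_i(p_k))} — the area
#' under the projection of the subject's integrand path onto the
#' \eqn{(p, s)}-plane.  Works for training data or an independent test
#' set.  Test subjects whose quantiles leave the training q-range are
#' flagged; for the nonlinear kind their `q` values are clamped to the
#' training range before evaluation (tensor splines are unreliable outside
#' the fitted range), while the linear surface extends naturally.
#'
#' @param surface an `integrand_surface` (sign-adjusted or not).
#' @param Q a [quantile_matrix()]; its own grid is used for quadrature, so
#'   train and test grids may differ.
#' @return An object of class `qi_result`: a data.frame with columns
#'   `subject_id`, `qi`, `extrapolated`, and attributes recording the
#'   index kind (QI / nlQI), sign factor and reference probability.
#' @export
compute_qi <- function(surface, Q) {
  stopifnot(inherits(surface, "integrand_surface"),
            inherits(Q, "quantile_matrix"))
  g <- q_grid(Q)
  m <- surface$model
  r <- surface$q_range
  extrap <- apply(Q, 1, function(row) any(row < r[1] | row > r[2]))
  if (m$kind == "linear") {
    b <- as.numeric(eval_basis(m$basis, g$p) %*% m$theta)
    qi <- as.numeric(unclass(Q) %*% (g$w * b))
  } else {
    Qc <- pmin(pmax(unclass(Q), r[1]), r[2])
    qi <- vapply(seq_len(nrow(Q)), function(i) {
      sum(g$w * as.numeric(eval_tensor(m$basis, g$p, Qc[i, ]) %*% m$theta))
    }, numeric(1))
  }
  qi <- qi * as.numeric(surface$c_hat)
  out <- data.frame(subject_id = rownames(Q), qi = qi,
                    extrapolated = as.integer(extrap),
                    stringsAsFactors = FALSE)
  structure(out, class = c("qi_result", "data.frame"),
            kind = if (m$kind == "linear") "QI" else "nlQI",
            c_hat = surface$c_hat, p_tilde = surface$p_tilde,
            family = m$family)
}

#' Evaluate a quantile index as an outcome predictor
#'
#' Reports the association between the computed indices and the outcome:
#' Pearson correlation and R-squared for continuous outcomes, AUC for
#' binary outcomes, Harrell's concordance (index treated as a risk score)
#' for survival.  Evaluations on the training set are labelled optimistic:
#' indices optimized on the same data overstate out-of-sample performance,
#' so report test-set values for any claim about predictive value.
#'
#' @param result a `qi_result` from [compute_qi()].
#' @param outcomes an [outcome_table()] overlapping `result` in at least
#'   3 subjects.
#' @param training set `TRUE` when `result` was computed on the subjects
#'   the model was fitted to.
#' @return A list of class `qi_evaluation` with the metric name, value,
#'   number of subjects and the `optimistic` label.
#' @export
evaluate_predictor <- function(result, outcomes, training = FALSE) {
  stopifnot(inherits(result, "qi_result"), inherits(outcomes, "outcome_table"))
  kind <- attr(outcomes, "kind")
  idx <- match(result$subject_id, outcomes$subject_id)
  keep <- !is.na(idx) & is.finite(result$qi)
  if (sum(keep) < 3L)
    stop("fewer than 3 overlapping subjects with finite indices")
  qi <- result$qi[keep]
  oc <- outcomes[idx[keep], , drop = FALSE]
  metrics <- switch(kind,
    continuous = {
      r <- cor(qi, oc$y)
      list(metric = "pearson_r", value = r, r_squared = r^2)
    },
    binary = {
      roc <- pROC::roc(response = oc$y, predictor = qi,
                       levels = c(0, 1), direction = "<", quiet = TRUE)
      list(metric = "auc", value = as.numeric(pROC::auc(roc)))
    },
    survival = {
      cc <- survival::concordance(
        survival::Surv(oc$time, oc$event) ~ qi, reverse = TRUE)
      list(metric = "concordance", value = as.numeric(cc$concordance))
    })
  structure(c(metrics,
              list(outcome_kind = kind, n = sum(keep),
                   n_extrapolated = sum(result$extrapolated[keep]),
                   optimistic = isTRUE(training))),
            class = "qi_evaluation")
}

#' @export
print.qi_evaluation <- function(x, ...) {
  cat(sprintf("Quantile-index evaluation (%s outcome, n = %d)\n",
              x$outcome_kind, x$n))
  cat(sprintf("  %s = %.4f%s\n", x$metric, x$value,
              if (x$optimistic)
                "  [training data: optimistically biased]" else ""))
  if (x$n_extrapolated > 0)
    cat("  note:", x$n_extrapolated, "subjects flagged as extrapolated\n")
  invisible(x)
}
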