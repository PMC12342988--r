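#' Fit a quantile-index model (Step 2)
#'
#' High-level interface: builds the basis and functional design from a
#' subject-level quantile matrix and dispatches to the penalized GLM or
#' Cox engine.  The family is taken from the outcome table when not given
#' (continuous -> gaussian, binary -> binomial, survival -> cox).
#'
#' @param Q a [quantile_matrix()] of training subjects.
#' @param outcomes an [outcome_table()] covering the subjects of `Q`, or a
#'   plain numeric vector aligned with `rownames(Q)` (gaussian/binomial).
#' @param kind `"linear"` (coefficient function beta(p), giving QI) or
#'   `"nonlinear"` (bivariate surface F(p, q), giving nlQI).
#' @param family `"gaussian"`, `"binomial"` or `"cox"`; default inferred
#'   from `outcomes`.
#' @param n_basis basis dimension for beta(p) (linear kind).
#' @param n_basis_p,n_basis_q marginal dimensions of the tensor surface
#'   (nonlinear kind).
#' @param lambda optional fixed smoothing parameter(s); selected by
#'   GCV / cross-validated partial likelihood when omitted.
#' @param ... passed to the fitting engine (e.g. `lambda_grid`).
#' @return A `qi_fit` object.
#' @examples
#' cfg <- sim_config(n_subjects = 40, seed = 7)
#' cells <- simulate_cells(cfg)
#' Q <- aggregate_quantile(grouped_samples(cells, "intensity"))
#' sim <- simulate_outcomes(cfg, Q)
#' fit <- fit_qi_model(Q, sim$outcomes, kind = "linear")
#' @export
fit_qi_model <- function(Q, outcomes, kind = c("linear", "nonlinear"),
                         family = NULL, n_basis = 10L,
                         n_basis_p = 8L, n_basis_q = 8L,
                         lambda = NULL, ...) {
  kind <- match.arg(kind)
  stopifnot(inherits(Q, "quantile_matrix"))
  if (inherits(outcomes, "outcome_table")) {
    idx <- match(rownames(Q), outcomes$subject_id)
    if (any(is.na(idx)))
      stop("outcomes missing for subject ",
           rownames(Q)[which(is.na(idx))[1]],
           "; use join_outcomes() first")
    outcomes <- outcomes[idx, , drop = FALSE]
    okind <- attr(outcomes, "kind")
    if (is.null(family))
      family <- c(continuous = "gaussian", binary = "binomial",
                  survival = "cox")[[okind]]
  } else if (is.null(family)) {
    family <- "gaussian"
  }
  family <- match.arg(family, c("gaussian", "binomial", "cox"))

  basis <- if (kind == "linear") {
    spline_basis(n_basis = n_basis, range = c(0, 1))
  } else {
    tensor_basis(spline_basis(n_basis = n_basis_p, range = c(0, 1)),
                 q_basis_for(Q, n_basis = n_basis_q))
  }
  design <- functional_design(Q, basis, kind)
  fit <- if (family == "cox") {
    fit_penalized_cox(design, outcomes$time, outcomes$event,
                      lambda = lambda, ...)
  } else {
    y <- if (is.numeric(outcomes)) outcomes else outcomes$y
    fit_penalized_glm(design, y, family = family, lambda = lambda, ...)
  }
  fit$subjects <- rownames(Q)
  fit
}

#' Evaluate the fitted coefficient function beta(p)
#'
#' Linear kind only: \eqn{\hat\beta(p) = \sum_j \hat\theta_j B_j(p)}.
#'
#' @param model a `qi_fit` of linear kind.
#' @param p probabilities at which to evaluate.
#' @export
beta_hat <- function(model, p) {
  stopifnot(inherits(model, "qi_fit"))
  if (model$kind != "linear")
    stop("beta_hat() is defined for the linear kind only")
  as.numeric(eval_basis(model$basis, p) %*% model$theta)
}

#' Serialize / restore a fitted model as JSON
#'
#' Stores the basis specification (knots, degree), coefficients,
#' smoothing parameters, centering offsets, training q-range and — when
#' attached via [sign_adjust()] — the sign factor and reference
#' probability, so a model fitted in one session can score new subjects
#' in another.
#'
#' @param model a `qi_fit`, or an `integrand_surface` wrapping one.
#' @param path output (input) file path.
#' @export
model_to_json <- function(model, path) {
  surf <- NULL
  if (inherits(model, "integrand_surface")) {
    surf <- list(c_hat = model$c_hat, p_tilde = model$p_tilde)
    model <- model$model
  }
  stopifnot(inherits(model, "qi_fit"))
  b <- model$basis
  basis_spec <- if (model$kind == "linear") {
    list(kind = "linear", n_basis = b$n_basis, degree = b$degree,
         range = b$range, penalty_order = b$penalty_order)
  } else {
    list(kind = "nonlinear",
         p = list(n_basis = b$basis_p$n_basis, degree = b$basis_p$degree,
                  range = b$basis_p$range,
                  penalty_order = b$basis_p$penalty_order),
         q = list(n_basis = b$basis_q$n_basis, degree = b$basis_q$degree,
                  range = b$basis_q$range,
                  penalty_order = b$basis_q$penalty_order))
  }
  obj <- list(package = "quindex", object = "qi_fit",
              family = model$family, kind = model$kind,
              basis = basis_spec,
              theta = model$theta, intercept = model$intercept,
              offsets = model$offsets, lambda = as.list(model$lambda),
              q_range = model$q_range, grid_p = model$grid$p,
              edf = model$edf, converged = model$converged,
              surface = surf)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname model_to_json
#' @export
model_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$object, "qi_fit")) stop("not a serialized qi_fit: ", path)
  basis <- if (obj$kind == "linear") {
    spline_basis(obj$basis$n_basis, obj$basis$degree,
                 as.numeric(obj$basis$range), obj$basis$penalty_order)
  } else {
    tensor_basis(
      spline_basis(obj$basis$p$n_basis, obj$basis$p$degree,
                   as.numeric(obj$basis$p$range), obj$basis$p$penalty_order),
      spline_basis(obj$basis$q$n_basis, obj$basis$q$degree,
                   as.numeric(obj$basis$q$range), obj$basis$q$penalty_order))
  }
  model <- structure(list(
    family = obj$family, kind = obj$kind,
    theta = as.numeric(obj$theta), intercept = as.numeric(obj$intercept),
    coefficients = c(obj$intercept, obj$theta),
    offsets = as.numeric(obj$offsets),
    lambda = unlist(obj$lambda),
    basis = basis, grid = prob_grid(p = as.numeric(obj$grid_p)),
    q_range = as.numeric(obj$q_range),
    edf = obj$edf, converged = isTRUE(obj$converged),
    flags = character(), n = NA_integer_), class = "qi_fit")
  surface <- integrand_surface(model)
  if (!is.null(obj$surface)) {
    surface$c_hat <- as.integer(obj$surface$c_hat)
    surface$p_tilde <- as.numeric(obj$surface$p_tilde)
  }
  surface
}
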