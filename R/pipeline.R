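#' Run configuration for the end-to-end pipeline
#'
#' Collects every knob of a quantile-index run: input paths, column
#' mappings, probability grid, aggregation method, model kind and family,
#' smoothing-parameter policy, sign adjustment, seed and output
#' directory.  The full configuration is serialized next to every output
#' as a provenance record.  Train/test splitting is the caller's
#' responsibility: the pipeline fits on the files it is given and
#' [predict_qi_csv()] scores held-out files with the saved model.
#'
#' @param cells path to the long per-cell CSV.
#' @param outcomes path to the subject-level outcome CSV.
#' @param out_dir output directory (created if needed).
#' @param subject_col,cluster_col,value_col column mappings for the cell
#'   file.
#' @param outcome_kind `"continuous"`, `"binary"` or `"survival"`.
#' @param K probability grid size.
#' @param aggregate point-wise aggregation method.
#' @param kind model kind (`"linear"` / `"nonlinear"`).
#' @param family model family, or `NULL` to infer from `outcome_kind`.
#' @param lambda `"auto"` or fixed numeric value(s).
#' @param sign_adjust apply the sign adjustment.
#' @param p_tilde reference probability for the sign adjustment.
#' @param log_intensity take `log()` of the intensity column at ingestion
#'   (for raw-scale exports; quantiles are computed on values as given).
#' @param seed seed recorded and used for any stochastic step.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(cells, outcomes, out_dir = ".",
                       subject_col = "subject_id",
                       cluster_col = "cluster_id",
                       value_col = "intensity",
                       outcome_kind = "continuous",
                       K = 100L, aggregate = "mean",
                       kind = "linear", family = NULL,
                       lambda = "auto", sign_adjust = TRUE,
                       p_tilde = 0.5, log_intensity = FALSE,
                       seed = 1L) {
  outcome_kind <- match.arg(outcome_kind,
                            c("continuous", "binary", "survival"))
  aggregate <- match.arg(aggregate, c("mean", "median", "min", "max"))
  kind <- match.arg(kind, c("linear", "nonlinear"))
  if (!is.null(family))
    family <- match.arg(family, c("gaussian", "binomial", "cox"))
  if (!identical(lambda, "auto")) lambda <- as.numeric(lambda)
  stopifnot(p_tilde > 0, p_tilde < 1, K >= 2)
  structure(list(cells = cells, outcomes = outcomes, out_dir = out_dir,
                 subject_col = subject_col, cluster_col = cluster_col,
                 value_col = value_col, outcome_kind = outcome_kind,
                 K = as.integer(K), aggregate = aggregate,
                 kind = kind, family = family, lambda = lambda,
                 sign_adjust = isTRUE(sign_adjust), p_tilde = p_tilde,
                 log_intensity = isTRUE(log_intensity),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' @rdname run_config
#' @param path a YAML file whose keys are `run_config()` arguments.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  do.call(run_config, yaml::read_yaml(path))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "': ", conditionMessage(e),
         call. = FALSE))
}

#' Execute the full quantile-index pipeline
#'
#' Step 1 (aggregate quantiles) -> Step 2 (fit + optional sign
#' adjustment) -> Step 3 (compute indices, evaluate on the training data,
#' labelled optimistic).  All artifacts are computed first and written
#' together at the end, so a failing stage leaves no partial outputs:
#' `quantiles.csv`, `model.json`, `qi.csv`, `evaluation.json` and
#' `provenance.json` (config, package and R versions, seed).
#'
#' @param config a [run_config()] (or path to its YAML file).
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with the in-memory artifacts and the output
#'   paths.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(...)

  cells <- stage("read", {
    df <- read_cells_csv(config$cells, config$subject_col,
                         config$cluster_col, config$value_col,
                         quiet = quiet)
    if (config$log_intensity) {
      if (any(df[[config$value_col]] <= 0))
        stop("log transform requested but non-positive intensities present")
      df[[config$value_col]] <- log(df[[config$value_col]])
    }
    df
  })
  grouped <- stage("group", grouped_samples(cells, config$value_col))
  outcomes <- stage("outcomes", {
    odf <- read.csv(config$outcomes, stringsAsFactors = FALSE)
    outcome_table(odf, config$outcome_kind)
  })
  joined <- stage("join", join_outcomes(grouped, outcomes, quiet = quiet))
  say("Step 1: aggregated quantiles (K = ", config$K,
      ", method = ", config$aggregate, ")")
  Q <- stage("quantiles",
             aggregate_quantile(joined$grouped, prob_grid(config$K),
                                config$aggregate))
  say("Step 2: fitting ", config$kind, " scalar-on-function model")
  set.seed(config$seed)
  fit <- stage("fit", fit_qi_model(
    Q, joined$outcomes, kind = config$kind, family = config$family,
    lambda = if (identical(config$lambda, "auto")) NULL else config$lambda))
  surface <- integrand_surface(fit)
  if (config$sign_adjust)
    surface <- stage("sign_adjust",
                     sign_adjust(surface, Q, config$p_tilde))
  say("Step 3: computing quantile indices")
  qi <- stage("predict", compute_qi(surface, Q))
  eval_ <- stage("evaluate",
                 evaluate_predictor(qi, joined$outcomes, training = TRUE))

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(config$out_dir,
                     c(quantiles = "quantiles.csv", model = "model.json",
                       qi = "qi.csv", evaluation = "evaluation.json",
                       provenance = "provenance.json"))
  names(paths) <- c("quantiles", "model", "qi", "evaluation", "provenance")
  stage("write", {
    write_quantiles_csv(Q, paths[["quantiles"]])
    model_to_json(surface, paths[["model"]])
    write.csv(as.data.frame(qi), paths[["qi"]], row.names = FALSE)
    jsonlite::write_json(
      list(metric = eval_$metric, value = eval_$value,
           outcome_kind = eval_$outcome_kind, n = eval_$n,
           optimistic = eval_$optimistic),
      paths[["evaluation"]], auto_unbox = TRUE, digits = NA)
    cfg <- config
    cfg$family <- fit$family
    jsonlite::write_json(
      list(config = unclass(cfg),
           lambda_used = as.list(fit$lambda),
           package_version = as.character(utils::packageVersion("quindex")),
           r_version = R.version.string,
           seed = config$seed),
      paths[["provenance"]], auto_unbox = TRUE, digits = NA)
  })
  say("Wrote artifacts to ", config$out_dir)
  invisible(list(Q = Q, fit = fit, surface = surface, qi = qi,
                 evaluation = eval_, paths = paths))
}

#' Score a quantile CSV with a saved model
#'
#' Companion to [run_pipeline()] for independent test data: loads a
#' `model.json`, reads subject-level quantiles, computes (sign-adjusted)
#' indices with the training-time sign factor and writes
#' `subject_id, qi, extrapolated`.
#'
#' @param model_path path to a `model.json` written by the pipeline.
#' @param quantiles_path CSV written by [write_quantiles_csv()].
#' @param out_path output CSV.
#' @return Invisibly, the `qi_result`.
#' @export
predict_qi_csv <- function(model_path, quantiles_path, out_path) {
  surface <- model_from_json(model_path)
  Q <- read_quantiles_csv(quantiles_path)
  qi <- compute_qi(surface, Q)
  write.csv(as.data.frame(qi), out_path, row.names = FALSE)
  invisible(qi)
}
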