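#' Read a long-format single-cell intensity table
#'
#' Reads a CSV with one row per cell and standardizes it to the columns
#' `subject_id`, `cluster_id` plus one numeric column per marker.  The
#' nesting is always subject -> cluster -> cell (exactly two grouping
#' levels, e.g. patient/ROI or patient/TMA-core); cluster labels may be
#' reused across subjects because they are interpreted as nested within
#' subject everywhere downstream.
#'
#' Rows with non-finite marker values are dropped (with a reported count)
#' when `drop_nonfinite = TRUE`; otherwise they raise an error, since a
#' quantile function has no meaningful NaN semantics.
#'
#' @param path path to a CSV file, one row per cell.
#' @param subject_col,cluster_col names of the subject and cluster id
#'   columns in the file.
#' @param value_cols character vector of marker (intensity) column names;
#'   by default every numeric column other than the id columns.
#' @param drop_nonfinite drop rows with non-finite marker values (default)
#'   instead of failing.
#' @param quiet suppress the dropped-row message.
#'
#' @return A `data.frame` with columns `subject_id`, `cluster_id` and one
#'   column per marker; attribute `n_dropped` records dropped rows.
#' @seealso [grouped_samples()] to nest the result by subject and cluster.
#' @export
read_cells_csv <- function(path, subject_col = "subject_id",
                           cluster_col = "cluster_id", value_cols = NULL,
                           drop_nonfinite = TRUE, quiet = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0L) stop("empty input: no cell rows in ", path)
  roles <- c(subject = subject_col, cluster = cluster_col)
  for (r in names(roles)) {
    if (!roles[[r]] %in% names(df))
      stop("configuration error: column '", roles[[r]], "' (role: ", r,
           ") not present in ", path)
  }
  if (is.null(value_cols)) {
    value_cols <- setdiff(names(df)[vapply(df, is.numeric, logical(1))],
                          c(subject_col, cluster_col))
    if (length(value_cols) == 0L)
      stop("no numeric marker columns found in ", path)
  } else {
    missing <- setdiff(value_cols, names(df))
    if (length(missing))
      stop("configuration error: column '", missing[1],
           "' (role: value) not present in ", path)
  }
  out <- data.frame(subject_id = as.character(df[[subject_col]]),
                    cluster_id = as.character(df[[cluster_col]]),
                    stringsAsFactors = FALSE)
  for (v in value_cols) out[[v]] <- as.numeric(df[[v]])
  ok <- rowSums(!is.finite(as.matrix(out[value_cols]))) == 0L
  n_dropped <- sum(!ok)
  if (n_dropped > 0L) {
    if (!drop_nonfinite)
      stop(n_dropped, " rows carry non-finite marker values; ",
           "set drop_nonfinite = TRUE to drop them")
    out <- out[ok, , drop = FALSE]
    if (!quiet)
      message("read_cells_csv: dropped ", n_dropped,
              " rows with non-finite marker values")
    if (nrow(out) == 0L) stop("empty input: all rows dropped as non-finite")
  }
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Nest per-cell intensities by subject and cluster
#'
#' Builds the nested subject -> cluster -> cell-value structure that the
#' quantile step consumes, for a single marker.  Cluster labels are
#' namespaced by subject (two subjects may reuse the label "core1" without
#' collision), input cell order is preserved within each cluster, and the
#' total cell count is conserved.
#'
#' @param cells a long `data.frame` with columns `subject_id`, `cluster_id`
#'   and at least the column named by `marker` (as produced by
#'   [read_cells_csv()] or [simulate_cells()]).
#' @param marker name of the intensity column to extract.
#'
#' @return An object of class `grouped_samples`: a list with `data`
#'   (named list subject -> named list cluster -> numeric vector) and
#'   `marker`.
#' @export
grouped_samples <- function(cells, marker) {
  stopifnot(is.data.frame(cells))
  if (nrow(cells) == 0L) stop("empty input: no cell records")
  for (col in c("subject_id", "cluster_id"))
    if (!col %in% names(cells)) stop("'cells' lacks column ", col)
  if (!marker %in% names(cells))
    stop("marker '", marker, "' absent from the cell records")
  vals <- as.numeric(cells[[marker]])
  if (any(!is.finite(vals))) {
    bad <- unique(cells$subject_id[!is.finite(vals)])
    stop("marker '", marker, "' has non-finite values for subject ",
         bad[1], "; drop them at ingestion (drop_nonfinite)")
  }
  subj <- factor(cells$subject_id, levels = unique(cells$subject_id))
  data <- lapply(split(seq_len(nrow(cells)), subj), function(idx) {
    cl <- factor(cells$cluster_id[idx], levels = unique(cells$cluster_id[idx]))
    lapply(split(vals[idx], cl), as.numeric)
  })
  structure(list(data = data, marker = marker), class = "grouped_samples")
}

#' @export
print.grouped_samples <- function(x, ...) {
  ncl <- vapply(x$data, length, integer(1))
  cat(sprintf(
    "Grouped single-cell samples: marker '%s'\n  %d subjects, %d clusters, %d cells\n",
    x$marker, length(x$data), sum(ncl), n_cells(x)))
  invisible(x)
}

#' @rdname grouped_samples
#' @param grouped a `grouped_samples` object.
#' @export
subjects <- function(grouped) names(grouped$data)

#' @rdname grouped_samples
#' @export
n_cells <- function(grouped) {
  sum(vapply(grouped$data, function(cl) sum(lengths(cl)), numeric(1)))
}

#' Flatten grouped samples back to a long table
#'
#' Inverse of [grouped_samples()]; writing the result with
#' [write.csv()] and re-reading reproduces the identical nested vectors.
#'
#' @param x a `grouped_samples` object.
#' @param row.names,optional,... ignored (S3 signature).
#' @export
as.data.frame.grouped_samples <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  rows <- lapply(names(x$data), function(s) {
    cl <- x$data[[s]]
    data.frame(subject_id = s,
               cluster_id = rep(names(cl), lengths(cl)),
               value = unlist(cl, use.names = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[3] <- x$marker
  rownames(out) <- NULL
  out
}

#' Subject-level outcome table
#'
#' Validates and types a subject-level outcome table.  Continuous and
#' binary outcomes use column `y`; survival outcomes use `time` (strictly
#' positive) and `event` (0/1).  Any additional numeric columns are kept
#' as scalar covariates.
#'
#' @param df a data.frame with a `subject_id` column plus outcome columns.
#' @param kind one of `"continuous"`, `"binary"`, `"survival"`.
#' @return The validated data.frame, classed `outcome_table`, with
#'   attribute `kind`.
#' @export
outcome_table <- function(df, kind = c("continuous", "binary", "survival")) {
  kind <- match.arg(kind)
  stopifnot(is.data.frame(df))
  if (!"subject_id" %in% names(df)) stop("'df' lacks column subject_id")
  df$subject_id <- as.character(df$subject_id)
  if (anyDuplicated(df$subject_id))
    stop("duplicated subject_id in the outcome table")
  if (kind == "survival") {
    for (col in c("time", "event"))
      if (!col %in% names(df)) stop("survival outcomes need column ", col)
    if (any(!is.finite(df$time)) || any(df$time <= 0))
      stop("survival times must be strictly positive")
    if (!all(df$event %in% c(0, 1)))
      stop("event indicator must be 0/1")
  } else {
    if (!"y" %in% names(df)) stop(kind, " outcomes need column y")
    if (any(!is.finite(df$y))) stop("outcome y must be finite")
    if (kind == "binary" && !all(df$y %in% c(0, 1)))
      stop("binary outcome y must be 0/1")
  }
  structure(df, class = c("outcome_table", "data.frame"), kind = kind)
}

#' Match grouped samples with their outcomes
#'
#' Inner join on subject id: subjects present in only one input are
#' reported and dropped; an empty intersection is an error.
#'
#' @param grouped a `grouped_samples` object.
#' @param outcomes an `outcome_table`.
#' @param quiet suppress the exclusion message.
#' @return A list with the subsetted `grouped` and `outcomes`, aligned to
#'   the same subject order.
#' @export
join_outcomes <- function(grouped, outcomes, quiet = FALSE) {
  stopifnot(inherits(grouped, "grouped_samples"),
            inherits(outcomes, "outcome_table"))
  gs <- subjects(grouped)
  os <- outcomes$subject_id
  common <- intersect(gs, os)
  if (length(common) == 0L)
    stop("no subjects in common between cell data and outcomes")
  n_excl <- (length(gs) - length(common)) + (length(os) - length(common))
  if (n_excl > 0L && !quiet)
    message("join_outcomes: excluded ", n_excl,
            " subjects present in only one input")
  grouped$data <- grouped$data[common]
  kind <- attr(outcomes, "kind")
  out <- outcomes[match(common, os), , drop = FALSE]
  rownames(out) <- NULL
  list(grouped = grouped,
       outcomes = structure(out, class = class(outcomes), kind = kind))
}
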