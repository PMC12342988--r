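#' Numeric data behind an integrand-surface plot
#'
#' Computes every series a surface plot renders, using only the public
#' quantile / index operations, so plots never drift from the computation:
#' the surface evaluated on a rendering grid, each overlaid subject's
#' integration path \eqn{(p_k, Q_i(p_k), \hat S^*(p_k, Q_i(p_k)))}, its
#' projections onto the (p, q)-plane (the sample quantile function) and
#' onto the (p, s)-plane (whose quadrature area equals the subject's
#' index), and — for the linear kind — the \eqn{\hat\beta(p)} curve.
#'
#' @param surface an [integrand_surface()].
#' @param Q a [quantile_matrix()] supplying the paths.
#' @param subjects subject ids (or indices) to overlay; default all, capped
#'   at `max_subjects` with a warning and deterministic subsampling.
#' @param resolution rendering grid size per axis (independent of the
#'   analysis grid).
#' @param max_subjects overlay cap.
#' @return A list with elements `p`, `q`, `S` (resolution x resolution),
#'   `paths` (per subject: data.frame p/q/s), `indices` (named, equal to
#'   [compute_qi()] values), `beta` (or NULL) and `q_range`.
#' @export
surface_plot_data <- function(surface, Q, subjects = NULL, resolution = 50L,
                              max_subjects = 20L) {
  stopifnot(inherits(surface, "integrand_surface"),
            inherits(Q, "quantile_matrix"))
  g <- q_grid(Q)
  if (is.null(subjects)) subjects <- rownames(Q)
  if (is.numeric(subjects)) subjects <- rownames(Q)[subjects]
  subjects <- intersect(subjects, rownames(Q))
  if (length(subjects) == 0L) stop("no matching subjects to overlay")
  if (length(subjects) > max_subjects) {
    warning("overlaying ", max_subjects, " of ", length(subjects),
            " subjects (evenly subsampled)")
    subjects <- subjects[round(seq(1, length(subjects),
                                   length.out = max_subjects))]
  }
  r <- surface$q_range
  pg <- seq(0, 1, length.out = resolution)
  qg <- seq(r[1], r[2], length.out = resolution)
  S <- outer(pg, qg, function(p, q) surface_eval(surface, p, q))
  qi <- compute_qi(surface, Q)
  idx <- setNames(qi$qi, qi$subject_id)[subjects]
  Qs <- unclass(Q)[subjects, , drop = FALSE]
  # evaluation follows the compute_qi() extrapolation policy: clamp the
  # path's q only for tensor surfaces
  Qe <- if (surface$model$kind == "linear") Qs else pmin(pmax(Qs, r[1]), r[2])
  paths <- lapply(seq_along(subjects), function(i) {
    data.frame(p = g$p, q = Qs[i, ],
               s = surface_eval(surface, g$p, Qe[i, ]))
  })
  names(paths) <- subjects
  beta <- if (surface$model$kind == "linear") {
    data.frame(p = pg,
               beta = as.numeric(surface$c_hat) *
                 beta_hat(surface$model, pg))
  } else NULL
  list(p = pg, q = qg, S = S, paths = paths, indices = idx,
       beta = beta, q_range = r, grid = g)
}

#' Plot an integrand surface with integration paths (Fig-style 3-D view)
#'
#' Renders the sign-adjusted surface as a 3-D wireframe with each overlaid
#' subject's integration path on the surface, its projection onto the
#' (p, q)-plane drawn on the floor (the subject's quantile function) and
#' its projection onto the (p, s)-plane drawn on the back wall (the curve
#' whose area is the subject's index).  For linear surfaces the estimated
#' coefficient function \eqn{\hat\beta(p)} is drawn in the q = 1 plane
#' when 1 lies in the q-range, otherwise at the wall.
#'
#' `file = "*.png"` writes a static raster (the default device is used
#' when `file` is NULL); `file = "*.html"` writes a standalone HTML page
#' embedding the rendered image together with the full numeric plot data
#' as JSON.
#'
#' @inheritParams surface_plot_data
#' @param file optional output path (`.png` or `.html`).
#' @param theta,phi viewing angles passed to [graphics::persp()].
#' @param main plot title.
#' @return Invisibly, the [surface_plot_data()] list.
#' @export
plot_integrand_surface <- function(surface, Q, subjects = NULL,
                                   resolution = 50L, file = NULL,
                                   theta = -40, phi = 22,
                                   main = "Integrand surface") {
  dat <- surface_plot_data(surface, Q, subjects, resolution)
  fmt <- plot_format(file)
  if (fmt == "html") {
    png_tmp <- tempfile(fileext = ".png")
    png(png_tmp, width = 900, height = 700, res = 110)
    draw_surface_3d(dat, theta, phi, main)
    dev.off()
    write_plot_html(file, png_tmp, dat, main)
  } else {
    if (fmt == "png") png(file, width = 900, height = 700, res = 110)
    draw_surface_3d(dat, theta, phi, main)
    if (fmt == "png") dev.off()
  }
  invisible(dat)
}

plot_format <- function(file) {
  if (is.null(file)) return("device")
  ext <- tolower(tools::file_ext(file))
  if (!ext %in% c("png", "html"))
    stop("unsupported plot format: .", ext, " (use .png or .html)")
  ext
}

draw_surface_3d <- function(dat, theta, phi, main) {
  s_all <- c(dat$S, unlist(lapply(dat$paths, `[[`, "s")), 0,
             dat$beta$beta)
  zlim <- range(s_all, finite = TRUE)
  if (diff(zlim) == 0) zlim <- zlim + c(-1, 1)   # flat surface
  pm <- persp(dat$p, dat$q, dat$S, theta = theta, phi = phi,
              xlab = "p (probability)", ylab = "q (quantile)",
              zlab = "s", zlim = zlim, col = NA, border = "grey70",
              ticktype = "detailed", main = main)
  qfloor <- dat$q_range[1]
  swall <- zlim[1]
  cols <- grDevices::hcl.colors(max(length(dat$paths), 2L), "Dark 3")
  for (i in seq_along(dat$paths)) {
    pp <- dat$paths[[i]]
    lines(trans3d(pp$p, pp$q, pp$s, pm), col = cols[i], lwd = 2)
    lines(trans3d(pp$p, pp$q, rep(swall, nrow(pp)), pm),
          col = cols[i], lty = 3)                      # (p, q) projection
    lines(trans3d(pp$p, rep(qfloor, nrow(pp)), pp$s, pm),
          col = cols[i], lty = 2)                      # (p, s) projection
  }
  if (!is.null(dat$beta)) {
    qb <- if (dat$q_range[1] <= 1 && dat$q_range[2] >= 1) 1 else qfloor
    lines(trans3d(dat$beta$p, rep(qb, nrow(dat$beta)), dat$beta$beta, pm),
          col = "purple", lwd = 2)
  }
}

write_plot_html <- function(file, png_path, dat, title) {
  b64 <- jsonlite::base64_enc(readBin(png_path, "raw",
                                      file.info(png_path)$size))
  payload <- jsonlite::toJSON(
    list(p = dat$p, q = dat$q, S = dat$S,
         paths = dat$paths, indices = as.list(dat$indices),
         beta = dat$beta, q_range = dat$q_range),
    digits = NA, auto_unbox = TRUE, dataframe = "columns")
  html <- paste0(
    "<!DOCTYPE html><html><head><meta charset='utf-8'><title>", title,
    "</title></head><body>\n<h2>", title, "</h2>\n",
    "<img alt='integrand surface' style='max-width:100%' ",
    "src='data:image/png;base64,", gsub("\n", "", b64), "'/>\n",
    "<script type='application/json' id='quindex-plot-data'>\n",
    payload, "\n</script>\n",
    "<p>Numeric plot data embedded in the JSON block above.</p>\n",
    "</body></html>\n")
  writeLines(html, file)
  invisible(file)
}

#' Plot cluster-level quantile functions and their aggregates
#'
#' For one subject: each cluster's quantile function (dashed) plus the
#' four point-wise aggregate curves (min <= mean / median <= max).  With a
#' single cluster all aggregate curves coincide with the cluster curve.
#'
#' @param grouped a [grouped_samples()] object.
#' @param subject subject id (default: first).
#' @param grid a [prob_grid()].
#' @param file optional `.png` or `.html` output path.
#' @return Invisibly, a list with the cluster quantile matrix and the four
#'   aggregate rows.
#' @export
plot_quantile_functions <- function(grouped, subject = NULL,
                                    grid = prob_grid(), file = NULL) {
  stopifnot(inherits(grouped, "grouped_samples"))
  grid <- as_prob_grid(grid)
  if (is.null(subject)) subject <- subjects(grouped)[1]
  if (!subject %in% subjects(grouped)) stop("unknown subject: ", subject)
  cq <- cluster_quantiles(grouped, grid)[[subject]]
  aggs <- rbind(min = apply(cq, 2, min),
                mean = colMeans(cq),
                median = apply(cq, 2, median),
                max = apply(cq, 2, max))
  dat <- list(p = grid$p, clusters = cq, aggregates = aggs,
              subject = subject)
  fmt <- plot_format(file)
  draw <- function() {
    matplot(grid$p, t(cq), type = "l", lty = 2, col = "grey40",
            xlab = "p", ylab = sprintf("Q(p) [%s]", grouped$marker),
            main = paste("Quantile functions:", subject))
    cols <- c(min = "blue", mean = "forestgreen",
              median = "orange", max = "red")
    for (a in rownames(aggs))
      lines(grid$p, aggs[a, ], col = cols[[a]], lwd = 2)
    legend("topleft", bty = "n",
           legend = c("clusters", rownames(aggs)),
           col = c("grey40", cols), lty = c(2, 1, 1, 1, 1), lwd = c(1, 2, 2, 2, 2))
  }
  if (fmt == "html") {
    png_tmp <- tempfile(fileext = ".png")
    png(png_tmp, width = 800, height = 600, res = 110)
    draw()
    dev.off()
    b64 <- jsonlite::base64_enc(readBin(png_tmp, "raw",
                                        file.info(png_tmp)$size))
    payload <- jsonlite::toJSON(dat, digits = NA, auto_unbox = TRUE)
    writeLines(paste0(
      "<!DOCTYPE html><html><head><meta charset='utf-8'></head><body>\n",
      "<img style='max-width:100%' src='data:image/png;base64,",
      gsub("\n", "", b64), "'/>\n",
      "<script type='application/json' id='quindex-plot-data'>\n",
      payload, "\n</script></body></html>\n"), file)
  } else {
    if (fmt == "png") png(file, width = 800, height = 600, res = 110)
    draw()
    if (fmt == "png") dev.off()
  }
  invisible(dat)
}
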