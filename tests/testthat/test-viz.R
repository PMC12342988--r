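viz_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_scenario("linear", n_subjects = 25, seed = 606)
      st <- simulate_study(cfg, seed = 606)
      fit <- fit_qi_model(st$Q, st$outcomes)
      cache <<- list(st = st,
                     surface = sign_adjust(integrand_surface(fit), st$Q))
    }
    cache
  }
})

test_that("areas under (p,s) projections equal the computed indices", {
  fx <- viz_fixture()
  dat <- surface_plot_data(fx$surface, fx$st$Q,
                           subjects = rownames(fx$st$Q)[1:6])
  qi <- compute_qi(fx$surface, fx$st$Q)
  for (s in names(dat$paths)) {
    area <- sum(dat$grid$w * dat$paths[[s]]$s)   # same quadrature rule
    expect_lt(abs(area - dat$indices[[s]]), 1e-6)
    expect_equal(dat$indices[[s]], qi$qi[qi$subject_id == s])
  }
  # projections are coordinate pairs of the path itself
  p1 <- dat$paths[[1]]
  expect_equal(p1$q, as.numeric(fx$st$Q[names(dat$paths)[1], ]))
})

test_that("nonlinear surface areas also match their indices", {
  stn <- simulate_study(sim_scenario("nonlinear", n_subjects = 30,
                                     seed = 99), seed = 99)
  fitn <- fit_qi_model(stn$Q, stn$outcomes, kind = "nonlinear")
  sn <- sign_adjust(integrand_surface(fitn), stn$Q)
  dat <- surface_plot_data(sn, stn$Q, subjects = rownames(stn$Q)[1:4])
  for (s in names(dat$paths))
    expect_lt(abs(sum(dat$grid$w * dat$paths[[s]]$s) - dat$indices[[s]]),
              1e-6)
  expect_null(dat$beta)
})

test_that("one overlaid subject yields one path; caps subsample with warning", {
  fx <- viz_fixture()
  one <- surface_plot_data(fx$surface, fx$st$Q,
                           subjects = rownames(fx$st$Q)[3])
  expect_length(one$paths, 1L)
  expect_named(one$paths[[1]], c("p", "q", "s"))
  expect_warning(
    capped <- surface_plot_data(fx$surface, fx$st$Q, max_subjects = 5),
    "subsampled")
  expect_length(capped$paths, 5L)
})

test_that("a flat zero surface renders without error", {
  grid <- prob_grid(20)
  fit0 <- manual_linear_fit(rep(0, 8), grid = grid, q_range = c(0, 4))
  Q <- quantile_matrix(rbind(sort(runif(20, 0, 4))), grid)
  png_path <- withr::local_tempfile(fileext = ".png")
  dat <- plot_integrand_surface(integrand_surface(fit0), Q,
                                file = png_path)
  expect_true(file.exists(png_path))
  expect_equal(max(abs(dat$S)), 0)
})

test_that("surface plots export both PNG and standalone HTML", {
  fx <- viz_fixture()
  png_path <- withr::local_tempfile(fileext = ".png")
  html_path <- withr::local_tempfile(fileext = ".html")
  subj <- rownames(fx$st$Q)[1:3]
  d1 <- plot_integrand_surface(fx$surface, fx$st$Q, subjects = subj,
                               file = png_path)
  d2 <- plot_integrand_surface(fx$surface, fx$st$Q, subjects = subj,
                               file = html_path)
  expect_true(file.exists(png_path) && file.info(png_path)$size > 0)
  html <- readLines(html_path)
  expect_true(any(grepl("quindex-plot-data", html)))
  expect_identical(d1$indices, d2$indices)
  # embedded JSON carries the same indices as the computation
  json <- paste(html, collapse = "\n")
  block <- sub(".*<script type='application/json' id='quindex-plot-data'>\\s*", "", json)
  block <- sub("\\s*</script>.*", "", block)
  parsed <- jsonlite::fromJSON(block)
  expect_equal(unlist(parsed$indices), d1$indices, tolerance = 1e-12)
  expect_error(plot_integrand_surface(fx$surface, fx$st$Q,
                                      subjects = subj, file = "x.pdf"),
               "unsupported")
})

test_that("cluster quantile plots overlay envelopes correctly", {
  g2 <- tiny_grouped(list(A = list(c1 = rlnorm(40), c2 = rlnorm(40, 0.5))))
  png_path <- withr::local_tempfile(fileext = ".png")
  dat <- plot_quantile_functions(g2, "A", prob_grid(30), file = png_path)
  expect_true(file.exists(png_path))
  expect_equal(dat$aggregates["min", ],
               apply(dat$clusters, 2, min))   # lower envelope
  expect_true(all(dat$aggregates["min", ] <= dat$aggregates["max", ]))

  g1 <- tiny_grouped(list(B = list(only = rlnorm(30))))
  html_path <- withr::local_tempfile(fileext = ".html")
  dat1 <- plot_quantile_functions(g1, "B", prob_grid(15), file = html_path)
  expect_true(file.exists(html_path))
  for (a in rownames(dat1$aggregates))
    expect_equal(unname(dat1$aggregates[a, ]),
                 unname(dat1$clusters[1, ]))  # single cluster coincides
})
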