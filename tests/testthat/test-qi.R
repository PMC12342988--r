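qi_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_scenario("linear", n_subjects = 80, seed = 505)
      st <- simulate_study(cfg, seed = 505)
      fit <- fit_qi_model(st$Q, st$outcomes)
      cache <<- list(st = st, fit = fit,
                     surface = integrand_surface(fit))
    }
    cache
  }
})

test_that("linear surfaces are linear in q and vanish at q = 0", {
  s <- qi_fixture()$surface
  p <- runif(20); q1 <- rnorm(20); q2 <- rnorm(20)
  expect_equal(surface_eval(s, p, rep(0, 20)), rep(0, 20))
  expect_equal(surface_eval(s, p, q1 + q2),
               surface_eval(s, p, q1) + surface_eval(s, p, q2),
               tolerance = 1e-12)
  expect_equal(surface_eval(s, p, 2 * q1), 2 * surface_eval(s, p, q1),
               tolerance = 1e-12)
})

test_that("indices are quadrature areas: beta = 1 recovers sample means", {
  # beta(p) set exactly to 1 through the partition of unity
  grid <- prob_grid(100)
  fit1 <- manual_linear_fit(rep(1, 10), grid = grid)
  s <- integrand_surface(fit1)
  set.seed(77)
  x <- sample(1:100)
  Q <- quantile_matrix(rbind(empirical_quantile(x, grid)), grid)
  qi <- compute_qi(s, Q)$qi
  expect_lt(abs(qi - mean(x)) / mean(x), 0.01)   # 50.5 within 1%

  fit0 <- manual_linear_fit(rep(0, 10), grid = grid)
  expect_equal(compute_qi(integrand_surface(fit0), Q)$qi, 0)
})

test_that("positive coefficient functions preserve subject ordering", {
  grid <- prob_grid(50)
  fit <- manual_linear_fit(rep(1, 8) + 0.5 * seq_len(8) / 8, grid = grid)
  s <- integrand_surface(fit)
  set.seed(8)
  base <- sort(rlnorm(50))
  Q <- quantile_matrix(rbind(base, base + 0.5, base + 1.2), grid)
  qi <- compute_qi(s, Q)$qi
  # direct-summation oracle
  b <- as.numeric(eval_basis(fit$basis, grid$p) %*% fit$theta)
  oracle <- as.numeric(unclass(Q) %*% (grid$w * b))
  expect_equal(qi, oracle, tolerance = 1e-12)
  expect_true(all(b > 0))
  expect_true(all(diff(qi) > 0))
})

test_that("sign adjustment flips negative surfaces and is idempotent", {
  fx <- qi_fixture()
  st <- fx$st
  # fitting the negated outcome gives an index negatively correlated
  # with the median quantile
  neg <- outcome_table(
    data.frame(subject_id = st$outcomes$subject_id, y = -st$outcomes$y),
    "continuous")
  fit_neg <- fit_qi_model(st$Q, neg)
  s0 <- integrand_surface(fit_neg)
  g <- attr(st$Q, "grid")
  k <- which.min(abs(g$p - 0.5))
  r0 <- cor(st$Q[, k], compute_qi(s0, st$Q)$qi)
  expect_lt(r0, 0)

  s1 <- sign_adjust(s0, st$Q)
  expect_equal(s1$c_hat, -1L)
  r1 <- cor(st$Q[, k], compute_qi(s1, st$Q)$qi)
  expect_equal(r1, -r0)
  expect_gte(r1, 0)

  s2 <- sign_adjust(s1, st$Q)          # idempotent
  expect_equal(s2$c_hat, s1$c_hat)
  expect_equal(compute_qi(s2, st$Q)$qi, compute_qi(s1, st$Q)$qi)

  # already-positive surfaces are unchanged
  sp <- sign_adjust(integrand_surface(fx$fit), st$Q)
  expect_equal(sp$c_hat, 1L)
})

test_that("exactly zero or undefined correlations keep sign +1", {
  # K = 4 midpoint grid; beta = 1 exactly; rows crafted so that
  # cor(Q(p~), QI) is exactly zero: Q(p~) = (0, 1, 2), QI = (1, 2, 1)
  grid <- prob_grid(4)
  fit1 <- manual_linear_fit(rep(1, 8), grid = grid)
  Q <- quantile_matrix(rbind(c(0, 0, 2, 2),
                             c(1, 1, 3, 3),
                             c(-2, 2, 2, 2)), grid)
  s <- sign_adjust(integrand_surface(fit1), Q)
  expect_equal(cor(Q[, 2], compute_qi(integrand_surface(fit1), Q)$qi), 0)
  expect_equal(s$c_hat, 1L)

  # constant Q(p~): correlation undefined
  Qc <- quantile_matrix(rbind(c(0, 1, 2, 3), c(0, 1, 2, 4),
                              c(0, 1, 2, 5)), grid)
  expect_warning(sc <- sign_adjust(integrand_surface(fit1), Qc),
                 "undefined")
  expect_equal(sc$c_hat, 1L)
})

test_that("training indices reproduce the fitted functional contribution", {
  fx <- qi_fixture()
  qi <- compute_qi(fx$surface, fx$st$Q)$qi
  contrib <- fx$fit$fitted_eta - fx$fit$intercept
  # equal up to the constant induced by design centering
  expect_lt(sd(qi - contrib), 1e-8)
})

test_that("indices are stable under grid refinement", {
  fx <- qi_fixture()
  s <- sign_adjust(fx$surface, fx$st$Q)
  cells <- fx$st$cells
  Q200 <- aggregate_quantile(grouped_samples(cells, "intensity"),
                             prob_grid(200))
  q100 <- compute_qi(s, fx$st$Q)$qi
  q200 <- compute_qi(s, Q200)$qi
  # relative to the index scale (individual indices can be near zero)
  expect_lt(max(abs(q100 - q200)) / max(abs(q100)), 1e-2)
})

test_that("linear indices scale with the quantile rows (equivariance)", {
  fx <- qi_fixture()
  g <- attr(fx$st$Q, "grid")
  a <- 3.5
  Qa <- quantile_matrix(unclass(fx$st$Q) * a, g)
  expect_equal(compute_qi(fx$surface, Qa)$qi,
               a * compute_qi(fx$surface, fx$st$Q)$qi, tolerance = 1e-12)
})

test_that("out-of-range test subjects are flagged; tensors clamp", {
  fx <- qi_fixture()
  g <- attr(fx$st$Q, "grid")
  Qbig <- quantile_matrix(unclass(fx$st$Q) + diff(fx$surface$q_range),
                          g)
  res <- compute_qi(fx$surface, Qbig)
  expect_true(all(res$extrapolated == 1))
  expect_true(all(is.finite(res$qi)))

  # nonlinear: clamped evaluation equals evaluation at the range edge
  stn <- simulate_study(sim_scenario("nonlinear", n_subjects = 60,
                                     seed = 88), seed = 88)
  fitn <- fit_qi_model(stn$Q, stn$outcomes, kind = "nonlinear")
  sn <- integrand_surface(fitn)
  Qhi <- quantile_matrix(unclass(stn$Q) + 10 * diff(sn$q_range), g)
  Qedge <- quantile_matrix(matrix(sn$q_range[2], nrow(Qhi), g$K), g)
  rhi <- compute_qi(sn, Qhi)
  expect_true(all(rhi$extrapolated == 1))
  expect_equal(rhi$qi, compute_qi(sn, Qedge)$qi, tolerance = 1e-10)
  expect_equal(attr(rhi, "kind"), "nlQI")
})

test_that("a constrained tensor surface nests the linear model", {
  fx <- qi_fixture()
  st <- fx$st
  fitL <- fx$fit
  bq <- q_basis_for(st$Q, 8)
  tb <- tensor_basis(fitL$basis, bq)
  # Greville coefficients represent q exactly, so outer(theta, greville)
  # encodes F(p, q) = beta(p) * q in the tensor basis
  theta_t <- as.numeric(outer(fitL$theta, quindex:::greville(bq)))
  fitT <- fitL
  fitT$kind <- "nonlinear"
  fitT$basis <- tb
  fitT$theta <- theta_t
  sT <- integrand_surface(fitT)
  sL <- integrand_surface(fitL)
  expect_lt(max(abs(compute_qi(sT, st$Q)$qi - compute_qi(sL, st$Q)$qi)),
            1e-6)
})

test_that("nonlinear fits recover the q-profile of a known surface", {
  cfgq <- sim_config(n_subjects = 150, effect = "nonlinear",
                     surface_fun = function(p, q) q^2, seed = 9)
  stq <- simulate_study(cfgq)
  fq <- fit_qi_model(stq$Q, stq$outcomes, kind = "nonlinear")
  sfq <- integrand_surface(fq)
  g <- attr(stq$Q, "grid")
  # identified region: data-supported band, per-p level removed (a p-only
  # component is absorbed by the intercept and not identifiable)
  ks <- round(seq(5, 95, length.out = 10))
  pts <- do.call(rbind, lapply(ks, function(k) {
    qs <- seq(quantile(stq$Q[, k], 0.1), quantile(stq$Q[, k], 0.9),
              length.out = 20)
    cbind(p = g$p[k], q = qs)
  }))
  sv <- surface_eval(sfq, pts[, 1], pts[, 2])
  sv_c <- sv - ave(sv, pts[, 1])
  tr_c <- pts[, 2]^2 - ave(pts[, 2]^2, pts[, 1])
  expect_gte(cor(sv_c, tr_c, method = "spearman"), 0.9)
})

test_that("predictor evaluation reports the right metric per outcome", {
  fx <- qi_fixture()
  res <- compute_qi(fx$surface, fx$st$Q)
  # index used as its own continuous outcome: perfect association
  oc <- outcome_table(data.frame(subject_id = res$subject_id, y = res$qi),
                      "continuous")
  ev <- evaluate_predictor(res, oc)
  expect_equal(ev$r_squared, 1, tolerance = 1e-12)
  expect_false(ev$optimistic)
  expect_true(evaluate_predictor(res, oc, training = TRUE)$optimistic)

  # independent binary outcome: AUC near 1/2
  set.seed(123)
  ocb <- outcome_table(data.frame(subject_id = res$subject_id,
                                  y = rbinom(nrow(res), 1, 0.5)), "binary")
  expect_lt(abs(evaluate_predictor(res, ocb)$value - 0.5), 0.15)

  # survival with hazard increasing in the index: concordance above 1/2
  z <- scale(res$qi)[, 1]
  ocs <- outcome_table(data.frame(subject_id = res$subject_id,
                                  time = rexp(nrow(res), exp(z)),
                                  event = 1L), "survival")
  expect_gt(evaluate_predictor(res, ocs)$value, 0.5)

  few <- outcome_table(data.frame(subject_id = res$subject_id[1:2],
                                  y = 1:2), "continuous")
  expect_error(evaluate_predictor(res, few), "fewer than 3")
})
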