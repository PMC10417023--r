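test_that("Jarzynski reduces to identities on degenerate inputs", {
  ws1 <- work_set(forward = 5.0)
  expect_equal(jarzynski(ws1, "forward")$dG, 5.0)
  wsc <- work_set(forward = rep(3.2, 10), reverse = rep(-3.2, 10))
  expect_equal(jarzynski(wsc, "forward")$dG, 3.2)
  expect_equal(jarzynski(wsc, "reverse")$dG, 3.2)
  expect_equal(jarzynski(wsc, "combined")$dG, 3.2)
  expect_identical(jarzynski(wsc, "combined")$method, "JAR")
  expect_error(jarzynski(work_set(forward = 1), "reverse"), "insufficient data")
  # log-sum-exp keeps huge beta W finite
  expect_equal(jarzynski(work_set(forward = rep(5000, 3)), "forward")$dG, 5000)
})

test_that("Jarzynski converges to the analytic Gaussian limit", {
  # forward samples from N(mu, sigma^2) give dG -> mu - beta sigma^2 / 2
  mu <- 10 + 2^2 / (2 * RT_298)
  set.seed(424)
  ws <- work_set(forward = rnorm(1e5, mu, 2))
  expect_equal(jarzynski(ws, "forward")$dG, 10.0, tolerance = 0.2 / 10)
})

test_that("CGI matches the midpoint and the density-intersection oracle", {
  # equal variances: exact midpoint. Moments are set exactly by construction:
  # a +/- c sample has mean a and sd c for any placement
  f <- 12 + c(-2, 2); r <- -(8 + c(-2, 2))
  est <- cgi(work_set(forward = f, reverse = r))
  expect_equal(est$dG, 10.0)
  expect_false(est$flagged)

  # unequal variances: root of the Gaussian log-density equality in (8, 12),
  # frozen from a dense numeric scan of the two densities (2e6 grid points).
  # a two-point sample m +/- sqrt(v/2) has mean m and unbiased variance v
  mk <- function(m, v) m + c(-1, 1) * sqrt(v / 2)
  f2 <- mk(12, 4); r2 <- -mk(8, 1)
  est2 <- cgi(work_set(forward = f2, reverse = r2))
  expect_equal(est2$dG, 9.6599096559, tolerance = 1e-6)
  expect_equal(est2$dG, cgi_scan_oracle(12, 4, 8, 1), tolerance = 1e-5)

  expect_error(cgi(work_set(forward = 1, reverse = -1)), "insufficient data")
  expect_error(cgi(work_set(forward = c(2, 2), reverse = c(-7, -7))),
               "degenerate fit")
})

test_that("BAR solves the Bennett equation and matches the grid oracle", {
  # degenerate Crooks-consistent case
  ws <- ws_degenerate(4.2, n = 6)
  expect_equal(bar(ws)$dG, 4.2, tolerance = 1e-8)

  # grid-search oracle on small instances
  set.seed(88)
  for (k in 1:5) {
    n_f <- sample(3:10, 1); n_r <- sample(3:10, 1)
    dg <- runif(1, -10, 10)
    w_f <- rnorm(n_f, dg + 1, 2); w_r <- rnorm(n_r, -dg + 1, 2)
    est <- bar(work_set(forward = w_f, reverse = w_r))
    expect_equal(est$dG, bar_grid_oracle(w_f, w_r), tolerance = 1e-6)
  }

  # the residual is strictly monotone in dG on random instances
  wsr <- sample_crooks_gaussian(3, 4, 20, 15, seed = 5)
  beta <- 1 / RT_298
  grid <- seq(-30, 30, length.out = 200)
  resid <- vapply(grid, bar_residual_plain, numeric(1),
                  w_f = wsr$forward, w_r = wsr$reverse, beta = beta)
  expect_true(all(diff(resid) > 0))

  expect_error(bar(work_set(forward = 1:3)), "both directions")
})

test_that("estimators are antisymmetric and shift-equivariant", {
  set.seed(17)
  for (k in 1:5) {
    ws <- sample_crooks_gaussian(runif(1, -8, 8), runif(1, 0.5, 4),
                                 30, 40, seed = 100 + k)
    swapped <- work_set(forward = ws$reverse, reverse = ws$forward,
                        temperature = ws$temperature)
    c_shift <- runif(1, -20, 20)
    shifted <- work_set(forward = ws$forward + c_shift,
                        reverse = ws$reverse - c_shift,
                        temperature = ws$temperature)
    for (est in list(function(w) jarzynski(w, "combined")$dG,
                     function(w) cgi(w)$dG,
                     function(w) bar(w)$dG)) {
      expect_equal(est(swapped), -est(ws), tolerance = 1e-10)
      expect_equal(est(shifted), est(ws) + c_shift, tolerance = 1e-10)
    }
  }
})

test_that("estimators recover the truth on Crooks-consistent Gaussian samples", {
  # dG = 10, sigma = 2, n = 200/direction, 50 seeds: CGI and BAR unbiased
  # within 0.5 kJ/mol; one-sided JAR biases have opposite signs
  ests <- t(vapply(1:50, function(s) {
    ws <- sample_crooks_gaussian(10, 2, 200, 200, seed = 1000 + s)
    c(bar = bar(ws)$dG, cgi = cgi(ws)$dG,
      jf = jarzynski(ws, "forward")$dG, jr = jarzynski(ws, "reverse")$dG)
  }, numeric(4)))
  expect_lt(abs(mean(ests[, "bar"]) - 10), 0.5)
  expect_lt(abs(mean(ests[, "cgi"]) - 10), 0.5)

  # the one-sided JAR bias (positive forward, negative reverse) is resolvable
  # above Monte-Carlo noise at wide work distributions and small n, and
  # shrinks as n grows
  bias_at <- function(n) {
    colMeans(t(vapply(1:60, function(s) {
      ws <- sample_crooks_gaussian(10, 4, n, n, seed = 7000 + s)
      c(jf = jarzynski(ws, "forward")$dG, jr = jarzynski(ws, "reverse")$dG)
    }, numeric(2)))) - 10
  }
  b30 <- bias_at(30); b300 <- bias_at(300)
  expect_gt(b30[["jf"]], 0.1)
  expect_lt(b30[["jr"]], -0.1)
  expect_lt(abs(b300[["jf"]]), abs(b30[["jf"]]))
  expect_lt(abs(b300[["jr"]]), abs(b30[["jr"]]))
})

test_that("bootstrap SE is zero on degenerate data, deterministic, and shrinks with n", {
  ws <- ws_degenerate(2.5, n = 8)
  expect_equal(bootstrap_se(ws, "BAR", n_boot = 50, seed = 1), 0)
  expect_equal(bootstrap_se(ws, "JAR", n_boot = 50, seed = 1), 0)

  ws2 <- sample_crooks_gaussian(5, 2, 60, 60, seed = 2)
  expect_identical(bootstrap_se(ws2, "BAR", n_boot = 100, seed = 9),
                   bootstrap_se(ws2, "BAR", n_boot = 100, seed = 9))

  # ~1/sqrt(n) scaling at fixed sigma, averaged over seeds
  se_at <- function(n) mean(vapply(1:20, function(s) {
    ws <- sample_crooks_gaussian(5, 2, n, n, seed = 300 + s)
    bootstrap_se(ws, "BAR", n_boot = 60, seed = s)
  }, numeric(1)))
  ratio <- se_at(50) / se_at(200)
  expect_gt(ratio, 1.5); expect_lt(ratio, 2.7) # ideal 2

  expect_error(bootstrap_se(ws2, "BAR", n_boot = 1), "n_boot")
})

test_that("estimate_all applies every estimator whose preconditions hold", {
  ws <- sample_crooks_gaussian(3, 1, 20, 20, seed = 6)
  res <- estimate_all(ws)
  expect_setequal(names(res$estimates), c("JAR", "CGI", "BAR"))
  expect_length(res$skipped, 0)

  fwd_only <- work_set(forward = rnorm(10, 2), temperature = 298.15)
  res2 <- estimate_all(fwd_only)
  expect_named(res2$estimates, "JAR_forward")
  expect_setequal(names(res2$skipped), c("CGI", "BAR"))
  expect_match(res2$skipped[["BAR"]], "both directions")

  # degenerate Crooks-consistent set: all three agree
  res3 <- estimate_all(ws_degenerate(7, n = 5))
  dgs <- vapply(res3$estimates, `[[`, numeric(1), "dG")
  expect_equal(unname(dgs), rep(7, 3), tolerance = 1e-7)
})
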