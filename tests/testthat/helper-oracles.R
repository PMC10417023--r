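# Independent oracles used across the suite. Each is written directly from
# the defining equation it checks, without calling the package's own solver.

RT_298 <- 8.314462618e-3 * 298.15

# Bennett residual written plainly (no logistic shortcut); used by the
# grid-search BAR oracle
bar_residual_plain <- function(dG, w_f, w_r, beta) {
  n_f <- length(w_f); n_r <- length(w_r)
  sum(1 / (1 + (n_f / n_r) * exp(beta * (w_f - dG)))) -
    sum(1 / (1 + (n_r / n_f) * exp(beta * (w_r + dG))))
}

# two-stage dense grid search minimizing the squared Bennett residual
bar_grid_oracle <- function(w_f, w_r, temperature = 298.15) {
  beta <- 1 / (8.314462618e-3 * temperature)
  lo <- min(c(w_f, -w_r)) - 50; hi <- max(c(w_f, -w_r)) + 50
  refine <- function(lo, hi, n) {
    g <- seq(lo, hi, length.out = n)
    r <- vapply(g, function(d) bar_residual_plain(d, w_f, w_r, beta)^2, numeric(1))
    g[which.min(r)]
  }
  centre <- refine(lo, hi, 20001L)
  step <- (hi - lo) / 20000
  for (k in 1:3) {
    lo <- centre - 2 * step; hi <- centre + 2 * step
    centre <- refine(lo, hi, 20001L)
    step <- (hi - lo) / 20000
  }
  centre
}

# density-intersection oracle for CGI: dense scan of the two fitted normal
# densities on the interval spanned by the means
cgi_scan_oracle <- function(m_f, v_f, m_r, v_r, n_grid = 2e6) {
  g <- seq(min(m_f, m_r), max(m_f, m_r), length.out = n_grid)
  d <- dnorm(g, m_f, sqrt(v_f)) - dnorm(g, m_r, sqrt(v_r))
  i <- which(d[-1] * d[-length(d)] <= 0)[1]
  if (is.na(i)) return(NA_real_)
  # linear interpolation of the sign change
  g[i] + (g[i + 1] - g[i]) * abs(d[i]) / (abs(d[i]) + abs(d[i + 1]))
}

# closed-form orthogonal (lambda = 1) Deming slope for equal constant SEs
deming_lambda1_slope <- function(x, y) {
  sxx <- sum((x - mean(x))^2); syy <- sum((y - mean(y))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  (syy - sxx + sqrt((syy - sxx)^2 + 4 * sxy^2)) / (2 * sxy)
}

# work moments that make a Gaussian pair Crooks-consistent around dG
crooks_means <- function(dG, sigma, temperature = 298.15) {
  beta <- 1 / (8.314462618e-3 * temperature)
  list(forward = dG + beta * sigma^2 / 2, reverse = -dG + beta * sigma^2 / 2)
}

# fixture: the packaged CDK IC50 panel
cdk_ic50_path <- function() {
  system.file("extdata", "cdk_ic50.csv", package = "neqsel", mustWork = TRUE)
}

# small deterministic work_set builders
ws_degenerate <- function(g, n = 4, temperature = 298.15, ...) {
  work_set(forward = rep(g, n), reverse = rep(-g, n),
           temperature = temperature, ...)
}
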