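#' Free energy estimate container
#'
#' @param dG estimate, kJ/mol.
#' @param method one of `"JAR_forward"`, `"JAR_reverse"`, `"JAR"`, `"CGI"`,
#'   `"BAR"`.
#' @param se bootstrap standard error, kJ/mol, or `NA` when not computed.
#' @param n_forward,n_reverse sample counts used.
#' @param flagged logical; `TRUE` when the estimator had to fall back from its
#'   preferred rule (CGI root outside the bracketing means).
#' @param n_boot,seed bootstrap settings, when `se` was computed.
#' @return an object of class `"fe_estimate"`.
#' @keywords internal
fe_estimate <- function(dG, method, se = NA_real_, n_forward = 0L, n_reverse = 0L,
                        flagged = FALSE, n_boot = NA_integer_, seed = NA_integer_) {
  methods_ok <- c("JAR_forward", "JAR_reverse", "JAR", "CGI", "BAR")
  if (!method %in% methods_ok)
    stop("unknown estimator method tag: ", method, call. = FALSE)
  if (!is.na(se) && se < 0) stop("`se` must be >= 0", call. = FALSE)
  structure(list(dG = dG, se = se, method = method,
                 n_forward = as.integer(n_forward), n_reverse = as.integer(n_reverse),
                 flagged = isTRUE(flagged), n_boot = n_boot, seed = seed),
            class = "fe_estimate")
}

#' @export
print.fe_estimate <- function(x, ...) {
  se_txt <- if (is.na(x$se)) "" else sprintf(" +/- %.3f", x$se)
  cat(sprintf("<fe_estimate> %s: dG = %.4f%s kJ/mol (n_F = %d, n_R = %d)%s\n",
              x$method, x$dG, se_txt, x$n_forward, x$n_reverse,
              if (x$flagged) " [flagged]" else ""))
  invisible(x)
}

# log(mean(exp(x))) without overflow
log_mean_exp <- function(x) {
  m <- max(x)
  m + log(mean(exp(x - m)))
}

#' Jarzynski free energy estimator
#'
#' One-sided exponential work averages, computed with a log-sum-exp
#' formulation so that large beta W products cannot overflow. The forward
#' estimate is -(1/beta) log mean exp(-beta W_F); the reverse estimate is
#' +(1/beta) log mean exp(-beta W_R) (the negated free energy of the reverse
#' process, in the forward direction's sign). `"combined"` averages the two
#' one-sided estimates and requires both directions.
#'
#' @param works a [work_set()].
#' @param direction `"forward"`, `"reverse"`, or `"combined"`.
#' @return an `fe_estimate` with method tag `JAR_forward`, `JAR_reverse`, or
#'   `JAR`.
#' @examples
#' jarzynski(work_set(forward = 5), "forward") # dG = 5
#' @export
jarzynski <- function(works, direction = c("combined", "forward", "reverse")) {
  stopifnot(inherits(works, "work_set"))
  direction <- match.arg(direction)
  beta <- beta_of(works)
  need_f <- direction %in% c("forward", "combined")
  need_r <- direction %in% c("reverse", "combined")
  if (need_f && length(works$forward) == 0L)
    stop("insufficient data: no forward works for Jarzynski ", direction, call. = FALSE)
  if (need_r && length(works$reverse) == 0L)
    stop("insufficient data: no reverse works for Jarzynski ", direction, call. = FALSE)
  dg_f <- if (need_f) -log_mean_exp(-beta * works$forward) / beta else NULL
  dg_r <- if (need_r) +log_mean_exp(-beta * works$reverse) / beta else NULL
  out <- switch(direction,
    forward  = fe_estimate(dg_f, "JAR_forward", n_forward = length(works$forward)),
    reverse  = fe_estimate(dg_r, "JAR_reverse", n_reverse = length(works$reverse)),
    combined = fe_estimate((dg_f + dg_r) / 2, "JAR",
                           n_forward = length(works$forward),
                           n_reverse = length(works$reverse)))
  out
}

#' Crooks Gaussian intersection estimator
#'
#' Fits a normal density to the forward works (sample mean, unbiased
#' variance) and another to the negated reverse works, and returns the
#' intersection point of the two fitted densities. With equal variances
#' (relative tolerance 1e-9) this is the midpoint of the means; otherwise the
#' quadratic from equating the two Gaussian log-densities is solved and the
#' root lying between the means is returned. If neither root falls between
#' the means the root closer to their midpoint is returned and the estimate
#' is flagged.
#'
#' @param works a [work_set()] with at least 2 samples per direction.
#' @return an `fe_estimate` with method tag `"CGI"`.
#' @export
cgi <- function(works) {
  stopifnot(inherits(works, "work_set"))
  if (length(works$forward) < 2L || length(works$reverse) < 2L)
    stop("insufficient data: CGI needs >= 2 samples in each direction", call. = FALSE)
  m_f <- mean(works$forward);  v_f <- stats::var(works$forward)
  m_r <- mean(-works$reverse); v_r <- stats::var(-works$reverse)
  n_f <- length(works$forward); n_r <- length(works$reverse)
  eps <- 1e-12
  if ((v_f < eps || v_r < eps) && abs(m_f - m_r) > eps * max(1, abs(m_f), abs(m_r)))
    stop("degenerate fit: zero variance with unequal means in CGI", call. = FALSE)
  if (abs(v_f - v_r) <= 1e-9 * max(v_f, v_r, eps)) {
    return(fe_estimate((m_f + m_r) / 2, "CGI", n_forward = n_f, n_reverse = n_r))
  }
  # (x - m_f)^2 / v_f - (x - m_r)^2 / v_r + log(v_f / v_r) = 0
  a <- 1 / v_f - 1 / v_r
  b <- -2 * (m_f / v_f - m_r / v_r)
  cc <- m_f^2 / v_f - m_r^2 / v_r + log(v_f / v_r)
  disc <- b^2 - 4 * a * cc
  if (disc < 0) disc <- 0 # numerically tangent densities
  roots <- (-b + c(1, -1) * sqrt(disc)) / (2 * a)
  lo <- min(m_f, m_r); hi <- max(m_f, m_r)
  inside <- roots >= lo & roots <= hi
  if (any(inside)) {
    fe_estimate(roots[inside][1L], "CGI", n_forward = n_f, n_reverse = n_r)
  } else {
    mid <- (m_f + m_r) / 2
    fe_estimate(roots[which.min(abs(roots - mid))], "CGI",
                n_forward = n_f, n_reverse = n_r, flagged = TRUE)
  }
}

# Bennett residual; strictly increasing in dG (each forward term increases,
# each reverse term decreases), so the root is unique
bar_residual <- function(dG, w_f, w_r, beta) {
  n_f <- length(w_f); n_r <- length(w_r)
  lr <- log(n_f / n_r)
  sum(stats::plogis(-(lr + beta * (w_f - dG)))) -
    sum(stats::plogis(-(-lr + beta * (w_r + dG))))
}

#' Bennett acceptance ratio estimator
#'
#' Solves the Bennett self-consistency equation
#' sum_i \[1 + (n_F/n_R) exp(beta (W_F,i - dG))\]^-1 =
#' sum_j \[1 + (n_R/n_F) exp(beta (W_R,j + dG))\]^-1
#' for dG by bracketed root finding. The residual is strictly monotone in dG,
#' so the root is unique; the initial bracket spans the work range padded by
#' 50 kJ/mol and is doubled up to 3 times before a convergence error is
#' raised.
#'
#' @param works a [work_set()] with both directions non-empty.
#' @param tol absolute convergence tolerance on dG, kJ/mol.
#' @return an `fe_estimate` with method tag `"BAR"`.
#' @export
bar <- function(works, tol = 1e-8) {
  stopifnot(inherits(works, "work_set"))
  if (length(works$forward) == 0L || length(works$reverse) == 0L)
    stop("insufficient data: BAR needs both directions", call. = FALSE)
  beta <- beta_of(works)
  support <- c(works$forward, -works$reverse)
  pad <- 50
  f <- function(x) bar_residual(x, works$forward, works$reverse, beta)
  for (k in 0:3) {
    lo <- min(support) - pad; hi <- max(support) + pad
    flo <- f(lo); fhi <- f(hi)
    if (flo <= 0 && fhi >= 0) {
      root <- stats::uniroot(f, c(lo, hi), f.lower = flo, f.upper = fhi,
                             tol = tol, maxiter = 10000L)$root
      return(fe_estimate(root, "BAR",
                         n_forward = length(works$forward),
                         n_reverse = length(works$reverse)))
    }
    pad <- pad * 2
  }
  stop(sprintf(paste0("BAR convergence error: residual not bracketed on ",
                      "[%.1f, %.1f] (f = %.3g / %.3g) after bracket expansion"),
               lo, hi, flo, fhi), call. = FALSE)
}

#' Bootstrap standard error of a work estimator
#'
#' Resamples with replacement independently within each direction, preserving
#' the per-direction sample sizes, and returns the standard deviation of the
#' estimator across replicates. Deterministic for a fixed seed. If the
#' estimator fails in more than 20% of replicates a bootstrap-failure error
#' is raised.
#'
#' @param works a [work_set()].
#' @param method `"JAR"`, `"JAR_forward"`, `"JAR_reverse"`, `"CGI"`, or
#'   `"BAR"`.
#' @param n_boot number of replicates (>= 2).
#' @param seed integer seed.
#' @return bootstrap SE in kJ/mol.
#' @export
bootstrap_se <- function(works, method = c("BAR", "CGI", "JAR", "JAR_forward", "JAR_reverse"),
                         n_boot = 1000L, seed = NULL) {
  stopifnot(inherits(works, "work_set"))
  method <- match.arg(method)
  n_boot <- as.integer(n_boot)
  if (n_boot < 2L) stop("`n_boot` must be >= 2", call. = FALSE)
  est_fun <- switch(method,
    JAR = function(ws) jarzynski(ws, "combined")$dG,
    JAR_forward = function(ws) jarzynski(ws, "forward")$dG,
    JAR_reverse = function(ws) jarzynski(ws, "reverse")$dG,
    CGI = function(ws) cgi(ws)$dG,
    BAR = function(ws) bar(ws)$dG)
  est_fun(works) # preconditions must hold on the full sample
  n_f <- length(works$forward); n_r <- length(works$reverse)
  vals <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      ws_b <- works
      if (n_f > 0L) ws_b$forward <- works$forward[sample.int(n_f, n_f, replace = TRUE)]
      if (n_r > 0L) ws_b$reverse <- works$reverse[sample.int(n_r, n_r, replace = TRUE)]
      tryCatch(est_fun(ws_b), error = function(e) NA_real_)
    }, numeric(1))
  })
  n_fail <- sum(is.na(vals))
  if (n_fail > 0.2 * n_boot)
    stop(sprintf("bootstrap failure: estimator failed in %d of %d replicates",
                 n_fail, n_boot), call. = FALSE)
  stats::sd(vals[!is.na(vals)])
}

#' Run every applicable estimator on one work set
#'
#' Applies JAR (combined when both directions exist, else the available
#' side), CGI and BAR where their preconditions hold; methods whose
#' preconditions fail are recorded with the reason rather than raised.
#'
#' @param works a [work_set()].
#' @param n_boot bootstrap replicates for standard errors; `0` skips SEs.
#' @param seed integer seed for the bootstrap.
#' @return list with `estimates` (list of `fe_estimate`) and `skipped`
#'   (named character vector of reasons).
#' @export
estimate_all <- function(works, n_boot = 0L, seed = NULL) {
  stopifnot(inherits(works, "work_set"))
  both <- length(works$forward) > 0L && length(works$reverse) > 0L
  jar_dir <- if (both) "combined" else if (length(works$forward)) "forward" else "reverse"
  plan <- list(
    JAR = function() jarzynski(works, jar_dir),
    CGI = function() cgi(works),
    BAR = function() bar(works))
  estimates <- list(); skipped <- character()
  for (m in names(plan)) {
    res <- tryCatch(plan[[m]](), error = function(e) conditionMessage(e))
    if (inherits(res, "fe_estimate")) {
      if (n_boot >= 2L) {
        res$se <- bootstrap_se(works, res$method, n_boot = n_boot,
                               seed = if (is.null(seed)) NULL
                                      else derive_seed(seed, res$method))
        res$n_boot <- as.integer(n_boot)
        res$seed <- if (is.null(seed)) NA_integer_ else as.integer(seed)
      }
      estimates[[res$method]] <- res
    } else {
      skipped[[m]] <- res
    }
  }
  list(estimates = estimates, skipped = skipped)
}
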