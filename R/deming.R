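#' Generalized Deming (errors-in-variables) regression
#'
#' Fits y = intercept + slope * x when both variables carry known
#' measurement uncertainty, by minimizing
#' sum_i (x_i - xi_i)^2 / x_se_i^2 + (y_i - intercept - slope * xi_i)^2 / y_se_i^2
#' over the latent true abscissae xi and the line parameters — the
#' generalized Deming objective with per-point variances (equivalently, the
#' York errors-in-variables formulation, to which it reduces after profiling
#' out xi). The minimizer is found by the standard iteratively reweighted
#' scheme (relative parameter change below `tol`, at most `max_iter`
#' iterations). Points with a zero standard error are assigned the smallest
#' positive standard error present on that axis (or 1 when all are zero).
#'
#' The 95% confidence interval of the slope is computed by leave-one-out
#' jackknife with the normal quantile z = 1.959964; the fitted relationship
#' is declared significant when that interval excludes zero. Agreement
#' statistics (R^2 as the squared Pearson correlation, and RMSE/MAE measured
#' against the identity line y = x, not against the fit) are attached for
#' convenience.
#'
#' @param formula model formula `y ~ x` (one predictor).
#' @param data data frame holding the variables.
#' @param xse,yse per-point standard errors of x and y: numeric vectors,
#'   single numbers (recycled), or column names in `data`.
#' @param tol relative convergence tolerance of the slope iteration.
#' @param max_iter iteration cap.
#' @return an object of class `"deming"` with components `coefficients`
#'   (intercept, slope), `slope_ci`, `significant`, `r2`, `rmse`, `mae`,
#'   `n`, `iterations`, `converged`, plus the data used.
#' @examples
#' d <- data.frame(x = 1:6, y = 2 * (1:6) + 1)
#' fit <- deming(y ~ x, d, xse = 0.3, yse = 0.3)
#' coef(fit) # intercept 1, slope 2
#' @export
deming <- function(formula, data, xse = 1, yse = 1,
                   tol = 1e-10, max_iter = 100L) {
  mf <- stats::model.frame(formula, data)
  if (ncol(mf) != 2L) stop("`formula` must be of the form y ~ x", call. = FALSE)
  y <- mf[[1L]]; x <- mf[[2L]]
  resolve_se <- function(se, n) {
    if (is.character(se) && length(se) == 1L) se <- data[[se]]
    se <- rep_len(as.numeric(se), n)
    if (any(!is.finite(se)) || any(se < 0)) stop("standard errors must be finite and >= 0", call. = FALSE)
    se
  }
  n <- length(x)
  if (n < 3L) stop("insufficient data: Deming regression needs n >= 3", call. = FALSE)
  if (length(unique(x)) == 1L)
    stop("degenerate design: all x identical", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("x and y must be finite", call. = FALSE)
  xse <- fill_zero_se(resolve_se(xse, n))
  yse <- fill_zero_se(resolve_se(yse, n))

  core <- york_fit(x, y, xse, yse, tol = tol, max_iter = max_iter)

  # leave-one-out jackknife for the slope CI
  loo <- vapply(seq_len(n), function(i) {
    york_fit(x[-i], y[-i], xse[-i], yse[-i], tol = tol, max_iter = max_iter,
             b_init = core$slope)$slope
  }, numeric(1))
  se_jack <- sqrt((n - 1) / n * sum((loo - mean(loo))^2))
  ci <- core$slope + c(-1, 1) * Z_95 * se_jack

  ag <- agreement_stats(x, y)
  structure(list(
    coefficients = c(intercept = core$intercept, slope = core$slope),
    slope_ci = c(lower = ci[1L], upper = ci[2L]),
    slope_se = se_jack,
    significant = ci[1L] > 0 || ci[2L] < 0,
    r2 = ag$r2, rmse = ag$rmse, mae = ag$mae,
    n = n, iterations = core$iterations, converged = core$converged,
    x = x, y = y, xse = xse, yse = yse,
    call = match.call()
  ), class = "deming")
}

fill_zero_se <- function(se) {
  if (all(se == 0)) return(rep(1, length(se)))
  se[se == 0] <- min(se[se > 0])
  se
}

# weighted errors-in-variables line fit (York's iteration); minimizes
# sum_i (y_i - a - b x_i)^2 / (yse_i^2 + b^2 xse_i^2)
york_fit <- function(x, y, xse, yse, tol = 1e-10, max_iter = 100L, b_init = NULL) {
  w_x <- 1 / xse^2; w_y <- 1 / yse^2
  b <- if (is.null(b_init)) {
    bx <- stats::cov(x, y) / stats::var(x)
    if (!is.finite(bx) || bx == 0) 1 else bx
  } else b_init
  converged <- FALSE; it <- 0L
  for (it in seq_len(max_iter)) {
    w <- w_x * w_y / (w_x + b^2 * w_y)
    xb <- sum(w * x) / sum(w); yb <- sum(w * y) / sum(w)
    u <- x - xb; v <- y - yb
    beta_i <- w * (u / w_y + b * v / w_x)
    b_new <- sum(w * beta_i * v) / sum(w * beta_i * u)
    if (!is.finite(b_new)) break
    done <- abs(b_new - b) <= tol * max(abs(b_new), abs(b), 1e-300)
    b <- b_new
    if (done) { converged <- TRUE; break }
  }
  w <- w_x * w_y / (w_x + b^2 * w_y)
  a <- sum(w * y) / sum(w) - b * sum(w * x) / sum(w)
  list(slope = b, intercept = a, iterations = it, converged = converged)
}

#' Agreement statistics against the identity line
#'
#' R^2 is the squared Pearson correlation of (x, y); RMSE and MAE measure
#' the deviation of y from x directly (against the identity, not against any
#' fitted line). When either variable has zero variance the correlation is
#' undefined and R^2 is returned as `NA` with a warning.
#'
#' @param x,y numeric vectors of equal length (n >= 2).
#' @return list with `r2`, `rmse`, `mae`.
#' @examples
#' agreement_stats(c(0, 1, 2), c(0, 1, 5))
#' @export
agreement_stats <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  r2 <- if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance: R^2 undefined", call. = FALSE)
    NA_real_
  } else stats::cor(x, y)^2
  list(r2 = r2, rmse = sqrt(mean((y - x)^2)), mae = mean(abs(y - x)))
}

#' @export
print.deming <- function(x, digits = 4, ...) {
  cat("Generalized Deming regression (errors in both variables)\n")
  cat(sprintf("  n = %d, slope = %.*f [%.*f, %.*f], intercept = %.*f\n",
              x$n, digits, x$coefficients["slope"],
              digits, x$slope_ci["lower"], digits, x$slope_ci["upper"],
              digits, x$coefficients["intercept"]))
  cat(sprintf("  slope CI excludes zero: %s\n", if (x$significant) "yes" else "no"))
  cat(sprintf("  R^2 = %.*f, RMSE = %.*f, MAE = %.*f (vs identity)\n",
              digits, x$r2, digits, x$rmse, digits, x$mae))
  invisible(x)
}

#' @export
summary.deming <- function(object, ...) {
  print(object, ...)
  if (!object$converged)
    cat("  warning: slope iteration did not converge\n")
  invisible(object)
}

#' @export
coef.deming <- function(object, ...) object$coefficients

#' @export
confint.deming <- function(object, parm = "slope", level = 0.95, ...) {
  if (!isTRUE(all.equal(level, 0.95)))
    stop("only the 95% jackknife interval is computed", call. = FALSE)
  m <- matrix(object$slope_ci, nrow = 1,
              dimnames = list("slope", c("2.5 %", "97.5 %")))
  m[parm, , drop = FALSE]
}

#' @export
predict.deming <- function(object, newdata = NULL, ...) {
  xx <- if (is.null(newdata)) object$x else {
    if (is.data.frame(newdata)) newdata[[1L]] else as.numeric(newdata)
  }
  unname(object$coefficients["intercept"] + object$coefficients["slope"] * xx)
}

#' @export
residuals.deming <- function(object, ...) object$y - predict(object)

#' @export
plot.deming <- function(x, xlab = "experimental (kJ/mol)",
                        ylab = "calculated (kJ/mol)", ...) {
  graphics::plot(x$x, x$y, xlab = xlab, ylab = ylab, pch = 19, ...)
  graphics::arrows(x$x - x$xse, x$y, x$x + x$xse, x$y,
                   angle = 90, code = 3, length = 0.02, col = "grey50")
  graphics::arrows(x$x, x$y - x$yse, x$x, x$y + x$yse,
                   angle = 90, code = 3, length = 0.02, col = "grey50")
  graphics::abline(0, 1, lty = 2)
  graphics::abline(x$coefficients["intercept"], x$coefficients["slope"], col = "red3")
  invisible(x)
}

#' Validate a calculated table against an experimental table
#'
#' Joins calculated and experimental ddG (or selectivity) tables on the
#' compound pair and target, and fits one Deming regression per estimator
#' method with x = experimental, y = calculated, using each table's
#' propagated standard errors. Rows that do not match across the tables are
#' reported in the diagnostics.
#'
#' @param calculated data frame with `compound_i`, `compound_j`,
#'   `target`/`target_k`, `method`, and `ddG`/`dS` with `se`.
#' @param experimental same shape, without `method`.
#' @param mode `"ddg"` or `"selectivity"`.
#' @return list of class `"neqsel_validation"`: `fits` (named list of
#'   [deming()] objects per method), `points` (joined tidy data frame),
#'   `diagnostics`.
#' @export
validate_tables <- function(calculated, experimental, mode = c("ddg", "selectivity")) {
  mode <- match.arg(mode)
  val_col <- if (mode == "ddg") "ddG" else "dS"
  tgt_col <- if (mode == "ddg") "target" else "target_k"
  key_cols <- c("compound_i", "compound_j", tgt_col)
  for (nm in c(key_cols, val_col, "se"))
    if (!nm %in% names(calculated) || !nm %in% names(experimental))
      stop("contract error: tables lack column ", nm, call. = FALSE)
  if (!"method" %in% names(calculated)) calculated$method <- "calculated"
  diagnostics <- character()
  fits <- list(); pts <- list()
  for (m in unique(calculated$method)) {
    sub <- calculated[calculated$method == m, ]
    j <- merge(sub, experimental, by = key_cols, suffixes = c("_calc", "_exp"))
    if (nrow(j) == 0L)
      stop("contract error: empty join between calculated and experimental tables",
           call. = FALSE)
    if (nrow(j) < nrow(sub))
      diagnostics <- c(diagnostics, sprintf(
        "method %s: %d calculated row(s) had no experimental match",
        m, nrow(sub) - nrow(j)))
    d <- data.frame(method = m,
                    j[key_cols],
                    x = j[[paste0(val_col, "_exp")]], x_se = j$se_exp,
                    y = j[[paste0(val_col, "_calc")]], y_se = j$se_calc,
                    stringsAsFactors = FALSE)
    fits[[m]] <- deming(y ~ x, d, xse = d$x_se, yse = d$y_se)
    pts[[m]] <- d
  }
  structure(list(fits = fits,
                 points = do.call(rbind, c(pts, list(make.row.names = FALSE))),
                 diagnostics = diagnostics, mode = mode),
            class = "neqsel_validation")
}

#' @export
print.neqsel_validation <- function(x, ...) {
  cat(sprintf("Validation (%s), %d method(s):\n", x$mode, length(x$fits)))
  for (m in names(x$fits)) {
    f <- x$fits[[m]]
    cat(sprintf("  %-4s n = %2d  slope %6.3f [%6.3f, %6.3f]%s  R^2 %5.3f  RMSE %5.2f  MAE %5.2f\n",
                m, f$n, f$coefficients["slope"], f$slope_ci["lower"], f$slope_ci["upper"],
                if (f$significant) "*" else " ", f$r2, f$rmse, f$mae))
  }
  cat("  (* slope 95% CI excludes zero)\n")
  invisible(x)
}
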