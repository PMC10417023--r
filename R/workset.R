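#' Forward/reverse work samples for one alchemical transformation leg
#'
#' A `work_set` holds the non-equilibrium work values measured while switching
#' one ligand into another (forward, 0 to 1) and back (reverse, 1 to 0), for a
#' single leg of the thermodynamic cycle. Reverse works are stored in the
#' reverse direction's own sign convention — the work done during the 1 to 0
#' switch — and every estimator negates them internally where needed.
#'
#' @param forward numeric vector of forward work values, kJ/mol (may be empty).
#' @param reverse numeric vector of reverse work values, kJ/mol (may be empty).
#' @param temperature temperature in Kelvin.
#' @param pair transformation identifier, `"from->to"` (reference compound to
#'   alternate compound).
#' @param target kinase identifier.
#' @param leg `"complex"` or `"solvent"`.
#' @param conformer conformer label (e.g. `"sin"`, `"anti"`, `"default"`).
#' @return an object of class `"work_set"`.
#' @examples
#' ws <- work_set(forward = c(10.2, 11.5), reverse = c(-9.8, -10.4))
#' ws
#' @export
work_set <- function(forward = numeric(), reverse = numeric(),
                     temperature = 298.15, pair = "A->B", target = NA_character_,
                     leg = c("complex", "solvent"), conformer = "default") {
  leg <- match.arg(leg)
  forward <- as.numeric(forward)
  reverse <- as.numeric(reverse)
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      !is.finite(temperature) || temperature <= 0)
    stop("`temperature` must be a single positive Kelvin value", call. = FALSE)
  if (length(forward) == 0L && length(reverse) == 0L)
    stop("a work_set needs at least one work value in some direction", call. = FALSE)
  if (anyNA(forward) || anyNA(reverse) ||
      any(!is.finite(forward)) || any(!is.finite(reverse)))
    stop("work values must be finite", call. = FALSE)
  structure(list(
    forward = forward, reverse = reverse, temperature = temperature,
    pair = as.character(pair), target = as.character(target),
    leg = leg, conformer = as.character(conformer)
  ), class = "work_set")
}

#' @export
print.work_set <- function(x, ...) {
  cat(sprintf("<work_set> %s | %s | %s leg | conformer '%s' | T = %.2f K\n",
              x$pair, x$target, x$leg, x$conformer, x$temperature))
  cat(sprintf("  forward: n = %d%s\n", length(x$forward),
              if (length(x$forward)) sprintf(", mean = %.3f kJ/mol", mean(x$forward)) else ""))
  cat(sprintf("  reverse: n = %d%s\n", length(x$reverse),
              if (length(x$reverse)) sprintf(", mean = %.3f kJ/mol", mean(x$reverse)) else ""))
  invisible(x)
}

# inverse temperature, (kJ/mol)^-1
beta_of <- function(ws) 1 / rt_kJ(ws$temperature)

#' Draw Crooks-consistent Gaussian work samples
#'
#' Samples forward works from N(dG + beta sigma^2 / 2, sigma^2) and reverse
#' works from N(-dG + beta sigma^2 / 2, sigma^2) (reverse direction's own
#' sign), so that the two distributions satisfy the Crooks fluctuation theorem
#' P_F(W) / P_R(-W) = exp(beta (W - dG)) exactly in law: the negated reverse
#' distribution has mean dG - beta sigma^2 / 2 and the same width.
#'
#' @param dG true free energy difference of the transformation, kJ/mol.
#' @param sigma work distribution standard deviation, kJ/mol (> 0).
#' @param n_forward,n_reverse sample counts (>= 0, not both zero).
#' @param temperature Kelvin.
#' @param seed integer seed; the draw is reproducible for a fixed seed.
#' @param ... tags passed to [work_set()] (`pair`, `target`, `leg`, `conformer`).
#' @return a [work_set()].
#' @examples
#' ws <- sample_crooks_gaussian(10, 2, 100, 100, seed = 1)
#' mean(ws$forward) # near 10 + sigma^2 / (2 RT)
#' @export
sample_crooks_gaussian <- function(dG, sigma, n_forward, n_reverse,
                                   temperature = 298.15, seed = NULL, ...) {
  if (!is.finite(sigma) || sigma <= 0)
    stop("`sigma` must be positive", call. = FALSE)
  if (!is.finite(temperature) || temperature <= 0)
    stop("`temperature` must be positive", call. = FALSE)
  n_forward <- as.integer(n_forward); n_reverse <- as.integer(n_reverse)
  if (n_forward < 0L || n_reverse < 0L || (n_forward == 0L && n_reverse == 0L))
    stop("sample counts must be >= 0 with at least one positive", call. = FALSE)
  beta <- 1 / rt_kJ(temperature)
  shift <- beta * sigma^2 / 2
  with_seed(seed, {
    fwd <- if (n_forward > 0L) stats::rnorm(n_forward, dG + shift, sigma) else numeric()
    rev <- if (n_reverse > 0L) stats::rnorm(n_reverse, -dG + shift, sigma) else numeric()
    work_set(forward = fwd, reverse = rev, temperature = temperature, ...)
  })
}

#' Integrate a dH/dlambda trace into a work value
#'
#' Trapezoidal integration of the Hamiltonian derivative over the switching
#' coordinate. The sign follows the orientation of the lambda grid: a
#' descending grid yields the reverse-direction work in its own sign.
#'
#' @param lambda_values strictly monotone grid in \[0, 1\] (length >= 2).
#' @param dhdl_values dH/dlambda values, kJ/mol, same length.
#' @return work in kJ/mol.
#' @examples
#' integrate_work(c(0, 0.5, 1), c(0, 1, 2)) # 1
#' @export
integrate_work <- function(lambda_values, dhdl_values) {
  if (length(lambda_values) != length(dhdl_values) || length(lambda_values) < 2L)
    stop("lambda and dH/dlambda grids must have equal length >= 2", call. = FALSE)
  d <- diff(lambda_values)
  if (!(all(d > 0) || all(d < 0)))
    stop("lambda grid must be strictly monotone", call. = FALSE)
  sum(d * (utils::head(dhdl_values, -1) + utils::tail(dhdl_values, -1)) / 2)
}
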