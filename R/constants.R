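#' Physical constants and unit conversions
#'
#' Molar gas constant in kJ/(mol K). All free energies in this package are in
#' kJ/mol; kcal appears only at presentation boundaries.
#'
#' @keywords internal
#' @name constants
NULL

# kJ/(mol K)
GAS_CONSTANT_KJ <- 8.314462618e-3

# normal quantile for a 95% two-sided interval
Z_95 <- 1.959964

#' Thermal energy RT
#'
#' @param temperature temperature in Kelvin.
#' @return RT in kJ/mol.
#' @examples
#' rt_kJ(298.15) # about 2.479
#' @export
rt_kJ <- function(temperature) {
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      !is.finite(temperature) || temperature <= 0) {
    stop("`temperature` must be a single positive number (Kelvin)", call. = FALSE)
  }
  GAS_CONSTANT_KJ * temperature
}

#' Convert kJ/mol to kcal/mol
#'
#' Two calorie conventions are in circulation: the thermochemical calorie
#' (4.184 J) and the International Table calorie (4.1868 J). The raw quotient
#' is returned; rounding or truncation for display is the caller's choice.
#' Note that 3.5 kJ/mol is 0.8365 kcal/mol (thermochemical), which prints as
#' 0.84 under round-half-up at two decimals and as 0.83 under truncation.
#'
#' @param x value(s) in kJ/mol.
#' @param convention `"thermochemical"` (divide by 4.184, default) or
#'   `"IT"` (divide by 4.1868).
#' @return value(s) in kcal/mol (unrounded).
#' @examples
#' kj_to_kcal(3.5)          # 0.8365...
#' kj_to_kcal(5.9)          # 1.4102...
#' @export
kj_to_kcal <- function(x, convention = c("thermochemical", "IT")) {
  convention <- match.arg(convention)
  stopifnot(is.numeric(x), all(is.finite(x)))
  x / switch(convention, thermochemical = 4.184, IT = 4.1868)
}

# run a block with a private RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# deterministic 31-bit sub-seed from a root seed and a string label
derive_seed <- function(seed, label) {
  h <- 0
  for (k in utf8ToInt(label)) h <- (h * 131 + k) %% 2147483647
  as.integer((h + as.numeric(seed) * 2654435761) %% 2147483647)
}

#' Default run configuration
#'
#' Bundles the constants and defaults shared by the pipeline stages: the
#' experimental-conversion temperature (the 30 degree C assay, 303.15 K), the
#' simulation temperature (298.15 K), bootstrap replicate count, reference
#' compound and reference kinase.
#'
#' @param temperature_K temperature for experimental IC50 conversion, Kelvin.
#' @param sim_temperature_K temperature for simulated work samples, Kelvin.
#' @param n_boot bootstrap replicates for estimator standard errors.
#' @param seed integer seed; required by any stochastic step.
#' @param reference_compound compound identifier used as the transformation
#'   reference.
#' @param reference_target kinase against which selectivity is referenced.
#' @return a list of class `"run_config"`.
#' @export
run_config <- function(temperature_K = 303.15, sim_temperature_K = 298.15,
                       n_boot = 1000L, seed = NULL,
                       reference_compound = "1", reference_target = "CDK2") {
  stopifnot(temperature_K > 0, sim_temperature_K > 0, n_boot >= 2)
  structure(list(
    temperature_K = temperature_K,
    sim_temperature_K = sim_temperature_K,
    n_boot = as.integer(n_boot),
    seed = if (is.null(seed)) NULL else as.integer(seed),
    reference_compound = as.character(reference_compound),
    reference_target = as.character(reference_target),
    z_95 = Z_95,
    kcal_per_kJ = 4.184
  ), class = "run_config")
}
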