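#' Specification of a synthetic compound-by-kinase study
#'
#' Describes a full synthetic study emulating the study design of the
#' motivating application: a set of compounds with a designated reference,
#' transformed pairwise against a panel of kinases, with Crooks-consistent
#' work samples for the complex and solvent legs of each transformation and
#' log-normally noised IC50 measurements derived from the same underlying
#' truth through the Cheng-Prusoff relation.
#'
#' Defaults reproduce a realistic 4-compound x 4-CDK study: true binding free
#' energies derived from sub-micromolar-to-tens-of-micromolar inhibition
#' constants, switching-work noise of 2 kJ/mol, 100 transitions per
#' direction, and IC50 log-noise of 0.15 (natural-log units).
#'
#' @param compounds character vector of compound identifiers.
#' @param reference_compound identifier of the transformation reference.
#' @param targets character vector of kinase identifiers.
#' @param reference_target kinase used as the selectivity reference.
#' @param true_dG matrix of true binding free energies, kJ/mol, with
#'   `rownames = compounds` and `colnames = targets`.
#' @param solvent_dG named numeric, one true solvent-leg dG per non-reference
#'   compound (the solvent leg of the transformation reference -> compound),
#'   kJ/mol. The solvent leg is target independent.
#' @param work_sigma work distribution SD, kJ/mol (> 0).
#' @param n_forward,n_reverse work sample counts per direction (>= 1).
#' @param ic50_noise_sd SD of the multiplicative log-IC50 noise, natural-log
#'   units (>= 0).
#' @param atp_conc assay ATP concentration, uM.
#' @param km named numeric, ATP Km per target, uM.
#' @param temperature Kelvin, used for both the work sampling and the
#'   truth-side IC50 model.
#' @param selectivity_compound compound the selectivity truth table is
#'   referenced to.
#' @param seed root integer seed; per-work-set streams are derived from it
#'   deterministically.
#' @return a list of class `"synthetic_study_spec"`.
#' @export
synthetic_study_spec <- function(compounds = c("1", "2", "3", "4"),
                                 reference_compound = "1",
                                 targets = c("CDK1", "CDK2", "CDK5", "CDK9"),
                                 reference_target = "CDK2",
                                 true_dG = NULL,
                                 solvent_dG = NULL,
                                 work_sigma = 2,
                                 n_forward = 100L, n_reverse = 100L,
                                 ic50_noise_sd = 0.15,
                                 atp_conc = 1,
                                 km = NULL,
                                 temperature = 298.15,
                                 selectivity_compound = "2",
                                 seed = 1L) {
  compounds <- as.character(compounds); targets <- as.character(targets)
  if (!reference_compound %in% compounds)
    stop("configuration error: reference compound not in `compounds`", call. = FALSE)
  if (!reference_target %in% targets)
    stop("configuration error: reference target not in `targets`", call. = FALSE)
  if (!selectivity_compound %in% compounds)
    stop("configuration error: selectivity compound not in `compounds`", call. = FALSE)
  if (is.null(true_dG)) {
    # binding free energies of micromolar-range inhibitors, kJ/mol at ~300 K
    rt <- rt_kJ(temperature)
    ki_uM <- matrix(c(14, 0.71, 40, 3.0,
                      0.72, 0.16, 0.88, 1.0,
                      30, 1.2, 79, 4.3,
                      6.2, 0.27, 20, 0.88),
                    nrow = 4, byrow = TRUE,
                    dimnames = list(c("1", "2", "3", "4"),
                                    c("CDK1", "CDK2", "CDK5", "CDK9")))
    if (!all(compounds %in% rownames(ki_uM)) || !all(targets %in% colnames(ki_uM)))
      stop("`true_dG` must be supplied for non-default compound/target panels",
           call. = FALSE)
    true_dG <- rt * log(ki_uM[compounds, targets, drop = FALSE] * 1e-6)
  }
  if (!all(compounds %in% rownames(true_dG)) || !all(targets %in% colnames(true_dG)))
    stop("`true_dG` must be a compounds x targets matrix with dimnames", call. = FALSE)
  alts <- setdiff(compounds, reference_compound)
  if (is.null(solvent_dG))
    solvent_dG <- stats::setNames(seq(-5, 5, length.out = max(length(alts), 2L))[seq_along(alts)],
                                  alts)
  if (!all(alts %in% names(solvent_dG)))
    stop("`solvent_dG` must name every non-reference compound", call. = FALSE)
  if (is.null(km)) km <- stats::setNames(rep(10, length(targets)), targets)
  if (!all(targets %in% names(km))) stop("`km` must name every target", call. = FALSE)
  stopifnot(work_sigma > 0, n_forward >= 1L, n_reverse >= 1L,
            ic50_noise_sd >= 0, atp_conc > 0, all(km > 0), temperature > 0)
  structure(list(
    compounds = compounds, reference_compound = reference_compound,
    targets = targets, reference_target = reference_target,
    true_dG = true_dG[compounds, targets, drop = FALSE],
    solvent_dG = solvent_dG[alts],
    work_sigma = work_sigma,
    n_forward = as.integer(n_forward), n_reverse = as.integer(n_reverse),
    ic50_noise_sd = ic50_noise_sd, atp_conc = atp_conc, km = km[targets],
    temperature = temperature,
    selectivity_compound = selectivity_compound,
    seed = as.integer(seed)
  ), class = "synthetic_study_spec")
}

#' Generate a full synthetic study
#'
#' For each (compound pair, target) the generator emits a complex-leg work
#' set centred on `solvent_dG + (dG[alt, target] - dG[ref, target])` and a
#' solvent-leg work set centred on `solvent_dG`, so that the thermodynamic
#' cycle (complex minus solvent) recovers the true relative binding free
#' energy. For each (compound, target) an IC50 record is derived from the
#' same truth: Ki = exp(dG / RT) in molar units, IC50 = Ki (1 + \[ATP\]/Km),
#' multiplied by exp(N(0, ic50_noise_sd^2)), with a symmetric-in-log 95% CI
#' whose half-width matches the noise SD. Truth tables of all relative
#' binding free energies and selectivities are returned for
#' parameter-recovery tests.
#'
#' @param spec a [synthetic_study_spec()].
#' @return a list of class `"synthetic_study"` with elements `works` (list of
#'   [work_set()]), `ic50` (data frame of inhibition records), `truth`
#'   (list with `ddg` and `ds` data frames), and `spec`.
#' @examples
#' study <- make_synthetic_study(synthetic_study_spec(seed = 7))
#' length(study$works) # 3 pairs x 4 targets x 2 legs = 24
#' @export
make_synthetic_study <- function(spec) {
  stopifnot(inherits(spec, "synthetic_study_spec"))
  ref <- spec$reference_compound
  alts <- setdiff(spec$compounds, ref)
  rt <- rt_kJ(spec$temperature)

  works <- list()
  ddg_rows <- list()
  for (a in alts) {
    pair <- paste0(ref, "->", a)
    for (t in spec$targets) {
      ddg_true <- spec$true_dG[a, t] - spec$true_dG[ref, t]
      dg_complex <- spec$solvent_dG[[a]] + ddg_true
      for (leg in c("complex", "solvent")) {
        dg_leg <- if (leg == "complex") dg_complex else spec$solvent_dG[[a]]
        ws <- sample_crooks_gaussian(
          dG = dg_leg, sigma = spec$work_sigma,
          n_forward = spec$n_forward, n_reverse = spec$n_reverse,
          temperature = spec$temperature,
          seed = derive_seed(spec$seed, paste(pair, t, leg, sep = "|")),
          pair = pair, target = t, leg = leg)
        works[[paste(pair, t, leg, sep = "|")]] <- ws
      }
      ddg_rows[[paste(pair, t)]] <- data.frame(
        compound_i = a, compound_j = ref, target = t,
        ddG_true = ddg_true, stringsAsFactors = FALSE)
    }
  }
  truth_ddg <- do.call(rbind, c(ddg_rows, list(make.row.names = FALSE)))

  # selectivity truth, re-referenced to the selectivity compound
  i <- spec$selectivity_compound
  ds_rows <- list()
  for (j in setdiff(spec$compounds, i)) {
    for (t in setdiff(spec$targets, spec$reference_target)) {
      dd_k <- (spec$true_dG[i, t] - spec$true_dG[j, t])
      dd_ref <- (spec$true_dG[i, spec$reference_target] -
                   spec$true_dG[j, spec$reference_target])
      ds_rows[[paste(i, j, t)]] <- data.frame(
        compound_i = i, compound_j = j, target_k = t,
        reference_target = spec$reference_target,
        dS_true = dd_k - dd_ref, stringsAsFactors = FALSE)
    }
  }
  truth_ds <- do.call(rbind, c(ds_rows, list(make.row.names = FALSE)))

  ic50_rows <- list()
  for (cpd in spec$compounds) {
    for (t in spec$targets) {
      ki_uM <- exp(spec$true_dG[cpd, t] / rt) * 1e6 # molar standard state -> uM
      ic50_true <- ki_uM * (1 + spec$atp_conc / spec$km[[t]])
      noise <- with_seed(derive_seed(spec$seed, paste("ic50", cpd, t, sep = "|")),
                         stats::rnorm(1, 0, spec$ic50_noise_sd))
      ic50 <- ic50_true * exp(noise)
      half <- Z_95 * spec$ic50_noise_sd
      ic50_rows[[paste(cpd, t)]] <- data.frame(
        compound = cpd, target = t,
        ic50_uM = ic50,
        ci_low_uM = ic50 * exp(-half), ci_high_uM = ic50 * exp(half),
        atp_uM = spec$atp_conc, km_uM = spec$km[[t]],
        stringsAsFactors = FALSE)
    }
  }
  ic50 <- do.call(rbind, c(ic50_rows, list(make.row.names = FALSE)))

  structure(list(works = works, ic50 = ic50,
                 truth = list(ddg = truth_ddg, ds = truth_ds), spec = spec),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("<synthetic_study> %d compounds x %d targets (ref %s / %s)\n",
              length(x$spec$compounds), length(x$spec$targets),
              x$spec$reference_compound, x$spec$reference_target))
  cat(sprintf("  %d work sets, %d inhibition records, seed %d\n",
              length(x$works), nrow(x$ic50), x$spec$seed))
  invisible(x)
}
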