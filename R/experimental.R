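#' Read an IC50 inhibition table
#'
#' CSV with columns `compound,target,ic50_uM,ci_low_uM,ci_high_uM` and
#' optional `atp_uM`, `km_uM`. The packaged fixture
#' `system.file("extdata", "cdk_ic50.csv", package = "neqsel")` carries the
#' in vitro CDK panel (IC50 with 95% CI, uM; 1 uM ATP) used throughout the
#' examples.
#'
#' @param path CSV path.
#' @return data frame of inhibition records, validated.
#' @export
read_ic50 <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("compound", "target", "ic50_uM", "ci_low_uM", "ci_high_uM")
  if (!all(need %in% names(df)))
    stop("IC50 table must have columns ", paste(need, collapse = ", "), call. = FALSE)
  df$compound <- as.character(df$compound)
  df$target <- as.character(df$target)
  validate_ic50(df)
  df
}

validate_ic50 <- function(df) {
  bad <- !(df$ci_low_uM > 0 & df$ci_low_uM <= df$ic50_uM &
             df$ic50_uM <= df$ci_high_uM)
  if (any(bad))
    stop("invalid inhibition record(s): need 0 < ci_low <= ic50 <= ci_high (rows ",
         paste(which(bad), collapse = ", "), ")", call. = FALSE)
  if ("atp_uM" %in% names(df) && any(df$atp_uM <= 0))
    stop("`atp_uM` must be positive", call. = FALSE)
  if ("km_uM" %in% names(df) && any(!is.na(df$km_uM) & df$km_uM <= 0))
    stop("`km_uM` must be positive when present", call. = FALSE)
  invisible(df)
}

#' Cheng-Prusoff conversion of IC50 to Ki
#'
#' For a competitive, ATP-site inhibitor assayed at substrate concentration
#' \[ATP\] against a target with Michaelis constant Km:
#' Ki = IC50 / (1 + \[ATP\]/Km). The Km must be supplied explicitly; there is
#' no silent default, because within-target free energy differences never
#' need it (the correction factor cancels in the ratio).
#'
#' @param ic50 IC50, uM.
#' @param atp_conc assay ATP concentration, uM.
#' @param km target ATP Km, uM.
#' @return Ki, uM.
#' @examples
#' cheng_prusoff(2, atp_conc = 1, km = 1) # 1
#' @export
cheng_prusoff <- function(ic50, atp_conc, km) {
  if (missing(km) || is.null(km) || anyNA(km))
    stop("Km unavailable: Cheng-Prusoff conversion needs an explicit Km", call. = FALSE)
  stopifnot(all(ic50 > 0), all(atp_conc > 0), all(km > 0))
  ic50 / (1 + atp_conc / km)
}

# log-scale SE of one IC50 from its symmetric-in-log 95% CI
log_se_from_ci <- function(ci_low, ci_high) log(ci_high / ci_low) / (2 * Z_95)

#' Experimental relative binding free energy of a compound pair
#'
#' Converts two inhibition records on the same target into
#' ddG_exp = RT ln(K_i / K_j). When Km is available for the target the Ki
#' values go through the Cheng-Prusoff conversion; when it is not, the raw
#' IC50 ratio is used, which is exact within one target at fixed \[ATP\]
#' because the Cheng-Prusoff factor cancels. The standard error comes from
#' the symmetric-in-log 95% confidence intervals:
#' se = RT sqrt(s_i^2 + s_j^2) with s = ln(ci_high/ci_low) / (2 z),
#' z = 1.959964.
#'
#' @param record_i,record_j one-row inhibition data frames (same target).
#' @param temperature Kelvin (default 303.15 K, the 30 degree C assay).
#' @return one-row data frame: `compound_i`, `compound_j`, `target`, `ddG`,
#'   `se`, `temperature`.
#' @export
ddg_exp_pair <- function(record_i, record_j, temperature = 303.15) {
  for (r in list(record_i, record_j)) validate_ic50(r)
  if (!identical(record_i$target, record_j$target))
    stop("contract error: records are on different targets", call. = FALSE)
  rt <- rt_kJ(temperature)
  have_km <- all(c("km_uM", "atp_uM") %in% names(record_i)) &&
    all(c("km_uM", "atp_uM") %in% names(record_j)) &&
    !anyNA(c(record_i$km_uM, record_j$km_uM))
  if (have_km) {
    k_i <- cheng_prusoff(record_i$ic50_uM, record_i$atp_uM, record_i$km_uM)
    k_j <- cheng_prusoff(record_j$ic50_uM, record_j$atp_uM, record_j$km_uM)
  } else {
    k_i <- record_i$ic50_uM; k_j <- record_j$ic50_uM
  }
  s_i <- log_se_from_ci(record_i$ci_low_uM, record_i$ci_high_uM)
  s_j <- log_se_from_ci(record_j$ci_low_uM, record_j$ci_high_uM)
  data.frame(compound_i = record_i$compound, compound_j = record_j$compound,
             target = record_i$target,
             ddG = rt * log(k_i / k_j),
             se = rt * sqrt(s_i^2 + s_j^2),
             temperature = temperature, stringsAsFactors = FALSE)
}

#' Experimental ddG table referenced to one compound
#'
#' One experimental relative binding free energy per (non-reference
#' compound, target), oriented (compound, reference) so that the pairs match
#' calculated transformations reference -> compound. Targets on which the
#' reference compound was not measured are skipped with a diagnostic.
#'
#' @param records inhibition data frame (as from [read_ic50()]).
#' @param reference_compound the reference compound identifier.
#' @param temperature Kelvin.
#' @return list with `ddg` (data frame) and `diagnostics`.
#' @export
exp_table <- function(records, reference_compound = "1", temperature = 303.15) {
  validate_ic50(records)
  records <- records[order(records$compound, records$target), ]
  diagnostics <- character()
  rows <- list()
  for (t in sort(unique(records$target))) {
    sub <- records[records$target == t, ]
    ref <- sub[sub$compound == reference_compound, ]
    if (nrow(ref) != 1L) {
      diagnostics <- c(diagnostics, sprintf(
        "target %s skipped: %d measurement(s) of reference compound %s",
        t, nrow(ref), reference_compound))
      next
    }
    for (cpd in setdiff(sub$compound, reference_compound)) {
      rows[[paste(cpd, t)]] <- ddg_exp_pair(sub[sub$compound == cpd, ], ref,
                                            temperature = temperature)
    }
  }
  ddg <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  list(ddg = ddg, diagnostics = diagnostics)
}
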