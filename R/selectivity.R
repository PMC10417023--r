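#' Relative selectivity change between two kinases
#'
#' The selectivity change of a compound pair between a kinase of interest
#' and the reference kinase is the difference of the pair's relative binding
#' free energies on the two targets: dS = ddG^k - ddG^ref, with the two
#' errors combined in quadrature (the dS metric carries the total error of
#' both ddG values).
#'
#' @param ddg_on_k,ddg_on_reference one-row ddG data frames for the same
#'   compound pair and method/source on two different targets.
#' @return one-row data frame: `compound_i`, `compound_j`, `target_k`,
#'   `reference_target`, `dS`, `se`.
#' @export
delta_s <- function(ddg_on_k, ddg_on_reference) {
  k <- ddg_on_k; r <- ddg_on_reference
  if (!identical(k$compound_i, r$compound_i) || !identical(k$compound_j, r$compound_j))
    stop("contract error: selectivity needs the same compound pair on both targets",
         call. = FALSE)
  if (!is.null(k$method) && !is.null(r$method) && !identical(k$method, r$method))
    stop("contract error: selectivity inputs from different methods", call. = FALSE)
  if (identical(k$target, r$target))
    stop("contract error: selectivity needs two different targets", call. = FALSE)
  out <- data.frame(compound_i = k$compound_i, compound_j = k$compound_j,
                    target_k = k$target, reference_target = r$target,
                    dS = k$ddG - r$ddG,
                    se = sqrt(k$se^2 + r$se^2), stringsAsFactors = FALSE)
  if (!is.null(k$method)) out$method <- k$method
  out
}

#' Selectivity table re-referenced to one compound
#'
#' Re-expresses a reference-compound-anchored ddG table as pairs
#' (selectivity compound i, other compound j) via [rebase_pair()], then
#' computes the selectivity change of every such pair on every non-reference
#' target. On a 4-compound x 4-kinase panel this yields 3 pairs x 3 targets
#' = 9 records per method. Pairs missing their reference-target ddG are
#' skipped with a diagnostic.
#'
#' @param ddg a ddG data frame (columns `compound_i`, `compound_j`, `target`,
#'   `ddG`, `se`, optionally `method`) in which every row is oriented
#'   (compound, shared reference compound).
#' @param reference_target kinase against which selectivity is measured.
#' @param compound_i the compound the pairs are re-referenced to.
#' @return list with `ds` (data frame) and `diagnostics`.
#' @export
selectivity_table <- function(ddg, reference_target = "CDK2", compound_i = "2") {
  stopifnot(is.data.frame(ddg), nrow(ddg) > 0L)
  if (!"method" %in% names(ddg)) ddg$method <- "experimental"
  study_ref <- unique(ddg$compound_j)
  if (length(study_ref) != 1L)
    stop("`ddg` must be anchored to a single reference compound", call. = FALSE)
  diagnostics <- character()
  rows <- list()
  for (m in unique(ddg$method)) {
    sub <- ddg[ddg$method == m, ]
    # pair (i, j) on target t, both expressed against the study reference
    pair_ddg <- function(i, j, t) {
      row_for <- function(cpd) sub[sub$compound_i == cpd & sub$target == t, ]
      if (i == study_ref && j == study_ref) return(NULL)
      if (j == study_ref) return(row_for(i))
      if (i == study_ref) { # ddG(j->ref) = -ddG(ref->j)
        rj <- row_for(j)
        if (nrow(rj) != 1L) return(rj[0, ])
        rj$compound_i <- i; rj$compound_j <- j; rj$ddG <- -rj$ddG
        return(rj)
      }
      ra <- row_for(i); rb <- row_for(j)
      if (nrow(ra) != 1L || nrow(rb) != 1L) return(ra[0, ])
      out <- rebase_pair(rb, ra) # ddG(j->i) = ddG(ref->i) - ddG(ref->j)
      out
    }
    others <- setdiff(unique(c(ddg$compound_i, study_ref)), compound_i)
    for (j in others) {
      dd_ref <- pair_ddg(compound_i, j, reference_target)
      if (is.null(dd_ref) || nrow(dd_ref) != 1L) {
        diagnostics <- c(diagnostics, sprintf(
          "pair (%s,%s) method %s skipped: no ddG on reference target %s",
          compound_i, j, m, reference_target))
        next
      }
      for (t in setdiff(unique(ddg$target), reference_target)) {
        dd_k <- pair_ddg(compound_i, j, t)
        if (is.null(dd_k) || nrow(dd_k) != 1L) {
          diagnostics <- c(diagnostics, sprintf(
            "pair (%s,%s) method %s skipped on target %s: missing ddG",
            compound_i, j, m, t))
          next
        }
        rows[[paste(m, j, t)]] <- delta_s(dd_k, dd_ref)
      }
    }
  }
  ds <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  list(ds = ds, diagnostics = diagnostics)
}
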