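#' Relative binding free energy from the thermodynamic cycle
#'
#' The relative binding free energy of an alchemical transformation is the
#' transformation free energy in the complex minus that in solvent; errors
#' combine in quadrature. Both legs must come from the same estimator.
#'
#' @param complex_leg,solvent_leg `fe_estimate` objects sharing a method tag.
#' @param pair transformation identifier `"from->to"`.
#' @param target kinase identifier.
#' @param conformer conformer label.
#' @return one-row data frame: `compound_i` (end state), `compound_j`
#'   (start/reference), `target`, `conformer`, `method`, `ddG`, `se`.
#' @examples
#' cl <- neqsel:::fe_estimate(12, "BAR", se = 0.3)
#' sv <- neqsel:::fe_estimate(2, "BAR", se = 0.4)
#' leg_difference(cl, sv, pair = "1->2", target = "CDK2") # ddG = 10, se = 0.5
#' @export
leg_difference <- function(complex_leg, solvent_leg, pair, target,
                           conformer = "default") {
  stopifnot(inherits(complex_leg, "fe_estimate"), inherits(solvent_leg, "fe_estimate"))
  if (!identical(complex_leg$method, solvent_leg$method))
    stop("contract error: legs estimated with different methods (",
         complex_leg$method, " vs ", solvent_leg$method, ")", call. = FALSE)
  ends <- split_pair(pair)
  se <- if (is.na(complex_leg$se) || is.na(solvent_leg$se)) NA_real_
        else sqrt(complex_leg$se^2 + solvent_leg$se^2)
  data.frame(compound_i = ends[2L], compound_j = ends[1L],
             target = as.character(target), conformer = as.character(conformer),
             method = complex_leg$method,
             ddG = complex_leg$dG - solvent_leg$dG, se = se,
             stringsAsFactors = FALSE)
}

split_pair <- function(pair) {
  parts <- strsplit(as.character(pair), "->", fixed = TRUE)[[1L]]
  if (length(parts) != 2L || any(!nzchar(parts)))
    stop("a pair must be written 'from->to'", call. = FALSE)
  parts
}

#' Select the lowest-ddG conformer
#'
#' Alternative starting conformers of the same transformation are resolved by
#' keeping the candidate with the lowest relative binding free energy; exact
#' ties break lexicographically on the conformer label. The selected
#' candidate's own standard error is carried unchanged.
#'
#' @param candidates data frame of ddG rows (as from [leg_difference()]) for
#'   one (pair, target, method).
#' @return the selected row, with a logical `selected` column set.
#' @export
select_conformer <- function(candidates) {
  if (!is.data.frame(candidates) || nrow(candidates) == 0L)
    stop("contract error: no conformer candidates", call. = FALSE)
  key <- unique(candidates[c("compound_i", "compound_j", "target", "method")])
  if (nrow(key) != 1L)
    stop("contract error: candidates span several (pair, target, method) cells",
         call. = FALSE)
  ord <- order(candidates$ddG, candidates$conformer)
  out <- candidates[ord[1L], , drop = FALSE]
  out$selected <- TRUE
  rownames(out) <- NULL
  out
}

#' Re-reference a transformation pair
#'
#' Given the relative binding free energies of two transformations that share
#' the same reference compound (ref -> a and ref -> b), the free energy of
#' the derived transformation a -> b is their difference, with errors in
#' quadrature: ddG(a->b) = ddG(ref->b) - ddG(ref->a).
#'
#' @param ddg_ref_to_a,ddg_ref_to_b one-row ddG data frames sharing
#'   `compound_j` (the reference), `target`, and `method`.
#' @return a one-row ddG data frame for the pair (b, a).
#' @export
rebase_pair <- function(ddg_ref_to_a, ddg_ref_to_b) {
  a <- ddg_ref_to_a; b <- ddg_ref_to_b
  if (!identical(a$compound_j, b$compound_j) || !identical(a$target, b$target) ||
      !identical(a$method, b$method))
    stop("contract error: rebase requires a shared reference compound, target and method",
         call. = FALSE)
  data.frame(compound_i = b$compound_i, compound_j = a$compound_i,
             target = a$target, conformer = NA_character_, method = a$method,
             ddG = b$ddG - a$ddG,
             se = sqrt(a$se^2 + b$se^2),
             stringsAsFactors = FALSE)
}

#' Assemble the selected ddG table from per-leg estimates
#'
#' Pairs each complex leg with its solvent leg per (pair, target, method,
#' conformer), forms the cycle difference, and applies the lowest-ddG
#' conformer rule per estimator method independently. Cells missing a leg are
#' reported in the diagnostics, never silently dropped or imputed.
#'
#' @param estimates data frame with columns `pair`, `target`, `leg`,
#'   `conformer`, `method`, `dG`, `se` (one row per estimated leg), e.g. from
#'   [estimate_study()].
#' @return list with `ddg` (selected long-format table) and `diagnostics`
#'   (character vector describing incomplete cells).
#' @export
assemble_ddg <- function(estimates) {
  need <- c("pair", "target", "leg", "conformer", "method", "dG", "se")
  if (!all(need %in% names(estimates)))
    stop("`estimates` must have columns ", paste(need, collapse = ", "), call. = FALSE)
  diagnostics <- character()
  rows <- list()
  cells <- unique(estimates[c("pair", "target", "method", "conformer")])
  for (r in seq_len(nrow(cells))) {
    cell <- cells[r, ]
    sub <- estimates[estimates$pair == cell$pair & estimates$target == cell$target &
                       estimates$method == cell$method &
                       estimates$conformer == cell$conformer, ]
    cx <- sub[sub$leg == "complex", ]; sv <- sub[sub$leg == "solvent", ]
    if (nrow(cx) != 1L || nrow(sv) != 1L) {
      diagnostics <- c(diagnostics, sprintf(
        "incomplete cell %s | %s | %s | conformer '%s': %d complex, %d solvent leg(s)",
        cell$pair, cell$target, cell$method, cell$conformer, nrow(cx), nrow(sv)))
      next
    }
    rows[[r]] <- leg_difference(
      fe_estimate(cx$dG, cx$method, se = cx$se),
      fe_estimate(sv$dG, sv$method, se = sv$se),
      pair = cell$pair, target = cell$target, conformer = cell$conformer)
  }
  full <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(full) || nrow(full) == 0L)
    stop("no complete (complex, solvent) leg pairs to assemble", call. = FALSE)
  sel_rows <- list()
  keys <- unique(full[c("compound_i", "compound_j", "target", "method")])
  for (r in seq_len(nrow(keys))) {
    k <- keys[r, ]
    cand <- full[full$compound_i == k$compound_i & full$compound_j == k$compound_j &
                   full$target == k$target & full$method == k$method, ]
    sel_rows[[r]] <- select_conformer(cand)
  }
  ddg <- do.call(rbind, c(sel_rows, list(make.row.names = FALSE)))
  list(ddg = ddg, diagnostics = diagnostics)
}

#' Estimate every leg of a study's work sets
#'
#' Runs [estimate_all()] over a collection of work sets and returns the
#' long-format per-leg estimate table consumed by [assemble_ddg()].
#'
#' @param works list of [work_set()] objects.
#' @param n_boot bootstrap replicates per estimate (0 skips SEs).
#' @param seed root seed for the bootstrap streams.
#' @return data frame with one row per (work set, method).
#' @export
estimate_study <- function(works, n_boot = 0L, seed = NULL) {
  rows <- list()
  for (ws in works) {
    res <- estimate_all(ws, n_boot = n_boot,
                        seed = if (is.null(seed)) NULL
                               else derive_seed(seed, paste(ws$pair, ws$target,
                                                            ws$leg, ws$conformer,
                                                            sep = "|")))
    for (est in res$estimates) {
      rows[[length(rows) + 1L]] <- data.frame(
        pair = ws$pair, target = ws$target, leg = ws$leg,
        conformer = ws$conformer, method = est$method,
        dG = est$dG, se = est$se,
        n_forward = est$n_forward, n_reverse = est$n_reverse,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
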