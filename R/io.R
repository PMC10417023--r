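#' Read a work file
#'
#' Two plain-text dialects are supported. `"scalar"`: one finite work value
#' (kJ/mol) per line, `#` comment lines ignored. `"dhdl"`: two
#' whitespace-separated columns, lambda and dH/dlambda (kJ/mol), with `#`
#' and `@` lines ignored (the xvg-style header convention); the trace is
#' integrated into a single work value with [integrate_work()], so a
#' descending lambda grid yields the reverse-direction work in its own sign.
#'
#' @param path file path.
#' @param dialect `"scalar"` or `"dhdl"`.
#' @return numeric vector of work values (length 1 for `"dhdl"`).
#' @export
read_work_file <- function(path, dialect = c("scalar", "dhdl")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such work file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|@|$)", lines)
  body <- lines[keep]
  if (length(body) == 0L)
    stop("insufficient data: work file ", path, " has no data lines", call. = FALSE)
  if (dialect == "scalar") {
    vals <- suppressWarnings(as.numeric(trimws(body)))
    bad <- which(!is.finite(vals))
    if (length(bad))
      stop(sprintf("format error in %s line %d: '%s' is not a finite number",
                   path, which(keep)[bad[1L]], body[bad[1L]]), call. = FALSE)
    vals
  } else {
    mat <- t(vapply(strsplit(trimws(body), "\\s+"), function(f) {
      v <- suppressWarnings(as.numeric(f[1:2]))
      v
    }, numeric(2)))
    bad <- which(!stats::complete.cases(mat) | !is.finite(rowSums(mat)))
    if (length(bad))
      stop(sprintf("format error in %s line %d: expected two numeric columns",
                   path, which(keep)[bad[1L]]), call. = FALSE)
    integrate_work(mat[, 1L], mat[, 2L])
  }
}

write_scalar_work_file <- function(values, path, comment = NULL) {
  lines <- c(if (!is.null(comment)) paste0("# ", comment),
             sprintf("%.17g", values))
  writeLines(lines, path)
  invisible(path)
}

#' Write a study's work sets to disk
#'
#' Each direction of each work set becomes a scalar work file (one kJ/mol
#' value per line, `#` header), and a manifest CSV
#' (`path,pair,target,leg,conformer,direction,temperature_K`) records the
#' tags — the file tagging is manifest driven, never parsed from file names.
#'
#' @param works list of [work_set()] objects.
#' @param dir output directory (created if missing).
#' @return the manifest data frame, invisibly; written as `manifest.csv`.
#' @seealso [read_work_manifest()]
#' @export
write_work_sets <- function(works, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (k in seq_along(works)) {
    ws <- works[[k]]
    for (direction in c("forward", "reverse")) {
      vals <- ws[[direction]]
      if (length(vals) == 0L) next
      fname <- sprintf("work_%03d_%s.dat", k, direction)
      write_scalar_work_file(vals, file.path(dir, fname),
                             comment = sprintf("%s | %s | %s | %s | %s work (kJ/mol)",
                                               ws$pair, ws$target, ws$leg,
                                               ws$conformer, direction))
      rows[[paste(k, direction)]] <- data.frame(
        path = fname, pair = ws$pair, target = ws$target, leg = ws$leg,
        conformer = ws$conformer, direction = direction,
        temperature_K = ws$temperature, stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read work sets back from a manifest
#'
#' @param dir directory containing `manifest.csv` and the work files it
#'   names (paths are relative to `dir`).
#' @param dialect passed to [read_work_file()].
#' @return named list of [work_set()] objects keyed `pair|target|leg`.
#' @export
read_work_manifest <- function(dir, dialect = "scalar") {
  mf_path <- file.path(dir, "manifest.csv")
  if (!file.exists(mf_path)) stop("no manifest.csv in ", dir, call. = FALSE)
  manifest <- utils::read.csv(mf_path, stringsAsFactors = FALSE)
  need <- c("path", "pair", "target", "leg", "conformer", "direction", "temperature_K")
  if (!all(need %in% names(manifest)))
    stop("manifest must have columns ", paste(need, collapse = ", "), call. = FALSE)
  out <- list()
  keys <- unique(manifest[c("pair", "target", "leg", "conformer", "temperature_K")])
  for (r in seq_len(nrow(keys))) {
    k <- keys[r, ]
    sub <- manifest[manifest$pair == k$pair & manifest$target == k$target &
                      manifest$leg == k$leg & manifest$conformer == k$conformer, ]
    grab <- function(dirn) {
      rows <- sub[sub$direction == dirn, ]
      if (nrow(rows) == 0L) return(numeric())
      unlist(lapply(file.path(dir, rows$path), read_work_file, dialect = dialect))
    }
    out[[paste(k$pair, k$target, k$leg, sep = "|")]] <-
      work_set(forward = grab("forward"), reverse = grab("reverse"),
               temperature = k$temperature_K, pair = k$pair, target = k$target,
               leg = k$leg, conformer = k$conformer)
  }
  out
}

#' Write a complete synthetic study to a directory
#'
#' Emits the work files with their manifest, the IC50 table
#' (`ic50.csv`, schema `compound,target,ic50_uM,ci_low_uM,ci_high_uM,
#' atp_uM,km_uM`), and the truth tables (`truth_ddg.csv`, `truth_ds.csv`).
#'
#' @param study a [make_synthetic_study()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_work_sets(study$works, file.path(dir, "works"))
  utils::write.csv(study$ic50, file.path(dir, "ic50.csv"), row.names = FALSE)
  utils::write.csv(study$truth$ddg, file.path(dir, "truth_ddg.csv"), row.names = FALSE)
  utils::write.csv(study$truth$ds, file.path(dir, "truth_ds.csv"), row.names = FALSE)
  invisible(dir)
}
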