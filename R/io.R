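#' Read a cohort CSV
#'
#' Comma-separated, UTF-8, '.' decimal, header row with the columns of
#' [cohort_columns()] (plus optional `prior_refractive_surgery`).
#'
#' @param path File path.
#' @return Data frame (unvalidated; pass to [validate_cohort()]).
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(d) == 0) stop("cohort file is empty: ", path, call. = FALSE)
  d
}

#' Write a cohort CSV (and optional ground-truth sidecar)
#'
#' @param x A cohort data frame or a `synthetic_cohort` (in which case the
#'   ground truth is written next to the CSV as `<path>.truth.json` and the
#'   generator parameters as `<path>.config.json`).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(x, path) {
  if (inherits(x, "synthetic_cohort")) {
    utils::write.csv(x$cohort, path, row.names = FALSE, quote = FALSE)
    jsonlite::write_json(x$truth, paste0(path, ".truth.json"),
                         digits = NA, auto_unbox = TRUE)
    cfg <- x$config
    cfg$params <- unclass(cfg$params)
    cfg$true_constants <- lapply(cfg$true_constants, unclass)
    jsonlite::write_json(unclass(cfg), paste0(path, ".config.json"),
                         digits = NA, auto_unbox = TRUE)
  } else {
    utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Write optimized constants as JSON
#'
#' One entry per formula and stratum, consumable by downstream evaluation.
#'
#' @param optimization Nested list from [optimize_all()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_constants_json <- function(optimization, path) {
  out <- lapply(optimization, function(o) {
    lapply(o, function(r) {
      list(constant = r$constant_value,
           mean_spe_at_optimum = r$mean_spe_at_optimum,
           n_train = r$n_train, converged = r$converged,
           bounds = r$search_bounds, tolerance = r$tolerance)
    })
  })
  jsonlite::write_json(out, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Write report tables as TSV files
#'
#' @param report List from [make_report()].
#' @param dir Output directory (created if missing).
#' @return Character vector of written paths, invisibly.
#' @export
write_report_tsv <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(names(report), function(nm) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    utils::write.table(report[[nm]], p, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    p
  }, character(1))
  invisible(paths)
}
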