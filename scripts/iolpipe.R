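#!/usr/bin/env Rscript
# Thin command-line front end over the iolstrat package.
#
#   Rscript scripts/iolpipe.R simulate --out cohort.csv [--n 5519] [--seed 1]
#       [--offset-female 0] [--offset-male 0] [--noise-sd 0.4]
#   Rscript scripts/iolpipe.R validate --cohort cohort.csv
#   Rscript scripts/iolpipe.R run --cohort cohort.csv --out-dir results
#       [--split-seed 1] [--tol 1e-3]
#
# `run` writes constants.json, predictions_pooled.csv,
# predictions_by_gender.csv, the four report TSVs and a manifest.json
# capturing every parameter and seed needed to reproduce the outputs.

suppressMessages({
  library(iolstrat)
  library(optparse)
})

argv <- commandArgs(trailingOnly = TRUE)
if (length(argv) < 1) {
  stop("usage: iolpipe.R <simulate|validate|run> [options]", call. = FALSE)
}
cmd <- argv[1]
rest <- argv[-1]

fail <- function(...) { message("error: ", ...); quit(status = 1) }

if (cmd == "simulate") {
  opts <- parse_args(OptionParser(option_list = list(
    make_option("--out", type = "character"),
    make_option("--n", type = "integer", default = 5519),
    make_option("--seed", type = "integer", default = 1),
    make_option("--offset-female", type = "double", default = 0,
                dest = "offset_female"),
    make_option("--offset-male", type = "double", default = 0,
                dest = "offset_male"),
    make_option("--noise-sd", type = "double", default = 0.4,
                dest = "noise_sd"))), args = rest)
  if (is.null(opts$out)) fail("simulate requires --out")
  sc <- tryCatch(
    generate_cohort(generator_config(
      n_patients = opts$n, seed = opts$seed, noise_sd = opts$noise_sd,
      gender_offsets = c(female = opts$offset_female,
                         male = opts$offset_male))),
    error = function(e) fail(conditionMessage(e)))
  write_cohort_csv(sc, opts$out)
  message(sprintf("simulate: wrote %d eyes of %d patients to %s",
                  nrow(sc$cohort), length(unique(sc$cohort$patient_id)),
                  opts$out))
} else if (cmd == "validate") {
  opts <- parse_args(OptionParser(option_list = list(
    make_option("--cohort", type = "character"))), args = rest)
  if (is.null(opts$cohort)) fail("validate requires --cohort")
  raw <- tryCatch(read_cohort_csv(opts$cohort),
                  error = function(e) fail(conditionMessage(e)))
  v <- tryCatch(validate_cohort(raw),
                error = function(e) fail(conditionMessage(e)))
  message(sprintf("validate: %d rows, %d accepted, %d rejected",
                  nrow(raw), nrow(v$records), sum(v$rejections$n)))
  if (nrow(v$rejections)) {
    apply(v$rejections, 1, function(r) {
      message(sprintf("  %-35s %s", r[["reason"]], r[["n"]]))
    })
  }
} else if (cmd == "run") {
  opts <- parse_args(OptionParser(option_list = list(
    make_option("--cohort", type = "character"),
    make_option("--out-dir", type = "character", dest = "out_dir"),
    make_option("--split-seed", type = "integer", default = 1,
                dest = "split_seed"),
    make_option("--tol", type = "double", default = 1e-3))), args = rest)
  if (is.null(opts$cohort) || is.null(opts$out_dir)) {
    fail("run requires --cohort and --out-dir")
  }
  raw <- tryCatch(read_cohort_csv(opts$cohort),
                  error = function(e) fail(conditionMessage(e)))
  res <- tryCatch(
    run_pipeline(raw, split_seed = opts$split_seed, tol = opts$tol),
    error = function(e) fail(conditionMessage(e)))
  dir.create(opts$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_constants_json(res$optimization,
                       file.path(opts$out_dir, "constants.json"))
  utils::write.csv(res$eval_pooled$predictions,
                   file.path(opts$out_dir, "predictions_pooled.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(res$eval_by_gender$predictions,
                   file.path(opts$out_dir, "predictions_by_gender.csv"),
                   row.names = FALSE, quote = FALSE)
  write_report_tsv(res$report, opts$out_dir)
  manifest <- list(
    cohort = normalizePath(opts$cohort),
    split_seed = opts$split_seed, tol = opts$tol,
    formulas = res$formulas,
    reference_formula = res$reference_formula,
    n_input = nrow(raw),
    n_after_validation = nrow(res$validation$records),
    n_outliers_removed = res$outliers$n_removed,
    n_train = nrow(res$split$train), n_test = nrow(res$split$test),
    package_version = as.character(utils::packageVersion("iolstrat")),
    r_version = R.version.string)
  jsonlite::write_json(manifest, file.path(opts$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  message(sprintf("run: %d train / %d test eyes; outputs in %s",
                  nrow(res$split$train), nrow(res$split$test), opts$out_dir))
} else {
  fail("unknown subcommand '", cmd, "'")
}
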