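#' Run the full analysis pipeline on a cohort
#'
#' Reproduces the study workflow end to end: validate records, exclude
#' prediction-error outliers under a reference formula (one pass, before
#' splitting), split patients 1:1 into training and testing sets keeping
#' one randomly chosen eye per test patient, optimize each formula's lens
#' constant on the training eyes (pooled and separately per gender), then
#' evaluate both constant sets on the test eyes and run the group
#' comparisons and the prediction-error regression.
#'
#' @param cohort Data frame in the schema of [cohort_columns()].
#' @param split_seed Seed for the patient-level split and test-eye choice.
#' @param formulas Formula ids to analyze.
#' @param reference_formula Formula whose signed prediction error (at the
#'   starting constants) defines outliers.
#' @param z_threshold Outlier threshold in SD units (default 1.96).
#' @param tol Optimizer tolerance on |mean SPE| (D).
#' @param params,acd_source Optical model configuration.
#' @return Object of class `iol_pipeline_result`: list with `validation`,
#'   `outliers`, `split`, `optimization` (nested constants), `eval_pooled`,
#'   `eval_by_gender`, `mae_comparison`, `gender_tests`, `regression`,
#'   and `report` (see [make_report()]).
#' @export
run_pipeline <- function(cohort, split_seed = 1,
                         formulas = iol_formulas(),
                         reference_formula = "srkt",
                         z_threshold = 1.96, tol = 1e-3,
                         params = optical_params(), acd_source = "acd") {
  val <- validate_cohort(cohort)
  records <- val$records
  if (nrow(records) < 10) {
    stop("fewer than 10 valid records after validation", call. = FALSE)
  }

  ref_const <- default_constants(reference_formula)
  ref_pred <- predict_refraction(reference_formula, ref_const, records,
                                 records$iol_power_d, params, acd_source)
  out <- exclude_outliers(records, ref_pred - records$postop_se_d,
                          z_threshold)
  records <- out$records

  split <- split_train_test(records, split_seed)
  optimization <- optimize_all(split$train, formulas, tol = tol,
                               params = params, acd_source = acd_source)

  eval_pooled <- evaluate_formulas(split$test, optimization, "pooled",
                                   formulas, params, acd_source)
  eval_gender <- evaluate_formulas(split$test, optimization, "by_gender",
                                   formulas, params, acd_source)

  mae_comparison <- compare_mae(eval_pooled, eval_gender, formulas)
  gender_tests <- gender_spe_tests(eval_pooled, formulas)
  regression <- pe_regression(split$test, eval_pooled$predictions,
                              depth_var = acd_source_col(acd_source))

  res <- structure(list(validation = val, outliers = out, split = split,
                        optimization = optimization,
                        eval_pooled = eval_pooled,
                        eval_by_gender = eval_gender,
                        mae_comparison = mae_comparison,
                        gender_tests = gender_tests,
                        regression = regression,
                        formulas = formulas,
                        reference_formula = reference_formula,
                        split_seed = split_seed),
                   class = "iol_pipeline_result")
  res$report <- make_report(res)
  res
}

acd_source_col <- function(acd_source) {
  if (identical(acd_source, "ad")) "ad_mm" else "acd_mm"
}

# MAE under pooled vs gender-stratified constants, paired per eye
compare_mae <- function(eval_pooled, eval_gender, formulas) {
  do.call(rbind, lapply(formulas, function(fid) {
    pp <- eval_pooled$predictions
    pg <- eval_gender$predictions
    a <- pp$ape_d[pp$formula == fid]
    key_p <- paste(pp$patient_id, pp$eye)[pp$formula == fid]
    key_g <- paste(pg$patient_id, pg$eye)[pg$formula == fid]
    b <- pg$ape_d[pg$formula == fid][match(key_p, key_g)]
    wt <- wilcoxon_signed_rank(a - b)
    data.frame(formula = fid,
               mae_pooled = mean(a),
               mae_by_gender = mean(b),
               pct_reduction = 100 * (mean(a) - mean(b)) / mean(a),
               p_value = wt$p_value,
               n = length(a),
               stringsAsFactors = FALSE)
  }))
}

# per-formula gender contrast of SPE and APE under pooled constants
gender_spe_tests <- function(eval_pooled, formulas) {
  do.call(rbind, lapply(formulas, function(fid) {
    p <- eval_pooled$predictions[eval_pooled$predictions$formula == fid, ]
    f <- p[p$gender == "female", ]
    m <- p[p$gender == "male", ]
    spe_t <- welch_t(f$spe_d, m$spe_d)
    ape_t <- welch_t(f$ape_d, m$ape_d)
    data.frame(formula = fid,
               mean_spe_female = mean(f$spe_d), sd_spe_female = stats::sd(f$spe_d),
               mean_spe_male = mean(m$spe_d), sd_spe_male = stats::sd(m$spe_d),
               p_spe = spe_t$p_value,
               mean_ape_female = mean(f$ape_d), mean_ape_male = mean(m$ape_d),
               p_ape = ape_t$p_value,
               stringsAsFactors = FALSE)
  }))
}

#' Assemble report tables from a pipeline result
#'
#' Builds the four deterministic summary tables of the analysis: per-gender
#' biometry/demographics (mean, SD, median, normal-approximation 95% CI of
#' the mean, rank-sum p), per-formula signed and absolute prediction errors
#' by gender with Welch p-values, the lens-constant table (pooled and
#' per-gender optima), and the MAE comparison of pooled versus
#' gender-stratified constants with percent reduction and signed-rank
#' p-values.
#'
#' @param result An `iol_pipeline_result` from [run_pipeline()].
#' @return List of data frames: `biometry`, `prediction_errors`,
#'   `constants`, `mae`.
#' @export
make_report <- function(result) {
  stopifnot(inherits(result, "iol_pipeline_result"))
  test <- result$split$test
  for (g in c("female", "male")) {
    if (!any(test$gender == g)) {
      stop("test stratum '", g, "' is empty; cannot build report",
           call. = FALSE)
    }
  }
  vars <- c("age_years", "al_mm", "cct_um", "ad_mm", "acd_mm", "lt_mm",
            "km_d", "ast_d", "wtw_mm", "postop_se_d")
  biometry <- do.call(rbind, lapply(vars, function(v) {
    x <- test[[v]]
    f <- x[test$gender == "female"]
    m <- x[test$gender == "male"]
    ci <- function(z) mean(z) + c(-1, 1) * 1.96 * stats::sd(z) / sqrt(length(z))
    p <- wilcoxon_rank_sum(f, m)$p_value
    data.frame(variable = v,
               mean = mean(x), sd = stats::sd(x), median = stats::median(x),
               ci_lo = ci(x)[1], ci_hi = ci(x)[2],
               mean_female = mean(f), sd_female = stats::sd(f),
               median_female = stats::median(f),
               ci_lo_female = ci(f)[1], ci_hi_female = ci(f)[2],
               mean_male = mean(m), sd_male = stats::sd(m),
               median_male = stats::median(m),
               ci_lo_male = ci(m)[1], ci_hi_male = ci(m)[2],
               p_value = p, stringsAsFactors = FALSE)
  }))

  constants <- do.call(rbind, lapply(result$formulas, function(fid) {
    o <- result$optimization[[fid]]
    data.frame(formula = fid,
               constant = constant_label(fid),
               pooled = o$pooled$constant_value,
               male = o$male$constant_value,
               female = o$female$constant_value,
               stringsAsFactors = FALSE)
  }))

  list(biometry = biometry,
       prediction_errors = result$gender_tests,
       constants = constants,
       mae = result$mae_comparison)
}

constant_label <- function(formula_id) {
  switch(formula_id,
         srkt = "A constant", holladay1 = "Surgeon Factor",
         hofferq = "pACD", haigis = "a0")
}

#' @export
print.iol_pipeline_result <- function(x, ...) {
  cat("IOL prediction-error pipeline\n")
  cat(sprintf("  eyes after validation/outlier screen: %d (removed %d outliers)\n",
              nrow(x$outliers$records), x$outliers$n_removed))
  cat(sprintf("  train eyes: %d; test eyes (1/patient): %d; split seed %d\n",
              nrow(x$split$train), nrow(x$split$test), x$split_seed))
  cat("  constants (pooled / female / male):\n")
  for (fid in x$formulas) {
    o <- x$optimization[[fid]]
    cat(sprintf("    %-10s %9.4f / %9.4f / %9.4f\n", fid,
                o$pooled$constant_value, o$female$constant_value,
                o$male$constant_value))
  }
  invisible(x)
}
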