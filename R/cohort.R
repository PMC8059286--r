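#' Column schema of a cohort table
#'
#' One row per operated eye. `postop_se_d` is the spherical equivalent
#' sphere + cylinder/2; the optional logical `prior_refractive_surgery`
#' column marks eyes excluded by protocol.
#'
#' @return Character vector of required column names.
#' @export
cohort_columns <- function() {
  c("patient_id", "eye", "gender", "age_years",
    "al_mm", "acd_mm", "ad_mm", "cct_um", "lt_mm", "km_d", "ast_d", "wtw_mm",
    "iol_power_d", "postop_sphere_d", "postop_cyl_d", "postop_se_d")
}

#' Validate a raw cohort table
#'
#' Checks the schema, row-level invariants and protocol exclusions. Rows are
#' rejected (never silently dropped) for: missing or non-finite refraction
#' components, a spherical equivalent inconsistent with sphere + cyl/2,
#' unknown gender or eye codes, biometry outside physiologic bounds, an IOL
#' power off the half-diopter grid or outside \[-10, 40\], duplicate
#' (patient, eye) records, or a prior-refractive-surgery flag.
#'
#' @param raw Data frame with the columns of [cohort_columns()].
#' @param se_tol Tolerance for the SE = sphere + cyl/2 identity (default
#'   1e-6 D, generous against CSV round-trips).
#' @return List with `records` (clean rows, class `iol_cohort`) and
#'   `rejections` (data frame of reason counts).
#' @export
validate_cohort <- function(raw, se_tol = 1e-6) {
  missing_cols <- setdiff(cohort_columns(), names(raw))
  if (length(missing_cols)) {
    stop("cohort table lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  n <- nrow(raw)
  reason <- rep(NA_character_, n)
  flag <- function(bad, why) {
    bad[is.na(bad)] <- TRUE
    reason[is.na(reason) & bad] <<- why
  }

  if ("prior_refractive_surgery" %in% names(raw)) {
    flag(isTRUE_vec(raw$prior_refractive_surgery), "prior refractive surgery")
  }
  flag(!(raw$gender %in% c("female", "male")), "unknown gender code")
  flag(!(raw$eye %in% c("OD", "OS")), "unknown eye code")
  num <- c("postop_sphere_d", "postop_cyl_d", "postop_se_d")
  flag(Reduce(`|`, lapply(raw[num], function(x) !is.finite(x))),
       "incomplete refraction")
  flag(abs(raw$postop_se_d - (raw$postop_sphere_d + raw$postop_cyl_d / 2)) >
         se_tol, "inconsistent spherical equivalent")
  flag(!is.finite(raw$iol_power_d) |
         raw$iol_power_d < -10 | raw$iol_power_d > 40 |
         abs(raw$iol_power_d / 0.5 - round(raw$iol_power_d / 0.5)) > 1e-9,
       "implausible IOL power")
  bio_ok <- is.finite(raw$al_mm) & raw$al_mm > 15 & raw$al_mm < 40 &
    is.finite(raw$km_d) & raw$km_d > 30 & raw$km_d < 60 &
    is.finite(raw$acd_mm) & raw$acd_mm > 1.5 & raw$acd_mm < 6 &
    is.finite(raw$ad_mm) & is.finite(raw$cct_um) & is.finite(raw$lt_mm) &
    is.finite(raw$wtw_mm) & is.finite(raw$ast_d) & raw$ast_d >= 0
  flag(!bio_ok, "biometry out of range")
  flag(duplicated(paste(raw$patient_id, raw$eye)), "duplicate patient-eye")

  keep <- is.na(reason)
  rej <- reason[!keep]
  rejections <- if (length(rej)) {
    as.data.frame(table(reason = rej), responseName = "n",
                  stringsAsFactors = FALSE)
  } else {
    data.frame(reason = character(), n = integer())
  }
  records <- raw[keep, , drop = FALSE]
  rownames(records) <- NULL
  class(records) <- c("iol_cohort", "data.frame")
  list(records = records, rejections = rejections)
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Exclude prediction-error outliers
#'
#' Removes eyes whose signed prediction error under a reference formula lies
#' more than `z_threshold` sample standard deviations from the cohort mean.
#' A single pass (no re-iteration after removal); a zero-variance SPE vector
#' removes nothing.
#'
#' @param records Cohort data frame.
#' @param spe Numeric vector of signed prediction errors, one per record,
#'   from the reference formula.
#' @param z_threshold Exclusion threshold in SD units (default 1.96).
#' @return List with `records` (kept rows), `n_removed`, and `kept` (logical
#'   index into the input).
#' @export
exclude_outliers <- function(records, spe, z_threshold = 1.96) {
  stopifnot(nrow(records) == length(spe))
  if (nrow(records) < 3) stop("need at least 3 records", call. = FALSE)
  s <- stats::sd(spe)
  keep <- if (!is.finite(s) || s == 0) {
    rep(TRUE, length(spe))
  } else {
    abs(spe - mean(spe)) <= z_threshold * s
  }
  if (!any(keep)) {
    stop("outlier exclusion removed every record (mean ", mean(spe),
         ", sd ", s, ")", call. = FALSE)
  }
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(records = out, n_removed = sum(!keep), kept = keep)
}

#' Patient-level 1:1 train/test split with one test eye per patient
#'
#' Patients (not eyes) are assigned train or test by a seeded fair coin, so
#' both eyes of a bilateral patient always land on the same side. For each
#' test patient one eye is chosen uniformly at random; test-set statistics
#' then weight every patient equally.
#'
#' @param records Cohort data frame.
#' @param seed Integer seed; the assignment is a deterministic function of
#'   the patient-id set and this seed.
#' @return List with `assignment` (data frame `patient_id`, `split`),
#'   `test_eye` (data frame `patient_id`, `eye`), `train` (all eyes of
#'   training patients), `test` (exactly one eye per test patient), and
#'   `seed`.
#' @export
split_train_test <- function(records, seed) {
  ids <- sort(unique(records$patient_id))
  if (length(ids) < 2) stop("need at least 2 patients", call. = FALSE)
  test_eye <- NULL
  side <- NULL
  withr::with_seed(seed, {
    side <- ifelse(stats::runif(length(ids)) < 0.5, "train", "test")
    test_ids <- ids[side == "test"]
    chosen <- vapply(test_ids, function(pid) {
      eyes <- sort(records$eye[records$patient_id == pid])
      if (length(eyes) == 1) eyes else eyes[1 + (stats::runif(1) >= 0.5)]
    }, character(1))
    test_eye <- data.frame(patient_id = test_ids, eye = chosen,
                           stringsAsFactors = FALSE)
  })
  assignment <- data.frame(patient_id = ids, split = side,
                           stringsAsFactors = FALSE)

  split_of <- stats::setNames(side, ids)
  train <- records[split_of[records$patient_id] == "train", , drop = FALSE]
  key <- paste(records$patient_id, records$eye)
  test <- records[key %in% paste(test_eye$patient_id, test_eye$eye), ,
                  drop = FALSE]
  rownames(train) <- rownames(test) <- NULL
  list(assignment = assignment, test_eye = test_eye,
       train = train, test = test, seed = seed)
}

#' Evaluate formulas on a test set
#'
#' Computes per-eye predictions and prediction errors for each formula under
#' a set of optimized constants, pooled (`mode = "pooled"`) or with each
#' gender stratum using its own constant (`mode = "by_gender"`).
#'
#' @param test Cohort data frame (typically the one-eye-per-patient test
#'   set).
#' @param constants Nested list from [optimize_all()], or any list shaped
#'   `constants[[formula]][[stratum]]$constants`.
#' @param mode `"pooled"` or `"by_gender"`.
#' @param formulas Formula ids to evaluate.
#' @param params,acd_source Optical model configuration.
#' @return List with `predictions` (long data frame: patient_id, eye,
#'   gender, formula, predicted_se_d, spe_d, ape_d) and `summary` (per
#'   formula and gender: n, mean/SD of SPE and APE, MAE).
#' @export
evaluate_formulas <- function(test, constants, mode = c("pooled", "by_gender"),
                              formulas = names(constants),
                              params = optical_params(), acd_source = "acd") {
  mode <- match.arg(mode)
  stopifnot(nrow(test) > 0)
  pred_list <- lapply(formulas, function(fid) {
    fc <- constants[[fid]]
    if (is.null(fc)) stop("no constants for formula '", fid, "'",
                          call. = FALSE)
    pred <- numeric(nrow(test))
    if (mode == "pooled") {
      pred[] <- predict_refraction(fid, fc$pooled$constants, test,
                                   test$iol_power_d, params, acd_source)
    } else {
      for (g in c("female", "male")) {
        rows <- test$gender == g
        if (!any(rows)) next
        if (is.null(fc[[g]])) {
          stop("no '", g, "' constants for formula '", fid, "'",
               call. = FALSE)
        }
        sub <- test[rows, , drop = FALSE]
        pred[rows] <- predict_refraction(fid, fc[[g]]$constants, sub,
                                         sub$iol_power_d, params, acd_source)
      }
    }
    spe <- pred - test$postop_se_d
    data.frame(patient_id = test$patient_id, eye = test$eye,
               gender = test$gender, formula = fid,
               predicted_se_d = pred, spe_d = spe, ape_d = abs(spe),
               stringsAsFactors = FALSE)
  })
  predictions <- do.call(rbind, pred_list)

  grp <- interaction(predictions$formula, predictions$gender, drop = FALSE)
  agg <- function(v, f) tapply(v, grp, f)
  by_gender <- data.frame(
    formula = sub("\\..*$", "", levels(grp)),
    gender = sub("^.*\\.", "", levels(grp)),
    n = as.vector(agg(predictions$spe_d, length)),
    mean_spe = as.vector(agg(predictions$spe_d, mean)),
    sd_spe = as.vector(agg(predictions$spe_d, stats::sd)),
    mean_ape = as.vector(agg(predictions$ape_d, mean)),
    sd_ape = as.vector(agg(predictions$ape_d, stats::sd)),
    stringsAsFactors = FALSE)
  overall <- do.call(rbind, lapply(formulas, function(fid) {
    p <- predictions[predictions$formula == fid, ]
    data.frame(formula = fid, n = nrow(p), mean_spe = mean(p$spe_d),
               sd_spe = stats::sd(p$spe_d), mae = mean(p$ape_d),
               stringsAsFactors = FALSE)
  }))
  list(predictions = predictions,
       summary = list(by_gender = by_gender, overall = overall),
       mode = mode)
}
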