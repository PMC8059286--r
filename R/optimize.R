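#' Mean signed prediction error of a formula on a set of eyes
#'
#' Signed prediction error (SPE) is predicted minus observed postoperative
#' spherical-equivalent refraction; a positive mean means the formula
#' predicts more hyperopic outcomes than were observed.
#'
#' @param records Cohort data frame (see [validate_cohort()]) carrying the
#'   biometry columns plus `iol_power_d` and `postop_se_d`.
#' @param formula_id Formula id.
#' @param constants A matching [lens_constants()] object.
#' @param params An [optical_params()] object.
#' @param acd_source Passed to the Haigis ELP model.
#' @return Mean SPE in diopters.
#' @export
mean_signed_pe <- function(records, formula_id, constants,
                           params = optical_params(), acd_source = "acd") {
  if (is.null(records) || nrow(records) == 0) {
    stop("mean_signed_pe needs at least one record", call. = FALSE)
  }
  pred <- predict_refraction(formula_id, constants, records,
                             records$iol_power_d, params, acd_source)
  mean(pred - records$postop_se_d)
}

#' Optimize a formula's lens constant on a training stratum
#'
#' Zeroization: the optimal constant is the one whose mean signed prediction
#' error on the training records vanishes. Because mean SPE is strictly
#' increasing in the constant (a larger constant implies a more posterior
#' assumed lens position, hence a more hyperopic prediction), the criterion
#' "minimize |mean error|" is solved as a bracketed root-find; when the
#' bracket contains no sign change, golden-section minimization of the
#' absolute mean error is used as a fallback.
#'
#' @param train Training cohort data frame.
#' @param formula_id Formula id.
#' @param start_constant Center of the search; defaults to
#'   [default_constants()].
#' @param bounds Length-2 search interval; defaults to [default_bounds()].
#' @param tol Convergence tolerance on |mean SPE| in diopters (default 1e-3).
#' @param params,acd_source Optical model configuration.
#' @return An object of class `optimization_result`: list with
#'   `formula_id`, `stratum`, `constant_value`, `constants` (a
#'   [lens_constants()] object at the optimum), `mean_spe_at_optimum`,
#'   `search_bounds`, `tolerance`, `n_train`, `converged`, `method`.
#' @param stratum Label stored in the result (`"all"`, `"female"`, `"male"`).
#' @export
optimize_constant <- function(train, formula_id,
                              start_constant = NULL, bounds = NULL,
                              tol = 1e-3, stratum = "all",
                              params = optical_params(),
                              acd_source = "acd") {
  stopifnot(tol > 0)
  if (is.null(train) || nrow(train) == 0) {
    stop("empty training stratum '", stratum, "'", call. = FALSE)
  }
  base <- default_constants(formula_id)
  if (is.null(start_constant)) start_constant <- constant_value(base)
  if (is.null(bounds)) bounds <- default_bounds(formula_id, start_constant)
  stopifnot(length(bounds) == 2, bounds[1] < bounds[2])

  f <- function(c_val) {
    mean_signed_pe(train, formula_id, set_constant_value(base, c_val),
                   params, acd_source)
  }
  f_lo <- f(bounds[1])
  f_hi <- f(bounds[2])

  if (is.finite(f_lo) && is.finite(f_hi) && f_lo * f_hi <= 0) {
    root <- stats::uniroot(f, interval = bounds, f.lower = f_lo,
                           f.upper = f_hi, tol = .Machine$double.eps^0.5)
    c_opt <- root$root
    method <- "root"
  } else {
    opt <- stats::optimize(function(c_val) abs(f(c_val)),
                           interval = bounds,
                           tol = .Machine$double.eps^0.25)
    c_opt <- opt$minimum
    method <- "golden-section"
  }
  spe_opt <- f(c_opt)
  converged <- abs(spe_opt) <= tol
  if (!converged) {
    warning("lens-constant optimization for '", formula_id, "' (stratum ",
            stratum, ") did not reach |mean SPE| <= ", tol,
            "; best |mean SPE| = ", signif(abs(spe_opt), 4),
            " at constant ", signif(c_opt, 6),
            " (bounds ", bounds[1], "..", bounds[2], ")", call. = FALSE)
  }
  structure(list(formula_id = formula_id,
                 stratum = stratum,
                 constant_value = c_opt,
                 constants = set_constant_value(base, c_opt),
                 mean_spe_at_optimum = spe_opt,
                 search_bounds = bounds,
                 tolerance = tol,
                 n_train = nrow(train),
                 converged = converged,
                 method = method),
            class = "optimization_result")
}

#' @export
print.optimization_result <- function(x, ...) {
  cat(sprintf(
    "Lens-constant optimization: %s [%s]\n  constant = %.4f  (bounds %.3f..%.3f, %s)\n  mean SPE at optimum = %+.2e D on n = %d eyes  (converged: %s)\n",
    x$formula_id, x$stratum, x$constant_value,
    x$search_bounds[1], x$search_bounds[2], x$method,
    x$mean_spe_at_optimum, x$n_train, x$converged))
  invisible(x)
}

#' Pooled and gender-stratified lens-constant optimization
#'
#' Runs [optimize_constant()] on the whole training set and independently on
#' its female and male strata.
#'
#' @inheritParams optimize_constant
#' @return List with elements `pooled`, `female`, `male`, each an
#'   `optimization_result`.
#' @export
optimize_by_gender <- function(train, formula_id,
                               start_constant = NULL, bounds = NULL,
                               tol = 1e-3, params = optical_params(),
                               acd_source = "acd") {
  for (g in c("female", "male")) {
    if (!any(train$gender == g)) {
      stop("training stratum '", g, "' is empty", call. = FALSE)
    }
  }
  run <- function(rows, label) {
    optimize_constant(train[rows, , drop = FALSE], formula_id,
                      start_constant, bounds, tol, stratum = label,
                      params = params, acd_source = acd_source)
  }
  list(pooled = run(rep(TRUE, nrow(train)), "all"),
       female = run(train$gender == "female", "female"),
       male = run(train$gender == "male", "male"))
}

#' Optimize constants for several formulas at once
#'
#' Convenience wrapper used by the pipeline: pooled and by-gender constants
#' for each formula, as a nested list `constants[[formula]][[stratum]]`.
#'
#' @inheritParams optimize_constant
#' @param formulas Character vector of formula ids.
#' @return Nested list of `optimization_result` objects, indexed by formula
#'   then stratum (`pooled`, `female`, `male`).
#' @export
optimize_all <- function(train, formulas = iol_formulas(), tol = 1e-3,
                         params = optical_params(), acd_source = "acd") {
  out <- lapply(formulas, function(fid) {
    optimize_by_gender(train, fid, tol = tol, params = params,
                       acd_source = acd_source)
  })
  names(out) <- formulas
  out
}
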