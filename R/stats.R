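#' Two-sample Wilcoxon rank-sum test
#'
#' Two-sided Mann-Whitney/Wilcoxon comparison of two independent samples,
#' exact when both samples are small and tie-free, otherwise the normal
#' approximation with tie and continuity correction. Used for gender
#' comparisons of biometry with one eye per patient.
#'
#' @param x,y Numeric samples.
#' @return A `stat_test_result`: list with `test`, `statistic`, `p_value`,
#'   `n`, `group_means`, `group_sds`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (!length(x) || !length(y)) stop("empty sample", call. = FALSE)
  exact <- min(length(x), length(y)) <= 25 && !anyDuplicated(c(x, y))
  ht <- stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                           correct = TRUE)
  stat_test_result("wilcoxon_rank_sum", ht$statistic, ht$p.value, x, y)
}

#' Welch two-sample t-test
#'
#' Two-sided unequal-variance t-test with Welch-Satterthwaite degrees of
#' freedom; the comparison behind the prediction-error gender contrasts.
#'
#' @param x,y Numeric samples of length >= 2.
#' @return A `stat_test_result` (statistic is Welch's t).
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) {
    stop("welch_t needs >= 2 observations per group", call. = FALSE)
  }
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    stop("both samples have zero variance", call. = FALSE)
  }
  ht <- stats::t.test(x, y, var.equal = FALSE)
  stat_test_result("welch_t", ht$statistic, ht$p.value, x, y,
                   df = unname(ht$parameter))
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on paired differences (for example, per-eye
#' absolute prediction error under pooled versus gender-stratified
#' constants). Zero differences are dropped per standard practice; exact
#' when at most 25 nonzero tie-free pairs remain, normal approximation
#' otherwise. An all-zero difference vector returns p = 1 with a warning.
#'
#' @param d Numeric vector of paired differences.
#' @return A `stat_test_result`.
#' @export
wilcoxon_signed_rank <- function(d) {
  if (!length(d)) stop("empty difference vector", call. = FALSE)
  nz <- d[d != 0]
  if (!length(nz)) {
    warning("all paired differences are zero; p = 1", call. = FALSE)
    return(structure(list(test = "wilcoxon_signed_rank", statistic = 0,
                          p_value = 1, n = c(n = length(d)),
                          group_means = mean(d), group_sds = stats::sd(d)),
                     class = "stat_test_result"))
  }
  exact <- length(nz) <= 25 && !anyDuplicated(abs(nz))
  ht <- stats::wilcox.test(nz, alternative = "two.sided", mu = 0,
                           exact = exact, correct = TRUE)
  structure(list(test = "wilcoxon_signed_rank",
                 statistic = unname(ht$statistic), p_value = ht$p.value,
                 n = c(n = length(d), n_nonzero = length(nz)),
                 group_means = mean(d), group_sds = stats::sd(d)),
            class = "stat_test_result")
}

stat_test_result <- function(test, statistic, p_value, x, y, df = NULL) {
  structure(list(test = test, statistic = unname(statistic),
                 p_value = unname(p_value), df = df,
                 n = c(n_x = length(x), n_y = length(y)),
                 group_means = c(mean(x), mean(y)),
                 group_sds = c(stats::sd(x), stats::sd(y))),
            class = "stat_test_result")
}

#' @export
print.stat_test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (n = %s)\n",
              x$test, x$statistic, x$p_value,
              paste(x$n, collapse = "/")))
  invisible(x)
}

#' Regression of prediction error on biometry, age and gender
#'
#' Ordinary least squares of each formula's signed prediction error on
#' axial length, central corneal thickness, anterior chamber depth (or
#' aqueous depth), lens thickness, keratometry, astigmatism, white-to-white,
#' age, and a male indicator (male = 1, female = 0). The gender effect is
#' additionally tested with a nested-model F test (full versus
#' gender-dropped model).
#'
#' @param test Cohort data frame (one eye per patient recommended).
#' @param predictions Long prediction table from [evaluate_formulas()].
#' @param depth_var `"acd_mm"` or `"ad_mm"`: which chamber-depth column
#'   enters the design.
#' @return Named list per formula, each with `fit` (the `lm` object),
#'   `coefficients` (coefficient table), and `gender_test` (data frame with
#'   the F statistic and p-value of the nested-model gender test).
#' @export
pe_regression <- function(test, predictions, depth_var = c("acd_mm", "ad_mm")) {
  depth_var <- match.arg(depth_var)
  if (nrow(test) < 50) {
    stop("pe_regression needs >= 50 records", call. = FALSE)
  }
  covars <- c("al_mm", "cct_um", depth_var, "lt_mm", "km_d", "ast_d",
              "wtw_mm", "age_years")
  lapply(split(predictions, predictions$formula), function(p) {
    key <- paste(test$patient_id, test$eye)
    m <- match(paste(p$patient_id, p$eye), key)
    dat <- test[m, covars, drop = FALSE]
    dat$male <- as.integer(test$gender[m] == "male")
    dat$spe_d <- p$spe_d
    x <- as.matrix(dat[, c(covars, "male")])
    qrx <- qr(cbind(1, x))
    if (qrx$rank < ncol(x) + 1) {
      keep <- qrx$pivot[seq_len(qrx$rank)]
      dropped <- setdiff(colnames(cbind(`(Intercept)` = 1, x)),
                         colnames(cbind(`(Intercept)` = 1, x))[keep])
      stop("rank-deficient design; collinear column(s): ",
           paste(dropped, collapse = ", "), call. = FALSE)
    }
    full <- stats::lm(stats::reformulate(c(covars, "male"), "spe_d"),
                      data = dat)
    reduced <- stats::lm(stats::reformulate(covars, "spe_d"), data = dat)
    cmp <- stats::anova(reduced, full)
    list(fit = full,
         coefficients = summary(full)$coefficients,
         gender_test = data.frame(statistic = cmp$F[2],
                                  df = cmp$Df[2],
                                  p_value = cmp$`Pr(>F)`[2]))
  })
}
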