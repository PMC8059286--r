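#' Configuration of the synthetic biometry cohort generator
#'
#' Defines every parameter of the simulated study population: cohort shape
#' (patients, gender mix, bilateral fraction), per-gender biometry marginals
#' (truncated Gaussians; defaults are the study-population means and SDs of
#' a large optical-biometry cataract cohort), a correlation structure on the
#' (AL, ACD, Km, LT, WTW) block, the "world" formula and true lens constants
#' that generate outcomes, gender-specific refraction offsets, refraction
#' noise, and the surgeon's IOL selection policy (target refraction and
#' power rounding step).
#'
#' Aqueous depth is not drawn: it is derived as `AD = ACD - CCT/1000`, so
#' its marginal follows from the ACD and CCT marginals.
#'
#' @param n_patients Number of patients (default 5519).
#' @param prop_female Proportion of female patients (default 0.569).
#' @param prob_bilateral Probability a patient contributes both eyes
#'   (default 8431/5519 - 1, about 0.528, reproducing an eyes-per-patient
#'   ratio of about 1.53).
#' @param biometry Per-gender marginal moments: a list with elements
#'   `female` and `male`, each a named list of `c(mean, sd)` for `al_mm`,
#'   `acd_mm`, `km_d`, `lt_mm`, `wtw_mm`, `cct_um`, `ast_d`, `age_years`.
#' @param correlations Correlation matrix for the block
#'   (al_mm, acd_mm, km_d, lt_mm, wtw_mm); must be positive definite.
#' @param bounds Named list of truncation intervals per variable.
#' @param intra_patient_cor Correlation between a patient's two eyes on the
#'   correlated block and on CCT/AST (default 0.9).
#' @param world_formula Formula generating true outcomes (default "srkt").
#' @param true_constants Per-gender true [lens_constants()]: list with
#'   `female` and `male` (default: the formula's [default_constants()] for
#'   both genders).
#' @param gender_offsets Named vector `c(female=, male=)` of systematic
#'   refraction offsets delta (D). Observed SE is generated as
#'   prediction - delta + noise, so the pipeline's signed prediction error
#'   (predicted - observed) equals +delta in expectation for that gender.
#' @param noise_sd SD of the manifest-refraction noise (D, default 0.40).
#' @param target_refraction Surgeon's refractive target (D, default 0).
#' @param power_step IOL power rounding step (D, default 0.5; 0 disables
#'   rounding). Midpoint ties round to the higher power (myopic bias).
#' @param cyl_factor Spectacle-plane scaling of corneal astigmatism used to
#'   emit a consistent sphere/cylinder pair (default 0.7).
#' @param seed Integer seed for the whole cohort draw.
#' @param params [optical_params()] used by the generating world.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_patients = 5519,
                             prop_female = 0.569,
                             prob_bilateral = 8431 / 5519 - 1,
                             biometry = default_biometry_marginals(),
                             correlations = default_biometry_correlations(),
                             bounds = default_biometry_bounds(),
                             intra_patient_cor = 0.9,
                             world_formula = "srkt",
                             true_constants = NULL,
                             gender_offsets = c(female = 0, male = 0),
                             noise_sd = 0.40,
                             target_refraction = 0,
                             power_step = 0.5,
                             cyl_factor = 0.7,
                             seed = 1,
                             params = optical_params()) {
  stopifnot(n_patients >= 1, prop_female > 0, prop_female < 1,
            prob_bilateral >= 0, prob_bilateral <= 1, noise_sd >= 0,
            power_step >= 0, intra_patient_cor >= 0, intra_patient_cor < 1)
  ev <- eigen(correlations, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop("biometry correlation matrix is not positive definite",
         call. = FALSE)
  }
  for (g in c("female", "male")) {
    for (v in names(bounds)) {
      m <- biometry[[g]][[v]][1]
      if (m < bounds[[v]][1] || m > bounds[[v]][2]) {
        stop("bounds for ", v, " do not contain the ", g, " mean",
             call. = FALSE)
      }
    }
  }
  if (is.null(true_constants)) {
    true_constants <- list(female = default_constants(world_formula),
                           male = default_constants(world_formula))
  }
  structure(list(n_patients = n_patients, prop_female = prop_female,
                 prob_bilateral = prob_bilateral, biometry = biometry,
                 correlations = correlations, bounds = bounds,
                 intra_patient_cor = intra_patient_cor,
                 world_formula = world_formula,
                 true_constants = true_constants,
                 gender_offsets = gender_offsets, noise_sd = noise_sd,
                 target_refraction = target_refraction,
                 power_step = power_step, cyl_factor = cyl_factor,
                 seed = seed, params = params),
            class = "generator_config")
}

#' Default per-gender biometry marginals
#'
#' Means and SDs of a large gender-stratified cataract-surgery biometry
#' population (axial length, chamber depth and corneal power differ by
#' gender; women have shorter, steeper eyes).
#'
#' @return List with `female` and `male`, each a named list of
#'   `c(mean, sd)`.
#' @export
default_biometry_marginals <- function() {
  list(
    female = list(al_mm = c(23.90, 1.35), acd_mm = c(3.19, 0.40),
                  km_d = c(44.17, 1.58), lt_mm = c(4.53, 0.44),
                  wtw_mm = c(12.04, 0.50), cct_um = c(549.34, 36.29),
                  ast_d = c(0.91, 0.77), age_years = c(71.16, 9.38)),
    male = list(al_mm = c(24.49, 1.32), acd_mm = c(3.31, 0.42),
                km_d = c(43.44, 1.63), lt_mm = c(4.55, 0.47),
                wtw_mm = c(12.24, 0.54), cct_um = c(554.04, 36.53),
                ast_d = c(0.97, 0.86), age_years = c(70.65, 10.15)))
}

#' Default correlation matrix of the (AL, ACD, Km, LT, WTW) block
#'
#' Plausible adult-eye correlations: longer eyes have deeper chambers
#' (AL-ACD 0.45), flatter corneas (AL-Km -0.30) and wider corneal diameters
#' (AL-WTW 0.25); remaining pairs are left uncorrelated. Fully
#' configurable; only the marginals are treated as calibrated.
#'
#' @return 5x5 correlation matrix with dimnames.
#' @export
default_biometry_correlations <- function() {
  v <- c("al_mm", "acd_mm", "km_d", "lt_mm", "wtw_mm")
  r <- diag(5)
  dimnames(r) <- list(v, v)
  r["al_mm", "acd_mm"] <- r["acd_mm", "al_mm"] <- 0.45
  r["al_mm", "km_d"] <- r["km_d", "al_mm"] <- -0.30
  r["al_mm", "wtw_mm"] <- r["wtw_mm", "al_mm"] <- 0.25
  r
}

#' Default truncation bounds per biometry variable
#' @return Named list of `c(lower, upper)` intervals.
#' @export
default_biometry_bounds <- function() {
  list(al_mm = c(19, 32), acd_mm = c(1.8, 5.2), km_d = c(36, 52),
       lt_mm = c(3.0, 6.2), wtw_mm = c(10, 14), cct_um = c(420, 680),
       ast_d = c(0, 5), age_years = c(40, 100))
}

block_vars <- function() c("al_mm", "acd_mm", "km_d", "lt_mm", "wtw_mm")

# redraw rows violating bounds until all pass; draws_fn(n) -> matrix/vector
redraw_until_in_bounds <- function(n, draw_fn, in_bounds_fn,
                                   max_rounds = 10000) {
  x <- draw_fn(n)
  bad <- !in_bounds_fn(x)
  rounds <- 0
  while (any(bad)) {
    rounds <- rounds + 1
    if (rounds > max_rounds) {
      stop("truncation bounds inconsistent with configured moments: ",
           sum(bad), " draws still rejected after ", max_rounds, " rounds",
           call. = FALSE)
    }
    repl <- draw_fn(sum(bad))
    if (is.matrix(x)) x[bad, ] <- repl else x[bad] <- repl
    bad <- !in_bounds_fn(x)
  }
  x
}

#' Draw gender-specific eye biometry
#'
#' Truncated correlated Gaussian draws: the (AL, ACD, Km, LT, WTW) block
#' comes from a multivariate normal with the configured marginals and
#' correlation matrix; CCT and AST are independent Gaussians (AST bounded
#' below by 0 via its truncation interval); out-of-bounds draws are
#' rejected and redrawn. Aqueous depth is derived as ACD - CCT/1000.
#'
#' @param config A [generator_config()].
#' @param gender `"female"` or `"male"`.
#' @param n Number of eyes to draw.
#' @param seed Optional seed; when `NULL` the current RNG stream is used
#'   (as inside [generate_cohort()]).
#' @return An [eye_biometry()] data frame with `n` rows.
#' @export
sample_biometry <- function(config, gender, n, seed = NULL) {
  draw <- function() {
    marg <- config$biometry[[gender]]
    bv <- block_vars()
    mu <- vapply(marg[bv], `[`, numeric(1), 1)
    sdv <- vapply(marg[bv], `[`, numeric(1), 2)
    sigma <- diag(sdv) %*% config$correlations %*% diag(sdv)
    lo <- vapply(config$bounds[bv], `[`, numeric(1), 1)
    hi <- vapply(config$bounds[bv], `[`, numeric(1), 2)

    block <- redraw_until_in_bounds(
      n,
      function(k) {
        m <- MASS::mvrnorm(k, mu = mu, Sigma = sigma)
        if (k == 1) m <- matrix(m, nrow = 1)
        m
      },
      function(m) {
        ok <- rep(TRUE, nrow(m))
        for (j in seq_along(bv)) ok <- ok & m[, j] >= lo[j] & m[, j] <= hi[j]
        ok
      })
    colnames(block) <- bv

    indep <- function(v) {
      b <- config$bounds[[v]]
      redraw_until_in_bounds(
        n,
        function(k) stats::rnorm(k, marg[[v]][1], marg[[v]][2]),
        function(x) x >= b[1] & x <= b[2])
    }
    cct <- indep("cct_um")
    ast <- indep("ast_d")
    eye_biometry(al_mm = block[, "al_mm"], acd_mm = block[, "acd_mm"],
                 km_d = block[, "km_d"], cct_um = cct,
                 lt_mm = block[, "lt_mm"], ast_d = ast,
                 wtw_mm = block[, "wtw_mm"])
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# fellow-eye biometry: correlated redraw around the first eye
sample_fellow_biometry <- function(config, gender, first) {
  rho <- config$intra_patient_cor
  n <- nrow(first)
  marg <- config$biometry[[gender]]
  bv <- block_vars()
  mu <- vapply(marg[bv], `[`, numeric(1), 1)
  sdv <- vapply(marg[bv], `[`, numeric(1), 2)
  sigma <- diag(sdv) %*% config$correlations %*% diag(sdv)
  lo <- vapply(config$bounds[bv], `[`, numeric(1), 1)
  hi <- vapply(config$bounds[bv], `[`, numeric(1), 2)
  x1 <- as.matrix(first[, bv])

  # conditional draw x2 | x1 with correlation rho, then per-row rejection
  cond_draw <- function(rows) {
    k <- length(rows)
    z <- MASS::mvrnorm(k, mu = rep(0, length(bv)), Sigma = sigma)
    if (k == 1) z <- matrix(z, nrow = 1)
    sweep(rho * (x1[rows, , drop = FALSE] -
                   matrix(mu, k, length(bv), byrow = TRUE)) +
            sqrt(1 - rho^2) * z, 2, mu, `+`)
  }
  block <- cond_draw(seq_len(n))
  in_bounds <- function(m) {
    ok <- rep(TRUE, nrow(m))
    for (j in seq_along(bv)) ok <- ok & m[, j] >= lo[j] & m[, j] <= hi[j]
    ok
  }
  rounds <- 0
  bad <- !in_bounds(block)
  while (any(bad)) {
    rounds <- rounds + 1
    if (rounds > 10000) {
      stop("fellow-eye truncation bounds inconsistent with moments",
           call. = FALSE)
    }
    block[bad, ] <- cond_draw(which(bad))
    bad <- !in_bounds(block)
  }
  colnames(block) <- bv

  cond_indep <- function(v, x1v) {
    b <- config$bounds[[v]]
    m <- marg[[v]][1]
    s <- marg[[v]][2]
    x <- m + rho * (x1v - m) + sqrt(1 - rho^2) * stats::rnorm(n, 0, s)
    bad <- x < b[1] | x > b[2]
    rounds <- 0
    while (any(bad)) {
      rounds <- rounds + 1
      if (rounds > 10000) stop("fellow-eye bounds unreachable", call. = FALSE)
      x[bad] <- m + rho * (x1v[bad] - m) +
        sqrt(1 - rho^2) * stats::rnorm(sum(bad), 0, s)
      bad <- x < b[1] | x > b[2]
    }
    x
  }
  cct <- cond_indep("cct_um", first$cct_um)
  ast <- cond_indep("ast_d", first$ast_d)
  eye_biometry(al_mm = block[, "al_mm"], acd_mm = block[, "acd_mm"],
               km_d = block[, "km_d"], cct_um = cct,
               lt_mm = block[, "lt_mm"], ast_d = ast,
               wtw_mm = block[, "wtw_mm"])
}

#' Select the implanted IOL power for an eye
#'
#' Emulates surgeon selection: the power whose predicted refraction equals
#' the target (closed-form inversion of the world formula's vergence chain),
#' rounded to the manufacturing step. Midpoint ties round to the higher
#' power, biasing residual refraction to the myopic side, and the result is
#' clamped to the \[-10, 40\] D range.
#'
#' @param eye [eye_biometry()] rows.
#' @param world_formula Formula id generating the world.
#' @param true_constants Matching [lens_constants()].
#' @param target_refraction Spectacle target (D).
#' @param step Rounding step (D); 0 disables rounding.
#' @param params [optical_params()].
#' @return Implanted power (D), one per eye.
#' @export
assign_iol_power <- function(eye, world_formula, true_constants,
                             target_refraction = 0, step = 0.5,
                             params = optical_params()) {
  elp <- formula_elp(world_formula, true_constants, eye, params)
  p <- power_for_target(params, elp, target_refraction)
  if (step > 0) p <- round_half_up(p, step)
  pmin(pmax(p, -10), 40)
}

# half-up rounding: a midpoint tie goes to the higher power, biasing the
# residual refraction toward myopia as surgeons conventionally prefer
round_half_up <- function(p, step) step * floor(p / step + 0.5)

#' Simulate observed postoperative refraction
#'
#' Observed spherical equivalent = world-formula prediction at the true
#' constant, minus the gender offset delta, plus Gaussian refraction noise.
#' Subtracting delta from the observed SE makes the pipeline's signed
#' prediction error (predicted - observed) equal +delta in expectation. A
#' consistent sphere/cylinder pair is emitted with the cylinder taken from
#' the corneal astigmatism scaled to the spectacle plane.
#'
#' @param eye [eye_biometry()] rows.
#' @param iol_power_d Implanted power (D).
#' @param world_formula,true_constants The generating world.
#' @param offset_d Gender offset delta (D) for these eyes.
#' @param noise_sd Refraction noise SD (D).
#' @param cyl_factor Corneal-to-spectacle astigmatism scale.
#' @param params [optical_params()].
#' @return Data frame with `postop_se_d`, `postop_sphere_d`,
#'   `postop_cyl_d`, `noise_d`, `true_pred_d`.
#' @export
simulate_postop_refraction <- function(eye, iol_power_d, world_formula,
                                       true_constants, offset_d = 0,
                                       noise_sd = 0.40, cyl_factor = 0.7,
                                       params = optical_params()) {
  pred <- predict_refraction(world_formula, true_constants, eye,
                             iol_power_d, params)
  noise <- stats::rnorm(nrow(eye), 0, noise_sd)
  se <- pred - offset_d + noise
  cyl <- cyl_factor * eye$ast_d
  data.frame(postop_se_d = se, postop_sphere_d = se - cyl / 2,
             postop_cyl_d = cyl, noise_d = noise, true_pred_d = pred)
}

#' Generate a full synthetic cohort with ground truth
#'
#' Draws patients (gender, age, 1-2 eyes with intra-patient correlation),
#' per-eye biometry, an implanted IOL power from the selection policy, and
#' observed postoperative refraction from the configured world. Returns the
#' cohort table in the schema of [cohort_columns()] together with a
#' ground-truth sidecar recording, for every eye, the generating formula,
#' true constant, injected offset and noise draw.
#'
#' @param config A [generator_config()].
#' @return Object of class `synthetic_cohort`: list with `cohort` (data
#'   frame), `truth` (data frame), `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  withr::with_seed(config$seed, {
    n <- config$n_patients
    gender <- ifelse(stats::runif(n) < config$prop_female, "female", "male")
    bilateral <- stats::runif(n) < config$prob_bilateral
    first_od <- stats::runif(n) < 0.5

    rows <- list()
    truths <- list()
    for (g in c("female", "male")) {
      idx <- which(gender == g)
      if (!length(idx)) {
        stop("gender stratum '", g, "' is empty; increase n_patients",
             call. = FALSE)
      }
      marg <- config$biometry[[g]]
      b <- config$bounds$age_years
      age <- redraw_until_in_bounds(
        length(idx),
        function(k) stats::rnorm(k, marg$age_years[1], marg$age_years[2]),
        function(x) x >= b[1] & x <= b[2])

      eye1 <- sample_biometry(config, g, length(idx))
      tc <- config$true_constants[[g]]
      off <- unname(config$gender_offsets[[g]])

      mk <- function(bio, sub_idx, eye_label, sub_age) {
        pow <- assign_iol_power(bio, config$world_formula, tc,
                                config$target_refraction,
                                config$power_step, config$params)
        ref <- simulate_postop_refraction(bio, pow, config$world_formula,
                                          tc, off, config$noise_sd,
                                          config$cyl_factor, config$params)
        cohort <- data.frame(
          patient_id = sprintf("P%05d", sub_idx),
          eye = eye_label, gender = g, age_years = sub_age,
          bio[, c("al_mm", "acd_mm", "ad_mm", "cct_um", "lt_mm", "km_d",
                  "ast_d", "wtw_mm")],
          iol_power_d = pow,
          postop_sphere_d = ref$postop_sphere_d,
          postop_cyl_d = ref$postop_cyl_d,
          postop_se_d = ref$postop_se_d,
          stringsAsFactors = FALSE)
        truth <- data.frame(
          patient_id = cohort$patient_id, eye = eye_label,
          world_formula = config$world_formula,
          true_constant = constant_value(tc),
          offset_d = off, noise_d = ref$noise_d,
          true_pred_d = ref$true_pred_d,
          stringsAsFactors = FALSE)
        list(cohort = cohort, truth = truth)
      }

      e1 <- mk(eye1, idx, ifelse(first_od[idx], "OD", "OS"), age)
      rows[[g]] <- e1$cohort
      truths[[g]] <- e1$truth

      bi <- which(bilateral[idx])
      if (length(bi)) {
        eye2 <- sample_fellow_biometry(config, g, eye1[bi, , drop = FALSE])
        e2 <- mk(eye2, idx[bi], ifelse(first_od[idx][bi], "OS", "OD"),
                 age[bi])
        rows[[g]] <- rbind(rows[[g]], e2$cohort)
        truths[[g]] <- rbind(truths[[g]], e2$truth)
      }
    }
    cohort <- do.call(rbind, rows[c("female", "male")])
    truth <- do.call(rbind, truths[c("female", "male")])
    ord <- order(cohort$patient_id, cohort$eye)
    cohort <- cohort[ord, , drop = FALSE]
    truth <- truth[ord, , drop = FALSE]
    rownames(cohort) <- rownames(truth) <- NULL
    structure(list(cohort = cohort, truth = truth, config = config),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic cohort: %d eyes of %d patients (%.1f%% female eyes)\n  world formula: %s; noise SD %.2f D; offsets (F %+.2f, M %+.2f) D; seed %d\n",
    nrow(x$cohort), length(unique(x$cohort$patient_id)),
    100 * mean(x$cohort$gender == "female"),
    x$config$world_formula, x$config$noise_sd,
    x$config$gender_offsets[["female"]], x$config$gender_offsets[["male"]],
    x$config$seed))
  invisible(x)
}
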