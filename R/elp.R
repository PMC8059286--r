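#' @title Effective lens position models
#' @description Each formula's ELP model maps biometry plus its lens
#'   constant to the triple the vergence core needs: the assumed effective
#'   lens position `elp_mm`, the optical axial length `l_opt_mm`, and the
#'   corneal power `dc_d` computed with the formula's own fictitious corneal
#'   index. Constants follow the formulas' original publications and errata.
#' @name elp_models
NULL

elp_result <- function(elp_mm, l_opt_mm, dc_d) {
  structure(list(elp_mm = elp_mm, l_opt_mm = l_opt_mm, dc_d = dc_d),
            class = "elp_result")
}

# corneal power from anterior radius with a formula-specific index
corneal_power <- function(r_mm, n_cornea) 1000 * (n_cornea - 1) / r_mm

#' @describeIn elp_models SRK/T: the A-constant is mapped to an ACD constant
#'   (0.62467 A - 68.747) and an offset (ACD constant - 3.336); axial length
#'   above 24.2 mm is remapped by the published quadratic (LCOR); corneal
#'   width and corneal height give the sagittal ELP; a retinal-thickness
#'   term is added to AL; corneal power uses n_c = 1.333.
#' @param constants A [lens_constants()] object matching the formula.
#' @param eye An [eye_biometry()] data frame (rows are eyes).
#' @param params An [optical_params()] object (keratometer index).
#' @return An `elp_result` with vector fields `elp_mm`, `l_opt_mm`, `dc_d`.
#' @export
elp_srkt <- function(constants, eye, params = optical_params()) {
  stopifnot(inherits(constants, "lens_constants"),
            constants$formula == "srkt")
  al <- eye$al_mm
  km <- eye$km_d
  r <- keratometry_to_radius(km, params$keratometer_index)

  acd_const <- 0.62467 * constants$a_const - 68.747
  offset <- acd_const - 3.336

  lcor <- ifelse(al <= 24.2, al, -3.446 + 1.716 * al - 0.0237 * al^2)
  cw <- -5.41 + 0.58412 * lcor + 0.098 * km
  sag_arg <- r^2 - cw^2 / 4
  if (any(sag_arg < 0)) {
    warning("SRK/T corneal-height sqrt argument clamped to 0 for ",
            sum(sag_arg < 0), " eye(s)", call. = FALSE)
  }
  h <- r - sqrt(pmax(0, sag_arg))
  elp <- h + offset

  rethick <- 0.65696 - 0.02029 * al
  l_opt <- al + rethick
  dc <- corneal_power(r, 1.333)
  elp_result(elp, l_opt, dc)
}

#' @describeIn elp_models Holladay 1: anatomic ACD from the corneal dome
#'   (radius floored at 7 mm, chord AG = 12.5 AL / 23.45 capped at 13.5 mm)
#'   plus the published 0.56 mm constant, plus the Surgeon Factor; 0.200 mm
#'   retinal thickness; corneal power uses n_c = 4/3.
#' @export
elp_holladay1 <- function(constants, eye, params = optical_params()) {
  stopifnot(inherits(constants, "lens_constants"),
            constants$formula == "holladay1")
  al <- eye$al_mm
  r <- keratometry_to_radius(eye$km_d, params$keratometer_index)

  rag <- pmax(r, 7.0)
  ag <- pmin(12.5 * al / 23.45, 13.5)
  sag_arg <- rag^2 - ag^2 / 4
  if (any(sag_arg < 0)) {
    warning("Holladay corneal-height sqrt argument clamped to 0 for ",
            sum(sag_arg < 0), " eye(s)", call. = FALSE)
  }
  aacd <- 0.56 + rag - sqrt(pmax(0, sag_arg))
  elp <- aacd + constants$sf_mm

  l_opt <- al + 0.200
  dc <- corneal_power(r, 4 / 3)
  elp_result(elp, l_opt, dc)
}

#' @describeIn elp_models Hoffer Q: the published tangent model with
#'   degree-argument tangents, the short/long-eye correction switching at
#'   AL = 23 mm ((M, G) = (+1, 28) below, (-1, 23.5) above), axial length
#'   clamped to \[18.5, 31\] mm inside the ELP expression only, and the
#'   published -0.99166 constant; corneal power is the keratometry itself;
#'   the vergence stage adds the published 0.05 mm to the ELP.
#' @export
elp_hofferq <- function(constants, eye, params = optical_params()) {
  stopifnot(inherits(constants, "lens_constants"),
            constants$formula == "hofferq")
  al <- eye$al_mm
  km <- eye$km_d

  alc <- pmin(pmax(al, 18.5), 31)
  m <- ifelse(al <= 23, 1, -1)
  g <- ifelse(al <= 23, 28, 23.5)
  tan_deg <- function(x) tan(x * pi / 180)
  elp <- constants$pacd_mm +
    0.3 * (alc - 23.5) +
    tan_deg(km)^2 +
    0.1 * m * (23.5 - alc)^2 * tan_deg(0.1 * (g - alc)^2) -
    0.99166
  # the published prediction equation positions the lens 0.05 mm behind ELP
  elp_result(elp + 0.05, al, km)
}

#' @describeIn elp_models Haigis: the linear model ELP = a0 + a1 ACD + a2 AL
#'   with the preoperative (epithelium-referenced) ACD by default; corneal
#'   power uses n_c = 1.3315; axial length enters unmodified.
#' @param acd_source Which biometer column feeds the Haigis ACD term:
#'   `"acd"` (epithelium to lens, default) or `"ad"` (aqueous depth).
#' @export
elp_haigis <- function(constants, eye, params = optical_params(),
                       acd_source = c("acd", "ad")) {
  stopifnot(inherits(constants, "lens_constants"),
            constants$formula == "haigis")
  acd_source <- match.arg(acd_source)
  acd <- if (acd_source == "acd") eye$acd_mm else eye$ad_mm
  elp <- constants$haigis_a0 + constants$haigis_a1 * acd +
    constants$haigis_a2 * eye$al_mm
  r <- keratometry_to_radius(eye$km_d, params$keratometer_index)
  elp_result(elp, eye$al_mm, corneal_power(r, 1.3315))
}

#' Predicted postoperative refraction for one formula
#'
#' Dispatches to the formula's ELP model and runs the shared vergence core.
#' Pure and deterministic; all randomness in this package lives in the
#' cohort generator.
#'
#' @param formula_id One of `"srkt"`, `"holladay1"`, `"hofferq"`, `"haigis"`.
#' @param constants A matching [lens_constants()] object.
#' @param eye An [eye_biometry()] data frame.
#' @param iol_power_d Implanted IOL power (D); scalar or one per eye.
#' @param params An [optical_params()] object.
#' @param acd_source Passed to [elp_haigis()].
#' @return Predicted spectacle spherical-equivalent refraction (D), one per
#'   eye.
#' @export
predict_refraction <- function(formula_id, constants, eye, iol_power_d,
                               params = optical_params(),
                               acd_source = "acd") {
  if (!identical(constants$formula, formula_id)) {
    stop("constants are for '", constants$formula,
         "' but formula_id is '", formula_id, "'", call. = FALSE)
  }
  elp <- formula_elp(formula_id, constants, eye, params, acd_source)
  tryCatch(
    vergence_refraction(params, elp, iol_power_d),
    error = function(e) {
      stop("prediction failed for formula '", formula_id, "': ",
           conditionMessage(e), call. = FALSE)
    })
}

# internal ELP dispatch shared by prediction and power selection
formula_elp <- function(formula_id, constants, eye,
                        params = optical_params(), acd_source = "acd") {
  switch(formula_id,
         srkt = elp_srkt(constants, eye, params),
         holladay1 = elp_holladay1(constants, eye, params),
         hofferq = elp_hofferq(constants, eye, params),
         haigis = elp_haigis(constants, eye, params, acd_source),
         stop("unknown formula_id '", formula_id, "'", call. = FALSE))
}

#' All formula identifiers handled by the package
#' @return Character vector of formula ids.
#' @export
iol_formulas <- function() c("srkt", "holladay1", "hofferq", "haigis")
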