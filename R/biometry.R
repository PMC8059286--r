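#' Construct and validate a table of eye biometry
#'
#' Columns follow optical-biometer conventions: axial length `al_mm`,
#' anterior chamber depth `acd_mm` (corneal epithelium to anterior lens
#' surface), aqueous depth `ad_mm` (endothelium to lens, i.e. ACD minus
#' corneal thickness), central corneal thickness `cct_um`, lens thickness
#' `lt_mm`, mean keratometry `km_d`, corneal astigmatism magnitude `ast_d`,
#' and white-to-white `wtw_mm`.
#'
#' @param al_mm Axial length (mm), in (15, 40).
#' @param acd_mm Anterior chamber depth, epithelium to lens (mm), in (1.5, 6).
#' @param km_d Mean keratometry (D), in (30, 60).
#' @param ad_mm Aqueous depth (mm); defaults to `acd_mm - cct_um/1000`.
#' @param cct_um Central corneal thickness (micrometers).
#' @param lt_mm Lens thickness (mm).
#' @param ast_d Corneal astigmatism magnitude (D), non-negative.
#' @param wtw_mm White-to-white corneal diameter (mm).
#' @return A `data.frame` with class `eye_biometry`.
#' @export
eye_biometry <- function(al_mm, acd_mm, km_d,
                         cct_um = 550, lt_mm = 4.5,
                         ad_mm = acd_mm - cct_um / 1000,
                         ast_d = 0.9, wtw_mm = 12.1) {
  d <- data.frame(al_mm = al_mm, acd_mm = acd_mm, ad_mm = ad_mm,
                  cct_um = cct_um, lt_mm = lt_mm, km_d = km_d,
                  ast_d = ast_d, wtw_mm = wtw_mm)
  validate_biometry(d)
  class(d) <- c("eye_biometry", class(d))
  d
}

validate_biometry <- function(d) {
  with(d, {
    if (any(!is.finite(al_mm)) || any(al_mm <= 15 | al_mm >= 40))
      stop("al_mm outside (15, 40)", call. = FALSE)
    if (any(!is.finite(km_d)) || any(km_d <= 30 | km_d >= 60))
      stop("km_d outside (30, 60)", call. = FALSE)
    if (any(!is.finite(acd_mm)) || any(acd_mm <= 1.5 | acd_mm >= 6))
      stop("acd_mm outside (1.5, 6)", call. = FALSE)
    if (any(!is.finite(ast_d)) || any(ast_d < 0))
      stop("ast_d must be finite and >= 0", call. = FALSE)
    if (any(!is.finite(ad_mm) | !is.finite(cct_um) |
            !is.finite(lt_mm) | !is.finite(wtw_mm)))
      stop("all biometry fields must be finite", call. = FALSE)
  })
  invisible(TRUE)
}

#' Lens constants for one formula
#'
#' Each formula personalizes its effective-lens-position model through a
#' single scalar: the SRK/T A-constant, the Holladay 1 Surgeon Factor, the
#' Hoffer Q personalized ACD, or the Haigis a0 intercept (a1, a2 stay at
#' their configured defaults unless overridden, mirroring single-constant
#' optimization practice).
#'
#' @param formula One of `"srkt"`, `"holladay1"`, `"hofferq"`, `"haigis"`.
#' @param a_const SRK/T A-constant (dimensionless, 110-125).
#' @param sf_mm Holladay Surgeon Factor (mm, 0-4).
#' @param pacd_mm Hoffer Q personalized ACD (mm, 3-8).
#' @param haigis_a0,haigis_a1,haigis_a2 Haigis intercept (mm), ACD slope and
#'   AL slope; a1 and a2 default to 0.4 and 0.1.
#' @return An object of class `lens_constants`.
#' @export
lens_constants <- function(formula = c("srkt", "holladay1", "hofferq", "haigis"),
                           a_const = NULL, sf_mm = NULL, pacd_mm = NULL,
                           haigis_a0 = NULL, haigis_a1 = 0.4, haigis_a2 = 0.1) {
  formula <- match.arg(formula)
  x <- switch(formula,
    srkt = {
      if (is.null(a_const)) stop("srkt requires a_const", call. = FALSE)
      if (a_const <= 110 || a_const >= 125)
        stop("a_const outside (110, 125)", call. = FALSE)
      list(a_const = a_const)
    },
    holladay1 = {
      if (is.null(sf_mm)) stop("holladay1 requires sf_mm", call. = FALSE)
      if (sf_mm <= 0 || sf_mm >= 4)
        stop("sf_mm outside (0, 4)", call. = FALSE)
      list(sf_mm = sf_mm)
    },
    hofferq = {
      if (is.null(pacd_mm)) stop("hofferq requires pacd_mm", call. = FALSE)
      if (pacd_mm <= 3 || pacd_mm >= 8)
        stop("pacd_mm outside (3, 8)", call. = FALSE)
      list(pacd_mm = pacd_mm)
    },
    haigis = {
      if (is.null(haigis_a0)) stop("haigis requires haigis_a0", call. = FALSE)
      list(haigis_a0 = haigis_a0, haigis_a1 = haigis_a1,
           haigis_a2 = haigis_a2)
    })
  structure(c(list(formula = formula), x), class = "lens_constants")
}

#' The single personalization scalar held by a `lens_constants` object
#' @param constants A [lens_constants()] object.
#' @return Numeric scalar (A-constant, SF, pACD or a0 depending on formula).
#' @export
constant_value <- function(constants) {
  stopifnot(inherits(constants, "lens_constants"))
  switch(constants$formula,
         srkt = constants$a_const,
         holladay1 = constants$sf_mm,
         hofferq = constants$pacd_mm,
         haigis = constants$haigis_a0)
}

#' Replace the personalization scalar of a `lens_constants` object
#' @inheritParams constant_value
#' @param value New value of the formula's optimizable constant.
#' @return A new `lens_constants` object.
#' @export
set_constant_value <- function(constants, value) {
  stopifnot(inherits(constants, "lens_constants"))
  switch(constants$formula,
         srkt = lens_constants("srkt", a_const = value),
         holladay1 = lens_constants("holladay1", sf_mm = value),
         hofferq = lens_constants("hofferq", pacd_mm = value),
         haigis = lens_constants("haigis", haigis_a0 = value,
                                 haigis_a1 = constants$haigis_a1,
                                 haigis_a2 = constants$haigis_a2))
}

#' Default (starting) lens constants for the modelled single-piece IOL
#'
#' Nominal constants of the kind an optical biometer ships for an acrylic
#' monofocal lens with A-constant 119.0; the Holladay and Hoffer Q values
#' use the standard A-constant conversions (SF = 0.5663 A - 65.60,
#' pACD = 0.62467 A - 68.747) and the Haigis intercept uses
#' a0 = 0.62467 A - 72.434 with the fixed slopes a1 = 0.4, a2 = 0.1. These
#' seed the optimizer's search interval and the synthetic world's true
#' constants.
#'
#' @param formula Formula id.
#' @return A [lens_constants()] object.
#' @export
default_constants <- function(formula = c("srkt", "holladay1", "hofferq",
                                          "haigis")) {
  formula <- match.arg(formula)
  switch(formula,
         srkt = lens_constants("srkt", a_const = 119.0),
         holladay1 = lens_constants("holladay1", sf_mm = 1.79),
         hofferq = lens_constants("hofferq", pacd_mm = 5.59),
         haigis = lens_constants("haigis", haigis_a0 = 1.902))
}

#' Default optimizer search bounds per formula
#'
#' Generous half-widths around a starting constant: A-constant +-2.0,
#' Surgeon Factor +-1.0 mm, pACD +-1.5 mm, Haigis a0 +-1.0 mm — an order of
#' magnitude wider than clinically plausible inter-stratum differences.
#'
#' @param formula Formula id.
#' @param center Center of the interval (defaults to [default_constants()]).
#' @return Length-2 numeric vector `c(lower, upper)`.
#' @export
default_bounds <- function(formula, center = NULL) {
  if (is.null(center)) center <- constant_value(default_constants(formula))
  half <- switch(formula, srkt = 2.0, holladay1 = 1.0,
                 hofferq = 1.5, haigis = 1.0)
  c(center - half, center + half)
}
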