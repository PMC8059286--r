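#' Optical model parameters
#'
#' Bundles the physical constants shared by the vergence core of all four
#' formulas. Every index lives here (never inlined in formula code) so that
#' divergent formula dialects can be configured and tested explicitly.
#'
#' @param n_aqueous Refractive index of aqueous/vitreous used for all
#'   intraocular vergence propagation. Default 1.336.
#' @param keratometer_index Fictitious index the keratometer assumed when it
#'   converted the anterior corneal radius to dioptric power; 1.3375 gives
#'   the familiar r = 337.5/K. Default 1.3375.
#' @param vertex_mm Spectacle vertex distance in mm at which predicted
#'   refractions are reported. Default 12.
#' @return An object of class `optical_params`.
#' @export
optical_params <- function(n_aqueous = 1.336,
                           keratometer_index = 1.3375,
                           vertex_mm = 12) {
  stopifnot(n_aqueous > 1, keratometer_index > 1, vertex_mm >= 0)
  structure(list(n_aqueous = n_aqueous,
                 keratometer_index = keratometer_index,
                 vertex_mm = vertex_mm),
            class = "optical_params")
}

#' Convert mean keratometry to corneal radius of curvature
#'
#' r = 1000 * (index - 1) / K, the inverse of the keratometer's own
#' power calibration.
#'
#' @param km_d Mean keratometry in diopters (> 0). Vectorized.
#' @param keratometer_index Keratometer calibration index (default 1.3375).
#' @return Anterior corneal radius in mm.
#' @examples
#' keratometry_to_radius(45)   # 7.5 mm
#' @export
keratometry_to_radius <- function(km_d, keratometer_index = 1.3375) {
  if (any(!is.finite(km_d)) || any(km_d <= 0)) {
    stop("keratometry must be finite and positive", call. = FALSE)
  }
  1000 * (keratometer_index - 1) / km_d
}

#' Transpose a refraction from the corneal plane to the spectacle plane
#'
#' Standard vertex transposition: Rs = Rc / (1 + (v/1000) * Rc).
#'
#' @param rc_d Corneal-plane refraction in diopters. Vectorized.
#' @param vertex_mm Vertex distance in mm.
#' @return Spectacle-plane refraction in diopters.
#' @seealso [spectacle_to_corneal()] for the inverse.
#' @export
corneal_to_spectacle <- function(rc_d, vertex_mm = 12) {
  den <- 1 + (vertex_mm / 1000) * rc_d
  if (any(abs(den) < 1e-12)) {
    stop("vertex transposition singular: 1 + v*Rc is zero", call. = FALSE)
  }
  rc_d / den
}

#' Transpose a refraction from the spectacle plane to the corneal plane
#'
#' Inverse of [corneal_to_spectacle()]; the two round-trip to better than
#' 1e-12 D over the clinical range.
#'
#' @inheritParams corneal_to_spectacle
#' @param rs_d Spectacle-plane refraction in diopters. Vectorized.
#' @return Corneal-plane refraction in diopters.
#' @export
spectacle_to_corneal <- function(rs_d, vertex_mm = 12) {
  den <- 1 - (vertex_mm / 1000) * rs_d
  if (any(abs(den) < 1e-12)) {
    stop("vertex transposition singular: 1 - v*Rs is zero", call. = FALSE)
  }
  rs_d / den
}

#' Predicted spectacle refraction from the thin-lens vergence model
#'
#' The shared pseudophakic vergence skeleton of SRK/T, Holladay 1, Hoffer Q
#' and Haigis. With lengths in meters and n the aqueous index, the
#' corneal-plane refraction for an IOL of power P at effective lens position
#' ELP in an eye of optical axial length L with corneal power Dc is
#'
#'   Rc = n / (ELP + n / (n/(L - ELP) - P)) - Dc
#'
#' which is then transposed to the spectacle plane. The function is
#' continuous and strictly decreasing in P over the clinical power range.
#'
#' @param params An [optical_params()] object.
#' @param elp An `elp_result` (see [elp_srkt()] and friends) or a list with
#'   numeric fields `elp_mm`, `l_opt_mm`, `dc_d`. Fields may be vectors.
#' @param iol_power_d IOL power in diopters, in \[-10, 40\]. Vectorized.
#' @return Predicted spectacle-plane spherical-equivalent refraction (D).
#' @export
vergence_refraction <- function(params, elp, iol_power_d) {
  stopifnot(inherits(params, "optical_params"))
  check_elp(elp)
  if (any(iol_power_d < -10 | iol_power_d > 40)) {
    stop("iol_power_d outside [-10, 40]", call. = FALSE)
  }
  n <- params$n_aqueous
  C <- elp$elp_mm / 1000
  L <- elp$l_opt_mm / 1000
  # vergence needed at the IOL plane minus the IOL power: remaining
  # object-side vergence that must come from the cornea
  z <- n / (L - C) - iol_power_d
  if (any(z <= 0)) {
    stop("non-physical eye: object vergence at IOL plane (n/(L-ELP) - P) <= 0",
         call. = FALSE)
  }
  d <- C + n / z
  if (any(d <= 0)) {
    stop("non-physical eye: corneal object distance (ELP + n/vergence) <= 0",
         call. = FALSE)
  }
  rc <- n / d - elp$dc_d
  corneal_to_spectacle(rc, params$vertex_mm)
}

#' IOL power giving emmetropia for a given effective lens position
#'
#' Closed-form inversion of [vergence_refraction()] at zero refraction:
#' P* = n/(L - ELP) - n/(n/Dc - ELP) (lengths in meters). Feeding P* back
#' through the vergence model returns 0 D to numerical precision.
#'
#' @inheritParams vergence_refraction
#' @return Emmetropizing IOL power in diopters.
#' @export
emmetropic_power <- function(params, elp) {
  power_for_target(params, elp, target_d = 0)
}

#' IOL power whose predicted spectacle refraction equals a target
#'
#' Generalization of [emmetropic_power()]: the target spectacle refraction
#' is transposed to the corneal plane and the vergence chain is inverted in
#' closed form.
#'
#' @inheritParams vergence_refraction
#' @param target_d Desired spectacle refraction in diopters (default 0).
#' @return IOL power in diopters (unrounded).
#' @export
power_for_target <- function(params, elp, target_d = 0) {
  stopifnot(inherits(params, "optical_params"))
  check_elp(elp)
  n <- params$n_aqueous
  C <- elp$elp_mm / 1000
  L <- elp$l_opt_mm / 1000
  tc <- spectacle_to_corneal(target_d, params$vertex_mm)
  v <- elp$dc_d + tc          # corneal vergence including the target error
  den <- n / v - C
  if (any(v <= 0) || any(den <= 0)) {
    stop("non-physical eye: corneal focal distance n/Dc - ELP <= 0",
         call. = FALSE)
  }
  n / (L - C) - n / den
}

# shared structural check for elp_result-like inputs
check_elp <- function(elp) {
  need <- c("elp_mm", "l_opt_mm", "dc_d")
  if (!all(need %in% names(elp))) {
    stop("elp must carry fields elp_mm, l_opt_mm, dc_d", call. = FALSE)
  }
  bad <- !is.finite(elp$elp_mm) | !is.finite(elp$l_opt_mm) |
    !is.finite(elp$dc_d) | elp$elp_mm <= 0 | elp$elp_mm >= elp$l_opt_mm
  if (any(bad)) {
    stop("invalid ELP: require 0 < elp_mm < l_opt_mm, all finite",
         call. = FALSE)
  }
  invisible(TRUE)
}
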