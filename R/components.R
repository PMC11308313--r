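# Physical component models: tube geometry, catheters, syringes, manifolds.

#' Cylindrical tube geometry
#'
#' Infusion lines and catheters are modelled as cylindrical tubes described by
#' their length and inner diameter; internal volume and hydraulic resistance
#' follow from these two numbers.
#'
#' @param length_m tube length in metres.
#' @param inner_diameter_mm inner (lumen) diameter in millimetres.
#' @return A `tube_geometry` object.
#' @examples
#' tube_geometry(1, 1.0)
#' tube_volume(tube_geometry(1, 1.0))
#' @export
tube_geometry <- function(length_m, inner_diameter_mm) {
  stopifnot_positive(length_m = length_m, inner_diameter_mm = inner_diameter_mm)
  structure(
    list(length_m = length_m, inner_diameter_mm = inner_diameter_mm),
    class = "tube_geometry"
  )
}

#' @export
print.tube_geometry <- function(x, ...) {
  cat(sprintf("<tube_geometry> L = %g m, ID = %g mm, V = %.4g mL\n",
              x$length_m, x$inner_diameter_mm, tube_volume(x)))
  invisible(x)
}

#' Tube geometry with a prescribed internal volume
#'
#' Convenience constructor: given a target internal volume and a length,
#' solves for the inner diameter. Useful when a scenario states a line volume
#' (for example "a 3 mL infusion line") rather than a diameter.
#'
#' @param volume_ml internal volume in mL.
#' @param length_m tube length in metres.
#' @return A `tube_geometry` with `tube_volume()` equal to `volume_ml`.
#' @export
tube_geometry_for_volume <- function(volume_ml, length_m = 1) {
  stopifnot_positive(volume_ml = volume_ml, length_m = length_m)
  # area [mm^2] * length [m] = volume [mL]
  area_mm2 <- volume_ml / length_m
  tube_geometry(length_m, 2 * sqrt(area_mm2 / pi))
}

#' Internal volume of a cylindrical tube
#'
#' @param geometry a [tube_geometry()].
#' @return volume in mL.
#' @export
tube_volume <- function(geometry) {
  if (!inherits(geometry, "tube_geometry")) {
    abort("`geometry` must be a tube_geometry object.",
          class = "infusim_invalid_parameter")
  }
  # 1 mm^2 x 1 m = 1 mL
  pi * (geometry$inner_diameter_mm / 2)^2 * geometry$length_m
}

#' Hagen-Poiseuille hydraulic resistance of a tube
#'
#' Laminar flow in a cylindrical tube gives a pressure drop proportional to
#' flow, with resistance \deqn{R = \frac{128\,\mu L}{\pi d^4}} so halving the
#' lumen diameter multiplies the resistance by sixteen. Evaluated in SI and
#' returned in clinical units (mbar·h/mL).
#'
#' @param geometry a [tube_geometry()].
#' @param viscosity_mpas dynamic viscosity of the infusate in mPa·s
#'   (default 1.0, water-like).
#' @return resistance in mbar·h/mL.
#' @examples
#' g <- tube_geometry(0.1, 0.5)
#' poiseuille_resistance(g)
#' # d^-4 scaling: doubling the diameter divides resistance by 16
#' poiseuille_resistance(tube_geometry(0.1, 1.0)) * 16
#' @export
poiseuille_resistance <- function(geometry, viscosity_mpas = 1.0) {
  if (!inherits(geometry, "tube_geometry")) {
    abort("`geometry` must be a tube_geometry object.",
          class = "infusim_invalid_parameter")
  }
  stopifnot_positive(viscosity_mpas = viscosity_mpas)
  mu <- viscosity_mpas * .MPAS_TO_PAS
  d <- geometry$inner_diameter_mm * .MM_TO_M
  r_si <- 128 * mu * geometry$length_m / (pi * d^4)
  si_resistance_to_clinical(r_si)
}

#' Catheter specification
#'
#' A vascular access device: named, sized in French gauge (1 Fr = 1/3 mm
#' outer diameter; the inner diameter is product-specific), with a tube
#' geometry from which resistance is computed unless overridden.
#'
#' @param name label.
#' @param french_size French gauge of the catheter.
#' @param geometry a [tube_geometry()] for the lumen.
#' @param resistance_mbar_h_ml hydraulic resistance; defaults to
#'   `poiseuille_resistance(geometry, viscosity_mpas)`.
#' @param viscosity_mpas viscosity used for the default resistance.
#' @return A `catheter_spec` object.
#' @export
catheter_spec <- function(name, french_size, geometry,
                          resistance_mbar_h_ml = NULL,
                          viscosity_mpas = 1.0) {
  stopifnot_positive(french_size = french_size)
  if (!inherits(geometry, "tube_geometry")) {
    abort("`geometry` must be a tube_geometry object.",
          class = "infusim_invalid_parameter")
  }
  if (is.null(resistance_mbar_h_ml)) {
    resistance_mbar_h_ml <- poiseuille_resistance(geometry, viscosity_mpas)
  }
  stopifnot_positive(resistance_mbar_h_ml = resistance_mbar_h_ml)
  structure(
    list(name = name, french_size = french_size, geometry = geometry,
         resistance_mbar_h_ml = resistance_mbar_h_ml),
    class = "catheter_spec"
  )
}

#' @export
print.catheter_spec <- function(x, ...) {
  cat(sprintf("<catheter_spec> %s (%g Fr): ID %g mm, L %g m, R %.4g mbar.h/mL, V %.4g mL\n",
              x$name, x$french_size, x$geometry$inner_diameter_mm,
              x$geometry$length_m, x$resistance_mbar_h_ml, tube_volume(x$geometry)))
  invisible(x)
}

#' Syringe specification
#'
#' Mechanical compliance lives almost entirely in the syringe (notably the
#' air-filled rubber plunger): stored volume per unit pressure. A compliance
#' of zero denotes an idealized rigid syringe.
#'
#' @param name label.
#' @param nominal_volume_ml nominal syringe volume in mL.
#' @param compliance_ml_mbar mechanical compliance in mL/mbar (>= 0).
#' @return A `syringe_spec` object.
#' @export
syringe_spec <- function(name, nominal_volume_ml, compliance_ml_mbar) {
  stopifnot_positive(nominal_volume_ml = nominal_volume_ml)
  stopifnot_nonnegative(compliance_ml_mbar = compliance_ml_mbar)
  structure(
    list(name = name, nominal_volume_ml = nominal_volume_ml,
         compliance_ml_mbar = compliance_ml_mbar),
    class = "syringe_spec"
  )
}

#' @export
print.syringe_spec <- function(x, ...) {
  cat(sprintf("<syringe_spec> %s: %g mL, C = %g mL/mbar\n",
              x$name, x$nominal_volume_ml, x$compliance_ml_mbar))
  invisible(x)
}

#' Mixing point specification
#'
#' The manifold (or Y-piece) where pump lines join. Everything downstream of
#' the mixing point and upstream of the vascular access point is shared by
#' all fluids — the "dead volume" that must be flushed before a new mixing
#' ratio reaches the patient.
#'
#' @param name label.
#' @param dead_volume_ml shared volume between mixing point and the catheter
#'   hub, in mL (>= 0).
#' @return A `mixing_point_spec` object.
#' @export
mixing_point_spec <- function(name, dead_volume_ml) {
  stopifnot_nonnegative(dead_volume_ml = dead_volume_ml)
  structure(
    list(name = name, dead_volume_ml = dead_volume_ml),
    class = "mixing_point_spec"
  )
}

#' @export
print.mixing_point_spec <- function(x, ...) {
  cat(sprintf("<mixing_point_spec> %s: dead volume %g mL\n",
              x$name, x$dead_volume_ml))
  invisible(x)
}
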