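# Pump branches, the full infusion network, and the simulation grid.

#' One syringe pump and its line
#'
#' A branch of the infusion network: a (possibly compliant) syringe driven at
#' the set flow, connected to the mixing point by its own tubing. The branch
#' line resistance defaults to the Hagen-Poiseuille resistance of the tubing
#' at the branch's infusate viscosity.
#'
#' @param drug label of the stock solution in the syringe.
#' @param syringe a [syringe_spec()].
#' @param line a [tube_geometry()] for the tubing between pump and mixing
#'   point.
#' @param schedule a [flow_schedule()].
#' @param line_resistance_mbar_h_ml optional override of the line resistance.
#' @param viscosity_mpas infusate viscosity in mPa·s (default 1.0).
#' @param concentration_mg_ml optional drug concentration; when supplied,
#'   dose rates can also be reported as mass rates.
#' @return A `pump_branch` object.
#' @export
pump_branch <- function(drug, syringe, line, schedule,
                        line_resistance_mbar_h_ml = NULL,
                        viscosity_mpas = 1.0,
                        concentration_mg_ml = NULL) {
  if (!inherits(syringe, "syringe_spec")) {
    abort("`syringe` must be a syringe_spec.", class = "infusim_invalid_parameter")
  }
  if (!inherits(line, "tube_geometry")) {
    abort("`line` must be a tube_geometry.", class = "infusim_invalid_parameter")
  }
  if (!inherits(schedule, "flow_schedule")) {
    abort("`schedule` must be a flow_schedule.", class = "infusim_invalid_parameter")
  }
  if (is.null(line_resistance_mbar_h_ml)) {
    line_resistance_mbar_h_ml <- poiseuille_resistance(line, viscosity_mpas)
  }
  stopifnot_positive(line_resistance_mbar_h_ml = line_resistance_mbar_h_ml)
  structure(
    list(drug = drug, syringe = syringe, line = line, schedule = schedule,
         line_resistance_mbar_h_ml = line_resistance_mbar_h_ml,
         viscosity_mpas = viscosity_mpas,
         concentration_mg_ml = concentration_mg_ml),
    class = "pump_branch"
  )
}

#' @export
print.pump_branch <- function(x, ...) {
  cat(sprintf("<pump_branch> drug \"%s\": C = %g mL/mbar, R_line = %.4g mbar.h/mL\n",
              x$drug, x$syringe$compliance_ml_mbar, x$line_resistance_mbar_h_ml))
  invisible(x)
}

#' Multi-pump infusion network
#'
#' The full simulated system: N pump branches joining at a mixing point,
#' whose dead volume plus the catheter lumen forms the shared volume through
#' which all fluids travel to the vascular access point.
#'
#' @param branches list of [pump_branch()] objects (N >= 1).
#' @param mixing_point a [mixing_point_spec()].
#' @param catheter a [catheter_spec()].
#' @param venous_pressure_mbar constant back-pressure at the vascular access
#'   point, mbar gauge (default 0).
#' @return An `infusion_network` object.
#' @export
infusion_network <- function(branches, mixing_point, catheter,
                             venous_pressure_mbar = 0) {
  if (inherits(branches, "pump_branch")) branches <- list(branches)
  if (length(branches) < 1L || !all(vapply(branches, inherits, TRUE, "pump_branch"))) {
    abort("`branches` must be a non-empty list of pump_branch objects.",
          class = "infusim_invalid_parameter")
  }
  if (!inherits(mixing_point, "mixing_point_spec")) {
    abort("`mixing_point` must be a mixing_point_spec.",
          class = "infusim_invalid_parameter")
  }
  if (!inherits(catheter, "catheter_spec")) {
    abort("`catheter` must be a catheter_spec.",
          class = "infusim_invalid_parameter")
  }
  if (!is.numeric(venous_pressure_mbar) || !is.finite(venous_pressure_mbar)) {
    abort("`venous_pressure_mbar` must be finite.",
          class = "infusim_invalid_parameter")
  }
  if (is.null(names(branches)) || any(names(branches) == "")) {
    names(branches) <- paste0("pump_", LETTERS[seq_along(branches)])
  }
  structure(
    list(branches = branches, mixing_point = mixing_point, catheter = catheter,
         venous_pressure_mbar = venous_pressure_mbar),
    class = "infusion_network"
  )
}

#' @export
print.infusion_network <- function(x, ...) {
  cat(sprintf("<infusion_network> %d pump(s) -> %s -> %s, P_venous = %g mbar\n",
              length(x$branches), x$mixing_point$name, x$catheter$name,
              x$venous_pressure_mbar))
  cat(sprintf("  shared volume (dead volume + catheter lumen): %.4g mL\n",
              shared_volume(x)))
  for (nm in names(x$branches)) {
    cat("  ", nm, ": ", sep = ""); print(x$branches[[nm]])
  }
  invisible(x)
}

#' Shared (dead + catheter) volume of a network
#'
#' Volume between the mixing point and the vascular access point: the
#' manifold dead volume plus the catheter lumen volume. This is the volume
#' that must be flushed before a changed mixing ratio reaches the patient.
#'
#' @param network an [infusion_network()].
#' @return volume in mL.
#' @export
shared_volume <- function(network) {
  network$mixing_point$dead_volume_ml + tube_volume(network$catheter$geometry)
}

# per-branch vectors used by the solver
branch_params <- function(network) {
  list(
    R = vapply(network$branches, function(b) b$line_resistance_mbar_h_ml, 0),
    C = vapply(network$branches, function(b) b$syringe$compliance_ml_mbar, 0),
    drug = vapply(network$branches, function(b) b$drug, "")
  )
}

#' Simulation grid
#'
#' Time step, duration and transport slice volume for a simulation. When
#' `dt_h` or `slice_volume_ml` are `NULL` they are chosen from the network at
#' simulation time: the slice volume defaults to 1/200 of the shared volume
#' (floor 1e-5 mL) and the time step to a value well below both the smallest
#' branch pressure time constant and the time to advect one slice at the
#' largest scheduled total flow.
#'
#' @param duration_h simulated duration in hours.
#' @param dt_h time step in hours, or `NULL` for automatic.
#' @param slice_volume_ml transport slice volume in mL, or `NULL` for
#'   automatic.
#' @return A `simulation_grid` object.
#' @export
simulation_grid <- function(duration_h, dt_h = NULL, slice_volume_ml = NULL) {
  stopifnot_positive(duration_h = duration_h)
  if (!is.null(dt_h)) {
    stopifnot_positive(dt_h = dt_h)
    if (duration_h < dt_h) {
      abort("`duration_h` must be at least `dt_h`.",
            class = "infusim_invalid_parameter")
    }
  }
  if (!is.null(slice_volume_ml)) stopifnot_positive(slice_volume_ml = slice_volume_ml)
  structure(
    list(duration_h = duration_h, dt_h = dt_h, slice_volume_ml = slice_volume_ml),
    class = "simulation_grid"
  )
}

# Fill in automatic dt / slice volume for a given network.
resolve_grid <- function(grid, network) {
  if (!inherits(grid, "simulation_grid")) {
    abort("`grid` must be a simulation_grid.", class = "infusim_invalid_parameter")
  }
  slice <- grid$slice_volume_ml
  if (is.null(slice)) {
    slice <- max(shared_volume(network) / 200, 1e-5)
  }
  dt <- grid$dt_h
  if (is.null(dt)) {
    p <- branch_params(network)
    r_c <- network$catheter$resistance_mbar_h_ml
    tau <- ifelse(p$C > 0, p$C * (p$R + r_c), Inf)
    qmax <- max(vapply(network$branches,
                       function(b) max(b$schedule$events$set_flow_ml_h), 0))
    qtot <- sum(vapply(network$branches,
                       function(b) max(b$schedule$events$set_flow_ml_h), 0))
    cand <- c(min(tau) / 20,
              if (qtot > 0) slice / (2 * qtot) else Inf,
              grid$duration_h / 200)
    dt <- min(cand[is.finite(cand)])
    # keep runs tractable: never more than ~2e5 steps
    dt <- max(dt, grid$duration_h / 2e5)
  }
  structure(
    list(duration_h = grid$duration_h, dt_h = dt, slice_volume_ml = slice),
    class = "simulation_grid"
  )
}

#' @export
print.simulation_grid <- function(x, ...) {
  cat(sprintf("<simulation_grid> duration %g h, dt %s, slice volume %s\n",
              x$duration_h,
              if (is.null(x$dt_h)) "auto" else sprintf("%g h", x$dt_h),
              if (is.null(x$slice_volume_ml)) "auto" else sprintf("%g mL", x$slice_volume_ml)))
  invisible(x)
}
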