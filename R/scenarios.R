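# Scenario definitions: the four built-in teaching cases, a YAML scenario
# reader, and a randomized fixture generator for property testing.

new_scenario <- function(name, network, grid, initial_mixture = NULL,
                         events = "", expected_qualitative = NULL, id = NA) {
  check_schedule_coverage(network, grid)
  structure(
    list(name = name, id = id, network = network, grid = grid,
         initial_mixture = initial_mixture, events = events,
         expected_qualitative = expected_qualitative),
    class = "infusim_scenario"
  )
}

#' @export
print.infusim_scenario <- function(x, ...) {
  cat(sprintf("<infusim_scenario> %s\n  events: %s\n", x$name, x$events))
  if (!is.null(x$expected_qualitative)) {
    cat("  expected:", x$expected_qualitative, "\n")
  }
  print(x$network)
  invisible(x)
}

#' Built-in teaching cases
#'
#' Four scenarios of increasing subtlety, built from the packaged component
#' catalog: \describe{
#'   \item{1}{One pump at 6 mL/h pushing a newly loaded medicine through a
#'     3 mL line: when does the first bit arrive? (Laminar profile: at half
#'     the mean transit time.)}
#'   \item{2}{Two pumps into a 7 Fr catheter; the high-flow pump A is
#'     stepped up 10 to 20 mL/h while pump B runs critical medication at
#'     1 mL/h: drug B is transiently overdosed while the old mixture is
#'     pushed out.}
#'   \item{3}{As case 2 but pump A steps down 20 to 10 mL/h: transient
#'     underdose of drug B.}
#'   \item{4}{As case 2 but through a 1 Fr neonatal catheter: the high
#'     resistance makes the syringe compliances dominate, giving a biphasic
#'     overdose-then-underdose of drug B.}
#' }
#' The case 2-4 flow rates are illustrative (the regimes, not the exact
#' magnitudes, are the point) and everything is rebuildable with other
#' components via [infusion_network()].
#'
#' @param id case number, 1 to 4.
#' @param catalog a [component_catalog()].
#' @return An `infusim_scenario`: name, network, grid, initial mixture,
#'   event description and the qualitatively expected outcome.
#' @examples
#' builtin_case(1)
#' @export
builtin_case <- function(id, catalog = component_catalog()) {
  if (!id %in% 1:4) {
    abort("Unknown case id; built-in cases are 1, 2, 3, 4.",
          class = "infusim_unknown_case")
  }
  syr <- catalog_lookup("Omnifix 50mL", catalog)
  line <- catalog_lookup("Standard line 1m", catalog)
  manifold <- catalog_lookup("Discofix C 3-gang", catalog)
  cath7 <- catalog_lookup("Careflow 7Fr", catalog)
  cath1 <- catalog_lookup("Premicath 1Fr", catalog)

  if (id == 1) {
    line_volume <- 3
    dead <- mixing_point_spec(
      "Single line (3 mL to access point)",
      line_volume - tube_volume(cath7$geometry)
    )
    br <- pump_branch("drug_new", syr, line, constant_flow(6, duration_h = 2))
    net <- infusion_network(list(pump_A = br), dead, cath7)
    return(new_scenario(
      "case_1_first_arrival", net, simulation_grid(1.5, dt_h = 2e-3),
      initial_mixture = c(drug_old = 1),
      events = "syringe exchanged at t = 0: new medicine at a constant 6 mL/h through a 3 mL line",
      expected_qualitative = "first arrival of the new medicine at half the mean transit time",
      id = 1
    ))
  }

  t_change <- 0.1
  duration <- 0.6
  sched_a <- if (id == 3) {
    flow_schedule(c(0, t_change), c(20, 10), duration_h = duration)
  } else {
    flow_schedule(c(0, t_change), c(10, 20), duration_h = duration)
  }
  br_a <- pump_branch("drug_A", syr, line, sched_a)
  br_b <- pump_branch("drug_B", syr, line, constant_flow(1, duration_h = duration))
  cath <- if (id == 4) cath1 else cath7
  net <- infusion_network(list(pump_A = br_a, pump_B = br_b), manifold, cath)
  events <- sprintf("pump A stepped %s at t = %g h; pump B constant at 1 mL/h",
                    if (id == 3) "20 -> 10 mL/h" else "10 -> 20 mL/h", t_change)
  expected <- switch(as.character(id),
    "2" = "transient overdose of drug B, then recovery",
    "3" = "transient underdose of drug B, then recovery",
    "4" = "biphasic drug-B deviation (overdose then underdose), compliance-dominated")
  new_scenario(sprintf("case_%d%s", id,
                       switch(as.character(id), "2" = "_step_up_7Fr",
                              "3" = "_step_down_7Fr", "4" = "_step_up_1Fr")),
               net, simulation_grid(duration), events = events,
               expected_qualitative = expected, id = id)
}

#' Simulate a scenario
#'
#' @param scenario an `infusim_scenario` from [builtin_case()],
#'   [read_scenario()] or [generate_fixture()].
#' @param kernel transport kernel, as in [simulate_delivery()].
#' @param compliance logical, as in [simulate_delivery()].
#' @return A `dose_sim`.
#' @export
simulate_scenario <- function(scenario, kernel = "poiseuille", compliance = TRUE) {
  if (!inherits(scenario, "infusim_scenario")) {
    abort("`scenario` must be an infusim_scenario.",
          class = "infusim_invalid_parameter")
  }
  simulate_delivery(scenario$network, scenario$grid, kernel = kernel,
                    initial_mixture = scenario$initial_mixture,
                    compliance = compliance)
}

#' Classify the shape of a deviation curve
#'
#' Qualitative tag for one drug's deviation after the last set-flow change:
#' `"none"` (never leaves the noise band), `"overdose-then-recovery"`,
#' `"underdose-then-recovery"`, or `"biphasic"` (both signs reached). The
#' band is 10% of the peak absolute deviation (floor `min_ml_h`).
#'
#' @param dev deviation tibble ([deviation()]) for a single drug or with a
#'   `drug` column to split on.
#' @param after_h ignore times before this (e.g. the change time).
#' @param min_ml_h absolute floor of the significance band, mL/h.
#' @return A tibble `drug`, `pattern`, `peak_overdose_ml_h`,
#'   `peak_underdose_ml_h`.
#' @export
classify_deviation <- function(dev, after_h = 0, min_ml_h = 0.005) {
  dev |>
    dplyr::filter(.data$time_h >= after_h) |>
    dplyr::group_by(.data$drug) |>
    dplyr::summarise(
      pattern = classify_one(.data$deviation_ml_h, min_ml_h),
      peak_overdose_ml_h = max(c(0, .data$deviation_ml_h)),
      peak_underdose_ml_h = -min(c(0, .data$deviation_ml_h)),
      .groups = "drop"
    )
}

classify_one <- function(d, min_ml_h) {
  peak <- max(abs(d))
  if (peak <= min_ml_h) return("none")
  thr <- max(0.1 * peak, min_ml_h)
  pos <- any(d > thr)
  neg <- any(d < -thr)
  if (pos && neg) "biphasic"
  else if (pos) "overdose-then-recovery"
  else "underdose-then-recovery"
}

#' Randomized physically-valid scenario for property tests
#'
#' Draws an N-pump network with parameters in realistic clinical ranges and
#' one set-flow step on pump A. Reproducible: the same seed always yields
#' the same scenario, and the caller's RNG state is left untouched.
#'
#' @param seed integer seed.
#' @param n_pumps number of pumps (1-4), or `NULL` to draw it.
#' @param rigid force all syringe compliances to zero.
#' @param plug_catheter_7fr force the low-resistance 7 Fr catheter instead
#'   of drawing one.
#' @param flow_range range (mL/h) for the initial set flows.
#' @param dead_volume_range range (mL) for the manifold dead volume.
#' @param compliance_range range (mL/mbar) for syringe compliances.
#' @return An `infusim_scenario`.
#' @examples
#' generate_fixture(7)$network
#' @export
generate_fixture <- function(seed, n_pumps = NULL, rigid = FALSE,
                             plug_catheter_7fr = FALSE,
                             flow_range = c(0.5, 15),
                             dead_volume_range = c(0.2, 1),
                             compliance_range = c(5e-4, 3e-3)) {
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)

  catalog <- component_catalog()
  if (is.null(n_pumps)) n_pumps <- sample(1:4, 1)
  if (!n_pumps %in% 1:4) {
    abort("`n_pumps` must be in 1..4.", class = "infusim_invalid_parameter")
  }
  t_change <- stats::runif(1, 0.05, 0.15)
  duration <- t_change + 0.5
  cath <- if (plug_catheter_7fr) {
    catalog_lookup("Careflow 7Fr", catalog)
  } else {
    catalog_lookup(sample(c("Careflow 7Fr", "Premicath 1Fr"), 1), catalog)
  }
  line <- catalog_lookup("Standard line 1m", catalog)
  branches <- lapply(seq_len(n_pumps), function(i) {
    q0 <- stats::runif(1, flow_range[1], flow_range[2])
    sched <- if (i == 1) {
      q1 <- q0 * stats::runif(1, 0.3, 2.5)
      flow_schedule(c(0, t_change), c(q0, q1), duration_h = duration)
    } else {
      constant_flow(q0, duration_h = duration)
    }
    cmp <- if (rigid) 0 else stats::runif(1, compliance_range[1], compliance_range[2])
    pump_branch(sprintf("drug_%d", i),
                syringe_spec("Omnifix 50mL", 50, cmp),
                line, sched)
  })
  names(branches) <- paste0("pump_", LETTERS[seq_len(n_pumps)])
  net <- infusion_network(
    branches,
    mixing_point_spec("Discofix C 3-gang",
                      stats::runif(1, dead_volume_range[1], dead_volume_range[2])),
    cath
  )
  new_scenario(sprintf("fixture_seed%d", seed), net, simulation_grid(duration),
               events = sprintf("pump A step at t = %.3g h", t_change),
               id = NA)
}

#' Read a scenario from a YAML file
#'
#' Scenario files are declarative: components may reference catalog entries
#' by name or spell out their parameters. See the packaged example
#' `system.file("extdata", "case2_scenario.yaml", package = "infusim")` for
#' the schema.
#'
#' @param path path to a scenario YAML file.
#' @param catalog a [component_catalog()] for named references.
#' @return An `infusim_scenario`.
#' @export
read_scenario <- function(path, catalog = component_catalog()) {
  y <- yaml::read_yaml(path)
  need <- c("name", "branches", "mixing_point", "catheter", "grid")
  missing <- setdiff(need, names(y))
  if (length(missing) > 0) {
    abort(sprintf("Scenario file lacks field(s): %s.", paste(missing, collapse = ", ")),
          class = "infusim_invalid_parameter")
  }
  as_syringe <- function(s) {
    if (is.character(s)) catalog_lookup(s, catalog)
    else syringe_spec(s$name %||% "syringe", s$nominal_volume_ml,
                      s$compliance_ml_mbar)
  }
  as_tube <- function(s) {
    if (is.character(s)) catalog_lookup(s, catalog)
    else tube_geometry(s$length_m, s$inner_diameter_mm)
  }
  branches <- lapply(y$branches, function(b) {
    pump_branch(b$drug, as_syringe(b$syringe), as_tube(b$line),
                flow_schedule(vapply(b$schedule$events, `[[`, 0, "time_h"),
                              vapply(b$schedule$events, `[[`, 0, "set_flow_ml_h"),
                              duration_h = b$schedule$duration_h),
                viscosity_mpas = b$viscosity_mpas %||% 1.0)
  })
  mp <- if (is.character(y$mixing_point)) {
    catalog_lookup(y$mixing_point, catalog)
  } else {
    mixing_point_spec(y$mixing_point$name %||% "mixing point",
                      y$mixing_point$dead_volume_ml)
  }
  cath <- if (is.character(y$catheter)) {
    catalog_lookup(y$catheter, catalog)
  } else {
    catheter_spec(y$catheter$name %||% "catheter", y$catheter$french_size,
                  tube_geometry(y$catheter$length_m, y$catheter$inner_diameter_mm),
                  resistance_mbar_h_ml = y$catheter$resistance_mbar_h_ml)
  }
  net <- infusion_network(branches, mp, cath,
                          venous_pressure_mbar = y$venous_pressure_mbar %||% 0)
  grid <- simulation_grid(y$grid$duration_h, dt_h = y$grid$dt_h,
                          slice_volume_ml = y$grid$slice_volume_ml)
  im <- if (!is.null(y$initial_mixture)) unlist(y$initial_mixture) else NULL
  new_scenario(y$name, net, grid, initial_mixture = im,
               events = y$events %||% "", id = y$id %||% NA)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
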