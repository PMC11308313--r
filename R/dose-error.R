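# Dosing-error analysis: deviation curves, integrated errors, and the
# three-way mechanism decomposition (push-out / Poiseuille / compliance).

#' Deviation of delivered from set dose rates
#'
#' @param sim a `dose_sim` from [simulate_delivery()], or a dose tibble with
#'   columns `time_h`, `drug`, `set_rate_ml_h`, `delivered_rate_ml_h`.
#' @return A tibble `time_h`, `drug`, `deviation_ml_h` with
#'   deviation = delivered - set.
#' @export
deviation <- function(sim) {
  dose <- if (inherits(sim, "dose_sim")) sim$dose else sim
  need <- c("time_h", "drug", "set_rate_ml_h", "delivered_rate_ml_h")
  if (!all(need %in% names(dose))) {
    abort("Need columns time_h, drug, set_rate_ml_h, delivered_rate_ml_h.",
          class = "infusim_alignment_error")
  }
  dplyr::transmute(dose, time_h = .data$time_h, drug = .data$drug,
                   deviation_ml_h = .data$delivered_rate_ml_h - .data$set_rate_ml_h)
}

#' Integrated dosing error
#'
#' Trapezoidal integral of the deviation over a time window, reported as the
#' signed error plus the overdose (positive part) and underdose (negative
#' part) magnitudes separately.
#'
#' @param dev a deviation tibble from [deviation()] (columns `time_h`,
#'   `drug`, `deviation_ml_h`).
#' @param window numeric length-2 `c(from, to)` in hours, or `NULL` for the
#'   whole series.
#' @return A tibble `drug`, `signed_ml`, `overdose_ml`, `underdose_ml`.
#' @export
integrate_error <- function(dev, window = NULL) {
  if (!all(c("time_h", "drug", "deviation_ml_h") %in% names(dev))) {
    abort("`dev` must have columns time_h, drug, deviation_ml_h.",
          class = "infusim_alignment_error")
  }
  if (!is.null(window)) {
    if (length(window) != 2 || window[2] <= window[1]) {
      abort("`window` must be c(from, to) with to > from.",
            class = "infusim_invalid_window")
    }
    dev <- dplyr::filter(dev, .data$time_h >= window[1], .data$time_h <= window[2])
  }
  if (nrow(dev) == 0) {
    abort("Empty integration window.", class = "infusim_invalid_window")
  }
  dev |>
    dplyr::group_by(.data$drug) |>
    dplyr::summarise(
      signed_ml = trapz(.data$time_h, .data$deviation_ml_h),
      overdose_ml = trapz(.data$time_h, pmax(.data$deviation_ml_h, 0)),
      underdose_ml = -trapz(.data$time_h, pmin(.data$deviation_ml_h, 0)),
      .groups = "drop"
    )
}

trapz <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

#' Decompose the dosing error into its three mechanisms
#'
#' Runs three nested simulations of the same scenario — (a) rigid syringes
#' with plug transport (push-out effect only), (b) rigid syringes with the
#' laminar kernel (push-out + Poiseuille profile), (c) the full model — and
#' reports \describe{
#'   \item{push_out}{deviation of (a),}
#'   \item{poiseuille}{deviation of (b) minus (a),}
#'   \item{compliance}{deviation of (c) minus (b).}
#' }
#' By construction the three components sum exactly to the full-model
#' deviation at every grid point. The split is an ablation differencing and
#' therefore order-dependent; this nesting isolates compliance last because
#' it is the mechanism that interacts with both others.
#'
#' @param network an [infusion_network()].
#' @param grid a [simulation_grid()].
#' @param initial_mixture passed to [simulate_delivery()].
#' @param kernel transport kernel of the full model (and of ablation (b));
#'   with `"plug"` the Poiseuille component is identically zero.
#' @return An `error_decomposition` object: tibble `components` with columns
#'   `time_h`, `drug`, `set_rate_ml_h`, `delivered_rate_ml_h`, `push_out`,
#'   `poiseuille`, `compliance`, `total_deviation` (all mL/h), plus a
#'   `summary` tibble of integrated per-drug, per-mechanism errors.
#' @examples
#' dec <- decompose(builtin_case(2)$network, simulation_grid(0.3))
#' glance(dec)
#' @export
decompose <- function(network, grid, initial_mixture = NULL,
                      kernel = c("poiseuille", "plug")) {
  kernel <- match.arg(kernel)
  sim_a <- simulate_delivery(network, grid, kernel = "plug",
                             initial_mixture = initial_mixture, compliance = FALSE)
  sim_b <- simulate_delivery(network, grid, kernel = kernel,
                             initial_mixture = initial_mixture, compliance = FALSE)
  sim_c <- simulate_delivery(network, grid, kernel = kernel,
                             initial_mixture = initial_mixture, compliance = TRUE)
  dev_a <- deviation(sim_a)$deviation_ml_h
  dev_b <- deviation(sim_b)$deviation_ml_h
  dev_c <- deviation(sim_c)$deviation_ml_h
  components <- sim_c$dose |>
    dplyr::mutate(
      push_out = dev_a,
      poiseuille = dev_b - dev_a,
      compliance = dev_c - dev_b,
      total_deviation = dev_c
    )
  long <- components |>
    tidyr::pivot_longer(c("push_out", "poiseuille", "compliance", "total_deviation"),
                        names_to = "component", values_to = "deviation_ml_h")
  summary <- long |>
    dplyr::group_by(.data$drug, .data$component) |>
    dplyr::summarise(
      signed_ml = trapz(.data$time_h, .data$deviation_ml_h),
      overdose_ml = trapz(.data$time_h, pmax(.data$deviation_ml_h, 0)),
      underdose_ml = -trapz(.data$time_h, pmin(.data$deviation_ml_h, 0)),
      .groups = "drop"
    )
  structure(
    list(components = components, summary = summary,
         network = network, grid = sim_c$grid,
         sims = list(push_out_only = sim_a, no_compliance = sim_b, full = sim_c)),
    class = "error_decomposition"
  )
}

#' @export
print.error_decomposition <- function(x, ...) {
  cat("<error_decomposition> integrated per-drug, per-mechanism errors (mL):\n")
  print(x$summary)
  invisible(x)
}

#' Time for deviations to die out
#'
#' First time after `after_h` from which every drug's deviation stays within
#' `tol_ml_h` of zero for the rest of the series, or `NA` if it never
#' settles.
#'
#' @param dev deviation tibble from [deviation()].
#' @param after_h only consider times at or after this (default 0).
#' @param tol_ml_h settling tolerance in mL/h.
#' @return time in hours, or `NA_real_`.
#' @export
time_to_recovery <- function(dev, after_h = 0, tol_ml_h = 0.01) {
  wide <- dev |>
    dplyr::group_by(.data$time_h) |>
    dplyr::summarise(m = max(abs(.data$deviation_ml_h)), .groups = "drop") |>
    dplyr::filter(.data$time_h >= after_h)
  ok <- rev(cumprod(rev(wide$m <= tol_ml_h))) > 0
  if (!any(ok)) return(NA_real_)
  wide$time_h[which(ok)[1]]
}
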