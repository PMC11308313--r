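# broom-style tidiers and ggplot2 autoplot methods for result objects.

#' Tidy a dose simulation
#'
#' @param x a `dose_sim`.
#' @param ... unused.
#' @return The per-drug dose tibble (`time_h`, `drug`, `set_rate_ml_h`,
#'   `delivered_rate_ml_h`).
#' @export
tidy.dose_sim <- function(x, ...) x$dose

#' One-row-per-drug summary of a dose simulation
#'
#' @param x a `dose_sim`.
#' @param ... unused.
#' @return A tibble with integrated signed error, overdose and underdose
#'   volumes (mL) and the peak absolute deviation (mL/h) per drug.
#' @export
glance.dose_sim <- function(x, ...) {
  dev <- deviation(x)
  integrate_error(dev) |>
    dplyr::left_join(
      dev |>
        dplyr::group_by(.data$drug) |>
        dplyr::summarise(peak_deviation_ml_h = max(abs(.data$deviation_ml_h)),
                         .groups = "drop"),
      by = "drug"
    )
}

#' @rdname tidy.error_decomposition
#' @export
glance.error_decomposition <- function(x, ...) x$summary

#' Tidy an error decomposition
#'
#' @param x an `error_decomposition` from [decompose()].
#' @param ... unused.
#' @return Long tibble `time_h`, `drug`, `component`, `deviation_ml_h` with
#'   components `push_out`, `poiseuille`, `compliance`, `total_deviation`.
#' @export
tidy.error_decomposition <- function(x, ...) {
  x$components |>
    tidyr::pivot_longer(c("push_out", "poiseuille", "compliance", "total_deviation"),
                        names_to = "component", values_to = "deviation_ml_h") |>
    dplyr::select("time_h", "drug", "component", "deviation_ml_h")
}

#' Plot set versus delivered dose rates
#'
#' One panel per drug: the set rate (dashed) and the rate actually delivered
#' at the vascular access point.
#'
#' @param object a `dose_sim`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.dose_sim <- function(object, ...) {
  d <- object$dose |>
    tidyr::pivot_longer(c("set_rate_ml_h", "delivered_rate_ml_h"),
                        names_to = "series", values_to = "rate_ml_h") |>
    dplyr::mutate(series = dplyr::recode(.data$series,
                                         set_rate_ml_h = "set",
                                         delivered_rate_ml_h = "delivered"))
  ggplot2::ggplot(d, ggplot2::aes(.data$time_h, .data$rate_ml_h,
                                  colour = .data$series,
                                  linetype = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::scale_linetype_manual(values = c(set = "dashed", delivered = "solid")) +
    ggplot2::facet_wrap(~drug, scales = "free_y") +
    ggplot2::labs(x = "time (h)", y = "dose rate (mL/h of stock solution)",
                  colour = NULL, linetype = NULL)
}

#' Plot the mechanism decomposition of the dosing error
#'
#' @param object an `error_decomposition`.
#' @param drug optional drug label to restrict to.
#' @param ... unused.
#' @return A ggplot of the push-out, Poiseuille and compliance components
#'   plus their sum (the total deviation) over time.
#' @export
autoplot.error_decomposition <- function(object, drug = NULL, ...) {
  d <- tidy(object)
  if (!is.null(drug)) d <- dplyr::filter(d, .data$drug %in% .env$drug)
  ggplot2::ggplot(d, ggplot2::aes(.data$time_h, .data$deviation_ml_h,
                                  colour = .data$component)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~drug, scales = "free_y") +
    ggplot2::labs(x = "time (h)", y = "deviation from set rate (mL/h)",
                  colour = "mechanism")
}

#' Plot branch flows into the mixing point
#'
#' Set versus actual branch flows; negative actual flow is backflow into
#' that line.
#'
#' @param sim a `dose_sim` (or the tibble from [solve_flows()]).
#' @return A ggplot.
#' @export
plot_flows <- function(sim) {
  fl <- if (inherits(sim, "dose_sim")) sim$flows else sim
  d <- fl |>
    tidyr::pivot_longer(c("set_flow_ml_h", "actual_flow_ml_h"),
                        names_to = "series", values_to = "flow_ml_h") |>
    dplyr::mutate(series = dplyr::recode(.data$series,
                                         set_flow_ml_h = "set",
                                         actual_flow_ml_h = "actual"))
  ggplot2::ggplot(d, ggplot2::aes(.data$time_h, .data$flow_ml_h,
                                  colour = .data$series,
                                  linetype = .data$series)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line() +
    ggplot2::scale_linetype_manual(values = c(set = "dashed", actual = "solid")) +
    ggplot2::facet_wrap(~branch, scales = "free_y") +
    ggplot2::labs(x = "time (h)", y = "flow into mixing point (mL/h)",
                  colour = NULL, linetype = NULL)
}
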