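# Piecewise-constant pump set-flow schedules.

#' Piecewise-constant set-flow schedule
#'
#' A pump programme: the set flow holds each value from its event time until
#' the next event (right-continuous step function). Pumps only infuse, so set
#' flows are non-negative.
#'
#' @param times_h event times in hours; strictly increasing, starting at 0.
#' @param flows_ml_h set flow at each event, mL/h (>= 0).
#' @param duration_h schedule duration in hours.
#' @return A `flow_schedule` object with an `events` tibble.
#' @examples
#' flow_schedule(c(0, 0.1), c(10, 20), duration_h = 0.6)
#' @export
flow_schedule <- function(times_h, flows_ml_h, duration_h = max(times_h) + 1) {
  if (length(times_h) != length(flows_ml_h) || length(times_h) < 1L) {
    abort("`times_h` and `flows_ml_h` must have equal, positive length.",
          class = "infusim_invalid_parameter")
  }
  if (times_h[1] != 0 || any(diff(times_h) <= 0)) {
    abort("Event times must start at 0 and be strictly increasing.",
          class = "infusim_invalid_parameter")
  }
  if (any(flows_ml_h < 0) || any(!is.finite(flows_ml_h))) {
    abort("Set flows must be finite and non-negative (pumps do not aspirate).",
          class = "infusim_invalid_parameter")
  }
  stopifnot_positive(duration_h = duration_h)
  structure(
    list(events = tibble(time_h = as.numeric(times_h),
                         set_flow_ml_h = as.numeric(flows_ml_h)),
         duration_h = duration_h),
    class = "flow_schedule"
  )
}

#' Constant set-flow schedule
#' @param flow_ml_h set flow in mL/h.
#' @param duration_h duration in hours.
#' @return A `flow_schedule`.
#' @export
constant_flow <- function(flow_ml_h, duration_h = 1) {
  flow_schedule(0, flow_ml_h, duration_h)
}

#' Set flow at a given time
#'
#' @param schedule a [flow_schedule()].
#' @param time_h time (may be a vector) in hours.
#' @return set flow(s) in mL/h; the value of the last event at or before
#'   `time_h` (0 before the first event).
#' @export
set_flow_at <- function(schedule, time_h) {
  ev <- schedule$events
  idx <- findInterval(time_h, ev$time_h)
  out <- numeric(length(time_h))
  out[idx > 0] <- ev$set_flow_ml_h[idx[idx > 0]]
  out
}

#' @export
print.flow_schedule <- function(x, ...) {
  cat(sprintf("<flow_schedule> %d event(s), duration %g h\n",
              nrow(x$events), x$duration_h))
  print(x$events)
  invisible(x)
}
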