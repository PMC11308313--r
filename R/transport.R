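# Drug transport through the shared volume: plug advection over the slice
# chain, backflow buffering in branch lines, and the laminar (Poiseuille)
# residence-time kernel.

#' Advect the slice chain by one step
#'
#' Pushes one step's worth of junction mixture onto the proximal end of the
#' chain and emits the same volume from the distal end. The emitted
#' composition is the volume-weighted mixture of the distal slices removed;
#' volume is conserved exactly. The junction node itself stores nothing, so
#' the summed branch inflow must equal the catheter outflow.
#'
#' @param chain a [slice_chain()].
#' @param inflows named numeric vector of per-branch (or per-drug) inflow
#'   rates in mL/h whose names are drug labels present in the chain; entries
#'   may repeat a drug. All entries must be non-negative here — backflow is
#'   handled on the branch side by [handle_backflow()].
#' @param outflow_ml_h catheter outflow in mL/h; must equal `sum(inflows)`.
#' @param dt_h step length in hours.
#' @return list with `chain` (advanced [slice_chain()]), `effluent`
#'   (named per-drug fractions of the emitted volume) and `volume_ml` (the
#'   emitted volume).
#' @examples
#' ch <- slice_chain(0.5, c(A = 0.5, B = 0.5), 0.05)
#' advect(ch, c(A = 2, B = 0), outflow_ml_h = 2, dt_h = 0.01)$effluent
#' @export
advect <- function(chain, inflows, outflow_ml_h, dt_h) {
  if (!inherits(chain, "slice_chain")) {
    abort("`chain` must be a slice_chain.", class = "infusim_invalid_parameter")
  }
  stopifnot_positive(dt_h = dt_h)
  if (outflow_ml_h < 0) {
    abort("Negative catheter outflow (net aspiration) is not a supported regime.",
          class = "infusim_unsupported_regime")
  }
  if (any(inflows < 0)) {
    abort("`inflows` must be non-negative; route backflow through handle_backflow().",
          class = "infusim_invalid_parameter")
  }
  if (abs(sum(inflows) - outflow_ml_h) > 1e-9 * max(1, outflow_ml_h)) {
    abort("Junction imbalance: sum(inflows) must equal outflow (zero-volume node).",
          class = "infusim_invalid_parameter")
  }
  unknown <- setdiff(names(inflows), chain$drugs)
  if (length(unknown) > 0) {
    abort(sprintf("Unknown drug label(s) in `inflows`: %s.",
                  paste(unknown, collapse = ", ")),
          class = "infusim_invalid_parameter")
  }
  dv <- outflow_ml_h * dt_h
  if (dv == 0) {
    return(list(chain = chain,
                effluent = setNames(chain$fractions[, 1], chain$drugs),
                volume_ml = 0))
  }
  mix <- vapply(chain$drugs, function(d) sum(inflows[names(inflows) == d]), 0)
  mix <- mix / sum(mix)
  d <- dq_from_chain(chain)
  dq_push(d, dv, mix)
  eff <- dq_pop(d, dv)
  list(chain = dq_to_chain(d, chain$drugs),
       effluent = setNames(eff, chain$drugs),
       volume_ml = dv)
}

#' Branch-line backflow buffer
#'
#' When a set-flow change raises the junction pressure above a branch
#' pressure, junction mixture is pressed back into that branch's tubing.
#' The intruded fluid is stored in a last-in-first-out buffer (plug flow is
#' reversible at these Reynolds numbers); when the branch flows forward
#' again the buffered mixture re-enters the junction before fresh stock
#' solution.
#'
#' @param drugs character vector of drug labels.
#' @return An empty `line_buffer` object.
#' @export
line_buffer <- function(drugs) {
  structure(list(volumes_ml = numeric(0),
                 fractions = matrix(0, length(drugs), 0,
                                    dimnames = list(drugs, NULL)),
                 drugs = drugs),
            class = "line_buffer")
}

#' @rdname line_buffer
#' @param buffer a `line_buffer`.
#' @param volume_ml backflow volume to store (mL, >= 0).
#' @param fractions named per-drug fractions of the backflowing mixture.
#' @param line_volume_ml internal volume of the branch tubing; exceeding it
#'   raises a warning (the excess is treated as displacing fluid toward the
#'   syringe) but is still buffered.
#' @return `handle_backflow()`: the updated buffer.
#' @export
handle_backflow <- function(buffer, volume_ml, fractions, line_volume_ml = Inf) {
  if (!inherits(buffer, "line_buffer")) {
    abort("`buffer` must be a line_buffer.", class = "infusim_invalid_parameter")
  }
  stopifnot_nonnegative(volume_ml = volume_ml)
  if (volume_ml == 0) return(buffer)
  check_fractions(fractions)
  fr <- fractions[buffer$drugs]
  buffer$volumes_ml <- c(buffer$volumes_ml, volume_ml)
  buffer$fractions <- cbind(buffer$fractions, as.numeric(fr))
  if (sum(buffer$volumes_ml) > line_volume_ml) {
    warn(sprintf(
      "Backflow (%.4g mL) exceeds the branch line volume (%.4g mL); excess displaces fluid toward the syringe.",
      sum(buffer$volumes_ml), line_volume_ml))
  }
  buffer
}

#' @rdname line_buffer
#' @return `draw_backflow()`: list with the updated `buffer`, the
#'   `volume_ml` actually drawn (may be less than requested if the buffer
#'   runs out; the remainder is fresh stock) and the mixture `fractions`.
#' @export
draw_backflow <- function(buffer, volume_ml) {
  if (!inherits(buffer, "line_buffer")) {
    abort("`buffer` must be a line_buffer.", class = "infusim_invalid_parameter")
  }
  stopifnot_nonnegative(volume_ml = volume_ml)
  acc <- numeric(length(buffer$drugs))
  drawn <- 0
  while (drawn < volume_ml && length(buffer$volumes_ml) > 0) {
    i <- length(buffer$volumes_ml)
    v <- buffer$volumes_ml[i]
    need <- volume_ml - drawn
    if (v <= need) {
      acc <- acc + v * buffer$fractions[, i]
      drawn <- drawn + v
      buffer$volumes_ml <- buffer$volumes_ml[-i]
      buffer$fractions <- buffer$fractions[, -i, drop = FALSE]
    } else {
      acc <- acc + need * buffer$fractions[, i]
      buffer$volumes_ml[i] <- v - need
      drawn <- volume_ml
    }
  }
  list(buffer = buffer, volume_ml = drawn,
       fractions = setNames(if (drawn > 0) acc / drawn else acc, buffer$drugs))
}

#' Laminar breakthrough (washout) curve
#'
#' In fully developed laminar flow the velocity profile is parabolic: the
#' centerline moves at twice the cross-sectional average, so after a
#' composition front enters a tube of volume V at flow Q the first new fluid
#' reaches the far end at half the mean transit time tau = V/Q. With no
#' radial mixing, the fraction of new fluid in the effluent is
#' \deqn{F(t) = 0 \quad (t < \tau/2), \qquad F(t) = 1 - (\tau/2t)^2 \quad (t \ge \tau/2).}
#'
#' @param tube_volume_ml internal volume of the tube segment (mL, >= 0).
#' @param flow_ml_h volumetric flow (mL/h, > 0).
#' @param t_h time since the front entered (h, vectorized).
#' @return fraction of new fluid in the effluent, in `[0, 1]`; monotone
#'   non-decreasing in `t_h` and tending to 1.
#' @examples
#' poiseuille_breakthrough(3, 6, c(0.2, 0.25, 0.5, 5))
#' @export
poiseuille_breakthrough <- function(tube_volume_ml, flow_ml_h, t_h) {
  stopifnot_nonnegative(tube_volume_ml = tube_volume_ml)
  stopifnot_positive(flow_ml_h = flow_ml_h)
  if (any(t_h < 0)) {
    abort("`t_h` must be non-negative.", class = "infusim_invalid_parameter")
  }
  if (tube_volume_ml == 0) return(rep(1, length(t_h)))
  tau <- tube_volume_ml / flow_ml_h
  ifelse(t_h < tau / 2, 0, 1 - (tau / (2 * t_h))^2)
}

#' First-arrival time of a new fluid
#'
#' Half the mean transit time V/Q: the centerline of a laminar profile
#' travels at twice the average velocity.
#'
#' @inheritParams poiseuille_breakthrough
#' @return time in hours.
#' @examples
#' first_arrival_time(3, 6)       # 0.25 h = 15 min
#' first_arrival_time(3, 6) * 60  # in minutes
#' @export
first_arrival_time <- function(tube_volume_ml, flow_ml_h) {
  stopifnot_nonnegative(tube_volume_ml = tube_volume_ml)
  stopifnot_positive(flow_ml_h = flow_ml_h)
  (tube_volume_ml / flow_ml_h) / 2
}

# Residence-volume distribution of the laminar kernel: fraction of fluid
# that has left the tube after `u` mL have flowed through, for a front that
# entered at u = 0. Volume-coordinate form of poiseuille_breakthrough, valid
# for time-varying flow.
laminar_Fv <- function(u, tube_volume_ml) {
  ifelse(u < tube_volume_ml / 2, 0, 1 - (tube_volume_ml / (2 * u))^2)
}

# Core of the laminar smearing: given a piecewise-constant entry composition
# history in cumulative-volume coordinate (entry value frac[, k] over
# (cumv[k-1], cumv[k]]), the pre-entry composition `init`, and the shared
# segment volume, return the effluent composition at the exit volumes
# `cumv`. Discretized on a uniform volume grid and convolved with the
# residence-volume weights.
laminar_effluent <- function(cumv, frac, init, tube_volume_ml, n_grid_min = 512L) {
  total <- cumv[length(cumv)]
  if (total <= 0) {
    return(matrix(rep(init, length(cumv)), nrow = length(init)))
  }
  dv_u <- tube_volume_ml / n_grid_min
  dv_u <- max(dv_u, total / 2e5)  # cap grid size for very long runs
  n <- ceiling(total / dv_u)
  grid_hi <- seq_len(n) * dv_u
  # entry composition sampled on the grid cells (value over ((j-1)dv, j dv])
  idx <- findInterval(grid_hi * (1 - 1e-12), cumv) + 1L
  idx[idx > ncol(frac)] <- ncol(frac)
  entry <- frac[, idx, drop = FALSE]
  # kernel weights: w[m] = F(m dv) - F((m-1) dv)
  Fhi <- laminar_Fv(grid_hi, tube_volume_ml)
  w <- diff(c(0, Fhi))
  nd <- nrow(entry)
  out <- matrix(0, nd, n)
  for (drg in seq_len(nd)) {
    z <- stats::convolve(entry[drg, ], rev(w), type = "open")[seq_len(n)]
    out[drg, ] <- z
  }
  # analytic tail: fluid still in the tube from before the record began
  tail_w <- 1 - c(0, Fhi[-n])  # residual weight at each exit volume
  out <- out + outer(init, tail_w)
  out <- pmin(pmax(out, 0), 1)
  # renormalize the tiny discretization slack so fractions sum to one
  s <- colSums(out)
  out <- sweep(out, 2, ifelse(s > 0, s, 1), "/")
  # sample at the requested exit volumes
  res <- matrix(0, nd, length(cumv))
  for (drg in seq_len(nd)) {
    res[drg, ] <- approx(grid_hi, out[drg, ], xout = pmax(cumv, grid_hi[1]),
                         rule = 2)$y
  }
  res
}

#' Apply the laminar residence-time kernel to a plug-flow effluent series
#'
#' Replaces ideal plug transport through the shared segment by laminar
#' transport with a parabolic velocity profile and no radial mixing. The
#' kernel acts in cumulative-volume coordinate (so it generalizes to
#' time-varying flow): the plug effluent is first un-shifted by one tube
#' volume to recover the entry history, then convolved with the laminar
#' residence-volume distribution. A constant composition passes through
#' unchanged; a step becomes the [poiseuille_breakthrough()] curve.
#'
#' @param effluent a tibble with columns `time_h`, `volume_ml` (cumulative
#'   emitted volume, non-decreasing) and one numeric column per drug holding
#'   plug-flow effluent fractions.
#' @param tube_volume_ml shared segment volume (mL).
#' @param initial named per-drug fractions of the segment content before the
#'   series begins; defaults to the composition of the first row.
#' @return A tibble of the same shape with laminar-smeared fractions.
#' @export
apply_poiseuille_kernel <- function(effluent, tube_volume_ml, initial = NULL) {
  stopifnot_positive(tube_volume_ml = tube_volume_ml)
  need <- c("time_h", "volume_ml")
  if (!all(need %in% names(effluent))) {
    abort("`effluent` needs columns time_h and volume_ml.",
          class = "infusim_invalid_parameter")
  }
  if (any(diff(effluent$volume_ml) < -1e-12)) {
    warn("Cumulative volume decreases (flow reversal); plug transport is kept for the reversed interval.")
  }
  drugs <- setdiff(names(effluent), need)
  if (length(drugs) == 0) {
    abort("`effluent` has no drug fraction columns.",
          class = "infusim_invalid_parameter")
  }
  plug <- t(as.matrix(effluent[, drugs]))
  if (is.null(initial)) {
    initial <- setNames(plug[, 1], drugs)
  }
  cumv <- cummax(effluent$volume_ml)
  # entry history = plug effluent advanced by one tube volume
  entry_idx <- findInterval(pmin(cumv + tube_volume_ml, max(cumv)) * (1 - 1e-12),
                            cumv) + 1L
  entry_idx[entry_idx > ncol(plug)] <- ncol(plug)
  entry <- plug[, entry_idx, drop = FALSE]
  lam <- laminar_effluent(cumv, entry, as.numeric(initial[drugs]), tube_volume_ml)
  out <- effluent
  for (j in seq_along(drugs)) out[[drugs[j]]] <- lam[j, ]
  out
}
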