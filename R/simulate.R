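# End-to-end simulation: hydraulic transients + composition transport
# through the shared volume, producing per-drug delivered dose rates at the
# vascular access point.

#' Simulate drug delivery at the vascular access point
#'
#' Runs the transient hydraulic network to obtain each branch's actual flow
#' into the mixing point, advects the junction mixture through the shared
#' dead-volume + catheter slice chain (buffering any backflow in the
#' affected branch lines, last-in-first-out), and converts the effluent
#' composition into per-drug delivered dose rates. With
#' `kernel = "poiseuille"` the shared-segment transport additionally carries
#' the laminar residence-time distribution of a parabolic velocity profile;
#' `kernel = "plug"` gives ideal piston flow.
#'
#' @param network an [infusion_network()].
#' @param grid a [simulation_grid()]; `NULL` picks a grid automatically for
#'   the longest schedule in the network.
#' @param kernel `"poiseuille"` (default) or `"plug"`.
#' @param initial_mixture named per-drug fractions filling the shared volume
#'   at t = 0. Default: the steady mixture of the initial set flows (labels
#'   not infused by any branch may appear, e.g. a drug left over from a
#'   previous syringe).
#' @param compliance logical; `FALSE` forces rigid syringes (C = 0).
#' @return A `dose_sim` object: list with tibbles `dose` (`time_h`, `drug`,
#'   `set_rate_ml_h`, `delivered_rate_ml_h`), `flows` (per-branch set and
#'   actual flows), `junction` (`time_h`, `outflow_ml_h`,
#'   `junction_pressure_mbar`, `emitted_volume_ml`) and `effluent` (wide
#'   per-drug effluent fractions), plus the network, grid and kernel used.
#' @examples
#' sim <- simulate_delivery(builtin_case(2)$network, simulation_grid(0.3))
#' head(tidy(sim))
#' glance(sim)
#' @export
simulate_delivery <- function(network, grid = NULL, kernel = c("poiseuille", "plug"),
                              initial_mixture = NULL, compliance = TRUE) {
  kernel <- match.arg(kernel)
  if (!inherits(network, "infusion_network")) {
    abort("`network` must be an infusion_network.",
          class = "infusim_invalid_parameter")
  }
  if (is.null(grid)) {
    dur <- min(vapply(network$branches, function(b) b$schedule$duration_h, 0))
    grid <- simulation_grid(dur)
  }
  grid <- resolve_grid(grid, network)
  check_schedule_coverage(network, grid)

  core <- hydraulic_core(network, grid, compliance_on = compliance)
  nb <- length(core$branch)
  n_t <- length(core$times)
  dt <- core$dt

  branch_drugs <- core$drugs
  drugs <- unique(c(branch_drugs, names(initial_mixture)))
  nd <- length(drugs)
  # stock[, i] is the unit composition vector of branch i's syringe
  stock <- matrix(0, nd, nb)
  stock[cbind(match(branch_drugs, drugs), seq_len(nb))] <- 1

  init <- initial_fractions(core, drugs, initial_mixture)
  v_shared <- shared_volume(network)
  chain0 <- slice_chain(v_shared, setNames(init, drugs), grid$slice_volume_ml)
  # chain state kept in local vectors so column writes happen in place
  # (an environment- or list-held matrix would be copied on every push)
  n0 <- length(chain0$volumes_ml)
  cap <- n0 + n_t + 16L
  ch_vol <- numeric(cap)
  ch_frac <- matrix(0, nd, cap)
  ch_vol[seq_len(n0)] <- chain0$volumes_ml
  ch_frac[, seq_len(n0)] <- chain0$fractions
  ch_lo <- 1L
  ch_hi <- n0
  buffers <- lapply(seq_len(nb), function(i) new_stack(nd))
  line_vols <- vapply(network$branches, function(b) tube_volume(b$line), 0)
  overflow_warned <- logical(nb)

  eff <- matrix(0, nd, n_t)   # plug effluent fractions
  entry <- matrix(0, nd, n_t) # junction mixture entering the chain
  eff[, 1] <- init
  entry[, 1] <- init
  emitted <- numeric(n_t)

  for (k in 2:n_t) {
    dv <- core$Q[k, ] * dt
    dv_out <- sum(dv)
    if (dv_out < -1e-12 * max(1, max(abs(dv)))) {
      abort(sprintf(
        "Net aspiration at t = %g h (outflow %g mL/h) is not a supported regime.",
        core$times[k], dv_out / dt), class = "infusim_unsupported_regime")
    }
    pos <- which(dv > 0)
    neg <- which(dv < 0)
    if (length(pos) == 0L || dv_out <= 0) {
      # nothing moves through the catheter this step
      eff[, k] <- eff[, k - 1L]
      entry[, k] <- entry[, k - 1L]
      emitted[k] <- emitted[k - 1L]
      next
    }
    # junction mixture from forward-flowing branches: buffered (previously
    # backflowed) mixture re-enters before fresh stock solution
    mix <- numeric(nd)
    for (i in pos) {
      want <- dv[i]
      got <- st_draw(buffers[[i]], want)
      if (got$volume_ml > 0) mix <- mix + got$volume_ml * got$fractions
      fresh <- want - got$volume_ml
      if (fresh > 0) mix <- mix + fresh * stock[, i]
    }
    v_in <- sum(dv[pos])
    mix <- mix / v_in
    # backflow: junction mixture pressed into the reversed branch lines
    for (i in neg) {
      st_push(buffers[[i]], -dv[i], mix)
      if (!overflow_warned[i] && st_total(buffers[[i]]) > line_vols[i]) {
        overflow_warned[i] <- TRUE
        warn(sprintf(
          "Backflow into branch \"%s\" exceeds its line volume (%.3g mL); excess displaces fluid toward the syringe.",
          core$branch[i], line_vols[i]))
      }
    }
    # push the mixture onto the proximal end, emit dv_out from the distal end
    ch_hi <- ch_hi + 1L
    if (ch_hi > cap) {
      ch_vol <- c(ch_vol, numeric(cap))
      ch_frac <- cbind(ch_frac, matrix(0, nd, cap))
      cap <- 2L * cap
    }
    ch_vol[ch_hi] <- dv_out
    ch_frac[, ch_hi] <- mix
    acc <- numeric(nd)
    remaining <- dv_out
    while (remaining > 0 && ch_lo <= ch_hi) {
      v <- ch_vol[ch_lo]
      if (v <= remaining) {
        acc <- acc + v * ch_frac[, ch_lo]
        remaining <- remaining - v
        ch_lo <- ch_lo + 1L
      } else {
        acc <- acc + remaining * ch_frac[, ch_lo]
        ch_vol[ch_lo] <- v - remaining
        remaining <- 0
      }
    }
    eff[, k] <- acc / dv_out
    entry[, k] <- mix
    emitted[k] <- emitted[k - 1L] + dv_out
  }

  if (kernel == "poiseuille") {
    lam <- laminar_effluent(emitted, entry, init, v_shared)
    frac_out <- lam
  } else {
    frac_out <- eff
  }

  set_rate <- matrix(0, nd, n_t)
  for (i in seq_len(nb)) {
    j <- match(branch_drugs[i], drugs)
    set_rate[j, ] <- set_rate[j, ] + core$qset[, i]
  }
  delivered <- sweep(frac_out, 2, core$q_out, "*")

  dose <- tibble(
    time_h = rep(core$times, each = nd),
    drug = rep(drugs, n_t),
    set_rate_ml_h = as.numeric(set_rate),
    delivered_rate_ml_h = as.numeric(delivered)
  )
  flows <- tibble(
    time_h = rep(core$times, nb),
    branch = rep(core$branch, each = n_t),
    drug = rep(branch_drugs, each = n_t),
    set_flow_ml_h = as.numeric(core$qset),
    actual_flow_ml_h = as.numeric(core$Q)
  )
  junction <- tibble(
    time_h = core$times,
    outflow_ml_h = core$q_out,
    junction_pressure_mbar = core$PJ,
    emitted_volume_ml = emitted
  )
  effluent <- as_tibble(c(
    list(time_h = core$times, volume_ml = emitted),
    setNames(lapply(seq_len(nd), function(j) eff[j, ]), drugs)
  ))

  structure(
    list(dose = dose, flows = flows, junction = junction, effluent = effluent,
         network = network, grid = grid, kernel = kernel,
         initial_mixture = setNames(init, drugs), compliance = compliance),
    class = "dose_sim"
  )
}

initial_fractions <- function(core, drugs, initial_mixture) {
  nd <- length(drugs)
  if (!is.null(initial_mixture)) {
    check_fractions(initial_mixture)
    f <- setNames(numeric(nd), drugs)
    f[names(initial_mixture)] <- as.numeric(initial_mixture)
    return(as.numeric(f))
  }
  q0 <- core$qset[1L, ]
  f <- setNames(numeric(nd), drugs)
  if (sum(q0) > 0) {
    for (i in seq_along(q0)) f[core$drugs[i]] <- f[core$drugs[i]] + q0[i]
  } else {
    f[unique(core$drugs)] <- 1
  }
  as.numeric(f / sum(f))
}

#' @export
print.dose_sim <- function(x, ...) {
  cat(sprintf("<dose_sim> %s kernel, %d drug(s), %d pump(s), %g h @ dt = %g h\n",
              x$kernel, length(unique(x$dose$drug)),
              length(x$network$branches), x$grid$duration_h, x$grid$dt_h))
  print(glance(x))
  invisible(x)
}
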