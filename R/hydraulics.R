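# Transient pressure/flow solver for the N-branch compliance-resistance
# network. Each branch is an ideal flow source (the pump) feeding a lumped
# compliance C at pressure P_i, connected through its line resistance R_i to
# the junction (mixing point); the junction drains through the catheter
# resistance R_c to the venous pressure. The junction itself stores no
# volume, so its pressure is algebraic:
#   sum_i (P_i - P_j)/R_i = (P_j - P_v)/R_c
# and the branch pressures obey C_i dP_i/dt = Q_set,i - (P_i - P_j)/R_i.
# Rigid branches (C = 0) are solved algebraically: they deliver their set
# flow instantly.

#' Branch pressure state
#'
#' @param pressures_mbar numeric vector of branch pressures (one per branch).
#' @param time_h simulation time the state refers to.
#' @return A `pressure_state` object.
#' @export
pressure_state <- function(pressures_mbar, time_h = 0) {
  if (any(!is.finite(pressures_mbar))) {
    abort("Branch pressures must be finite.", class = "infusim_invalid_parameter")
  }
  structure(list(pressures_mbar = pressures_mbar, time_h = time_h),
            class = "pressure_state")
}

#' Steady-state pressures for a network
#'
#' Solves the network at the set flows in force at `time_h`: every branch
#' delivers its set flow, so the junction pressure is
#' `P_v + R_c * sum(Q_set)` and each branch pressure sits one resistive drop
#' above it.
#'
#' @param network an [infusion_network()].
#' @param time_h time at which to read the schedules (default 0).
#' @return A [pressure_state()].
#' @export
steady_state <- function(network, time_h = 0) {
  qset <- vapply(network$branches, function(b) set_flow_at(b$schedule, time_h), 0)
  p <- branch_params(network)
  pj <- network$venous_pressure_mbar +
    network$catheter$resistance_mbar_h_ml * sum(qset)
  pressure_state(pj + qset * p$R, time_h)
}

#' Junction (mixing point) pressure
#'
#' Flow balance at the zero-volume junction node: inflow from every branch
#' equals outflow through the catheter. Compliant branches contribute through
#' their pressures; rigid branches (C = 0) inject their set flow directly.
#'
#' @param state a [pressure_state()].
#' @param network an [infusion_network()].
#' @return junction pressure in mbar.
#' @export
junction_pressure <- function(state, network) {
  p <- branch_params(network)
  qset <- vapply(network$branches,
                 function(b) set_flow_at(b$schedule, state$time_h), 0)
  g <- 1 / p$R
  g_c <- 1 / network$catheter$resistance_mbar_h_ml
  compliant <- p$C > 0
  G <- sum(g[compliant]) + g_c
  if (!is.finite(G) || G <= 0) {
    abort("Singular network: no finite conductance at the junction.",
          class = "infusim_singular_network")
  }
  (sum(g[compliant] * state$pressures_mbar[compliant]) +
      sum(qset[!compliant]) +
      g_c * network$venous_pressure_mbar) / G
}

# Implicit-Euler update matrices for one piecewise-constant schedule segment.
# Returns A, b such that P_S' = A %*% P_S + b for the compliant subset S.
segment_stepper <- function(R, C, qset, r_cath, p_ven, dt) {
  g <- 1 / R
  g_c <- 1 / r_cath
  S <- which(C > 0)
  if (length(S) == 0L) return(NULL)
  gS <- g[S]
  G <- sum(gS) + g_c
  q0 <- sum(qset[-S])  # rigid branches inject set flow directly
  M <- -outer(gS, gS) / G
  diag(M) <- C[S] / dt + gS - gS^2 / G
  Minv <- solve(M)
  list(
    A = Minv %*% diag(C[S] / dt, nrow = length(S)),
    b = as.numeric(Minv %*% (qset[S] + gS * (q0 + g_c * p_ven) / G)),
    S = S, gS = gS, G = G, q0 = q0, g_c = g_c
  )
}

#' Advance branch pressures by one time step
#'
#' One implicit (backward) Euler step of the branch-pressure ODE
#' `C_i dP_i/dt = Q_set,i - (P_i - P_j)/R_i`, with the junction pressure
#' eliminated algebraically. Implicit Euler is unconditionally stable, which
#' matters for thin-catheter setups where a small compliance meets a very
#' large resistance (a stiff system). Rigid branches are pinned at
#' `P_j + Q_set * R` after the step.
#'
#' @param state a [pressure_state()].
#' @param network an [infusion_network()].
#' @param dt_h time step in hours.
#' @return A [pressure_state()] at `time_h + dt_h`.
#' @export
step_pressures <- function(state, network, dt_h) {
  stopifnot_positive(dt_h = dt_h)
  p <- branch_params(network)
  # implicit scheme: the step is driven by the schedule at its end point
  qset <- vapply(network$branches,
                 function(b) set_flow_at(b$schedule, state$time_h + dt_h), 0)
  stp <- segment_stepper(p$R, p$C, qset,
                         network$catheter$resistance_mbar_h_ml,
                         network$venous_pressure_mbar, dt_h)
  pres <- state$pressures_mbar
  if (!is.null(stp)) {
    pres[stp$S] <- as.numeric(stp$A %*% pres[stp$S] + stp$b)
  }
  if (any(!is.finite(pres))) {
    abort(sprintf(
      "Pressure update diverged; reduce the time step (try dt <= %g h).",
      dt_h / 10), class = "infusim_step_size_error")
  }
  new_state <- pressure_state(pres, state$time_h + dt_h)
  pj <- junction_pressure(new_state, network)
  rigid <- p$C <= 0
  pres[rigid] <- pj + qset[rigid] * p$R[rigid]
  pressure_state(pres, state$time_h + dt_h)
}

# Full hydraulic trajectory on a resolved grid. Returns matrices indexed
# [time, branch]: set flows, actual branch flows into the junction, plus the
# junction pressure, outflow and branch pressures. Flows at row k are the
# flows over step k-1 -> k evaluated at the step end (implicit convention);
# row 1 holds the initial steady state.
hydraulic_core <- function(network, grid, compliance_on = TRUE,
                           cold_start = FALSE) {
  p <- branch_params(network)
  C <- if (compliance_on) p$C else rep(0, length(p$C))
  R <- p$R
  r_c <- network$catheter$resistance_mbar_h_ml
  p_v <- network$venous_pressure_mbar
  dt <- grid$dt_h
  n_steps <- max(1L, as.integer(round(grid$duration_h / dt)))
  times <- seq(0, by = dt, length.out = n_steps + 1L)
  nb <- length(R)

  # schedule evaluated on the grid (value governing the step starting there)
  qset_mat <- vapply(network$branches,
                     function(b) set_flow_at(b$schedule, times), numeric(n_steps + 1L))
  qset_mat <- matrix(qset_mat, nrow = n_steps + 1L)

  # initial state
  if (cold_start) {
    pres <- rep(p_v, nb)
  } else {
    pj0 <- p_v + r_c * sum(qset_mat[1L, ])
    pres <- pj0 + qset_mat[1L, ] * R
  }

  g <- 1 / R
  g_c <- 1 / r_c
  compliant <- C > 0
  S <- which(compliant)

  Q <- matrix(0, n_steps + 1L, nb)
  P <- matrix(0, n_steps + 1L, nb)
  PJ <- numeric(n_steps + 1L)

  pj_of <- function(pres, qset) {
    G <- sum(g[S]) + g_c
    (sum(g[S] * pres[S]) + sum(qset[!compliant]) + g_c * p_v) / G
  }
  flows_of <- function(pres, qset) {
    pj <- pj_of(pres, qset)
    q <- qset
    q[S] <- g[S] * (pres[S] - pj)
    list(q = q, pj = pj)
  }

  if (cold_start && length(S) > 0L) {
    # rigid branches still deliver set flow; compliant start at venous pressure
    fl <- flows_of(pres, qset_mat[1L, ])
  } else {
    fl <- flows_of(pres, qset_mat[1L, ])
  }
  Q[1L, ] <- fl$q; PJ[1L] <- fl$pj
  pres[!compliant] <- fl$pj + qset_mat[1L, !compliant] * R[!compliant]
  P[1L, ] <- pres

  # segment boundaries: steps sharing identical set-flow vectors share a
  # precomputed update matrix. The step from t_k to t_{k+1} is driven by the
  # schedule at t_{k+1} (the implicit-Euler evaluation point), so reported
  # set and actual flows refer to the same instant.
  seg_id <- cumsum(c(TRUE, rowSums(abs(diff(qset_mat))) > 0))
  stepper <- NULL
  cur_seg <- -1L
  for (k in seq_len(n_steps)) {
    qset <- qset_mat[k + 1L, ]
    if (length(S) > 0L) {
      if (seg_id[k + 1L] != cur_seg) {
        stepper <- segment_stepper(R, C, qset, r_c, p_v, dt)
        cur_seg <- seg_id[k + 1L]
      }
      pres[S] <- as.numeric(stepper$A %*% pres[S] + stepper$b)
      if (any(!is.finite(pres[S]))) {
        abort(sprintf(
          "Pressure update diverged at t = %g h; reduce the time step (try dt <= %g h).",
          times[k], dt / 10), class = "infusim_step_size_error")
      }
    }
    fl <- flows_of(pres, qset)
    Q[k + 1L, ] <- fl$q
    PJ[k + 1L] <- fl$pj
    pres[!compliant] <- fl$pj + qset[!compliant] * R[!compliant]
    P[k + 1L, ] <- pres
  }

  q_out <- rowSums(Q)
  list(times = times, qset = qset_mat, Q = Q, P = P, PJ = PJ, q_out = q_out,
       dt = dt, drugs = p$drug, branch = names(network$branches))
}

#' Solve branch flows over time
#'
#' Runs the transient hydraulic network over the simulation grid and returns
#' a tidy per-branch flow series. The actual flow a branch pushes into the
#' mixing point deviates from its set flow while the syringe compliances
#' charge or discharge after a set-flow change, and can be transiently
#' negative (backflow into that line). At every time point the branch flows
#' sum exactly to the catheter outflow: the junction stores no volume.
#'
#' @param network an [infusion_network()].
#' @param grid a [simulation_grid()].
#' @param compliance logical; `FALSE` forces all compliances to zero (rigid
#'   idealization, flows equal set flows exactly).
#' @return A tibble with columns `time_h`, `branch`, `drug`,
#'   `set_flow_ml_h`, `actual_flow_ml_h`. The catheter outflow and junction
#'   pressure are attached as the `"junction"` attribute (a tibble with
#'   `time_h`, `outflow_ml_h`, `junction_pressure_mbar`).
#' @examples
#' net <- builtin_case(4)$network
#' fl <- solve_flows(net, simulation_grid(0.2))
#' head(fl)
#' @export
solve_flows <- function(network, grid, compliance = TRUE) {
  grid <- resolve_grid(grid, network)
  check_schedule_coverage(network, grid)
  core <- hydraulic_core(network, grid, compliance_on = compliance)
  nb <- length(core$branch)
  out <- tibble(
    time_h = rep(core$times, nb),
    branch = rep(core$branch, each = length(core$times)),
    drug = rep(core$drugs, each = length(core$times)),
    set_flow_ml_h = as.numeric(core$qset),
    actual_flow_ml_h = as.numeric(core$Q)
  )
  attr(out, "junction") <- tibble(
    time_h = core$times,
    outflow_ml_h = core$q_out,
    junction_pressure_mbar = core$PJ
  )
  out
}

check_schedule_coverage <- function(network, grid) {
  for (nm in names(network$branches)) {
    b <- network$branches[[nm]]
    if (b$schedule$duration_h < grid$duration_h - 1e-12) {
      abort(sprintf(
        "Schedule of branch \"%s\" (%g h) does not cover the grid duration (%g h).",
        nm, b$schedule$duration_h, grid$duration_h),
        class = "infusim_invalid_parameter")
    }
  }
  invisible(TRUE)
}
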