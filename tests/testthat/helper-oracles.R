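# Independent oracles used across the suite. These deliberately avoid the
# package's own formulas: resistance is rebuilt by dimensional analysis in
# SI, the laminar washout by radial integration of the velocity profile, and
# the push-out excess by volume bookkeeping.

# Hagen-Poiseuille resistance assembled unit by unit in SI, then converted.
oracle_resistance_mbar_h_ml <- function(length_m, diameter_mm, viscosity_mpas) {
  mu_pas <- viscosity_mpas / 1000
  d_m <- diameter_mm / 1000
  r_si <- 128 * mu_pas * length_m / (pi * d_m^4)  # Pa per (m^3/s)
  pa_per_mbar <- 100
  m3s_per_mlh <- 1e-6 / 3600
  (r_si / pa_per_mbar) * m3s_per_mlh
}

# Laminar washout fraction by radial integration: fluid at radius r moves at
# v(r) = 2*vbar*(1 - (r/R)^2); new fluid is present in the effluent where
# v(r)*t >= L. The threshold radius is found numerically and the
# flow-weighted fraction integrated with Simpson's rule.
oracle_breakthrough <- function(tube_volume_ml, flow_ml_h, t_h, n = 20001L) {
  # work in reduced coordinates: R = 1, L/vbar = tau
  tau <- tube_volume_ml / flow_ml_h
  v <- function(rho) 2 * (1 - rho^2)          # velocity / vbar
  if (t_h <= 0 || v(0) * t_h < tau) return(0)
  # largest rho still arriving by t: v(rho)*t = tau
  g <- function(rho) v(rho) * t_h - tau
  rho_star <- if (g(1) >= 0) 1 else stats::uniroot(g, c(0, 1), tol = 1e-14)$root
  # flow through r < rho*: integral of v(rho)*2*rho drho / integral over all
  rho <- seq(0, rho_star, length.out = n)
  integrand <- v(rho) * 2 * rho
  h <- rho[2] - rho[1]
  simpson <- (h / 3) * (integrand[1] + integrand[n] +
                          4 * sum(integrand[seq(2, n - 1, by = 2)]) +
                          2 * sum(integrand[seq(3, n - 2, by = 2)]))
  simpson  # total flow-weighted fraction is 1 by construction
}

# Push-out excess volume delivered of a non-stepped drug after a set-flow
# change, for rigid syringes and plug transport.
oracle_pushout_excess <- function(shared_volume_ml, f_old, f_new) {
  shared_volume_ml * (f_old - f_new)
}

# Closed-form single-branch RC step response of the flow into the patient.
oracle_rc_response <- function(t_h, q_old, q_new, compliance, r_branch, r_cath) {
  tau <- compliance * (r_branch + r_cath)
  q_old + (q_new - q_old) * (1 - exp(-t_h / tau))
}

# small two-pump rigid network used by several tests
make_two_pump_network <- function(q_a = c(10, 20), q_b = 1, t_change = 0.1,
                                  duration = 0.6, compliance = 0.002,
                                  catheter = "Careflow 7Fr",
                                  dead_volume = 0.5) {
  catalog <- component_catalog()
  line <- catalog_lookup("Standard line 1m", catalog)
  syr <- syringe_spec("syringe", 50, compliance)
  infusion_network(
    list(
      pump_A = pump_branch("drug_A", syr, line,
                           flow_schedule(c(0, t_change), q_a, duration_h = duration)),
      pump_B = pump_branch("drug_B", syr, line,
                           constant_flow(q_b, duration_h = duration))
    ),
    mixing_point_spec("manifold", dead_volume),
    catalog_lookup(catheter, catalog)
  )
}
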