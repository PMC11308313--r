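test_that("slice chains are built with consistent volumes and fractions", {
  ch <- slice_chain(0.5, c(A = 0.8, B = 0.2), 0.05)
  expect_equal(sum(ch$volumes_ml), 0.5, tolerance = 1e-12)
  expect_true(all(abs(colSums(ch$fractions) - 1) < 1e-12))
  expect_error(slice_chain(0.5, c(A = 0.5, B = 0.2)),  # fractions must sum to 1
               class = "infusim_invalid_parameter")
  expect_error(slice_chain(0.5, c(0.5, 0.5)),          # names required
               class = "infusim_invalid_parameter")
})

test_that("advect conserves volume and passes a steady mixture unchanged", {
  ch <- slice_chain(0.5, c(A = 0.7, B = 0.3), 0.02)
  for (i in 1:30) {
    out <- advect(ch, c(A = 7, B = 3), outflow_ml_h = 10, dt_h = 0.005)
    ch <- out$chain
    expect_equal(unname(out$effluent), c(0.7, 0.3), tolerance = 1e-12)
    expect_equal(sum(ch$volumes_ml), 0.5, tolerance = 1e-12)
  }
})

test_that("a composition step leaves only after the dead volume is flushed", {
  v_d <- 0.4
  ch <- slice_chain(v_d, c(old = 1, new = 0), 0.02)
  dt <- 0.002
  q <- 12
  emitted <- 0
  repeat {
    out <- advect(ch, c(new = q, old = 0), outflow_ml_h = q, dt_h = dt)
    ch <- out$chain
    prev <- emitted
    emitted <- emitted + out$volume_ml
    if (emitted < v_d - 1e-9) {
      expect_equal(unname(out$effluent["old"]), 1, tolerance = 1e-12)
    }
    if (prev > v_d + 1e-9) {
      expect_equal(unname(out$effluent["new"]), 1, tolerance = 1e-12)
      break
    }
  }
})

test_that("advect validates its flow-balance contract", {
  ch <- slice_chain(0.5, c(A = 1), 0.05)
  expect_error(advect(ch, c(A = 5), outflow_ml_h = 4, dt_h = 0.01),
               class = "infusim_invalid_parameter")   # junction imbalance
  expect_error(advect(ch, c(A = -1), outflow_ml_h = -1, dt_h = 0.01),
               class = "infusim_unsupported_regime")  # net aspiration
  expect_error(advect(ch, c(Z = 1), outflow_ml_h = 1, dt_h = 0.01),
               class = "infusim_invalid_parameter")   # unknown drug
})

test_that("backflow buffers are last-in-first-out and reversible", {
  buf <- line_buffer(c("A", "B"))
  expect_identical(handle_backflow(buf, 0, c(A = 1, B = 0)), buf)  # no-op
  buf <- handle_backflow(buf, 0.10, c(A = 0.9, B = 0.1))
  buf <- handle_backflow(buf, 0.05, c(A = 0.2, B = 0.8))
  # drawing 0.05 returns the last mixture pushed, untouched
  out <- draw_backflow(buf, 0.05)
  expect_equal(out$volume_ml, 0.05)
  expect_equal(unname(out$fractions), c(0.2, 0.8), tolerance = 1e-12)
  # the remainder is the first mixture
  out2 <- draw_backflow(out$buffer, 0.2)
  expect_equal(out2$volume_ml, 0.10)  # only what the buffer held
  expect_equal(unname(out2$fractions), c(0.9, 0.1), tolerance = 1e-12)
  # overflowing the line volume warns
  expect_warning(
    handle_backflow(line_buffer("A"), 1.0, c(A = 1), line_volume_ml = 0.5),
    "exceeds"
  )
})

test_that("laminar breakthrough matches the radial-annuli oracle", {
  v <- 3; q <- 6
  tau <- v / q
  # nothing arrives before half the mean transit time
  expect_equal(poiseuille_breakthrough(v, q, tau / 2 - 1e-9), 0)
  expect_equal(poiseuille_breakthrough(v, q, tau), 0.75, tolerance = 1e-12)
  ts <- seq(0.05, 5 * tau, length.out = 20)
  got <- poiseuille_breakthrough(v, q, ts)
  want <- vapply(ts, function(t) oracle_breakthrough(v, q, t), 0)
  expect_equal(got, want, tolerance = 1e-6)
  # monotone, complete washout in the long run
  expect_true(all(diff(got) >= 0))
  expect_equal(poiseuille_breakthrough(v, q, 1e6), 1, tolerance = 1e-9)
  expect_error(poiseuille_breakthrough(v, -1, 1),
               class = "infusim_invalid_parameter")
})

test_that("centerline fluid travels at twice the mean velocity", {
  # first arrival is exactly half the mean transit time for any V, Q
  set.seed(5)
  for (i in 1:10) {
    v <- stats::runif(1, 0.5, 5)
    q <- stats::runif(1, 1, 30)
    expect_equal(first_arrival_time(v, q), (v / q) / 2, tolerance = 1e-12)
  }
  expect_equal(first_arrival_time(3, 6), 0.25)       # 15 min
  expect_equal(3 / 6, 0.5)                            # mean transit 0.5 h
  expect_equal(first_arrival_time(0, 6), 0)           # degenerate tube
  expect_error(first_arrival_time(3, 0), class = "infusim_invalid_parameter")
})

test_that("the laminar kernel conserves a constant composition", {
  n <- 400
  eff <- tibble::tibble(
    time_h = seq(0, 1, length.out = n),
    volume_ml = seq(0, 8, length.out = n),
    A = rep(0.6, n), B = rep(0.4, n)
  )
  out <- apply_poiseuille_kernel(eff, tube_volume_ml = 1)
  expect_equal(out$A, rep(0.6, n), tolerance = 1e-9)
  expect_equal(out$B, rep(0.4, n), tolerance = 1e-9)
})

test_that("a step through the laminar kernel reproduces the washout curve", {
  v_t <- 1
  q <- 10
  n <- 2000
  t <- seq(0, 2, length.out = n)
  vol <- q * t
  # plug effluent of an entry step at t = 0: switches when one tube volume
  # has been emitted
  eff <- tibble::tibble(time_h = t, volume_ml = vol,
                        new = as.numeric(vol >= v_t),
                        old = as.numeric(vol < v_t))
  out <- apply_poiseuille_kernel(eff, v_t, initial = c(new = 0, old = 1))
  want <- poiseuille_breakthrough(v_t, q, t)
  expect_lt(max(abs(out$new - want)), 0.01)
  # mean residence time of the smeared front equals V/Q
  dF <- diff(out$new)
  t_mid <- (t[-1] + t[-n]) / 2
  mean_delay <- sum(t_mid * dF) / sum(dF)
  # the analytic RTD mean is V/Q; the simulated series truncates the t^-2
  # tail at 2 h, which removes V/Q * (tau/2)/t_max of the mean
  tau <- v_t / q
  want_mean <- tau * (1 - tau / 2 / 2)
  expect_equal(mean_delay, want_mean, tolerance = 0.02)
})

test_that("push-out excess volume matches the closed form", {
  # Q_A steps 10 -> 20 mL/h with Q_B = 1 mL/h through a 0.5 mL dead volume,
  # rigid syringes, plug transport: excess drug-B volume = V (f_old - f_new)
  t_change <- 0.1
  net <- make_two_pump_network(q_a = c(10, 20), q_b = 1, t_change = t_change,
                               duration = 0.6, compliance = 0)
  v_shared <- shared_volume(net)
  sim <- simulate_delivery(net, simulation_grid(0.6), kernel = "plug")
  dev <- deviation(sim)
  got <- integrate_error(dplyr::filter(dev, drug == "drug_B"),
                         window = c(t_change, 0.6))$signed_ml
  want <- oracle_pushout_excess(v_shared, 1 / 11, 1 / 21)
  tol <- max(sim$grid$slice_volume_ml,
             sim$grid$dt_h * 21)  # one slice / one step volume
  expect_lt(abs(got - want), tol)
  expect_equal(got, 0.5216 * (1 / 11 - 1 / 21), tolerance = 0.05)
})

test_that("every drug's emitted volume equals its injected volume after washout", {
  for (seed in c(2, 9)) {
    sc <- generate_fixture(seed, n_pumps = 3, rigid = TRUE,
                           flow_range = c(3, 12))
    sim <- simulate_scenario(sc, kernel = "plug")
    dose <- sim$dose
    dt <- diff(sim$junction$time_h[1:2])
    totals <- dose |>
      dplyr::group_by(drug) |>
      dplyr::summarise(
        emitted = sum(delivered_rate_ml_h) * dt,
        injected = sum(set_rate_ml_h) * dt,
        .groups = "drop"
      )
    # initial shared-volume content distorts the balance by at most the
    # shared volume itself; compare after subtracting the start-up content
    v_shared <- shared_volume(sc$network)
    expect_true(all(abs(totals$emitted - totals$injected) < v_shared + 1e-6))
    # total volume is conserved to high precision
    expect_equal(sum(totals$emitted), sum(totals$injected), tolerance = 1e-6)
  }
})

test_that("refining the grid leaves delivered-dose curves unchanged to first order", {
  net <- make_two_pump_network(q_a = c(6, 12), q_b = 2, t_change = 0.05,
                               duration = 0.3, compliance = 0.001,
                               catheter = "Premicath 1Fr")
  coarse <- simulate_delivery(net, simulation_grid(0.3, dt_h = 4e-4,
                                                   slice_volume_ml = 8e-3))
  fine <- simulate_delivery(net, simulation_grid(0.3, dt_h = 2e-4,
                                                 slice_volume_ml = 4e-3))
  b_coarse <- dplyr::filter(coarse$dose, drug == "drug_B")
  b_fine <- dplyr::filter(fine$dose, drug == "drug_B")
  interp <- stats::approx(b_fine$time_h, b_fine$delivered_rate_ml_h,
                          xout = b_coarse$time_h, rule = 2)$y
  # halving the grid moves the curve by at most one coarse step along its
  # steepest stretch (a front-position error of order dt)
  slope_max <- max(abs(diff(b_coarse$delivered_rate_ml_h))) / 4e-4
  expect_lt(max(abs(b_coarse$delivered_rate_ml_h - interp)),
            max(2 * slope_max * 4e-4, 0.01))
  # integrated dose differs by far less than a slice volume
  dtc <- diff(b_coarse$time_h[1:2])
  expect_lt(abs(sum(b_coarse$delivered_rate_ml_h - interp) * dtc), 8e-3)
})
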