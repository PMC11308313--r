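test_that("built-in cases are wired as described", {
  c1 <- builtin_case(1)
  expect_length(c1$network$branches, 1)
  expect_equal(shared_volume(c1$network), 3, tolerance = 1e-12)
  expect_equal(first_arrival_time(shared_volume(c1$network), 6), 0.25)
  expect_equal(names(c1$initial_mixture), "drug_old")

  c2 <- builtin_case(2); c3 <- builtin_case(3); c4 <- builtin_case(4)
  # cases 2 and 3 differ only in the direction of the pump-A change
  ev2 <- c2$network$branches$pump_A$schedule$events$set_flow_ml_h
  ev3 <- c3$network$branches$pump_A$schedule$events$set_flow_ml_h
  expect_equal(ev2, rev(ev3))
  expect_equal(c2$network$catheter$name, c3$network$catheter$name)
  # case 4 is case 2 with the catheter swapped to the thin 1 Fr
  expect_equal(c4$network$branches$pump_A$schedule$events,
               c2$network$branches$pump_A$schedule$events)
  expect_equal(c4$network$catheter$french_size, 1)
  expect_equal(c2$network$catheter$french_size, 7)

  expect_error(builtin_case(5), class = "infusim_unknown_case")
})

test_that("fixtures are reproducible and leave the RNG state alone", {
  a <- generate_fixture(123)
  b <- generate_fixture(123)
  expect_equal(a, b)
  set.seed(99)
  before <- stats::runif(1)
  set.seed(99)
  invisible(generate_fixture(7))
  expect_identical(stats::runif(1), before)
  # generated scenarios satisfy the network invariants
  for (seed in 1:5) {
    sc <- generate_fixture(seed)
    expect_s3_class(sc$network, "infusion_network")
    for (br in sc$network$branches) {
      expect_gte(br$syringe$compliance_ml_mbar, 0)
      expect_gt(br$line_resistance_mbar_h_ml, 0)
      expect_true(all(br$schedule$events$set_flow_ml_h >= 0))
    }
  }
  expect_error(generate_fixture(1, n_pumps = 9),
               class = "infusim_invalid_parameter")
})

test_that("rigid plug fixtures reproduce the push-out closed form", {
  sc <- generate_fixture(57, n_pumps = 2, rigid = TRUE, flow_range = c(3, 12))
  sim <- simulate_scenario(sc, kernel = "plug")
  t_change <- sc$network$branches$pump_A$schedule$events$time_h[2]
  q_old <- vapply(sc$network$branches,
                  function(b) set_flow_at(b$schedule, 0), 0)
  q_new <- vapply(sc$network$branches,
                  function(b) set_flow_at(b$schedule, t_change), 0)
  f_old <- q_old / sum(q_old)
  f_new <- q_new / sum(q_new)
  dev <- deviation(sim) |> dplyr::filter(drug == "drug_2")
  got <- integrate_error(dev, window = c(t_change, sc$grid$duration_h))$signed_ml
  want <- oracle_pushout_excess(shared_volume(sc$network), f_old[2], f_new[2])
  expect_lt(abs(got - want), sim$grid$slice_volume_ml + 1e-4)
})

test_that("scenario files round-trip through the YAML reader", {
  path <- system.file("extdata", "case2_scenario.yaml", package = "infusim")
  sc <- read_scenario(path)
  ref <- builtin_case(2)
  expect_equal(sc$network$catheter$resistance_mbar_h_ml,
               ref$network$catheter$resistance_mbar_h_ml, tolerance = 1e-12)
  expect_equal(sc$network$branches[[1]]$schedule$events,
               ref$network$branches$pump_A$schedule$events)
  expect_equal(shared_volume(sc$network), shared_volume(ref$network))
  # and it simulates to the same delivered doses
  sim_a <- simulate_scenario(sc)
  sim_b <- simulate_scenario(ref)
  expect_equal(sim_a$dose$delivered_rate_ml_h, sim_b$dose$delivered_rate_ml_h,
               tolerance = 1e-9)
})

test_that("run_scenario writes a complete, deterministic bundle", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  sc <- builtin_case(1)
  res <- run_scenario(sc, dir1)
  files <- c("flows.csv", "dose.csv", "decomposition.csv", "summary.json", "run.log")
  expect_true(all(file.exists(file.path(dir1, files))))
  expect_equal(res$summary$first_arrival_h, 0.25)
  expect_equal(res$summary$mean_transit_h, 0.5)
  # rerun is byte-identical (the core has no randomness)
  run_scenario(sc, dir2)
  for (f in files) {
    expect_identical(readLines(file.path(dir1, f)), readLines(file.path(dir2, f)))
  }
})

test_that("case 4 bundle flags the biphasic drug-B deviation", {
  dir <- withr::local_tempdir()
  res <- run_scenario(builtin_case(4), dir)
  expect_equal(res$summary$deviation_pattern$drug_B, "biphasic")
  js <- jsonlite::read_json(file.path(dir, "summary.json"))
  expect_equal(js$deviation_pattern$drug_B, "biphasic")
})

test_that("the command-line interface runs and signals failure properly", {
  root <- system.file(package = "infusim")
  # installed layout puts exec/ under the package root; a source load
  # resolves system.file() to inst/, with exec/ one level up
  exe <- Filter(file.exists, c(file.path(root, "exec", "infusim"),
                               file.path(root, "..", "exec", "infusim")))[1]
  expect_false(is.na(exe))
  rscript <- file.path(R.home("bin"), "Rscript")
  out <- system2(rscript, c(exe, "list-components"), stdout = TRUE, stderr = TRUE)
  expect_identical(attr(out, "status"), NULL)  # exit 0
  expect_true(any(grepl("Premicath 1Fr", out)))
  bad <- suppressWarnings(
    system2(rscript, c(exe, "run-case", "9"), stdout = TRUE, stderr = TRUE)
  )
  expect_identical(attr(bad, "status"), 1L)
})
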