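test_that("flux follows the P*A*(C1 - C2/Kp) law with a lag gate", {
  ifc <- interface("a", "b", P = 1, A = 1, Kp = 1, lag_time = 0)
  expect_equal(flux(ifc, 2, 0, 1), 2)
  # zero flux at partition equilibrium, any Kp
  ifc3 <- interface("a", "b", P = 2, A = 3, Kp = 3)
  expect_equal(flux(ifc3, 1.5, 4.5, 10), 0)
  # gate shut before the lag
  ifcl <- interface("a", "b", P = 1, A = 1, Kp = 1, lag_time = 1)
  expect_identical(flux(ifcl, 5, 0, 0.5), 0)
  expect_gt(flux(ifcl, 5, 0, 1.0), 0)
  expect_error(flux(ifc, -1, 0, 0), "concentrations")
  expect_error(flux(ifc, NaN, 0, 0), "finite")
})

test_that("build_rhs balances fluxes and conserves mass pointwise", {
  rhs <- build_rhs(two_comp_system())
  expect_equal(rhs(0, c(10, 0)), c(-10, 10))
  # isolated compartments have zero derivatives
  iso <- compartment_system(list(compartment("A", 1, 5), compartment("B", 2, 3)))
  expect_equal(build_rhs(iso)(1, c(5, 3)), c(0, 0))
  # derivatives of any closed chain sum to zero at arbitrary states
  sys <- random_chain_system(4, seed = 11)
  rhs4 <- build_rhs(sys)
  set.seed(1)
  for (k in 1:5)
    expect_equal(sum(rhs4(k / 2, stats::runif(4, 0, 10))), 0)
  expect_error(
    compartment_system(list(compartment("A", 1)),
                       list(interface("A", "Z", P = 1, A = 1))),
    "unknown compartment")
})

test_that("system construction rejects duplicates and reverse interfaces", {
  expect_error(
    compartment_system(list(compartment("A", 1), compartment("A", 2))),
    "unique")
  expect_error(
    compartment_system(
      list(compartment("A", 1), compartment("B", 1)),
      list(interface("A", "B", P = 1, A = 1),
           interface("B", "A", P = 1, A = 1))),
    "one interface per compartment pair")
})

test_that("two identical compartments equilibrate to half the load each", {
  res <- simulate_system(two_comp_system(), seq(0, 40, 1))
  expect_equal(unname(res$amounts[nrow(res$amounts), ]), c(5, 5),
               tolerance = 1e-8)
  # amounts at t = 0 equal initial amounts exactly
  expect_identical(unname(res$amounts[1, ]), c(10, 0))
})

test_that("simulation matches the closed-form solution of the 2x2 system", {
  res <- simulate_system(two_comp_system(), seq(0, 2, 0.05))
  diff_cf <- 10 * exp(-2 * res$times)
  diff_num <- res$amounts[, 1] - res$amounts[, 2]
  expect_lt(max(abs(diff_num - diff_cf)[-1] / diff_cf[-1]), 1e-6)
})

test_that("closed systems conserve total mass at every output time", {
  for (seed in 1:3) {
    n <- sample(3:5, 1)
    res <- simulate_system(random_chain_system(n, seed), seq(0, 20, 0.5))
    expect_lt(max(abs(rowSums(res$amounts) - 10)) / 10, 1e-6)
  }
})

test_that("steady-state concentration ratio equals the configured Kp", {
  for (Kp in c(0.25, 1, 4)) {
    res <- simulate_system(two_comp_system(V2 = 2, Kp = Kp), c(0, 50, 400))
    conc <- concentrations(res)
    expect_equal(unname(conc[3, 2] / conc[3, 1]), Kp, tolerance = 1e-3)
  }
})

test_that("integrator agrees with the matrix-exponential oracle", {
  skip_if_not_installed("Matrix")
  for (seed in c(2, 5, 9)) {
    n <- 3 + (seed %% 3)
    sys <- random_chain_system(n, seed)
    times <- seq(0, 10, 0.5)
    res <- simulate_system(sys, times)
    oracle <- expm_solution(sys, times)
    expect_lt(max(abs(res$amounts - oracle)) / 10, 1e-5)
  }
})

test_that("a lag on the only outgoing interface freezes everything downstream", {
  res <- simulate_system(two_comp_system(lag = 2), seq(0, 6, 0.25))
  expect_true(all(res$amounts[res$times <= 2, 2] <= 1e-10))
  expect_gt(res$amounts[res$times == 3, 2], 0)
  # amounts never dip below -atol before clipping
  expect_gt(res$min_raw_amount, -res$atol)
})

test_that("total_mass interpolates and range-checks", {
  res <- simulate_system(two_comp_system(), seq(0, 4, 0.5))
  expect_equal(total_mass(res, 0), 10)
  expect_equal(total_mass(res, 1.25), 10, tolerance = 1e-8)
  expect_error(total_mass(res, 5), "outside")
  single <- compartment_system(list(compartment("only", 2, 500)))
  ress <- simulate_system(single, c(0, 1, 2))
  expect_equal(unname(ress$amounts[, 1]), rep(500, 3))
})

test_that("system JSON serialization round-trips", {
  sys <- two_comp_system(V2 = 2, Kp = 3, lag = 1.5)
  path <- tempfile(fileext = ".json")
  system_to_json(sys, path)
  back <- system_from_json(path)
  expect_equal(back$compartments, sys$compartments)
  expect_equal(back$interfaces, sys$interfaces)
  expect_equal(back$closed, sys$closed)
  res1 <- simulate_system(sys, seq(0, 3, 0.5))
  res2 <- simulate_system(back, seq(0, 3, 0.5))
  expect_identical(res1$amounts, res2$amounts)
})

test_that("simulation results export to long-format CSV", {
  res <- simulate_system(two_comp_system(), c(0, 1, 2))
  path <- tempfile(fileext = ".csv")
  write_simulation_csv(res, path)
  df <- read.csv(path)
  expect_named(df, c("time_h", "compartment", "amount_ug",
                     "concentration_ug_mL"))
  expect_equal(nrow(df), 6)
  expect_equal(df$amount_ug[df$compartment == "A" & df$time_h == 0], 10)
})
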