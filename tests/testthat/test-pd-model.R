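test_that("the sigmoid Emax model honors its algebraic identities", {
  p <- emax_params(Emax = 10, EC50 = 3, E0 = 2, n = 1.7)
  expect_equal(emax_effect(p, 0), 2)
  expect_equal(emax_effect(p, 3), 2 + 5)          # half-maximal at EC50
  p1 <- emax_params(Emax = 10, EC50 = 1, E0 = 0, n = 1)
  expect_equal(emax_effect(p1, 9), 9)
  # E(EC50) - E0 = (E(inf) - E0)/2 for every n; the infinity limit is
  # approximated at a concentration giving c^n/EC50^n = 1e6
  for (n in c(0.5, 1, 2, 4)) {
    pn <- emax_params(Emax = -7, EC50 = 0.4, E0 = 20, n = n)
    half <- emax_effect(pn, 0.4) - 20
    sat <- emax_effect(pn, 0.4 * 10^(6 / n)) - 20
    expect_equal(half, sat / 2, tolerance = 1e-4)
  }
  expect_error(emax_effect(p, -1), ">= 0")
  expect_error(emax_params(Emax = 1, EC50 = 0, E0 = 0), "EC50")
})

test_that("the proportional-error likelihood matches closed forms", {
  p <- emax_params(Emax = -10, EC50 = 2, E0 = 100, n = 1)
  ex <- c(0, 1, 2, 4)
  f <- emax_effect(p, ex)
  rec <- data.frame(value = f, exposure_ug_mL = ex)
  b <- 0.2
  m <- length(ex)
  # zero residuals: only the normalization terms remain
  expect_equal(individual_neg2ll(rec, p, b),
               -2 * sum(log(1 / (sqrt(2 * pi) * b * f))))
  # doubling b at zero residual adds 2*m*log(2)
  expect_equal(individual_neg2ll(rec, p, 2 * b) - individual_neg2ll(rec, p, b),
               2 * m * log(2))
  # one-sigma observation adds exactly 1 to the quadratic term
  rec1 <- data.frame(value = f[2] * (1 + b), exposure_ug_mL = ex[2])
  expect_equal(individual_neg2ll(rec1, p, b),
               -2 * log(1 / (sqrt(2 * pi) * b * f[2])) + 1)
})

test_that("the likelihood matches a brute-force density product", {
  set.seed(8)
  for (k in 1:20) {
    p <- emax_params(Emax = stats::runif(1, -20, -1),
                     EC50 = stats::runif(1, 0.5, 5),
                     E0 = stats::runif(1, 50, 150),
                     n = stats::runif(1, 0.5, 3))
    ex <- sort(stats::runif(5, 0, 10))
    f <- emax_effect(p, ex)
    b <- stats::runif(1, 0.05, 0.3)
    y <- f * (1 + b * stats::rnorm(5))
    rec <- data.frame(value = y, exposure_ug_mL = ex)
    brute <- -2 * log(prod(stats::dnorm(y, f, b * f)))
    expect_equal(individual_neg2ll(rec, p, b), brute, tolerance = 1e-10)
  }
})

test_that("EBEs vanish for population-typical subjects and shrink with omega", {
  pop <- population_model(emax_params(Emax = -10, EC50 = 2, E0 = 100, n = 1),
                          omega2 = c(Emax = 0.09, EC50 = 0.09, E0 = 0.09),
                          b = 0.05, sigmoidicity = FALSE)
  ex <- c(0, 1, 2, 4, 8, 16)
  rec <- data.frame(value = emax_effect(pop$theta, ex), exposure_ug_mL = ex)
  e <- estimate_ebes(rec, pop)
  expect_lt(max(abs(e$eta)), 0.01)
  # omega -> 0: estimates shrink to zero no matter the data
  pop0 <- population_model(pop$theta,
                           omega2 = c(Emax = 1e-8, EC50 = 1e-8, E0 = 1e-8),
                           b = 0.05, sigmoidicity = FALSE)
  rec_shift <- rec
  rec_shift$value <- rec$value * 1.5
  e0 <- estimate_ebes(rec_shift, pop0)
  expect_lt(max(abs(e0$eta)), 1e-3)
  # flat prior: the EBE approaches the subject's own MLE
  pop_flat <- population_model(pop$theta, omega2 = c(E0 = 100), b = 0.05,
                               sigmoidicity = FALSE)
  rec3 <- data.frame(
    value = emax_effect(individual_params(pop$theta, c(E0 = 0.3)), ex),
    exposure_ug_mL = ex)
  e3 <- estimate_ebes(rec3, pop_flat)
  expect_equal(unname(e3$eta["E0"]), 0.3, tolerance = 0.01)
})

test_that("EBE magnitude is monotone in the BSV variance", {
  theta <- emax_params(Emax = -10, EC50 = 2, E0 = 100, n = 1)
  ex <- c(0, 2, 8)
  rec <- data.frame(
    value = emax_effect(individual_params(theta, c(E0 = 0.4)), ex),
    exposure_ug_mL = ex)
  etas <- vapply(c(1, 0.1, 0.01, 0.001), function(w2) {
    pop <- population_model(theta, omega2 = c(E0 = w2), b = 0.1,
                            sigmoidicity = FALSE)
    unname(abs(estimate_ebes(rec, pop)$eta["E0"]))
  }, numeric(1))
  expect_true(all(diff(etas) < 1e-8))
})

test_that("information criteria implement their defining formulas", {
  r <- information_criteria(100, 5, 6, 18)
  expect_equal(r$aic, 110)
  expect_equal(r$bic - r$ofv, 5 * log(6))
  expect_equal(r$bic - r$ofv, 8.9588, tolerance = 1e-4)
  expect_equal(r$bicc, 100 + 4 * log(6) + 1 * log(18))
  r0 <- information_criteria(42, 0, 6, 18, n_observation_level = 0)
  expect_equal(r0$aic, 42)
  expect_equal(r0$bic, 42)
  expect_equal(r0$bicc, 42)
})
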