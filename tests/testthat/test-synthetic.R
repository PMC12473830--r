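test_that("identical seeds reproduce every dataset bit for bit", {
  form <- default_formulations()$Differin
  cell <- franz_cell_config()
  g1 <- gen_ivrt_dataset(form, cell, seed = 12)
  g2 <- gen_ivrt_dataset(form, cell, seed = 12)
  expect_identical(g1$data, g2$data)
  g3 <- gen_ivrt_dataset(form, cell, seed = 13)
  expect_false(identical(g1$data$conc_ug_mL, g3$data$conc_ug_mL))

  skin <- skin_config(); tr <- skin_transport_params()
  i1 <- gen_ivpt_dataset(form, skin, tr, seed = 5)
  i2 <- gen_ivpt_dataset(form, skin, tr, seed = 5)
  expect_identical(i1$data, i2$data)

  pop <- default_pd_truth("sc_thickness")
  ex <- list(Differin = c(0, 50, 150), AcneFree = c(0, 40, 120),
             Effaclar = c(0, 30, 100))
  p1 <- gen_pd_dataset(pop, ex, seed = 9)
  p2 <- gen_pd_dataset(pop, ex, seed = 9)
  expect_identical(p1$data, p2$data)
})

test_that("below-LOQ censoring stores zeros and flags, never values in (0, loq)", {
  form <- default_formulations()$AcneFree
  cell <- franz_cell_config()
  loq <- 0.05
  g <- gen_ivrt_dataset(form, cell, noise = noise_spec(0.05, 0, loq), seed = 2)
  cc <- g$data$conc_ug_mL
  expect_true(all(cc == 0 | cc >= loq))
  expect_identical(g$data$bloq, cc == 0)
  expect_gt(sum(g$data$bloq), 0)  # the early lag points are censored
  # loq above every concentration: everything censored
  g2 <- gen_ivrt_dataset(form, cell, noise = noise_spec(0, 0, 1e3), seed = 2)
  expect_true(all(g2$data$conc_ug_mL == 0))
  expect_true(all(g2$data$bloq))
})

test_that("noise-free generation reproduces the deterministic pipeline exactly", {
  form <- default_formulations()$Effaclar
  cell <- franz_cell_config()
  g <- gen_ivrt_dataset(form, cell, noise = noise_spec(0, 0, 0), seed = 1)
  per_rep <- split(g$data$cumulative_ug_per_cm2, g$data$replicate)
  for (r in per_rep) expect_equal(r, g$truth$cumulative_ug_per_cm2)

  skin <- skin_config(); tr <- skin_transport_params()
  i <- gen_ivpt_dataset(form, skin, tr, noise = noise_spec(0, 0, 0), seed = 1)
  expect_equal(unique(round(i$data$recovery_pct, 6)), 100)
  expect_equal(i$truth$recovery_pct, rep(100, 4), tolerance = 1e-8)
  per_rep_epi <- split(i$data$epidermis_ug_per_mg, i$data$replicate)
  for (r in per_rep_epi) expect_equal(r, i$truth$epidermis_ug_per_mg)
})

test_that("noisy IVPT recovery spans the experimentally plausible range", {
  form <- default_formulations()$Differin
  skin <- skin_config(); tr <- skin_transport_params()
  i <- gen_ivpt_dataset(form, skin, tr, noise = noise_spec(0.04, 0, 0.05),
                        seed = 3)
  expect_true(all(i$data$recovery_pct > 85 & i$data$recovery_pct < 115))
  expect_gt(stats::sd(i$data$recovery_pct), 0.5)
})

test_that("replicate and residual CVs converge to their nominal values", {
  form <- default_formulations()$Differin
  cell <- franz_cell_config()
  des <- study_design(ivrt = list(n_replicates = 1000,
                                  sampling_times = cell$sampling_times))
  g <- gen_ivrt_dataset(form, cell, des, noise = noise_spec(0.05, 0, 0),
                        seed = 8)
  late <- g$data[g$data$time_h == 24, "conc_ug_mL"]
  expect_equal(stats::sd(late) / mean(late), 0.05, tolerance = 0.05)

  pop <- population_model(emax_params(Emax = -10, EC50 = 2, E0 = 100, n = 1),
                          omega2 = c(Emax = 0, EC50 = 0, E0 = 0), b = 0.05,
                          sigmoidicity = FALSE)
  des_pd <- study_design(pd = list(n_subjects = 1000,
                                   observation_times = c(0, 5, 48),
                                   formulations = "A"))
  gp <- gen_pd_dataset(pop, list(A = c(0, 2, 8)), des_pd, seed = 8)
  f <- emax_effect(pop$theta, gp$data$exposure_ug_mL)
  resid_cv <- stats::sd(gp$data$value / f - 1)
  expect_equal(resid_cv, 0.05, tolerance = 0.05)
})

test_that("PD baseline observations center on the individual E0", {
  pop <- population_model(emax_params(Emax = -10, EC50 = 2, E0 = 100, n = 1),
                          omega2 = c(E0 = 0.04), b = 1e-4,
                          sigmoidicity = FALSE)
  des <- study_design(pd = list(n_subjects = 12,
                                observation_times = c(0, 5, 48),
                                formulations = "A"))
  g <- gen_pd_dataset(pop, list(A = c(0, 2, 8)), des, seed = 2)
  base <- g$data[g$data$time_h == 0, ]
  e0_i <- g$truth$subjects$E0
  expect_equal(base$value, e0_i, tolerance = 1e-3)
  # with zero variability everything lies on the structural curve
  pop0 <- population_model(pop$theta, omega2 = c(E0 = 0), b = 1e-8,
                           sigmoidicity = FALSE)
  g0 <- gen_pd_dataset(pop0, list(A = c(0, 2, 8)), des, seed = 2)
  f <- emax_effect(pop0$theta, g0$data$exposure_ug_mL)
  expect_equal(g0$data$value, f, tolerance = 1e-6)
})
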