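test_that("skin configuration derives volumes and weights from anatomy", {
  skin <- skin_config()
  expect_equal(skin$sc_mg, 12 * 1e-4 * 0.69 * 1.2 * 1000)
  expect_equal(skin$sc_mg, 1, tolerance = 0.01)
  expect_equal(skin$ve_mg, 4.4, tolerance = 0.01)
  expect_equal(skin$dm_mg, 75, tolerance = 0.02)
  expect_equal(skin$sc_thickness + skin$ve_thickness + skin$dm_thickness,
               skin$total_thickness)
  expect_equal(skin$sebum_volume, 0.001 * skin$sc_volume)
  expect_error(skin_config(sc_thickness = 100), "within 2%")
})

test_that("the IVPT system has the full compartment and interface layout", {
  sys <- build_ivpt_system(default_formulations()$Differin, skin_config(),
                           skin_transport_params())
  nm <- vapply(sys$compartments, `[[`, character(1), "name")
  expect_identical(nm, c("DP", "CP", "SC", "SB", "VE", "DM", "REC"))
  expect_length(sys$interfaces, 9)
  expect_equal(sys$compartments[[1]]$initial_amount, 500)
  expect_equal(sys$compartments[[7]]$volume, 4.9)
  pairs <- vapply(sys$interfaces, function(i) paste(i$source, i$target),
                  character(1))
  expect_setequal(pairs, c("DP CP", "CP SC", "CP SB", "SB SC", "SB VE",
                           "SB DM", "SC VE", "VE DM", "DM REC"))
  expect_error(
    build_ivpt_system(default_formulations()$Differin, skin_config(),
                      structure(list(cp_sc = list(P = 1, Kp = 1)),
                                class = "skin_transport_params")),
    "missing transport")
})

test_that("disabling pathways isolates the matching compartments", {
  skin <- skin_config()
  tr_no_sb <- skin_transport_params(cp_sb = list(P = 0), sb_sc = list(P = 0),
                                    sb_ve = list(P = 0), sb_dm = list(P = 0))
  res <- simulate_system(
    build_ivpt_system(default_formulations()$Differin, skin, tr_no_sb),
    seq(0, 36, 2))
  expect_true(all(res$amounts[, "SB"] == 0))
  tr_block <- skin_transport_params(dm_rec = list(P = 0))
  res2 <- simulate_system(
    build_ivpt_system(default_formulations()$Differin, skin, tr_block),
    seq(0, 36, 2))
  expect_true(all(res2$amounts[, "REC"] == 0))
})

test_that("layer accumulation normalizes amounts by tissue weight", {
  skin <- skin_config()
  res <- list(
    times = c(0, 1),
    amounts = rbind(c(DP = 0, CP = 0, SC = 0, SB = 0, VE = 0, DM = 0, REC = 0),
                    c(DP = 0, CP = 0, SC = 0.8, SB = 0, VE = 0.3, DM = 0.5,
                      REC = 0.1)),
    volumes = c(DP = 1, CP = 1, SC = 1, SB = 1, VE = 1, DM = 1, REC = 1),
    system = compartment_system(list(compartment("dummy", 1))))
  acc <- layer_accumulation(res, skin)
  expect_equal(acc$epidermis_ug_per_mg[2], 1.1 / (skin$sc_mg + skin$ve_mg))
  expect_equal(acc$epidermis_ug_per_mg[2], 0.2037, tolerance = 0.01)
  expect_equal(acc$dermis_ug_per_mg[2], 0.5 / skin$dm_mg)
  expect_equal(acc$receptor_ug[2], 0.1)
  expect_true(all(acc[1, c("epidermis_ug_per_mg", "dermis_ug_per_mg")] == 0))
  # sebum assignment is configurable
  res$amounts[2, "SB"] <- 0.2
  expect_equal(layer_accumulation(res, skin, "epidermis")$epidermis_ug_per_mg[2],
               1.3 / (skin$sc_mg + skin$ve_mg))
  expect_equal(layer_accumulation(res, skin, "dermis")$dermis_ug_per_mg[2],
               0.7 / skin$dm_mg)
  expect_equal(layer_accumulation(res, skin, "none")$epidermis_ug_per_mg[2],
               1.1 / (skin$sc_mg + skin$ve_mg))
})

test_that("percent recovery is the mass-balance identity", {
  expect_equal(percent_recovery(40, 5, 450, 5, 500), 100)
  expect_equal(percent_recovery(0, 0, 500, 0, 500), 100)
  expect_equal(percent_recovery(40, 5, 430, 0, 500), 95)
  expect_error(percent_recovery(1, 1, 1, 1, 0), "dose")
  expect_error(percent_recovery(-1, 1, 1, 1, 500), ">= 0")
})

test_that("simulated IVPT recovery is exactly 100 percent at every time", {
  skin <- skin_config()
  res <- simulate_system(
    build_ivpt_system(default_formulations()$AcneFree, skin,
                      skin_transport_params()),
    seq(0, 36, 1))
  a <- res$amounts
  rec <- percent_recovery(
    a[, "SC"] + a[, "VE"] + a[, "SB"], a[, "DM"],
    a[, "DP"] + a[, "CP"], a[, "REC"], 500)
  expect_equal(rec, rep(100, nrow(a)), tolerance = 1e-6)
})

test_that("SC and infundibular exposure derive from the SC compartment", {
  skin <- skin_config()
  res <- list(times = c(0, 1),
              amounts = rbind(c(SC = 0), c(SC = 1)),
              volumes = c(SC = skin$sc_volume),
              system = compartment_system(list(compartment("dummy", 1))))
  colnames(res$amounts) <- "SC"
  csc <- sc_concentration(res, skin)
  expect_equal(csc$conc_ug_mL[2], 1 / skin$sc_volume)
  expect_equal(csc$conc_ug_mL[2], 1205, tolerance = 0.005)
  expect_equal(csc$conc_ug_mL[1], 0)
  expect_equal(infundibular_concentration(100), 0.1)
  expect_equal(infundibular_concentration(0), 0)
  expect_equal(infundibular_concentration(2500), 2.5)
  expect_error(infundibular_concentration(-1), ">= 0")
})

test_that("the system is linear in dose and formulation-swap is bit-stable", {
  skin <- skin_config()
  tr <- skin_transport_params()
  f1 <- default_formulations()$Differin
  f2 <- f1
  f2$drug_mass_fraction <- 2 * f1$drug_mass_fraction  # volumes unchanged
  t_grid <- seq(0, 36, 3)
  r1 <- simulate_system(build_ivpt_system(f1, skin, tr), t_grid)
  r2 <- simulate_system(build_ivpt_system(f2, skin, tr), t_grid)
  expect_equal(r2$amounts, 2 * r1$amounts, tolerance = 1e-8)
  # identical formulation parameters give bit-identical tissue outputs
  f3 <- f1
  f3$name <- "clone"
  r3 <- simulate_system(build_ivpt_system(f3, skin, tr), t_grid)
  expect_identical(r3$amounts, r1$amounts)
})

test_that("defaults accumulate more drug per weight in epidermis than dermis", {
  skin <- skin_config()
  res <- simulate_system(
    build_ivpt_system(default_formulations()$Differin, skin,
                      skin_transport_params()),
    seq(0, 36, 2))
  acc <- layer_accumulation(res, skin)
  expect_true(all(acc$epidermis_ug_per_mg >= acc$dermis_ug_per_mg))
})

test_that("with all Kp = 1 the layers equilibrate to equal concentrations", {
  skin <- skin_config()
  tr <- skin_transport_params(
    cp_sc = list(P = 1, Kp = 1), cp_sb = list(P = 1, Kp = 1),
    sb_sc = list(P = 1, Kp = 1), sb_ve = list(P = 1, Kp = 1),
    sb_dm = list(P = 1, Kp = 1), sc_ve = list(P = 1, Kp = 1),
    ve_dm = list(P = 1, Kp = 1), dm_rec = list(P = 1, Kp = 1))
  form <- formulation_params("eq", Kp_dp_cp = 1, P_dp_cp = 0.5)
  res <- simulate_system(build_ivpt_system(form, skin, tr),
                         c(0, 5000, 10000), rtol = 1e-10, atol = 1e-12)
  conc <- concentrations(res)[3, ]
  expect_equal(max(conc) / min(conc), 1, tolerance = 1e-3)
})
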