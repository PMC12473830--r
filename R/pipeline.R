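#' Validate a pipeline dataset file
#'
#' Machine-readable structural checks for the CSV dialects the pipeline
#' exchanges: required columns, sorted times within each series, and
#' non-negative values.
#'
#' @param path Path to a CSV file.
#' @param schema One of `"release"` (IVRT profiles), `"accumulation"` (IVPT
#'   tissue tables), `"pd"` (clinical PD observations).
#' @return List with `valid` (logical) and `findings` (data frame `check`,
#'   `detail`).
#' @export
validate_dataset <- function(path, schema = c("release", "accumulation", "pd")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e)
                   stop("malformed CSV: ", conditionMessage(e), call. = FALSE))
  req <- switch(schema,
    release = c("formulation", "time_h", "cumulative_ug_per_cm2"),
    accumulation = c("formulation", "time_h", "epidermis_ug_per_mg",
                     "dermis_ug_per_mg"),
    pd = c("subject_id", "formulation", "time_h", "value", "exposure_ug_mL"))
  findings <- list()
  add <- function(check, detail)
    findings[[length(findings) + 1L]] <<- data.frame(check = check,
                                                     detail = detail)
  miss <- setdiff(req, names(df))
  if (length(miss))
    add("missing columns", paste(miss, collapse = ", "))
  if (!length(miss)) {
    key <- if (schema == "pd") df$subject_id
           else if ("replicate" %in% names(df))
             paste(df$formulation, df$replicate) else df$formulation
    for (g in unique(key)) {
      tt <- df$time_h[key == g]
      if (is.unsorted(tt))
        add("times not sorted", paste0("series '", g, "'"))
    }
    num_cols <- setdiff(req, c("formulation", "subject_id"))
    for (cc in num_cols) {
      v <- df[[cc]]
      if (any(!is.finite(v)))
        add("non-finite value", paste0("column ", cc, ", row ",
                                       which(!is.finite(v))[1]))
      else if (any(v < 0))
        add("negative value", paste0("column ", cc, ", row ",
                                     which(v < 0)[1]))
    }
  }
  findings <- if (length(findings)) do.call(rbind, findings)
    else data.frame(check = character(0), detail = character(0))
  list(valid = nrow(findings) == 0L, findings = findings)
}

#' Run the full pipeline
#'
#' End-to-end orchestration on synthetic data: generate IVRT datasets per
#' formulation, calibrate the release parameters, generate IVPT datasets,
#' calibrate the skin partition coefficients once on the pooled data, extract
#' the SC and infundibular exposure series, generate a clinical PD dataset,
#' fit the population model, and run VPC and residual diagnostics. Every
#' stage's outputs and seeds are recorded in a JSON manifest; outputs are
#' written as CSV/JSON into `out_dir`.
#'
#' @param config List with elements `out_dir` (required), `seed` (default 1),
#'   and optional overrides: `formulations` (named list of
#'   [formulation_params()]), `cell`, `skin`, `transport`, `design`
#'   ([study_design()]), `noise` ([noise_spec()]), `pd_truth`
#'   (a [population_model()] used to generate the PD data), `pd_endpoint`
#'   (`"infundibular_area"` or `"sc_thickness"`), `n_vpc_replicates`
#'   (default 500), `calibrate` (logical, default TRUE; FALSE skips the two
#'   calibration stages and uses the shipped parameters directly).
#' @return The manifest (list), invisibly; also written to
#'   `out_dir/manifest.json`.
#' @export
run_pipeline <- function(config) {
  if (is.null(config$out_dir)) stop("config$out_dir is required", call. = FALSE)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  forms <- config$formulations %||% default_formulations()
  cell <- config$cell %||% franz_cell_config()
  skin <- config$skin %||% skin_config()
  transport <- config$transport %||% skin_transport_params()
  design <- config$design %||% study_design()
  noise <- config$noise %||% noise_spec()
  endpoint <- config$pd_endpoint %||% "infundibular_area"
  do_calibrate <- config$calibrate %||% TRUE
  manifest <- list(seed = seed, endpoint = endpoint, stages = list())
  note <- function(stage, ...) {
    manifest$stages[[stage]] <<- list(...)
    message("[", stage, "] done")
  }

  # --- IVRT: synthetic data + release calibration per formulation ----------
  ivrt_data <- list()
  release_fits <- list()
  for (i in seq_along(forms)) {
    f <- forms[[i]]
    gen <- gen_ivrt_dataset(f, cell, design, noise, seed = seed + i)
    ivrt_data[[f$name]] <- gen$data
    if (do_calibrate) {
      spec <- calibration_spec(
        "release", gen$data,
        free = list(Kp_dp_cp = c(1e-7, 1e-4), P_dp_cp = c(1e-8, 1e-5),
                    release_lag = c(0, 12)),
        form = f, cell = cell, objective = "weighted_sse")
      release_fits[[f$name]] <- calibrate(spec, seed = seed)
      for (p in names(release_fits[[f$name]]$par))
        forms[[i]][[p]] <- release_fits[[f$name]]$par[[p]]
    }
  }
  ivrt_df <- do.call(rbind, ivrt_data)
  write_release_csv(ivrt_df, file.path(out_dir, "ivrt_release.csv"))
  if (do_calibrate)
    fit_to_json(release_fits[[1]], file.path(out_dir, "release_fit.json"))
  note("ivrt", file = "ivrt_release.csv", seed = seed,
       calibrated = do_calibrate,
       release_parameters = lapply(forms, function(f)
         f[c("Kp_dp_cp", "P_dp_cp", "release_lag")]))

  # --- IVPT: synthetic data + pooled skin calibration ----------------------
  ivpt_data <- list()
  for (i in seq_along(forms)) {
    gen <- gen_ivpt_dataset(forms[[i]], skin, transport, design, noise,
                            seed = seed + 100 + i)
    ivpt_data[[forms[[i]]$name]] <- gen$data
  }
  ivpt_df <- do.call(rbind, ivpt_data)
  write_accumulation_csv(ivpt_df, file.path(out_dir, "ivpt_accumulation.csv"))
  if (do_calibrate) {
    skin_spec <- calibration_spec(
      "skin", ivpt_df,
      free = list(Kp_cp_sc = c(100, 20000), Kp_ve_dm = c(0.01, 5),
                  Kp_sb_dm = c(1e-4, 1), Kp_dm_rec = c(0.001, 2)),
      form = forms, skin = skin, transport = transport)
    skin_fit <- calibrate(skin_spec, seed = seed)
    fit_to_json(skin_fit, file.path(out_dir, "skin_fit.json"))
    for (p in names(skin_fit$par))
      transport[[sub("^Kp_", "", p)]]$Kp <- skin_fit$par[[p]]
  }
  note("ivpt", file = "ivpt_accumulation.csv", seed = seed + 101,
       calibrated = do_calibrate)

  # --- Exposure extraction --------------------------------------------------
  sim_times <- sort(unique(c(seq(0, 48, by = 0.5),
                             design$pd$observation_times)))
  exposure <- list()
  for (f in forms) {
    sys <- build_ivpt_system(f, skin, transport)
    res <- simulate_system(sys, sim_times)
    csc <- sc_concentration(res, skin)
    exposure[[f$name]] <- if (endpoint == "infundibular_area")
      data.frame(time_h = csc$time_h,
                 conc_ug_mL = infundibular_concentration(csc$conc_ug_mL))
    else csc
  }
  expo_df <- do.call(rbind, lapply(names(exposure), function(nm)
    cbind(formulation = nm, exposure[[nm]])))
  utils::write.csv(expo_df, file.path(out_dir, "exposure.csv"),
                   row.names = FALSE)
  note("exposure", file = "exposure.csv", endpoint = endpoint)

  # --- PD: synthetic clinical data + population fit ------------------------
  pd_truth <- config$pd_truth %||% default_pd_truth(endpoint)
  gen_pd <- gen_pd_dataset(pd_truth, exposure, design, seed = seed + 200)
  utils::write.csv(gen_pd$data, file.path(out_dir, "pd_observations.csv"),
                   row.names = FALSE)
  fit <- fit_population(gen_pd$data, pd_truth, seed = seed)
  utils::write.csv(fit$ebes, file.path(out_dir, "pd_ebes.csv"),
                   row.names = FALSE)
  report_json <- jsonlite::toJSON(
    list(theta = fit$pop$theta[c("Emax", "EC50", "E0", "n")],
         omega2 = as.list(fit$pop$omega2), b = fit$pop$b,
         report = unclass(fit$report), converged = fit$converged,
         seed = fit$seed),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(report_json, file.path(out_dir, "pd_fit.json"))
  note("pd_fit", file = "pd_fit.json", seed = seed + 200,
       converged = fit$converged)

  # --- VPC + residual diagnostics ------------------------------------------
  vt <- design$pd$observation_times
  vdesign <- list(times = vt,
                  exposure = stats::approx(exposure[[1]]$time_h,
                                           exposure[[1]]$conc_ug_mL,
                                           xout = vt, rule = 2)$y,
                  n_subjects = design$pd$n_subjects)
  v <- vpc(fit$pop, vdesign, n_replicates = config$n_vpc_replicates %||% 500,
           seed = seed + 300)
  utils::write.csv(as.data.frame(v), file.path(out_dir, "vpc.csv"),
                   row.names = FALSE)
  diag <- residual_diagnostics(gen_pd$data, fit$pop, fit, n_sim = 500,
                               seed = seed + 400)
  utils::write.csv(diag, file.path(out_dir, "residual_diagnostics.csv"),
                   row.names = FALSE)
  note("diagnostics", files = c("vpc.csv", "residual_diagnostics.csv"),
       seed = c(vpc = seed + 300, npde = seed + 400))

  manifest_json <- jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                                    pretty = TRUE)
  writeLines(manifest_json, file.path(out_dir, "manifest.json"))
  invisible(manifest)
}

#' Default generating truth for the synthetic PD stage
#'
#' Synthetic population parameters for the two clinical endpoints. Both
#' endpoints decrease with exposure, so `Emax` is negative; baselines are in
#' the anatomical range of the endpoint (infundibular cross-sectional area
#' ~10^4 um2; SC thickness ~15 um). EC50 values sit inside the exposure range
#' the IVPT model produces for each driver (infundibular exposure is 0.1 % of
#' the SC concentration).
#'
#' @param endpoint `"infundibular_area"` or `"sc_thickness"`.
#' @return A [population_model()].
#' @export
default_pd_truth <- function(endpoint = c("infundibular_area", "sc_thickness")) {
  endpoint <- match.arg(endpoint)
  if (endpoint == "infundibular_area") {
    population_model(
      emax_params(Emax = -6000, EC50 = 0.5, E0 = 12000, n = 2),
      omega2 = c(Emax = 0.04, EC50 = 0.09, E0 = 0.04, n = 0.04),
      b = 0.1, sigmoidicity = TRUE)
  } else {
    population_model(
      emax_params(Emax = -6, EC50 = 500, E0 = 15, n = 1),
      omega2 = c(Emax = 0.04, EC50 = 0.09, E0 = 0.04),
      b = 0.08, sigmoidicity = FALSE)
  }
}
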