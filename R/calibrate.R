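#' Calibration specification
#'
#' Describes one step of the stepwise calibration. The `release` stage frees
#' only the formulation release parameters (`Kp_dp_cp`, `P_dp_cp`,
#' `release_lag`) against IVRT release profiles, one formulation at a time.
#' The `skin` stage consumes the calibrated release parameters unchanged and
#' frees only the partition coefficient between the gel continuous phase and
#' the SC lipids plus the partition coefficients at DM-involving interfaces
#' (`Kp_cp_sc`, `Kp_ve_dm`, `Kp_sb_dm`, `Kp_dm_rec`), fitted once on pooled
#' tissue-accumulation data across formulations. Attempts to free any other
#' parameter are a configuration error.
#'
#' @param stage `"release"` or `"skin"`.
#' @param data For `release`: a `release_profile` data frame (columns
#'   `formulation`, optional `replicate`, `time_h`, `cumulative_ug_per_cm2`).
#'   For `skin`: a `tissue_accumulation` data frame (columns `formulation`,
#'   optional `replicate`, `time_h`, `epidermis_ug_per_mg`,
#'   `dermis_ug_per_mg`).
#' @param free Named list of free parameters: `list(name = c(lower, upper))`.
#'   Initial values are taken from `form`/`transport`.
#' @param form For `release`: a single [formulation_params()] supplying fixed
#'   values and initial guesses. For `skin`: a named list of
#'   [formulation_params()] (the calibrated release parameter sets, used as
#'   is) covering every formulation in `data`.
#' @param cell A [franz_cell_config()] (release stage).
#' @param skin A [skin_config()] (skin stage).
#' @param transport A [skin_transport_params()] (skin stage) supplying fixed
#'   values and initial guesses.
#' @param receptor_volume IVPT receptor volume, mL (skin stage).
#' @param objective `"sse"` (default) or `"weighted_sse"` (weights `1/obs^2`
#'   over positive observations).
#' @return An object of class `calibration_spec`.
#' @export
calibration_spec <- function(stage = c("release", "skin"), data, free,
                             form = NULL, cell = NULL, skin = NULL,
                             transport = NULL, receptor_volume = 4.9,
                             objective = c("sse", "weighted_sse")) {
  stage <- match.arg(stage)
  objective <- match.arg(objective)
  allowed <- switch(stage,
    release = c("Kp_dp_cp", "P_dp_cp", "release_lag"),
    skin = paste0("Kp_", skin_calibratable_kps())
  )
  bad <- setdiff(names(free), allowed)
  if (length(bad))
    stop("stage '", stage, "' cannot free parameter(s): ",
         paste(bad, collapse = ", "), " (allowed: ",
         paste(allowed, collapse = ", "), ")", call. = FALSE)
  if (!length(free)) stop("at least one free parameter required", call. = FALSE)
  for (nmf in names(free)) {
    b <- free[[nmf]]
    if (length(b) != 2 || any(!is.finite(b)) || b[1] >= b[2])
      stop("bounds for '", nmf, "' must be finite c(lower, upper)", call. = FALSE)
  }
  if (stage == "release") {
    if (!inherits(form, "formulation_params"))
      stop("release stage requires a single formulation_params 'form'", call. = FALSE)
    if (!inherits(cell, "franz_cell_config"))
      stop("release stage requires a franz_cell_config 'cell'", call. = FALSE)
  } else {
    if (!is.list(form) || !all(vapply(form, inherits, logical(1), "formulation_params")))
      stop("skin stage requires a named list of formulation_params 'form'", call. = FALSE)
    if (!inherits(skin, "skin_config"))
      stop("skin stage requires a skin_config", call. = FALSE)
    if (!inherits(transport, "skin_transport_params"))
      stop("skin stage requires skin_transport_params", call. = FALSE)
    miss <- setdiff(unique(data$formulation), names(form))
    if (length(miss))
      stop("no formulation_params supplied for: ", paste(miss, collapse = ", "),
           call. = FALSE)
  }
  structure(
    list(stage = stage, data = data, free = free, form = form, cell = cell,
         skin = skin, transport = transport, receptor_volume = receptor_volume,
         objective = objective),
    class = "calibration_spec"
  )
}

# Pool replicates: mean observed value per formulation x time.
pool_replicates <- function(data, value_cols) {
  agg <- stats::aggregate(data[value_cols],
                          by = list(formulation = data$formulation,
                                    time_h = data$time_h),
                          FUN = mean)
  agg[order(agg$formulation, agg$time_h), , drop = FALSE]
}

# Sum of squares with optional 1/obs^2 weighting (zeros get weight 0).
sse_objective <- function(pred, obs, objective) {
  if (objective == "weighted_sse") {
    w <- ifelse(obs > 0, 1 / obs^2, 0)
    sum(w * (pred - obs)^2)
  } else {
    sum((pred - obs)^2)
  }
}

release_predictor <- function(spec, pooled) {
  # the forward model replays the sample-and-replace protocol at the data's
  # own sampling times, so noise-free data are exactly reproducible
  times <- sort(unique(pooled$time_h[pooled$time_h > 0]))
  function(par) {
    fm <- spec$form
    for (nmp in names(par)) fm[[nmp]] <- par[[nmp]]
    sim <- simulate_release_sampled(fm, spec$cell, times)
    stats::approx(c(0, sim$times), c(0, sim$cumulative_ug_per_cm2),
                  xout = pooled$time_h)$y
  }
}

skin_predictor <- function(spec, pooled) {
  times <- sort(unique(c(0, pooled$time_h)))
  function(par) {
    tr <- spec$transport
    for (nmp in names(par)) {
      key <- sub("^Kp_", "", nmp)
      tr[[key]]$Kp <- par[[nmp]]
    }
    pred <- numeric(0)
    for (f in unique(pooled$formulation)) {
      sys <- build_ivpt_system(spec$form[[f]], spec$skin, tr,
                               receptor_volume = spec$receptor_volume)
      acc <- layer_accumulation(simulate_system(sys, times), spec$skin)
      rows <- pooled[pooled$formulation == f, ]
      pe <- stats::approx(acc$time_h, acc$epidermis_ug_per_mg, xout = rows$time_h)$y
      pd <- stats::approx(acc$time_h, acc$dermis_ug_per_mg, xout = rows$time_h)$y
      pred <- c(pred, pe, pd)
    }
    pred
  }
}

# Bounded-logit transform between the box constraints and the real line.
to_unconstrained <- function(x, lo, hi) stats::qlogis(pmin(pmax((x - lo) / (hi - lo), 1e-10), 1 - 1e-10))
to_constrained <- function(z, lo, hi) lo + (hi - lo) * stats::plogis(z)

#' Calibrate model parameters against observed profiles
#'
#' Bounded derivative-free minimization (Nelder-Mead on a bounded-logit
#' reparameterization, with a refinement restart and optional seeded
#' multi-start) of the sum-of-squares objective over the stage's free
#' parameters only. Fixed parameters are never touched, so a skin-stage fit
#' leaves the release parameters bit-identical to its input.
#'
#' @param spec A [calibration_spec()].
#' @param seed Integer seed controlling the multi-start draws.
#' @param multi_start Number of starting points (1 = supplied start only;
#'   extra starts are drawn uniformly within bounds).
#' @param control Passed to [stats::optim()] (Nelder-Mead).
#' @return An object of class `fit_result`: calibrated parameter values,
#'   bounds-hit flags, objective at start and solution, per-formulation
#'   [compute_metrics()] reports, convergence diagnostics and the seed.
#' @export
calibrate <- function(spec, seed = 1, multi_start = 1,
                      control = list(maxit = 500, reltol = 1e-12)) {
  stopifnot(inherits(spec, "calibration_spec"))
  data <- spec$data
  if ("bloq" %in% names(data)) {
    # below-LOQ observations are recorded as zero by convention; they carry
    # no quantitative information and are excluded from the fit objective
    data <- data[!data$bloq, , drop = FALSE]
    spec$data <- data
  }
  if (spec$stage == "release") {
    pooled <- pool_replicates(spec$data, "cumulative_ug_per_cm2")
    obs <- pooled$cumulative_ug_per_cm2
    predictor <- release_predictor(spec, pooled)
    init_source <- spec$form
  } else {
    pooled <- pool_replicates(spec$data, c("epidermis_ug_per_mg", "dermis_ug_per_mg"))
    obs <- numeric(0)
    for (f in unique(pooled$formulation)) {
      rows <- pooled[pooled$formulation == f, ]
      obs <- c(obs, rows$epidermis_ug_per_mg, rows$dermis_ug_per_mg)
    }
    predictor <- skin_predictor(spec, pooled)
    init_source <- NULL
  }

  free_names <- names(spec$free)
  lo <- vapply(spec$free, `[`, numeric(1), 1)
  hi <- vapply(spec$free, `[`, numeric(1), 2)
  init <- vapply(free_names, function(nmp) {
    if (spec$stage == "release") init_source[[nmp]]
    else spec$transport[[sub("^Kp_", "", nmp)]]$Kp
  }, numeric(1))
  init <- pmin(pmax(init, lo), hi)

  obj <- function(z) {
    par <- to_constrained(z, lo, hi)
    names(par) <- free_names
    v <- sse_objective(predictor(par), obs, spec$objective)
    if (!is.finite(v)) 1e300 else v
  }
  z0 <- to_unconstrained(init, lo, hi)
  f0 <- obj(z0)
  if (!is.finite(f0) || f0 >= 1e300)
    stop("objective is non-finite at the initial point", call. = FALSE)

  starts <- list(z0)
  if (multi_start > 1) {
    set.seed(seed)
    for (k in seq_len(multi_start - 1L))
      starts[[k + 1L]] <- to_unconstrained(stats::runif(length(lo), lo, hi), lo, hi)
  }
  best <- list(par = z0, value = f0, convergence = NA_integer_)
  for (z in starts) {
    if (length(z) == 1L) {
      fit <- stats::optim(z, obj, method = "Brent", lower = -30, upper = 30,
                          control = list(reltol = 1e-12))
    } else {
      fit <- stats::optim(z, obj, method = "Nelder-Mead", control = control)
      fit <- stats::optim(fit$par, obj, method = "Nelder-Mead",
                          control = control)
    }
    if (fit$value < best$value) best <- fit
  }

  par <- to_constrained(best$par, lo, hi)
  names(par) <- free_names
  rel_pos <- (par - lo) / (hi - lo)
  bounds_hit <- rel_pos < 1e-4 | rel_pos > 1 - 1e-4
  if (any(bounds_hit))
    warning("parameter(s) at a bound: ",
            paste(free_names[bounds_hit], collapse = ", "), call. = FALSE)

  pred <- predictor(par)
  metrics <- list()
  if (spec$stage == "release") {
    for (f in unique(pooled$formulation)) {
      idx <- pooled$formulation == f
      metrics[[f]] <- compute_metrics(pred[idx], obs[idx])
    }
  } else {
    off <- 0L
    for (f in unique(pooled$formulation)) {
      nt <- sum(pooled$formulation == f)
      idx <- off + seq_len(2L * nt)
      metrics[[f]] <- compute_metrics(pred[idx], obs[idx])
      off <- off + 2L * nt
    }
  }

  structure(
    list(stage = spec$stage, par = as.list(par), free = free_names,
         fixed = if (spec$stage == "release") {
           fx <- spec$form[setdiff(names(spec$form), free_names)]
           fx
         } else {
           list(formulations = spec$form,
                transport_fixed = spec$transport)
         },
         objective_value = best$value, objective_at_init = f0,
         bounds_hit = as.list(bounds_hit), metrics = metrics,
         convergence = best$convergence, n_starts = length(starts),
         seed = seed),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result> stage =", x$stage, "\n")
  for (nmp in names(x$par))
    cat(sprintf("  %-14s %.6g%s\n", nmp, x$par[[nmp]],
                if (isTRUE(x$bounds_hit[[nmp]])) " [at bound]" else ""))
  cat(sprintf("  objective: %.6g (start %.6g), %d start(s)\n",
              x$objective_value, x$objective_at_init, x$n_starts))
  invisible(x)
}

#' Serialize a fit result to JSON
#'
#' @param fit A `fit_result`.
#' @param path Optional output path; if `NULL`, returns the JSON string.
#' @return `path` invisibly, or a JSON string.
#' @export
fit_to_json <- function(fit, path = NULL) {
  obj <- list(stage = fit$stage, parameters = fit$par,
              bounds_hit = fit$bounds_hit,
              objective_value = fit$objective_value, seed = fit$seed,
              metrics = lapply(fit$metrics, function(m)
                m[c("rmse", "mape", "afe", "aafe", "bias", "r_squared", "pearson_r")]))
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(as.character(txt))
  writeLines(txt, path)
  invisible(path)
}
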