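# Simulate one dataset (n_subjects x times) under the population model.
# Returns the matrix of simulated observations [subject x time]. Non-positive
# draws are redrawn (the proportional error model requires y > 0); the number
# of redraws is accumulated in the environment counter if supplied.
simulate_pd_matrix <- function(pop, exposure, n_subjects, counter = NULL) {
  free <- names(pop$omega2)[pop$omega2 > 0]
  nt <- length(exposure)
  y <- matrix(NA_real_, n_subjects, nt)
  for (s in seq_len(n_subjects)) {
    # truncated BSV, matching the data generator: random effects implying a
    # non-positive structural prediction are redrawn
    for (try in 1:100) {
      eta <- stats::setNames(
        stats::rnorm(length(free), 0, sqrt(pop$omega2[free])), free)
      th <- individual_params(pop$theta, eta)
      f <- emax_effect(th, exposure)
      if (all(f > 0)) break
      if (!is.null(counter)) counter$n <- counter$n + 1L
    }
    ys <- f * (1 + pop$b * stats::rnorm(nt))
    bad <- which(ys <= 0)
    tries <- 0L
    while (length(bad) && tries < 100L) {
      ys[bad] <- f[bad] * (1 + pop$b * stats::rnorm(length(bad)))
      if (!is.null(counter)) counter$n <- counter$n + length(bad)
      bad <- which(ys <= 0)
      tries <- tries + 1L
    }
    y[s, ] <- ys
  }
  y
}

#' Visual predictive check
#'
#' Monte Carlo simulation of `n_replicates` datasets under the population
#' model at a fixed design (time grid, exposure series, number of subjects).
#' For each replicate the requested percentiles of the simulated observations
#' are computed per time point; across replicates the median and a confidence
#' band of each percentile trajectory are returned.
#'
#' @param pop A [population_model()].
#' @param design List with `times` (h), `exposure` (ug/mL, one value per
#'   time) and `n_subjects`.
#' @param n_replicates Number of Monte Carlo replicates (>= 100).
#' @param percentiles Percentiles of the simulated observations (default
#'   10th/50th/90th).
#' @param seed Integer seed; results are reproducible for a fixed seed.
#' @param ci Confidence level of the percentile bands (default 0.9).
#' @return A `vpc_result` data frame: `time_h`, `percentile`, `median`,
#'   `lower`, `upper`; attributes `n_replicates`, `seed`, `n_resampled`
#'   (count of non-positive draws that were redrawn).
#' @export
vpc <- function(pop, design, n_replicates = 1000,
                percentiles = c(0.1, 0.5, 0.9), seed = 1, ci = 0.9) {
  if (n_replicates < 100) stop("n_replicates must be >= 100", call. = FALSE)
  stopifnot(length(design$times) == length(design$exposure),
            design$n_subjects >= 1)
  set.seed(seed)
  counter <- new.env()
  counter$n <- 0L
  nt <- length(design$times)
  np <- length(percentiles)
  sims <- array(NA_real_, c(n_replicates, np, nt))
  for (r in seq_len(n_replicates)) {
    y <- simulate_pd_matrix(pop, design$exposure, design$n_subjects, counter)
    sims[r, , ] <- apply(y, 2, stats::quantile, probs = percentiles)
  }
  if (counter$n > 0L)
    warning(counter$n, " non-positive simulated observation(s) redrawn",
            call. = FALSE)
  alpha <- (1 - ci) / 2
  out <- do.call(rbind, lapply(seq_len(np), function(i) {
    data.frame(
      time_h = design$times,
      percentile = percentiles[i],
      median = apply(sims[, i, , drop = FALSE], 3, stats::median),
      lower = apply(sims[, i, , drop = FALSE], 3, stats::quantile, probs = alpha),
      upper = apply(sims[, i, , drop = FALSE], 3, stats::quantile, probs = 1 - alpha)
    )
  }))
  structure(out, class = c("vpc_result", "data.frame"),
            n_replicates = n_replicates, seed = seed,
            n_resampled = counter$n)
}

#' Residual diagnostics: IWRES and NPDE
#'
#' Individual weighted residuals `IWRES = (y - f_i) / (b * f_i)` use each
#' subject's individual (EBE-based) predictions `f_i`. Normalized prediction
#' distribution errors are simulation-based: for each observation, `n_sim`
#' replicates are simulated under the population model (fresh random effects
#' per replicate), the observation's rank within its simulated distribution
#' is transformed by the inverse normal CDF. Under the true model both are
#' approximately standard normal.
#'
#' @param data PD dataset (columns `subject_id`, `time_h`, `value`,
#'   `exposure_ug_mL`).
#' @param pop A fitted [population_model()].
#' @param ebes EBE table from [fit_population()] (or a `population_fit`,
#'   whose `$ebes` is used).
#' @param n_sim Number of simulation replicates for NPDE.
#' @param seed Integer seed.
#' @return Data frame: `subject_id`, `time_h`, `value`, `pred` (population
#'   prediction), `ipred` (individual prediction), `iwres`, `npde`.
#' @export
residual_diagnostics <- function(data, pop, ebes, n_sim = 1000, seed = 1) {
  if (inherits(ebes, "population_fit")) ebes <- ebes$ebes
  set.seed(seed)
  out <- data[c("subject_id", "time_h", "value")]
  out$pred <- emax_effect(pop$theta, data$exposure_ug_mL)
  out$ipred <- NA_real_
  out$iwres <- NA_real_
  out$npde <- NA_real_
  for (sid in unique(data$subject_id)) {
    idx <- which(data$subject_id == sid)
    rec <- data[idx, ]
    row <- ebes[ebes$subject_id == sid, ]
    if (nrow(row) != 1)
      stop("no (or duplicate) EBE row for subject ", sid, call. = FALSE)
    th_i <- emax_params(row$Emax, row$EC50, row$E0, row$n)
    f_i <- emax_effect(th_i, rec$exposure_ug_mL)
    out$ipred[idx] <- f_i
    out$iwres[idx] <- (rec$value - f_i) / (pop$b * f_i)
    sims <- t(simulate_pd_matrix(pop, rec$exposure_ug_mL, n_sim))  # obs x sims
    pd <- vapply(seq_along(idx), function(i) {
      (sum(sims[i, ] < rec$value[i]) + 0.5 * sum(sims[i, ] == rec$value[i]) + 0.5) /
        (n_sim + 1)
    }, numeric(1))
    out$npde[idx] <- stats::qnorm(pd)
  }
  out
}

#' Summarize empirical Bayes estimates by formulation
#'
#' Per-formulation medians and interquartile ranges of the individual
#' parameter values (`theta_pop * exp(eta)`), for box-plot style comparison
#' of formulation effects on the PD response.
#'
#' @param ebes EBE table from [fit_population()] (or a `population_fit`).
#' @param parameter One of `"Emax"`, `"EC50"`, `"E0"`, `"n"`.
#' @return Data frame: `formulation`, `n`, `median`, `q25`, `q75`.
#' @export
ebe_by_formulation <- function(ebes, parameter) {
  if (inherits(ebes, "population_fit")) ebes <- ebes$ebes
  if (!parameter %in% c("Emax", "EC50", "E0", "n"))
    stop("unknown parameter '", parameter, "'", call. = FALSE)
  if (!parameter %in% names(ebes))
    stop("EBE table has no column '", parameter, "'", call. = FALSE)
  groups <- split(ebes[[parameter]], ebes$formulation, drop = TRUE)
  empty <- names(groups)[vapply(groups, length, integer(1)) == 0]
  if (length(empty)) {
    warning("empty formulation group(s) omitted: ",
            paste(empty, collapse = ", "), call. = FALSE)
    groups <- groups[vapply(groups, length, integer(1)) > 0]
  }
  do.call(rbind, lapply(names(groups), function(g) {
    q <- stats::quantile(groups[[g]], c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(formulation = g, n = length(groups[[g]]),
               median = q[2], q25 = q[1], q75 = q[3])
  }))
}
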