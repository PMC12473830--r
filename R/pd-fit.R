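# Split a PD dataset into per-subject records, preserving subject order.
split_subjects <- function(data) {
  stopifnot(all(c("subject_id", "value", "exposure_ug_mL") %in% names(data)))
  split(data, factor(data$subject_id, levels = unique(data$subject_id)))
}

# Laplace-approximated -2 log marginal likelihood for the whole dataset:
# sum over subjects of 2*l(eta_hat) - d*log(2*pi) + log det H, where l is the
# negative log joint and H its Hessian at the mode. `warm` optionally carries
# the previous per-subject modes as starting points.
ofv_laplace <- function(split, pop, warm = NULL) {
  d <- sum(pop$omega2 > 0)
  ebes <- lapply(seq_along(split), function(i)
    estimate_ebes(split[[i]], pop,
                  eta_start = if (is.null(warm)) NULL else warm[[i]]$eta))
  ofv <- sum(vapply(ebes, function(e)
    e$neg2ll_joint - d * log(2 * pi) + e$log_det_hessian, numeric(1)))
  list(ofv = ofv, ebes = ebes)
}

# Pooled -2 log-likelihood with the error parameter b profiled out
# (its conditional MLE is the RMS relative residual).
pooled_neg2ll <- function(data, theta) {
  f <- emax_effect(theta, data$exposure_ug_mL)
  if (any(f <= 0)) return(Inf)
  b2 <- mean(((data$value - f) / f)^2)
  if (b2 <= 0) b2 <- 1e-12
  -2 * sum(stats::dnorm(data$value, f, sqrt(b2) * f, log = TRUE))
}

#' Information criteria for population model selection
#'
#' `AIC = OFV + 2 P`; `BIC = OFV + P log(N_subjects)`. The corrected BIC
#' splits the penalty by the level at which a parameter acts: subject-level
#' parameters (fixed effects and BSV variances) are penalized by
#' `log(n_subjects)` and observation-level parameters (the residual error
#' parameter) by `log(n_observations)`.
#'
#' @param ofv Objective function value (-2 log-likelihood).
#' @param n_parameters Total number of estimated parameters P.
#' @param n_subjects Number of subjects.
#' @param n_observations Total number of observations.
#' @param n_observation_level How many of the P parameters act at the
#'   observation level (default 1: the proportional error parameter).
#' @return An object of class `model_selection_report`: list with `ofv`,
#'   `aic`, `bic`, `bicc`, `n_parameters`, `n_subjects`, `n_observations`.
#' @export
information_criteria <- function(ofv, n_parameters, n_subjects, n_observations,
                                 n_observation_level = 1) {
  stopifnot(n_parameters >= 0, n_subjects > 0, n_observations > 0,
            n_observation_level >= 0, n_observation_level <= n_parameters)
  p_subj <- n_parameters - n_observation_level
  structure(
    list(ofv = ofv,
         aic = ofv + 2 * n_parameters,
         bic = ofv + n_parameters * log(n_subjects),
         bicc = ofv + p_subj * log(n_subjects) +
           n_observation_level * log(n_observations),
         n_parameters = n_parameters, n_subjects = n_subjects,
         n_observations = n_observations),
    class = "model_selection_report"
  )
}

#' @export
print.model_selection_report <- function(x, ...) {
  cat(sprintf("OFV %.2f | AIC %.2f | BIC %.2f | BICc %.2f (P = %d, N = %d, n = %d)\n",
              x$ofv, x$aic, x$bic, x$bicc, x$n_parameters, x$n_subjects,
              x$n_observations))
  invisible(x)
}

# Assemble the per-subject EBE data frame of a fitted model.
ebe_table <- function(split, ebes, pop) {
  free <- names(pop$omega2)[pop$omega2 > 0]
  rows <- lapply(seq_along(split), function(i) {
    rec <- split[[i]]
    e <- ebes[[i]]
    out <- data.frame(subject_id = rec$subject_id[1],
                      formulation = if ("formulation" %in% names(rec))
                        rec$formulation[1] else NA_character_)
    for (p in free) out[[paste0("eta_", p)]] <- unname(e$eta[p])
    for (p in c("Emax", "EC50", "E0", "n")) out[[p]] <- e$params[[p]]
    out
  })
  do.call(rbind, rows)
}

#' Fit the population PD model
#'
#' Safeguarded iterative two-stage (ITS) estimation: each outer iteration
#' alternates (1) empirical Bayes estimation of every subject's random
#' effects with (2) population updates (fixed effects via the geometric mean
#' of individual parameters, BSV variances via centered second moments plus
#' the Laplace posterior variances, the error parameter via the RMS relative
#' residual of the individual predictions). A proposed update is accepted
#' only if the Laplace-approximated OFV does not increase; otherwise the step
#' is damped (halved in log space), so the OFV trace is monotone
#' non-increasing by construction. With all BSV variances at 0 the model
#' collapses to a pooled fixed-effects fit by direct likelihood optimization.
#'
#' Every structural fixed effect is estimated (the polish moves fixed
#' effects that carry no BSV, which the moment updates alone cannot); `n` is
#' held at 1 when sigmoidicity is disabled.
#'
#' @param data PD dataset: data frame with `subject_id`, `formulation`,
#'   `time_h`, `value`, `exposure_ug_mL` (>= 2 subjects, >= 2 observations
#'   each; pooled fits accept a single subject).
#' @param init A [population_model()] with starting values.
#' @param seed Integer seed (recorded; the algorithm itself is
#'   deterministic).
#' @param max_iter Maximum outer iterations.
#' @param tol OFV convergence tolerance.
#' @param polish_maxit Evaluation budget of the final Nelder-Mead polish
#'   (0 disables it).
#' @return An object of class `population_fit`: `pop` (the fitted
#'   [population_model()]), `ebes` (per-subject data frame of random effects
#'   and individual parameters), `report` (a `model_selection_report`),
#'   `ofv_trace`, `converged`, `iterations`, `seed`.
#' @export
fit_population <- function(data, init, seed = 1, max_iter = 40, tol = 1e-4,
                           polish_maxit = 300) {
  stopifnot(inherits(init, "population_model"))
  split <- split_subjects(data)
  n_subj <- length(split)
  n_obs <- nrow(data)
  if (any(vapply(split, nrow, integer(1)) < 2))
    stop("every subject needs >= 2 observations", call. = FALSE)
  free_bsv <- names(init$omega2)[init$omega2 > 0]

  if (!length(free_bsv)) {
    # pooled fixed-effects fit: all theta free (n only with sigmoidicity)
    th_names <- c("Emax", "EC50", "E0", if (init$sigmoidicity) "n")
    x0 <- vapply(th_names, function(p) init$theta[[p]], numeric(1))
    wrap <- function(x) {
      th <- init$theta
      for (i in seq_along(th_names)) th[[th_names[i]]] <- x[i]
      if (th$EC50 <= 0 || th$n <= 0) return(1e300)
      v <- pooled_neg2ll(data, th)
      if (!is.finite(v)) 1e300 else v
    }
    opt <- stats::optim(x0, wrap, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
    opt <- stats::optim(opt$par, wrap, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
    th <- init$theta
    for (i in seq_along(th_names)) th[[th_names[i]]] <- unname(opt$par[i])
    f <- emax_effect(th, data$exposure_ug_mL)
    b <- sqrt(mean(((data$value - f) / f)^2))
    pop <- population_model(th, omega2 = stats::setNames(
      numeric(length(init$omega2)), names(init$omega2)),
      b = max(b, 1e-6), sigmoidicity = init$sigmoidicity)
    p_total <- length(th_names) + 1L
    report <- information_criteria(opt$value, p_total, n_subj, n_obs)
    ebes_df <- do.call(rbind, lapply(split, function(rec) {
      data.frame(subject_id = rec$subject_id[1],
                 formulation = if ("formulation" %in% names(rec))
                   rec$formulation[1] else NA_character_,
                 Emax = th$Emax, EC50 = th$EC50, E0 = th$E0, n = th$n)
    }))
    return(structure(
      list(pop = pop, ebes = ebes_df, report = report,
           ofv_trace = opt$value, converged = opt$convergence == 0,
           iterations = 0L, seed = seed, n_subjects = n_subj,
           n_observations = n_obs),
      class = "population_fit"))
  }

  if (n_subj < 2) stop("need >= 2 subjects", call. = FALSE)
  set.seed(seed)
  pop <- init
  cur <- ofv_laplace(split, pop)
  trace <- cur$ofv
  converged <- FALSE
  iter <- 0L

  propose <- function(pop, ebes) {
    eta_mat <- do.call(rbind, lapply(ebes, function(e) e$eta[free_bsv]))
    pvar_mat <- do.call(rbind, lapply(ebes, function(e) e$posterior_var[free_bsv]))
    mean_eta <- colMeans(eta_mat)
    th <- pop$theta
    for (p in free_bsv) th[[p]] <- unname(th[[p]] * exp(mean_eta[p]))
    om <- pop$omega2
    centered <- sweep(eta_mat, 2, mean_eta)
    om[free_bsv] <- pmax(colMeans(centered^2) + colMeans(pvar_mat), 1e-6)
    sq <- unlist(lapply(seq_along(split), function(i) {
      f <- emax_effect(ebes[[i]]$params, split[[i]]$exposure_ug_mL)
      ((split[[i]]$value - f) / f)^2
    }))
    b <- max(sqrt(mean(sq)), 1e-4)
    list(theta = th, omega2 = om, b = b)
  }

  blend <- function(pop, prop, gamma) {
    th <- pop$theta
    for (p in free_bsv)
      th[[p]] <- th[[p]] * exp(gamma * log(prop$theta[[p]] / th[[p]]))
    om <- pop$omega2
    om[free_bsv] <- exp((1 - gamma) * log(pop$omega2[free_bsv]) +
                          gamma * log(prop$omega2[free_bsv]))
    b <- exp((1 - gamma) * log(pop$b) + gamma * log(prop$b))
    population_model(th, omega2 = om, b = b, sigmoidicity = pop$sigmoidicity)
  }

  for (iter in seq_len(max_iter)) {
    prop <- propose(pop, cur$ebes)
    gamma <- 1
    accepted <- FALSE
    for (try in 1:5) {
      pop_try <- blend(pop, prop, gamma)
      cand <- ofv_laplace(split, pop_try, warm = cur$ebes)
      if (cand$ofv <= cur$ofv + 1e-8) {
        delta <- cur$ofv - cand$ofv
        pop <- pop_try
        cur <- cand
        trace <- c(trace, cand$ofv)
        accepted <- TRUE
        break
      }
      gamma <- gamma / 2
    }
    if (!accepted) { converged <- TRUE; break }
    if (delta < tol) { converged <- TRUE; break }
  }

  # Final polish: bounded Nelder-Mead on the Laplace OFV over all population
  # parameters — every structural fixed effect (including those carrying no
  # BSV, which the ITS moment updates cannot move), the BSV variances and the
  # error parameter, as log-scaled multiplicative offsets from the ITS
  # solution. Accepted only if it improves the OFV, keeping the trace
  # monotone.
  its_pop <- pop
  est_theta <- c("Emax", "EC50", "E0", if (init$sigmoidicity) "n")
  nt <- length(est_theta)
  np <- length(free_bsv)
  unpack <- function(z) {
    th <- its_pop$theta
    for (i in seq_len(nt)) th[[est_theta[i]]] <- th[[est_theta[i]]] * exp(z[i])
    om <- its_pop$omega2
    om[free_bsv] <- pmax(om[free_bsv] * exp(z[nt + seq_len(np)]), 1e-8)
    b <- max(its_pop$b * exp(z[nt + np + 1L]), 1e-6)
    population_model(th, omega2 = om, b = b,
                     sigmoidicity = its_pop$sigmoidicity)
  }
  warm_env <- new.env()
  warm_env$ebes <- cur$ebes
  polish_obj <- function(z) {
    if (any(abs(z) > 3)) return(1e300)
    res <- tryCatch(ofv_laplace(split, unpack(z), warm = warm_env$ebes),
                    error = function(e) NULL)
    if (is.null(res) || !is.finite(res$ofv)) return(1e300)
    warm_env$ebes <- res$ebes
    res$ofv
  }
  pol <- if (polish_maxit > 0) tryCatch(
    stats::optim(rep(0, nt + np + 1L), polish_obj, method = "Nelder-Mead",
                 control = list(maxit = polish_maxit, reltol = 1e-9)),
    error = function(e) NULL
  ) else NULL
  if (!is.null(pol) && is.finite(pol$value) && pol$value < cur$ofv - 1e-8) {
    pop_pol <- unpack(pol$par)
    cur_pol <- ofv_laplace(split, pop_pol, warm = warm_env$ebes)
    if (cur_pol$ofv <= cur$ofv) {
      pop <- pop_pol
      cur <- cur_pol
      trace <- c(trace, cur$ofv)
      converged <- TRUE
    }
  }

  d <- length(free_bsv)
  # estimated fixed effects + BSV variances + the error parameter
  p_total <- nt + d + 1L
  report <- information_criteria(cur$ofv, p_total, n_subj, n_obs)
  structure(
    list(pop = pop, ebes = ebe_table(split, cur$ebes, pop), report = report,
         ofv_trace = trace, converged = converged, iterations = iter,
         seed = seed, n_subjects = n_subj, n_observations = n_obs),
    class = "population_fit"
  )
}

#' @export
print.population_fit <- function(x, ...) {
  cat("<population_fit> ", x$n_subjects, " subjects, ", x$n_observations,
      " observations, ", x$iterations, " iterations",
      if (x$converged) " (converged)" else " (NOT converged)", "\n", sep = "")
  th <- x$pop$theta
  cat(sprintf("  theta: Emax %.4g, EC50 %.4g, E0 %.4g, n %.4g | b %.4g\n",
              th$Emax, th$EC50, th$E0, th$n, x$pop$b))
  om <- x$pop$omega2[x$pop$omega2 > 0]
  if (length(om))
    cat("  omega2:", paste(sprintf("%s %.4g", names(om), om), collapse = ", "), "\n")
  print(x$report)
  invisible(x)
}
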