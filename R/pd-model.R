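#' Sigmoid Emax structural parameters
#'
#' Parameters of the direct-response model
#' `Effect = Emax * C^n / (EC50^n + C^n) + E0`. `Emax` may take either sign:
#' the measured endpoints here (infundibular cross-sectional area,
#' SC thickness) decrease with exposure, so `Emax` is typically negative.
#' With sigmoidicity disabled, `n` is fixed at 1.
#'
#' @param Emax Maximum drug effect (response units, sign-free).
#' @param EC50 Concentration of half-maximal effect, ug/mL (> 0).
#' @param E0 Baseline response (response units).
#' @param n Hill coefficient (> 0).
#' @return An object of class `emax_params` (named list).
#' @export
emax_params <- function(Emax, EC50, E0, n = 1) {
  if (!is.finite(EC50) || EC50 <= 0) stop("EC50 must be > 0", call. = FALSE)
  if (!is.finite(n) || n <= 0) stop("n must be > 0", call. = FALSE)
  if (!is.finite(Emax) || !is.finite(E0))
    stop("Emax and E0 must be finite", call. = FALSE)
  structure(list(Emax = Emax, EC50 = EC50, E0 = E0, n = n),
            class = "emax_params")
}

#' Evaluate the sigmoid Emax effect
#'
#' `E0 + Emax * c^n / (EC50^n + c^n)`, continuous and monotone in `c` for
#' `Emax` of fixed sign; equals `E0` at `c = 0` and `E0 + Emax/2` at
#' `c = EC50` for every `n`.
#'
#' @param params An [emax_params()] (or named list with `Emax`, `EC50`, `E0`,
#'   `n`).
#' @param c Concentration(s), ug/mL (>= 0).
#' @return Effect in response units.
#' @export
emax_effect <- function(params, c) {
  if (any(!is.finite(c)) || any(c < 0))
    stop("concentration must be finite and >= 0", call. = FALSE)
  cn <- c^params$n
  params$E0 + params$Emax * cn / (params$EC50^params$n + cn)
}

#' Population PD model
#'
#' Combines population fixed effects (an [emax_params()]), log-normal
#' between-subject variability (`theta_i = theta_pop * exp(eta_i)`,
#' `eta_i ~ N(0, omega2)`) and a proportional residual error model
#' `y = f * (1 + b * eps)` with `eps ~ N(0, 1)` (the error exponent is fixed
#' at 1). Parameters with `omega2 = 0` carry no random effect.
#'
#' @param theta An [emax_params()] of population fixed effects.
#' @param omega2 Named numeric vector of BSV variances (log scale, >= 0) for
#'   a subset of `c("Emax", "EC50", "E0", "n")`; omitted names default to 0.
#'   If left at the default, all structural parameters (including `n` when
#'   sigmoidicity is enabled) carry BSV with variance 0.09.
#' @param b Proportional error parameter (> 0).
#' @param sigmoidicity Logical; if `FALSE`, `n` is fixed at 1 and carries no
#'   BSV.
#' @return An object of class `population_model`.
#' @export
population_model <- function(theta, omega2 = NULL, b = 0.1, sigmoidicity = TRUE) {
  if (!inherits(theta, "emax_params")) theta <- do.call(emax_params, theta)
  if (is.null(omega2)) {
    omega2 <- c(Emax = 0.09, EC50 = 0.09, E0 = 0.09)
    if (sigmoidicity) omega2 <- c(omega2, n = 0.09)
  }
  full <- stats::setNames(numeric(4), c("Emax", "EC50", "E0", "n"))
  bad <- setdiff(names(omega2), names(full))
  if (length(bad))
    stop("unknown omega2 name(s): ", paste(bad, collapse = ", "), call. = FALSE)
  full[names(omega2)] <- omega2
  if (any(full < 0)) stop("omega2 entries must be >= 0", call. = FALSE)
  if (!is.finite(b) || b <= 0) stop("b must be > 0", call. = FALSE)
  if (!sigmoidicity) {
    theta$n <- 1
    full["n"] <- 0
  }
  structure(list(theta = theta, omega2 = full, b = b,
                 sigmoidicity = sigmoidicity),
            class = "population_model")
}

#' Individual parameters from population parameters and random effects
#'
#' Applies the log-normal BSV model `theta_i = theta_pop * exp(eta)` for the
#' named entries of `eta`; parameters not named in `eta` are returned
#' unchanged.
#'
#' @param theta An [emax_params()] of population fixed effects.
#' @param eta Named numeric vector of random effects.
#' @return An [emax_params()] with the subject's individual values.
#' @export
individual_params <- function(theta, eta) {
  th <- theta
  for (p in names(eta)) th[[p]] <- unname(theta[[p]] * exp(eta[[p]]))
  th
}

#' Individual -2 log-likelihood under proportional error
#'
#' For a subject with observations `y` at exposures where the structural
#' model predicts `f`, the proportional error model gives
#' `y ~ Normal(f, (b * f)^2)`, hence
#' `-2 * sum(log dnorm(y, f, b * f))`. Predictions must be strictly positive
#' (the proportional error model is undefined at `f <= 0`).
#'
#' @param record Subject record: a list or data frame with `value`
#'   (observations) and `exposure_ug_mL` (matched concentrations).
#' @param params An [emax_params()] (the subject's individual parameters).
#' @param b Proportional error parameter (> 0).
#' @return The subject's -2 log-likelihood (dimensionless).
#' @export
individual_neg2ll <- function(record, params, b) {
  y <- record$value
  f <- emax_effect(params, record$exposure_ug_mL)
  if (any(f <= 0))
    stop("model prediction f <= 0 at an observation: proportional error ",
         "model/data mismatch", call. = FALSE)
  -2 * sum(stats::dnorm(y, mean = f, sd = b * f, log = TRUE))
}

# Negative log joint density of (y, eta): 0.5 * individual_neg2ll plus the
# full log-normal prior terms. The returned closure is the optimization hot
# path: plain vectorized arithmetic, no S3 dispatch or input checking.
subject_joint_fn <- function(record, pop, free) {
  y <- record$value
  ex <- record$exposure_ug_mL
  theta_vec <- c(pop$theta$Emax, pop$theta$EC50, pop$theta$E0, pop$theta$n)
  free_idx <- match(free, c("Emax", "EC50", "E0", "n"))
  om <- pop$omega2[free]
  b <- pop$b
  m <- length(y)
  const <- 0.5 * m * log(2 * pi) + 0.5 * sum(log(2 * pi * om))
  function(eta) {
    th <- theta_vec
    th[free_idx] <- th[free_idx] * exp(eta)
    cn <- ex^th[4]
    f <- th[3] + th[1] * cn / (th[2]^th[4] + cn)
    if (any(f <= 0) || any(!is.finite(f))) return(1e300)
    bf <- b * f
    r <- (y - f) / bf
    v <- 0.5 * sum(r * r) + sum(log(bf)) + const + 0.5 * sum(eta * eta / om)
    if (!is.finite(v)) 1e300 else v
  }
}

# Central-difference Hessian of fn at x (small d).
num_hessian <- function(fn, x, h = 1e-4) {
  d <- length(x)
  H <- matrix(0, d, d)
  for (i in seq_len(d)) {
    for (j in i:d) {
      ei <- ej <- numeric(d); ei[i] <- h; ej[j] <- h
      H[i, j] <- H[j, i] <-
        (fn(x + ei + ej) - fn(x + ei - ej) - fn(x - ei + ej) + fn(x - ei - ej)) /
        (4 * h^2)
    }
  }
  H
}

#' Empirical Bayes (post hoc) estimates for one subject
#'
#' The EBE is the mode of the subject's random-effect posterior: the `eta`
#' minimizing `individual_neg2ll(theta_pop * exp(eta)) + sum(eta^2 / omega2)`
#' over the parameters that carry BSV. Deterministic given its inputs. As
#' `omega2 -> 0` the estimate shrinks to 0 (the population prior dominates);
#' as `omega2` grows it approaches the individual maximum-likelihood
#' estimate.
#'
#' @param record Subject record (see [individual_neg2ll()]).
#' @param pop A [population_model()] with `omega2 > 0` for at least one
#'   parameter.
#' @param eta_start Optional warm-start value for the mode search (defaults
#'   to 0, the prior mean).
#' @return List with `eta` (named vector over BSV parameters), `params` (the
#'   individual [emax_params()]), `posterior_var` (diagonal of the inverse
#'   Laplace Hessian), `neg2ll_joint` (2x the negative log joint at the
#'   mode), `log_det_hessian`, and `converged`.
#' @export
estimate_ebes <- function(record, pop, eta_start = NULL) {
  free <- names(pop$omega2)[pop$omega2 > 0]
  if (!length(free))
    stop("estimate_ebes requires omega2 > 0 for at least one parameter",
         call. = FALSE)
  d <- length(free)
  fn <- subject_joint_fn(record, pop, free)
  x0 <- rep(0, d)
  if (!is.null(eta_start) && length(eta_start) == d && all(is.finite(eta_start)))
    x0 <- as.numeric(eta_start)
  opt <- tryCatch(
    if (d == 1L) {
      o <- stats::optimize(function(e) fn(e), interval = x0 + c(-6, 6),
                           tol = 1e-10)
      list(par = o$minimum, value = o$objective, convergence = 0L)
    } else {
      o <- stats::optim(x0, fn, method = "Nelder-Mead",
                        control = list(maxit = 250, reltol = 1e-10))
      if (is.null(eta_start)) {
        # cold starts get one restart against premature simplex collapse
        o <- stats::optim(o$par, fn, method = "Nelder-Mead",
                          control = list(maxit = 150, reltol = 1e-10))
      }
      o
    },
    error = function(e) NULL
  )
  if (is.null(opt) || !is.finite(opt$value) || opt$value >= 1e300) {
    eta <- stats::setNames(rep(0, d), free)
    return(list(eta = eta, params = individual_params(pop$theta, eta),
                posterior_var = stats::setNames(pop$omega2[free], free),
                neg2ll_joint = 2 * fn(rep(0, d)),
                log_det_hessian = -sum(log(pop$omega2[free])),
                converged = FALSE))
  }
  eta <- stats::setNames(opt$par, free)
  H <- num_hessian(fn, opt$par)
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) {
    # fall back to the prior curvature where the Laplace Hessian is not PD
    H <- diag(1 / pop$omega2[free], d)
    ev <- 1 / pop$omega2[free]
  }
  pvar <- diag(solve(H))
  list(eta = eta,
       params = individual_params(pop$theta, eta),
       posterior_var = stats::setNames(pmax(pvar, 0), free),
       neg2ll_joint = 2 * opt$value,
       log_det_hessian = sum(log(ev)),
       converged = TRUE)
}
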