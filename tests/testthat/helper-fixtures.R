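# Shared fixtures; everything is generated in code.

two_comp_system <- function(V1 = 1, V2 = 1, Kp = 1, P = 1, A = 1, a0 = 10,
                            lag = 0) {
  compartment_system(
    list(compartment("A", V1, initial_amount = a0), compartment("B", V2)),
    list(interface("A", "B", P = P, A = A, Kp = Kp, lag_time = lag))
  )
}

# Random closed linear chain of n compartments (no lags), loaded in the first.
random_chain_system <- function(n, seed) {
  set.seed(seed)
  V <- stats::runif(n, 0.5, 3)
  comps <- lapply(seq_len(n), function(i)
    compartment(paste0("C", i), V[i], initial_amount = if (i == 1) 10 else 0))
  ifcs <- lapply(seq_len(n - 1), function(i)
    interface(paste0("C", i), paste0("C", i + 1),
              P = stats::runif(1, 0.1, 1), A = stats::runif(1, 0.5, 2),
              Kp = stats::runif(1, 0.2, 5)))
  compartment_system(comps, ifcs)
}

# The matrix-exponential solution of a lag-free linear system: independent
# oracle for the ODE integrator (requires Matrix).
expm_solution <- function(system, times) {
  M <- dermapkpd:::transport_matrix(system,
                                    rep(TRUE, length(system$interfaces)))
  y0 <- dermapkpd:::system_initial_amounts(system)
  t(vapply(times, function(t)
    as.vector(Matrix::expm(M * t) %*% y0), numeric(length(y0))))
}

# Naive re-implementation of the six-metric battery, kept deliberately
# independent of compute_metrics().
naive_metrics <- function(p, o) {
  ok <- o > 0
  ok2 <- ok & p > 0
  list(
    rmse = sqrt(sum((p - o)^2) / length(p)),
    mape = 100 * sum(abs((p[ok] - o[ok]) / o[ok])) / sum(ok),
    afe = 10^(sum(log10(p[ok2]) - log10(o[ok2])) / sum(ok2)),
    bias = sum(p - o) / length(p),
    r_squared = 1 - sum((o - p)^2) / sum((o - sum(o) / length(o))^2),
    pearson_r = sum((p - mean(p)) * (o - mean(o))) /
      sqrt(sum((p - mean(p))^2) * sum((o - mean(o))^2))
  )
}

# A rich PD design used by the recovery checks: 13 observations per subject
# and exposures spanning well past the generating EC50, so Emax, the Hill
# coefficient and the BSV variances are all identified. BSV sits on Emax,
# EC50 and E0; the Hill coefficient is estimated as a pure fixed effect.
rich_pd_design <- function(n_subjects = 50) {
  study_design(pd = list(
    n_subjects = n_subjects,
    observation_times = seq(0, 48, 4),
    formulations = c("Differin", "AcneFree", "Effaclar")))
}

rich_pd_exposure <- function() 0.65 * (seq(0, 48, 4) / 48)^1.2

rich_pd_truth <- function() {
  population_model(
    emax_params(Emax = -6000, EC50 = 0.15, E0 = 12000, n = 2),
    omega2 = c(Emax = 0.04, EC50 = 0.09, E0 = 0.04), b = 0.1,
    sigmoidicity = TRUE)
}

# Expensive fits computed at most once per test run.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

big_pd_recovery_fit <- function() {
  cached("big_pd_fit", {
    truth <- rich_pd_truth()
    ex <- rich_pd_exposure()
    gen <- gen_pd_dataset(truth,
                          list(Differin = ex, AcneFree = ex, Effaclar = ex),
                          rich_pd_design(), seed = 7)
    init <- population_model(
      emax_params(Emax = -3500, EC50 = 0.3, E0 = 9000, n = 1.3),
      omega2 = c(Emax = 0.1, EC50 = 0.1, E0 = 0.1), b = 0.2,
      sigmoidicity = TRUE)
    list(truth = truth, gen = gen,
         fit = fit_population(gen$data, init, seed = 1))
  })
}
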