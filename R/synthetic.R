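#' Measurement noise specification
#'
#' Noise and censoring applied by the synthetic-data generators:
#' multiplicative (proportional) noise `x * (1 + cv * eps)`, additive noise
#' `+ sd * eps`, and a limit of quantification below which measured
#' concentrations are recorded as zero (and flagged `bloq`), following the
#' assay convention that below-LOQ values are treated as zero.
#'
#' @param proportional_cv Proportional noise coefficient of variation (>= 0,
#'   default 0.05).
#' @param additive_sd Additive noise SD in measurement units (>= 0).
#' @param loq Limit of quantification in ug/mL (>= 0, default 0.05).
#' @param seed Optional integer seed stored with the spec.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(proportional_cv = 0.05, additive_sd = 0, loq = 0.05,
                       seed = NULL) {
  if (proportional_cv < 0 || additive_sd < 0 || loq < 0)
    stop("cv, sd and loq must be >= 0", call. = FALSE)
  structure(list(proportional_cv = proportional_cv, additive_sd = additive_sd,
                 loq = loq, seed = seed),
            class = "noise_spec")
}

#' Study design for the synthetic datasets
#'
#' Mirrors the experimental designs the generators emulate: 6-replicate IVRT
#' sampling over 24 h, 6-replicate IVPT tissue sampling at 8/12/24/36 h, and
#' a 6-subject clinical PD design observed at baseline, ~5 h (the 4-6 h
#' window) and 48 h.
#'
#' @param ivrt List: `n_replicates`, `sampling_times` (h).
#' @param ivpt List: `n_replicates`, `sampling_times` (h).
#' @param pd List: `n_subjects`, `observation_times` (h), `formulations`
#'   (allocation is round-robin over this vector).
#' @return An object of class `study_design`.
#' @export
study_design <- function(
    ivrt = list(n_replicates = 6,
                sampling_times = c(0.5, 1, 2, 3, 4, 5, 6, 8, 10, 12, 16, 20,
                                   24)),
    ivpt = list(n_replicates = 6, sampling_times = c(8, 12, 24, 36)),
    pd = list(n_subjects = 6, observation_times = c(0, 5, 48),
              formulations = c("Differin", "AcneFree", "Effaclar"))) {
  for (blk in list(ivrt$sampling_times, ivpt$sampling_times,
                   pd$observation_times)) {
    if (any(blk < 0) || is.unsorted(blk, strictly = TRUE))
      stop("design times must be non-negative and strictly increasing",
           call. = FALSE)
  }
  structure(list(ivrt = ivrt, ivpt = ivpt, pd = pd), class = "study_design")
}

# Apply proportional + additive noise, then LOQ censoring (values below loq
# recorded as 0 with a bloq flag). Negative noisy values are clamped to 0
# and flagged bloq as well.
apply_noise <- function(x, noise) {
  n <- length(x)
  y <- x * (1 + noise$proportional_cv * stats::rnorm(n)) +
    noise$additive_sd * stats::rnorm(n)
  y <- pmax(y, 0)
  bloq <- y < noise$loq
  y[bloq] <- 0
  list(value = y, bloq = bloq)
}

#' Generate a synthetic IVRT dataset
#'
#' Simulates the IVRT system under an explicit sample-and-replace protocol:
#' the integration is restarted at every sampling time, with the withdrawn
#' mass (`C * sample_volume`) removed from the receptor and the volume
#' replaced by fresh medium. Per replicate, the sampled receptor
#' concentrations receive proportional/additive noise and below-LOQ
#' censoring, and the cumulative release per area is reconstructed with
#' [sampling_corrected_cumulative()].
#'
#' @param form A [formulation_params()].
#' @param cell A [franz_cell_config()].
#' @param design A [study_design()] (its `ivrt` block is used).
#' @param noise A [noise_spec()].
#' @param seed Integer seed; identical seeds give identical datasets.
#' @return List with `data` (data frame: `formulation`, `replicate`,
#'   `time_h`, `conc_ug_mL`, `bloq`, `cumulative_ug_per_cm2`) and `truth`
#'   (generating parameters, noise-free sampled concentrations and the
#'   noise-free cumulative profile).
#' @export
gen_ivrt_dataset <- function(form, cell, design = study_design(),
                             noise = noise_spec(), seed = 1) {
  set.seed(seed)
  st <- design$ivrt$sampling_times
  sim <- simulate_release_sampled(form, cell, st)
  conc_true <- sim$conc_ug_mL
  q_true <- sim$cumulative_ug_per_cm2

  out <- do.call(rbind, lapply(seq_len(design$ivrt$n_replicates), function(r) {
    nz <- apply_noise(conc_true, noise)
    data.frame(formulation = form$name, replicate = r, time_h = st,
               conc_ug_mL = nz$value, bloq = nz$bloq,
               cumulative_ug_per_cm2 = sampling_corrected_cumulative(nz$value, cell))
  }))
  class(out) <- c("release_profile", "data.frame")
  list(data = out,
       truth = list(form = form, cell = cell, seed = seed,
                    conc_ug_mL = conc_true, cumulative_ug_per_cm2 = q_true,
                    sampling_times = st))
}

#' Generate a synthetic IVPT dataset
#'
#' Simulates the IVPT system once (tissue sampling is destructive, so no
#' sample-and-replace perturbation applies), reads epidermis/dermis
#' accumulation per tissue weight at the design times, applies proportional/
#' additive noise per replicate, and emits per-replicate mass-balance
#' components (residual donor, epidermis, dermis, receptor) whose noise-free
#' recovery is exactly 100 %.
#'
#' @param form A [formulation_params()].
#' @param skin A [skin_config()].
#' @param transport A [skin_transport_params()].
#' @param design A [study_design()] (its `ivpt` block is used).
#' @param noise A [noise_spec()]. The LOQ applies to the receptor
#'   concentration; tissue amounts receive noise only.
#' @param receptor_volume Receptor volume, mL.
#' @param seed Integer seed.
#' @return List with `data` (data frame: `formulation`, `replicate`,
#'   `time_h`, `epidermis_ug_per_mg`, `dermis_ug_per_mg`, `receptor_ug`,
#'   `receptor_bloq`, `donor_ug`, `recovery_pct`) and `truth` (generating
#'   configs and the noise-free series).
#' @export
gen_ivpt_dataset <- function(form, skin, transport, design = study_design(),
                             noise = noise_spec(), receptor_volume = 4.9,
                             seed = 1) {
  set.seed(seed)
  st <- design$ivpt$sampling_times
  sys <- build_ivpt_system(form, skin, transport,
                           receptor_volume = receptor_volume)
  res <- simulate_system(sys, sort(unique(c(0, st))))
  idx <- match(st, res$times)
  acc <- layer_accumulation(res, skin)
  dose <- attr(sys, "ivpt_meta")$dose
  epi_w <- skin$sc_mg + skin$ve_mg
  epi_true <- acc$epidermis_ug_per_mg[idx]
  der_true <- acc$dermis_ug_per_mg[idx]
  rec_true <- acc$receptor_ug[idx]
  donor_true <- res$amounts[idx, "DP"] + res$amounts[idx, "CP"]

  out <- do.call(rbind, lapply(seq_len(design$ivpt$n_replicates), function(r) {
    epi <- apply_noise(epi_true, noise_spec(noise$proportional_cv,
                                            noise$additive_sd, loq = 0))
    der <- apply_noise(der_true, noise_spec(noise$proportional_cv,
                                            noise$additive_sd, loq = 0))
    rec_conc <- apply_noise(rec_true / receptor_volume, noise)
    donor <- apply_noise(donor_true, noise_spec(noise$proportional_cv,
                                                noise$additive_sd, loq = 0))
    data.frame(
      formulation = form$name, replicate = r, time_h = st,
      epidermis_ug_per_mg = epi$value, dermis_ug_per_mg = der$value,
      receptor_ug = rec_conc$value * receptor_volume,
      receptor_bloq = rec_conc$bloq,
      donor_ug = donor$value,
      recovery_pct = percent_recovery(epi$value * epi_w,
                                      der$value * skin$dm_mg,
                                      donor$value,
                                      rec_conc$value * receptor_volume, dose)
    )
  }))
  class(out) <- c("tissue_accumulation", "data.frame")
  list(data = out,
       truth = list(form = form, skin = skin, transport = transport,
                    seed = seed, dose = dose, sampling_times = st,
                    epidermis_ug_per_mg = epi_true,
                    dermis_ug_per_mg = der_true,
                    receptor_ug = rec_true, donor_ug = unname(donor_true),
                    recovery_pct = percent_recovery(
                      epi_true * epi_w, der_true * skin$dm_mg,
                      unname(donor_true), rec_true, dose)))
}

#' Generate a synthetic clinical PD dataset
#'
#' Draws per-subject random effects `eta ~ N(0, omega2)` for every parameter
#' carrying BSV, computes the sigmoid Emax prediction at the subject's
#' formulation exposure, and emits observations `y = f * (1 + b * eps)`
#' (non-positive draws are redrawn). Subjects are allocated to formulations
#' round-robin.
#'
#' @param pop A [population_model()] (the generating truth).
#' @param exposure_per_formulation Named list (by formulation) of data frames
#'   `time_h`, `conc_ug_mL`, or numeric vectors aligned to the design's
#'   observation times.
#' @param design A [study_design()] (its `pd` block is used).
#' @param seed Integer seed.
#' @return List with `data` (a `pd_dataset` data frame: `subject_id`,
#'   `formulation`, `time_h`, `value`, `exposure_ug_mL`) and `truth`
#'   (generating model plus per-subject `eta` and individual parameters).
#' @export
gen_pd_dataset <- function(pop, exposure_per_formulation,
                           design = study_design(), seed = 1) {
  set.seed(seed)
  times <- design$pd$observation_times
  forms <- design$pd$formulations
  free <- names(pop$omega2)[pop$omega2 > 0]
  get_exposure <- function(f) {
    ex <- exposure_per_formulation[[f]]
    if (is.null(ex)) stop("no exposure series for formulation '", f, "'",
                          call. = FALSE)
    if (is.data.frame(ex)) {
      out <- stats::approx(ex$time_h, ex$conc_ug_mL, xout = times, rule = 2)$y
    } else {
      if (length(ex) != length(times))
        stop("exposure vector for '", f, "' must match the observation times",
             call. = FALSE)
      out <- ex
    }
    out
  }
  rows <- list()
  truth_rows <- list()
  for (s in seq_len(design$pd$n_subjects)) {
    f <- forms[((s - 1L) %% length(forms)) + 1L]
    expo <- get_exposure(f)
    # truncated BSV: redraw random effects whose structural prediction is not
    # strictly positive (a negative area or thickness is unphysical)
    for (try in 1:100) {
      eta <- stats::setNames(
        stats::rnorm(length(free), 0, sqrt(pop$omega2[free])), free)
      th_i <- individual_params(pop$theta, eta)
      fpred <- emax_effect(th_i, expo)
      if (all(fpred > 0)) break
    }
    if (any(fpred <= 0))
      stop("could not draw a subject with positive predictions; ",
           "check Emax/E0 and the BSV variances", call. = FALSE)
    y <- fpred * (1 + pop$b * stats::rnorm(length(times)))
    tries <- 0L
    while (any(y <= 0) && tries < 100L) {
      bad <- y <= 0
      y[bad] <- fpred[bad] * (1 + pop$b * stats::rnorm(sum(bad)))
      tries <- tries + 1L
    }
    sid <- sprintf("S%02d", s)
    rows[[s]] <- data.frame(subject_id = sid, formulation = f, time_h = times,
                            value = y, exposure_ug_mL = expo)
    tr <- data.frame(subject_id = sid, formulation = f)
    for (p in free) tr[[paste0("eta_", p)]] <- unname(eta[p])
    for (p in c("Emax", "EC50", "E0", "n")) tr[[p]] <- th_i[[p]]
    truth_rows[[s]] <- tr
  }
  data <- do.call(rbind, rows)
  class(data) <- c("pd_dataset", "data.frame")
  list(data = data,
       truth = list(pop = pop, seed = seed,
                    subjects = do.call(rbind, truth_rows)))
}
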