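#' Formulation parameters for a two-phase gel
#'
#' The gel donor is modeled as two phases: discrete solid drug particles
#' suspended in a viscous, polymer-like continuous phase. Drug release is
#' diffusion from the discrete phase (DP) into the continuous phase (CP) and
#' onward through the membrane (IVRT) or into the skin (IVPT). An explicit
#' lag on the DP -> CP interface captures delayed release onset that
#' permeability/partitioning alone cannot reproduce.
#'
#' @param name Formulation identifier.
#' @param drug_mass_fraction Drug mass fraction of the gel (w/w), e.g. 0.001
#'   for a 0.1 % gel.
#' @param applied_mass Applied gel mass in mg.
#' @param density_discrete,density_continuous Phase densities in g/cm3.
#' @param fraction_discrete Mass fraction of the gel in the discrete phase
#'   (0-1). Default 0.01: the suspended drug particles are a trace phase.
#' @param Kp_dp_cp Partition coefficient CP relative to DP.
#' @param P_dp_cp Permeability of the DP -> CP interface, cm/h.
#' @param A_dp_cp Exchange area of the DP -> CP interface, cm2. The product
#'   `P_dp_cp * A_dp_cp` is what the dynamics see; `A_dp_cp` is fixed at
#'   1 cm2 by default and `P_dp_cp` carries the calibration.
#' @param release_lag Release lag time in h.
#' @return An object of class `formulation_params`.
#' @export
formulation_params <- function(name,
                               drug_mass_fraction = 0.001,
                               applied_mass = 500,
                               density_discrete = 1.3,
                               density_continuous = 1.0,
                               fraction_discrete = 0.01,
                               Kp_dp_cp = 8.5e-6,
                               P_dp_cp = 2.9e-6,
                               A_dp_cp = 1,
                               release_lag = 0) {
  if (!is.finite(drug_mass_fraction) || drug_mass_fraction <= 0 ||
      drug_mass_fraction >= 1)
    stop("drug_mass_fraction must be in (0, 1)", call. = FALSE)
  if (fraction_discrete < 0 || fraction_discrete > 1)
    stop("fraction_discrete must be in [0, 1]", call. = FALSE)
  if (density_discrete <= 0 || density_continuous <= 0)
    stop("densities must be > 0", call. = FALSE)
  if (applied_mass < 0) stop("applied_mass must be >= 0", call. = FALSE)
  structure(
    list(name = name, drug_mass_fraction = drug_mass_fraction,
         applied_mass = applied_mass, density_discrete = density_discrete,
         density_continuous = density_continuous,
         fraction_discrete = fraction_discrete, Kp_dp_cp = Kp_dp_cp,
         P_dp_cp = P_dp_cp, A_dp_cp = A_dp_cp, release_lag = release_lag),
    class = "formulation_params"
  )
}

#' Franz diffusion cell configuration (IVRT)
#'
#' @param receptor_volume Receptor chamber volume, mL.
#' @param orifice_area Diffusional orifice area, cm2.
#' @param membrane_thickness Synthetic membrane thickness, cm.
#' @param membrane_porosity Membrane porosity (0-1]; the accessible membrane
#'   volume is `area * thickness * porosity`.
#' @param membrane_permeability Permeability of the donor/membrane and
#'   membrane/receptor interfaces, cm/h. The inert cellulose membrane is
#'   treated as non-selective (`membrane_partition = 1`).
#' @param membrane_partition Partition coefficient membrane vs donor (and its
#'   reciprocal receptor vs membrane), default 1.
#' @param sample_volume Withdrawn (and replaced) sample volume per time
#'   point, mL.
#' @param sampling_times Sampling schedule in h.
#' @return An object of class `franz_cell_config`.
#' @export
franz_cell_config <- function(receptor_volume = 5.1,
                              orifice_area = 0.69,
                              membrane_thickness = 0.0025,
                              membrane_porosity = 0.7,
                              membrane_permeability = 0.5,
                              membrane_partition = 1,
                              sample_volume = 0.5,
                              sampling_times = c(0.5, 1, 2, 3, 4, 5, 6, 8, 10,
                                                 12, 16, 20, 24)) {
  if (receptor_volume <= 0) stop("receptor_volume must be > 0", call. = FALSE)
  if (orifice_area <= 0) stop("orifice_area must be > 0", call. = FALSE)
  if (membrane_porosity <= 0 || membrane_porosity > 1)
    stop("membrane_porosity must be in (0, 1]", call. = FALSE)
  if (sample_volume < 0 || sample_volume >= receptor_volume)
    stop("sample_volume must be in [0, receptor_volume)", call. = FALSE)
  structure(
    list(receptor_volume = receptor_volume, orifice_area = orifice_area,
         membrane_thickness = membrane_thickness,
         membrane_porosity = membrane_porosity,
         membrane_permeability = membrane_permeability,
         membrane_partition = membrane_partition,
         sample_volume = sample_volume, sampling_times = sampling_times),
    class = "franz_cell_config"
  )
}

#' Initial drug mass loaded in the donor
#'
#' `applied_mass (mg) * drug_mass_fraction`, returned in ug. 500 mg of a
#' 0.1 % w/w gel loads 500 ug. All drug is initially placed in the discrete
#' phase (suspended micronized drug).
#'
#' @param applied_mass Applied gel mass, mg (>= 0).
#' @param drug_mass_fraction Drug mass fraction (0-1 exclusive).
#' @return Initial drug mass, ug.
#' @export
initial_drug_mass <- function(applied_mass, drug_mass_fraction) {
  if (!is.finite(applied_mass) || applied_mass < 0)
    stop("applied_mass must be >= 0", call. = FALSE)
  if (!is.finite(drug_mass_fraction) || drug_mass_fraction <= 0 ||
      drug_mass_fraction >= 1)
    stop("drug_mass_fraction must be in (0, 1)", call. = FALSE)
  applied_mass * drug_mass_fraction * 1000
}

# Gel phase volumes (mL) from applied mass (mg), phase mass fractions and
# densities (g/cm3). A zero applied mass keeps nominal (1 mg) phase volumes
# so the system stays well-posed; its drug load is zero either way.
gel_phase_volumes <- function(form) {
  m_g <- max(form$applied_mass, 1) / 1000  # g
  c(dp = m_g * form$fraction_discrete / form$density_discrete,
    cp = m_g * (1 - form$fraction_discrete) / form$density_continuous)
}

#' Build the IVRT compartment system
#'
#' Four compartments: donor discrete phase (DP), donor continuous phase (CP),
#' synthetic membrane (MEM, volume = orifice area x thickness x porosity),
#' and receptor (REC). Interfaces: DP -> CP (carrying the release lag),
#' CP -> MEM, MEM -> REC. When `fraction_discrete` is 0 or 1 one gel phase has
#' zero volume and the system collapses to a 3-compartment variant (with a
#' warning); all drug then starts in the single remaining gel phase.
#'
#' @param form A [formulation_params()].
#' @param cell A [franz_cell_config()].
#' @return A [compartment_system()] with attribute `ivrt_meta` (dose,
#'   orifice area, formulation name).
#' @export
build_ivrt_system <- function(form, cell) {
  dose <- initial_drug_mass(form$applied_mass, form$drug_mass_fraction)
  vol <- gel_phase_volumes(form)
  v_mem <- cell$orifice_area * cell$membrane_thickness * cell$membrane_porosity
  mem <- compartment("MEM", v_mem)
  rec <- compartment("REC", cell$receptor_volume)
  kp_m <- cell$membrane_partition
  if (form$fraction_discrete %in% c(0, 1)) {
    warning("fraction_discrete is ", form$fraction_discrete,
            ": collapsing to a 3-compartment (single gel phase) system",
            call. = FALSE)
    single <- if (form$fraction_discrete == 0)
      compartment("CP", vol[["cp"]], initial_amount = dose)
    else
      compartment("DP", vol[["dp"]], initial_amount = dose)
    sys <- compartment_system(
      list(single, mem, rec),
      list(
        interface(single$name, "MEM", P = cell$membrane_permeability,
                  A = cell$orifice_area, Kp = kp_m,
                  lag_time = if (form$fraction_discrete == 1) form$release_lag else 0),
        interface("MEM", "REC", P = cell$membrane_permeability,
                  A = cell$orifice_area, Kp = 1 / kp_m)
      ),
      closed = TRUE
    )
  } else {
    sys <- compartment_system(
      list(
        compartment("DP", vol[["dp"]], initial_amount = dose,
                    density = form$density_discrete),
        compartment("CP", vol[["cp"]], density = form$density_continuous),
        mem, rec
      ),
      list(
        interface("DP", "CP", P = form$P_dp_cp, A = form$A_dp_cp,
                  Kp = form$Kp_dp_cp, lag_time = form$release_lag),
        interface("CP", "MEM", P = cell$membrane_permeability,
                  A = cell$orifice_area, Kp = kp_m),
        interface("MEM", "REC", P = cell$membrane_permeability,
                  A = cell$orifice_area, Kp = 1 / kp_m)
      ),
      closed = TRUE
    )
  }
  attr(sys, "ivrt_meta") <- list(dose = dose, orifice_area = cell$orifice_area,
                                 formulation = form$name)
  sys
}

#' Simulate cumulative release per membrane area
#'
#' Runs the IVRT system and converts the receptor amount to the cumulative
#' amount released per cm2 of membrane: `Q(t) = REC(t) / orifice_area`.
#'
#' @param system A system from [build_ivrt_system()].
#' @param times Output time grid in h starting at 0.
#' @param ... Passed to [simulate_system()].
#' @return A `release_profile` data frame with columns `formulation`,
#'   `time_h`, `cumulative_ug_per_cm2`.
#' @export
simulate_release <- function(system, times, ...) {
  meta <- attr(system, "ivrt_meta")
  if (is.null(meta))
    stop("simulate_release expects a system built by build_ivrt_system()",
         call. = FALSE)
  res <- simulate_system(system, times, ...)
  q <- res$amounts[, "REC"] / meta$orifice_area
  out <- data.frame(formulation = meta$formulation, time_h = times,
                    cumulative_ug_per_cm2 = unname(q))
  class(out) <- c("release_profile", "data.frame")
  attr(out, "simulation") <- res
  out
}

#' Simulate the IVRT protocol with explicit sample-and-replace withdrawals
#'
#' Integrates the IVRT system piecewise between sampling times; at each
#' sampling time the receptor concentration is recorded and the withdrawn
#' mass (`C * sample_volume`) is removed, emulating replacement with fresh
#' medium. This is the protocol-faithful counterpart of
#' [simulate_release()] and the forward model behind both the synthetic-data
#' generator and the release calibration.
#'
#' @param form A [formulation_params()].
#' @param cell A [franz_cell_config()].
#' @param times Sampling times in h (> 0, strictly increasing); defaults to
#'   `cell$sampling_times`.
#' @return List with `times`, `conc_ug_mL` (receptor concentration at each
#'   sampling time, before withdrawal), `cumulative_ug_per_cm2` (the
#'   sample-and-replace corrected cumulative release) and `amounts`
#'   (time x compartment matrix of pre-withdrawal amounts, ug).
#' @export
simulate_release_sampled <- function(form, cell, times = cell$sampling_times) {
  if (any(times <= 0) || is.unsorted(times, strictly = TRUE))
    stop("sampling times must be positive and strictly increasing",
         call. = FALSE)
  sys <- build_ivrt_system(form, cell)
  nm <- system_names(sys)
  y <- system_initial_amounts(sys)
  conc <- numeric(length(times))
  amounts <- matrix(NA_real_, length(times), length(nm),
                    dimnames = list(NULL, nm))
  t_prev <- 0
  for (i in seq_along(times)) {
    sys_i <- sys
    # shift lag gates into segment-local time
    sys_i$interfaces <- lapply(sys$interfaces, function(ifc) {
      ifc$lag_time <- max(ifc$lag_time - t_prev, 0)
      ifc
    })
    for (k in seq_along(sys_i$compartments))
      sys_i$compartments[[k]]$initial_amount <- unname(y[nm[k]])
    res <- simulate_system(sys_i, c(0, times[i] - t_prev))
    y <- res$amounts[nrow(res$amounts), ]
    names(y) <- nm
    amounts[i, ] <- y
    conc[i] <- y["REC"] / cell$receptor_volume
    y["REC"] <- y["REC"] * (1 - cell$sample_volume / cell$receptor_volume)
    t_prev <- times[i]
  }
  list(times = times, conc_ug_mL = conc,
       cumulative_ug_per_cm2 = sampling_corrected_cumulative(conc, cell),
       amounts = amounts)
}

#' Reconstruct cumulative release from sampled receptor concentrations
#'
#' Under a sample-and-replace protocol (a fixed volume withdrawn and replaced
#' with fresh medium at each time point), the cumulative amount released per
#' area is `Q(t_n) = (C_n * V_receptor + sum_{i<n} C_i * V_sample) / A`:
#' mass currently in the receptor plus mass already carried away in earlier
#' samples.
#'
#' @param conc Receptor concentrations (ug/mL) at the sampling times, in time
#'   order.
#' @param cell A [franz_cell_config()] providing `receptor_volume`,
#'   `sample_volume` and `orifice_area`.
#' @return Cumulative amounts per area (ug/cm2), one per sampling time.
#' @export
sampling_corrected_cumulative <- function(conc, cell) {
  if (any(!is.finite(conc)) || any(conc < 0))
    stop("concentrations must be finite and >= 0", call. = FALSE)
  withdrawn <- c(0, cumsum(conc * cell$sample_volume))[seq_along(conc)]
  (conc * cell$receptor_volume + withdrawn) / cell$orifice_area
}

#' Write a release profile as CSV
#'
#' Columns: `formulation`, `replicate` (if present), `time_h`,
#' `cumulative_ug_per_cm2`.
#'
#' @param profile A `release_profile` data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_release_csv <- function(profile, path) {
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE)
  invisible(path)
}

#' Shipped example formulations
#'
#' Three synthetic example parameter sets for 0.1 % adapalene gels, ordered
#' fastest-to-slowest in early release (Differin > AcneFree > Effaclar) with
#' release lags of 0, 4 and 6 h and cumulative 24-h release of a few ug/cm2
#' (well under 1 % of the dose, as expected for a highly lipophilic drug
#' with very low solubility in the aqueous continuous phase; receptor
#' concentrations stay below the 0.05 ug/mL LOQ for the first hours and
#' become quantifiable mid-study). The release-kinetic values are synthetic
#' placeholders intended as
#' calibration starting points and test fixtures, not measured properties of
#' the marketed products.
#'
#' @return Named list of three [formulation_params()].
#' @export
default_formulations <- function() {
  list(
    Differin = formulation_params("Differin", P_dp_cp = 2.9e-6,
                                  Kp_dp_cp = 8.5e-6, release_lag = 0),
    AcneFree = formulation_params("AcneFree", P_dp_cp = 2.4e-6,
                                  Kp_dp_cp = 7.0e-6, release_lag = 4),
    Effaclar = formulation_params("Effaclar", P_dp_cp = 2.7e-6,
                                  Kp_dp_cp = 7.7e-6, release_lag = 6)
  )
}
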