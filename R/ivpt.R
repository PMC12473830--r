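#' Skin physiology configuration
#'
#' Layer thicknesses, densities and exposed area of the dermatomed-skin IVPT
#' setup. Tissue weights are derived as `thickness x area x density`. The
#' default split (SC 12 um, VE 53 um, DM 735 um over a 0.69 cm2 orifice, with
#' epidermis density 1.2 g/cm3 and dermis density 1.5 g/cm3) reproduces
#' tissue weights of about 1 mg (SC), 4.4 mg (VE) and 75 mg (DM) at a total
#' thickness of 800 um.
#'
#' @param total_thickness Total skin thickness, um.
#' @param sc_thickness,ve_thickness,dm_thickness Layer thicknesses, um. Must
#'   sum to `total_thickness` within 2 %.
#' @param epidermis_density Density of SC and VE, g/cm3.
#' @param dermis_density Density of DM, g/cm3.
#' @param area Exposed skin area, cm2.
#' @param sebum_volume Sebum (pilosebaceous) compartment volume, mL. Default
#'   `NULL` uses 0.1 % of the SC volume, consistent with hair follicles
#'   occupying at most 0.1 % of the skin surface area.
#' @return An object of class `skin_config` with derived fields `sc_volume`,
#'   `ve_volume`, `dm_volume` (mL) and `sc_mg`, `ve_mg`, `dm_mg` (mg).
#' @export
skin_config <- function(total_thickness = 800,
                        sc_thickness = 12,
                        ve_thickness = 53,
                        dm_thickness = 735,
                        epidermis_density = 1.2,
                        dermis_density = 1.5,
                        area = 0.69,
                        sebum_volume = NULL) {
  if (any(c(sc_thickness, ve_thickness, dm_thickness, total_thickness) <= 0))
    stop("thicknesses must be > 0", call. = FALSE)
  s <- sc_thickness + ve_thickness + dm_thickness
  if (abs(s - total_thickness) / total_thickness > 0.02)
    stop("layer thicknesses (", s, " um) must sum to total_thickness (",
         total_thickness, " um) within 2%", call. = FALSE)
  if (epidermis_density <= 0 || dermis_density <= 0)
    stop("densities must be > 0", call. = FALSE)
  if (area <= 0) stop("area must be > 0", call. = FALSE)
  um_to_cm <- 1e-4
  sc_volume <- sc_thickness * um_to_cm * area
  ve_volume <- ve_thickness * um_to_cm * area
  dm_volume <- dm_thickness * um_to_cm * area
  if (is.null(sebum_volume)) sebum_volume <- 0.001 * sc_volume
  if (sebum_volume <= 0) stop("sebum_volume must be > 0", call. = FALSE)
  structure(
    list(total_thickness = total_thickness, sc_thickness = sc_thickness,
         ve_thickness = ve_thickness, dm_thickness = dm_thickness,
         epidermis_density = epidermis_density, dermis_density = dermis_density,
         area = area, sebum_volume = sebum_volume,
         sc_volume = sc_volume, ve_volume = ve_volume, dm_volume = dm_volume,
         sc_mg = sc_volume * epidermis_density * 1000,
         ve_mg = ve_volume * epidermis_density * 1000,
         dm_mg = dm_volume * dermis_density * 1000),
    class = "skin_config"
  )
}

# Interface keys of the IVPT skin model, in build order. dp_cp carries the
# formulation release parameters and is not part of skin transport.
ivpt_interface_keys <- function() {
  c("cp_sc", "cp_sb", "sb_sc", "sb_ve", "sb_dm", "sc_ve", "ve_dm", "dm_rec")
}

# Interfaces whose partition coefficients are calibratable in the skin stage:
# gel continuous phase -> SC lipids, and every DM-involving interface.
skin_calibratable_kps <- function() c("cp_sc", "ve_dm", "sb_dm", "dm_rec")

#' Skin transport parameters
#'
#' Permeability and partition coefficients for the eight transport interfaces
#' of the IVPT skin model: CP->SC, CP->SB, SB->SC, SB->VE, SB->DM, SC->VE,
#' VE->DM, DM->REC. Only the CP->SC partition coefficient and the partition
#' coefficients at DM-involving interfaces (VE->DM, SB->DM, DM->REC) are
#' calibratable in the skin stage; all other parameters stay fixed.
#'
#' Defaults are synthetic placeholders for a highly lipophilic drug:
#' favorable partitioning into the lipid-rich SC, unfavorable egress into the
#' aqueous viable tissue, and minimal receptor permeation.
#'
#' @param ... Named overrides, e.g. `cp_sc = list(P = 0.02, Kp = 40)` or a
#'   partial `list(Kp = 40)` merged over the default.
#' @return An object of class `skin_transport_params`: a named list with
#'   entries `list(P =, Kp =)` per interface.
#' @export
skin_transport_params <- function(...) {
  defaults <- list(
    cp_sc  = list(P = 0.030,  Kp = 2000),
    cp_sb  = list(P = 0.005,  Kp = 2000),
    sb_sc  = list(P = 0.010,  Kp = 1),
    sb_ve  = list(P = 0.001,  Kp = 0.01),
    sb_dm  = list(P = 0.0005, Kp = 0.005),
    sc_ve  = list(P = 0.005,  Kp = 0.01),
    ve_dm  = list(P = 0.010,  Kp = 0.5),
    dm_rec = list(P = 0.0005, Kp = 0.1)
  )
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad))
    stop("unknown transport interface(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  for (k in names(over)) {
    for (f in names(over[[k]])) {
      if (!f %in% c("P", "Kp"))
        stop("transport entry '", k, "' may only set P and Kp", call. = FALSE)
      defaults[[k]][[f]] <- over[[k]][[f]]
    }
  }
  for (k in names(defaults)) {
    if (!is.finite(defaults[[k]]$P) || defaults[[k]]$P < 0)
      stop("transport '", k, "': P must be finite and >= 0", call. = FALSE)
    if (!is.finite(defaults[[k]]$Kp) || defaults[[k]]$Kp <= 0)
      stop("transport '", k, "': Kp must be finite and > 0", call. = FALSE)
  }
  structure(defaults, class = "skin_transport_params")
}

#' Build the IVPT compartment system
#'
#' Seven compartments: gel discrete phase (DP), gel continuous phase (CP),
#' stratum corneum (SC), sebum (SB), viable epidermis (VE), dermis (DM) and
#' receptor (REC). Nine interfaces: DP->CP (formulation release, with lag),
#' CP->SC, CP->SB, SB->SC, SB->VE, SB->DM, SC->VE, VE->DM, DM->REC. The
#' CP->SB feed enters through the follicular openings, taken as 0.1 % of the
#' exposed area; the deeper sebum exchanges use the same follicular area.
#' The system is closed (dermatomed skin: DM->REC is the only exit, no
#' systemic clearance).
#'
#' @param form A [formulation_params()].
#' @param skin A [skin_config()].
#' @param transport A [skin_transport_params()].
#' @param receptor_volume Receptor chamber volume, mL (default 4.9).
#' @return A [compartment_system()] with attribute `ivpt_meta`.
#' @export
build_ivpt_system <- function(form, skin, transport, receptor_volume = 4.9) {
  if (!inherits(transport, "skin_transport_params"))
    stop("transport must be a skin_transport_params object", call. = FALSE)
  missing <- setdiff(ivpt_interface_keys(), names(transport))
  if (length(missing))
    stop("missing transport parameters for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  dose <- initial_drug_mass(form$applied_mass, form$drug_mass_fraction)
  vol <- gel_phase_volumes(form)
  a_skin <- skin$area
  a_foll <- 0.001 * skin$area
  tp <- transport
  sys <- compartment_system(
    list(
      compartment("DP", vol[["dp"]], initial_amount = dose,
                  density = form$density_discrete),
      compartment("CP", vol[["cp"]], density = form$density_continuous),
      compartment("SC", skin$sc_volume, density = skin$epidermis_density),
      compartment("SB", skin$sebum_volume),
      compartment("VE", skin$ve_volume, density = skin$epidermis_density),
      compartment("DM", skin$dm_volume, density = skin$dermis_density),
      compartment("REC", receptor_volume)
    ),
    list(
      interface("DP", "CP", P = form$P_dp_cp, A = form$A_dp_cp,
                Kp = form$Kp_dp_cp, lag_time = form$release_lag),
      interface("CP", "SC", P = tp$cp_sc$P, A = a_skin, Kp = tp$cp_sc$Kp),
      interface("CP", "SB", P = tp$cp_sb$P, A = a_foll, Kp = tp$cp_sb$Kp),
      interface("SB", "SC", P = tp$sb_sc$P, A = a_foll, Kp = tp$sb_sc$Kp),
      interface("SB", "VE", P = tp$sb_ve$P, A = a_foll, Kp = tp$sb_ve$Kp),
      interface("SB", "DM", P = tp$sb_dm$P, A = a_foll, Kp = tp$sb_dm$Kp),
      interface("SC", "VE", P = tp$sc_ve$P, A = a_skin, Kp = tp$sc_ve$Kp),
      interface("VE", "DM", P = tp$ve_dm$P, A = a_skin, Kp = tp$ve_dm$Kp),
      interface("DM", "REC", P = tp$dm_rec$P, A = a_skin, Kp = tp$dm_rec$Kp)
    ),
    closed = TRUE
  )
  attr(sys, "ivpt_meta") <- list(dose = dose, formulation = form$name,
                                 skin = skin)
  sys
}

#' Tissue accumulation per unit tissue weight
#'
#' Converts an IVPT simulation into the quantities the wet-lab assay reports:
#' the skin is mechanically separated into epidermis (SC + viable epidermis)
#' and dermis, so the epidermis series is `(SC + VE [+ SB]) / (sc_mg + ve_mg)`
#' in ug/mg and the dermis series `DM / dm_mg`. The sebum/follicle amount
#' cannot be isolated by mechanical separation; by default it is assigned to
#' the epidermis fraction (the infundibulum opens at the epidermal level),
#' configurable to `"dermis"` or `"none"`.
#'
#' @param result A `simulation_result` from an IVPT system.
#' @param skin A [skin_config()].
#' @param sebum_to Where the sebum amount is counted: `"epidermis"`
#'   (default), `"dermis"`, or `"none"`.
#' @return A `tissue_accumulation` data frame: `formulation`, `time_h`,
#'   `epidermis_ug_per_mg`, `dermis_ug_per_mg`, `receptor_ug`.
#' @export
layer_accumulation <- function(result, skin,
                               sebum_to = c("epidermis", "dermis", "none")) {
  sebum_to <- match.arg(sebum_to)
  need <- c("SC", "VE", "DM", "REC")
  if (!all(need %in% colnames(result$amounts)))
    stop("result does not look like an IVPT simulation (missing ",
         paste(setdiff(need, colnames(result$amounts)), collapse = ", "), ")",
         call. = FALSE)
  if (skin$sc_mg + skin$ve_mg <= 0 || skin$dm_mg <= 0)
    stop("tissue weights must be > 0", call. = FALSE)
  sb <- if ("SB" %in% colnames(result$amounts)) result$amounts[, "SB"] else 0
  epi <- result$amounts[, "SC"] + result$amounts[, "VE"] +
    if (sebum_to == "epidermis") sb else 0
  der <- result$amounts[, "DM"] + if (sebum_to == "dermis") sb else 0
  meta <- attr(result$system, "ivpt_meta")
  out <- data.frame(
    formulation = if (is.null(meta)) NA_character_ else meta$formulation,
    time_h = result$times,
    epidermis_ug_per_mg = unname(epi) / (skin$sc_mg + skin$ve_mg),
    dermis_ug_per_mg = unname(der) / skin$dm_mg,
    receptor_ug = unname(result$amounts[, "REC"])
  )
  class(out) <- c("tissue_accumulation", "data.frame")
  out
}

#' Percent recovery (mass balance)
#'
#' `100 * (epidermis + dermis + remaining_donor + receptor) / dose`. On a
#' simulated closed system this is identically 100 %; in the wet lab it
#' quantifies assay mass balance.
#'
#' @param epidermis,dermis,remaining_donor,receptor Amounts in ug (>= 0;
#'   vectorized).
#' @param dose Applied dose in ug (> 0).
#' @return Percent recovery.
#' @export
percent_recovery <- function(epidermis, dermis, remaining_donor, receptor, dose) {
  if (any(!is.finite(dose)) || any(dose <= 0))
    stop("dose must be > 0", call. = FALSE)
  comp <- cbind(epidermis, dermis, remaining_donor, receptor)
  if (any(!is.finite(comp)) || any(comp < 0))
    stop("recovery components must be finite and >= 0", call. = FALSE)
  100 * (epidermis + dermis + remaining_donor + receptor) / dose
}

#' Stratum corneum concentration series
#'
#' SC amount divided by SC volume at each simulated time, in ug/mL. This is
#' the exposure driver for the SC-thickness pharmacodynamic endpoint.
#'
#' @param result A `simulation_result` from an IVPT system.
#' @param skin A [skin_config()].
#' @return Data frame `time_h`, `conc_ug_mL`.
#' @export
sc_concentration <- function(result, skin) {
  if (!"SC" %in% colnames(result$amounts))
    stop("result has no SC compartment", call. = FALSE)
  data.frame(time_h = result$times,
             conc_ug_mL = unname(result$amounts[, "SC"]) / skin$sc_volume)
}

#' Infundibular concentration from SC concentration
#'
#' The infundibular (follicular opening) exposure is taken as 0.1 % of the SC
#' concentration, consistent with hair follicles occupying at most 0.1 % of
#' the skin surface area. This is the exposure driver for the
#' infundibular-area pharmacodynamic endpoint.
#'
#' @param c_sc SC concentration(s), ug/mL (>= 0).
#' @return `0.001 * c_sc`, ug/mL.
#' @export
infundibular_concentration <- function(c_sc) {
  if (any(!is.finite(c_sc)) || any(c_sc < 0))
    stop("c_sc must be finite and >= 0", call. = FALSE)
  0.001 * c_sc
}

#' Write a tissue accumulation table as CSV
#'
#' Columns: `formulation`, `replicate` (if present), `time_h`,
#' `epidermis_ug_per_mg`, `dermis_ug_per_mg`, `receptor_ug`.
#'
#' @param accum A `tissue_accumulation` data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_accumulation_csv <- function(accum, path) {
  utils::write.csv(as.data.frame(accum), path, row.names = FALSE)
  invisible(path)
}
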