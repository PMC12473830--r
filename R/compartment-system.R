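#' Define a compartment
#'
#' A compartment is a well-mixed volume holding a drug amount. The state
#' variable throughout the package is amount (ug), so that mass balance is a
#' direct sum over compartments; concentrations are derived as amount/volume.
#'
#' @param name Compartment identifier, unique within a system.
#' @param volume Compartment volume in mL (> 0).
#' @param initial_amount Initial drug amount in ug (>= 0).
#' @param density Optional tissue density in g/cm3, used for per-weight
#'   normalization of tissue accumulation.
#' @return An object of class `compartment`.
#' @export
compartment <- function(name, volume, initial_amount = 0, density = NA_real_) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.finite(volume) || volume <= 0)
    stop("compartment '", name, "': volume must be finite and > 0", call. = FALSE)
  if (!is.finite(initial_amount) || initial_amount < 0)
    stop("compartment '", name, "': initial_amount must be finite and >= 0",
         call. = FALSE)
  structure(
    list(name = name, volume = volume, initial_amount = initial_amount,
         density = density),
    class = "compartment"
  )
}

#' Define a transport interface between two compartments
#'
#' Transport across an interface follows the generalized flux law
#' `J = P * A * (C_source - C_target / Kp)` (ug/h), which is physically
#' bidirectional: the sign of the driving force sets the direction. At steady
#' state the concentration ratio `C_target / C_source` equals `Kp`. The flux
#' is gated to zero for `t < lag_time`.
#'
#' @param source,target Names of the connected compartments.
#' @param P Permeability coefficient in cm/h (>= 0).
#' @param A Exchange area in cm2 (> 0).
#' @param Kp Partition coefficient, target relative to source (> 0).
#' @param lag_time Lag time in h (>= 0); flux is identically zero before it.
#' @return An object of class `interface`.
#' @export
interface <- function(source, target, P, A, Kp = 1, lag_time = 0) {
  stopifnot(is.character(source), is.character(target))
  if (source == target)
    stop("interface cannot connect a compartment to itself", call. = FALSE)
  if (!is.finite(P) || P < 0) stop("P must be finite and >= 0", call. = FALSE)
  if (!is.finite(A) || A <= 0) stop("A must be finite and > 0", call. = FALSE)
  if (!is.finite(Kp) || Kp <= 0) stop("Kp must be finite and > 0", call. = FALSE)
  if (!is.finite(lag_time) || lag_time < 0)
    stop("lag_time must be finite and >= 0", call. = FALSE)
  structure(
    list(source = source, target = target, P = P, A = A, Kp = Kp,
         lag_time = lag_time),
    class = "interface"
  )
}

#' Assemble a compartment system
#'
#' @param compartments List of [compartment()] objects (order is preserved).
#' @param interfaces List of [interface()] objects. At most one interface is
#'   allowed per unordered compartment pair (the flux law is bidirectional, so
#'   a reverse interface would double-count transport).
#' @param closed Logical; `TRUE` (default) declares the system mass-closed,
#'   enabling conservation checks.
#' @return An object of class `compartment_system`.
#' @export
compartment_system <- function(compartments, interfaces = list(), closed = TRUE) {
  stopifnot(is.list(compartments), length(compartments) >= 1L)
  nm <- vapply(compartments, function(x) x$name, character(1))
  if (anyDuplicated(nm))
    stop("compartment names must be unique: ", paste(nm[duplicated(nm)], collapse = ", "),
         call. = FALSE)
  for (ifc in interfaces) {
    if (!ifc$source %in% nm || !ifc$target %in% nm)
      stop("interface ", ifc$source, " -> ", ifc$target,
           " references an unknown compartment", call. = FALSE)
  }
  pairs <- vapply(interfaces, function(i) paste(sort(c(i$source, i$target)), collapse = "|"),
                  character(1))
  if (anyDuplicated(pairs))
    stop("at most one interface per compartment pair is allowed", call. = FALSE)
  structure(
    list(compartments = compartments, interfaces = interfaces, closed = closed),
    class = "compartment_system"
  )
}

#' @export
print.compartment_system <- function(x, ...) {
  cat("<compartment_system> ", length(x$compartments), " compartments, ",
      length(x$interfaces), " interfaces, ",
      if (isTRUE(x$closed)) "closed" else "open", "\n", sep = "")
  for (cp in x$compartments)
    cat(sprintf("  %-6s V = %.6g mL, A0 = %.6g ug\n", cp$name, cp$volume,
                cp$initial_amount))
  for (ifc in x$interfaces)
    cat(sprintf("  %s -> %s: P = %.4g cm/h, A = %.4g cm2, Kp = %.4g, lag = %.3g h\n",
                ifc$source, ifc$target, ifc$P, ifc$A, ifc$Kp, ifc$lag_time))
  invisible(x)
}

system_names <- function(system) vapply(system$compartments, `[[`, character(1), "name")
system_volumes <- function(system) {
  v <- vapply(system$compartments, `[[`, numeric(1), "volume")
  names(v) <- system_names(system)
  v
}
system_initial_amounts <- function(system) {
  a <- vapply(system$compartments, `[[`, numeric(1), "initial_amount")
  names(a) <- system_names(system)
  a
}

#' Serialize a compartment system to JSON
#'
#' The JSON schema uses unit-suffixed field names so files are
#' self-describing: `volume_mL`, `initial_amount_ug`, `density_g_cm3`,
#' `P_cm_h`, `A_cm2`, `Kp`, `lag_h`.
#'
#' @param system A [compartment_system()].
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return `path` (invisibly) if written to file, else a JSON string.
#' @export
system_to_json <- function(system, path = NULL) {
  obj <- list(
    compartments = lapply(system$compartments, function(cp) {
      out <- list(name = cp$name, volume_mL = cp$volume,
                  initial_amount_ug = cp$initial_amount)
      if (!is.na(cp$density)) out$density_g_cm3 <- cp$density
      out
    }),
    interfaces = lapply(system$interfaces, function(ifc) list(
      source = ifc$source, target = ifc$target, P_cm_h = ifc$P, A_cm2 = ifc$A,
      Kp = ifc$Kp, lag_h = ifc$lag_time
    )),
    closed = isTRUE(system$closed)
  )
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(as.character(txt))
  writeLines(txt, path)
  invisible(path)
}

#' Deserialize a compartment system from JSON
#'
#' @param path Path to a JSON file, or a JSON string.
#' @return A [compartment_system()].
#' @export
system_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  comps <- lapply(obj$compartments, function(cp) compartment(
    name = cp$name, volume = cp$volume_mL,
    initial_amount = cp$initial_amount_ug %||% 0,
    density = cp$density_g_cm3 %||% NA_real_
  ))
  ifcs <- lapply(obj$interfaces, function(i) interface(
    source = i$source, target = i$target, P = i$P_cm_h, A = i$A_cm2,
    Kp = i$Kp %||% 1, lag_time = i$lag_h %||% 0
  ))
  compartment_system(comps, ifcs, closed = isTRUE(obj$closed))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
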