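#' Zero-point vibrational energy
#'
#' ZPE = (N_A h c / 2) * sum of the real (positive) wavenumbers. Imaginary
#' modes (negative entries) are excluded from the sum; modes below
#' `soft_threshold` are excluded with a warning, since near-zero
#' finite-difference modes carry no reliable thermochemical information.
#'
#' @param wavenumbers Numeric vector in cm^-1 (negatives = imaginary).
#' @param soft_threshold Exclusion threshold in cm^-1 (default 5).
#' @return ZPE in kJ mol^-1.
#' @examples
#' zpe(1000)  # 5.9815 kJ/mol
#' @export
zpe <- function(wavenumbers, soft_threshold = 5) {
  w <- thermo_modes(wavenumbers, soft_threshold)
  0.5 * surfkin_constants$wavenumber_kJmol * sum(w)
}

# real, non-soft modes entering thermochemistry
thermo_modes <- function(wavenumbers, soft_threshold = 5) {
  w <- wavenumbers[wavenumbers > 0]
  soft <- w < soft_threshold
  if (any(soft)) {
    warning(sum(soft), " soft mode(s) below ", soft_threshold,
            " cm^-1 excluded from thermochemistry", call. = FALSE)
    w <- w[!soft]
  }
  w
}

#' Harmonic-oscillator thermal corrections at temperature T
#'
#' Per-mode harmonic partition functions give the vibrational internal
#' energy above the ZPE and the vibrational entropy in closed form; the
#' Gibbs correction is assembled as ZPE + thermal - T*S. Only vibrational
#' contributions are included: for surface-anchored species there are no
#' free translations or rotations, and no pressure/standard-state term is
#' modeled for these unimolecular steps.
#'
#' @param wavenumbers Numeric vector in cm^-1; imaginary (negative) and soft
#'   modes are excluded as in [zpe()].
#' @param T Temperature in K, > 0.
#' @param soft_threshold Soft-mode exclusion threshold, cm^-1.
#' @return A one-row data.frame (a "thermo record") with columns
#'   `temperature` (K), `zpe` (kJ mol^-1), `thermal_enthalpy_correction`
#'   (kJ mol^-1), `entropy` (J mol^-1 K^-1), `gibbs_correction`
#'   (kJ mol^-1).
#' @examples
#' vibrational_thermo(100, 300)$entropy  # ~14.5 J/mol/K
#' @export
vibrational_thermo <- function(wavenumbers, T, soft_threshold = 5) {
  if (!is.numeric(T) || length(T) != 1L || !is.finite(T) || T <= 0)
    stop("vibrational_thermo: T must be a single positive temperature")
  w <- thermo_modes(wavenumbers, soft_threshold)
  cst <- surfkin_constants
  z <- 0.5 * cst$wavenumber_kJmol * sum(w)
  x <- cst$wavenumber_J * w / (cst$kB * T)          # h c nu / kB T per mode
  # U - U(0) = R T sum x/(e^x - 1); S = R sum [x/(e^x-1) - ln(1 - e^-x)]
  occ <- x / expm1(x)                                # -> 0 as T -> 0
  u_th <- cst$R * T * sum(occ) / 1000                # kJ/mol
  s <- cst$R * sum(occ - log1p(-exp(-x)))            # J/mol/K
  data.frame(temperature = T, zpe = z,
             thermal_enthalpy_correction = u_th,
             entropy = s,
             gibbs_correction = z + u_th - T * s / 1000)
}

# Gibbs correction (kJ/mol) for a species' mode set at each temperature;
# same closed forms as vibrational_thermo() without the record overhead
# (called in tight calibration loops)
gibbs_correction <- function(wavenumbers, temperatures, soft_threshold = 5) {
  w <- thermo_modes(wavenumbers, soft_threshold)
  cst <- surfkin_constants
  z <- 0.5 * cst$wavenumber_kJmol * sum(w)
  vapply(temperatures, function(T) {
    x <- cst$wavenumber_J * w / (cst$kB * T)
    occ <- x / expm1(x)
    u_th <- cst$R * T * sum(occ) / 1000
    s <- cst$R * sum(occ - log1p(-exp(-x)))
    z + u_th - T * s / 1000
  }, 0)
}

#' Relative Gibbs energies along a reaction path
#'
#' For each node, Delta G(T) = Delta E_composite + Delta(ZPE + thermal -
#' T*S) relative to the path's declared zero-energy reference node, with the
#' electronic energy taken at the composite level ("high//low": single-point
#' energy at `level$energy_level` on geometries/frequencies from
#' `level$geometry_level`) and all vibrational corrections from each node's
#' own mobile-mask frequency set. Per-step activation Gibbs energies are
#' additionally reported against the step's own pre-reaction minimum (the
#' intrinsic convention).
#'
#' @param path A [reaction_path()]; every node must carry an electronic
#'   energy at `level$energy_level` and a wavenumber set.
#' @param level A [theory_level()] (or a single level identifier string).
#' @param T Temperature in K.
#' @return List with `nodes` (data.frame: label, role, dG in kJ mol^-1
#'   vs the reference) and `steps` (data.frame: step label, dG_act intrinsic
#'   activation Gibbs energy, dG_rxn intrinsic reaction Gibbs energy, both
#'   kJ mol^-1; dG_act is NA for barrierless steps).
#' @export
relative_gibbs <- function(path, level, T) {
  lev <- as_theory_level(level)
  e <- vapply(path$nodes, function(s) {
    if (is.null(s$energies[[lev$energy_level]]))
      stop("node '", s$label, "' has no energy at level '",
           lev$energy_level, "'")
    composite_energy(s, lev$energy_level, lev$geometry_level)
  }, 0)
  g <- vapply(path$nodes, function(s) {
    if (length(s$wavenumbers) == 0L)
      stop("node '", s$label, "' has no wavenumbers")
    gibbs_correction(s$wavenumbers, T)
  }, 0)
  ref <- path$reference_index
  abs_g <- hartree_to_kjmol(e) + g
  dG <- abs_g - abs_g[ref]
  nodes <- data.frame(
    label = vapply(path$nodes, function(s) s$label, ""),
    role = vapply(path$nodes, function(s) s$role, ""),
    dG = dG)
  steps <- path_steps(path)
  step_df <- do.call(rbind, lapply(steps, function(st) data.frame(
    step = st$label,
    dG_act = if (is.na(st$ts)) NA_real_ else abs_g[st$ts] - abs_g[st$from],
    dG_rxn = abs_g[st$to] - abs_g[st$from])))
  list(temperature = T, nodes = nodes, steps = step_df)
}
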