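#' Physical constants (CODATA 2018)
#'
#' Named list of the physical constants and unit conversions used throughout
#' the package. All SI exact values from the 2019 redefinition.
#'
#' @format A list with elements:
#' \describe{
#'   \item{h}{Planck constant, J s (exact).}
#'   \item{kB}{Boltzmann constant, J K^-1 (exact).}
#'   \item{c}{Speed of light, m s^-1 (exact).}
#'   \item{c_cm}{Speed of light, cm s^-1.}
#'   \item{NA_}{Avogadro constant, mol^-1 (exact).}
#'   \item{R}{Molar gas constant, J mol^-1 K^-1 (= NA * kB).}
#'   \item{hartree_J}{Hartree energy, J.}
#'   \item{hartree_kJmol}{Hartree -> kJ mol^-1.}
#'   \item{wavenumber_J}{1 cm^-1 -> J per particle (h c).}
#'   \item{kJmol_wavenumber}{1 kJ mol^-1 -> cm^-1.}
#'   \item{angstrom_m}{1 Angstrom in m.}
#'   \item{amu_kg}{Atomic mass unit, kg.}
#' }
#' @export
surfkin_constants <- local({
  h  <- 6.62607015e-34
  kB <- 1.380649e-23
  c  <- 2.99792458e8
  NA_ <- 6.02214076e23
  hartree_J <- 4.3597447222071e-18
  wavenumber_J <- h * c * 100          # J per particle per cm^-1
  list(
    h = h, kB = kB, c = c, c_cm = c * 100, NA_ = NA_,
    R = NA_ * kB,
    hartree_J = hartree_J,
    hartree_kJmol = hartree_J * NA_ / 1000,
    wavenumber_J = wavenumber_J,
    wavenumber_kJmol = wavenumber_J * NA_ / 1000,
    kJmol_wavenumber = 1000 / (wavenumber_J * NA_),
    angstrom_m = 1e-10,
    amu_kg = 1.66053906660e-27
  )
})

#' Unit conversions
#'
#' Convert energies between the units used in the pipeline. Electronic
#' energies are stored in hartree and converted to kJ mol^-1 only at
#' presentation/comparison boundaries; state counting works in cm^-1.
#'
#' @param x Numeric vector of values to convert.
#' @return Numeric vector of converted values.
#' @examples
#' hartree_to_kjmol(1)           # 2625.4996...
#' kjmol_to_wavenumber(1)        # 83.593...
#' @name units
NULL

#' @rdname units
#' @export
hartree_to_kjmol <- function(x) x * surfkin_constants$hartree_kJmol

#' @rdname units
#' @export
kjmol_to_hartree <- function(x) x / surfkin_constants$hartree_kJmol

#' @rdname units
#' @export
kjmol_to_wavenumber <- function(x) x * surfkin_constants$kJmol_wavenumber

#' @rdname units
#' @export
wavenumber_to_kjmol <- function(x) x / surfkin_constants$kJmol_wavenumber
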