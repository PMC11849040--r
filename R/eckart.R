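#' Asymmetric Eckart barrier
#'
#' One-dimensional tunneling model for an elementary step, parameterized by
#' the ZPE-corrected forward and reverse barriers and the magnitude of the
#' transition state's imaginary wavenumber (which sets the barrier
#' curvature).
#'
#' @param V_f Forward ZPE-corrected barrier, kJ mol^-1 (> 0).
#' @param V_r Reverse ZPE-corrected barrier, kJ mol^-1 (> 0).
#' @param im_wavenumber Magnitude of the TS imaginary mode, cm^-1 (> 0).
#' @return Object of class `eckart_barrier`.
#' @export
eckart_barrier <- function(V_f, V_r, im_wavenumber) {
  if (!is.finite(V_f) || V_f <= 0) stop("eckart_barrier: V_f must be > 0")
  if (!is.finite(V_r) || V_r <= 0) stop("eckart_barrier: V_r must be > 0")
  if (!is.finite(im_wavenumber) || im_wavenumber <= 0)
    stop("eckart_barrier: im_wavenumber must be > 0")
  structure(list(V_f = V_f, V_r = V_r, im_wavenumber = im_wavenumber),
            class = "eckart_barrier")
}

# ratio (cosh(x2) - cosh(x1)) / (cosh(x2) + cosh(d)) computed without
# overflow for large arguments (all x >= 0)
cosh_ratio <- function(x1, x2, d) {
  m <- max(x1, x2, d)
  ch <- function(x) 0.5 * (exp(x - m) + exp(-x - m))
  (ch(x2) - ch(x1)) / (ch(x2) + ch(d))
}

#' Eckart transmission probability
#'
#' Closed-form quantum transmission probability through an asymmetric
#' Eckart barrier at energy `E` above the reactant-side asymptote (the
#' reactant zero-point level). Tends to 0 as E -> 0 and to 1 as E ->
#' infinity.
#'
#' @param E Energy in kJ mol^-1 (>= 0; vectorized).
#' @param barrier An [eckart_barrier()].
#' @return Transmission probability in [0, 1].
#' @export
eckart_transmission <- function(E, barrier) {
  stopifnot(inherits(barrier, "eckart_barrier"))
  nu <- barrier$im_wavenumber
  V1 <- kjmol_to_wavenumber(barrier$V_f)   # cm^-1
  V2 <- kjmol_to_wavenumber(barrier$V_r)
  alpha1 <- 2 * pi * V1 / nu
  alpha2 <- 2 * pi * V2 / nu
  denom <- 1 / sqrt(alpha1) + 1 / sqrt(alpha2)
  twopid <- 2 * sqrt(max(alpha1 * alpha2 - pi^2 / 4, 0))
  vapply(E, function(e) {
    if (e < 0) stop("eckart_transmission: E must be >= 0")
    if (e == 0) return(0)
    xi <- kjmol_to_wavenumber(e) / V1
    twopia <- 2 * sqrt(alpha1 * xi) / denom
    twopib <- 2 * sqrt(abs((xi - 1) * alpha1 + alpha2)) / denom
    p <- cosh_ratio(abs(twopia - twopib), twopia + twopib, twopid)
    min(max(p, 0), 1)
  }, 0)
}

#' Thermal Eckart tunneling correction
#'
#' Canonical transmission coefficient
#' kappa(T) = exp(V_f/kBT) / kBT * integral_0^Inf P(E) exp(-E/kBT) dE
#' by adaptive quadrature. kappa -> 1 in the classical (high-temperature)
#' limit and grows without bound as T -> 0 for light-particle transfer.
#'
#' @param T Temperature in K.
#' @param barrier An [eckart_barrier()].
#' @param rel_tol Relative tolerance passed to the quadrature.
#' @return Dimensionless kappa >= 0.
#' @export
eckart_kappa <- function(T, barrier, rel_tol = 1e-8) {
  stopifnot(inherits(barrier, "eckart_barrier"))
  if (!is.finite(T) || T <= 0) stop("eckart_kappa: T must be > 0")
  cst <- surfkin_constants
  kT <- cst$R * T / 1000                       # kJ/mol
  V1 <- barrier$V_f
  # integrate P(E) e^{-(E - V1)/kT}: the integrand is O(1) near E = V1,
  # which keeps the quadrature in range even when exp(V1/kT) overflows
  f <- function(E) eckart_transmission(E, barrier) * exp(-(E - V1) / kT)
  upper <- V1 + 50 * kT
  res <- tryCatch(
    stats::integrate(f, 0, upper, rel.tol = rel_tol, subdivisions = 500L),
    error = function(e)
      stop("eckart_kappa: quadrature failed (T = ", T, " K, V_f = ", V1,
           " kJ/mol, nu_im = ", barrier$im_wavenumber, " cm^-1): ",
           conditionMessage(e)))
  if (res$message != "OK")
    stop("eckart_kappa: quadrature did not converge: ", res$message)
  res$value / kT
}

#' Wigner tunneling estimate
#'
#' Leading-order small-curvature series kappa = 1 + (1/24) (h c nu / kB
#' T)^2, useful as an independent check on the Eckart correction in the
#' high-temperature / high-barrier regime.
#'
#' @param T Temperature in K.
#' @param im_wavenumber TS imaginary-mode magnitude, cm^-1.
#' @return Dimensionless kappa.
#' @export
wigner_kappa <- function(T, im_wavenumber) {
  cst <- surfkin_constants
  u <- cst$wavenumber_J * im_wavenumber / (cst$kB * T)
  1 + u^2 / 24
}
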