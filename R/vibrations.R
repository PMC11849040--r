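#' Model potential for numerical vibrational analysis
#'
#' Wraps an analytic potential energy function so the finite-difference
#' Hessian machinery can be exercised end-to-end without an
#' electronic-structure backend. The energy function takes an n_atoms x 3
#' coordinate matrix in Angstrom and returns kJ mol^-1.
#'
#' @param energy Function `(coords) -> kJ mol^-1`.
#' @param masses Numeric vector of atomic masses in amu (one per atom).
#' @param coords0 n_atoms x 3 matrix of the stationary-point coordinates
#'   (Angstrom).
#' @param mobile_mask 0-based indices of the atoms allowed to be displaced;
#'   defaults to all atoms.
#' @param label Optional name.
#' @return An object of class `model_potential`.
#' @export
model_potential <- function(energy, masses, coords0,
                            mobile_mask = NULL, label = "model") {
  coords0 <- as.matrix(coords0)
  if (ncol(coords0) != 3L) stop("model_potential: coords0 must be n x 3")
  if (length(masses) != nrow(coords0))
    stop("model_potential: one mass per atom required")
  if (any(masses <= 0)) stop("model_potential: masses must be positive")
  if (is.null(mobile_mask)) mobile_mask <- seq_len(nrow(coords0)) - 1L
  structure(list(energy = energy, masses = as.numeric(masses),
                 coords0 = coords0, mobile_mask = as.integer(mobile_mask),
                 label = label),
            class = "model_potential")
}

# flat indices (into the 3N coordinate vector) of the mobile coordinates
mobile_coord_indices <- function(potential) {
  as.vector(vapply(potential$mobile_mask + 1L,
                   function(a) (a - 1L) * 3L + 1:3, integer(3)))
}

eval_potential <- function(potential, flat) {
  coords <- matrix(flat, ncol = 3L, byrow = TRUE)
  e <- potential$energy(coords)
  if (!is.finite(e))
    stop("model potential returned a non-finite energy at coordinates [",
         paste(sprintf("%.6f", flat), collapse = ", "), "]")
  e
}

#' Central-difference Hessian over the mobile subspace
#'
#' Second derivatives of the potential energy surface from energy
#' evaluations at displaced geometries: each mobile atom is displaced from
#' its equilibrium position along each Cartesian coordinate by +/- `step`
#' (default 0.003 Angstrom). Diagonal elements use the 3-point central
#' formula, off-diagonals the 4-point (+/-, +/-) formula. The result is
#' symmetrized as (H + t(H))/2 and contains only mobile-atom rows/columns.
#'
#' @param potential A [model_potential()] whose `coords0` is a stationary
#'   point of the mobile subspace (checked numerically against
#'   `grad_tol`).
#' @param step Displacement in Angstrom.
#' @param grad_tol Largest acceptable |dV/dx| at `coords0`,
#'   kJ mol^-1 Angstrom^-1.
#' @return Symmetric matrix of second derivatives (kJ mol^-1 Angstrom^-2)
#'   over the mobile coordinates, ordered atom-major (x, y, z per atom).
#' @export
central_difference_hessian <- function(potential, step = 0.003,
                                       grad_tol = 1e-6) {
  x0 <- as.vector(t(potential$coords0))
  idx <- mobile_coord_indices(potential)
  m <- length(idx)
  # stationary-point check on the restricted subspace; Richardson-
  # extrapolated central differences so the O(step^2) term of anharmonic
  # potentials does not mask a true stationary point
  grad1 <- function(i, h) {
    xp <- x0; xp[i] <- xp[i] + h
    xm <- x0; xm[i] <- xm[i] - h
    (eval_potential(potential, xp) - eval_potential(potential, xm)) / (2 * h)
  }
  grad <- vapply(idx, function(i)
    (4 * grad1(i, step / 2) - grad1(i, step)) / 3, 0)
  if (max(abs(grad)) > grad_tol)
    stop("coordinates are not a stationary point of the mobile subspace: ",
         "max |gradient| = ", format(max(abs(grad))),
         " kJ mol^-1 A^-1 exceeds ", grad_tol)
  e0 <- eval_potential(potential, x0)
  H <- matrix(0, m, m)
  for (a in seq_len(m)) {
    i <- idx[a]
    xp <- x0; xp[i] <- xp[i] + step
    xm <- x0; xm[i] <- xm[i] - step
    H[a, a] <- (eval_potential(potential, xp) - 2 * e0 +
                eval_potential(potential, xm)) / step^2
    if (a < m) for (b in (a + 1L):m) {
      j <- idx[b]
      xpp <- x0; xpp[i] <- xpp[i] + step; xpp[j] <- xpp[j] + step
      xpm <- x0; xpm[i] <- xpm[i] + step; xpm[j] <- xpm[j] - step
      xmp <- x0; xmp[i] <- xmp[i] - step; xmp[j] <- xmp[j] + step
      xmm <- x0; xmm[i] <- xmm[i] - step; xmm[j] <- xmm[j] - step
      H[a, b] <- (eval_potential(potential, xpp) - eval_potential(potential, xpm) -
                  eval_potential(potential, xmp) + eval_potential(potential, xmm)) /
                 (4 * step^2)
      H[b, a] <- H[a, b]
    }
  }
  (H + t(H)) / 2
}

#' Harmonic frequencies from a mobile-subspace Hessian
#'
#' Solves the mass-weighted eigenproblem. Eigenvalues map to wavenumbers as
#' sign(lambda) * sqrt(|lambda|) / (2 pi c), so imaginary modes come out as
#' negative wavenumbers. The stationary point is classified from the count
#' of negative wavenumbers (0 = minimum, 1 = transition state, >1 =
#' higher-order saddle). Near-zero modes (|wavenumber| < `soft_threshold`)
#' are reported but flagged soft — they sit at the numerical noise floor of
#' finite differences and are excluded from the classification count.
#'
#' @param hessian Mobile-subspace Hessian, kJ mol^-1 Angstrom^-2 (e.g. from
#'   [central_difference_hessian()]).
#' @param masses Atomic masses in amu, one per mobile atom (or per atom of
#'   the full system if `mobile_mask` is given).
#' @param mobile_mask Optional 0-based indices selecting which entries of
#'   `masses` belong to the mobile atoms.
#' @param project_translations If `TRUE`, project the three rigid
#'   translations out of the mass-weighted Hessian before diagonalizing
#'   (useful for gas-phase test molecules; off by default because the mobile
#'   subspace of a surface-anchored species is not translation-invariant).
#' @param soft_threshold Soft-mode flag threshold, cm^-1.
#' @return Object of class `harmonic_result`: list with `wavenumbers`
#'   (cm^-1, decreasing), `modes` (mass-weighted normal mode vectors, one
#'   column per mode), `classification`, and `soft` (logical per mode).
#' @export
harmonic_frequencies <- function(hessian, masses, mobile_mask = NULL,
                                 project_translations = FALSE,
                                 soft_threshold = 5) {
  if (!is.null(mobile_mask)) masses <- masses[mobile_mask + 1L]
  n3 <- nrow(hessian)
  if (n3 != 3L * length(masses))
    stop("mass vector mismatch: Hessian is ", n3, " x ", n3,
         " but 3 x n_atoms = ", 3L * length(masses))
  cst <- surfkin_constants
  mvec <- rep(masses, each = 3L)
  W <- hessian / sqrt(outer(mvec, mvec))
  # kJ/mol/A^2/amu -> s^-2
  to_si <- 1000 / (cst$NA_ * cst$angstrom_m^2 * cst$amu_kg)
  if (project_translations) {
    n_at <- length(masses)
    Tr <- matrix(0, n3, 3L)
    for (d in 1:3) Tr[seq(d, n3, by = 3L), d] <- sqrt(masses)
    Tr <- qr.Q(qr(Tr))
    P <- diag(n3) - Tr %*% t(Tr)
    W <- P %*% W %*% P
  }
  eig <- eigen(W, symmetric = TRUE)
  lambda <- eig$values * to_si
  nu <- sign(lambda) * sqrt(abs(lambda)) / (2 * pi * cst$c_cm)
  ord <- order(nu, decreasing = TRUE)
  nu <- nu[ord]
  modes <- eig$vectors[, ord, drop = FALSE]
  soft <- abs(nu) < soft_threshold
  structure(list(wavenumbers = nu, modes = modes,
                 classification = characterize_stationary_point(nu[!soft]),
                 soft = soft),
            class = "harmonic_result")
}

#' @export
print.harmonic_result <- function(x, ...) {
  cat("<harmonic_result> ", length(x$wavenumbers), " modes, ",
      x$classification, "\n", sep = "")
  cat("  wavenumbers (cm^-1): ",
      paste(sprintf("%.1f", x$wavenumbers), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Classify a stationary point from its wavenumbers
#'
#' @param wavenumbers Numeric vector, negatives = imaginary modes.
#' @return `"minimum"`, `"transition_state"`, or `"higher_order_saddle"`.
#' @export
characterize_stationary_point <- function(wavenumbers) {
  if (length(wavenumbers) == 0L) return("minimum")
  n_imag <- sum(wavenumbers < 0)
  if (n_imag == 0L) "minimum"
  else if (n_imag == 1L) "transition_state"
  else "higher_order_saddle"
}
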