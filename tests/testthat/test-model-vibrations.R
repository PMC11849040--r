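nm_to_kjA2 <- surfkin_constants$NA_ * surfkin_constants$angstrom_m^2 / 1000

test_that("central differences are exact on quadratics", {
  pot <- generate_model_potential("harmonic_well",
                                  list(f = 100, mass = 1, dims = 1L))
  H <- central_difference_hessian(pot, step = 0.003)
  expect_equal(H[1, 1] / nm_to_kjA2, 100, tolerance = 1e-6)
  # unused coordinates stay flat
  expect_equal(H[2, 2], 0, tolerance = 1e-8)
})

test_that("quartic curvature at the origin vanishes to step^2 order", {
  pot <- model_potential(function(xyz) xyz[1, 1]^4, masses = 1,
                         coords0 = matrix(0, 1, 3))
  H <- central_difference_hessian(pot, step = 0.003)
  # exact second derivative is 0; central differences leave O(step^2)
  expect_lt(abs(H[1, 1]), 10 * 0.003^2)
})

test_that("2-D saddle gives eigenvalues +f and -f", {
  pot <- generate_model_potential("saddle_2d", list(f = 100, mass = 1))
  H <- central_difference_hessian(pot)
  ev <- sort(eigen(H, symmetric = TRUE)$values / nm_to_kjA2)
  expect_equal(ev, c(-100, 0, 100), tolerance = 1e-5)
  hr <- harmonic_frequencies(H, pot$masses)
  expect_equal(sum(hr$wavenumbers < 0), 1L)
  expect_equal(hr$classification, "transition_state")
})

test_that("harmonic frequency matches the closed form for one particle", {
  # nu = (1/2 pi c) sqrt(f/m): f = 100 N/m, m = 1 amu -> ~1303 cm^-1
  pot <- generate_model_potential("harmonic_well", list(f = 100, mass = 1))
  H <- central_difference_hessian(pot)
  hr <- harmonic_frequencies(H, pot$masses)
  expect_equal(hr$wavenumbers,
               rep(attr(pot, "analytic")$wavenumber, 3),
               tolerance = 1e-6)
  expect_equal(hr$wavenumbers[1], 1302.79, tolerance = 1e-4)
})

test_that("doubling all masses scales wavenumbers by 1/sqrt(2)", {
  pot <- generate_model_potential("harmonic_well", list(f = 80, mass = 2.5))
  H <- central_difference_hessian(pot)
  w1 <- harmonic_frequencies(H, 2.5)$wavenumbers
  w2 <- harmonic_frequencies(H, 5.0)$wavenumbers
  expect_equal(w2, w1 / sqrt(2), tolerance = 1e-10)
})

test_that("morse potential reproduces its harmonic limit", {
  pot <- generate_model_potential("morse_1d",
                                  list(D = 400, a = 2, mass = 1))
  H <- central_difference_hessian(pot)
  hr <- harmonic_frequencies(H, pot$masses)
  expect_equal(max(hr$wavenumbers),
               attr(pot, "analytic")$wavenumber, tolerance = 0.01)
})

test_that("stationary points classify by imaginary-mode count", {
  expect_equal(characterize_stationary_point(c(100, 200, 3300)), "minimum")
  expect_equal(characterize_stationary_point(c(-450, 80, 300)),
               "transition_state")
  expect_equal(characterize_stationary_point(c(-100, -50)),
               "higher_order_saddle")
})

test_that("frequencies are invariant under atom re-indexing", {
  # two decoupled particles with different force constants
  f1 <- 100 * nm_to_kjA2; f2 <- 400 * nm_to_kjA2
  pot_a <- model_potential(
    function(xyz) 0.5 * (f1 * sum(xyz[1, ]^2) + f2 * sum(xyz[2, ]^2)),
    masses = c(1, 16), coords0 = matrix(0, 2, 3))
  pot_b <- model_potential(
    function(xyz) 0.5 * (f2 * sum(xyz[1, ]^2) + f1 * sum(xyz[2, ]^2)),
    masses = c(16, 1), coords0 = matrix(0, 2, 3))
  wa <- harmonic_frequencies(central_difference_hessian(pot_a),
                             pot_a$masses)$wavenumbers
  wb <- harmonic_frequencies(central_difference_hessian(pot_b),
                             pot_b$masses)$wavenumbers
  expect_equal(sort(wa), sort(wb), tolerance = 1e-9)
})

test_that("partial Hessian reproduces decoupled-block frequencies", {
  # mobile atom 1 only: with an exactly decoupled second atom the partial
  # result must equal the corresponding block of the full calculation
  f1 <- 150 * nm_to_kjA2; f2 <- 700 * nm_to_kjA2
  energy <- function(xyz) 0.5 * (f1 * sum(xyz[1, ]^2) + f2 * sum(xyz[2, ]^2))
  full <- model_potential(energy, masses = c(2, 12),
                          coords0 = matrix(0, 2, 3))
  part <- model_potential(energy, masses = c(2, 12),
                          coords0 = matrix(0, 2, 3), mobile_mask = 0L)
  w_full <- harmonic_frequencies(central_difference_hessian(full),
                                 full$masses)$wavenumbers
  w_part <- harmonic_frequencies(central_difference_hessian(part),
                                 c(2, 12), mobile_mask = 0L)$wavenumbers
  expect_equal(sort(w_part), sort(w_full)[4:6], tolerance = 1e-8)
})

test_that("non-stationary input and bad masses are rejected", {
  shifted <- model_potential(function(xyz) sum((xyz[1, ] - 0.05)^2) * 500,
                             masses = 1, coords0 = matrix(0, 1, 3))
  expect_error(central_difference_hessian(shifted), "stationary point")
  expect_error(harmonic_frequencies(diag(3), masses = c(1, 1)),
               "mass vector mismatch")
  diverging <- model_potential(function(xyz)
    ifelse(abs(xyz[1, 1]) > 0.001, Inf, 0),
    masses = 1, coords0 = matrix(0, 1, 3))
  expect_error(central_difference_hessian(diverging), "non-finite")
})
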