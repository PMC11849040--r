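cst <- surfkin_constants

test_that("Eyring rates follow the canonical TST expression", {
  # zero barrier: the universal frequency factor kB T / h
  expect_equal(eyring_rate(0, 300), cst$kB * 300 / cst$h)
  expect_equal(eyring_rate(0, 300), 6.25e12, tolerance = 1e-3)
  # the published 300 K barrier of the (120)BC C-C step
  expect_equal(eyring_rate(95.8, 300), 1.3e-4, tolerance = 0.01)
  # strictly increasing in T at fixed barrier
  k <- eyring_rate(80, c(100, 150, 200, 250, 300))
  expect_true(all(diff(k) > 0))
  expect_error(eyring_rate(50, -10), "T must be")
})

test_that("state counts match direct enumeration", {
  sc <- sum_states(100, 250, grain = 5)
  expect_equal(sc$N[sc$energy == 250], 3)  # levels 0, 100, 200
  sc2 <- sum_states(c(100, 100), 250, grain = 5)
  expect_equal(sc2$N[sc2$energy == 250], 6)
  expect_equal(sc2$N[1], 1)                # N(0) = 1
  expect_true(all(diff(sc2$N) >= 0))
  # brute-force oracle over quantum-number tuples, <= 4 modes
  # (grain-commensurate wavenumbers isolate the counting from binning)
  for (modes in list(c(310), c(115, 525), c(95, 310, 1250),
                     c(80, 80, 410, 1600))) {
    sc <- sum_states(modes, 2000, grain = 5)
    for (E in c(200, 650, 1337, 2000)) {
      expect_equal(sc$N[which.min(abs(sc$energy - E))],
                   brute_count(modes, E),
                   info = paste("modes", paste(modes, collapse = ","),
                                "E", E))
    }
  }
  # degenerate contract: no modes -> a single state at E = 0
  sc0 <- sum_states(numeric(0), 100, grain = 5)
  expect_true(all(sc0$N == 1))
  expect_equal(sc0$counts[1], 1)
  expect_error(sum_states(c(-100, 200), 500), "positive")
})

test_that("microcanonical k(E) has the N/(h rho) structure", {
  ts <- sum_states(c(300, 900), 3000, grain = 5)
  re <- sum_states(c(150, 450, 1200), 3000, grain = 5)
  E0 <- 900                                          # a populated bin
  h_cm_s <- cst$h / cst$wavenumber_J
  expect_equal(rrkm_k_of_E(ts, re, E0, 500), 0)      # below threshold
  k_at_E0 <- rrkm_k_of_E(ts, re, E0, E0)
  i <- which(re$energy == E0)
  expect_equal(k_at_E0, 1 / (h_cm_s * re$rho[i]))     # N(0) = 1
  # k(E) over populated bins matches the N/(h rho) array expression
  E_grid <- re$energy[re$energy >= E0 & re$counts > 0]
  kE <- rrkm_k_of_E(ts, re, E0, E_grid)
  iN <- floor((E_grid - E0) / 5) + 1L
  expect_equal(kE, ts$N[iN] / (h_cm_s * re$rho[re$energy %in% E_grid]))
})

test_that("canonical RRKM reduces to the closed form for identical modes", {
  w <- c(90, 420, 1200, 2900)
  r <- species("R", "reactant_complex", list(pbe = -100), w)
  ts <- species("TS", "transition_state", list(pbe = -99.98), c(-700, w))
  E0 <- 45   # kJ/mol
  for (T in c(150, 300)) {
    k <- rrkm_canonical(r, ts, E0, T, grain = 5)
    k_closed <- (cst$kB * T / cst$h) * exp(-E0 * 1000 / (cst$R * T))
    expect_equal(k, k_closed, tolerance = 1e-4)
  }
})

test_that("canonical RRKM agrees with Eyring and converges in grain", {
  sp <- synthetic_case_spec("rrkm-check", seed = 77,
    steps = list(list(label = "CC", target_dG_act = 70, target_dG_rxn = -20,
                      im_wavenumber = 420)))
  case <- generate_reaction_case(sp)
  prof <- build_profile(case$path, "bhlyp//pbe")
  E0 <- prof$steps$dH0_act
  r <- case$path$nodes[[1]]; ts <- case$path$nodes[[2]]
  for (T in c(150, 200, 300)) {
    rg <- relative_gibbs(case$path, "bhlyp//pbe", T)
    expect_equal(rrkm_canonical(r, ts, E0, T, grain = 5),
                 eyring_rate(rg$steps$dG_act, T), tolerance = 0.01)
  }
  # grain convergence: doubling 5 -> 10 moves k(300 K) by < 0.5%
  k5 <- rrkm_canonical(r, ts, E0, 300, grain = 5)
  k10 <- rrkm_canonical(r, ts, E0, 300, grain = 10)
  expect_lt(abs(k10 / k5 - 1), 0.005)
  # a too-short grid is refused rather than silently truncated
  expect_error(rrkm_canonical(r, ts, E0, 300, grain = 5, n_kT = 2),
               "widen")
})

test_that("Eckart transmission and kappa obey their limits", {
  b <- eckart_barrier(90, 90, 300)
  # P -> 1 at high energy, P(0) = 0, monotone through the barrier top
  expect_equal(eckart_transmission(500, b), 1, tolerance = 1e-6)
  expect_equal(eckart_transmission(0, b), 0)
  expect_equal(eckart_transmission(90, b), 0.5, tolerance = 0.05)
  # classical limit: kappa -> 1 within 1% once kB T >= 20 h c nu
  nu <- 50
  T_hot <- 20 * cst$wavenumber_J * nu / cst$kB
  expect_equal(eckart_kappa(T_hot, eckart_barrier(120, 120, nu)), 1,
               tolerance = 0.01)
  # Wigner series check at 300 cm^-1, 300 K
  expect_equal(wigner_kappa(300, 300), 1.0863, tolerance = 1e-3)
  expect_equal(eckart_kappa(300, b), wigner_kappa(300, 300),
               tolerance = 0.05)
  # kappa >= 1 below the classical regime and non-increasing in T
  b2 <- eckart_barrier(25, 75, 1250)
  kap <- vapply(c(50, 100, 150, 200, 300), eckart_kappa, 0, barrier = b2)
  expect_true(all(kap >= 1))
  expect_true(all(diff(kap) < 0))
  expect_error(eckart_barrier(-5, 50, 1000), "V_f")
})

test_that("half-lives invert first-order rates exactly", {
  expect_equal(half_life(log(2) / 3600), 1)
  expect_equal(half_life(4.3e-4), 0.45, tolerance = 0.01)
  expect_equal(half_life(0), Inf)
  # table mode: the 1e-19 floor maps to infinity
  expect_equal(half_life(1e-20, floor_k = 1e-19), Inf)
  expect_gt(half_life(1e-20), 0)
  expect_error(half_life(-1), "k must be")
  # t_half * k * 3600 = ln 2 identically
  k <- 10^seq(-15, 3, by = 3)
  expect_equal(half_life(k) * k * 3600, rep(log(2), length(k)))
})

test_that("Arrhenius fits recover exact inputs and TST identities", {
  # exact Arrhenius data: machine-precision recovery
  A <- 2.5e12; Ea <- 65
  T <- seq(150, 300, by = 25)
  rec <- data.frame(temperature = T,
                    k_tunn = A * exp(-Ea * 1000 / (cst$R * T)))
  fit <- fit_arrhenius(rec)
  expect_equal(fit$A, A, tolerance = 1e-10)
  expect_equal(fit$Ea, Ea, tolerance = 1e-12)
  expect_error(fit_arrhenius(transform(rec, k_tunn = c(0, k_tunn[-1]))),
               "k = 0")
  expect_error(fit_arrhenius(rec[1:2, ]), "3 temperatures")
  # pure Eyring input: fitted Ea ~ dH_act + R Tbar over a narrow window
  path <- make_path()
  Tw <- c(280, 290, 300, 310, 320)
  rec2 <- arrhenius_table(path, "bhlyp//pbe", "CC", Tw,
                          tunnel = "none", method = "eyring")
  fitc <- fit_arrhenius(rec2, use = "k_class")
  Tbar <- mean(Tw)
  g1 <- relative_gibbs(path, "bhlyp//pbe", Tbar - 1)$steps$dG_act
  g2 <- relative_gibbs(path, "bhlyp//pbe", Tbar + 1)$steps$dG_act
  dS <- -(g2 - g1) / 2                                  # kJ/mol/K
  dH <- relative_gibbs(path, "bhlyp//pbe", Tbar)$steps$dG_act + Tbar * dS
  expect_equal(fitc$Ea, dH + cst$R * Tbar / 1000, tolerance = 0.02)
})

test_that("tunneling curves the Arrhenius plot upward at low T", {
  sp <- profile_case_specs()[["(120)BC"]]
  case <- generate_reaction_case(sp)
  rec_lo <- arrhenius_table(case$path, "bhlyp//pbe", "dept",
                            c(50, 100, 150), tunnel = "all")
  rec_hi <- arrhenius_table(case$path, "bhlyp//pbe", "dept",
                            c(200, 250, 300), tunnel = "all")
  expect_lt(fit_arrhenius(rec_lo)$Ea, fit_arrhenius(rec_hi)$Ea)
  # k_tunn = kappa * k_class exactly, and kappa >= 1 for a proton transfer
  expect_equal(rec_lo$k_tunn, rec_lo$kappa * rec_lo$k_class)
  expect_true(all(rec_lo$kappa > 1))
})
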