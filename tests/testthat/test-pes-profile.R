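test_that("composite energies follow the high//low convention", {
  sp <- species("x", "intermediate",
                list(pbe = -100.02, bhlyp = -100.00), 500)
  # identical levels: the plain energy
  expect_equal(composite_energy(sp, "pbe", "pbe"), -100.02)
  # composite: high-level energy on the low-level geometry
  expect_equal(composite_energy(sp, "bhlyp", "pbe"), -100.00)
  expect_error(composite_energy(sp, "b3lyp", "pbe"), "b3lyp")
})

test_that("a high-level shift on the TS alone shifts the composite barrier", {
  d10 <- kjmol_to_hartree(10)
  r <- make_min("R", -100)
  ts <- make_ts("TS", -99.96)
  ts$energies$bhlyp <- ts$energies$pbe + 0.01 + d10  # +10 kJ/mol at high level
  p <- make_min("P", -100.01, role = "product_complex")
  path <- reaction_path("shifted", list(r, ts, p), 1L, "CC")
  low <- build_profile(path, "pbe", include_zpe = FALSE)
  hi <- build_profile(path, "bhlyp//pbe", include_zpe = FALSE)
  expect_equal(hi$steps$dE_act, low$steps$dE_act + 10, tolerance = 1e-9)
})

test_that("degenerate and shifted profiles behave as identities", {
  # a two-node path of the same species: all relative energies zero
  r <- make_min("A", -100)
  p <- make_min("A", -100, role = "product_complex")
  path <- reaction_path("null", list(r, p), 1L, "step1",
                        barrierless = TRUE)
  prof <- build_profile(path, "bhlyp//pbe")
  expect_equal(prof$nodes$dE, c(0, 0))
  expect_equal(prof$nodes$dH0, c(0, 0))
  # uniform shift of all absolute energies leaves the profile unchanged
  path2 <- make_path(); path3 <- make_path()
  for (i in seq_along(path3$nodes))
    path3$nodes[[i]]$energies <- lapply(path3$nodes[[i]]$energies,
                                        function(e) e + 0.5)
  expect_equal(build_profile(path2, "bhlyp//pbe")$nodes$dH0,
               build_profile(path3, "bhlyp//pbe")$nodes$dH0,
               tolerance = 1e-9)
})

test_that("per-step enthalpies telescope along the path", {
  cases <- table1_cases_cached()
  prof <- build_profile(cases[["(120)BC"]]$path, "bhlyp//pbe")
  n <- nrow(prof$nodes)
  expect_equal(sum(prof$steps$dH0_rxn),
               prof$nodes$dH0[n] - prof$nodes$dH0[1], tolerance = 1e-9)
})

test_that("binding energies follow the complex-minus-parts convention", {
  lev <- "pbe"
  mk <- function(lab, e, role = "free_molecule")
    species(lab, role, stats::setNames(list(e), lev), 500)
  complex <- mk("cpx", kjmol_to_hartree(-100), "reactant_complex")
  surface <- mk("slab", kjmol_to_hartree(-60), "bare_surface")
  ads <- list(mk("hcn1", kjmol_to_hartree(-20)),
              mk("hcn2", kjmol_to_hartree(-10)))
  be <- binding_energy(complex, surface, ads, lev)
  expect_equal(be$BE, -10, tolerance = 1e-9)
  # complex == surface, no adsorbates: BE = 0
  expect_equal(binding_energy(surface, surface, list(), lev)$BE, 0)
  # all species must carry the common level
  bad <- mk("other", -1); bad$energies <- list(bhlyp = -1)
  expect_error(binding_energy(complex, surface, list(bad), lev), "level")
})

test_that("site-by-site binding-energy differences match the reference", {
  ref <- reference_binding_energies()
  get <- function(cs, cpx) ref$BE[ref$case == cs & ref$complex == cpx]
  rbe <- data.frame(complex = c("R1", "R2"),
                    BE = c(get("(101)AB", "R_CC"), get("(101)BC", "R_CC")))
  pbe <- data.frame(complex = c("P1", "P2"),
                    BE = c(get("(101)AB", "IAN_anion"),
                           get("(101)BC", "IAN_anion")))
  cmp <- delta_be_consistency(rbe, pbe, site = c("(101)AB", "(101)BC"))
  expect_equal(cmp$per_site$dBE, c(93.8, -16.3), tolerance = 1e-9)
  expect_equal(cmp$cross_site$ddBE, 93.8 - (-16.3), tolerance = 1e-9)
  # identical records: zero differences
  same <- delta_be_consistency(rbe, rbe, site = c("a", "b"))
  expect_equal(same$per_site$dBE, c(0, 0))
})

test_that("profile validation flags inversions against the DFT tolerance", {
  # shared real mode set so dH0 gaps equal the electronic gaps exactly
  w0 <- c(500, 1500, 3000)
  pathE <- function(ts_kj, p_kj) {
    r <- make_min("R", -100, modes = w0)
    ts <- make_ts("TS", -100 + kjmol_to_hartree(ts_kj), modes = w0)
    p <- make_min("P", -100 + kjmol_to_hartree(p_kj),
                  modes = w0, role = "product_complex")
    build_profile(reaction_path("inv", list(r, ts, p), 1L, "CC"),
                  "bhlyp//pbe")
  }
  # TS 10 kJ/mol above both neighbors: no inversion
  fl <- validate_profile(pathE(10, -5))
  expect_false(any(fl$type == "inversion"))
  # TS 10 kJ/mol below the reactant: inversion beyond tolerance
  fl2 <- validate_profile(pathE(-10, -30))
  inv <- fl2[fl2$type == "inversion", ]
  expect_gte(nrow(inv), 1L)
  expect_true(all(inv$severity == "beyond_tolerance"))
  # small gap: within DFT accuracy, and the tolerance is overridable
  fl3 <- validate_profile(pathE(20, 21.8))
  inv3 <- fl3[fl3$type == "inversion", ]
  expect_equal(inv3$gap, 1.8, tolerance = 1e-6)
  expect_equal(inv3$severity, "within_dft_accuracy")
  fl4 <- validate_profile(pathE(20, 21.8), tolerance = 1)
  expect_equal(fl4$severity[fl4$type == "inversion"], "beyond_tolerance")
})
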