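test_that("species files round-trip field-for-field", {
  sp <- species("ads_complex", "intermediate",
                energies = list(bhlyp = -186.123456789012,
                                pbe = -186.101234567891),
                wavenumbers = c(55.25, 450.5, 3310.125),
                geometry = data.frame(element = c("C", "N"),
                                      x = c(0, 1.16), y = 0, z = 0),
                mobile_mask = c(0L, 1L))
  f <- withr::local_tempfile(fileext = ".species")
  write_species(sp, f)
  sp2 <- read_species(f)
  expect_equal(sp2$label, sp$label)
  expect_equal(sp2$role, sp$role)
  # energies to at least 12 significant figures
  expect_equal(sp2$energies$bhlyp, sp$energies$bhlyp, tolerance = 1e-13)
  expect_equal(sp2$energies$pbe, sp$energies$pbe, tolerance = 1e-13)
  expect_equal(sp2$wavenumbers, sp$wavenumbers)
  expect_equal(sp2$geometry, sp$geometry)
  expect_equal(sp2$mobile_mask, sp$mobile_mask)
})

test_that("imaginary modes parse from negative numbers and i-suffix strings", {
  f <- system.file("extdata", "species", "gas_TS.species",
                   package = "surfkin")
  sp <- read_species(f)
  expect_s3_class(sp, "species")
  expect_equal(sum(sp$wavenumbers < 0), 1L)
  expect_equal(min(sp$wavenumbers), -1000)
})

test_that("species invariants are enforced", {
  # TS with more than one imaginary mode
  expect_error(
    species("bad_ts", "transition_state", list(pbe = -1),
            c(-450, -100, 300)),
    "exactly one")
  # minimum with an imaginary mode
  expect_error(
    species("bad_min", "intermediate", list(pbe = -1), c(-100, 300)),
    "zero imaginary")
  # wavenumber magnitude cap
  expect_error(
    species("too_stiff", "intermediate", list(pbe = -1), c(100, 5100)),
    "5000")
  # non-finite energy
  expect_error(
    species("nan_e", "intermediate", list(pbe = NaN), c(100)),
    "finite")
})

test_that("missing required species fields are reported by name", {
  f <- withr::local_tempfile(fileext = ".species")
  yaml::write_yaml(list(label = "x", role = "intermediate",
                        wavenumbers = list(100)), f)
  expect_error(read_species(f), "energies")
})

test_that("XYZ I/O round-trips and rejects malformed files", {
  g <- data.frame(element = c("Mg", "O"),
                  x = c(0, 1.234567), y = c(0, -0.654321), z = c(0.5, 2))
  f <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(g, f, comment = "two atoms")
  g2 <- read_xyz(f)
  expect_equal(g2$element, g$element)
  expect_equal(g2$x, g$x, tolerance = 1e-7)
  expect_equal(g2$y, g$y, tolerance = 1e-7)

  writeLines(c("3", "broken", "H 0 0 0", "H 1 0 0"), f)
  expect_error(read_xyz(f), "atom count")
  writeLines(c("1", "", "Xx 0 0 0"), f)
  expect_error(read_xyz(f), "Xx")
})

test_that("unit conversions compose to identity", {
  x <- c(-400.123, 0.5, 311.3)
  expect_equal(kjmol_to_hartree(hartree_to_kjmol(x)), x, tolerance = 1e-11)
  expect_equal(wavenumber_to_kjmol(kjmol_to_wavenumber(x)), x,
               tolerance = 1e-11)
  # cross-consistency of the constant set: hc * (cm^-1 per kJ/mol) * NA = 1000
  cst <- surfkin_constants
  expect_equal(cst$wavenumber_J * cst$kJmol_wavenumber * cst$NA_, 1000,
               tolerance = 1e-9)
})

test_that("rate table rendering follows the reporting conventions", {
  rec <- data.frame(
    case = "(111)BC", step = "CC", temperature = c(150, 200, 300),
    dG_act = c(174.3, 175.1, 177.5), dG_rxn = c(156.1, 156.5, 157.9),
    k_class = c(1e-20, 1e-20, 7.9e-17), kappa = 1,
    k_tunn = c(1e-20, 1e-20, 7.9e-17),
    half_life = c(Inf, Inf, 2.4e12))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_rate_table(rec, f)
  lines <- readLines(f)
  krow <- strsplit(grep("\tk\\^", lines, value = TRUE), "\t")[[1]]
  # below the 1e-19 floor renders as 0; a finite small rate keeps 2 s.f.
  expect_equal(krow[3:5], c("0", "0", "7.9e-17"))
  trow <- strsplit(grep("t_half", lines, value = TRUE), "\t")[[1]]
  expect_equal(trow[3:4], c("inf", "inf"))
  # deterministic: identical input, byte-identical output
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_rate_table(rec, f2)
  expect_identical(readLines(f), readLines(f2))
  # empty input: header only
  write_rate_table(rec[0, ], f2)
  expect_length(readLines(f2), 1L)
  # ragged temperature grids are rejected
  bad <- rbind(rec, transform(rec[1, ], case = "other", temperature = 250))
  expect_error(write_rate_table(bad, f2), "temperature grid")
})
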