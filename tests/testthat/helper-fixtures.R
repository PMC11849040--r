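# shared fixtures, built in code

# a small minimum/TS pair sharing the reactant's mode set except one
make_min <- function(label = "R", e = -100, modes = c(100, 500, 1500, 3000),
                     role = "reactant_complex", level = "bhlyp") {
  en <- list(); en[[level]] <- e
  if (level != "pbe") en$pbe <- e - 0.01
  species(label, role, en, modes)
}

make_ts <- function(label = "TS", e = -99.96, modes = c(500, 1500, 3000),
                    im = 1000, level = "bhlyp") {
  en <- list(); en[[level]] <- e
  if (level != "pbe") en$pbe <- e - 0.01
  species(label, "transition_state", en, c(-im, modes))
}

make_path <- function(e_r = -100, e_ts = -99.96, e_p = -100.01,
                      case = "toy") {
  r <- make_min("R", e_r)
  ts <- make_ts("TS", e_ts)
  p <- make_min("P", e_p, role = "product_complex")
  reaction_path(case, list(r, ts, p), reference_index = 1L,
                step_labels = "CC")
}

# brute-force harmonic state count: enumerate all quantum-number tuples
# with sum n_i * nu_i <= E (independent of the package's counting code)
brute_count <- function(wavenumbers, E) {
  grids <- lapply(wavenumbers, function(nu) 0:floor(E / nu))
  combos <- expand.grid(grids)
  sum(as.matrix(combos) %*% wavenumbers <= E + 1e-9)
}

# table1-calibrated cases are expensive to generate; build once per run
table1_cases_cached <- local({
  cases <- NULL
  function() {
    if (is.null(cases)) cases <<- lapply(table1_case_specs(),
                                         generate_reaction_case)
    cases
  }
})

profile_cases_cached <- local({
  cases <- NULL
  function() {
    if (is.null(cases)) cases <<- lapply(profile_case_specs(),
                                         generate_reaction_case)
    cases
  }
})
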