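# Synthetic stationary-point generator: reaction cases with known ground
# truth, standing in for the electronic-structure calculations so every
# pipeline stage is testable at desk scale.

# run code under a private RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic reaction case
#'
#' Describes one surface reaction case to be generated with known ground
#' truth: the number of mobile-frame vibrational modes per stationary
#' point, the range the real wavenumbers are drawn from, and per-step
#' calibration targets. Electronic energies of the TS and product nodes are
#' solved so the pipeline reproduces the targets exactly (see
#' [generate_reaction_case()]); frequencies control the temperature
#' dependence and are kept as sampled (up to the entropy-shaping
#' adjustment needed by multi-temperature targets).
#'
#' @param case_label Case name, e.g. `"(120)BC"`.
#' @param seed Integer seed; the same spec always generates a byte-identical
#'   fixture.
#' @param steps List of per-step target lists, each with elements `label`,
#'   `target_dG_act`, `target_dG_rxn` (numeric, one value per calibration
#'   temperature, kJ mol^-1), and `im_wavenumber` (cm^-1). With
#'   `target_kind = "dH0"` the targets are single ZPE-corrected enthalpies
#'   instead and calibration is temperature-free.
#' @param calibration_T Calibration temperature(s), K.
#' @param target_kind `"gibbs"` (default) or `"dH0"`.
#' @param n_modes Real modes per stationary point (default 30, emulating an
#'   adsorbate plus first-layer mobile set).
#' @param mode_range Sampling range for real wavenumbers, cm^-1; must lie
#'   within (20, 3800).
#' @param level_offset Energy offset (hartree) between the geometry level
#'   (`"pbe"`) and the single-point level (`"bhlyp"`) applied to every
#'   node, emulating a two-level composite scheme.
#' @return Object of class `synthetic_case_spec`.
#' @export
synthetic_case_spec <- function(case_label, seed, steps,
                                calibration_T = 300,
                                target_kind = c("gibbs", "dH0"),
                                n_modes = 30,
                                mode_range = c(75, 3600),
                                level_offset = 0.01) {
  target_kind <- match.arg(target_kind)
  if (n_modes < 1) stop("synthetic_case_spec: n_modes must be >= 1")
  if (mode_range[1] <= 20 || mode_range[2] >= 3800 ||
      mode_range[1] >= mode_range[2])
    stop("synthetic_case_spec: mode_range must lie within (20, 3800)")
  if (any(calibration_T <= 0))
    stop("synthetic_case_spec: calibration temperatures must be > 0")
  m <- length(calibration_T)
  for (st in steps) {
    for (f in c("label", "target_dG_act", "target_dG_rxn", "im_wavenumber"))
      if (is.null(st[[f]])) stop("synthetic_case_spec: step missing '", f, "'")
    if (target_kind == "gibbs" &&
        (length(st$target_dG_act) != m || length(st$target_dG_rxn) != m))
      stop("synthetic_case_spec: step '", st$label, "' needs one target per ",
           "calibration temperature")
    if (st$im_wavenumber <= 0)
      stop("synthetic_case_spec: im_wavenumber must be > 0")
    if (any(st$target_dG_act <= 0))
      stop("synthetic_case_spec: step '", st$label, "': unreachable target ",
           "(non-positive barrier)")
  }
  structure(list(case_label = case_label, seed = as.integer(seed),
                 steps = steps, calibration_T = calibration_T,
                 target_kind = target_kind, n_modes = as.integer(n_modes),
                 mode_range = mode_range, level_offset = level_offset),
            class = "synthetic_case_spec")
}

# gibbs correction at several temperatures, no soft warnings (sampled modes
# are all above the soft threshold by construction)
gcorr <- function(w, temps) gibbs_correction(w, temps)

# entropy shaping: replace a few low modes of the node so that its relative
# G(T) matches the targets at every calibration temperature (the electronic
# energy is solved exactly at the middle temperature inside the residual).
# Modes are parameterized through a logistic map so they stay in
# (21, 3799) cm^-1 — above the soft-mode floor, below the physical ceiling.
shape_modes <- function(base_modes, ref_g, targets, temps, mode_range) {
  stopifnot(length(targets) == length(temps))
  if (length(temps) == 1L) return(base_modes)
  if (length(temps) != 3L)
    stop("shape_modes: multi-temperature calibration supports exactly 3 ",
         "calibration temperatures")
  mid <- 2L
  lo <- 21; hi <- 3799
  inert <- 3700   # essentially frozen at <= 300 K: no entropy contribution
  to_w <- function(par) lo + (hi - lo) * stats::plogis(par)
  to_par <- function(w) stats::qlogis(pmin(pmax((w - lo) / (hi - lo),
                                                1e-6), 1 - 1e-6))
  ord <- order(base_modes)
  n <- length(base_modes)
  # temperature "shape" of one mode: thermal Gibbs correction at (150, 300)
  # relative to 200 K; ZPE cancels in the differences
  mode_shape <- function(w) {
    g <- gcorr(w, temps)
    c(g[1] - g[mid], g[3] - g[mid])
  }
  target_shape <- c(targets[1] - targets[mid], targets[3] - targets[mid])
  ref_shape <- c(ref_g[1] - ref_g[mid], ref_g[3] - ref_g[mid])
  base_shapes <- t(vapply(base_modes, mode_shape, numeric(2)))
  total_shape <- colSums(base_shapes)
  s_lo <- mode_shape(lo + 1)
  # Replace the k lowest base modes by m1 copies of mu1, m2 copies of mu2,
  # and inert padding. (mu1, mu2) is an exactly determined 2-unknown system
  # against the 150/300 K residuals (the electronic energy is pinned at
  # 200 K inside the residual); the multiplicities set the entropy budget.
  try_config <- function(k, m1, m2) {
    adj_idx <- ord[seq_len(k)]
    resid <- function(par) {
      w <- base_modes
      w[adj_idx] <- c(rep(to_w(par[1]), m1), rep(to_w(par[2]), m2),
                      rep(inert, k - m1 - m2))
      g <- gcorr(w, temps) - ref_g
      e <- targets[mid] - g[mid]
      (g + e - targets)[-mid]
    }
    obj <- function(par) sum(resid(par)^2)
    best <- NULL
    for (s in list(c(70, 350), c(35, 130), c(150, 800))) {
      fit <- stats::optim(to_par(s), obj, method = "Nelder-Mead",
                          control = list(maxit = 2000, reltol = 1e-16))
      if (is.null(best) || fit$value < best$value) best <- fit
      if (best$value < 1e-10) break
    }
    list(fit = best, adj_idx = adj_idx, m1 = m1, m2 = m2)
  }
  # analytic screen: removing the k lowest modes must leave a required
  # shape sum inside the cone reachable by real modes
  min_ratio <- -s_lo[2] / s_lo[1]
  need_for <- function(k)
    target_shape + ref_shape -
      (total_shape - colSums(base_shapes[ord[seq_len(k)], , drop = FALSE]))
  feasible <- function(k) {
    need <- need_for(k)
    need[1] > 0.02 && need[2] < -0.02 &&
      -need[2] / need[1] >= min_ratio - 0.02
  }
  ks <- Filter(feasible, 2:n)
  if (length(ks) == 0L) ks <- unique(c(4L, 8L, 16L, n))  # brute fallback
  # retry pass widens the k candidates and the multiplicity grid
  ks <- unique(c(utils::head(ks, 8L), utils::tail(ks, 4L)))
  best <- NULL
  for (k in ks) {
    need <- need_for(min(k, n))
    # enough copies of the soft mode to cover the budget, at least 1 each
    m1 <- max(1L, min(k - 1L, ceiling(max(need[1], 0.1) / (0.8 * s_lo[1]))))
    m1_opts <- unique(pmax(1L, pmin(c(m1, m1 + 1L, m1 - 1L), k - 1L)))
    for (m1 in m1_opts) {
      for (m2 in unique(pmin(c(1L, m1, 2L * m1), k - m1))) {
        if (m2 < 1L) next
        cand <- try_config(k, m1, m2)
        if (is.null(best) || cand$fit$value < best$fit$value) best <- cand
        if (best$fit$value < 1e-10) break
      }
      if (best$fit$value < 1e-10) break
    }
    if (best$fit$value < 1e-10) break
  }
  if (best$fit$value > 0.04^2)
    warning("entropy shaping residual ", sqrt(best$fit$value),
            " kJ/mol exceeds 0.04 at the calibration temperatures",
            call. = FALSE)
  w <- base_modes
  w[best$adj_idx] <- c(rep(to_w(best$fit$par[1]), best$m1),
                       rep(to_w(best$fit$par[2]), best$m2),
                       rep(inert, length(best$adj_idx) - best$m1 - best$m2))
  w
}

#' Generate a synthetic reaction case with known ground truth
#'
#' Builds a full [reaction_path()] for the spec: a reactant complex,
#' one transition state and one minimum per step, each carrying `n_modes`
#' real wavenumbers drawn uniformly from `mode_range` (transition states
#' get one imaginary mode at the step's `im_wavenumber`), plus two-level
#' electronic energies. TS and product electronic energies are solved so
#' that the pipeline's intrinsic Delta G_act and Delta G_rxn at the
#' calibration temperature(s) equal the targets: with a single calibration
#' temperature the solve is closed-form and exact; with several, three
#' low-frequency modes per calibrated node are additionally adjusted by
#' least squares to shape the activation entropy. With `target_kind =
#' "dH0"` the ZPE-corrected enthalpies are calibrated instead (exact).
#'
#' @param spec A [synthetic_case_spec()].
#' @return List of class `synthetic_case`: `path` (the [reaction_path()]),
#'   `spec`, and `truth` (data.frame of per-step targets and the
#'   calibration temperatures).
#' @export
generate_reaction_case <- function(spec) {
  stopifnot(inherits(spec, "synthetic_case_spec"))
  temps <- spec$calibration_T
  with_seed(spec$seed, {
    multi_T <- spec$target_kind == "gibbs" && length(temps) > 1L
    draw_modes <- function(n, lattice = FALSE) {
      w <- stats::runif(n, spec$mode_range[1], spec$mode_range[2])
      if (lattice && multi_T) {
        # surface minima carry a block of low lattice-like modes (first-layer
        # phonons); this also provides the activation-entropy budget that
        # multi-temperature calibration shapes against
        nl <- min(10L, n)
        w[order(w)[seq_len(nl)]] <-
          seq(65, 245, length.out = nl) * stats::runif(nl, 0.98, 1.02)
      }
      sort(w)
    }
    e_base <- -100 - stats::runif(1)          # hartree, arbitrary origin
    nodes <- list()
    w_r <- draw_modes(spec$n_modes, lattice = TRUE)
    nodes[[1]] <- species(
      label = paste0("R_", spec$case_label), role = "reactant_complex",
      energies = list(bhlyp = e_base, pbe = e_base - spec$level_offset),
      wavenumbers = w_r)
    truth <- list()
    prev_min_i <- 1L
    for (si in seq_along(spec$steps)) {
      st <- spec$steps[[si]]
      prev <- nodes[[prev_min_i]]
      e_prev <- prev$energies$bhlyp
      ref_g <- if (spec$target_kind == "gibbs")
        gcorr(prev$wavenumbers, temps) else zpe(prev$wavenumbers)
      make_node <- function(base_w, targets, imag) {
        w <- base_w
        if (spec$target_kind == "gibbs") {
          w <- shape_modes(base_w, ref_g, targets, temps, spec$mode_range)
          g <- gcorr(w, temps) - ref_g
          mid <- ceiling(length(temps) / 2)
          de <- kjmol_to_hartree(targets[mid] - g[mid])
        } else {
          de <- kjmol_to_hartree(targets[1] - (zpe(w) - ref_g))
        }
        if (imag > 0) w <- c(-imag, w)
        list(w = w, e = e_prev + de)
      }
      ts_n <- make_node(draw_modes(spec$n_modes - 1L), st$target_dG_act,
                        st$im_wavenumber)
      if (ts_n$e <= e_prev - 1e-12 && spec$target_kind == "gibbs" &&
          all(st$target_dG_act < 0))
        stop("generate_reaction_case: negative required barrier for step '",
             st$label, "'")
      nodes[[length(nodes) + 1L]] <- species(
        label = paste0("TS_", spec$case_label, "_", st$label),
        role = "transition_state",
        energies = list(bhlyp = ts_n$e, pbe = ts_n$e - spec$level_offset),
        wavenumbers = ts_n$w)
      min_n <- make_node(draw_modes(spec$n_modes), st$target_dG_rxn, 0)
      is_last <- si == length(spec$steps)
      nodes[[length(nodes) + 1L]] <- species(
        label = paste0(if (is_last) "P_" else "I_", spec$case_label,
                       if (!is_last) paste0("_", si) else ""),
        role = if (is_last) "product_complex" else "intermediate",
        energies = list(bhlyp = min_n$e, pbe = min_n$e - spec$level_offset),
        wavenumbers = min_n$w)
      prev_min_i <- length(nodes)
      truth[[si]] <- data.frame(
        step = st$label,
        temperature = temps,
        target_dG_act = st$target_dG_act,
        target_dG_rxn = st$target_dG_rxn,
        target_kind = spec$target_kind)
    }
    path <- reaction_path(
      case_label = spec$case_label, nodes = nodes, reference_index = 1L,
      step_labels = vapply(spec$steps, function(s) s$label, ""))
    structure(list(path = path, spec = spec, truth = do.call(rbind, truth)),
              class = "synthetic_case")
  })
}

#' Perturb a synthetic case with Gaussian energy noise
#'
#' Adds independent Gaussian noise (one draw per non-reference node,
#' applied to all theory levels of that node) to the electronic energies,
#' propagating a DFT-level uncertainty — typically ~4 kJ mol^-1 — into
#' downstream rates and profile flags for sensitivity analysis.
#'
#' @param case A `synthetic_case` from [generate_reaction_case()].
#' @param noise_sd Standard deviation of the energy noise, kJ mol^-1.
#' @param seed Integer seed for the noise draws.
#' @return A perturbed `synthetic_case`.
#' @export
perturb_case <- function(case, noise_sd, seed) {
  stopifnot(inherits(case, "synthetic_case"), noise_sd >= 0)
  if (noise_sd == 0) return(case)
  with_seed(seed, {
    nodes <- case$path$nodes
    for (i in seq_along(nodes)) {
      if (i == case$path$reference_index) next
      eps <- kjmol_to_hartree(stats::rnorm(1, 0, noise_sd))
      nodes[[i]]$energies <- lapply(nodes[[i]]$energies, function(e) e + eps)
    }
    case$path$nodes <- nodes
    case
  })
}

#' Model potentials with documented analytic Hessians
#'
#' Registry of simple analytic potentials for exercising the numerical
#' Hessian and harmonic-analysis machinery, each with a known closed-form
#' answer attached as attribute `analytic` (a list; contents depend on the
#' kind).
#'
#' * `harmonic_well`: isotropic well V = f/2 * |r|^2 on one atom
#'   (params `f` in N m^-1, `mass` in amu, optional `dims` in 1:3 to
#'   restrict the well to the first coordinates). `analytic$hessian_Nm`
#'   gives the diagonal in N m^-1; `analytic$wavenumber` the harmonic
#'   wavenumber (1/2 pi c) sqrt(f/m).
#' * `saddle_2d`: V = f/2 (x^2 - y^2) on one atom; eigenvalues {+f, -f}
#'   (and 0 for the unused z).
#' * `morse_1d`: V = D (1 - exp(-a x))^2; harmonic limit wavenumber from
#'   force constant 2 D a^2.
#'
#' @param kind One of `"harmonic_well"`, `"saddle_2d"`, `"morse_1d"`.
#' @param params Named list of parameters (see above; all have defaults
#'   `f = 100`, `mass = 1`, `D = 400` kJ mol^-1, `a = 2` per Angstrom).
#' @return A [model_potential()] with attribute `analytic`.
#' @export
generate_model_potential <- function(kind, params = list()) {
  cst <- surfkin_constants
  nm_to_kjA2 <- cst$NA_ * cst$angstrom_m^2 / 1000   # N/m -> kJ/mol/A^2
  p <- utils::modifyList(list(f = 100, mass = 1, D = 400, a = 2, dims = 3L),
                         params)
  if (kind == "harmonic_well") {
    fA <- p$f * nm_to_kjA2
    dims <- p$dims
    pot <- model_potential(
      energy = function(xyz) 0.5 * fA * sum(xyz[1, seq_len(dims)]^2),
      masses = p$mass, coords0 = matrix(0, 1, 3), label = "harmonic_well")
    attr(pot, "analytic") <- list(
      hessian_Nm = c(rep(p$f, dims), rep(0, 3L - dims)),
      wavenumber = sqrt(p$f / (p$mass * cst$amu_kg)) / (2 * pi * cst$c_cm))
    pot
  } else if (kind == "saddle_2d") {
    fA <- p$f * nm_to_kjA2
    pot <- model_potential(
      energy = function(xyz) 0.5 * fA * (xyz[1, 1]^2 - xyz[1, 2]^2),
      masses = p$mass, coords0 = matrix(0, 1, 3), label = "saddle_2d")
    attr(pot, "analytic") <- list(
      eigenvalues_Nm = c(p$f, -p$f, 0),
      im_wavenumber = sqrt(p$f / (p$mass * cst$amu_kg)) / (2 * pi * cst$c_cm))
    pot
  } else if (kind == "morse_1d") {
    pot <- model_potential(
      energy = function(xyz) p$D * (1 - exp(-p$a * xyz[1, 1]))^2,
      masses = p$mass, coords0 = matrix(0, 1, 3), label = "morse_1d")
    k_harm <- 2 * p$D * p$a^2 / nm_to_kjA2          # N/m
    attr(pot, "analytic") <- list(
      force_constant_Nm = k_harm,
      wavenumber = sqrt(k_harm / (p$mass * cst$amu_kg)) / (2 * pi * cst$c_cm))
    pot
  } else {
    stop("generate_model_potential: unknown kind '", kind, "'")
  }
}
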