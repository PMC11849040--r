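#' Eyring (canonical TST) rate constant
#'
#' k = (kB T / h) exp(-dG_act / RT) for a unimolecular elementary step.
#'
#' @param dG_act Activation Gibbs energy, kJ mol^-1.
#' @param T Temperature in K, > 0 (vectorized; `dG_act` and `T` recycle).
#' @return Rate constant in s^-1.
#' @examples
#' eyring_rate(0, 300)      # kB*300/h ~ 6.25e12
#' eyring_rate(95.8, 300)   # ~1.3e-4
#' @export
eyring_rate <- function(dG_act, T) {
  if (any(!is.finite(T)) || any(T <= 0))
    stop("eyring_rate: T must be > 0")
  cst <- surfkin_constants
  (cst$kB * T / cst$h) * exp(-dG_act * 1000 / (cst$R * T))
}

#' First-order half-life in hours
#'
#' t_1/2 = ln(2) / (3600 k). A zero rate maps to infinity. With a nonzero
#' `floor_k` (table mode), rates below the floor are treated as zero — the
#' convention used when rendering rate tables, where k < 1e-19 s^-1 prints
#' as 0 and the half-life as infinity. Computation elsewhere never floors.
#'
#' @param k Rate constant(s), s^-1, >= 0.
#' @param floor_k Rates below this are treated as zero (default 0: off).
#' @return Half-life in hours.
#' @examples
#' half_life(log(2) / 3600)  # exactly 1 h
#' half_life(4.3e-4)         # ~0.45 h
#' @export
half_life <- function(k, floor_k = 0) {
  if (any(!is.finite(k) | k < 0)) stop("half_life: k must be >= 0")
  k <- ifelse(k < floor_k, 0, k)
  ifelse(k == 0, Inf, log(2) / (3600 * k))
}

#' Per-temperature rate records for one elementary step
#'
#' Runs the kinetics pipeline for one elementary step of a reaction path at
#' each requested temperature: intrinsic activation/reaction Gibbs energies
#' from [relative_gibbs()], a classical rate constant (canonical RRKM by
#' default, bare Eyring optionally), an Eckart tunneling factor, the
#' tunneled rate, and the half-life of the reported rate.
#'
#' The tunneling policy mirrors common practice for surface proton
#' transfers: `"auto"` applies the Eckart correction only to steps whose
#' imaginary mode exceeds `tunnel_threshold` (light-particle motion),
#' `"all"` to every step with a usable barrier, `"none"` never. Steps whose
#' reverse ZPE-corrected barrier is non-positive (TS/product inversion)
#' fall back to kappa = 1 with a warning, since the 1-D Eckart model is
#' undefined there.
#'
#' @param path A [reaction_path()].
#' @param level Theory level (string or [theory_level()]).
#' @param step Step label (must match the path's step labels) or index.
#' @param temperatures Numeric vector of temperatures, K.
#' @param tunnel `"auto"`, `"all"`, or `"none"`.
#' @param tunnel_threshold Imaginary-mode threshold for `"auto"`, cm^-1.
#' @param method `"rrkm"` (canonical RRKM from the step's own species) or
#'   `"eyring"`.
#' @param grain RRKM energy grain, cm^-1.
#' @return Data.frame of rate records: `case`, `step`, `temperature`,
#'   `dG_act`, `dG_rxn` (kJ mol^-1), `k_class`, `kappa`, `k_tunn` (s^-1),
#'   `half_life` (h, from `k_tunn`).
#' @export
step_rates <- function(path, level, step, temperatures,
                       tunnel = c("auto", "all", "none"),
                       tunnel_threshold = 800,
                       method = c("rrkm", "eyring"), grain = 5) {
  tunnel <- match.arg(tunnel)
  method <- match.arg(method)
  steps <- path_steps(path)
  labels <- vapply(steps, function(s) s$label, "")
  i <- if (is.character(step)) match(step, labels) else as.integer(step)
  if (is.na(i) || i < 1L || i > length(steps))
    stop("step_rates: no step '", step, "' in path ", path$case_label)
  st <- steps[[i]]
  if (is.na(st$ts))
    stop("step_rates: step '", st$label, "' is barrierless; no TS rate")
  reactant <- path$nodes[[st$from]]
  ts <- path$nodes[[st$ts]]
  lev <- as_theory_level(level)
  prof <- build_profile(path, lev, include_zpe = TRUE)
  dH0_act <- prof$steps$dH0_act[i]
  dH0_rxn <- prof$steps$dH0_rxn[i]
  im <- abs(ts$wavenumbers[ts$wavenumbers < 0])
  want_kappa <- switch(tunnel, none = FALSE, all = TRUE,
                       auto = im > tunnel_threshold)
  barrier <- NULL
  if (want_kappa) {
    if (dH0_act <= 0 || dH0_act - dH0_rxn <= 0) {
      warning("step '", st$label, "': non-positive forward/reverse ",
              "ZPE-corrected barrier; Eckart tunneling skipped (kappa = 1)",
              call. = FALSE)
      want_kappa <- FALSE
    } else {
      barrier <- eckart_barrier(dH0_act, dH0_act - dH0_rxn, im)
    }
  }
  records <- lapply(temperatures, function(T) {
    rg <- relative_gibbs(path, lev, T)
    dG_act <- rg$steps$dG_act[i]
    dG_rxn <- rg$steps$dG_rxn[i]
    k_class <- if (method == "rrkm")
      rrkm_canonical(reactant, ts, E0 = max(dH0_act, 0), T = T,
                     grain = grain)
    else eyring_rate(dG_act, T)
    kap <- if (want_kappa) eckart_kappa(T, barrier) else 1
    k_tunn <- kap * k_class
    data.frame(case = path$case_label, step = st$label, temperature = T,
               dG_act = dG_act, dG_rxn = dG_rxn,
               k_class = k_class, kappa = kap, k_tunn = k_tunn,
               half_life = half_life(k_tunn))
  })
  do.call(rbind, records)
}

#' Arrhenius table and fit
#'
#' `arrhenius_table()` evaluates [step_rates()] on a temperature grid (the
#' classic presentation is 50-300 K); `fit_arrhenius()` least-squares fits
#' ln k = ln A - Ea/(R T) and returns the pre-exponential factor and
#' activation energy. With tunneling the Arrhenius plot curves upward at
#' low temperature, so the fitted Ea depends on the window — fit narrow
#' windows when comparing against classical expectations.
#'
#' @param path,level,step,tunnel,method,grain Passed to [step_rates()].
#' @param T_grid Temperatures in K (>= 3 for a fit).
#' @return `arrhenius_table()`: the rate-record data.frame.
#'   `fit_arrhenius()`: list with `A` (s^-1), `Ea` (kJ mol^-1), and the
#'   underlying `lm` fit.
#' @export
arrhenius_table <- function(path, level, step, T_grid,
                            tunnel = "auto", method = "rrkm", grain = 5) {
  step_rates(path, level, step, T_grid, tunnel = tunnel, method = method,
             grain = grain)
}

#' @rdname arrhenius_table
#' @param records Rate-record data.frame with columns `temperature` and
#'   either `k_tunn` or `k_class`.
#' @param use Which rate column to fit (`"k_tunn"` or `"k_class"`).
#' @export
fit_arrhenius <- function(records, use = c("k_tunn", "k_class")) {
  use <- match.arg(use)
  k <- records[[use]]
  T <- records$temperature
  if (length(k) < 3L) stop("fit_arrhenius: need at least 3 temperatures")
  if (any(k <= 0))
    stop("fit_arrhenius: all rates must be > 0 (log undefined at k = 0)")
  fit <- stats::lm(log(k) ~ I(1 / T))
  co <- stats::coef(fit)
  list(A = exp(unname(co[1])),
       Ea = -unname(co[2]) * surfkin_constants$R / 1000,
       fit = fit)
}

# 2-significant-figure rate/half-life formatting used in rendered tables
fmt_rate <- function(x) {
  vapply(x, function(v) {
    if (!is.finite(v)) return("inf")
    if (v == 0) return("0")
    s <- signif(v, 2)
    if (s >= 0.01 && s < 1e4) format(s, scientific = FALSE)
    else sprintf("%.1e", s)
  }, "")
}

#' Write a rate table to TSV
#'
#' Renders rate records in the customary reaction-table layout: one row per
#' quantity (dG_act, dG_rxn, k, t_half) per step per case, one column per
#' temperature. Energies print with 1 decimal, rates and half-lives with 2
#' significant figures; rates below 1e-19 s^-1 render as `0` and their
#' half-lives as `inf`. The writer is deterministic: identical input gives
#' byte-identical output.
#'
#' @param records Rate-record data.frame (from [step_rates()] or
#'   [run_pipeline()]); every (case, step) group must cover the same
#'   temperature grid.
#' @param path Output file path.
#' @param k_floor Rates below this render as zero (default 1e-19).
#' @param use Rate column to render.
#' @return `path`, invisibly.
#' @export
write_rate_table <- function(records, path, k_floor = 1e-19,
                             use = c("k_tunn", "k_class")) {
  use <- match.arg(use)
  temps <- sort(unique(records$temperature))
  header <- paste(c("case", "quantity", temps), collapse = "\t")
  lines <- header
  if (nrow(records) > 0) {
    groups <- unique(records[, c("case", "step")])
    for (gi in seq_len(nrow(groups))) {
      sel <- records$case == groups$case[gi] & records$step == groups$step[gi]
      rec <- records[sel, ]
      rec <- rec[order(rec$temperature), ]
      if (!identical(rec$temperature, temps))
        stop("write_rate_table: case ", groups$case[gi], " step ",
             groups$step[gi], " does not cover the common temperature grid")
      kk <- rec[[use]]
      kk_floored <- ifelse(kk < k_floor, 0, kk)
      tag <- function(q) paste0(q, "^", groups$step[gi])
      lines <- c(
        lines,
        paste(c(groups$case[gi], tag("dG_act"),
                sprintf("%.1f", rec$dG_act)), collapse = "\t"),
        paste(c(groups$case[gi], tag("dG_rxn"),
                sprintf("%.1f", rec$dG_rxn)), collapse = "\t"),
        paste(c(groups$case[gi], tag("k"),
                fmt_rate(kk_floored)), collapse = "\t"),
        paste(c(groups$case[gi], tag("t_half"),
                fmt_rate(half_life(kk, floor_k = k_floor))), collapse = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
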