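#' Theory level (plain or composite)
#'
#' A composite level "high//low" means: single-point electronic energy at
#' `energy_level` on geometries (and frequencies) optimized at
#' `geometry_level`. A plain level has both identifiers equal.
#'
#' @param energy_level Level used for the electronic energy.
#' @param geometry_level Level of the optimization/frequency calculation.
#' @return An object of class `theory_level`.
#' @export
theory_level <- function(energy_level, geometry_level = energy_level) {
  if (!nzchar(energy_level) || !nzchar(geometry_level))
    stop("theory_level: identifiers must be non-empty")
  structure(list(energy_level = energy_level,
                 geometry_level = geometry_level),
            class = "theory_level")
}

#' @export
print.theory_level <- function(x, ...) {
  cat("<theory_level> ", x$energy_level,
      if (x$energy_level != x$geometry_level)
        paste0("//", x$geometry_level), "\n", sep = "")
  invisible(x)
}

# accept a theory_level, a "high//low" string, or a plain level string
as_theory_level <- function(level) {
  if (inherits(level, "theory_level")) return(level)
  if (is.character(level) && length(level) == 1L) {
    parts <- strsplit(level, "//", fixed = TRUE)[[1]]
    if (length(parts) == 2L) return(theory_level(parts[1], parts[2]))
    return(theory_level(level))
  }
  stop("cannot interpret '", format(level), "' as a theory level")
}

#' Composite-level electronic energy of a species
#'
#' Returns the high-level single-point energy of a species whose geometry
#' (and frequency set) come from the low level. When the two identifiers
#' coincide this is the plain energy. All ZPE/thermal corrections applied
#' downstream always derive from the geometry-level frequencies.
#'
#' @param species A [species()] carrying energies at both levels.
#' @param high_level,low_level Theory-level identifiers.
#' @return Electronic energy in hartree.
#' @export
composite_energy <- function(species, high_level, low_level = high_level) {
  for (lev in unique(c(high_level, low_level))) {
    if (is.null(species$energies[[lev]]))
      stop("species '", species$label, "' has no energy at level '", lev, "'")
  }
  species$energies[[high_level]]
}

#' Build a (ZPE-corrected) reaction energy profile
#'
#' Computes, for every node of a reaction path, the relative composite
#' electronic energy Delta E and (optionally) the ZPE-corrected relative
#' enthalpy at 0 K, Delta H(0 K) = Delta E + Delta ZPE, against the path's
#' declared zero-energy reference. Per-step intrinsic barriers and reaction
#' energies (against the step's own pre-reaction minimum) are reported
#' alongside, since both conventions are in common use.
#'
#' @param path A [reaction_path()].
#' @param level A [theory_level()] or level string (e.g. `"bhlyp//pbe"`).
#' @param include_zpe Include the Delta H(0 K) column (default `TRUE`).
#' @return Object of class `reaction_profile`: list with `nodes`
#'   (data.frame: label, role, step tag, dE, dH0, kJ mol^-1) and `steps`
#'   (data.frame: label, dE_act, dE_rxn and, with ZPE, dH0_act, dH0_rxn —
#'   intrinsic, i.e. vs the preceding minimum).
#' @export
build_profile <- function(path, level, include_zpe = TRUE) {
  lev <- as_theory_level(level)
  e <- vapply(path$nodes, function(s)
    composite_energy(s, lev$energy_level, lev$geometry_level), 0)
  e_rel <- hartree_to_kjmol(e - e[path$reference_index])
  z <- if (include_zpe)
    vapply(path$nodes, function(s) zpe(s$wavenumbers), 0) else NULL
  roles <- vapply(path$nodes, function(s) s$role, "")
  steps <- path_steps(path)
  step_tag <- rep(NA_character_, length(path$nodes))
  for (st in steps) if (!is.na(st$ts)) step_tag[st$ts] <- st$label
  nodes <- data.frame(
    label = vapply(path$nodes, function(s) s$label, ""),
    role = roles, step = step_tag, dE = e_rel)
  if (include_zpe) {
    h0 <- e_rel + z
    nodes$dH0 <- h0 - h0[path$reference_index]
  }
  abs_e <- e_rel
  abs_h <- if (include_zpe) e_rel + z else NULL
  step_df <- do.call(rbind, lapply(steps, function(st) {
    row <- data.frame(
      step = st$label,
      dE_act = if (is.na(st$ts)) NA_real_ else abs_e[st$ts] - abs_e[st$from],
      dE_rxn = abs_e[st$to] - abs_e[st$from])
    if (include_zpe) {
      row$dH0_act <- if (is.na(st$ts)) NA_real_ else abs_h[st$ts] - abs_h[st$from]
      row$dH0_rxn <- abs_h[st$to] - abs_h[st$from]
    }
    row
  }))
  structure(list(case_label = path$case_label, level = lev,
                 nodes = nodes, steps = step_df,
                 include_zpe = include_zpe),
            class = "reaction_profile")
}

#' @export
print.reaction_profile <- function(x, ...) {
  cat("<reaction_profile> ", x$case_label, " @ ", x$level$energy_level,
      if (x$level$energy_level != x$level$geometry_level)
        paste0("//", x$level$geometry_level),
      "\n", sep = "")
  print(x$nodes, row.names = FALSE)
  invisible(x)
}

#' Binding (adsorption) energy of a surface complex
#'
#' BE = E(complex) - E(bare surface) - sum E(free adsorbates), all at the
#' same theory level. Negative = bound, following the usual adsorption
#' convention.
#'
#' @param complex,surface [species()] objects.
#' @param adsorbates List of [species()] (the free molecules).
#' @param level Theory-level identifier (plain level; all energies must
#'   carry it).
#' @return A one-row data.frame: `complex`, `BE` (kJ mol^-1), `level`.
#' @export
binding_energy <- function(complex, surface, adsorbates, level) {
  all_sp <- c(list(complex, surface), adsorbates)
  for (s in all_sp) {
    if (is.null(s$energies[[level]]))
      stop("species '", s$label, "' has no energy at level '", level,
           "': binding energies require a single common level")
  }
  e_ads <- if (length(adsorbates) > 0)
    sum(vapply(adsorbates, function(s) s$energies[[level]], 0)) else 0
  be <- hartree_to_kjmol(complex$energies[[level]] -
                         surface$energies[[level]] - e_ads)
  data.frame(complex = complex$label, BE = be, level = level,
             stringsAsFactors = FALSE)
}

#' Binding-energy difference bookkeeping across sites
#'
#' For each site, Delta BE = BE(product) - BE(reactant); across sites the
#' table reports the cross-site differences of Delta BE, side by side with a
#' user-supplied reaction-energy difference (e.g. Delta Delta H(0 K)) for
#' inspection. No equality is asserted: in the motivating study the binding
#' energies and the reaction energies come from different theory levels, so
#' the comparison is advisory only.
#'
#' @param reactant_BE,product_BE Data.frames from [binding_energy()] (or
#'   any with columns `complex`, `BE`), one row per site, aligned by `site`.
#' @param site Character vector of site labels, one per row.
#' @param ddH Optional numeric: the reaction-energy differences between
#'   consecutive site pairs for the side-by-side column.
#' @return List with `per_site` (site, dBE) and `cross_site` (site pair,
#'   ddBE, and ddH if supplied).
#' @export
delta_be_consistency <- function(reactant_BE, product_BE, site,
                                 ddH = NULL) {
  stopifnot(nrow(reactant_BE) == nrow(product_BE),
            length(site) == nrow(reactant_BE))
  dbe <- product_BE$BE - reactant_BE$BE
  per_site <- data.frame(site = site, dBE = dbe, stringsAsFactors = FALSE)
  cross <- NULL
  if (length(site) >= 2L) {
    pairs <- utils::combn(seq_along(site), 2L)
    cross <- data.frame(
      pair = apply(pairs, 2L, function(p)
        paste(site[p[1]], "vs", site[p[2]])),
      ddBE = apply(pairs, 2L, function(p) dbe[p[1]] - dbe[p[2]]),
      stringsAsFactors = FALSE)
    if (!is.null(ddH)) cross$ddH <- ddH
  }
  list(per_site = per_site, cross_site = cross)
}

#' Validate a reaction profile
#'
#' Scans a ZPE-corrected profile for (i) transition states lying below an
#' adjacent minimum — the TS/product "inversion of stability" that ZPE
#' corrections can produce — graded against a DFT-accuracy tolerance
#' (default 4 kJ mol^-1: gaps within it read "within DFT accuracy", i.e.
#' the step may effectively be barrierless); (ii) endothermic steps; and
#' (iii) steps flagged barrierless by construction.
#'
#' @param profile A [reaction_profile()] built with ZPE.
#' @param tolerance DFT-accuracy tolerance in kJ mol^-1 (default 4).
#' @return Data.frame of flags: `type` (`"inversion"`, `"endothermic_step"`,
#'   `"barrierless"`), `step`, `gap` (kJ mol^-1, for inversions the amount
#'   the TS lies below the neighbor), `severity` (`"within_dft_accuracy"`
#'   or `"beyond_tolerance"`, inversions only). Zero rows if nothing to
#'   flag.
#' @export
validate_profile <- function(profile, tolerance = 4) {
  stopifnot(inherits(profile, "reaction_profile"))
  if (!profile$include_zpe)
    stop("validate_profile: profile must be built with include_zpe = TRUE")
  energy <- profile$nodes$dH0
  roles <- profile$nodes$role
  flags <- list()
  add <- function(...) flags[[length(flags) + 1L]] <<- data.frame(...)
  for (i in which(roles == "transition_state")) {
    for (j in c(i - 1L, i + 1L)) {
      if (j < 1L || j > length(energy)) next
      gap <- energy[j] - energy[i]          # > 0: neighbor above the TS
      if (gap > 0) {
        add(type = "inversion",
            step = if (is.na(profile$nodes$step[i])) "" else profile$nodes$step[i],
            node = profile$nodes$label[j], gap = gap,
            severity = if (gap <= tolerance) "within_dft_accuracy"
                       else "beyond_tolerance")
      }
    }
  }
  if (nrow(profile$steps) > 0) {
    for (k in seq_len(nrow(profile$steps))) {
      if (profile$steps$dH0_rxn[k] > 0)
        add(type = "endothermic_step", step = profile$steps$step[k],
            node = "", gap = profile$steps$dH0_rxn[k], severity = "")
      if (is.na(profile$steps$dH0_act[k]))
        add(type = "barrierless", step = profile$steps$step[k],
            node = "", gap = NA_real_, severity = "")
    }
  }
  if (length(flags) == 0L)
    return(data.frame(type = character(), step = character(),
                      node = character(), gap = numeric(),
                      severity = character(), stringsAsFactors = FALSE))
  do.call(rbind, flags)
}
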