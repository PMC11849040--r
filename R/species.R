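#' Stationary-point species
#'
#' A `species` object holds everything the kinetics pipeline needs about one
#' stationary point of a potential energy surface: electronic energies at one
#' or more theory levels, the harmonic wavenumber set from a (possibly
#' partial) Hessian, and optionally the geometry and the mobile-atom mask
#' that generated the frequency set.
#'
#' Imaginary modes are stored as negative wavenumbers: a transition state
#' carries exactly one negative wavenumber, any minimum carries none.
#'
#' @param label Character scalar naming the stationary point.
#' @param role One of `"reactant_complex"`, `"intermediate"`,
#'   `"transition_state"`, `"product_complex"`, `"bare_surface"`,
#'   `"free_molecule"`.
#' @param energies Named numeric vector or list: electronic energy in hartree
#'   keyed by theory-level identifier (e.g. `"pbe"`, `"bhlyp"`).
#' @param wavenumbers Numeric vector of harmonic wavenumbers in cm^-1;
#'   negative values encode imaginary modes.
#' @param geometry Optional data.frame with columns `element`, `x`, `y`, `z`
#'   (Angstrom).
#' @param mobile_mask Optional integer vector of 0-based atom indices whose
#'   displacements generated the frequency set.
#' @return An object of class `species`.
#' @export
species <- function(label, role, energies, wavenumbers,
                    geometry = NULL, mobile_mask = NULL) {
  obj <- structure(
    list(label = label, role = role,
         energies = as.list(energies),
         wavenumbers = as.numeric(wavenumbers),
         geometry = geometry, mobile_mask = mobile_mask),
    class = "species")
  validate_species(obj)
}

species_roles <- c("reactant_complex", "intermediate", "transition_state",
                   "product_complex", "bare_surface", "free_molecule")

#' Validate a species object against its invariants
#'
#' Checks the role-dependent imaginary-mode count (a transition state has one
#' and only one imaginary frequency, minima have none), finiteness of the
#' energies, wavenumber magnitudes in (0, 5000) cm^-1, and mobile-mask
#' consistency with the geometry when both are present.
#'
#' @param x A `species` object.
#' @return `x`, invisibly-validated (returned unchanged) on success.
#' @export
validate_species <- function(x) {
  stopifnot(inherits(x, "species"))
  if (!is.character(x$label) || length(x$label) != 1L || !nzchar(x$label))
    stop("species: 'label' must be a non-empty string")
  if (!(x$role %in% species_roles))
    stop("species '", x$label, "': unknown role '", x$role, "'")
  if (length(x$energies) == 0L || is.null(names(x$energies)) ||
      any(!nzchar(names(x$energies))))
    stop("species '", x$label, "': 'energies' must be named by theory level")
  en <- unlist(x$energies)
  if (!is.numeric(en) || any(!is.finite(en)))
    stop("species '", x$label, "': all energies must be finite numbers")
  w <- x$wavenumbers
  if (length(w) == 0L || any(!is.finite(w)))
    stop("species '", x$label, "': wavenumbers must be non-empty and finite")
  if (any(abs(w) <= 0) || any(abs(w) >= 5000))
    stop("species '", x$label,
         "': wavenumber magnitudes must lie in (0, 5000) cm^-1")
  n_imag <- sum(w < 0)
  if (x$role == "transition_state" && n_imag != 1L)
    stop("species '", x$label, "': a transition_state must have exactly one ",
         "imaginary mode, found ", n_imag)
  if (x$role != "transition_state" && n_imag != 0L)
    stop("species '", x$label, "': role '", x$role,
         "' must have zero imaginary modes, found ", n_imag)
  if (!is.null(x$geometry)) {
    g <- x$geometry
    if (!is.data.frame(g) || !all(c("element", "x", "y", "z") %in% names(g)))
      stop("species '", x$label,
           "': geometry must have columns element, x, y, z")
    if (!is.null(x$mobile_mask)) {
      m <- x$mobile_mask
      if (any(m != floor(m)) || anyDuplicated(m) ||
          any(m < 0) || any(m >= nrow(g)))
        stop("species '", x$label,
             "': mobile_mask indices must be unique, 0-based, < n_atoms")
    }
  }
  x
}

#' @export
print.species <- function(x, ...) {
  cat("<species> ", x$label, " [", x$role, "]\n", sep = "")
  cat("  levels: ", paste(names(x$energies), collapse = ", "), "\n", sep = "")
  cat("  modes:  ", length(x$wavenumbers), " (",
      sum(x$wavenumbers < 0), " imaginary)\n", sep = "")
  invisible(x)
}

#' Number of imaginary modes of a species
#' @param x A `species`.
#' @return Integer count of negative wavenumbers.
#' @export
n_imaginary <- function(x) sum(x$wavenumbers < 0)

# parse one wavenumber entry that may be a negative number or an
# "i"-suffixed string form, e.g. "450i" == imaginary 450 cm^-1 == -450
parse_wavenumber <- function(v) {
  if (is.numeric(v)) return(as.numeric(v))
  s <- trimws(as.character(v))
  imag <- grepl("i$", s)
  num <- suppressWarnings(as.numeric(sub("i$", "", s)))
  if (any(is.na(num)))
    stop("unparseable wavenumber entry: '", s[is.na(num)][1], "'")
  ifelse(imag, -abs(num), num)
}

SPECIES_SCHEMA_VERSION <- 1L

#' Read / write a species file
#'
#' Species files are YAML with fields `schema_version`, `label`, `role`,
#' `energies` (map theory level -> hartree), `wavenumbers` (sequence;
#' imaginary modes either negative numbers or `"450i"`-style strings),
#' and optional `geometry` (sequence of `[element, x, y, z]`) and
#' `mobile_mask` (sequence of 0-based atom indices). The full schema is
#' described in the package vignette.
#'
#' @param path File path.
#' @return `read_species()` returns a validated [species()];
#'   `write_species()` returns `path` invisibly.
#' @export
read_species <- function(path) {
  doc <- yaml::read_yaml(path)
  for (f in c("label", "role", "energies", "wavenumbers")) {
    if (is.null(doc[[f]]))
      stop("species file '", path, "': missing required field '", f, "'")
  }
  geometry <- NULL
  if (!is.null(doc$geometry)) {
    rows <- doc$geometry
    geometry <- data.frame(
      element = vapply(rows, function(r) as.character(r[[1]]), ""),
      x = vapply(rows, function(r) as.numeric(r[[2]]), 0),
      y = vapply(rows, function(r) as.numeric(r[[3]]), 0),
      z = vapply(rows, function(r) as.numeric(r[[4]]), 0),
      stringsAsFactors = FALSE)
  }
  wn <- vapply(doc$wavenumbers, parse_wavenumber, 0)
  species(label = doc$label, role = doc$role,
          energies = lapply(doc$energies, as.numeric),
          wavenumbers = wn, geometry = geometry,
          mobile_mask = if (!is.null(doc$mobile_mask))
            as.integer(doc$mobile_mask))
}

#' @rdname read_species
#' @param x A `species` object to serialize.
#' @export
write_species <- function(x, path) {
  validate_species(x)
  doc <- list(
    schema_version = SPECIES_SCHEMA_VERSION,
    label = x$label,
    role = x$role,
    # format with full precision: round-trip to 12+ significant figures
    energies = lapply(x$energies, function(e) as.numeric(format(e, digits = 17))),
    wavenumbers = as.numeric(format(x$wavenumbers, digits = 17)))
  if (!is.null(x$geometry)) {
    doc$geometry <- lapply(seq_len(nrow(x$geometry)), function(i)
      list(x$geometry$element[i], x$geometry$x[i], x$geometry$y[i],
           x$geometry$z[i]))
  }
  if (!is.null(x$mobile_mask)) doc$mobile_mask <- as.integer(x$mobile_mask)
  yaml::write_yaml(doc, path, precision = 17)
  invisible(path)
}
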