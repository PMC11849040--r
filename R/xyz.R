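# standard XYZ geometry I/O (atom count, comment line, element x y z in Angstrom)

element_symbols <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
  "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr",
  "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba")

#' Read / write XYZ geometry files
#'
#' Standard XYZ dialect: first line is the atom count, second a free comment,
#' then one `element x y z` line per atom with coordinates in Angstrom.
#' Round trips preserve coordinates to at least 6 decimals.
#'
#' @param path File path.
#' @return `read_xyz()` returns a data.frame with columns `element`, `x`,
#'   `y`, `z`; `write_xyz()` returns `path` invisibly.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("XYZ file '", path, "': truncated header")
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) stop("XYZ file '", path, "': first line is not an atom count")
  body <- lines[-(1:2)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != n)
    stop("XYZ file '", path, "': atom count ", n, " but ",
         length(body), " atom lines")
  toks <- strsplit(trimws(body), "[[:space:]]+")
  bad <- vapply(toks, length, 0L) < 4L
  if (any(bad)) stop("XYZ file '", path, "': malformed atom line: '",
                     body[bad][1], "'")
  el <- vapply(toks, `[[`, "", 1L)
  unknown <- setdiff(el, element_symbols)
  if (length(unknown) > 0)
    stop("XYZ file '", path, "': unknown element token '", unknown[1], "'")
  data.frame(
    element = el,
    x = vapply(toks, function(t) as.numeric(t[2]), 0),
    y = vapply(toks, function(t) as.numeric(t[3]), 0),
    z = vapply(toks, function(t) as.numeric(t[4]), 0),
    stringsAsFactors = FALSE)
}

#' @rdname read_xyz
#' @param geometry Data.frame with columns `element`, `x`, `y`, `z`, or a
#'   [species()] carrying a geometry.
#' @param comment Comment line content.
#' @export
write_xyz <- function(geometry, path, comment = "") {
  if (inherits(geometry, "species")) {
    if (is.null(geometry$geometry))
      stop("species '", geometry$label, "' has no geometry")
    if (!nzchar(comment)) comment <- geometry$label
    geometry <- geometry$geometry
  }
  lines <- c(
    as.character(nrow(geometry)),
    comment,
    sprintf("%-3s %16.8f %16.8f %16.8f",
            geometry$element, geometry$x, geometry$y, geometry$z))
  writeLines(lines, path)
  invisible(path)
}
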