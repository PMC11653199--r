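# Molecular geometries. Coordinates are bohr internally; XYZ files are
# angstrom at the I/O boundary, per convention.

#' Construct a molecular geometry
#'
#' @param symbols character vector of element symbols (`"X"` = dummy).
#' @param coords N x 3 numeric matrix of positions.
#' @param units units of `coords`: `"bohr"` (default) or `"angstrom"`.
#' @param masses per-atom masses in electron masses; looked up from the
#'   element table when NULL.
#' @return an object of class `geometry` with coordinates in bohr.
#' @export
geometry <- function(symbols, coords, units = c("bohr", "angstrom"),
                     masses = NULL) {
  units <- match.arg(units)
  coords <- matrix(as.numeric(coords), ncol = 3)
  stopifnot(nrow(coords) >= 1, length(symbols) == nrow(coords),
            all(is.finite(coords)))
  if (units == "angstrom") coords <- coords * au$bohr_per_angstrom
  if (is.null(masses)) masses <- atomic_masses(symbols, "au")
  stopifnot(all(masses > 0), length(masses) == nrow(coords))
  structure(list(symbols = symbols, coords = coords, masses = masses),
            class = "geometry")
}

#' @export
print.geometry <- function(x, ...) {
  cat(sprintf("<geometry: %d atoms (bohr)>\n", nrow(x$coords)))
  for (i in seq_len(nrow(x$coords))) {
    cat(sprintf("  %-2s %12.6f %12.6f %12.6f\n", x$symbols[i],
                x$coords[i, 1], x$coords[i, 2], x$coords[i, 3]))
  }
  invisible(x)
}

#' Displace one Cartesian component of a geometry
#' @param geom a `geometry`; @param atom 1-based atom index;
#' @param axis 1 (x), 2 (y) or 3 (z); @param delta displacement in bohr.
#' @export
displace_geometry <- function(geom, atom, axis, delta) {
  geom$coords[atom, axis] <- geom$coords[atom, axis] + delta
  geom
}

#' Read an XYZ geometry file (angstrom)
#' @param path file path.
#' @return a `geometry` (bohr internally).
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1]))
  if (is.na(n) || length(lines) < n + 2) stop("malformed XYZ file: ", path)
  symbols <- character(n); coords <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    parts <- strsplit(trimws(lines[i + 2]), "\\s+")[[1]]
    symbols[i] <- parts[1]
    coords[i, ] <- as.numeric(parts[2:4])
  }
  geometry(symbols, coords, units = "angstrom")
}

#' Write an XYZ geometry file (angstrom)
#' @param geom a `geometry`; @param path file path;
#' @param comment second-line comment.
#' @export
write_xyz <- function(geom, path, comment = "") {
  ang <- geom$coords / au$bohr_per_angstrom
  lines <- c(sprintf("%d", nrow(ang)), comment,
             sprintf("%-2s %16.10f %16.10f %16.10f",
                     geom$symbols, ang[, 1], ang[, 2], ang[, 3]))
  writeLines(lines, path)
}
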