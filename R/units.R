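#' Physical constants and unit conversions
#'
#' All internal quantities are in Hartree atomic units (hartree, bohr,
#' electron mass, a.u. time). Angstrom, eV, fs and cm^-1 appear only at
#' I/O boundaries; these constants define the conversions.
#'
#' @format Named list with elements
#'   `bohr_per_angstrom`, `hartree_per_ev`, `fs_per_au_time`,
#'   `cm1_per_hartree`, `me_per_amu`.
#' @export
au <- list(
  bohr_per_angstrom = 1 / 0.52917721092,
  hartree_per_ev    = 1 / 27.211386245988,
  fs_per_au_time    = 0.02418884326509,
  cm1_per_hartree   = 219474.6313632,
  me_per_amu        = 1822.888486209
)

# isotope-averaged-ish standard masses (amu) for the elements this package
# is exercised on; most-abundant-isotope values, as customary in dynamics
.atomic_masses_amu <- c(
  H = 1.007825, D = 2.014102, He = 4.002603,
  C = 12.0, N = 14.003074, O = 15.994915, F = 18.998403,
  S = 31.972071, Cl = 34.968853, X = 1.0
)

#' Look up atomic masses
#'
#' @param symbols character vector of element symbols (`"X"` is a generic
#'   dummy atom of mass 1 amu, useful for model systems).
#' @param unit `"amu"` or `"au"` (electron masses).
#' @return numeric vector of masses.
#' @export
atomic_masses <- function(symbols, unit = c("au", "amu")) {
  unit <- match.arg(unit)
  m <- .atomic_masses_amu[symbols]
  if (anyNA(m)) {
    stop("unknown element symbol(s): ",
         paste(symbols[is.na(m)], collapse = ", "))
  }
  m <- unname(m)
  if (unit == "au") m * au$me_per_amu else m
}
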