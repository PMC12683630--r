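# Unit system.  Everything inside the package is atomic units: energies in
# hartree, lengths in bohr, times in atomic time units, temperatures in K.
# Conversions happen once, at the I/O boundary.  Factors are CODATA-2018.

# hartree expressed in each energy unit, etc.
.unit_factors <- list(
  energy = c(
    hartree    = 1,
    "cm-1"     = 219474.6313632,
    "kcal/mol" = 627.5094740631,
    eV         = 27.211386245988
  ),
  length = c(
    bohr     = 1,
    angstrom = 0.529177210903
  ),
  time = c(
    au_time = 1,
    fs      = 0.02418884326509
  ),
  temperature = c(K = 1)
)

# Boltzmann constant in hartree/K (molar gas constant on the per-molecule,
# atomic-unit scale; the (3N-6)RT energy target uses this).
.kB_hartree <- 3.166811563e-6

# atomic masses (standard atomic weights) in amu, and amu -> electron masses
.atomic_masses_amu <- c(C = 12.011, H = 1.008)
.amu_to_au <- 1822.888486209

.unit_dimension <- function(unit) {
  for (dim in names(.unit_factors)) {
    if (unit %in% names(.unit_factors[[dim]])) return(dim)
  }
  stop("unknown unit: '", unit, "'", call. = FALSE)
}

#' Convert a physical quantity between units
#'
#' Exact multiplicative conversion between units of the same dimension.
#' Supported units: energies \code{"hartree"}, \code{"cm-1"},
#' \code{"kcal/mol"}, \code{"eV"}; lengths \code{"bohr"},
#' \code{"angstrom"}; times \code{"au_time"}, \code{"fs"}; temperature
#' \code{"K"}.  Conversions round-trip to better than 1e-12 relative.
#'
#' @param value numeric vector.
#' @param from,to unit names.
#' @return numeric vector in the target unit.
#' @examples
#' convert_unit(5, "au_time", "fs")        # the MD step: 0.121 fs
#' convert_unit(115, "cm-1", "kcal/mol")   # 0.33
#' @export
convert_unit <- function(value, from, to) {
  df <- .unit_dimension(from)
  dt <- .unit_dimension(to)
  if (df != dt) {
    stop("incompatible dimensions: cannot convert ", from, " (", df,
         ") to ", to, " (", dt, ")", call. = FALSE)
  }
  if (from == to) return(value)
  f <- .unit_factors[[df]]
  value / f[[from]] * f[[to]]
}

#' Atomic masses
#'
#' Standard atomic weights for the supported element alphabet.
#'
#' @param elements character vector of element symbols ("C" or "H").
#' @param unit \code{"amu"} or \code{"au"} (electron masses).
#' @return numeric vector of masses.
#' @export
atomic_mass <- function(elements, unit = c("au", "amu")) {
  unit <- match.arg(unit)
  bad <- setdiff(unique(elements), names(.atomic_masses_amu))
  if (length(bad)) {
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  m <- .atomic_masses_amu[elements]
  names(m) <- elements
  if (unit == "au") m <- m * .amu_to_au
  m
}
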