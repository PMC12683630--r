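# Molecular structures and labelled datasets.  Coordinates are stored in
# bohr and energy labels in hartree, whatever the source units were.

#' Create a molecular structure
#'
#' A structure is an ordered set of atoms (element symbols from a
#' two-element alphabet, C and H by default) with Cartesian coordinates,
#' an optional energy label and an optional provenance tag.
#'
#' @param elements character vector of element symbols.
#' @param coords numeric N x 3 matrix of Cartesian coordinates.
#' @param energy optional scalar energy label.
#' @param units length unit of \code{coords} (\code{"angstrom"} or
#'   \code{"bohr"}).
#' @param energy_unit unit of \code{energy}.
#' @param tag optional provenance string (e.g. \code{"md"},
#'   \code{"displacement"}, \code{"random_pick"}).
#' @param bonds optional 2-column integer matrix of bonded atom pairs
#'   (used by the synthetic toy potential; carried through perturbations).
#' @param alphabet allowed element symbols.
#' @return an object of class \code{"mol_structure"}.
#' @export
mol_structure <- function(elements, coords, energy = NULL,
                          units = "angstrom", energy_unit = "hartree",
                          tag = NULL, bonds = NULL,
                          alphabet = c("C", "H")) {
  elements <- as.character(elements)
  coords <- matrix(as.numeric(coords), ncol = 3)
  if (nrow(coords) != length(elements)) {
    stop("coords must have one row per element (", length(elements),
         " elements, ", nrow(coords), " rows)", call. = FALSE)
  }
  bad <- setdiff(unique(elements), alphabet)
  if (length(bad)) {
    stop("element symbol(s) outside the declared alphabet {",
         paste(alphabet, collapse = ","), "}: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  x <- list(
    elements = elements,
    coords = convert_unit(coords, units, "bohr"),
    energy = if (!is.null(energy)) convert_unit(energy, energy_unit, "hartree"),
    tag = tag,
    bonds = bonds,
    alphabet = alphabet
  )
  class(x) <- "mol_structure"
  x
}

#' @export
print.mol_structure <- function(x, ...) {
  tab <- table(x$elements)
  formula <- paste0(names(tab), ifelse(tab > 1, tab, ""), collapse = "")
  cat("<mol_structure> ", formula, " (", length(x$elements), " atoms)",
      sep = "")
  if (!is.null(x$energy)) cat(sprintf("  E = %.8f hartree", x$energy))
  if (!is.null(x$tag)) cat("  [", x$tag, "]", sep = "")
  cat("\n")
  invisible(x)
}

n_atoms <- function(s) length(s$elements)

#' Coordinates of a structure
#'
#' @param s a \code{mol_structure}.
#' @param units target length unit.
#' @return N x 3 numeric matrix.
#' @export
coords <- function(s, units = "bohr") {
  convert_unit(s$coords, "bohr", units)
}

# replace coordinates (bohr), keeping everything else
set_coords <- function(s, xyz) {
  s$coords <- matrix(xyz, ncol = 3)
  s$energy <- NULL
  s
}

#' Create a dataset of labelled structures
#'
#' An ordered collection of \code{mol_structure} frames.  With
#' \code{dedup = TRUE}, frames that coincide with an earlier frame to
#' within a tight tolerance (max atom displacement < 1e-8 bohr and
#' energy difference < 1e-10 hartree) are dropped.
#'
#' @param frames list of \code{mol_structure}.
#' @param dedup drop near-duplicate frames?
#' @param require_energy require every frame to carry an energy label?
#' @return an object of class \code{"mol_dataset"}.
#' @export
mol_dataset <- function(frames, dedup = FALSE, require_energy = FALSE) {
  if (!is.list(frames) || (length(frames) &&
      !all(vapply(frames, inherits, logical(1), "mol_structure")))) {
    stop("frames must be a list of mol_structure objects", call. = FALSE)
  }
  if (require_energy) {
    miss <- which(vapply(frames, function(f) is.null(f$energy), logical(1)))
    if (length(miss)) {
      stop("frame(s) without an energy label: ",
           paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
    }
  }
  if (dedup && length(frames) > 1) {
    keep <- rep(TRUE, length(frames))
    for (i in seq_along(frames)[-1]) {
      for (j in which(keep[seq_len(i - 1)])) {
        a <- frames[[i]]; b <- frames[[j]]
        if (length(a$elements) != length(b$elements)) next
        if (!identical(a$elements, b$elements)) next
        if (max(abs(a$coords - b$coords)) >= 1e-8) next
        ea <- a$energy; eb <- b$energy
        if (is.null(ea) != is.null(eb)) next
        if (!is.null(ea) && abs(ea - eb) >= 1e-10) next
        keep[i] <- FALSE
        break
      }
    }
    frames <- frames[keep]
  }
  structure(list(frames = frames), class = "mol_dataset")
}

#' @export
length.mol_dataset <- function(x) length(x$frames)

#' @export
`[.mol_dataset` <- function(x, i) mol_dataset(x$frames[i])

#' @export
`[[.mol_dataset` <- function(x, i) x$frames[[i]]

#' @export
print.mol_dataset <- function(x, ...) {
  cat("<mol_dataset> ", length(x$frames), " frame(s)\n", sep = "")
  if (length(x$frames)) {
    e <- dataset_energies(x)
    if (!all(is.na(e))) {
      cat(sprintf("  energy range: [%.8f, %.8f] hartree\n",
                  min(e, na.rm = TRUE), max(e, na.rm = TRUE)))
    }
    tags <- table(unlist(lapply(x$frames,
                                function(f) if (is.null(f$tag)) "untagged" else f$tag)))
    cat("  tags:", paste(names(tags), tags, sep = ":", collapse = " "), "\n")
  }
  invisible(x)
}

#' Energy labels of a dataset
#'
#' @param ds a \code{mol_dataset}.
#' @param unit target energy unit.
#' @return numeric vector (NA where a frame carries no label).
#' @export
dataset_energies <- function(ds, unit = "hartree") {
  e <- vapply(ds$frames, function(f) {
    if (is.null(f$energy)) NA_real_ else f$energy
  }, numeric(1))
  convert_unit(e, "hartree", unit)
}
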