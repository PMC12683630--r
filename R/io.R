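# Multi-frame XYZ readers/writers (extended-XYZ comment conventions).

#' Read a multi-frame XYZ file
#'
#' Parses the plain multi-frame XYZ layout: an atom-count line, a comment
#' line, then one \code{element x y z} line per atom.  If the comment
#' line contains an \code{Energy=} (or \code{energy:}) token, possibly
#' surrounded by other text, the value is taken as the frame's energy
#' label in \code{energy_unit}.
#'
#' @param path file path.
#' @param length_unit unit of the coordinates in the file.
#' @param energy_unit unit of the comment-line energies.
#' @param alphabet allowed element symbols.
#' @return a \code{\link{mol_dataset}}.
#' @export
read_xyz <- function(path, length_unit = "angstrom",
                     energy_unit = "hartree", alphabet = c("C", "H")) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  frame_idx <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    frame_idx <- frame_idx + 1L
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat) || nat < 1) {
      stop("frame ", frame_idx, ": malformed atom-count line: '",
           lines[i], "'", call. = FALSE)
    }
    if (i + 1L + nat > length(lines)) {
      stop("frame ", frame_idx, ": file truncated (expected ", nat,
           " atom lines)", call. = FALSE)
    }
    comment <- lines[i + 1L]
    energy <- .parse_energy_comment(comment)
    atoms <- lines[(i + 2L):(i + 1L + nat)]
    toks <- strsplit(trimws(atoms), "\\s+")
    nf <- vapply(toks, length, integer(1))
    if (any(nf < 4)) {
      stop("frame ", frame_idx, ": malformed atom line: '",
           atoms[which(nf < 4)[1]], "'", call. = FALSE)
    }
    el <- vapply(toks, `[[`, character(1), 1L)
    xyz <- t(vapply(toks, function(t) as.numeric(t[2:4]), numeric(3)))
    if (anyNA(xyz)) {
      stop("frame ", frame_idx, ": non-numeric coordinates", call. = FALSE)
    }
    frames[[frame_idx]] <- mol_structure(
      el, xyz, energy = energy, units = length_unit,
      energy_unit = energy_unit, alphabet = alphabet)
    i <- i + 2L + nat
  }
  mol_dataset(frames)
}

.parse_energy_comment <- function(comment) {
  m <- regmatches(comment,
                  regexpr("[Ee][Nn][Ee][Rr][Gg][Yy]\\s*[=:]\\s*[-+0-9.eEdD]+",
                          comment))
  if (!length(m)) return(NULL)
  val <- sub("^[^=:]*[=:]\\s*", "", m[1])
  val <- gsub("[dD]", "e", val)
  out <- suppressWarnings(as.numeric(val))
  if (is.na(out)) NULL else out
}

#' Write a dataset (or single structure) to a multi-frame XYZ file
#'
#' @param x a \code{mol_dataset} or a single \code{mol_structure}.
#' @param path output file path.
#' @param length_unit unit in which to write coordinates.
#' @param energy_unit unit in which to write comment-line energies.
#' @return \code{path}, invisibly.
#' @export
write_xyz <- function(x, path, length_unit = "angstrom",
                      energy_unit = "hartree") {
  if (inherits(x, "mol_structure")) x <- mol_dataset(list(x))
  if (!inherits(x, "mol_dataset")) {
    stop("x must be a mol_dataset or mol_structure", call. = FALSE)
  }
  if (length(x) == 0) {
    stop("refusing to write an empty dataset", call. = FALSE)
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (f in x$frames) {
    writeLines(as.character(length(f$elements)), con)
    comment <- if (!is.null(f$energy)) {
      sprintf("Energy= %.12f %s", convert_unit(f$energy, "hartree", energy_unit),
              energy_unit)
    } else ""
    if (!is.null(f$tag)) comment <- paste(comment, "tag=", f$tag)
    writeLines(comment, con)
    xyz <- coords(f, length_unit)
    writeLines(sprintf("%-2s %18.10f %18.10f %18.10f",
                       f$elements, xyz[, 1], xyz[, 2], xyz[, 3]), con)
  }
  invisible(path)
}

#' Export dataset energies as a flat table
#'
#' Writes a two-column whitespace table (frame index, energy) for
#' plotting or external fitting tools.
#'
#' @param ds a \code{mol_dataset}.
#' @param path output path.
#' @param unit energy unit for the second column.
#' @return \code{path}, invisibly.
#' @export
write_energy_table <- function(ds, path, unit = "hartree") {
  e <- dataset_energies(ds, unit)
  utils::write.table(
    data.frame(frame = seq_along(e), energy = e),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
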