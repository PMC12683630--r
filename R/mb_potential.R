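# The many-body PIP potential: the total energy is a sum over atom tuples
# (2-, 3- and 4-body), each tuple's contribution being a linear combination
# of PIP basis functions in the Morse-transformed intra-tuple distances.

#' Morse variable transform
#'
#' \code{y = exp(-r / lambda)}: a bounded, smoothly decaying transform of
#' an internuclear distance, with range parameter \code{lambda}.
#'
#' @param r distance (bohr), non-negative.
#' @param lambda range parameter (bohr), positive.
#' @return dimensionless value in (0, 1].
#' @export
morse <- function(r, lambda) {
  if (any(lambda <= 0)) stop("lambda must be > 0", call. = FALSE)
  exp(-r / lambda)
}

.composition_symmetry <- function(composition) {
  el <- strsplit(composition, "")[[1]]
  if (!length(el) %in% 2:4) {
    stop("composition must have 2..4 atoms, got '", composition, "'",
         call. = FALSE)
  }
  tab <- sort(table(el), decreasing = TRUE)
  counts <- as.integer(tab)
  syms <- list("2" = "PAIR", "11" = "PAIR", "3" = "A3", "21" = "A2B",
               "4" = "A4", "31" = "A3B", "22" = "A2B2")
  sym <- syms[[paste(counts, collapse = "")]]
  if (is.null(sym)) stop("unsupported composition '", composition, "'",
                         call. = FALSE)
  # A group = most frequent element; ties (A2B2) broken alphabetically
  list(symmetry = sym,
       A_element = names(tab)[1],
       B_element = if (length(tab) > 1) names(tab)[2] else NA_character_,
       n_A = counts[1],
       n_B = if (length(counts) > 1) counts[2] else 0L)
}

#' Define one interaction type of an MB-PIP model
#'
#' An interaction spec fixes, for one composition (e.g. \code{"CC"},
#' \code{"CCH"}, \code{"CCHH"}), the Morse range parameter, the distance
#' cutoff, the maximum polynomial order, and the smoothing window of the
#' cutoff.  The permutational symmetry type follows from the composition.
#'
#' Cutoff semantics: a tuple contributes when every intra-tuple distance
#' is below \code{cutoff}.  With \code{switch_width = 0} the cutoff is
#' hard (the energy has a step there); with a positive width each edge is
#' multiplied by a cosine ramp falling from 1 at
#' \code{cutoff - switch_width} to 0 at \code{cutoff}, which keeps the
#' potential smooth for optimisation and NVE dynamics.
#'
#' @param composition element string, 2 to 4 symbols.
#' @param max_degree maximum polynomial order of the PIP basis.
#' @param lambda Morse range parameter (bohr).
#' @param cutoff maximum intra-tuple distance (bohr); may be \code{Inf}.
#' @param switch_width cosine switching window (bohr), 0 for a hard cutoff.
#' @param include basis pruning convention (see \code{\link{pip_basis}});
#'   the default \code{"connected"} reproduces the published coefficient
#'   counts.
#' @return an object of class \code{"interaction_spec"}.
#' @export
interaction_spec <- function(composition, max_degree, lambda = 2.0,
                             cutoff = Inf, switch_width = 0,
                             include = "connected") {
  if (lambda <= 0) stop("lambda must be > 0", call. = FALSE)
  if (cutoff <= 0) stop("cutoff must be > 0", call. = FALSE)
  if (switch_width < 0 || (is.finite(cutoff) && switch_width >= cutoff)) {
    stop("switch_width must be in [0, cutoff)", call. = FALSE)
  }
  cs <- .composition_symmetry(composition)
  spec <- list(composition = paste(sort(strsplit(composition, "")[[1]]),
                                   collapse = ""),
               symmetry = cs$symmetry, A_element = cs$A_element,
               B_element = cs$B_element, n_A = cs$n_A, n_B = cs$n_B,
               max_degree = as.integer(max_degree), lambda = lambda,
               cutoff = cutoff, switch_width = switch_width,
               include = include)
  class(spec) <- "interaction_spec"
  spec
}

#' @export
print.interaction_spec <- function(x, ...) {
  cat(sprintf("<interaction_spec> %-4s (%s) order %d, lambda %.3g bohr, cutoff %.3g bohr%s\n",
              x$composition, x$symmetry, x$max_degree, x$lambda, x$cutoff,
              if (x$switch_width > 0)
                sprintf(" (switch %.3g)", x$switch_width) else ""))
  invisible(x)
}

.spec_basis <- function(spec) {
  pip_basis(spec$symmetry, spec$max_degree, include = spec$include)
}

# ---- tuple enumeration -----------------------------------------------------

.tuple_cache <- new.env(parent = emptyenv())

# all index tuples matching a composition, in canonical slot order
# (A-group atoms ascending, then B-group atoms ascending); geometry-free
.all_tuples <- function(elements, spec) {
  key <- paste(spec$composition, paste(elements, collapse = ""), sep = "|")
  if (!is.null(.tuple_cache[[key]])) return(.tuple_cache[[key]])
  ia <- which(elements == spec$A_element)
  choose_k <- function(idx, k) {
    if (length(idx) < k) return(matrix(integer(0), nrow = 0, ncol = k))
    if (k == 1) return(matrix(idx, ncol = 1))
    t(utils::combn(idx, k))
  }
  A <- choose_k(ia, spec$n_A)
  if (spec$n_B > 0) {
    ib <- which(elements == spec$B_element)
    B <- choose_k(ib, spec$n_B)
    if (nrow(A) == 0 || nrow(B) == 0) {
      out <- matrix(integer(0), nrow = 0, ncol = spec$n_A + spec$n_B)
    } else {
      out <- cbind(A[rep(seq_len(nrow(A)), each = nrow(B)), , drop = FALSE],
                   B[rep(seq_len(nrow(B)), times = nrow(A)), , drop = FALSE])
    }
  } else {
    out <- A
  }
  storage.mode(out) <- "integer"
  .tuple_cache[[key]] <- out
  out
}

#' Enumerate atom tuples matching a composition within a cutoff
#'
#' Lists every unordered atom tuple of a structure whose elements match
#' the composition and whose maximum intra-tuple distance does not exceed
#' the cutoff.  Tuples are returned once, in canonical slot order (the
#' repeated-element group first, atoms ascending by index).
#'
#' @param structure a \code{\link{mol_structure}}.
#' @param composition element string (2 to 4 symbols).
#' @param cutoff maximum intra-tuple distance (bohr).
#' @return integer matrix, one tuple per row.
#' @examples
#' # all 946 pairs of a 44-atom molecule: choose(44, 2)
#' @export
enumerate_tuples <- function(structure, composition, cutoff = Inf) {
  spec <- interaction_spec(composition, max_degree = 1, cutoff = Inf)
  tuples <- .all_tuples(structure$elements, spec)
  if (nrow(tuples) == 0 || !is.finite(cutoff)) {
    if (cutoff <= 0) return(tuples[integer(0), , drop = FALSE])
    return(tuples)
  }
  R <- .tuple_distances(structure$coords, tuples,
                        pip_symmetry(spec$symmetry)$edges)
  keep <- apply(R <= cutoff, 1, all)
  tuples[keep, , drop = FALSE]
}

# distances for each tuple edge: (n_tuples x n_edges), bohr
.tuple_distances <- function(xyz, tuples, edges) {
  n <- nrow(xyz)
  out <- matrix(0, nrow(tuples), length(edges))
  for (v in seq_along(edges)) {
    p <- tuples[, edges[[v]][1]]
    q <- tuples[, edges[[v]][2]]
    d <- xyz[p, , drop = FALSE] - xyz[q, , drop = FALSE]
    out[, v] <- sqrt(rowSums(d * d))
  }
  out
}

# linear indices into the full n x n distance matrix, one column per edge
.tuple_dist_idx <- function(elements, spec, sym) {
  key <- paste("idx", spec$composition, paste(elements, collapse = ""),
               sep = "|")
  if (!is.null(.tuple_cache[[key]])) return(.tuple_cache[[key]])
  tuples <- .all_tuples(elements, spec)
  n <- length(elements)
  idx <- matrix(0L, nrow(tuples), length(sym$edges))
  for (v in seq_along(sym$edges)) {
    idx[, v] <- tuples[, sym$edges[[v]][1]] +
      (tuples[, sym$edges[[v]][2]] - 1L) * n
  }
  .tuple_cache[[key]] <- idx
  idx
}

# cosine switch and derivative
.switch_fun <- function(r, cutoff, width) {
  if (!is.finite(cutoff)) {
    return(list(s = rep(1, length(r)), ds = rep(0, length(r))))
  }
  if (width == 0) {
    return(list(s = as.numeric(r <= cutoff), ds = rep(0, length(r))))
  }
  s <- rep(1, length(r))
  ds <- rep(0, length(r))
  lo <- cutoff - width
  mid <- r > lo & r < cutoff
  t <- (r[mid] - lo) / width
  s[mid] <- 0.5 * (1 + cos(pi * t))
  ds[mid] <- -0.5 * pi * sin(pi * t) / width
  s[r >= cutoff] <- 0
  list(s = s, ds = ds)
}

# ---- the model -------------------------------------------------------------

#' Construct an MB-PIP potential model
#'
#' Bundles interaction specs, their PIP bases and linear coefficients
#' into an evaluable potential.  Coefficients default to zero; they are
#' normally filled in by \code{\link{mbpip_fit}}.
#'
#' @param specs list of \code{\link{interaction_spec}}.
#' @param coefficients list of numeric vectors (one per spec, lengths
#'   matching the basis sizes), or \code{NULL} for all-zero.
#' @param one_body named numeric vector of per-element constant offsets,
#'   or \code{NULL} for none.
#' @param energy_shift constant added to every prediction (hartree);
#'   stores the reference-energy convention of the fit.
#' @param metadata free-form list (provenance, fit statistics).
#' @return an object of class \code{"mbpip_model"}.
#' @export
mbpip_model <- function(specs, coefficients = NULL, one_body = NULL,
                        energy_shift = 0, metadata = list()) {
  if (inherits(specs, "interaction_spec")) specs <- list(specs)
  stopifnot(all(vapply(specs, inherits, logical(1), "interaction_spec")))
  comps <- vapply(specs, `[[`, character(1), "composition")
  if (anyDuplicated(comps)) {
    stop("duplicate interaction composition(s): ",
         paste(unique(comps[duplicated(comps)]), collapse = ", "),
         call. = FALSE)
  }
  sizes <- vapply(specs, function(s) .spec_basis(s)$n_fun, integer(1))
  if (is.null(coefficients)) {
    coefficients <- lapply(sizes, numeric)
  }
  if (length(coefficients) != length(specs) ||
      !all(lengths(coefficients) == sizes)) {
    stop("coefficients must be one numeric vector per spec with lengths ",
         paste(sizes, collapse = ", "), call. = FALSE)
  }
  alphabet <- sort(unique(unlist(strsplit(comps, ""))))
  m <- list(specs = specs, coefficients = lapply(coefficients, as.numeric),
            one_body = one_body, energy_shift = energy_shift,
            alphabet = alphabet, metadata = metadata)
  class(m) <- "mbpip_model"
  m
}

#' @export
print.mbpip_model <- function(x, ...) {
  tab <- basis_count_table(x$specs)
  cat("<mbpip_model> alphabet {", paste(x$alphabet, collapse = ","),
      "}, ", attr(tab, "total"), " coefficients over ",
      nrow(tab), " interaction types\n", sep = "")
  print(tab, row.names = FALSE)
  if (!is.null(x$one_body)) {
    cat("one-body offsets:",
        paste(names(x$one_body), sprintf("%.6g", x$one_body),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of linear coefficients of an MB-PIP model
#' @param model an \code{mbpip_model}.
#' @return integer.
#' @export
n_coefficients <- function(model) {
  sum(vapply(model$specs, function(s) .spec_basis(s)$n_fun, integer(1)))
}

.check_alphabet <- function(model, structure) {
  bad <- setdiff(unique(structure$elements), model$alphabet)
  if (length(bad)) {
    stop("structure contains element(s) outside the model alphabet: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
}

# per-spec geometry data for one structure: surviving tuples, distances,
# Morse variables, switch factors; D is the optional precomputed full
# distance matrix of the structure
.spec_frame <- function(spec, structure, D = NULL) {
  tuples <- .all_tuples(structure$elements, spec)
  sym <- pip_symmetry(spec$symmetry)
  if (nrow(tuples) == 0) {
    return(list(tuples = tuples, R = NULL, Y = NULL, S = NULL, sym = sym))
  }
  if (is.null(D)) D <- .dist_matrix(structure$coords)
  idx <- .tuple_dist_idx(structure$elements, spec, sym)
  R <- matrix(D[idx], nrow(tuples), length(sym$edges))
  if (is.finite(spec$cutoff)) {
    keep <- if (spec$switch_width > 0) rowSums(R >= spec$cutoff) == 0
            else rowSums(R > spec$cutoff) == 0
    if (!all(keep)) {
      tuples <- tuples[keep, , drop = FALSE]
      R <- R[keep, , drop = FALSE]
    }
  }
  sw <- .switch_fun(as.numeric(R), spec$cutoff, spec$switch_width)
  smat <- matrix(sw$s, nrow(R), ncol(R))
  dsmat <- matrix(sw$ds, nrow(R), ncol(R))
  S <- if (ncol(smat)) Reduce(`*`, lapply(seq_len(ncol(smat)),
                                          function(j) smat[, j])) else rep(1, nrow(R))
  list(tuples = tuples, R = R, Y = morse(R, spec$lambda), S = S,
       smat = smat, dsmat = dsmat, sym = sym)
}

#' Potential energy of a structure
#'
#' Generic energy evaluation; methods exist for \code{mbpip_model},
#' \code{delta_stack}, the synthetic toy potential and the harmonic
#' diatomic.  Returns hartree.
#'
#' @param pot a potential object.
#' @param structure a \code{\link{mol_structure}}.
#' @param ... passed to methods.
#' @return scalar energy (hartree).
#' @export
pot_energy <- function(pot, structure, ...) UseMethod("pot_energy")

#' Cartesian gradient of the potential energy
#'
#' Generic analytic gradient (hartree/bohr), same dispatch as
#' \code{\link{pot_energy}}.  For every potential the rows sum to zero
#' (translational invariance).
#'
#' @param pot a potential object.
#' @param structure a \code{\link{mol_structure}}.
#' @param ... passed to methods.
#' @return N x 3 matrix of partial derivatives.
#' @export
pot_gradient <- function(pot, structure, ...) UseMethod("pot_gradient")

.dist_matrix <- function(xyz) {
  as.matrix(stats::dist(xyz))
}

#' @export
pot_energy.mbpip_model <- function(pot, structure, ...) {
  .check_alphabet(pot, structure)
  D <- .dist_matrix(structure$coords)
  contribs <- numeric(0)
  for (k in seq_along(pot$specs)) {
    spec <- pot$specs[[k]]
    b <- .spec_basis(spec)
    if (b$n_fun == 0) next
    fd <- .spec_frame(spec, structure, D)
    if (nrow(fd$tuples) == 0) next
    P <- cpp_pip_contrib(fd$Y, b$expo, b$fun_id, b$n_fun,
                         pot$coefficients[[k]], b$group_mat)
    contribs <- c(contribs, fd$S * P)
  }
  # fixed ascending summation order: bitwise invariant under permutations
  # of like atoms (the contribution multiset is unchanged)
  e <- sum(sort(contribs))
  if (!is.null(pot$one_body)) {
    counts <- table(factor(structure$elements, levels = names(pot$one_body)))
    e <- e + sum(pot$one_body * as.numeric(counts))
  }
  e + pot$energy_shift
}

#' @export
pot_gradient.mbpip_model <- function(pot, structure, ...) {
  .check_alphabet(pot, structure)
  n <- n_atoms(structure)
  grad <- matrix(0, n, 3)
  xyz <- structure$coords
  D <- .dist_matrix(xyz)
  for (k in seq_along(pot$specs)) {
    spec <- pot$specs[[k]]
    b <- .spec_basis(spec)
    if (b$n_fun == 0) next
    fd <- .spec_frame(spec, structure, D)
    if (nrow(fd$tuples) == 0) next
    need_sw <- spec$switch_width > 0 && any(fd$S < 1)
    edge_mat <- do.call(rbind, fd$sym$edges)
    grad <- grad + cpp_spec_grad(xyz, fd$tuples, edge_mat, fd$Y, fd$R,
                                 fd$smat, fd$dsmat, fd$S, b$expo, b$fun_id,
                                 pot$coefficients[[k]], spec$lambda,
                                 need_sw, n)
  }
  grad
}

#' Predict energies from an MB-PIP model
#'
#' @param object an \code{mbpip_model}.
#' @param newdata a \code{mol_structure} or \code{mol_dataset}.
#' @param unit energy unit of the result.
#' @param ... unused.
#' @return numeric vector of energies.
#' @export
predict.mbpip_model <- function(object, newdata, unit = "hartree", ...) {
  frames <- if (inherits(newdata, "mol_structure")) list(newdata)
            else newdata$frames
  e <- vapply(frames, function(f) pot_energy(object, f), numeric(1))
  convert_unit(e, "hartree", unit)
}
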