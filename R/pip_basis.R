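# Permutationally invariant polynomial bases.
#
# A basis function is an orbit sum of monomials in the tuple's transformed
# internuclear distances: permuting like atoms permutes the distance slots,
# and summing a monomial over its whole orbit makes the result exactly
# invariant.  Six symmetry types cover every 2-, 3- and 4-atom tuple of a
# two-element molecule.

.perms_S3 <- list(c(1L, 2L, 3L), c(2L, 1L, 3L), c(1L, 3L, 2L),
                  c(3L, 2L, 1L), c(2L, 3L, 1L), c(3L, 1L, 2L))

.edge_perm <- function(atom_perm, edges) {
  key <- vapply(edges, function(e) paste(sort(e), collapse = "-"), character(1))
  vapply(edges, function(e) {
    match(paste(sort(atom_perm[e]), collapse = "-"), key)
  }, integer(1))
}

.perms_S4 <- local({
  g <- as.matrix(expand.grid(rep(list(1:4), 4)))
  g <- g[apply(g, 1, function(r) length(unique(r)) == 4), , drop = FALSE]
  lapply(seq_len(nrow(g)), function(i) as.integer(g[i, ]))
})

# canonical variable (edge) order: like-like edges first, lexicographic on
# atom slots, then cross edges, lexicographic
.sym_defs <- list(
  PAIR = list(n_atoms = 2L, edges = list(c(1L, 2L)), atom_perms = list(1:2)),
  A3   = list(n_atoms = 3L,
              edges = list(c(1L, 2L), c(1L, 3L), c(2L, 3L)),
              atom_perms = .perms_S3),
  A2B  = list(n_atoms = 3L,  # slots: A1 A2 B
              edges = list(c(1L, 2L), c(1L, 3L), c(2L, 3L)),
              atom_perms = list(c(1L, 2L, 3L), c(2L, 1L, 3L))),
  A4   = list(n_atoms = 4L,
              edges = list(c(1L, 2L), c(1L, 3L), c(1L, 4L),
                           c(2L, 3L), c(2L, 4L), c(3L, 4L)),
              atom_perms = .perms_S4),
  A3B  = list(n_atoms = 4L,  # slots: A1 A2 A3 B
              edges = list(c(1L, 2L), c(1L, 3L), c(2L, 3L),
                           c(1L, 4L), c(2L, 4L), c(3L, 4L)),
              atom_perms = lapply(.perms_S3, function(p) c(p, 4L))),
  A2B2 = list(n_atoms = 4L,  # slots: A1 A2 B1 B2
              edges = list(c(1L, 2L), c(3L, 4L), c(1L, 3L), c(1L, 4L),
                           c(2L, 3L), c(2L, 4L)),
              atom_perms = list(c(1L, 2L, 3L, 4L), c(2L, 1L, 3L, 4L),
                                c(1L, 2L, 4L, 3L), c(2L, 1L, 4L, 3L)))
)

#' Permutational symmetry type of an atom tuple
#'
#' Returns the symmetry descriptor for one of the six supported types:
#' \code{PAIR} (any 2 atoms), \code{A3}/\code{A2B} (3 atoms), and
#' \code{A4}/\code{A3B}/\code{A2B2} (4 atoms).  The descriptor holds the
#' canonical edge (variable) ordering -- like-like edges first -- and the
#' permutation group induced on the edge slots by permuting like atoms.
#'
#' @param name symmetry type name.
#' @return a list with elements \code{name}, \code{n_atoms},
#'   \code{n_variables}, \code{edges} (atom-slot pairs per variable) and
#'   \code{group} (list of variable-slot permutations).
#' @export
pip_symmetry <- function(name) {
  if (!name %in% names(.sym_defs)) {
    stop("unsupported symmetry type '", name, "'; must be one of ",
         paste(names(.sym_defs), collapse = ", "), call. = FALSE)
  }
  d <- .sym_defs[[name]]
  group <- unique(lapply(d$atom_perms, .edge_perm, edges = d$edges))
  list(name = name, n_atoms = d$n_atoms, n_variables = length(d$edges),
       edges = d$edges, group = group)
}

# exponent vectors of total degree 1..maxd over nv variables
.enum_monomials <- function(nv, maxd) {
  g <- as.matrix(expand.grid(rep(list(0:maxd), nv)))
  storage.mode(g) <- "integer"
  deg <- rowSums(g)
  g[deg >= 1L & deg <= maxd, , drop = FALSE]
}

.expo_key <- function(M) {
  do.call(paste, c(lapply(seq_len(ncol(M)), function(j) sprintf("%02d", M[, j])),
                   sep = "."))
}

# is the positive-exponent edge set connected and atom-spanning?
.support_connected <- function(expo, edges, natoms) {
  sel <- edges[expo > 0L]
  if (!length(sel)) return(FALSE)
  at <- unique(unlist(sel))
  if (length(at) < natoms) return(FALSE)
  comp <- at[1]
  repeat {
    touch <- vapply(sel, function(e) any(e %in% comp), logical(1))
    grow <- unique(unlist(sel[touch]))
    if (!length(setdiff(grow, comp))) break
    comp <- union(comp, grow)
  }
  length(comp) == natoms
}

.basis_cache <- new.env(parent = emptyenv())

#' Generate a symmetrized-monomial PIP basis
#'
#' Enumerates all monomials of total degree 1..\code{max_degree} in the
#' tuple's edge variables, partitions them into orbits of the symmetry
#' type's permutation group, and returns one orbit-sum function per orbit
#' (no constant term).  Orbit sums over distinct monomials have disjoint
#' supports, so the functions are linearly independent by construction.
#'
#' With \code{include = "connected"} only orbits whose positive-exponent
#' edge set forms a connected graph spanning all atoms of the tuple are
#' kept, i.e. genuine n-body terms; this is the pruning convention used
#' for model building (it reproduces the published coefficient counts of
#' 383 for the correction surface and 734 for the low-level surface).
#' \code{include = "all"} keeps every invariant.
#'
#' Functions are ordered by (degree, lexicographically minimal orbit
#' exponent vector) so basis files are deterministic.
#'
#' @param symmetry a symmetry name or a \code{\link{pip_symmetry}} object.
#' @param max_degree maximum total polynomial degree (>= 1).
#' @param include \code{"all"} or \code{"connected"}.
#' @return an object of class \code{"pip_basis"}.
#' @examples
#' pip_basis("PAIR", 6)$n_fun   # 6: y, y^2, ..., y^6
#' pip_basis("A3", 7)$n_fun     # 30
#' @export
pip_basis <- function(symmetry, max_degree, include = c("all", "connected")) {
  include <- match.arg(include)
  if (is.character(symmetry)) symmetry <- pip_symmetry(symmetry)
  if (max_degree < 1) stop("max_degree must be >= 1", call. = FALSE)
  key <- paste(symmetry$name, max_degree, include, sep = ":")
  if (!is.null(.basis_cache[[key]])) return(.basis_cache[[key]])

  nv <- symmetry$n_variables
  M <- .enum_monomials(nv, max_degree)
  keys <- lapply(symmetry$group, function(p) .expo_key(M[, p, drop = FALSE]))
  canon <- do.call(pmin, keys)
  reps_idx <- which(!duplicated(canon))
  # orbit representative = lexicographically minimal member
  reps <- vapply(reps_idx, function(i) {
    imgs <- matrix(vapply(symmetry$group, function(p) M[i, p], integer(nv)),
                   ncol = nv, byrow = TRUE)
    imgs[order(.expo_key(imgs))[1], ]
  }, integer(nv))
  reps <- matrix(reps, ncol = nv, byrow = TRUE)
  if (include == "connected") {
    def <- .sym_defs[[symmetry$name]]
    keep <- apply(reps, 1, .support_connected, edges = symmetry$edges,
                  natoms = symmetry$n_atoms)
    reps <- reps[keep, , drop = FALSE]
  }
  deg <- rowSums(reps)
  ord <- order(deg, .expo_key(reps))
  reps <- reps[ord, , drop = FALSE]
  deg <- deg[ord]

  # expand each orbit into its distinct members, lexicographically sorted
  expo_list <- vector("list", nrow(reps))
  fun_id <- vector("list", nrow(reps))
  for (f in seq_len(nrow(reps))) {
    imgs <- matrix(vapply(symmetry$group, function(p) reps[f, p], integer(nv)),
                   ncol = nv, byrow = TRUE)
    imgs <- unique(imgs)
    imgs <- imgs[order(.expo_key(imgs)), , drop = FALSE]
    expo_list[[f]] <- imgs
    fun_id[[f]] <- rep.int(f, nrow(imgs))
  }
  expo <- if (length(expo_list)) do.call(rbind, expo_list)
          else matrix(integer(0), 0, nv)
  b <- list(symmetry = symmetry, max_degree = max_degree, include = include,
            n_fun = nrow(reps), degrees = as.integer(deg), reps = reps,
            expo = expo,
            fun_id = as.integer(unlist(fun_id)),
            group_mat = matrix(unlist(symmetry$group), ncol = nv,
                               byrow = TRUE))
  class(b) <- "pip_basis"
  .basis_cache[[key]] <- b
  b
}

#' @export
print.pip_basis <- function(x, ...) {
  cat("<pip_basis> ", x$symmetry$name, " max degree ", x$max_degree,
      " (", x$include, "): ", x$n_fun, " functions, ",
      nrow(x$expo), " monomial terms\n", sep = "")
  invisible(x)
}

#' Evaluate a PIP basis at one point
#'
#' The variable vector is first replaced by its lexicographically
#' minimal group image (which leaves every basis function's value
#' unchanged, as the functions are group-invariant polynomials), so the
#' output is bitwise identical under any group permutation of
#' \code{y}.
#'
#' @param basis a \code{pip_basis}.
#' @param y numeric vector of length \code{n_variables}.
#' @return numeric vector of length \code{n_fun}.
#' @export
pip_evaluate <- function(basis, y) {
  if (length(y) != basis$symmetry$n_variables) {
    stop("y must have length ", basis$symmetry$n_variables, call. = FALSE)
  }
  drop(cpp_pip_eval(matrix(as.numeric(y), nrow = 1), basis$expo,
                    basis$fun_id, basis$n_fun, basis$group_mat))
}

#' Evaluate a PIP basis at many points
#'
#' @param basis a \code{pip_basis}.
#' @param Y numeric matrix (points x variables).
#' @return numeric matrix (points x functions).
#' @export
pip_evaluate_many <- function(basis, Y) {
  Y <- matrix(as.numeric(Y), ncol = basis$symmetry$n_variables)
  cpp_pip_eval(Y, basis$expo, basis$fun_id, basis$n_fun, basis$group_mat)
}

#' Jacobian of a PIP basis at one point
#'
#' Exact partial derivatives of every basis function with respect to
#' every variable.
#'
#' @param basis a \code{pip_basis}.
#' @param y numeric vector of length \code{n_variables}.
#' @return numeric matrix (functions x variables).
#' @export
pip_jacobian <- function(basis, y) {
  if (length(y) != basis$symmetry$n_variables) {
    stop("y must have length ", basis$symmetry$n_variables, call. = FALSE)
  }
  cpp_pip_jacobian(as.numeric(y), basis$expo, basis$fun_id, basis$n_fun)
}

#' Count linearly independent invariants of exact degree by group averaging
#'
#' Burnside/Molien-style oracle: the number of independent invariants of
#' exact total degree d equals the group average, over all variable-slot
#' permutations, of the number of degree-d monomials each permutation
#' fixes.  A monomial is fixed iff its exponents are constant on every
#' cycle, so the per-element count is the number of ways to write d as a
#' non-negative combination of the cycle lengths.  This counts all
#' invariants (the \code{include = "all"} convention) without enumerating
#' monomials, and serves as an independent check on the generator.
#'
#' @param symmetry a symmetry name or \code{\link{pip_symmetry}} object.
#' @param degree exact total degree (>= 0).
#' @return integer count.
#' @examples
#' pip_invariant_count("A3", 2)  # 2
#' @export
pip_invariant_count <- function(symmetry, degree) {
  if (is.character(symmetry)) symmetry <- pip_symmetry(symmetry)
  if (degree < 0) stop("degree must be >= 0", call. = FALSE)
  if (degree == 0) return(1L)
  total <- 0
  for (p in symmetry$group) {
    cyc <- .cycle_lengths(p)
    # coin-counting DP: ways to reach degree with parts = cycle lengths
    ways <- c(1, rep(0, degree))
    for (cl in cyc) {
      if (cl <= degree) {
        for (d in cl:degree) ways[d + 1] <- ways[d + 1] + ways[d + 1 - cl]
      }
    }
    total <- total + ways[degree + 1]
  }
  n <- total / length(symmetry$group)
  stopifnot(abs(n - round(n)) < 1e-9)
  as.integer(round(n))
}

.cycle_lengths <- function(perm) {
  n <- length(perm)
  seen <- logical(n)
  out <- integer(0)
  for (i in seq_len(n)) {
    if (seen[i]) next
    len <- 0L
    j <- i
    while (!seen[j]) {
      seen[j] <- TRUE
      j <- perm[j]
      len <- len + 1L
    }
    out <- c(out, len)
  }
  out
}

#' Per-type basis sizes for a set of interaction specs
#'
#' Tabulates, for each interaction type of a model specification, the
#' symmetry, polynomial order and number of basis functions; the total is
#' the number of linear coefficients of the fit.
#'
#' @param specs list of \code{\link{interaction_spec}} objects.
#' @return a data.frame with one row per spec plus a \code{total}
#'   attribute.
#' @export
basis_count_table <- function(specs) {
  rows <- lapply(specs, function(s) {
    b <- pip_basis(s$symmetry, s$max_degree, include = s$include)
    data.frame(composition = s$composition, symmetry = s$symmetry,
               max_degree = s$max_degree, n_functions = b$n_fun,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "total") <- sum(out$n_functions)
  out
}
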