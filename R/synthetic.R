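# Synthetic alkane test system: deterministic chain geometries (linear and
# hairpin templates) and a fully specified two-level toy potential -- a
# dispersionless "low level" versus a dispersion-containing "high level" --
# so that fitting, delta-ML, conformer scans and dynamics can be exercised
# without any electronic-structure data.

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.cross_rows <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

.unit <- function(v) v / sqrt(sum(v^2))

# natural-extension-reference-frame placement: atom d bonded to c with
# given bond length, angle b-c-d and dihedral a-b-c-d
.place_atom <- function(a, b, c, bond, angle, dihedral) {
  bc <- .unit(c - b)
  n <- .unit(.cross3(b - a, bc))
  m <- .cross3(n, bc)
  d <- c(-bond * cos(angle),
         bond * sin(angle) * cos(dihedral),
         bond * sin(angle) * sin(dihedral))
  c + d[1] * bc + d[2] * m + d[3] * n
}

# measured internal coordinates (used by the builder tests)
.measure_angle <- function(p1, p2, p3) {
  u <- .unit(p1 - p2); v <- .unit(p3 - p2)
  acos(max(-1, min(1, sum(u * v))))
}

.measure_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- .cross3(b1, b2); n2 <- .cross3(b2, b3)
  atan2(sum(.cross3(n1, n2) * .unit(b2)), sum(n1 * n2))
}

# template geometry constants (angstrom / degrees)
.chain_r_cc <- 1.54
.chain_r_ch <- 1.09
.chain_theta <- acos(-1 / 3)  # tetrahedral, 109.471 deg
# hairpin turn: four consecutive gauche backbone dihedrals; the sign
# pattern below folds the chain back on itself into two packed strands
.hairpin_turn_deg <- c(60, 60, -60, -60)

#' Build an alkane chain structure
#'
#' Deterministic template geometry for C(n)H(2n+2): ideal bond lengths
#' (C-C 1.54 A, C-H 1.09 A), tetrahedral angles, and backbone dihedrals
#' all-anti (180 deg) for the linear conformation or with a turn of four
#' consecutive gauche dihedrals (+-60 deg) mid-chain for the hairpin.
#' Carbons come first in the atom order, then hydrogens.  The bond graph
#' is attached to the structure and carried through perturbations.
#'
#' @param n_carbons number of carbons (>= 2; hairpin needs >= 8).
#' @param conformation \code{"linear"} or \code{"hairpin"}.
#' @param dihedrals optional numeric vector of n - 3 backbone dihedrals
#'   (degrees) overriding the template (e.g. gauche intermediates along
#'   the folding path).
#' @return a \code{\link{mol_structure}} with a bond graph.
#' @examples
#' s <- build_alkane(4)            # butane, C4H10
#' table(s$elements)
#' @export
build_alkane <- function(n_carbons, conformation = c("linear", "hairpin"),
                         dihedrals = NULL) {
  conformation <- match.arg(conformation)
  n <- as.integer(n_carbons)
  if (n < 2) stop("n_carbons must be >= 2", call. = FALSE)
  if (conformation == "hairpin" && n < 8) {
    stop("the hairpin template needs n_carbons >= 8 (a four-dihedral turn ",
         "plus at least one anti dihedral per strand)", call. = FALSE)
  }
  ndh <- n - 3L
  if (is.null(dihedrals)) {
    dihedrals <- rep(pi, max(ndh, 0))
    if (conformation == "hairpin") {
      start <- floor((ndh - 4L) / 2) + 1L
      dihedrals[start:(start + 3L)] <- .hairpin_turn_deg * pi / 180
    }
  } else {
    if (length(dihedrals) != ndh) {
      stop("dihedrals must have length n_carbons - 3 = ", ndh, call. = FALSE)
    }
    dihedrals <- dihedrals * pi / 180
  }

  rcc <- .chain_r_cc
  theta <- .chain_theta
  C <- matrix(0, n, 3)
  C[2, ] <- c(rcc, 0, 0)
  if (n >= 3) C[3, ] <- C[2, ] + rcc * c(cos(pi - theta), sin(pi - theta), 0)
  if (n >= 4) {
    for (i in 4:n) {
      C[i, ] <- .place_atom(C[i - 3, ], C[i - 2, ], C[i - 1, ],
                            rcc, theta, dihedrals[i - 3])
    }
  }

  rch <- .chain_r_ch
  H <- matrix(0, 0, 3)
  hbond_c <- integer(0)
  add_H <- function(pos, cidx) {
    H <<- rbind(H, pos)
    hbond_c <<- c(hbond_c, cidx)
  }
  methyl <- function(ci, cj, cref) {
    # three H on terminal carbon ci (bonded to cj), staggered w.r.t. cref
    axis <- .unit(C[cj, ] - C[ci, ])
    w <- C[cref, ] - C[cj, ]
    e1 <- .unit(w - sum(w * axis) * axis)
    e2 <- .cross3(axis, e1)
    for (phi in c(60, 180, 300) * pi / 180) {
      dir <- cos(theta) * axis + sin(theta) * (cos(phi) * e1 + sin(phi) * e2)
      add_H(C[ci, ] + rch * dir, ci)
    }
  }
  methylene <- function(ci) {
    u1 <- .unit(C[ci - 1, ] - C[ci, ])
    u2 <- .unit(C[ci + 1, ] - C[ci, ])
    bis <- -.unit(u1 + u2)
    perp <- .unit(.cross3(u1, u2))
    half <- theta / 2
    add_H(C[ci, ] + rch * (cos(half) * bis + sin(half) * perp), ci)
    add_H(C[ci, ] + rch * (cos(half) * bis - sin(half) * perp), ci)
  }
  if (n == 2) {
    # ethane: build the second methyl against a virtual reference
    axis <- .unit(C[2, ] - C[1, ])
    e1 <- c(0, 1, 0); e2 <- .cross3(axis, e1)
    for (phi in c(60, 180, 300) * pi / 180) {
      dir <- cos(theta) * axis + sin(theta) * (cos(phi) * e1 + sin(phi) * e2)
      add_H(C[1, ] + rch * dir, 1L)
    }
    for (phi in c(0, 120, 240) * pi / 180) {
      dir <- cos(theta) * (-axis) + sin(theta) * (cos(phi) * e1 + sin(phi) * e2)
      add_H(C[2, ] + rch * dir, 2L)
    }
  } else {
    methyl(1L, 2L, 3L)
    if (n > 2) for (ci in 2:(n - 1)) methylene(ci)
    methyl(n, n - 1L, n - 2L)
  }

  elements <- c(rep("C", n), rep("H", nrow(H)))
  xyz <- rbind(C, H)
  bonds <- rbind(
    if (n >= 2) cbind(1:(n - 1), 2:n),
    cbind(hbond_c, n + seq_along(hbond_c))
  )
  storage.mode(bonds) <- "integer"
  s <- mol_structure(elements, xyz, units = "angstrom", bonds = bonds,
                     tag = conformation)
  stopifnot(length(s$elements) == 3L * n + 2L)
  s
}

# ---- the two-level toy potential ------------------------------------------

# fixture constants (kcal/mol, angstrom); frozen, documented in the vignette
.toy_params_user <- list(
  k_bond = 300,                        # kcal/mol/A^2
  r0 = c(CC = 1.54, CH = 1.09),        # A
  k_angle = 60,                        # kcal/mol/rad^2
  theta0 = acos(-1 / 3),               # rad
  v3 = 3,                              # kcal/mol, backbone dihedrals
  c6 = c(CC = 1200, CH = 330, HH = 90),# kcal/mol A^6
  d_damp = 1.2,                        # A
  # Born-Mayer steric core, present in BOTH levels (from vdW contact
  # distances ~3.8/3.2/2.6 A for CC/CH/HH at this rho)
  a_rep = c(CC = 60000, CH = 7400, HH = 1150),  # kcal/mol
  rho_rep = 0.30                       # A
)

#' The synthetic two-level alkane potential
#'
#' A minimal molecular-mechanics surface over a structure's bond graph:
#' harmonic bonds \code{k_b (r - r0)^2}, harmonic angles
#' \code{k_theta (theta - theta0)^2}, a threefold torsion
#' \code{(V3/2)(1 + cos 3 phi)} on backbone C-C-C-C dihedrals, a
#' Born-Mayer steric core \code{A exp(-r / rho)} over atom pairs at
#' graph distance >= 3 bonds, and -- in the \code{"high"} level only --
#' a damped pairwise dispersion term \code{-C6 / (r^6 + d^6)} over the
#' same pairs.  The steric core is present in both levels, so high minus
#' low is exactly the dispersion sum: the low level plays the role of a
#' dispersionless (but sterically repulsive) electronic-structure
#' method, and dispersion is the only interaction that can favour chain
#' folding.  All constants are frozen fixture parameters.
#'
#' @param level \code{"high"} (with dispersion) or \code{"low"} (without).
#' @return a potential object of class \code{"toy_potential"} usable with
#'   \code{\link{pot_energy}} and \code{\link{pot_gradient}}.
#' @export
toy_alkane_potential <- function(level = c("high", "low")) {
  level <- match.arg(level)
  u <- .toy_params_user
  kcal <- function(x) convert_unit(x, "kcal/mol", "hartree")
  ang <- 1 / convert_unit(1, "bohr", "angstrom")  # bohr per angstrom
  p <- list(
    level = level,
    k_bond = kcal(u$k_bond) / ang^2,
    r0 = u$r0 * ang,
    k_angle = kcal(u$k_angle),
    theta0 = u$theta0,
    v3 = kcal(u$v3),
    c6 = kcal(u$c6) * ang^6,
    d_damp = u$d_damp * ang,
    a_rep = kcal(u$a_rep),
    rho_rep = u$rho_rep * ang
  )
  class(p) <- "toy_potential"
  p
}

#' @export
print.toy_potential <- function(x, ...) {
  cat("<toy_potential> level:", x$level,
      if (x$level == "high") "(bond + angle + torsion + dispersion)"
      else "(bond + angle + torsion; dispersionless)", "\n")
  invisible(x)
}

.toy_term_cache <- new.env(parent = emptyenv())

# bonded-term lists derived from the bond graph; cached per topology
.toy_terms <- function(structure) {
  b <- structure$bonds
  if (is.null(b)) {
    stop("structure carries no bond graph; build it with build_alkane() ",
         "or attach bonds explicitly", call. = FALSE)
  }
  n <- n_atoms(structure)
  key <- paste(c(n, structure$elements, t(b)), collapse = "")
  if (!is.null(.toy_term_cache[[key]])) return(.toy_term_cache[[key]])
  adj <- vector("list", n)
  for (r in seq_len(nrow(b))) {
    adj[[b[r, 1]]] <- c(adj[[b[r, 1]]], b[r, 2])
    adj[[b[r, 2]]] <- c(adj[[b[r, 2]]], b[r, 1])
  }
  el <- structure$elements
  pair_type <- function(i, j) paste(sort(c(el[i], el[j])), collapse = "")

  bonds <- b
  bond_type <- vapply(seq_len(nrow(b)),
                      function(r) pair_type(b[r, 1], b[r, 2]), character(1))

  angles <- NULL
  for (j in seq_len(n)) {
    nb <- sort(adj[[j]])
    if (length(nb) >= 2) {
      pr <- utils::combn(nb, 2)
      angles <- rbind(angles, cbind(pr[1, ], j, pr[2, ]))
    }
  }

  torsions <- NULL
  for (r in seq_len(nrow(b))) {
    j <- b[r, 1]; k <- b[r, 2]
    if (el[j] != "C" || el[k] != "C") next
    for (i in adj[[j]]) {
      if (i == k || el[i] != "C") next
      for (l in adj[[k]]) {
        if (l == j || el[l] != "C") next
        torsions <- rbind(torsions, c(i, j, k, l))
      }
    }
  }

  # graph distances by BFS, pairs at >= 3 bonds get dispersion
  gd <- matrix(Inf, n, n)
  for (s0 in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[s0] <- 0
    queue <- s0
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      for (nb in adj[[cur]]) {
        if (dist[nb] > dist[cur] + 1) {
          dist[nb] <- dist[cur] + 1
          queue <- c(queue, nb)
        }
      }
    }
    gd[s0, ] <- dist
  }
  idx <- which(upper.tri(gd) & gd >= 3, arr.ind = TRUE)
  nb_pairs <- idx
  nb_type <- vapply(seq_len(nrow(idx)),
                    function(r) pair_type(idx[r, 1], idx[r, 2]), character(1))

  out <- list(bonds = bonds, bond_type = bond_type, angles = angles,
              torsions = torsions, nb_pairs = nb_pairs, nb_type = nb_type)
  .toy_term_cache[[key]] <- out
  out
}

#' Per-term-class energies of the toy potential
#'
#' Returns the bond, angle, torsion, repulsion and dispersion sums
#' separately (hartree).  The level's total is the sum of its classes
#' (the low level omits dispersion), so high minus low equals the
#' dispersion class by construction.
#'
#' @param pot a \code{toy_potential}.
#' @param structure a \code{mol_structure} with a bond graph.
#' @return named numeric vector.
#' @export
toy_term_energies <- function(pot, structure) {
  tm <- .toy_terms(structure)
  xyz <- structure$coords
  rvec <- function(pairs) {
    d <- xyz[pairs[, 1], , drop = FALSE] - xyz[pairs[, 2], , drop = FALSE]
    sqrt(rowSums(d * d))
  }
  e_bond <- 0
  if (nrow(tm$bonds)) {
    r_b <- rvec(tm$bonds)
    e_bond <- sum(pot$k_bond * (r_b - pot$r0[tm$bond_type])^2)
  }

  e_angle <- 0
  if (!is.null(tm$angles)) {
    u <- xyz[tm$angles[, 1], , drop = FALSE] - xyz[tm$angles[, 2], , drop = FALSE]
    v <- xyz[tm$angles[, 3], , drop = FALSE] - xyz[tm$angles[, 2], , drop = FALSE]
    cth <- rowSums(u * v) / (sqrt(rowSums(u * u)) * sqrt(rowSums(v * v)))
    th <- acos(pmax(-1, pmin(1, cth)))
    e_angle <- sum(pot$k_angle * (th - pot$theta0)^2)
  }

  e_tor <- 0
  if (!is.null(tm$torsions)) {
    phi <- .dihedrals_of(xyz, tm$torsions)
    e_tor <- sum(pot$v3 / 2 * (1 + cos(3 * phi)))
  }

  e_rep <- 0; e_disp <- 0
  if (nrow(tm$nb_pairs)) {
    r_nb <- rvec(tm$nb_pairs)
    e_rep <- sum(pot$a_rep[tm$nb_type] * exp(-r_nb / pot$rho_rep))
    e_disp <- -sum(pot$c6[tm$nb_type] / (r_nb^6 + pot$d_damp^6))
  }

  c(bond = e_bond, angle = e_angle, torsion = e_tor,
    repulsion = e_rep, dispersion = e_disp)
}

.dihedrals_of <- function(xyz, t) {
  b1 <- xyz[t[, 2], , drop = FALSE] - xyz[t[, 1], , drop = FALSE]
  b2 <- xyz[t[, 3], , drop = FALSE] - xyz[t[, 2], , drop = FALSE]
  b3 <- xyz[t[, 4], , drop = FALSE] - xyz[t[, 3], , drop = FALSE]
  n1 <- .cross_rows(b1, b2)
  n2 <- .cross_rows(b2, b3)
  b2n <- b2 / sqrt(rowSums(b2 * b2))
  atan2(rowSums(.cross_rows(n1, n2) * b2n), rowSums(n1 * n2))
}

#' @export
pot_energy.toy_potential <- function(pot, structure, ...) {
  e <- toy_term_energies(pot, structure)
  if (pot$level == "low") e <- e[c("bond", "angle", "torsion", "repulsion")]
  sum(e)
}

#' @export
pot_gradient.toy_potential <- function(pot, structure, ...) {
  tm <- .toy_terms(structure)
  xyz <- structure$coords
  n <- n_atoms(structure)
  grad <- matrix(0, n, 3)
  acc <- function(idx, contrib) {
    g <- rowsum(contrib, idx)
    rows <- as.integer(rownames(g))
    grad[rows, ] <<- grad[rows, , drop = FALSE] + g
  }

  # bonds: dE/dr = 2 k (r - r0)
  if (nrow(tm$bonds)) {
    d <- xyz[tm$bonds[, 1], , drop = FALSE] - xyz[tm$bonds[, 2], , drop = FALSE]
    r <- sqrt(rowSums(d * d))
    dEdr <- 2 * pot$k_bond * (r - pot$r0[tm$bond_type])
    unit <- d / r
    acc(tm$bonds[, 1], unit * dEdr)
    acc(tm$bonds[, 2], -unit * dEdr)
  }

  # angles
  if (!is.null(tm$angles)) {
  i <- tm$angles[, 1]; j <- tm$angles[, 2]; k <- tm$angles[, 3]
  u <- xyz[i, , drop = FALSE] - xyz[j, , drop = FALSE]
  v <- xyz[k, , drop = FALSE] - xyz[j, , drop = FALSE]
  lu <- sqrt(rowSums(u * u)); lv <- sqrt(rowSums(v * v))
  cth <- pmax(-1, pmin(1, rowSums(u * v) / (lu * lv)))
  th <- acos(cth)
  sth <- pmax(sqrt(1 - cth^2), 1e-10)
  dEdth <- 2 * pot$k_angle * (th - pot$theta0)
  dth_di <- -(v / (lu * lv) - cth * u / lu^2) / sth
  dth_dk <- -(u / (lu * lv) - cth * v / lv^2) / sth
  acc(i, dth_di * dEdth)
  acc(k, dth_dk * dEdth)
  acc(j, -(dth_di + dth_dk) * dEdth)
  }

  # torsions
  if (!is.null(tm$torsions)) {
    t <- tm$torsions
    b1 <- xyz[t[, 2], , drop = FALSE] - xyz[t[, 1], , drop = FALSE]
    b2 <- xyz[t[, 3], , drop = FALSE] - xyz[t[, 2], , drop = FALSE]
    b3 <- xyz[t[, 4], , drop = FALSE] - xyz[t[, 3], , drop = FALSE]
    n1 <- .cross_rows(b1, b2)
    n2 <- .cross_rows(b2, b3)
    lb2 <- sqrt(rowSums(b2 * b2))
    phi <- atan2(rowSums(.cross_rows(n1, n2) * (b2 / lb2)), rowSums(n1 * n2))
    dEdphi <- -(3 * pot$v3 / 2) * sin(3 * phi)
    dphi_d1 <- -n1 * (lb2 / rowSums(n1 * n1))
    dphi_d4 <- n2 * (lb2 / rowSums(n2 * n2))
    s12 <- rowSums(b1 * b2) / lb2^2
    s32 <- rowSums(b3 * b2) / lb2^2
    dphi_d2 <- -(1 + s12) * dphi_d1 + s32 * dphi_d4
    dphi_d3 <- s12 * dphi_d1 - (1 + s32) * dphi_d4
    acc(t[, 1], dphi_d1 * dEdphi)
    acc(t[, 2], dphi_d2 * dEdphi)
    acc(t[, 3], dphi_d3 * dEdphi)
    acc(t[, 4], dphi_d4 * dEdphi)
  }

  # nonbonded: repulsion in both levels, dispersion in "high" only
  p <- tm$nb_pairs
  if (nrow(p)) {
    d <- xyz[p[, 1], , drop = FALSE] - xyz[p[, 2], , drop = FALSE]
    r <- sqrt(rowSums(d * d))
    dEdr <- -pot$a_rep[tm$nb_type] / pot$rho_rep * exp(-r / pot$rho_rep)
    if (pot$level == "high") {
      dEdr <- dEdr + 6 * pot$c6[tm$nb_type] * r^5 / (r^6 + pot$d_damp^6)^2
    }
    unit <- d / r
    acc(p[, 1], unit * dEdr)
    acc(p[, 2], -unit * dEdr)
  }
  grad
}

#' Gaussian coordinate perturbations of a structure
#'
#' Generates \code{n} frames whose Cartesian coordinates are the input
#' plus i.i.d. Gaussian displacements of standard deviation \code{sigma},
#' deterministically from \code{seed}.  The bond graph and element order
#' are carried through.
#'
#' @param structure a \code{mol_structure}.
#' @param sigma displacement standard deviation.
#' @param n number of frames.
#' @param seed RNG seed.
#' @param units unit of \code{sigma}.
#' @return a \code{\link{mol_dataset}} with frames tagged
#'   \code{"displacement"}.
#' @export
perturb_structure <- function(structure, sigma, n, seed,
                              units = "angstrom") {
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  sig_b <- convert_unit(sigma, units, "bohr")
  nat <- n_atoms(structure)
  frames <- .with_seed(seed, {
    lapply(seq_len(n), function(i) {
      s <- structure
      s$coords <- s$coords + matrix(stats::rnorm(3 * nat, sd = sig_b), nat, 3)
      s$energy <- NULL
      s$tag <- "displacement"
      s
    })
  })
  mol_dataset(frames)
}

#' Labelled toy dataset around a chain conformation
#'
#' Convenience generator: builds the requested chain template(s),
#' perturbs them, and labels every frame with its toy energy at the
#' requested level.
#'
#' @param n_carbons chain length.
#' @param level \code{"high"} or \code{"low"}.
#' @param frames number of frames per conformation.
#' @param sigma Gaussian displacement (angstrom).
#' @param seed RNG seed.
#' @param conformations character vector of template conformations.
#' @return a \code{\link{mol_dataset}} with energy labels (hartree).
#' @export
make_toy_dataset <- function(n_carbons, level = "high", frames = 100,
                             sigma = 0.05, seed = 1,
                             conformations = "linear") {
  pot <- toy_alkane_potential(level)
  all_frames <- list()
  for (ci in seq_along(conformations)) {
    tmpl <- build_alkane(n_carbons, conformations[ci])
    ds <- perturb_structure(tmpl, sigma, frames, seed + ci - 1L)
    for (f in ds$frames) {
      f$energy <- pot_energy(pot, f)
      all_frames[[length(all_frames) + 1]] <- f
    }
  }
  mol_dataset(all_frames)
}

# run expr with a local, restored RNG state
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
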