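# NVE molecular dynamics (velocity Verlet) with harmonic-oscillator
# energy targeting and zero total linear/angular momentum initial
# conditions, plus power spectra from the velocity autocorrelation
# function.

#' Classical harmonic-oscillator energy target
#'
#' For a non-linear N-atom molecule the classical equipartition average
#' energy at temperature T is \code{(3N - 6) R T} (one RT per vibrational
#' mode), measured from the potential minimum.  For the 44-atom chain
#' C14H30 the factor is 126.
#'
#' @param structure a \code{\link{mol_structure}} with N >= 3.
#' @param temperature temperature in K.
#' @return total energy in hartree.
#' @export
md_target_energy <- function(structure, temperature) {
  n <- n_atoms(structure)
  if (n < 3) {
    stop("the (3N - 6) mode count needs a non-linear molecule with ",
         "N >= 3 atoms", call. = FALSE)
  }
  if (temperature < 0) stop("temperature must be >= 0", call. = FALSE)
  (3 * n - 6) * .kB_hartree * temperature
}

#' Draw NVE initial velocities
#'
#' Velocities are drawn from a Maxwell-Boltzmann distribution, the
#' centre-of-mass momentum and the total angular momentum are projected
#' out, and the result is rescaled so the kinetic energy equals
#' \code{\link{md_target_energy}} -- the harmonic-oscillator
#' correspondence between average energy and temperature.  Deterministic
#' given the seed.
#'
#' @param structure starting structure (at or near a minimum of the
#'   potential to be used).
#' @param temperature temperature in K.
#' @param seed RNG seed.
#' @return an object of class \code{"md_state"}: \code{structure},
#'   \code{velocities} (N x 3, bohr per au time), \code{masses} (au).
#' @export
md_init_velocities <- function(structure, temperature, seed) {
  if (temperature < 0) stop("temperature must be >= 0", call. = FALSE)
  n <- n_atoms(structure)
  m <- unname(atomic_mass(structure$elements, "au"))
  v <- .with_seed(seed, {
    matrix(stats::rnorm(3 * n), n, 3) *
      sqrt(.kB_hartree * max(temperature, 1e-12) / m)
  })
  v <- .project_momenta(structure$coords, v, m)
  target <- md_target_energy(structure, temperature)
  ke <- 0.5 * sum(m * rowSums(v * v))
  v <- if (target > 0 && ke > 0) v * sqrt(target / ke) else v * 0
  out <- list(structure = structure, velocities = v, masses = m)
  class(out) <- "md_state"
  out
}

# remove centre-of-mass momentum and rigid-body angular momentum
.project_momenta <- function(xyz, v, m) {
  vcom <- colSums(v * m) / sum(m)
  v <- sweep(v, 2, vcom)
  com <- colSums(xyz * m) / sum(m)
  r <- sweep(xyz, 2, com)
  L <- colSums(.cross_rows(r, v * m))
  inertia <- diag(sum(m * rowSums(r * r)), 3) - t(r * m) %*% r
  omega <- tryCatch(solve(inertia, L), error = function(e) {
    # near-linear geometry: pseudo-inverse
    sv <- svd(inertia)
    keep <- sv$d > 1e-10 * sv$d[1]
    drop(sv$v[, keep, drop = FALSE] %*%
           (crossprod(sv$u[, keep, drop = FALSE], L) / sv$d[keep]))
  })
  v - .cross_rows(matrix(omega, nrow(v), 3, byrow = TRUE), r)
}

#' Run NVE molecular dynamics
#'
#' Velocity-Verlet integration at a fixed time step.  Equilibration
#' steps are integrated but not stored; production frames (every
#' \code{store_stride}-th step) record positions, velocities and the
#' kinetic/potential/total energies.
#'
#' @param pot a potential object.
#' @param state an \code{"md_state"} from
#'   \code{\link{md_init_velocities}} (or a compatible list).
#' @param dt time step in atomic units (the reference protocol uses 5.0
#'   au = 0.121 fs).
#' @param n_equil equilibration steps (not stored).
#' @param n_prod production steps.
#' @param store_stride store every k-th production frame.
#' @param abort_factor abort when |E_total| exceeds this multiple of
#'   (|E_0| + target scale); guards against integration blow-up.
#' @return an object of class \code{"md_trajectory"}: \code{times} (au),
#'   \code{positions}, \code{velocities} (frames x 3N), \code{energies}
#'   (data.frame: kinetic, potential, total), \code{dt_store} (au
#'   between stored frames), \code{masses}, \code{elements}.
#' @export
run_nve <- function(pot, state, dt = 5.0, n_equil = 0, n_prod = 1000,
                    store_stride = 1, abort_factor = 100) {
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  s <- state$structure
  m <- state$masses
  x <- s$coords
  v <- state$velocities
  f <- -pot_gradient(pot, s)
  e_pot <- pot_energy(pot, s)
  e0 <- 0.5 * sum(m * rowSums(v * v)) + e_pot
  scale0 <- abs(e0) + .Machine$double.eps

  n_store <- n_prod %/% store_stride
  pos <- matrix(NA_real_, n_store, 3 * nrow(x))
  vel <- matrix(NA_real_, n_store, 3 * nrow(x))
  ek <- ep <- numeric(n_store)
  stored <- 0L

  total <- n_equil + n_prod
  for (step in seq_len(total)) {
    v <- v + (0.5 * dt) * f / m
    x <- x + dt * v
    s <- set_coords(s, x)
    f <- -pot_gradient(pot, s)
    v <- v + (0.5 * dt) * f / m
    if (step > n_equil && (step - n_equil) %% store_stride == 0) {
      stored <- stored + 1L
      kin <- 0.5 * sum(m * rowSums(v * v))
      potl <- pot_energy(pot, s)
      if (!is.finite(kin + potl) || abs(kin + potl) > abort_factor * scale0) {
        stop("NVE integration diverged at production step ",
             step - n_equil, " (|E| = ", signif(abs(kin + potl), 4),
             " hartree); reduce dt or switch on cutoff smoothing",
             call. = FALSE)
      }
      pos[stored, ] <- as.numeric(x)
      vel[stored, ] <- as.numeric(v)
      ek[stored] <- kin
      ep[stored] <- potl
    }
  }
  out <- list(times = dt * store_stride * seq_len(n_store),
              positions = pos[seq_len(stored), , drop = FALSE],
              velocities = vel[seq_len(stored), , drop = FALSE],
              energies = data.frame(kinetic = ek[seq_len(stored)],
                                    potential = ep[seq_len(stored)],
                                    total = ek[seq_len(stored)] + ep[seq_len(stored)]),
              dt = dt, store_stride = store_stride,
              dt_store = dt * store_stride,
              masses = m, elements = s$elements, template = s)
  class(out) <- "md_trajectory"
  out
}

#' @export
print.md_trajectory <- function(x, ...) {
  drift <- diff(range(x$energies$total))
  cat(sprintf("<md_trajectory> %d frames, dt = %.3g au (%.4g fs), E drift %.3g hartree\n",
              nrow(x$positions), x$dt, convert_unit(x$dt, "au_time", "fs"),
              drift))
  invisible(x)
}

#' Extract stored frames of a trajectory as a dataset
#'
#' @param traj an \code{md_trajectory}.
#' @param idx frame indices (default all).
#' @param tag provenance tag for the frames.
#' @return a \code{\link{mol_dataset}}.
#' @export
trajectory_frames <- function(traj, idx = NULL, tag = "md") {
  if (is.null(idx)) idx <- seq_len(nrow(traj$positions))
  frames <- lapply(idx, function(i) {
    s <- set_coords(traj$template,
                    matrix(traj$positions[i, ], ncol = 3))
    s$energy <- traj$energies$potential[i]
    s$tag <- tag
    s
  })
  mol_dataset(frames)
}

# frequency conversion: 1/(au time) -> cm^-1
.au_freq_to_cm1 <- 1 / (2.4188843265857e-17 * 2.99792458e10)

#' Power spectrum from the velocity autocorrelation function
#'
#' The per-trajectory spectrum is the squared-magnitude Fourier
#' transform of the (optionally mass-weighted, tapered) Cartesian
#' velocities, summed over atoms and components -- the Wiener-Khinchin
#' estimate of the Fourier-transformed velocity autocorrelation
#' function.  The final spectrum is the mean over trajectories; the
#' frequency axis is in cm^-1.
#'
#' @param trajs an \code{md_trajectory} or list of them (all sharing dt
#'   and length).
#' @param window taper applied to the velocity series: \code{"hann"} or
#'   \code{"none"}.
#' @param mass_weight weight each atom's contribution by its mass?
#' @param zero_pad zero-padding factor (>= 1) refining the frequency
#'   grid.
#' @return an object of class \code{"power_spectrum"}: \code{frequency}
#'   (cm^-1), \code{intensity} (>= 0), \code{n_trajectories_averaged}.
#' @export
power_spectrum <- function(trajs, window = c("hann", "none"),
                           mass_weight = TRUE, zero_pad = 2) {
  window <- match.arg(window)
  if (inherits(trajs, "md_trajectory")) trajs <- list(trajs)
  stopifnot(length(trajs) >= 1)
  dt <- trajs[[1]]$dt_store
  nt <- nrow(trajs[[1]]$velocities)
  for (tr in trajs) {
    if (abs(tr$dt_store - dt) > 1e-12 || nrow(tr$velocities) != nt) {
      stop("all trajectories must share the time step and length",
           call. = FALSE)
    }
  }
  w <- switch(window,
              hann = 0.5 * (1 - cos(2 * pi * seq(0, nt - 1) / (nt - 1))),
              none = rep(1, nt))
  npad <- as.integer(round(zero_pad * nt))
  spec <- 0
  for (tr in trajs) {
    weights <- if (mass_weight) rep(tr$masses, each = 3) else
      rep(1, ncol(tr$velocities))
    vs <- tr$velocities * w
    S <- numeric(npad)
    for (j in seq_len(ncol(vs))) {
      ft <- stats::fft(c(vs[, j], numeric(npad - nt)))
      S <- S + weights[j] * (Mod(ft)^2)
    }
    spec <- spec + S / nt
  }
  spec <- spec / length(trajs)
  nfreq <- npad %/% 2 + 1
  freq <- (seq_len(nfreq) - 1) / (npad * dt) * .au_freq_to_cm1
  out <- list(frequency = freq, intensity = spec[seq_len(nfreq)],
              n_trajectories_averaged = length(trajs),
              window = window, mass_weight = mass_weight, dt = dt)
  class(out) <- "power_spectrum"
  out
}

#' @export
print.power_spectrum <- function(x, ...) {
  pk <- x$frequency[which.max(x$intensity)]
  cat(sprintf("<power_spectrum> %d bins to %.0f cm-1 (peak at %.0f cm-1), %d trajectories averaged\n",
              length(x$frequency), max(x$frequency), pk,
              x$n_trajectories_averaged))
  invisible(x)
}

#' @export
plot.power_spectrum <- function(x, xlim = c(0, 4000), ...) {
  plot(x$frequency, x$intensity, type = "l",
       xlab = expression(tilde(nu) ~ (cm^-1)), ylab = "intensity",
       xlim = xlim, ...)
  invisible(x)
}

#' A harmonic diatomic potential (validation fixture)
#'
#' \code{E = 0.5 k (r - r0)^2} between the first two atoms of a
#' structure: the oscillation period of the corresponding diatomic is
#' exactly \code{2 pi sqrt(mu / k)}, which pins down the integrator's
#' accuracy.  \code{k = 0} gives a free particle.
#'
#' @param k force constant (hartree/bohr^2).
#' @param r0 equilibrium distance (bohr).
#' @return a potential object of class \code{"harmonic_potential"}.
#' @export
harmonic_diatomic <- function(k, r0) {
  structure(list(k = k, r0 = r0), class = "harmonic_potential")
}

#' @export
pot_energy.harmonic_potential <- function(pot, structure, ...) {
  d <- structure$coords[1, ] - structure$coords[2, ]
  r <- sqrt(sum(d * d))
  0.5 * pot$k * (r - pot$r0)^2
}

#' @export
pot_gradient.harmonic_potential <- function(pot, structure, ...) {
  g <- matrix(0, n_atoms(structure), 3)
  d <- structure$coords[1, ] - structure$coords[2, ]
  r <- sqrt(sum(d * d))
  if (r > 0 && pot$k != 0) {
    gr <- pot$k * (r - pot$r0) * d / r
    g[1, ] <- gr
    g[2, ] <- -gr
  }
  g
}
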