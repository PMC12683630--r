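test_that("the harmonic-oscillator energy target counts vibrational modes", {
  expect_equal(md_target_energy(build_alkane(14), 300) /
                 (mbpip:::.kB_hartree * 300), 126)  # C14H30: 3*44 - 6
  tri <- mol_structure(c("C", "H", "H"),
                       rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)))
  expect_equal(md_target_energy(tri, 100), 3 * mbpip:::.kB_hartree * 100)
  expect_equal(md_target_energy(tri, 0), 0)
  dia <- mol_structure(c("C", "C"), rbind(c(0, 0, 0), c(1.5, 0, 0)))
  expect_error(md_target_energy(dia, 300), "N >= 3")
})

test_that("initial velocities have zero momenta and the target kinetic energy", {
  s <- build_alkane(6)
  st <- md_init_velocities(s, 300, seed = 17)
  p <- colSums(st$velocities * st$masses)
  expect_lt(max(abs(p)), 1e-10)
  com <- colSums(s$coords * st$masses) / sum(st$masses)
  r <- sweep(s$coords, 2, com)
  L <- colSums(mbpip:::.cross_rows(r, st$velocities * st$masses))
  expect_lt(max(abs(L)), 1e-10)
  ke <- 0.5 * sum(st$masses * rowSums(st$velocities^2))
  target <- md_target_energy(s, 300)
  expect_lt(abs(ke - target) / target, 1e-10)
  st2 <- md_init_velocities(s, 300, seed = 17)
  expect_identical(st2$velocities, st$velocities)
  expect_error(md_init_velocities(s, -5, 1), "temperature")
})

test_that("a free particle moves in an exact straight line", {
  s <- mol_structure(c("C", "C"), rbind(c(0, 0, 0), c(4, 0, 0)),
                     units = "bohr")
  v0 <- rbind(c(1e-4, 2e-4, 0), c(-1e-4, 0, 3e-4))
  state <- list(structure = s, velocities = v0,
                masses = unname(atomic_mass(s$elements, "au")))
  tr <- run_nve(harmonic_diatomic(k = 0, r0 = 1), state, dt = 5,
                n_prod = 100)
  expect_equal(matrix(tr$positions[100, ], ncol = 3),
               s$coords + 100 * 5 * v0, tolerance = 1e-12)
  expect_equal(matrix(tr$velocities[100, ], ncol = 3), v0)
})

test_that("the harmonic diatomic oscillates at its analytic period", {
  k <- 0.25; r0 <- 2.2
  pot <- harmonic_diatomic(k, r0)
  m <- unname(atomic_mass(c("C", "C"), "au"))
  mu <- prod(m) / sum(m)
  period <- 2 * pi * sqrt(mu / k)
  s <- mol_structure(c("C", "C"), rbind(c(0, 0, 0), c(r0 + 0.08, 0, 0)),
                     units = "bohr")
  state <- list(structure = s, velocities = matrix(0, 2, 3), masses = m)
  dt <- 2.0
  tr <- run_nve(pot, state, dt = dt, n_prod = 5000)
  # period from the separation time series via parabolic peak refinement
  sep <- sqrt(rowSums((tr$positions[, 1:3] - tr$positions[, 4:6])^2))
  pk <- which(diff(sign(diff(sep))) == -2) + 1
  refine <- vapply(pk, function(i) {
    a <- sep[i - 1]; b <- sep[i]; c <- sep[i + 1]
    i + 0.5 * (a - c) / (a - 2 * b + c)
  }, numeric(1))
  period_md <- mean(diff(refine)) * dt
  expect_lt(abs(period_md - period) / period, 1e-3)
})

test_that("NVE conserves total energy and momentum over the reference length", {
  hi <- toy_alkane_potential("high")
  s <- optimize_geometry(hi, build_alkane(4), gtol = 1e-8)$structure
  st <- md_init_velocities(s, 300, seed = 4)
  tr <- run_nve(hi, st, dt = 5.0, n_equil = 0, n_prod = 22500,
                store_stride = 25)
  drift <- diff(range(tr$energies$total))
  expect_lt(drift / md_target_energy(s, 300), 1e-3)
  # linear momentum stays zero throughout (translation-invariant forces);
  # stored velocity columns are x(1..N), y(1..N), z(1..N)
  N <- length(tr$masses)
  for (d in 1:3) {
    p_d <- tr$velocities[, ((d - 1) * N + 1):(d * N)] %*% tr$masses
    expect_lt(max(abs(p_d)), 1e-10)
  }
})

test_that("divergent integration aborts with a diagnostic", {
  pot <- harmonic_diatomic(k = 5, r0 = 2)   # stiff + huge dt -> blow-up
  s <- mol_structure(c("H", "H"), rbind(c(0, 0, 0), c(3, 0, 0)),
                     units = "bohr")
  state <- list(structure = s, velocities = matrix(0, 2, 3),
                masses = unname(atomic_mass(c("H", "H"), "au")))
  expect_error(run_nve(pot, state, dt = 400, n_prod = 5000,
                       abort_factor = 10), "diverged")
})

fake_traj <- function(vcols, dt = 5, masses = NULL) {
  nt <- nrow(vcols)
  structure(list(velocities = vcols, dt_store = dt,
                 masses = if (is.null(masses)) rep(1, ncol(vcols) / 3)
                          else masses,
                 times = dt * seq_len(nt)),
            class = "md_trajectory")
}

test_that("power spectra locate an injected frequency within one bin", {
  nt <- 2048; dt <- 5
  nu_cm <- 1500
  f_au <- nu_cm / mbpip:::.au_freq_to_cm1
  v <- matrix(0, nt, 3)
  v[, 1] <- cos(2 * pi * f_au * dt * (seq_len(nt) - 1))
  ps <- power_spectrum(fake_traj(v, dt), window = "hann", zero_pad = 2)
  expect_true(all(ps$intensity >= 0))
  pk <- ps$frequency[which.max(ps$intensity)]
  bin <- diff(ps$frequency[1:2])
  expect_lt(abs(pk - nu_cm), bin + 1e-9)
  # zero velocities give an identically zero spectrum
  ps0 <- power_spectrum(fake_traj(matrix(0, 256, 3)))
  expect_true(all(ps0$intensity == 0))
})

test_that("averaging five spectra equals the five-trajectory call", {
  withr::with_seed(12, {
    trs <- lapply(1:5, function(i) fake_traj(matrix(rnorm(256 * 6), 256, 6)))
    joint <- power_spectrum(trs, window = "hann")
    sep <- lapply(trs, power_spectrum, window = "hann")
    mean_sep <- Reduce(`+`, lapply(sep, `[[`, "intensity")) / 5
    expect_equal(joint$intensity, mean_sep, tolerance = 1e-12)
    expect_equal(joint$n_trajectories_averaged, 5L)
  })
})

test_that("the untapered spectrum satisfies Parseval's identity", {
  withr::with_seed(3, {
    v <- matrix(rnorm(512 * 3), 512, 3)
    ps <- power_spectrum(fake_traj(v), window = "none", mass_weight = FALSE,
                         zero_pad = 1)
    # full-spectrum integral (positive + mirrored negative frequencies)
    nf <- length(ps$frequency)
    total <- ps$intensity[1] + ps$intensity[nf] +
      2 * sum(ps$intensity[2:(nf - 1)])
    expect_equal(total, sum(v^2), tolerance = 1e-9)
  })
})

test_that("mismatched trajectories are refused", {
  a <- fake_traj(matrix(0, 128, 3), dt = 5)
  b <- fake_traj(matrix(0, 128, 3), dt = 2)
  expect_error(power_spectrum(list(a, b)), "share")
})
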