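test_that("chain builder produces ideal CnH2n+2 templates", {
  for (n in c(2, 4, 14)) {
    s <- build_alkane(n)
    expect_equal(length(s$elements), 3L * n + 2L)
    expect_equal(sum(s$elements == "C"), n)
    expect_equal(sum(s$elements == "H"), 2L * n + 2L)
  }
  s <- build_alkane(14)
  xyz <- coords(s, "angstrom")
  # all backbone dihedrals exactly anti
  for (i in 1:11) {
    d <- mbpip:::.measure_dihedral(xyz[i, ], xyz[i + 1, ], xyz[i + 2, ],
                                   xyz[i + 3, ])
    expect_equal(abs(d) * 180 / pi, 180, tolerance = 1e-6)
  }
  # ideal bonds and angles
  cc <- sqrt(rowSums((xyz[2:14, ] - xyz[1:13, ])^2))
  expect_equal(cc, rep(1.54, 13), tolerance = 1e-9)
  expect_gt(min(dist(xyz)), 1.05)
  b4 <- build_alkane(4)
  expect_equal(as.integer(table(b4$elements)[c("C", "H")]), c(4L, 10L))
})

test_that("the hairpin template folds the chain with a four-gauche turn", {
  expect_error(build_alkane(6, "hairpin"), ">= 8")
  s <- build_alkane(14, "hairpin")
  xyz <- coords(s, "angstrom")
  d <- vapply(1:11, function(i)
    mbpip:::.measure_dihedral(xyz[i, ], xyz[i + 1, ], xyz[i + 2, ],
                              xyz[i + 3, ]) * 180 / pi, numeric(1))
  expect_equal(sum(abs(abs(d) - 60) < 1e-6), 4L)  # exactly four gauche
  # folded: end-to-end far below the extended chain
  ee_h <- sqrt(sum((xyz[1, ] - xyz[14, ])^2))
  ee_l <- sqrt(sum((coords(build_alkane(14), "angstrom")[1, ] -
                    coords(build_alkane(14), "angstrom")[14, ])^2))
  expect_lt(ee_h, 0.35 * ee_l)
  # tightest template contact is the documented turn H-H pair
  expect_gt(min(dist(xyz)), 0.7)
})

test_that("custom dihedral vectors build gauche conformers", {
  s <- build_alkane(6, dihedrals = c(180, 60, 180))
  xyz <- coords(s, "angstrom")
  d2 <- mbpip:::.measure_dihedral(xyz[2, ], xyz[3, ], xyz[4, ], xyz[5, ])
  expect_equal(d2 * 180 / pi, 60, tolerance = 1e-6)
  expect_error(build_alkane(6, dihedrals = c(60, 60)), "length")
})

test_that("high minus low is exactly the dispersion sum", {
  hi <- toy_alkane_potential("high")
  lo <- toy_alkane_potential("low")
  withr::with_seed(2, {
    for (rep in 1:5) {
      st <- perturb_structure(build_alkane(6), 0.08, 1, rep)[[1]]
      terms <- toy_term_energies(hi, st)
      e_hi <- pot_energy(hi, st)
      e_lo <- pot_energy(lo, st)
      expect_equal(e_hi - e_lo, unname(terms["dispersion"]),
                   tolerance = 1e-12)
      expect_equal(e_hi, sum(terms), tolerance = 1e-14)
    }
  })
})

test_that("an isolated nonbonded pair follows the closed-form terms", {
  hi <- toy_alkane_potential("high")
  lo <- toy_alkane_potential("low")
  r_ang <- 3.1
  s <- mol_structure(c("C", "C"),
                     rbind(c(0, 0, 0), c(r_ang, 0, 0)),
                     bonds = matrix(integer(0), 0, 2))
  kcal <- function(x) convert_unit(x, "hartree", "kcal/mol")
  disp <- kcal(pot_energy(hi, s) - pot_energy(lo, s))
  expect_equal(disp, -1200 / (r_ang^6 + 1.2^6), tolerance = 1e-10)
  rep_only <- kcal(pot_energy(lo, s))
  expect_equal(rep_only, 60000 * exp(-r_ang / 0.3), tolerance = 1e-9)
})

test_that("toy gradients match finite differences on distorted chains", {
  hi <- toy_alkane_potential("high")
  st <- perturb_structure(build_alkane(5), 0.06, 1, 4)[[1]]
  expect_equal(pot_gradient(hi, st), fd_gradient(hi, st), tolerance = 1e-6)
  lo <- toy_alkane_potential("low")
  expect_equal(pot_gradient(lo, st), fd_gradient(lo, st), tolerance = 1e-6)
})

test_that("toy energies carry the molecular invariances", {
  hi <- toy_alkane_potential("high")
  st <- perturb_structure(build_alkane(4), 0.05, 1, 6)[[1]]
  e0 <- pot_energy(hi, st)
  # swapping like atoms that play the same topological role: the two
  # central carbons cannot be swapped (different bonds), but any rigid
  # motion must leave the energy unchanged
  st2 <- st
  st2$coords <- st$coords %*% random_rotation(3) +
    matrix(c(5, -2, 1), nrow(st$coords), 3, byrow = TRUE)
  expect_lt(abs(pot_energy(hi, st2) - e0), 1e-12)
})

test_that("perturbations are deterministic with calibrated width", {
  s <- build_alkane(3)
  d0 <- perturb_structure(s, 0, 4, 1)
  for (f in d0$frames) expect_identical(f$coords, s$coords)
  d1 <- perturb_structure(s, 0.05, 5, 99)
  d2 <- perturb_structure(s, 0.05, 5, 99)
  expect_identical(lapply(d1$frames, `[[`, "coords"),
                   lapply(d2$frames, `[[`, "coords"))
  # displacement sample standard deviation within 2 percent at n = 10,000
  s2 <- mol_structure(c("C", "H"), rbind(c(0, 0, 0), c(1.1, 0, 0)))
  big <- perturb_structure(s2, 0.1, 10000, 7)
  disp <- unlist(lapply(big$frames, function(f)
    convert_unit(f$coords - s2$coords, "bohr", "angstrom")))
  expect_lt(abs(sd(disp) - 0.1) / 0.1, 0.02)
})

test_that("the toy landscape realises the dispersion-driven folding pattern", {
  hi <- toy_alkane_potential("high")
  lo <- toy_alkane_potential("low")
  # at each chain length the dispersionless gap exceeds the dispersion-
  # containing one, and the high-level gap falls monotonically with n
  gaps <- vapply(c(8, 10), function(n) {
    rl <- optimize_geometry(hi, build_alkane(n, "linear"), gtol = 1e-6)
    rh <- optimize_geometry(hi, build_alkane(n, "hairpin"), gtol = 1e-6)
    ll <- optimize_geometry(lo, build_alkane(n, "linear"), gtol = 1e-6)
    lh <- optimize_geometry(lo, build_alkane(n, "hairpin"), gtol = 1e-6)
    c(high = conformer_gap(hi, rl, rh), low = conformer_gap(lo, ll, lh))
  }, numeric(2))
  expect_true(all(gaps["low", ] > gaps["high", ]))
  expect_true(all(gaps["low", ] > 0))          # low level always extended
  expect_lt(gaps["high", 2], gaps["high", 1])  # folding grows with n
})
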