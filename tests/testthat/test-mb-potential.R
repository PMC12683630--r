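test_that("tuple enumeration matches combinatorial counts", {
  s14 <- build_alkane(14)
  n_pairs <- sum(vapply(c("CC", "CH", "HH"), function(cc)
    nrow(enumerate_tuples(s14, cc)), integer(1)))
  expect_equal(n_pairs, choose(44, 2))  # 946
  expect_equal(nrow(enumerate_tuples(s14, "CC", cutoff = 1e-12)), 0L)
  # methane-like 5-atom toy: one C, four H -> C(4,2) CHH tuples
  ch4 <- mol_structure(c("C", "H", "H", "H", "H"),
                       rbind(c(0, 0, 0), c(1, 1, 1), c(1, -1, -1),
                             c(-1, 1, -1), c(-1, -1, 1)) * 0.63)
  expect_equal(nrow(enumerate_tuples(ch4, "CHH")), 6L)
  expect_equal(nrow(enumerate_tuples(ch4, "CCC")), 0L)
  # full 3-b + 4-b coverage of the same structure
  n3 <- sum(vapply(c("CCC", "CCH", "CHH", "HHH"), function(cc)
    nrow(enumerate_tuples(ch4, cc)), integer(1)))
  n4 <- sum(vapply(c("CCCC", "CCCH", "CCHH", "CHHH", "HHHH"), function(cc)
    nrow(enumerate_tuples(ch4, cc)), integer(1)))
  expect_equal(n3, choose(5, 3))
  expect_equal(n4, choose(5, 4))
})

test_that("Morse transform has the documented limits", {
  expect_equal(morse(0, 2), 1)
  expect_equal(morse(2, 2), exp(-1))
  expect_lt(morse(1e4, 2), 1e-300)
  expect_true(all(diff(morse(seq(0, 10, 0.5), 1.7)) < 0))
  expect_error(morse(1, -1), "lambda")
})

test_that("a single-pair model evaluates to its closed form", {
  sp <- interaction_spec("CH", max_degree = 4, lambda = 2.0)
  cf <- c(0.5, -0.2, 0.1, 0.05)
  m <- mbpip_model(list(sp), list(cf))
  r <- 2.2
  s <- mol_structure(c("C", "H"), rbind(c(0, 0, 0), c(r, 0, 0)),
                     units = "bohr")
  y <- exp(-r / 2)
  expect_equal(pot_energy(m, s), sum(cf * y^(1:4)), tolerance = 1e-15)
  # zero coefficients, no offsets -> exactly zero anywhere
  m0 <- mbpip_model(list(sp))
  expect_identical(pot_energy(m0, s), 0)
  expect_true(all(pot_gradient(m0, s) == 0))
})

test_that("energy is bitwise invariant under like-atom permutations", {
  m <- random_toy_model(42)
  st <- perturb_structure(build_alkane(6), 0.05, 1, 3)[[1]]
  e0 <- pot_energy(m, st)
  withr::with_seed(8, {
    for (rep in 1:20) {
      el <- if (rep %% 2) "H" else "C"
      idx <- sample(which(st$elements == el), 2)
      st2 <- st
      st2$coords[idx, ] <- st$coords[rev(idx), ]
      expect_identical(pot_energy(m, st2), e0)
    }
  })
})

test_that("energy is invariant under rigid rotations and translations", {
  m <- random_toy_model(42)
  withr::with_seed(21, {
    for (rep in 1:10) {
      st <- perturb_structure(build_alkane(5), 0.04, 1, rep)[[1]]
      e0 <- pot_energy(m, st)
      st2 <- st
      st2$coords <- st$coords %*% random_rotation(rep) +
        matrix(rnorm(3), nrow(st$coords), 3, byrow = TRUE)
      expect_lt(abs(pot_energy(m, st2) - e0), 1e-10)
    }
  })
})

test_that("analytic gradients match finite differences", {
  m <- random_toy_model(42)
  st <- perturb_structure(build_alkane(5), 0.05, 1, 9)[[1]]
  g <- pot_gradient(m, st)
  fd <- fd_gradient(m, st)
  expect_equal(g, fd, tolerance = 1e-6)
  expect_lt(max(abs(colSums(g))), 1e-12)   # translational invariance
  # net torque about the origin vanishes (rotational invariance)
  torque <- colSums(mbpip:::.cross_rows(st$coords, g))
  expect_lt(max(abs(torque)), 1e-10)
})

test_that("hard and switched cutoffs behave as documented", {
  sp_hard <- interaction_spec("HH", max_degree = 3, lambda = 2, cutoff = 5)
  sp_soft <- interaction_spec("HH", max_degree = 3, lambda = 2, cutoff = 5,
                              switch_width = 1)
  cf <- list(c(1, 1, 1))
  mh <- mbpip_model(list(sp_hard), cf)
  ms <- mbpip_model(list(sp_soft), cf)
  s_at <- function(r) mol_structure(c("H", "H"),
                                    rbind(c(0, 0, 0), c(r, 0, 0)),
                                    units = "bohr")
  expect_gt(pot_energy(mh, s_at(4.99)), 0)
  expect_identical(pot_energy(mh, s_at(5.01)), 0)
  # switched model ramps smoothly to zero at the cutoff
  expect_equal(pot_energy(ms, s_at(4)), pot_energy(mh, s_at(4)))
  mid <- pot_energy(ms, s_at(4.5))
  expect_true(mid > 0 && mid < pot_energy(mh, s_at(4.5)))
  expect_lt(pot_energy(ms, s_at(4.999)), 1e-5)
  g <- pot_gradient(ms, s_at(4.5))
  expect_equal(g, fd_gradient(ms, s_at(4.5)), tolerance = 1e-6)
})

test_that("model files round-trip bit-exactly through JSON", {
  m <- random_toy_model(13, o2 = 3, o3 = 3, o4 = 2)
  m$one_body <- c(C = -0.123456789012345, H = 0.98765432109876e-3)
  m$energy_shift <- pi
  m$metadata <- list(note = "round-trip fixture")
  f <- tempfile(fileext = ".json")
  write_mbpip(m, f)
  m2 <- read_mbpip(f)
  expect_identical(m2$coefficients, m$coefficients)
  expect_identical(m2$energy_shift, m$energy_shift)
  expect_identical(m2$one_body, m$one_body)
  expect_equal(length(m2$specs), length(m$specs))
  st <- perturb_structure(build_alkane(4), 0.03, 1, 2)[[1]]
  expect_identical(pot_energy(m2, st), pot_energy(m, st))
})

test_that("structures outside the model alphabet are refused", {
  m <- mbpip_model(list(interaction_spec("CC", max_degree = 2)))
  s <- mol_structure(c("C", "H"), rbind(c(0, 0, 0), c(2, 0, 0)),
                     units = "bohr")
  expect_error(pot_energy(m, s), "alphabet")
})
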