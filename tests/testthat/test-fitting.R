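test_that("design-matrix rows reproduce model energies", {
  m <- random_toy_model(42)
  ds <- perturb_structure(build_alkane(5), 0.04, 6, 9)
  X <- mbpip_design(m$specs, ds)
  pred_design <- drop(X %*% unlist(m$coefficients))
  pred_energy <- predict(m, ds)
  expect_equal(pred_design, pred_energy, tolerance = 1e-12)
  # collapsed cutoffs give an all-zero matrix
  sp0 <- interaction_spec("CC", max_degree = 2, cutoff = 1e-9)
  X0 <- mbpip_design(list(sp0), ds)
  expect_true(all(X0 == 0))
  # single diatomic frame on a PAIR spec is the Morse power row
  r <- 2.7
  dia <- mol_dataset(list(mol_structure(c("C", "C"),
                                        rbind(c(0, 0, 0), c(r, 0, 0)),
                                        units = "bohr")))
  Xd <- mbpip_design(list(interaction_spec("CC", max_degree = 3, lambda = 2)),
                     dia)
  expect_equal(unname(drop(Xd)), exp(-r / 2)^(1:3), tolerance = 1e-14)
})

test_that("fitting data drawn from the model family recovers it to machine precision", {
  m <- random_toy_model(42)
  ds <- perturb_structure(build_alkane(6), 0.06, 120, 10)
  ds$frames <- lapply(ds$frames, function(f) {
    f$energy <- pot_energy(m, f); f
  })
  fit <- mbpip_fit(m$specs, ds)
  expect_lt(fit$rmse, 1e-8)
  # predictions of the recovered model agree everywhere sampled
  expect_equal(predict(fit, ds), dataset_energies(ds), tolerance = 1e-9)
})

test_that("duplicating every frame leaves the coefficients unchanged", {
  m <- random_toy_model(4, o2 = 3, o3 = 2, o4 = 2)
  ds <- perturb_structure(build_alkane(4), 0.05, 60, 2)
  ds$frames <- lapply(ds$frames, function(f) {
    f$energy <- pot_energy(m, f); f
  })
  fit1 <- mbpip_fit(m$specs, ds)
  ds2 <- mol_dataset(c(ds$frames, ds$frames))
  fit2 <- mbpip_fit(m$specs, ds2)
  expect_equal(coef(fit1), coef(fit2), tolerance = 1e-7)
})

test_that("one frame and one coefficient interpolate exactly", {
  s <- mol_structure(c("C", "C"), rbind(c(0, 0, 0), c(2.9, 0, 0)),
                     units = "bohr", energy = -0.2)
  fit <- suppressWarnings(
    mbpip_fit(list(interaction_spec("CC", max_degree = 1)),
              mol_dataset(list(s))))
  expect_lt(abs(fit$rmse), 1e-12)
})

test_that("per-atom error reporting divides by the atom count", {
  expect_equal(round(report_per_atom(115, 44), 1), 2.6)
  expect_equal(report_per_atom(0, 17), 0)
  expect_equal(report_per_atom(3.2, 1), 3.2)
  expect_error(report_per_atom(1, 0), "n_atoms")
})

test_that("the fit reports honest statistics and diagnostics", {
  m <- random_toy_model(4, o2 = 3, o3 = 2, o4 = 2)
  ds <- perturb_structure(build_alkane(4), 0.05, 80, 3)
  ds$frames <- lapply(ds$frames, function(f) {
    f$energy <- pot_energy(m, f); f
  })
  fit <- mbpip_fit(m$specs, ds)
  # rmse recomputed independently from predictions
  res <- dataset_energies(ds) - predict(fit, ds)
  expect_equal(fit$rmse, sqrt(mean(res^2)), tolerance = 1e-10)
  expect_equal(fit$rmse_per_atom, fit$rmse / 14)
  expect_equal(fit$max_abs_residual, max(abs(res)), tolerance = 1e-10)
  expect_gte(fit$condition, 1)
  s <- summary(fit)
  expect_s3_class(s, "summary.mbpip_fit")
  expect_equal(length(coef(fit)), fit$n_coefficients - 1L)  # minus intercept
})

test_that("degenerate and invalid training inputs are handled loudly", {
  sp <- list(interaction_spec("CC", max_degree = 3))
  s <- mol_structure(c("C", "C"), rbind(c(0, 0, 0), c(2.9, 0, 0)),
                     units = "bohr", energy = 1)
  w_u <- capture_warnings(mbpip_fit(sp, mol_dataset(list(s))))
  expect_true(any(grepl("underdetermined", w_u)))
  s_bad <- s; s_bad$energy <- NaN
  expect_error(mbpip_fit(sp, mol_dataset(list(s_bad))), "non-finite")
  expect_error(mbpip_fit(sp, mol_dataset(list())), "empty")
  # duplicated frames at identical geometry: rank-deficient, warned
  ds <- mol_dataset(list(s, s))
  w2 <- capture_warnings(
    mbpip_fit(list(interaction_spec("CC", max_degree = 3)), ds))
  expect_true(any(grepl("rank-deficient|underdetermined", w2)))
})

test_that("close-contact training geometries trigger the distance warning", {
  s <- mol_structure(c("H", "H"), rbind(c(0, 0, 0), c(0.3, 0, 0)),
                     units = "bohr", energy = 2)
  w <- capture_warnings(
    mbpip_fit(list(interaction_spec("HH", max_degree = 1)),
              mol_dataset(list(s))))
  expect_true(any(grepl("0.300 bohr", w)))
})

test_that("energy-dependent down-weighting has the documented form", {
  e <- c(0, 0.01, 0.1)
  w <- energy_weights(e, e_ref = 0.02)
  expect_equal(w, 0.02 / (e + 0.02))
})
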