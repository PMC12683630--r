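test_that("the sampling-plan arithmetic matches the reference protocol", {
  pts <- replicate(9, build_alkane(4), simplify = FALSE)
  plan <- delta_sampling_plan(pts, frames_per_trajectory = 151,
                              displaced_per_point = 51,
                              n_random_picks = 2544, seed = 3)
  expect_equal(plan_n_frames(plan), 9L * (151L + 51L) + 2544L)  # 4362
  empty <- delta_sampling_plan(list(), 0, 0, 0, seed = 1)
  expect_equal(plan_n_frames(empty), 0L)
  expect_error(delta_sampling_plan(list(), 5, 0, 0, seed = 1), "non-empty")
})

test_that("training-set assembly tags, labels and reproduces deterministically", {
  lo <- toy_alkane_potential("low")
  pts <- lapply(list(c(180), c(60)), function(d)
    optimize_geometry(lo, build_alkane(4, dihedrals = d),
                      gtol = 1e-7)$structure)
  src <- perturb_structure(build_alkane(4), 0.05, 12, 5)
  plan <- delta_sampling_plan(pts, frames_per_trajectory = 5,
                              displaced_per_point = 3, n_random_picks = 4,
                              seed = 11, md_stride = 3, md_equil = 50)
  ds <- assemble_delta_training_set(plan, lo, src)
  expect_equal(length(ds), plan_n_frames(plan))
  tags <- vapply(ds$frames, `[[`, character(1), "tag")
  expect_equal(as.integer(table(tags)[c("md", "displacement", "random_pick")]),
               c(10L, 6L, 4L))
  expect_false(anyNA(dataset_energies(ds)))
  ds2 <- assemble_delta_training_set(plan, lo, src)
  expect_identical(dataset_energies(ds2), dataset_energies(ds))
  expect_identical(ds2[[3]]$coords, ds[[3]]$coords)
  # all counts zero -> empty dataset; oversized picks -> error
  expect_equal(length(assemble_delta_training_set(
    delta_sampling_plan(pts, 0, 0, 0, seed = 1), lo, src)), 0L)
  bad <- delta_sampling_plan(pts, 0, 0, 99, seed = 1)
  expect_error(assemble_delta_training_set(bad, lo, src), "exceeds")
})

test_that("identical high and low labels give a null correction", {
  ds <- perturb_structure(build_alkane(4), 0.04, 40, 7)
  e <- seq(0.1, 0.2, length.out = 40)
  fit <- suppressWarnings(
    delta_fit(list(interaction_spec("CC", max_degree = 3),
                   interaction_spec("CH", max_degree = 3)),
              ds, e_high = e, e_low = e))
  expect_lt(fit$rmse, 1e-14)
  expect_lt(max(abs(unlist(fit$model$coefficients))), 1e-9)
})

test_that("a known correction surface is recovered from difference data", {
  m_delta <- random_toy_model(31, o2 = 3, o3 = 3, o4 = 2, sd = 5e-4)
  ds <- perturb_structure(build_alkane(5), 0.06, 100, 13)
  e_low <- withr::with_seed(5, runif(100, -0.1, 0.1))  # arbitrary baseline
  e_high <- e_low + predict(m_delta, ds)
  fit <- delta_fit(m_delta$specs, ds, e_high, e_low)
  expect_lt(fit$rmse, 1e-8)
  st <- perturb_structure(build_alkane(5), 0.05, 1, 99)[[1]]
  expect_lt(abs(pot_energy(fit$model, st) - pot_energy(m_delta, st)), 1e-8)
})

test_that("stacked energies and gradients compose additively", {
  lo_m <- random_toy_model(1, o2 = 3, o3 = 2, o4 = 2, sd = 1e-3)
  d_m <- random_toy_model(2, o2 = 2, o3 = 2, o4 = 2, sd = 1e-4)
  stack <- delta_stack(lo_m, d_m)
  withr::with_seed(9, {
    for (rep in 1:20) {
      st <- perturb_structure(build_alkane(4), 0.06, 1, rep)[[1]]
      e_lo <- pot_energy(lo_m, st)
      e_d <- pot_energy(d_m, st)
      expect_identical(pot_energy(stack, st), e_lo + e_d)  # bitwise
      g <- pot_gradient(stack, st)
      expect_lt(max(abs(g - pot_gradient(lo_m, st) - pot_gradient(d_m, st))),
                1e-12)
    }
  })
  # a zero-coefficient correction leaves the low level untouched
  null_d <- mbpip_model(d_m$specs)
  st0 <- build_alkane(4)
  expect_identical(pot_energy(delta_stack(lo_m, null_d), st0),
                   pot_energy(lo_m, st0))
})

test_that("difference data spans far less than the raw high-level data", {
  lo <- toy_alkane_potential("low")
  hi <- toy_alkane_potential("high")
  ds <- perturb_structure(build_alkane(6), 0.07, 60, 21)
  e_low <- vapply(ds$frames, function(f) pot_energy(lo, f), numeric(1))
  e_high <- vapply(ds$frames, function(f) pot_energy(hi, f), numeric(1))
  specs <- list(interaction_spec("CC", max_degree = 4, lambda = 1.75),
                interaction_spec("CH", max_degree = 4, lambda = 1.75),
                interaction_spec("HH", max_degree = 4, lambda = 1.75))
  fit_delta <- suppressWarnings(delta_fit(specs, ds, e_high, e_low))
  expect_lt(fit_delta$span_delta, 0.2 * fit_delta$span_high)
  # and the small difference surface is far easier to fit than the raw
  # high-level surface with the same small basis
  ds_high <- ds
  ds_high$frames <- mapply(function(f, e) { f$energy <- e; f },
                           ds_high$frames, e_high, SIMPLIFY = FALSE)
  fit_high <- suppressWarnings(mbpip_fit(specs, ds_high))
  expect_lt(fit_delta$rmse, 0.1 * fit_high$rmse)
})

test_that("delta fits can correct against a low-level model instead of data", {
  lo <- toy_alkane_potential("low")
  hi <- toy_alkane_potential("high")
  ds <- perturb_structure(build_alkane(4), 0.05, 50, 33)
  e_high <- vapply(ds$frames, function(f) pot_energy(hi, f), numeric(1))
  specs <- list(interaction_spec("CC", max_degree = 3),
                interaction_spec("CH", max_degree = 3),
                interaction_spec("HH", max_degree = 3))
  fit <- suppressWarnings(delta_fit(specs, ds, e_high, e_low = lo))
  expect_identical(fit$model$metadata$delta_low_mode, "model")
  direct <- suppressWarnings(
    delta_fit(specs, ds, e_high,
              vapply(ds$frames, function(f) pot_energy(lo, f), numeric(1))))
  expect_identical(direct$model$metadata$delta_low_mode, "direct")
  expect_equal(coef(fit), coef(direct), tolerance = 1e-10)
})

test_that("stacked models serialise and reload", {
  lo_m <- random_toy_model(1, o2 = 2, o3 = 2, o4 = 2, sd = 1e-3)
  d_m <- random_toy_model(2, o2 = 2, o3 = 2, o4 = 2, sd = 1e-4)
  stack <- delta_stack(lo_m, d_m, metadata = list(low = "toy-low"))
  f <- tempfile(fileext = ".json")
  write_delta_stack(stack, f)
  stack2 <- read_delta_stack(f)
  st <- build_alkane(4)
  expect_identical(pot_energy(stack2, st), pot_energy(stack, st))
})
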