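# The package's reference end-to-end study on the synthetic two-level
# alkane system: build stationary points, sample training data, fit the
# low-level and delta surfaces, and measure hairpin-linear gap recovery.

# default interaction specs; ranges are matched to the physics each order
# must represent (bond/steric tails for 2-b, angle triangles for 3-b,
# 1-4 torsion spans for 4-b) so that every retained tuple geometry is
# constrained by training data at the training chain length
.default_low_specs <- function() {
  c(lapply(c("CC", "CH", "HH"), interaction_spec, max_degree = 10,
           lambda = 2.5, cutoff = 12, switch_width = 2),
    lapply(c("CCC", "CCH", "CHH", "HHH"), interaction_spec, max_degree = 8,
           lambda = 2.0, cutoff = 7, switch_width = 1.5),
    lapply(c("CCCC", "CCCH", "CCHH", "CHHH", "HHHH"), interaction_spec,
           max_degree = 6, lambda = 1.8, cutoff = 9.5, switch_width = 1.5))
}

.default_delta_specs <- function() {
  c(lapply(c("CC", "CH", "HH"), interaction_spec, max_degree = 6,
           lambda = 1.75, cutoff = 14, switch_width = 2),
    lapply(c("CCC", "CCH", "CHH", "HHH"), interaction_spec, max_degree = 7,
           lambda = 2.0, cutoff = 7, switch_width = 1.5),
    lapply(c("CCCC", "CCCH", "CCHH", "CHHH", "HHHH"), interaction_spec,
           max_degree = 5, lambda = 1.8, cutoff = 9.5, switch_width = 1.5))
}

#' Default interaction specifications of the reference workflow
#'
#' \code{mbpip_default_specs("low")} returns the low-level configuration
#' (polynomial orders 10/8/6 for 2-/3-/4-body, 734 coefficients);
#' \code{mbpip_default_specs("delta")} the correction configuration
#' (orders 6/7/5, 383 coefficients).
#'
#' @param which \code{"low"} or \code{"delta"}.
#' @return list of \code{\link{interaction_spec}}.
#' @export
mbpip_default_specs <- function(which = c("low", "delta")) {
  switch(match.arg(which), low = .default_low_specs(),
         delta = .default_delta_specs())
}

#' Stationary points of the toy low-level surface along the folding path
#'
#' Linear and hairpin minima plus gauche-conformer intermediates
#' (partial turns), each relaxed on the dispersionless toy surface.
#' Nine points for chains long enough to fold; for shorter chains, as
#' many distinct gauche conformers as the dihedral count allows.
#'
#' @param n_carbons chain length.
#' @param gtol minimiser tolerance.
#' @return list of \code{mol_structure} (relaxed stationary points).
#' @export
toy_stationary_points <- function(n_carbons, gtol = 1e-7) {
  lo <- toy_alkane_potential("low")
  n <- as.integer(n_carbons)
  ndh <- n - 3L
  anti <- rep(180, ndh)
  confs <- list(anti)
  if (n >= 8) confs <- c(confs, list(NULL))  # NULL marks the hairpin template
  # partial turns / single+double gauche intermediates, mid-chain first
  pos <- order(abs(seq_len(ndh) - (ndh + 1) / 2))
  cand <- list()
  if (ndh >= 1) for (p in pos) {
    d <- anti; d[p] <- 60; cand <- c(cand, list(d))
    d <- anti; d[p] <- -60; cand <- c(cand, list(d))
  }
  if (ndh >= 2) for (p in pos[pos < ndh]) {
    d <- anti; d[p] <- 60; d[p + 1] <- 60; cand <- c(cand, list(d))
  }
  if (ndh >= 3) for (p in pos[pos < ndh - 1]) {
    d <- anti; d[p] <- 60; d[p + 1] <- 60; d[p + 2] <- -60
    cand <- c(cand, list(d))
  }
  confs <- c(confs, cand[seq_len(min(9L - length(confs), length(cand)))])
  lapply(confs, function(d) {
    s <- if (is.null(d)) build_alkane(n, "hairpin")
         else build_alkane(n, dihedrals = d)
    optimize_geometry(lo, s, gtol = gtol)$structure
  })
}

#' Reference delta-machine-learning study on the synthetic alkane system
#'
#' Runs the package's end-to-end workflow: (1) locate stationary points
#' of the toy low-level surface at the training chain length (linear,
#' hairpin, gauche intermediates) plus the two high-level minima as
#' extra sampling centers; (2) sample NVE molecular-dynamics frames and
#' Gaussian displacements around every center, labelled with toy
#' low-level energies; (3) fit the low-level MB-PIP surface (adding
#' short-chain datasets and per-element one-body offsets for
#' size-transferability of the coefficients); (4) fit the correction
#' surface to direct high-minus-low differences on the training-length
#' data; (5) evaluate hairpin-minus-linear gaps of the stacked
#' potentials at the high-level reference minima for each requested
#' chain length (the fixed-geometry consistency protocol).
#'
#' Two stacks are evaluated: the fully fitted stack (fitted low-level
#' model + fitted correction) and the correction stacked on the
#' low-level surface evaluated directly.  The former tests the whole
#' machinery at the training length; the latter isolates the
#' transferability of the correction, which is the quantity the
#' delta-learning approach is responsible for.
#'
#' In addition to MD and displacement sampling, a "breathing ladder" of
#' uniformly scaled, jittered copies of the two high-level minima sweeps
#' every pair distance coherently through the nonbonded contact region;
#' this pins the two-body shape of the correction where folded
#' conformers are most sensitive and is what makes the fitted correction
#' transfer across chain lengths.
#'
#' @param seed integer seed controlling all sampling.
#' @param n_train training chain length (>= 8).
#' @param n_eval chain lengths at which gaps are evaluated.
#' @param small_chains extra chain lengths added (linear conformers
#'   only) to the low-level training set.
#' @param md_frames MD frames per sampling center.
#' @param displaced frames per center for each displacement width.
#' @param sigma Gaussian displacement widths (angstrom).
#' @param breathing scale factors for the contact-region ladder around
#'   the high-level minima (set \code{NULL} to disable).
#' @param breathing_frames jittered frames per ladder rung.
#' @param temperature MD temperature (K).
#' @param low_specs,delta_specs interaction specifications (defaults:
#'   \code{\link{mbpip_default_specs}}).
#' @param gtol minimiser tolerance for the reference geometries.
#' @return an object of class \code{"delta_toy_study"}: fields
#'   \code{fit_low}, \code{fit_delta}, \code{gaps} (data.frame with the
#'   true and stacked gaps and their errors per chain length),
#'   \code{n_train}, \code{seed}.
#' @export
delta_toy_study <- function(seed = 1, n_train = 8, n_eval = c(8, 10),
                            small_chains = c(4, 6),
                            md_frames = 150, displaced = c(100, 60),
                            sigma = c(0.04, 0.08), temperature = 300,
                            breathing = c(0.94, 0.97, 1.03, 1.07),
                            breathing_frames = 20,
                            low_specs = mbpip_default_specs("low"),
                            delta_specs = mbpip_default_specs("delta"),
                            gtol = 1e-6) {
  seed <- as.integer(seed)
  lo <- toy_alkane_potential("low")
  hi <- toy_alkane_potential("high")

  sp <- toy_stationary_points(n_train)
  hi_lin <- optimize_geometry(hi, build_alkane(n_train, "linear"),
                              gtol = 1e-7)$structure
  hi_hp <- optimize_geometry(hi, build_alkane(n_train, "hairpin"),
                             gtol = 1e-7)$structure
  centers <- c(sp, list(hi_lin, hi_hp))

  sample_center <- function(s, sd0) {
    st <- md_init_velocities(s, temperature, sd0)
    tr <- run_nve(lo, st, dt = 5, n_equil = 250,
                  n_prod = md_frames * 5, store_stride = 5)
    out <- trajectory_frames(tr)$frames
    for (j in seq_along(sigma)) {
      out <- c(out, perturb_structure(s, sigma[j], displaced[j],
                                      sd0 + j)$frames)
    }
    out
  }
  f_core <- list()
  for (i in seq_along(centers)) {
    f_core <- c(f_core, sample_center(centers[[i]], seed + 10L * i))
  }
  # contact-region breathing ladder: delta training only -- the scaled
  # frames carry large bonded strain that would blunt the low-level
  # fit's basin precision, while their dispersion signal is exactly what
  # pins the correction's two-body shape
  f_breath <- list()
  if (length(breathing)) {
    k <- 0L
    for (s0 in list(hi_lin, hi_hp)) {
      for (f in breathing) {
        k <- k + 1L
        sq <- s0
        sq$coords <- s0$coords * f
        f_breath <- c(f_breath, perturb_structure(sq, 0.03, breathing_frames,
                                                  seed + 900L + k)$frames)
      }
    }
  }
  label_low <- function(frames) lapply(frames, function(f) {
    f$energy <- pot_energy(lo, f); f
  })
  ds_train <- mol_dataset(label_low(c(f_core, f_breath)))

  f_small <- list()
  for (n in small_chains) {
    m0 <- optimize_geometry(lo, build_alkane(n, "linear"),
                            gtol = 1e-7)$structure
    f_small <- c(f_small, sample_center(m0, seed + 1000L + n))
  }
  ds_low <- mol_dataset(c(label_low(f_small), label_low(f_core)))

  fit_low <- suppressWarnings(mbpip_fit(low_specs, ds_low, one_body = TRUE))
  e_low <- dataset_energies(ds_train)
  e_high <- vapply(ds_train$frames, function(f) pot_energy(hi, f),
                   numeric(1))
  fit_delta <- suppressWarnings(delta_fit(delta_specs, ds_train,
                                          e_high, e_low))
  stack_fitted <- delta_stack(fit_low, fit_delta,
                              metadata = list(low = "fitted MB-PIP",
                                              delta = "fitted correction"))
  stack_direct <- delta_stack(lo, fit_delta,
                              metadata = list(low = "toy low-level surface",
                                              delta = "fitted correction"))

  rows <- lapply(sort(unique(c(n_train, n_eval))), function(n) {
    rl <- optimize_geometry(hi, build_alkane(n, "linear"), gtol = gtol)
    rh <- optimize_geometry(hi, build_alkane(n, "hairpin"), gtol = gtol)
    g_true <- conformer_gap(hi, rl, rh)
    g_fit <- conformer_gap(stack_fitted, rl$structure, rh$structure,
                           reference = hi)
    g_dir <- conformer_gap(stack_direct, rl$structure, rh$structure,
                           reference = hi)
    g_low <- conformer_gap(fit_low$model, rl$structure, rh$structure,
                           reference = hi)
    g_lowtrue <- conformer_gap(lo, rl$structure, rh$structure,
                               reference = hi)
    data.frame(n = n, gap_true = g_true,
               gap_stack_fitted = g_fit, err_stack_fitted = g_fit - g_true,
               gap_stack_direct = g_dir, err_stack_direct = g_dir - g_true,
               err_low_fit = g_low - g_lowtrue)
  })
  out <- list(fit_low = fit_low, fit_delta = fit_delta,
              stack_fitted = stack_fitted, stack_direct = stack_direct,
              gaps = do.call(rbind, rows), n_train = n_train,
              n_frames_train = length(ds_train),
              n_frames_low = length(ds_low), seed = seed)
  class(out) <- "delta_toy_study"
  out
}

#' @export
print.delta_toy_study <- function(x, ...) {
  cat("delta-ML reference study on the synthetic alkane system\n")
  cat(sprintf("  training chain: C%d (%d frames; low-level set %d frames)\n",
              x$n_train, x$n_frames_train, x$n_frames_low))
  cat(sprintf("  low-level fit rmse: %.4g kcal/mol (%d coefficients)\n",
              convert_unit(x$fit_low$rmse, "hartree", "kcal/mol"),
              n_coefficients(x$fit_low$model)))
  cat(sprintf("  correction fit rmse: %.4g kcal/mol (%d coefficients); difference span %.3g vs raw %.3g kcal/mol\n",
              convert_unit(x$fit_delta$rmse, "hartree", "kcal/mol"),
              n_coefficients(x$fit_delta$model),
              convert_unit(x$fit_delta$span_delta, "hartree", "kcal/mol"),
              convert_unit(x$fit_delta$span_high, "hartree", "kcal/mol")))
  cat("  hairpin - linear gaps (kcal/mol):\n")
  print(format(x$gaps, digits = 4), row.names = FALSE)
  invisible(x)
}
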