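# Delta machine learning: a correction surface fitted to high-minus-low
# energy differences with the same MB-PIP machinery, and the stacked
# potential V_low + Delta.

#' Sampling plan for a delta-correction training set
#'
#' The three-source protocol: (i) NVE molecular dynamics frames started
#' from each stationary point, (ii) random Gaussian displacements of
#' each stationary point, (iii) random picks from an existing dataset.
#' The reference protocol uses 9 stationary points x 151 MD frames,
#' 9 x 51 displacements and 2544 random picks.
#'
#' @param stationary_points list of \code{mol_structure} (minima/saddles
#'   of the low-level surface).
#' @param frames_per_trajectory MD frames kept per stationary point.
#' @param displaced_per_point Gaussian-displaced frames per stationary
#'   point.
#' @param n_random_picks frames drawn (without replacement) from the
#'   source dataset.
#' @param seed RNG seed controlling everything.
#' @param displacement_sigma Gaussian displacement width (angstrom).
#' @param temperature MD temperature (K).
#' @param dt MD step (au).
#' @param md_stride store every k-th MD step.
#' @param md_equil MD equilibration steps.
#' @return an object of class \code{"delta_sampling_plan"}.
#' @export
delta_sampling_plan <- function(stationary_points,
                                frames_per_trajectory = 151,
                                displaced_per_point = 51,
                                n_random_picks = 2544,
                                seed = 1,
                                displacement_sigma = 0.05,
                                temperature = 300,
                                dt = 5.0, md_stride = 5, md_equil = 250) {
  stopifnot(frames_per_trajectory >= 0, displaced_per_point >= 0,
            n_random_picks >= 0, displacement_sigma >= 0)
  if ((frames_per_trajectory > 0 || displaced_per_point > 0) &&
      !length(stationary_points)) {
    stop("stationary_points must be non-empty when per-point frames are ",
         "requested", call. = FALSE)
  }
  p <- list(stationary_points = stationary_points,
            frames_per_trajectory = as.integer(frames_per_trajectory),
            displaced_per_point = as.integer(displaced_per_point),
            n_random_picks = as.integer(n_random_picks),
            seed = as.integer(seed),
            displacement_sigma = displacement_sigma,
            temperature = temperature, dt = dt,
            md_stride = as.integer(md_stride),
            md_equil = as.integer(md_equil))
  class(p) <- "delta_sampling_plan"
  p
}

#' Total frame count of a sampling plan
#'
#' \code{n_points * (md + displaced) + picks}; the reference plan gives
#' 9 * (151 + 51) + 2544 = 4362.
#'
#' @param plan a \code{delta_sampling_plan}.
#' @return integer.
#' @export
plan_n_frames <- function(plan) {
  length(plan$stationary_points) *
    (plan$frames_per_trajectory + plan$displaced_per_point) +
    plan$n_random_picks
}

#' @export
print.delta_sampling_plan <- function(x, ...) {
  cat(sprintf(paste0("<delta_sampling_plan> %d stationary points x (%d md",
                     " + %d displaced) + %d picks = %d frames (seed %d)\n"),
              length(x$stationary_points), x$frames_per_trajectory,
              x$displaced_per_point, x$n_random_picks, plan_n_frames(x),
              x$seed))
  invisible(x)
}

#' Assemble a delta-correction training set
#'
#' Executes a \code{\link{delta_sampling_plan}} on the low-level
#' potential: runs one NVE trajectory per stationary point (uniform
#' frame stride), adds Gaussian-displaced copies of each stationary
#' point, and draws random picks without replacement from the source
#' dataset.  Frames carry provenance tags \code{"md"},
#' \code{"displacement"} and \code{"random_pick"}, and are labelled with
#' their low-level energies.  Deterministic given the plan's seed.
#'
#' @param plan a \code{delta_sampling_plan}.
#' @param low_pot the low-level potential driving the MD.
#' @param source_dataset a \code{mol_dataset} to pick from (required
#'   when \code{n_random_picks > 0}).
#' @return a \code{\link{mol_dataset}}.
#' @export
assemble_delta_training_set <- function(plan, low_pot,
                                        source_dataset = NULL) {
  frames <- list()
  for (k in seq_along(plan$stationary_points)) {
    sp <- plan$stationary_points[[k]]
    if (plan$frames_per_trajectory > 0) {
      state <- md_init_velocities(sp, plan$temperature,
                                  seed = plan$seed + 1000L * k)
      traj <- run_nve(low_pot, state, dt = plan$dt,
                      n_equil = plan$md_equil,
                      n_prod = plan$frames_per_trajectory * plan$md_stride,
                      store_stride = plan$md_stride)
      md <- trajectory_frames(traj, tag = "md")
      frames <- c(frames, md$frames[seq_len(plan$frames_per_trajectory)])
    }
    if (plan$displaced_per_point > 0) {
      disp <- perturb_structure(sp, plan$displacement_sigma,
                                plan$displaced_per_point,
                                seed = plan$seed + 1000L * k + 500L)
      disp$frames <- lapply(disp$frames, function(f) {
        f$energy <- pot_energy(low_pot, f)
        f
      })
      frames <- c(frames, disp$frames)
    }
  }
  if (plan$n_random_picks > 0) {
    if (is.null(source_dataset)) {
      stop("source_dataset is required for random picks", call. = FALSE)
    }
    if (plan$n_random_picks > length(source_dataset)) {
      stop("n_random_picks (", plan$n_random_picks,
           ") exceeds the source dataset size (", length(source_dataset),
           ")", call. = FALSE)
    }
    idx <- .with_seed(plan$seed + 99L,
                      sample.int(length(source_dataset),
                                 plan$n_random_picks, replace = FALSE))
    picks <- lapply(source_dataset$frames[idx], function(f) {
      f$tag <- "random_pick"
      if (is.null(f$energy)) f$energy <- pot_energy(low_pot, f)
      f
    })
    frames <- c(frames, picks)
  }
  mol_dataset(frames)
}

#' Fit a delta-correction MB-PIP surface
#'
#' Least-squares fit of the interaction specs' bases to high-minus-low
#' energy differences.  Reports, in addition to the usual fit
#' statistics, the span (max - min) of the difference data and of the
#' raw high-level data -- the correction's small span relative to the
#' raw surface is what makes the delta fit an easy problem.
#'
#' @param specs list of \code{\link{interaction_spec}} for the
#'   correction surface.
#' @param dataset a \code{mol_dataset} of training geometries.
#' @param e_high,e_low energy labels (hartree), one per frame.  If
#'   \code{e_low} is an \code{mbpip_model} or other potential it is
#'   evaluated on the frames (correction against the low-level model
#'   rather than direct low-level data; recorded in the metadata).
#' @param ... passed to \code{\link{mbpip_fit}}.
#' @return an object of class \code{c("delta_fit", "mbpip_fit")} with
#'   extra fields \code{span_delta} and \code{span_high} (hartree).
#' @export
delta_fit <- function(specs, dataset, e_high, e_low, ...) {
  if (length(e_high) != length(dataset)) {
    stop("e_high must have one value per frame", call. = FALSE)
  }
  low_mode <- "direct"
  if (!is.numeric(e_low)) {
    low_mode <- "model"
    e_low <- vapply(dataset$frames, function(f) pot_energy(e_low, f),
                    numeric(1))
  }
  if (length(e_low) != length(dataset)) {
    stop("e_low must have one value per frame", call. = FALSE)
  }
  if (anyNA(e_high) || anyNA(e_low)) {
    stop("missing energy label(s) in the high/low pair data", call. = FALSE)
  }
  diffs <- e_high - e_low
  ds <- dataset
  ds$frames <- mapply(function(f, e) { f$energy <- e; f },
                      ds$frames, diffs, SIMPLIFY = FALSE)
  fit <- mbpip_fit(specs, ds, ...)
  fit$model$metadata$delta_low_mode <- low_mode
  fit$span_delta <- max(diffs) - min(diffs)
  fit$span_high <- max(e_high) - min(e_high)
  class(fit) <- c("delta_fit", class(fit))
  fit
}

#' @export
print.delta_fit <- function(x, ...) {
  NextMethod()
  cat(sprintf("  difference-data span: %.4g hartree (%.4g cm-1); raw high-level span: %.4g hartree\n",
              x$span_delta, convert_unit(x$span_delta, "hartree", "cm-1"),
              x$span_high))
  invisible(x)
}

#' Stack a low-level potential with its delta correction
#'
#' The corrected potential \code{V = V_low + Delta}: energies and
#' gradients are the exact sums of the two components.
#'
#' @param v_ll the low-level potential (usually an \code{mbpip_model}).
#' @param delta the correction (an \code{mbpip_model} or
#'   \code{mbpip_fit}/\code{delta_fit}, whose model is taken).
#' @param metadata free-form list naming the two levels.
#' @return an object of class \code{"delta_stack"}.
#' @export
delta_stack <- function(v_ll, delta, metadata = list()) {
  if (inherits(v_ll, "mbpip_fit")) v_ll <- v_ll$model
  if (inherits(delta, "mbpip_fit")) delta <- delta$model
  s <- list(v_ll = v_ll, delta = delta, metadata = metadata)
  class(s) <- "delta_stack"
  s
}

#' @export
print.delta_stack <- function(x, ...) {
  cat("<delta_stack> V = V_low + Delta\n")
  if (length(x$metadata)) utils::str(x$metadata, give.attr = FALSE)
  invisible(x)
}

#' @export
pot_energy.delta_stack <- function(pot, structure, ...) {
  pot_energy(pot$v_ll, structure) + pot_energy(pot$delta, structure)
}

#' @export
pot_gradient.delta_stack <- function(pot, structure, ...) {
  pot_gradient(pot$v_ll, structure) + pot_gradient(pot$delta, structure)
}

#' @export
predict.delta_stack <- function(object, newdata, unit = "hartree", ...) {
  frames <- if (inherits(newdata, "mol_structure")) list(newdata)
            else newdata$frames
  e <- vapply(frames, function(f) pot_energy(object, f), numeric(1))
  convert_unit(e, "hartree", unit)
}
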