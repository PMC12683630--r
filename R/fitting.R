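# Linear least-squares fitting of MB-PIP coefficients: one design matrix
# over all interaction types, one overdetermined solve "at once".

#' Design matrix of an MB-PIP specification over a dataset
#'
#' Row f, column m holds the sum over type-matching tuples of frame f of
#' basis function m evaluated at the tuple's Morse variables (times the
#' cutoff switch, if any).  Column order matches the coefficient order of
#' \code{\link{mbpip_model}}; with \code{one_body = TRUE} per-element
#' atom-count columns are appended.
#'
#' @param specs list of \code{\link{interaction_spec}} (or an
#'   \code{mbpip_model}, whose specs are used).
#' @param dataset a non-empty \code{\link{mol_dataset}}.
#' @param one_body append per-element constant-offset columns?
#' @return numeric matrix with column names.
#' @export
mbpip_design <- function(specs, dataset, one_body = FALSE) {
  if (inherits(specs, "mbpip_model")) specs <- specs$specs
  if (inherits(specs, "interaction_spec")) specs <- list(specs)
  if (!length(dataset)) stop("dataset is empty", call. = FALSE)
  alphabet <- sort(unique(unlist(strsplit(
    vapply(specs, `[[`, character(1), "composition"), ""))))
  bases <- lapply(specs, .spec_basis)
  sizes <- vapply(bases, `[[`, integer(1), "n_fun")
  ncol_total <- sum(sizes) + if (one_body) length(alphabet) else 0
  X <- matrix(0, length(dataset), ncol_total)
  for (f in seq_along(dataset$frames)) {
    frame <- dataset$frames[[f]]
    D <- .dist_matrix(frame$coords)
    off <- 0L
    for (k in seq_along(specs)) {
      if (sizes[k] > 0) {
        fd <- .spec_frame(specs[[k]], frame, D)
        if (nrow(fd$tuples) > 0) {
          B <- cpp_pip_eval(fd$Y, bases[[k]]$expo, bases[[k]]$fun_id,
                            bases[[k]]$n_fun, bases[[k]]$group_mat)
          X[f, (off + 1):(off + sizes[k])] <- colSums(B * fd$S)
        }
      }
      off <- off + sizes[k]
    }
    if (one_body) {
      counts <- table(factor(frame$elements, levels = alphabet))
      X[f, (off + 1):(off + length(alphabet))] <- as.numeric(counts)
    }
  }
  cn <- unlist(lapply(seq_along(specs), function(k) {
    sprintf("%s.%03d", specs[[k]]$composition, seq_len(sizes[k]))
  }))
  if (one_body) cn <- c(cn, paste0("E1.", alphabet))
  colnames(X) <- cn
  X
}

#' Fit an MB-PIP potential by linear least squares
#'
#' Builds the design matrix for the interaction specs over the training
#' dataset and solves the single overdetermined least-squares problem for
#' all linear coefficients at once.  The solver is SVD-based
#' (rank-revealing): on rank deficiency it warns and returns the
#' minimum-norm solution; the ratio of extreme retained singular values
#' is reported as a conditioning diagnostic.
#'
#' Reference-energy convention: the basis has no constant term, so when
#' one-body offsets are off the training energies are shifted to the
#' dataset minimum and a free intercept is carried through the solve;
#' the combined shift is stored in the model and added back by
#' \code{predict}.  With one-body offsets on, the per-element count
#' columns play that role.
#'
#' @param specs list of \code{\link{interaction_spec}}.
#' @param dataset a \code{\link{mol_dataset}} whose frames all carry
#'   energy labels.
#' @param weights optional per-frame weights (default uniform).  For
#'   energy-dependent down-weighting see \code{\link{energy_weights}}.
#' @param one_body fit per-element constant offsets jointly?
#' @param svd_tol relative singular-value cutoff (default
#'   \code{max(dim(X)) * .Machine$double.eps}).
#' @return an object of class \code{"mbpip_fit"}: the fitted model plus
#'   training statistics.  Methods: \code{print}, \code{summary},
#'   \code{coef}, \code{predict}, \code{fitted}, \code{residuals}.
#' @export
mbpip_fit <- function(specs, dataset, weights = NULL, one_body = FALSE,
                      svd_tol = NULL) {
  if (inherits(specs, "interaction_spec")) specs <- list(specs)
  if (!length(dataset)) stop("dataset is empty", call. = FALSE)
  energies <- dataset_energies(dataset)
  if (anyNA(energies) || any(!is.finite(energies))) {
    stop("missing or non-finite training energy label(s)", call. = FALSE)
  }
  .warn_short_distances(dataset)

  shift <- if (one_body) 0 else min(energies)
  y <- energies - shift
  X <- mbpip_design(specs, dataset, one_body = one_body)
  # without one-body columns the basis has no constant term: solve with an
  # explicit intercept and fold it into the stored energy shift
  if (!one_body) X <- cbind(X, "(offset)" = 1)
  if (nrow(X) < ncol(X)) {
    warning("fewer training frames (", nrow(X), ") than coefficients (",
            ncol(X), "); fit is underdetermined", call. = FALSE)
  }
  if (is.null(weights)) weights <- rep(1, nrow(X))
  if (length(weights) != nrow(X) || any(weights < 0)) {
    stop("weights must be non-negative, one per frame", call. = FALSE)
  }
  sw <- sqrt(weights)
  sv <- svd(X * sw)
  if (is.null(svd_tol)) svd_tol <- max(dim(X)) * .Machine$double.eps
  keep <- sv$d > svd_tol * sv$d[1]
  r <- sum(keep)
  if (r < ncol(X)) {
    warning("rank-deficient least-squares system (rank ", r, " of ",
            ncol(X), "); returning the minimum-norm solution",
            call. = FALSE)
  }
  beta <- sv$v[, keep, drop = FALSE] %*%
    (crossprod(sv$u[, keep, drop = FALSE], y * sw) / sv$d[keep])
  beta <- drop(beta)
  condition <- sv$d[1] / sv$d[r]

  fitted_e <- drop(X %*% beta) + shift
  res <- energies - fitted_e
  rmse <- sqrt(mean(res^2))
  natoms <- vapply(dataset$frames, n_atoms, integer(1))
  rmse_per_atom <- if (length(unique(natoms)) == 1) rmse / natoms[1] else NA_real_

  sizes <- vapply(specs, function(s) .spec_basis(s)$n_fun, integer(1))
  ends <- cumsum(sizes)
  coefficients <- lapply(seq_along(specs), function(k) {
    if (sizes[k] == 0) numeric(0)
    else beta[(ends[k] - sizes[k] + 1):ends[k]]
  })
  ob <- NULL
  if (one_body) {
    alphabet <- sort(unique(unlist(strsplit(
      vapply(specs, `[[`, character(1), "composition"), ""))))
    ob <- beta[(sum(sizes) + 1):length(beta)]
    names(ob) <- alphabet
  } else {
    shift <- shift + beta[length(beta)]  # fitted intercept
  }
  model <- mbpip_model(specs, coefficients, one_body = ob,
                       energy_shift = shift,
                       metadata = list(n_train = nrow(X), rmse = rmse,
                                       condition = condition, rank = r))
  out <- list(model = model, rmse = rmse, rmse_per_atom = rmse_per_atom,
              max_abs_residual = max(abs(res)), n_train = nrow(X),
              n_coefficients = ncol(X), condition = condition, rank = r,
              fitted.values = fitted_e, residuals = res,
              energies = energies, energy_shift = shift)
  class(out) <- "mbpip_fit"
  out
}

.warn_short_distances <- function(dataset) {
  rmin <- Inf
  for (f in dataset$frames) {
    d <- stats::dist(f$coords)
    if (length(d)) rmin <- min(rmin, min(d))
  }
  if (is.finite(rmin) && rmin < 0.5) {
    warning(sprintf(paste0("training set contains internuclear distances ",
                           "down to %.3f bohr; the Morse transform is ",
                           "well-defined there but the fit may be poorly ",
                           "constrained"), rmin), call. = FALSE)
  }
  invisible(rmin)
}

#' Optional energy-dependent down-weighting
#'
#' \code{w = e_ref / (E - min(E) + e_ref)}: frames far above the dataset
#' minimum get smaller weight.  Off by default in \code{\link{mbpip_fit}}.
#'
#' @param energies training energies (hartree).
#' @param e_ref softening scale (hartree).
#' @return numeric weight vector.
#' @export
energy_weights <- function(energies, e_ref = 0.02) {
  e_ref / (energies - min(energies) + e_ref)
}

#' Per-atom error
#'
#' Divides a fit error by the atom count, the usual size-intensive way to
#' report precision for a single-species training set.
#'
#' @param rmse error (any unit).
#' @param n_atoms atom count (> 0).
#' @return \code{rmse / n_atoms}.
#' @examples
#' report_per_atom(115, 44)  # ~2.6 (cm-1 per atom)
#' @export
report_per_atom <- function(rmse, n_atoms) {
  if (n_atoms <= 0) stop("n_atoms must be > 0", call. = FALSE)
  rmse / n_atoms
}

#' @export
print.mbpip_fit <- function(x, ...) {
  cat("MB-PIP least-squares fit\n")
  cat(sprintf("  frames: %d   coefficients: %d (rank %d)\n",
              x$n_train, x$n_coefficients, x$rank))
  cat(sprintf("  rmse: %.6g hartree (%.4g cm-1, %.4g kcal/mol)\n",
              x$rmse, convert_unit(x$rmse, "hartree", "cm-1"),
              convert_unit(x$rmse, "hartree", "kcal/mol")))
  if (!is.na(x$rmse_per_atom)) {
    cat(sprintf("  per atom: %.4g cm-1\n",
                convert_unit(x$rmse_per_atom, "hartree", "cm-1")))
  }
  cat(sprintf("  max |residual|: %.6g hartree   condition: %.3g\n",
              x$max_abs_residual, x$condition))
  invisible(x)
}

#' @export
summary.mbpip_fit <- function(object, ...) {
  s <- object[c("rmse", "rmse_per_atom", "max_abs_residual", "n_train",
                "n_coefficients", "rank", "condition", "energy_shift")]
  s$coef_table <- basis_count_table(object$model$specs)
  s$residual_quantiles <- stats::quantile(object$residuals)
  class(s) <- "summary.mbpip_fit"
  s
}

#' @export
print.summary.mbpip_fit <- function(x, ...) {
  cat("MB-PIP fit summary\n")
  print(x$coef_table, row.names = FALSE)
  cat(sprintf("total coefficients: %d (rank %d, condition %.3g)\n",
              x$n_coefficients, x$rank, x$condition))
  cat(sprintf("n_train %d, rmse %.6g hartree, max |res| %.6g hartree\n",
              x$n_train, x$rmse, x$max_abs_residual))
  cat("residual quantiles (hartree):\n")
  print(x$residual_quantiles)
  invisible(x)
}

#' @export
coef.mbpip_fit <- function(object, ...) {
  m <- object$model
  out <- unlist(lapply(seq_along(m$specs), function(k) {
    v <- m$coefficients[[k]]
    names(v) <- sprintf("%s.%03d", m$specs[[k]]$composition, seq_along(v))
    v
  }))
  if (!is.null(m$one_body)) {
    ob <- m$one_body
    names(ob) <- paste0("E1.", names(m$one_body))
    out <- c(out, ob)
  }
  out
}

#' @export
predict.mbpip_fit <- function(object, newdata, unit = "hartree", ...) {
  predict(object$model, newdata, unit = unit, ...)
}

#' @export
fitted.mbpip_fit <- function(object, ...) object$fitted.values

#' @export
residuals.mbpip_fit <- function(object, ...) object$residuals
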