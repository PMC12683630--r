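# Model files: JSON documents with a versioned schema.  Numeric fields are
# written at full precision so read(write(model)) is bit-exact.

.mbpip_schema <- "mbpip-model/1"

.num17 <- function(x) sprintf("%.17g", x)

.spec_to_list <- function(spec) {
  list(composition = spec$composition, symmetry = spec$symmetry,
       max_degree = spec$max_degree, lambda = .num17(spec$lambda),
       cutoff = .num17(spec$cutoff), switch_width = .num17(spec$switch_width),
       include = spec$include)
}

#' Write an MB-PIP model to a JSON file
#'
#' The file holds the element alphabet, every interaction spec, the basis
#' function list (orbit-representative exponent vectors) per spec, the
#' coefficients, one-body offsets, the energy shift and metadata, under a
#' versioned schema key.  Floating-point fields are serialized with 17
#' significant digits, so a read/write round trip reproduces the model
#' bit-exactly.
#'
#' @param model an \code{\link{mbpip_model}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_mbpip <- function(model, path) {
  doc <- list(
    schema = .mbpip_schema,
    element_alphabet = model$alphabet,
    energy_shift = .num17(model$energy_shift),
    one_body = if (!is.null(model$one_body))
      as.list(stats::setNames(.num17(model$one_body), names(model$one_body))),
    specs = lapply(model$specs, .spec_to_list),
    basis_functions = lapply(model$specs, function(s) {
      b <- .spec_basis(s)
      if (b$n_fun == 0) character(0)
      else unname(apply(b$reps, 1, paste, collapse = " "))
    }),
    coefficients = lapply(model$coefficients, .num17),
    metadata = model$metadata
  )
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE,
                           digits = NA, null = "null")
  writeLines(json, path)
  invisible(path)
}

#' Read an MB-PIP model from a JSON file
#'
#' @param path file written by \code{\link{write_mbpip}}.
#' @return an \code{\link{mbpip_model}}.
#' @export
read_mbpip <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(doc$schema, .mbpip_schema)) {
    stop("not an mbpip model file (schema '", doc$schema, "')",
         call. = FALSE)
  }
  specs <- lapply(doc$specs, function(s) {
    interaction_spec(s$composition, max_degree = s$max_degree,
                     lambda = as.numeric(s$lambda),
                     cutoff = as.numeric(s$cutoff),
                     switch_width = as.numeric(s$switch_width),
                     include = s$include)
  })
  coefficients <- lapply(doc$coefficients, function(v)
    as.numeric(unlist(v)))
  ob <- NULL
  if (!is.null(doc$one_body)) {
    ob <- vapply(doc$one_body, function(v) as.numeric(v), numeric(1))
  }
  model <- mbpip_model(specs, coefficients, one_body = ob,
                       energy_shift = as.numeric(doc$energy_shift),
                       metadata = doc$metadata)
  # integrity: stored basis lists must match the regenerated bases
  for (k in seq_along(specs)) {
    b <- .spec_basis(specs[[k]])
    stored <- as.character(unlist(doc$basis_functions[[k]]))
    regen <- if (b$n_fun == 0) character(0)
             else unname(apply(b$reps, 1, paste, collapse = " "))
    if (length(stored) != b$n_fun || !identical(stored, regen)) {
      stop("basis function list in file does not match the regenerated ",
           "basis for spec ", k, call. = FALSE)
    }
  }
  model
}

#' Write a delta-stacked potential to a JSON file
#'
#' @param stack a \code{\link{delta_stack}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_delta_stack <- function(stack, path) {
  tmp_low <- tempfile(); tmp_delta <- tempfile()
  on.exit(unlink(c(tmp_low, tmp_delta)))
  write_mbpip(stack$v_ll, tmp_low)
  write_mbpip(stack$delta, tmp_delta)
  doc <- list(schema = "mbpip-delta-stack/1",
              metadata = stack$metadata,
              v_ll = jsonlite::fromJSON(tmp_low, simplifyVector = FALSE),
              delta = jsonlite::fromJSON(tmp_delta, simplifyVector = FALSE))
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA, null = "null"), path)
  invisible(path)
}

#' Read a delta-stacked potential from a JSON file
#'
#' @param path file written by \code{\link{write_delta_stack}}.
#' @return a \code{\link{delta_stack}}.
#' @export
read_delta_stack <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(doc$schema, "mbpip-delta-stack/1")) {
    stop("not a delta-stack file", call. = FALSE)
  }
  read_part <- function(part) {
    tmp <- tempfile()
    on.exit(unlink(tmp), add = TRUE)
    writeLines(jsonlite::toJSON(part, auto_unbox = TRUE, digits = NA,
                                null = "null"), tmp)
    read_mbpip(tmp)
  }
  delta_stack(read_part(doc$v_ll), read_part(doc$delta),
              metadata = doc$metadata)
}
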