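#' Serialize models and selections to JSON
#'
#' Audit/replay format: dual coefficients, bias, support indices, kernel
#' specification, and (for selections) sigma and the objective terms.
#'
#' @param model an `svr_model`.
#' @param path optional output path; when `NULL` the JSON string is
#'   returned.
#' @return JSON string, or `path` invisibly.
#' @export
svr_model_to_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "svr_model"))
  obj <- list(
    type = "svr_model",
    beta = model$beta, b = model$b,
    support_indices = model$support_indices,
    kernel = unclass(model$kernel),
    C = model$C, epsilon = model$epsilon,
    weights = model$weights,
    support_vectors = model$X[model$support_indices, , drop = FALSE]
  )
  if (is.null(path)) {
    jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
  }
}

#' @rdname svr_model_to_json
#' @param json JSON string or path to a JSON file.
#' @export
svr_model_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  stopifnot(identical(obj$type, "svr_model"))
  if (length(obj$kernel$gamma) == 0) obj$kernel$gamma <- NULL
  sv <- as.matrix(obj$support_vectors)
  X <- matrix(0, length(obj$beta), ncol(sv))
  X[obj$support_indices, ] <- sv
  structure(
    list(beta = as.numeric(obj$beta), b = obj$b,
         support_indices = as.integer(obj$support_indices),
         kernel = structure(obj$kernel, class = "kernel_spec"),
         X = X, C = obj$C, epsilon = obj$epsilon,
         weights = as.numeric(obj$weights),
         iterations = NA_integer_, kkt_gap = NA_real_),
    class = "svr_model"
  )
}

#' @rdname svr_model_to_json
#' @param selection a `neighborhood_selection`.
#' @export
selection_to_json <- function(selection, path = NULL) {
  stopifnot(inherits(selection, "neighborhood_selection"))
  obj <- list(
    type = "neighborhood_selection",
    sigma = selection$sigma, pool = selection$pool,
    kappa_row = selection$kappa_row,
    dispersion_terms = selection$dispersion_terms,
    stats = selection$stats,
    objective_value = selection$objective_value,
    omega = selection$omega
  )
  if (is.null(path)) {
    jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
  }
}
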