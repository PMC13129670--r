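#' Serialize a fitted model to versioned JSON
#'
#' Writes every parameter array at full double precision together with
#' the basis definition and a version tag, so that a reloaded model
#' reproduces posterior memberships on the training cohort to machine
#' precision.
#'
#' @param model an `fcm_model`.
#' @param path output JSON path.
#' @param extra optional named list echoed into the document (e.g. the
#'   fitting configuration and seed).
#' @return invisibly, `path`.
#' @export
write_fcm_model <- function(model, path, extra = NULL) {
  stopifnot(inherits(model, "fcm_model"))
  doc <- list(
    format = "mrdflow-fcm-model",
    version = model$version %||% "1.0",
    basis = list(p = model$basis$p, knots = model$basis$knots,
                 boundary = model$basis$boundary),
    G = model$G, h = model$h, p = model$p,
    lambda0 = model$lambda0,
    Lambda = model$Lambda,
    alpha = model$alpha,
    Gamma = model$Gamma,
    sigma2 = model$sigma2,
    priors = model$priors)
  if (!is.null(extra)) doc$config <- extra
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Read a fitted model from JSON
#'
#' @param path JSON path written by [write_fcm_model()].
#' @return an `fcm_model`.
#' @export
read_fcm_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "mrdflow-fcm-model"))
    stop_mrdflow("not an mrdflow model document: ", path,
                 class = "mrdflow_parse_error")
  basis <- structure(list(p = as.integer(doc$basis$p),
                          knots = as.numeric(doc$basis$knots %||% numeric(0)),
                          boundary = as.numeric(doc$basis$boundary),
                          range = as.numeric(doc$basis$boundary)),
                     class = "spline_basis")
  as_mat <- function(x, nr) matrix(as.numeric(x), nrow = nr)
  p <- as.integer(doc$p); G <- as.integer(doc$G); h <- as.integer(doc$h)
  structure(list(
    basis = basis, G = G, h = h, p = p,
    lambda0 = as.numeric(doc$lambda0),
    Lambda = if (is.matrix(doc$Lambda)) doc$Lambda else as_mat(doc$Lambda, p),
    alpha = if (is.matrix(doc$alpha)) doc$alpha else as_mat(doc$alpha, G),
    Gamma = if (is.matrix(doc$Gamma)) doc$Gamma else as_mat(doc$Gamma, p),
    sigma2 = as.numeric(doc$sigma2),
    priors = as.numeric(doc$priors),
    version = doc$version), class = "fcm_model")
}
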