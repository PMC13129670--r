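#' Natural cubic spline basis over the observed time range
#'
#' Builds a `p`-dimensional function basis used to represent latent MRD
#' curves: an intercept column plus a natural cubic spline with interior
#' knots at quantiles of the pooled observation times. The basis spans
#' constant functions and extrapolates linearly beyond the boundary knots,
#' so reconstructed trajectories stay well behaved just outside the
#' sampled window.
#'
#' @param all_times numeric vector of pooled observation times (months)
#'   across the whole cohort.
#' @param p basis dimension (number of columns), at least 2 and at most
#'   the number of distinct times in `all_times`.
#' @return An object of class `spline_basis` with elements `p`, `knots`
#'   (interior knots), `boundary` (boundary knots), and a `range`.
#' @examples
#' b <- build_basis(c(0, 3, 6, 12, 18, 24, 30, 42), p = 5)
#' S <- evaluate_basis(b, seq(0, 42, by = 6))
#' dim(S)  # 8 x 5
#' @export
build_basis <- function(all_times, p) {
  stopifnot(is.numeric(all_times), length(all_times) > 0, is.finite(all_times))
  tt <- sort(unique(all_times))
  if (p < 2)
    stop_mrdflow("basis dimension p must be >= 2, got ", p,
                 class = "mrdflow_config_error")
  if (p > length(tt))
    stop_mrdflow("basis dimension p = ", p, " exceeds the number of ",
                 "distinct observed times (", length(tt), ")",
                 class = "mrdflow_config_error")
  boundary <- range(tt)
  n_interior <- p - 2L  # intercept + ns(df = p - 1) with df = 1 + n_interior
  knots <- if (n_interior > 0)
    as.numeric(stats::quantile(tt, probs = seq_len(n_interior) / (n_interior + 1),
                               type = 7))
  else numeric(0)
  structure(list(p = as.integer(p), knots = knots, boundary = boundary,
                 range = boundary),
            class = "spline_basis")
}

#' Evaluate a spline basis at query times
#'
#' @param basis a `spline_basis` from [build_basis()].
#' @param times numeric vector of query times (months).
#' @return numeric matrix with `length(times)` rows and `basis$p` columns.
#' @export
evaluate_basis <- function(basis, times) {
  stopifnot(inherits(basis, "spline_basis"))
  if (length(times) == 0) return(matrix(0, 0, basis$p))
  ns_part <- splines::ns(times, knots = basis$knots,
                         Boundary.knots = basis$boundary, intercept = FALSE)
  S <- cbind(1, unclass(ns_part)[, , drop = FALSE])
  dimnames(S) <- NULL
  storage.mode(S) <- "double"
  S
}

#' @export
print.spline_basis <- function(x, ...) {
  cat("Natural cubic spline basis: p =", x$p,
      "| boundary [", x$boundary[1], ",", x$boundary[2], "]",
      "| interior knots:", if (length(x$knots)) paste(round(x$knots, 2), collapse = ", ") else "none",
      "\n")
  invisible(x)
}
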