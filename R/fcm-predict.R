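#' Posterior cluster membership of a trajectory
#'
#' Evaluates the posterior probability that a trajectory arose from each
#' cluster of a fitted model: the k-th entry is proportional to
#' `prior_k` times the Gaussian density of the observed values under the
#' cluster-k marginal (covariance `S Gamma S' + sigma2 I`). A
#' near-singular marginal is ridge-stabilized with a logged jitter.
#'
#' @param model an `fcm_model`.
#' @param trajectory an `mrd_trajectory`.
#' @return numeric probability vector of length `model$G`, summing to 1.
#' @export
posterior_membership <- function(model, trajectory) {
  stopifnot(inherits(model, "fcm_model"), inherits(trajectory, "mrd_trajectory"))
  S <- evaluate_basis(model$basis, trajectory$times)
  y <- trajectory$values
  Sig <- S %*% model$Gamma %*% t(S) + diag(model$sigma2, length(y))
  mu <- cluster_means(model)
  ld <- vapply(seq_len(model$G), function(k)
    dmvnorm_log(y, as.numeric(S %*% mu[, k]), Sig), 0) + log(model$priors)
  w <- exp(ld - max(ld))
  out <- w / sum(w)
  names(out) <- cluster_labels(model$G)
  out
}

#' Reconstruct a continuous trajectory from sparse measurements
#'
#' Membership-weighted best linear unbiased prediction: within each
#' cluster the posterior mean of the subject's spline coefficients
#' (`lambda0 + Lambda alpha_k + gamma_i` given the data) is pushed through
#' the basis at the query times, and the cluster curves are averaged with
#' the posterior membership weights.
#'
#' @param model an `fcm_model`.
#' @param trajectory an `mrd_trajectory`.
#' @param query_times numeric months at which to evaluate the curve.
#' @param weights optional membership weights; default
#'   [posterior_membership()].
#' @return numeric vector of predicted log10 MRD values, one per query time.
#' @export
predict_curve <- function(model, trajectory, query_times,
                          weights = posterior_membership(model, trajectory)) {
  stopifnot(inherits(model, "fcm_model"))
  if (length(query_times) == 0) return(numeric(0))
  S <- evaluate_basis(model$basis, trajectory$times)
  y <- trajectory$values
  Sig <- S %*% model$Gamma %*% t(S) + diag(model$sigma2, length(y))
  ch <- tryCatch(chol(Sig), error = function(e)
    chol(Sig + diag(1e-8 * mean(diag(Sig)), nrow(Sig))))
  GS <- model$Gamma %*% t(S)
  mu <- cluster_means(model)
  Sq <- evaluate_basis(model$basis, query_times)
  pred <- numeric(length(query_times))
  for (k in seq_len(model$G)) {
    res <- y - as.numeric(S %*% mu[, k])
    gam_hat <- as.numeric(GS %*% backsolve(ch, backsolve(ch, res, transpose = TRUE)))
    pred <- pred + weights[k] * as.numeric(Sq %*% (mu[, k] + gam_hat))
  }
  pred
}

#' Discriminant time-importance functions
#'
#' For a model with `G >= 2` clusters, returns `min(h, G - 1)` curves over
#' `time_grid` showing where along the time axis measurements carry the
#' most information for cluster assignment: the basis evaluated on the
#' grid, whitened by the marginal covariance on that grid, applied to the
#' columns of `Lambda` (the cluster-mean directions). Peaks in the
#' magnitude of a discriminant curve mark the sampling windows that drive
#' the stratification.
#'
#' @param model an `fcm_model`.
#' @param time_grid numeric months.
#' @return matrix `length(time_grid)` x `min(h, G - 1)` of discriminant
#'   values (empty when `G = 1`), with `attr(, "times") = time_grid`.
#' @export
discriminant_functions <- function(model, time_grid) {
  stopifnot(inherits(model, "fcm_model"))
  ncurves <- min(model$h, model$G - 1L)
  if (ncurves <= 0) {
    out <- matrix(0, length(time_grid), 0)
    attr(out, "times") <- time_grid
    return(out)
  }
  S <- evaluate_basis(model$basis, time_grid)
  Sig <- S %*% model$Gamma %*% t(S) + diag(model$sigma2, nrow(S))
  D <- solve(Sig, S %*% model$Lambda[, seq_len(ncurves), drop = FALSE])
  dimnames(D) <- list(NULL, paste0("discriminant_", seq_len(ncurves)))
  attr(D, "times") <- time_grid
  D
}
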