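## Functional clustering of sparse longitudinal trajectories.
##
## Model: for subject i with observations y_i at times t_i and basis
## matrix S_i, and latent cluster z_i = k,
##     y_i = S_i (lambda0 + Lambda alpha_k + gamma_i) + eps_i,
##     gamma_i ~ N_p(0, Gamma),  eps_i ~ N(0, sigma2 I),  P(z_i=k) = pi_k.
## Marginally within cluster k: y_i ~ N(S_i mu_k, Sigma_i) with
## mu_k = lambda0 + Lambda alpha_k and Sigma_i = S_i Gamma S_i' + sigma2 I.
## Estimation is a generalized EM: one half-step treats only z as missing
## and updates priors and the mean structure (lambda0, Lambda, alpha) by
## conditional GLS maximization of the observed likelihood; the second
## half-step treats (z, gamma) as missing and updates Gamma and sigma2 in
## closed form. Both half-steps increase the observed log-likelihood.

## Per-subject design: list of y, S for a cohort under a basis.
cohort_design <- function(cohort, basis) {
  lapply(cohort$trajectories, function(tr)
    list(y = tr$values, S = evaluate_basis(basis, tr$times),
         id = tr$patient_id, times = tr$times))
}

## Per-subject log density under each cluster: n x G matrix.
## Cholesky factors of the per-subject marginal covariances
## S_i Gamma S_i' + sigma2 I; shared by every sub-step that holds
## (Gamma, sigma2) fixed.
iter_chols <- function(design, Gamma, sigma2) {
  lapply(design, function(d) {
    ni <- length(d$y)
    Sig <- d$S %*% Gamma %*% t(d$S) + diag(sigma2, ni)
    tryCatch(chol(Sig), error = function(e) {
      jit <- 1e-8 * mean(diag(Sig))
      warning("singular marginal covariance; ridge-stabilized with jitter ",
              format(jit), call. = FALSE)
      chol(Sig + diag(jit, ni))
    })
  })
}

cluster_logdens <- function(design, mu, Gamma, sigma2, chols = NULL) {
  G <- ncol(mu)
  if (is.null(chols)) chols <- iter_chols(design, Gamma, sigma2)
  ld <- vapply(seq_along(design), function(i) {
    d <- design[[i]]; ch <- chols[[i]]
    RES <- d$y - d$S %*% mu                       # ni x G residuals
    z <- backsolve(ch, RES, transpose = TRUE)
    -0.5 * length(d$y) * log(2 * pi) - sum(log(diag(ch))) - 0.5 * colSums(z^2)
  }, numeric(G))
  if (is.matrix(ld)) t(ld) else matrix(ld, ncol = 1)
}

fcm_loglik <- function(design, priors, mu, Gamma, sigma2, chols = NULL) {
  ld <- cluster_logdens(design, mu, Gamma, sigma2, chols)
  sum(logsumexp(sweep(ld, 2, log(priors), `+`)))
}

## Responsibilities (E-step over z).
fcm_resp <- function(design, priors, mu, Gamma, sigma2, chols = NULL) {
  ld <- sweep(cluster_logdens(design, mu, Gamma, sigma2, chols), 2,
              log(priors), `+`)
  r <- exp(ld - logsumexp(ld))
  r / rowSums(r)
}

## Conditional GLS updates of the mean structure (lambda0, Lambda, alpha)
## given responsibilities and fixed Sigma_i. Each block update maximizes
## the responsibility-weighted observed log-likelihood in that block.
update_mean_structure <- function(design, r, lambda0, Lambda, alpha,
                                  Gamma, sigma2, chols = NULL, cycles = 1L) {
  G <- nrow(alpha); h <- ncol(alpha); p <- length(lambda0)
  if (is.null(chols)) chols <- iter_chols(design, Gamma, sigma2)
  ## Stack A_i = S' Sigma^-1 S (vectorized) and b_i = S' Sigma^-1 y.
  n <- length(design)
  Amat <- matrix(0, p * p, n); Bmat <- matrix(0, p, n)
  for (i in seq_len(n)) {
    d <- design[[i]]; ch <- chols[[i]]
    Wi_S <- backsolve(ch, backsolve(ch, d$S, transpose = TRUE))
    Amat[, i] <- crossprod(d$S, Wi_S)
    Bmat[, i] <- crossprod(Wi_S, d$y)
  }
  Abar <- lapply(seq_len(G), function(k) matrix(Amat %*% r[, k], p, p))
  bbar <- lapply(seq_len(G), function(k) Bmat %*% r[, k])
  for (cy in seq_len(cycles)) {
    for (k in seq_len(G)) {  # alpha_k | lambda0, Lambda
      M <- crossprod(Lambda, Abar[[k]] %*% Lambda)
      alpha[k, ] <- solve(M + diag(1e-10, h),
                          crossprod(Lambda, bbar[[k]] - Abar[[k]] %*% lambda0))
    }
    ## Lambda | lambda0, alpha (vectorized GLS on vec(Lambda))
    K <- matrix(0, p * h, p * h); rhs <- numeric(p * h)
    for (k in seq_len(G)) {
      K <- K + kronecker(tcrossprod(alpha[k, ]), Abar[[k]])
      rhs <- rhs + as.numeric((bbar[[k]] - Abar[[k]] %*% lambda0) %*%
                                alpha[k, , drop = FALSE])
    }
    Lambda <- matrix(solve(K + diag(1e-10, p * h), rhs), p, h)
    ## lambda0 | Lambda, alpha
    Atot <- Reduce(`+`, Abar)
    rtot <- Reduce(`+`, Map(function(k) bbar[[k]] - Abar[[k]] %*% Lambda %*% alpha[k, ],
                            seq_len(G)))
    lambda0 <- as.numeric(solve(Atot + diag(1e-10, p), rtot))
  }
  list(lambda0 = lambda0, Lambda = Lambda, alpha = alpha)
}

## Reparameterize to the identified form: alpha centered under the priors,
## Lambda with orthonormal columns. Leaves every cluster mean unchanged.
identify_params <- function(lambda0, Lambda, alpha, priors) {
  abar <- as.numeric(priors %*% alpha)
  lambda0 <- lambda0 + as.numeric(Lambda %*% abar)
  alpha <- sweep(alpha, 2, abar)
  sv <- svd(Lambda)
  d <- pmax(sv$d, 1e-12)
  Lambda <- sv$u
  alpha <- alpha %*% sv$v %*% diag(d, length(d))
  list(lambda0 = lambda0, Lambda = Lambda, alpha = alpha)
}

## Closed-form (Gamma, sigma2) M-step given fresh responsibilities.
update_variance <- function(design, r, mu, Gamma, sigma2, chols = NULL) {
  p <- nrow(Gamma); n <- length(design); G <- ncol(mu)
  if (is.null(chols)) chols <- iter_chols(design, Gamma, sigma2)
  Gamma_acc <- matrix(0, p, p); rss <- 0; N <- 0
  for (i in seq_len(n)) {
    d <- design[[i]]
    ni <- length(d$y); N <- N + ni
    ch <- chols[[i]]
    GS <- Gamma %*% t(d$S)                       # p x ni
    W_GS <- backsolve(ch, backsolve(ch, t(GS), transpose = TRUE))  # Sig^-1 S Gamma'
    Vi <- Gamma - GS %*% W_GS                    # conditional cov of gamma
    Gamma_acc <- Gamma_acc + Vi
    SVS <- sum(diag(d$S %*% Vi %*% t(d$S)))
    RES <- d$y - d$S %*% mu                      # ni x G
    GH <- GS %*% backsolve(ch, backsolve(ch, RES, transpose = TRUE))  # p x G
    Gamma_acc <- Gamma_acc + GH %*% (r[i, ] * t(GH))
    E <- RES - d$S %*% GH
    rss <- rss + sum(r[i, ] * colSums(E^2)) + SVS
  }
  list(Gamma = psd_clip(Gamma_acc / n), sigma2 = max(rss / N, 1e-8))
}

## Ridge-projected per-subject spline coefficients, used for initialization.
ridge_coefs <- function(design, p, ridge = 1e-2) {
  t(vapply(design, function(d)
    as.numeric(solve(crossprod(d$S) + diag(ridge, p), crossprod(d$S, d$y))),
    numeric(p)))
}

init_params <- function(design, p, G, h, hard) {
  n <- length(design)
  B <- ridge_coefs(design, p)
  mu <- vapply(seq_len(G), function(k) {
    idx <- which(hard == k)
    if (length(idx)) colMeans(B[idx, , drop = FALSE]) else B[sample.int(n, 1), ]
  }, numeric(p))
  priors <- pmax(tabulate(hard, G) / n, 1 / (2 * G * n))
  priors <- priors / sum(priors)
  lambda0 <- as.numeric(mu %*% priors)
  C <- sweep(mu, 1, lambda0)                    # p x G centered means
  sv <- svd(C)
  Lambda <- sv$u[, seq_len(h), drop = FALSE]
  alpha <- t(diag(sv$d[seq_len(h)], h) %*% t(sv$v[, seq_len(h), drop = FALSE]))
  s2 <- mean(vapply(seq_len(n), function(i) {
    d <- design[[i]]
    mean((d$y - as.numeric(d$S %*% mu[, hard[i]]))^2)
  }, 0))
  s2 <- max(s2, 1e-4)
  srow <- mean(vapply(design, function(d) mean(rowSums(d$S^2)), 0))
  list(lambda0 = lambda0, Lambda = Lambda, alpha = alpha,
       Gamma = diag(s2 / (2 * srow), p), sigma2 = s2 / 2, priors = priors)
}

#' Fit the functional clustering model by EM
#'
#' Fits a Gaussian mixed-effects mixture over spline-represented latent
#' curves to a cohort of sparse MRD trajectories. Cluster memberships are
#' treated as missing data and estimated by a generalized EM whose
#' observed-data log-likelihood is non-decreasing across iterations. The
#' fit is repeated from `n_starts` initializations (k-means on per-subject
#' ridge-projected spline coefficients, then random reassignments) and the
#' best final log-likelihood wins; everything is reproducible given
#' `seed`.
#'
#' @param cohort a filtered `mrd_cohort` (every trajectory needs at least
#'   2 points).
#' @param G number of clusters.
#' @param p spline-basis dimension (see [build_basis()]).
#' @param h dimension of the cluster-mean space, `1 <= h <= max(G - 1, 1)`;
#'   default `G - 1`.
#' @param n_starts number of EM initializations.
#' @param seed integer governing all randomness of the fit.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations per start.
#' @param basis optionally, a prebuilt `spline_basis` to use instead of
#'   quantile knots on this cohort's pooled times.
#' Clusters are relabeled `A`, `B`, ... in increasing order of
#' time-averaged mean-curve MRD burden, so `A` is always the
#' lowest-burden kinetic and the favorable/unfavorable merge of
#' [default_group_merge()] is phenotypically meaningful.
#'
#' @return An object of class `fcm_fit`: `model` (class `fcm_model` with
#'   `basis`, `G`, `h`, `lambda0`, `Lambda`, `alpha`, `Gamma`, `sigma2`,
#'   `priors`), `memberships` (n x G posterior probabilities),
#'   `assignments` (argmax labels, ties to the lowest index),
#'   `loglik_trace`, `converged`, and `patient_id`/`tissue` bookkeeping.
#' @examples
#' \donttest{
#' sim <- generate_cohort(default_archetypes(), simulation_config(n_subjects = 60, seed = 1))
#' fit <- fit_fcm(sim$cohort, G = 4, p = 5, n_starts = 3, seed = 1)
#' table(fit$assignments)
#' }
#' @export
fit_fcm <- function(cohort, G, p, h = max(G - 1L, 1L), n_starts = 10,
                    seed = 1, tol = 1e-6, max_iter = 500, basis = NULL) {
  stopifnot(inherits(cohort, "mrd_cohort"), G >= 1, p >= 2)
  if (G == 1) h <- 1L
  if (h < 1 || h > max(G - 1, 1))
    stop_mrdflow("h must satisfy 1 <= h <= G - 1 (h = 1 when G = 1)",
                 class = "mrdflow_config_error")
  npts <- vapply(cohort$trajectories, function(tr) length(tr$times), 0L)
  if (any(npts < 2))
    stop_mrdflow("every trajectory must have at least 2 points; filter first",
                 class = "mrdflow_config_error")
  n <- length(cohort$trajectories)
  all_times <- unlist(lapply(cohort$trajectories, `[[`, "times"))
  if (is.null(basis)) basis <- build_basis(all_times, p)
  design <- cohort_design(cohort, basis)
  if (!is.null(seed)) set.seed(seed)

  B <- ridge_coefs(design, p)
  best <- NULL
  for (s in seq_len(n_starts)) {
    hard <- if (s == 1 && G > 1) {
      stats::kmeans(B, centers = G, nstart = 5)$cluster
    } else if (G == 1) rep(1L, n) else sample.int(G, n, replace = TRUE)
    if (length(unique(hard)) < G) hard[sample.int(n, G)] <- seq_len(G)
    fit <- tryCatch(
      em_run(design, p, G, h, hard, tol, max_iter, n),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (is.null(best))
    stop_mrdflow("all EM starts failed", class = "mrdflow_fit_error")
  if (best$degenerate)
    warning("best fit has a degenerate cluster (prior < 1/(10 n))",
            call. = FALSE)

  ## canonical labels: clusters ordered by time-averaged mean MRD burden,
  ## so A is always the lowest-burden (most favorable) kinetic and the
  ## A/B vs C/D merge is phenotypically meaningful
  if (G > 1) {
    grid <- seq(basis$range[1], basis$range[2], length.out = 101)
    mu_grid <- evaluate_basis(basis, grid) %*%
      (best$lambda0 + best$Lambda %*% t(best$alpha))
    ord <- order(colMeans(mu_grid))
    best$alpha <- best$alpha[ord, , drop = FALSE]
    best$priors <- best$priors[ord]
  }

  model <- structure(
    list(basis = basis, G = as.integer(G), h = as.integer(h), p = as.integer(p),
         lambda0 = best$lambda0, Lambda = best$Lambda, alpha = best$alpha,
         Gamma = best$Gamma, sigma2 = best$sigma2, priors = best$priors,
         version = "1.0"),
    class = "fcm_model")
  memberships <- fcm_resp(design, best$priors, cluster_means(model),
                          best$Gamma, best$sigma2)
  colnames(memberships) <- cluster_labels(G)
  structure(
    list(model = model, memberships = memberships,
         assignments = cluster_labels(G)[apply(memberships, 1, which.max)],
         loglik_trace = best$trace, loglik = best$loglik,
         converged = best$converged,
         patient_id = vapply(cohort$trajectories, `[[`, "", "patient_id"),
         tissue = vapply(cohort$trajectories, `[[`, "", "tissue"),
         n = n),
    class = "fcm_fit")
}

cluster_labels <- function(G) LETTERS[seq_len(G)]

#' Cluster mean coefficients of a fitted model
#' @param model an `fcm_model`.
#' @return p x G matrix, column k = lambda0 + Lambda alpha_k.
#' @export
cluster_means <- function(model) {
  mu <- model$lambda0 + model$Lambda %*% t(model$alpha)
  matrix(mu, nrow = length(model$lambda0))
}

em_run <- function(design, p, G, h, hard, tol, max_iter, n) {
  par <- init_params(design, p, G, h, hard)
  mu <- par$lambda0 + par$Lambda %*% t(par$alpha)
  ll <- fcm_loglik(design, par$priors, mu, par$Gamma, par$sigma2)
  trace <- ll
  converged <- FALSE
  chols <- NULL
  for (it in seq_len(max_iter)) {
    ## (Gamma, sigma2) are fixed across both half-steps, so the subject
    ## covariance factorizations are computed once per iteration (and
    ## carried over from the likelihood evaluation of the previous one)
    if (is.null(chols)) chols <- iter_chols(design, par$Gamma, par$sigma2)
    ## half-step 1: z missing; priors + mean structure
    r <- fcm_resp(design, par$priors, mu, par$Gamma, par$sigma2, chols)
    par$priors <- pmax(colMeans(r), 1e-12); par$priors <- par$priors / sum(par$priors)
    ms <- update_mean_structure(design, r, par$lambda0, par$Lambda, par$alpha,
                                par$Gamma, par$sigma2, chols)
    idp <- identify_params(ms$lambda0, ms$Lambda, ms$alpha, par$priors)
    par$lambda0 <- idp$lambda0; par$Lambda <- idp$Lambda; par$alpha <- idp$alpha
    mu <- par$lambda0 + par$Lambda %*% t(par$alpha)
    ## half-step 2: (z, gamma) missing; Gamma + sigma2
    r <- fcm_resp(design, par$priors, mu, par$Gamma, par$sigma2, chols)
    vs <- update_variance(design, r, mu, par$Gamma, par$sigma2, chols)
    par$Gamma <- vs$Gamma; par$sigma2 <- vs$sigma2
    chols <- iter_chols(design, par$Gamma, par$sigma2)
    ll_new <- fcm_loglik(design, par$priors, mu, par$Gamma, par$sigma2, chols)
    trace <- c(trace, ll_new)
    if (abs(ll_new - ll) < tol * (abs(ll) + 1)) { converged <- TRUE; ll <- ll_new; break }
    ll <- ll_new
  }
  ## final polish: mean structure re-solved by GLS under the converged
  ## covariance, so the returned means satisfy the GLS normal equations
  ## for the returned (Gamma, sigma2) exactly
  if (is.null(chols)) chols <- iter_chols(design, par$Gamma, par$sigma2)
  r <- fcm_resp(design, par$priors, mu, par$Gamma, par$sigma2, chols)
  ms <- update_mean_structure(design, r, par$lambda0, par$Lambda, par$alpha,
                              par$Gamma, par$sigma2, chols)
  idp <- identify_params(ms$lambda0, ms$Lambda, ms$alpha, par$priors)
  par$lambda0 <- idp$lambda0; par$Lambda <- idp$Lambda; par$alpha <- idp$alpha
  mu <- par$lambda0 + par$Lambda %*% t(par$alpha)
  ll <- fcm_loglik(design, par$priors, mu, par$Gamma, par$sigma2, chols)
  trace <- c(trace, ll)
  list(lambda0 = par$lambda0, Lambda = par$Lambda, alpha = par$alpha,
       Gamma = par$Gamma, sigma2 = par$sigma2, priors = par$priors,
       loglik = ll, trace = trace, converged = converged,
       degenerate = any(par$priors < 1 / (10 * n)))
}

#' @export
print.fcm_fit <- function(x, ...) {
  cat("Functional clustering fit: G =", x$model$G, "| p =", x$model$p,
      "| h =", x$model$h, "\n")
  cat("log-likelihood:", format(x$loglik), "| converged:", x$converged,
      "(", length(x$loglik_trace), "iterations )\n")
  print(table(assignment = x$assignments))
  invisible(x)
}
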