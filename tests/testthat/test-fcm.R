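two_archetypes <- function(gap_at = NULL, lo = -6.5, hi = -2.5) {
  ## two kinetic profiles; with gap_at set, they differ only there
  tt <- c(0, 3, 6, 12, 18, 24, 30, 36, 42)
  a <- default_archetypes(gamma_scale = 0.15, sigma = 0.3)[1:2]
  if (!is.null(gap_at)) {
    flat <- rep(-5, length(tt))
    a[[1]]$control_times <- tt; a[[1]]$control_values <- flat
    a[[2]]$control_times <- tt
    a[[2]]$control_values <- ifelse(tt %in% gap_at, -3, -5)
  } else {
    a[[1]]$control_values <- rep(lo, length(a[[1]]$control_times))
    a[[2]]$control_values <- rep(hi, length(a[[2]]$control_times))
  }
  a[[1]]$proportion <- 0.5; a[[2]]$proportion <- 0.5
  ## keep everything quantifiable so censoring does not blur the gap
  a
}

test_that("EM log-likelihood is non-decreasing and multi-start is seeded", {
  sim <- simulate_mrd_study(config = simulation_config(n_subjects = 40, seed = 11))
  co <- filter_cohort(sim$cohort, 3)
  f1 <- fit_fcm(co, G = 3, p = 4, n_starts = 2, seed = 5, max_iter = 120)
  expect_true(all(diff(f1$loglik_trace) >= -1e-8))
  f2 <- fit_fcm(co, G = 3, p = 4, n_starts = 2, seed = 5, max_iter = 120)
  expect_identical(f1$memberships, f2$memberships)
  expect_identical(f1$loglik, f2$loglik)
  ## membership rows are probabilities; assignments are the argmax
  expect_equal(rowSums(f1$memberships), rep(1, f1$n))
  expect_identical(f1$assignments,
                   colnames(f1$memberships)[apply(f1$memberships, 1, which.max)])
})

test_that("G=1 fit solves the pooled mixed-model GLS problem", {
  sim <- simulate_mrd_study(config = simulation_config(n_subjects = 20, seed = 5))
  co <- filter_cohort(sim$cohort, 2)
  fit <- fit_fcm(co, G = 1, p = 4, n_starts = 1, seed = 1)
  m <- fit$model
  A <- matrix(0, 4, 4); b <- numeric(4)
  for (tr in co$trajectories) {
    S <- evaluate_basis(m$basis, tr$times)
    W <- solve(S %*% m$Gamma %*% t(S) + diag(m$sigma2, length(tr$values)))
    A <- A + t(S) %*% W %*% S
    b <- b + t(S) %*% W %*% tr$values
  }
  expect_lt(max(abs(cluster_means(m)[, 1] - solve(A, b))), 1e-6)
})

test_that("well-separated archetypes are recovered exactly (ARI = 1)", {
  skip_if_not_installed("mclust")
  cfg <- simulation_config(n_subjects = 50, seed = 21)
  gen <- generate_cohort(two_archetypes(), cfg)
  co <- filter_cohort(gen$cohort, 3)
  fit <- fit_fcm(co, G = 2, p = 4, n_starts = 3, seed = 2, max_iter = 150)
  truth <- gen$truth$archetype[match(fit$patient_id, gen$truth$patient_id)]
  expect_equal(mclust::adjustedRandIndex(fit$assignments, truth), 1.0)
})

test_that("posterior membership matches the closed-form Bayes oracle", {
  basis <- build_basis(c(0, 10, 21, 30, 42), p = 2)
  lambda0 <- c(-5, 0.4)
  Lambda <- matrix(c(1, 0.3), 2, 1); Lambda <- Lambda / sqrt(sum(Lambda^2))
  alpha <- matrix(c(-1.2, 1.2), 2, 1)
  Gamma <- diag(c(0.2, 0.05))
  model <- manual_model(basis, lambda0, Lambda, alpha, Gamma,
                        sigma2 = 0.09, priors = c(0.3, 0.7))
  tr <- mrd_trajectory("X", "BM", 21, -4.2)
  S <- evaluate_basis(basis, 21)
  v <- as.numeric(S %*% Gamma %*% t(S)) + 0.09     # scalar marginal variance
  mu <- as.numeric(S %*% cluster_means(model))
  lik <- dnorm(-4.2, mu, sqrt(v)) * c(0.3, 0.7)
  oracle <- lik / sum(lik)
  got <- posterior_membership(model, tr)
  expect_lt(max(abs(unname(got) - oracle)), 1e-10)
  expect_equal(sum(got), 1, tolerance = 1e-12)
  ## a noiseless draw from a cluster mean is assigned to that cluster
  grid <- c(0, 6, 12, 24, 36)
  y2 <- as.numeric(evaluate_basis(basis, grid) %*% cluster_means(model)[, 2])
  tr2 <- mrd_trajectory("Y", "BM", grid, y2)
  expect_equal(unname(which.max(posterior_membership(model, tr2))), 2L)
})

test_that("curve reconstruction obeys its degenerate limits", {
  basis <- build_basis(c(0, 6, 12, 24, 42), p = 3)
  ## G=1 with Gamma = 0: prediction is the fixed spline curve (here, the
  ## pooled OLS fit, which is GLS under iid noise)
  set.seed(4)
  tt <- seq(0, 42, by = 3)
  y <- -4 - 0.05 * tt + rnorm(length(tt), 0, 0.2)
  beta <- qr.solve(evaluate_basis(basis, tt), y)
  m0 <- manual_model(basis, beta, matrix(0, 3, 1), matrix(0, 1, 1),
                     Gamma = matrix(0, 3, 3), sigma2 = 0.04, priors = 1)
  tr <- mrd_trajectory("Z", "BM", c(0, 12, 30), c(-4, -5, -6))
  q <- c(0, 10, 20, 40)
  expect_equal(predict_curve(m0, tr, q),
               as.numeric(evaluate_basis(basis, q) %*% beta), tolerance = 1e-9)
  ## sigma2 -> 0 with a flexible random effect: interpolates the data
  m1 <- manual_model(basis, beta, matrix(0, 3, 1), matrix(0, 1, 1),
                     Gamma = diag(5, 3), sigma2 = 1e-10, priors = 1)
  obs <- mrd_trajectory("Z", "BM", c(0, 12, 30), c(-4, -5, -6))
  expect_equal(predict_curve(m1, obs, c(0, 12, 30)), c(-4, -5, -6),
               tolerance = 1e-4)
  ## degenerate weights use only that cluster's conditional mean
  model <- manual_model(basis, beta, matrix(c(1, 0, 0), 3, 1),
                        matrix(c(-1, 1), 2, 1), diag(0.1, 3), 0.05,
                        c(0.5, 0.5))
  w1 <- predict_curve(model, obs, q, weights = c(1, 0))
  w2 <- predict_curve(model, obs, q, weights = c(0, 1))
  expect_false(isTRUE(all.equal(w1, w2)))
  expect_equal(predict_curve(model, obs, numeric(0)), numeric(0))
})

test_that("fDB index matches a brute-force evaluation and its limits", {
  sim <- simulate_mrd_study(config = simulation_config(n_subjects = 45, seed = 31))
  co <- filter_cohort(sim$cohort, 3)
  fit <- fit_fcm(co, G = 3, p = 4, n_starts = 2, seed = 3, max_iter = 100)
  got <- fdb_index(fit, co)
  ## independent evaluation of the definition
  m <- fit$model
  grid <- seq(m$basis$range[1], m$basis$range[2], length.out = 200)
  dt <- diff(grid[1:2])
  l2 <- function(a, b) sqrt(sum((a - b)^2) * dt)
  mu <- evaluate_basis(m$basis, grid) %*% cluster_means(m)
  curves <- sapply(seq_along(co$trajectories), function(i)
    predict_curve(m, co$trajectories[[i]], grid,
                  weights = fit$memberships[i, ]))
  labs <- LETTERS[1:3]
  Sk <- sapply(1:3, function(k) {
    idx <- which(fit$assignments == labs[k])
    if (!length(idx)) 0 else mean(sapply(idx, function(i) l2(curves[, i], mu[, k])))
  })
  acc <- 0
  for (k in 1:3)
    acc <- acc + max(sapply(setdiff(1:3, k), function(j)
      (Sk[k] + Sk[j]) / l2(mu[, k], mu[, j])))
  expect_equal(got, acc / 3, tolerance = 1e-10)
  ## identical cluster means: infinite index with a warning
  basis <- m$basis
  same <- manual_model(basis, cluster_means(m)[, 1], matrix(0, 4, 1),
                       matrix(0, 2, 1), m$Gamma, m$sigma2, c(0.5, 0.5))
  fit_same <- fit
  fit_same$model <- same
  fit_same$memberships <- matrix(0.5, fit$n, 2)
  fit_same$assignments <- rep(c("A", "B"), length.out = fit$n)
  expect_warning(v <- fdb_index(fit_same, co), "infinite")
  expect_identical(v, Inf)
  expect_error(fdb_index(fit_fcm(co, G = 1, p = 4, n_starts = 1, seed = 1), co),
               class = "mrdflow_config_error")
})

test_that("relabeling clusters changes nothing observable", {
  sim <- simulate_mrd_study(config = simulation_config(n_subjects = 40, seed = 13))
  co <- filter_cohort(sim$cohort, 3)
  fit <- fit_fcm(co, G = 3, p = 4, n_starts = 2, seed = 9, max_iter = 100)
  perm <- c(3L, 1L, 2L)
  m2 <- fit$model
  m2$alpha <- fit$model$alpha[perm, , drop = FALSE]
  m2$priors <- fit$model$priors[perm]
  fit2 <- fit
  fit2$model <- m2
  fit2$memberships <- fit$memberships[, perm]
  colnames(fit2$memberships) <- LETTERS[1:3]
  fit2$assignments <- LETTERS[1:3][apply(fit2$memberships, 1, which.max)]
  ## per-subject posteriors permute; entropy and fDB are invariant
  tr <- co$trajectories[[7]]
  expect_equal(unname(posterior_membership(m2, tr)),
               unname(posterior_membership(fit$model, tr)[perm]))
  expect_equal(shannon_entropy(posterior_membership(m2, tr)),
               shannon_entropy(posterior_membership(fit$model, tr)))
  expect_equal(fdb_index(fit2, co), fdb_index(fit, co), tolerance = 1e-10)
})

test_that("discriminant functions localize the informative time window", {
  cfg <- simulation_config(n_subjects = 60, seed = 17)
  gen <- generate_cohort(two_archetypes(gap_at = c(24, 30)), cfg)
  co <- filter_cohort(gen$cohort, 3)
  fit <- fit_fcm(co, G = 2, p = 6, n_starts = 3, seed = 6, max_iter = 150)
  expect_equal(ncol(discriminant_functions(fit$model, 0:42)),
               min(fit$model$h, fit$model$G - 1L))
  D <- discriminant_functions(fit$model, seq(0, 42, length.out = 211))
  peak <- attr(D, "times")[which.max(abs(D[, 1]))]
  expect_gte(peak, 18); expect_lte(peak, 36)
  ## brute-force per-time-point Fisher ratio from the raw data agrees on
  ## where the information lives
  months <- unname(cfg$schedule)
  truth <- gen$truth$archetype
  fisher <- sapply(months, function(mo) {
    va <- unlist(lapply(which(truth == "A"), function(i) {
      tr <- gen$cohort$trajectories[[i]]; tr$values[tr$times == mo]
    }))
    vb <- unlist(lapply(which(truth == "B"), function(i) {
      tr <- gen$cohort$trajectories[[i]]; tr$values[tr$times == mo]
    }))
    (mean(va) - mean(vb))^2 / (var(c(va - mean(va), vb - mean(vb))))
  })
  expect_true(months[which.max(fisher)] %in% c(24, 30))
  ## G=1: nothing to discriminate
  g1 <- fit_fcm(co, G = 1, p = 4, n_starts = 1, seed = 1, max_iter = 50)
  expect_equal(ncol(discriminant_functions(g1$model, 0:42)), 0L)
})

test_that("a serialized model reloads to identical posteriors", {
  sim <- simulate_mrd_study(config = simulation_config(n_subjects = 30, seed = 23))
  co <- filter_cohort(sim$cohort, 3)
  fit <- fit_fcm(co, G = 2, p = 4, n_starts = 2, seed = 4, max_iter = 80)
  path <- tempfile(fileext = ".json")
  write_fcm_model(fit$model, path, extra = list(seed = 4))
  m2 <- read_fcm_model(path)
  memb1 <- t(sapply(co$trajectories, function(tr) posterior_membership(fit$model, tr)))
  memb2 <- t(sapply(co$trajectories, function(tr) posterior_membership(m2, tr)))
  expect_equal(memb1, memb2, tolerance = 1e-12)
  expect_identical(apply(memb1, 1, which.max), apply(memb2, 1, which.max))
  bad <- tempfile(fileext = ".json"); writeLines("{}", bad)
  expect_error(read_fcm_model(bad), class = "mrdflow_parse_error")
})

test_that("model selection finds the generative structure", {
  skip_if_not_installed("mclust")
  ## one archetype: no multi-cluster structure
  one <- two_archetypes()[1]; one[[1]]$proportion <- 1
  gen1 <- generate_cohort(one, simulation_config(n_subjects = 36, seed = 41))
  co1 <- filter_cohort(gen1$cohort, 3)
  sel1 <- select_model(co1, p_grid = 4, G_grid = 1:3, folds = 3,
                       n_starts = 2, seed = 2, max_iter = 80)
  expect_equal(sel1$G, 1L)
  ## two well-separated archetypes
  gen2 <- generate_cohort(two_archetypes(), simulation_config(n_subjects = 40, seed = 43))
  co2 <- filter_cohort(gen2$cohort, 3)
  sel2 <- select_model(co2, p_grid = c(3, 4), G_grid = 1:3, folds = 3,
                       n_starts = 2, seed = 2, max_iter = 80)
  expect_equal(sel2$G, 2L)
  truth <- gen2$truth$archetype[match(sel2$fit$patient_id, gen2$truth$patient_id)]
  expect_gte(mclust::adjustedRandIndex(sel2$fit$assignments, truth), 0.95)
})
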