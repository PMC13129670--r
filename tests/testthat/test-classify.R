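test_that("Shannon entropy has its closed forms in bits", {
  expect_equal(shannon_entropy(rep(0.25, 4)), 2)
  expect_equal(shannon_entropy(c(1, 0, 0, 0)), 0)
  expect_equal(shannon_entropy(c(0.5, 0.5, 0, 0)), 1)
  expect_equal(shannon_entropy(c(0.4, 0.3, 0.2, 0.1)),
               -sum(c(0.4, 0.3, 0.2, 0.1) * log2(c(0.4, 0.3, 0.2, 0.1))))
  expect_error(shannon_entropy(c(0.5, 0.4)), class = "mrdflow_validation_error")
  expect_error(shannon_entropy(c(1.2, -0.2)), class = "mrdflow_validation_error")
})

## a model whose posterior we can steer: 4 clusters, flat curves at
## chosen levels, tiny random effects
steer_model <- function(levels = c(-6.5, -5, -3.5, -2)) {
  basis <- build_basis(c(0, 6, 12, 24, 42), p = 2)
  ## flat curves: coefficient on the intercept column only
  lambda0 <- c(mean(levels), 0)
  Lambda <- matrix(c(1, 0), 2, 1)
  alpha <- matrix(levels - mean(levels), 4, 1)
  manual_model(basis, lambda0, Lambda, alpha, diag(1e-4, 2), 0.25,
               rep(0.25, 4))
}

test_that("the unclassified rule is the conjunction of both gates", {
  ## pure rule arithmetic on membership vectors around the (0.6, 1.0) gates
  rule <- function(p, cutoff = 0.6, entropy_max = 1)
    max(p) < cutoff && shannon_entropy(p) > entropy_max
  expect_false(rule(c(0.9, 0.05, 0.03, 0.02)))       # confident, low entropy
  expect_lt(shannon_entropy(c(0.9, 0.05, 0.03, 0.02)), 1)
  expect_true(rule(c(0.4, 0.3, 0.2, 0.1)))           # both gates open
  expect_equal(shannon_entropy(c(0.4, 0.3, 0.2, 0.1)), 1.84644, tolerance = 1e-4)
  ## max < 0.6 AND entropy just above 1
  expect_true(rule(c(0.58, 0.41, 0.01, 0.00)))
  expect_equal(shannon_entropy(c(0.58, 0.41, 0.01, 0)), 1.04957, tolerance = 1e-4)
  ## entropy <= 1: labeled even though max < 0.6
  expect_false(rule(c(0.58, 0.42, 0, 0)))
  expect_equal(shannon_entropy(c(0.58, 0.42, 0, 0)), 0.98145, tolerance = 1e-4)
  ## confident but diffuse tail: max >= 0.6 blocks unclassification
  expect_false(rule(c(0.62, 0.13, 0.13, 0.12)))
  ## exhaustive unit grid over probability vectors p = (m, r, r, r):
  ## the rule must equal the conjunction everywhere
  for (m in seq(0.25, 0.95, by = 0.05)) {
    p <- c(m, rep((1 - m) / 3, 3))
    expect_identical(rule(p), m < 0.6 && shannon_entropy(p) > 1)
  }
})

test_that("classify applies the gates to model posteriors end to end", {
  model <- steer_model()
  ## a trajectory sitting on cluster 3's flat curve: confident assignment
  tr <- mrd_trajectory("P1", "BM", c(0, 6, 12, 24, 42), rep(-3.5, 5))
  res <- classify(model, tr)
  expect_s3_class(res, "mrd_classification")
  expect_equal(res$label, "C")
  expect_lt(res$entropy_bits, 1)
  expect_equal(sum(res$memberships), 1, tolerance = 1e-12)
  expect_equal(nrow(res$reconstructed), 50)
  ## a single point between all clusters: uncertain
  tr2 <- mrd_trajectory("P2", "BM", 12, -4.25)
  res2 <- classify(model, tr2)
  expect_gt(res2$entropy_bits, 1)
  expect_equal(res2$label, "UNCLASSIFIED")
  ## gate monotonicity: cutoff 0 never unclassifies ...
  expect_false(classify(model, tr2, cutoff = 0)$label == "UNCLASSIFIED")
  ## ... cutoff 1 + entropy_max 0 unclassifies anything non-degenerate
  expect_equal(classify(model, tr2, cutoff = 1, entropy_max = 0)$label,
               "UNCLASSIFIED")
  expect_equal(classify(model, tr, cutoff = 1, entropy_max = 0)$label,
               "UNCLASSIFIED")
  ## disjunction variant for sensitivity analyses
  expect_equal(classify(model, tr2, cutoff = 0, entropy_max = 0,
                        rule = "or")$label, "UNCLASSIFIED")
  ## minimum time-point rule and support errors
  expect_error(classify(model, tr2, min_timepoints = 3),
               class = "mrdflow_config_error")
  far <- mrd_trajectory("P3", "BM", 200, -3)
  expect_error(classify(model, far), class = "mrdflow_support_error")
})

test_that("classifying a training trajectory reproduces its fitted membership", {
  sim <- simulate_mrd_study(config = simulation_config(n_subjects = 30, seed = 3))
  co <- filter_cohort(sim$cohort, 3)
  fit <- fit_fcm(co, G = 2, p = 4, n_starts = 2, seed = 8, max_iter = 80)
  i <- 11
  res <- classify(fit$model, co$trajectories[[i]])
  expect_equal(unname(res$memberships), unname(fit$memberships[i, ]),
               tolerance = 1e-12)
})

test_that("entropy grows as series shorten", {
  sim <- simulate_mrd_study(config = simulation_config(n_subjects = 50, seed = 19))
  co <- filter_cohort(sim$cohort, 3)
  fit <- fit_fcm(co, G = 4, p = 5, n_starts = 3, seed = 12, max_iter = 150)
  res <- classify_cohort(fit$model, co)
  ## subsample every series to 3 points: uncertainty cannot drop on median
  res_short <- lapply(co$trajectories, function(tr) {
    set.seed(sum(utf8ToInt(tr$patient_id)))
    keep <- sort(sample(seq_along(tr$times), 3))
    classify(fit$model, mrd_trajectory(tr$patient_id, tr$tissue,
                                       tr$times[keep], tr$values[keep]))
  })
  ent <- vapply(res, `[[`, 0, "entropy_bits")
  ent_short <- vapply(res_short, `[[`, 0, "entropy_bits")
  expect_gte(median(ent_short), median(ent))
  ## the summary table splits at the requested series length
  tab <- entropy_vs_length_table(c(res, res_short), split = 6)
  expect_named(tab$summary, c("group", "n", "median_entropy"))
  expect_equal(sum(tab$summary$n), length(res) + length(res_short))
  ## degenerate memberships give all-zero entropies
  deg <- list(structure(list(patient_id = "Q", memberships = c(1, 0),
                             entropy_bits = 0, label = "A",
                             reconstructed = NULL, n_timepoints = 1L),
                        class = "mrd_classification"))
  t1 <- entropy_vs_length_table(deg)
  expect_equal(nrow(t1$table), 1L)
  expect_equal(t1$table$entropy, 0)
})

test_that("landmark truncation keeps exactly the pre-landmark points", {
  tr <- mrd_trajectory("P", "BM", c(0, 3, 6, 12, 24), c(-3, -4, -5, -6, -6))
  expect_equal(truncate_trajectory(tr, 6)$times, c(0, 3, 6))  # closed at L
  expect_equal(truncate_trajectory(tr, 5.999)$times, c(0, 3))
  expect_equal(truncate_trajectory(tr, 100)$times, tr$times)  # identity
  ## idempotent and monotone
  t6 <- truncate_trajectory(tr, 6)
  expect_identical(truncate_trajectory(t6, 6), t6)
  expect_true(all(truncate_trajectory(tr, 6)$times %in%
                    truncate_trajectory(tr, 12)$times))
})
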