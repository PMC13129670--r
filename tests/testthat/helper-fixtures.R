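## Shared fixture builders. Everything is generated in code at test time.

## A hand-built fitted-model object (no EM involved), for tests that need
## full control over the parameters.
manual_model <- function(basis, lambda0, Lambda, alpha, Gamma, sigma2,
                         priors) {
  structure(list(basis = basis, G = nrow(alpha), h = ncol(alpha),
                 p = basis$p, lambda0 = lambda0, Lambda = Lambda,
                 alpha = alpha, Gamma = Gamma, sigma2 = sigma2,
                 priors = priors, version = "1.0"),
            class = "fcm_model")
}

## Tiny deterministic cohort: k subjects with given point counts, values
## drawn from a seeded stream.
toy_cohort <- function(lengths, seed = 1, tissue = "BM") {
  set.seed(seed)
  trs <- lapply(seq_along(lengths), function(i) {
    n <- lengths[i]
    mrd_trajectory(sprintf("P%02d", i), tissue,
                   sort(sample(c(0, 3, 6, 12, 18, 24, 30, 36, 42), n)),
                   round(runif(n, -7, -2), 3))
  })
  mrd_cohort(trs)
}

## Survival records data frame shortcut.
surv_df <- function(time, event, group = NULL, id = NULL) {
  n <- length(time)
  data.frame(patient_id = id %||% sprintf("P%02d", seq_len(n)),
             time = time, event = event,
             group = group %||% rep("X", n), stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Brute-force product-limit estimator (independent of the survival
## package): steps at event times only.
brute_km <- function(time, event) {
  tt <- sort(unique(time[event == 1]))
  s <- 1
  out <- data.frame(time = tt, surv = NA_real_)
  for (j in seq_along(tt)) {
    at_risk <- sum(time >= tt[j])
    d <- sum(time == tt[j] & event == 1)
    s <- s * (1 - d / at_risk)
    out$surv[j] <- s
  }
  out
}

## Grid-search maximizer of the Cox partial likelihood (Breslow ties)
## for a binary group indicator.
brute_cox_beta <- function(time, event, x, grid = seq(-5, 5, by = 1e-3)) {
  logpl <- vapply(grid, function(b) {
    s <- 0
    for (j in which(event == 1)) {
      risk <- time >= time[j]
      s <- s + b * x[j] - log(sum(exp(b * x[risk])))
    }
    s
  }, 0)
  grid[which.max(logpl)]
}
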