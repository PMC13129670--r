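#' @keywords internal
"_PACKAGE"

## Numerically safe log-sum-exp over the rows of a matrix of log terms.
logsumexp <- function(x) {
  m <- apply(x, 1L, max)
  m + log(rowSums(exp(x - m)))
}

## Project a symmetric matrix onto the PSD cone by eigenvalue clipping.
psd_clip <- function(A, floor = 0) {
  A <- (A + t(A)) / 2
  e <- eigen(A, symmetric = TRUE)
  vals <- pmax(e$values, floor)
  A <- e$vectors %*% (vals * t(e$vectors))
  (A + t(A)) / 2
}

## Log density of y ~ N(mu, Sigma) with a ridge retry on near-singular Sigma.
dmvnorm_log <- function(y, mu, Sigma) {
  r <- y - mu
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ch)) {
    jit <- 1e-8 * mean(diag(Sigma))
    warning("singular marginal covariance; ridge-stabilized with jitter ",
            format(jit), call. = FALSE)
    ch <- chol(Sigma + diag(jit, nrow(Sigma)))
  }
  z <- backsolve(ch, r, transpose = TRUE)
  -0.5 * length(y) * log(2 * pi) - sum(log(diag(ch))) - 0.5 * sum(z^2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_mrdflow <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "mrdflow_error")))
}
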