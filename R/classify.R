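#' Shannon entropy of a membership distribution, in bits
#'
#' `-sum(p * log2(p))` with the `0 * log 0 = 0` convention. Base 2 is
#' used throughout the package: with four clusters the entropy ranges
#' over [0, 2] bits, which makes the "entropy greater than one"
#' unclassified gate meaningful (one full bit of assignment uncertainty).
#'
#' @param probs nonnegative numeric vector summing to 1 (tolerance 1e-9).
#' @return entropy in bits.
#' @examples
#' shannon_entropy(rep(0.25, 4))  # 2
#' shannon_entropy(c(1, 0, 0, 0)) # 0
#' @export
shannon_entropy <- function(probs) {
  if (!is.numeric(probs) || any(probs < -1e-12) ||
      abs(sum(probs) - 1) > 1e-9)
    stop_mrdflow("probs must be a probability vector summing to 1",
                 class = "mrdflow_validation_error")
  p <- probs[probs > 0]
  -sum(p * log2(p))
}

#' Classify a new trajectory against a frozen fitted model
#'
#' Computes posterior memberships via [posterior_membership()], the
#' Shannon entropy of the membership distribution, and an assignment with
#' an uncertainty gate: a trajectory is UNCLASSIFIED only when both (i)
#' the maximal membership probability falls below `cutoff` and (ii) the
#' entropy exceeds `entropy_max`. Otherwise the label is the argmax
#' cluster (ties to the lowest index). The full continuous curve is
#' reconstructed on `curve_grid` via [predict_curve()].
#'
#' @param model an `fcm_model`.
#' @param trajectory an `mrd_trajectory`.
#' @param cutoff minimum winning probability for confident assignment.
#' @param entropy_max entropy (bits) above which an assignment is
#'   considered uncertain.
#' @param rule `"and"` (default) requires both gate conditions to fail a
#'   subject; `"or"` unclassifies when either holds, for sensitivity
#'   analyses.
#' @param min_timepoints minimum number of measurements required.
#' @param curve_grid months at which to reconstruct the curve.
#' @return An object of class `mrd_classification`: `patient_id`,
#'   `memberships`, `entropy_bits`, `label` (cluster letter or
#'   `"UNCLASSIFIED"`), `reconstructed` (data frame time/value),
#'   `n_timepoints`.
#' @export
classify <- function(model, trajectory, cutoff = 0.6, entropy_max = 1.0,
                     rule = c("and", "or"), min_timepoints = 1,
                     curve_grid = seq(model$basis$range[1],
                                      model$basis$range[2], length.out = 50)) {
  rule <- match.arg(rule)
  stopifnot(inherits(trajectory, "mrd_trajectory"))
  if (length(trajectory$times) < min_timepoints)
    stop_mrdflow("trajectory has ", length(trajectory$times),
                 " time points; minimum is ", min_timepoints,
                 class = "mrdflow_config_error")
  rng <- model$basis$range
  span <- diff(rng)
  if (all(trajectory$times < rng[1] - 0.5 * span |
          trajectory$times > rng[2] + 0.5 * span))
    stop_mrdflow("trajectory lies entirely outside the basis support [",
                 rng[1], ", ", rng[2], "]", class = "mrdflow_support_error")
  memb <- posterior_membership(model, trajectory)
  H <- shannon_entropy(memb)
  low_conf <- max(memb) < cutoff
  high_H <- H > entropy_max
  uncl <- if (rule == "and") low_conf && high_H else low_conf || high_H
  label <- if (uncl) "UNCLASSIFIED" else cluster_labels(model$G)[which.max(memb)]
  rec <- data.frame(time = curve_grid,
                    value = predict_curve(model, trajectory, curve_grid,
                                          weights = memb))
  structure(list(patient_id = trajectory$patient_id, memberships = memb,
                 entropy_bits = H, label = label, reconstructed = rec,
                 n_timepoints = length(trajectory$times)),
            class = "mrd_classification")
}

#' @export
print.mrd_classification <- function(x, ...) {
  cat("Patient", x$patient_id, "->", x$label,
      sprintf("(max p = %.3f, entropy = %.3f bits, %d time points)\n",
              max(x$memberships), x$entropy_bits, x$n_timepoints))
  invisible(x)
}

#' Classify every trajectory of a cohort
#'
#' @param model an `fcm_model`.
#' @param cohort an `mrd_cohort`.
#' @param ... passed to [classify()].
#' @return list of `mrd_classification` objects, one per trajectory.
#' @export
classify_cohort <- function(model, cohort, ...) {
  stopifnot(inherits(cohort, "mrd_cohort"))
  lapply(cohort$trajectories, function(tr) classify(model, tr, ...))
}

#' Tabulate classification results
#'
#' @param results list of `mrd_classification` objects.
#' @return data frame with membership columns `p_A..`, entropy, label and
#'   series length per subject.
#' @export
classification_table <- function(results) {
  stopifnot(length(results) > 0)
  G <- length(results[[1]]$memberships)
  probs <- t(vapply(results, `[[`, numeric(G), "memberships"))
  colnames(probs) <- paste0("p_", cluster_labels(G))
  data.frame(patient_id = vapply(results, `[[`, "", "patient_id"),
             probs,
             entropy = vapply(results, `[[`, 0, "entropy_bits"),
             label = vapply(results, `[[`, "", "label"),
             n_timepoints = vapply(results, `[[`, 0L, "n_timepoints"))
}

#' Entropy versus series length
#'
#' Per-subject entropy against the number of recorded time points, with a
#' summary comparing subjects with short series (fewer than `split` time
#' points) against the rest. Shorter series carry less information, so
#' their cluster assignments tend to be more uncertain.
#'
#' @param results list of `mrd_classification` objects.
#' @param split series-length threshold for the summary (default 6).
#' @return list with `table` (patient_id, n_timepoints, entropy) and
#'   `summary` (median entropy below/at-or-above the split).
#' @export
entropy_vs_length_table <- function(results, split = 6) {
  stopifnot(length(results) > 0)
  tab <- data.frame(
    patient_id = vapply(results, `[[`, "", "patient_id"),
    n_timepoints = vapply(results, `[[`, 0L, "n_timepoints"),
    entropy = vapply(results, `[[`, 0, "entropy_bits"))
  short <- tab$n_timepoints < split
  summ <- data.frame(
    group = c(paste0("n<", split), paste0("n>=", split)),
    n = c(sum(short), sum(!short)),
    median_entropy = c(
      if (any(short)) stats::median(tab$entropy[short]) else NA_real_,
      if (any(!short)) stats::median(tab$entropy[!short]) else NA_real_))
  list(table = tab, summary = summ)
}

#' Truncate a trajectory at a landmark time
#'
#' Keeps exactly the measurements with `time <= landmark` (closed at the
#' landmark). Downstream steps drop the subject if too few points remain.
#'
#' @param trajectory an `mrd_trajectory`.
#' @param landmark months, > 0.
#' @return the truncated `mrd_trajectory`.
#' @export
truncate_trajectory <- function(trajectory, landmark) {
  stopifnot(inherits(trajectory, "mrd_trajectory"), landmark > 0)
  keep <- trajectory$times <= landmark
  structure(list(patient_id = trajectory$patient_id, tissue = trajectory$tissue,
                 times = trajectory$times[keep],
                 values = trajectory$values[keep]),
            class = "mrd_trajectory")
}
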