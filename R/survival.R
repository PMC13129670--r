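## Post-processing survival layer. The estimators themselves come from
## the survival package (product-limit, log-rank, Cox partial
## likelihood); this layer applies the package's conventions: median TTP
## read off where the survival curve falls below 0.5, favorable vs
## unfavorable merged kinetic groups, landmark analysis with strictly
## leak-free classification.

#' Build survival records from clinical data and group labels
#'
#' @param clinical data frame with `patient_id`, `ttp_months`, `event`.
#' @param groups named character vector, patient_id -> group label.
#' @return data frame (patient_id, time, event, group) for patients
#'   present in both inputs.
#' @export
survival_records <- function(clinical, groups) {
  stopifnot(!is.null(names(groups)))
  ids <- intersect(clinical$patient_id, names(groups))
  cl <- clinical[match(ids, clinical$patient_id), , drop = FALSE]
  data.frame(patient_id = ids, time = cl$ttp_months, event = cl$event,
             group = unname(groups[ids]), stringsAsFactors = FALSE)
}

#' Default merge of kinetic clusters into prognostic groups
#'
#' Clusters A and B (rapid and stable negativization) form the favorable
#' group; clusters C and D (persistent, fluctuating, or reappearing MRD)
#' form the unfavorable group.
#'
#' @return named character vector cluster -> group.
#' @export
default_group_merge <- function() {
  c(A = "FAVORABLE", B = "FAVORABLE", C = "UNFAVORABLE", D = "UNFAVORABLE")
}

#' Merge cluster labels into favorable/unfavorable groups
#'
#' @param labels character vector of cluster labels.
#' @param mapping named vector cluster -> group; must cover every label
#'   except `"UNCLASSIFIED"`, which maps to `NA`.
#' @return character vector of group labels.
#' @export
merge_groups <- function(labels, mapping = default_group_merge()) {
  out <- unname(mapping[labels])
  out[labels == "UNCLASSIFIED"] <- NA_character_
  if (any(is.na(out) & labels != "UNCLASSIFIED"))
    stop_mrdflow("merge mapping does not cover label(s): ",
                 paste(setdiff(unique(labels), c(names(mapping), "UNCLASSIFIED")),
                       collapse = ", "),
                 class = "mrdflow_config_error")
  out
}

#' Kaplan-Meier estimate with below-0.5 median
#'
#' Product-limit estimator of the survival function, with the median
#' defined as the first event time at which the estimated survival
#' probability falls strictly below 0.5, and `NOT_REACHED` when the curve
#' never does (e.g. all subjects censored).
#'
#' @param records data frame with `time` and `event` (and optionally
#'   `group`, ignored here).
#' @return list with `curve` (data frame time, n_risk, n_event, surv),
#'   `median` (months or `NA`), `median_reached` (logical).
#' @export
km_estimate <- function(records) {
  stopifnot(nrow(records) > 0)
  sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = records)
  curve <- data.frame(time = sf$time, n_risk = sf$n.risk,
                      n_event = sf$n.event, surv = sf$surv)
  below <- which(curve$surv < 0.5)
  reached <- length(below) > 0
  list(curve = curve,
       median = if (reached) curve$time[below[1]] else NA_real_,
       median_reached = reached)
}

#' Log-rank test across groups
#'
#' @param records data frame with `time`, `event`, `group`.
#' @return list with `statistic` (chi-square), `df`, `p_value`, `n` per
#'   group. Groups with zero subjects are dropped with a warning.
#' @export
logrank_test <- function(records) {
  records <- records[!is.na(records$group), , drop = FALSE]
  tab <- table(records$group)
  if (any(tab == 0)) {
    warning("dropping empty group(s): ",
            paste(names(tab)[tab == 0], collapse = ", "), call. = FALSE)
    records <- droplevels(records)
  }
  if (length(unique(records$group)) < 2)
    stop_mrdflow("log-rank test needs >= 2 non-empty groups",
                 class = "mrdflow_config_error")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = records)
  df <- length(sd$n) - 1
  list(statistic = unname(sd$chisq), df = df,
       p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
       n = as.numeric(sd$n))
}

#' Univariate Cox hazard ratio between two groups
#'
#' Proportional-hazards partial-likelihood estimate of the hazard ratio
#' of the non-reference group relative to `reference`, with a 95% Wald
#' confidence interval on the log scale.
#'
#' @param records data frame with `time`, `event`, `group` (exactly two
#'   distinct non-missing groups).
#' @param reference the reference group label.
#' @return list with `hr`, `ci_lower`, `ci_upper`, `p_value`,
#'   `comparison` ("other vs reference"), and `degenerate` flag set when a
#'   group has no events (the HR estimate diverges).
#' @export
cox_hr <- function(records, reference) {
  records <- records[!is.na(records$group), , drop = FALSE]
  grps <- unique(records$group)
  if (length(grps) != 2 || !reference %in% grps)
    stop_mrdflow("cox_hr needs exactly two groups including the reference",
                 class = "mrdflow_config_error")
  other <- setdiff(grps, reference)
  records$g <- factor(records$group, levels = c(reference, other))
  ev <- tapply(records$event, records$g, sum)
  degenerate <- any(ev == 0)
  if (degenerate)
    warning("group without events: hazard ratio is degenerate", call. = FALSE)
  cf <- if (degenerate)
    suppressWarnings(survival::coxph(survival::Surv(time, event) ~ g,
                                     data = records))
  else survival::coxph(survival::Surv(time, event) ~ g, data = records)
  beta <- unname(stats::coef(cf)); se <- sqrt(unname(stats::vcov(cf)[1, 1]))
  list(hr = exp(beta),
       ci_lower = exp(beta - 1.96 * se), ci_upper = exp(beta + 1.96 * se),
       p_value = unname(summary(cf)$coefficients[1, "Pr(>|z|)"]),
       comparison = paste(other, "vs", reference),
       degenerate = degenerate)
}

#' Landmark analysis of classification-based stratification
#'
#' At each landmark `L`: trajectories are truncated to the measurements
#' taken at or before `L`; subjects whose progression or censoring time is
#' at or before `L` leave the risk set; survivors with at least
#' `min_timepoints` remaining measurements are classified against the
#' frozen model using only pre-landmark data; Kaplan-Meier and log-rank
#' statistics are computed on time measured from the landmark. By
#' construction no measurement after `L` can influence the landmark-`L`
#' classification.
#'
#' @param model a frozen `fcm_model`.
#' @param cohort an `mrd_cohort` with clinical records.
#' @param landmarks increasing vector of months.
#' @param min_timepoints minimum pre-landmark measurements to classify.
#' @param merge optional cluster -> group mapping applied before the
#'   survival comparison (default favorable/unfavorable); `NULL` keeps
#'   cluster labels.
#' @param ... passed to [classify()] (cutoff, entropy_max, ...).
#' @return list keyed by landmark; each element has `landmark`,
#'   `n_at_risk`, `n_classified`, `classifications` (table), `groups`,
#'   `km` (per group), `logrank` (or `NULL`), `evaluable`.
#' @export
landmark_analysis <- function(model, cohort, landmarks, min_timepoints = 3,
                              merge = default_group_merge(), ...) {
  stopifnot(inherits(cohort, "mrd_cohort"), !is.null(cohort$clinical),
            all(diff(landmarks) > 0))
  clin <- cohort$clinical
  out <- list()
  for (L in landmarks) {
    at_risk <- clin[clin$ttp_months > L, , drop = FALSE]
    trs <- Filter(function(tr) tr$patient_id %in% at_risk$patient_id,
                  cohort$trajectories)
    trs <- lapply(trs, truncate_trajectory, landmark = L)
    trs <- Filter(function(tr) length(tr$times) >= min_timepoints, trs)
    res <- list(landmark = L, n_at_risk = nrow(at_risk),
                n_classified = 0L, evaluable = FALSE,
                classifications = NULL, groups = NULL, km = NULL,
                logrank = NULL)
    if (length(trs) > 0) {
      cls <- lapply(trs, function(tr)
        classify(model, tr, min_timepoints = min_timepoints, ...))
      tab <- classification_table(cls)
      labels <- stats::setNames(tab$label, tab$patient_id)
      groups <- if (is.null(merge)) labels else
        stats::setNames(merge_groups(tab$label, merge), tab$patient_id)
      groups <- groups[!is.na(groups) & groups != "UNCLASSIFIED"]
      rec <- survival_records(at_risk, groups)
      rec$time <- rec$time - L  # clock restarts at the landmark
      res$n_classified <- length(groups)
      res$classifications <- tab
      res$groups <- rec
      gtab <- table(rec$group)
      if (length(gtab[gtab > 0]) >= 2) {
        res$evaluable <- TRUE
        res$km <- lapply(split(rec, rec$group), km_estimate)
        res$logrank <- logrank_test(rec)
      }
    }
    out[[as.character(L)]] <- res
  }
  out
}

#' Cross-tissue concordance of cluster allocation
#'
#' For patients clustered in both tissues, the fraction allocated to the
#' same merged prognostic group, plus the full cluster-to-cluster
#' transition counts (the chord-diagram table).
#'
#' @param bm_labels named character vector patient_id -> BM cluster.
#' @param pb_labels named character vector patient_id -> PB cluster.
#' @param merge cluster -> group mapping used for the agreement fraction.
#' @return list with `agreement` (fraction), `n_pairs`, and `transitions`
#'   (BM cluster x PB cluster count matrix).
#' @export
concordance_table <- function(bm_labels, pb_labels,
                              merge = default_group_merge()) {
  ids <- intersect(names(bm_labels), names(pb_labels))
  if (length(ids) == 0)
    stop_mrdflow("no paired subjects between the two label sets",
                 class = "mrdflow_config_error")
  bm <- bm_labels[ids]; pb <- pb_labels[ids]
  trans <- table(BM = bm, PB = pb)
  agree <- mean(merge_groups(bm, merge) == merge_groups(pb, merge))
  list(agreement = agree, n_pairs = length(ids), transitions = trans)
}
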