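#' Encode an MRD measurement on the log10 scale
#'
#' MRD results come in three flavors: quantified tumor-cell ratios
#' (`QUANT`), positivity below the quantifiable range (`PNQ`, conventionally
#' placed at 1e-6), and molecular negativity (`NEG`). All three are mapped
#' to a single log10 axis so that trajectories are real-valued:
#' `QUANT` becomes `log10(quant_value)`, `PNQ` becomes -6, and `NEG` is
#' placed at a configurable floor strictly below the PNQ level (default
#' -7), keeping the ordering NEG < PNQ < any quantified positivity above
#' 1e-6.
#'
#' @param status character vector with values `"QUANT"`, `"PNQ"` or `"NEG"`.
#' @param quant_value numeric vector of tumor-cell ratios in (0, 1];
#'   required where `status == "QUANT"`, ignored otherwise.
#' @param neg_floor log10 level assigned to negative samples; must be
#'   strictly below -6.
#' @return numeric vector of encoded log10 MRD levels.
#' @examples
#' encode_mrd_value("QUANT", 1e-3)   # -3
#' encode_mrd_value("PNQ")           # -6
#' encode_mrd_value("NEG")           # -7
#' @export
encode_mrd_value <- function(status, quant_value = NULL, neg_floor = -7) {
  status <- as.character(status)
  bad <- !status %in% c("QUANT", "PNQ", "NEG")
  if (any(bad))
    stop_mrdflow("unknown MRD status token(s): ",
                 paste(unique(status[bad]), collapse = ", "),
                 " (expected QUANT, PNQ or NEG)",
                 class = "mrdflow_parse_error")
  if (!is.numeric(neg_floor) || length(neg_floor) != 1 || neg_floor >= -6)
    stop_mrdflow("neg_floor must be a single number strictly below -6",
                 class = "mrdflow_config_error")
  n <- length(status)
  qv <- if (is.null(quant_value)) rep(NA_real_, n) else rep_len(as.numeric(quant_value), n)
  is_q <- status == "QUANT"
  if (any(is_q & (is.na(qv) | qv <= 0 | qv > 1)))
    stop_mrdflow("QUANT measurements require quant_value in (0, 1]",
                 class = "mrdflow_invalid_measurement")
  out <- numeric(n)
  out[is_q] <- log10(qv[is_q])
  out[status == "PNQ"] <- -6
  out[status == "NEG"] <- neg_floor
  out
}

#' Default protocol time-point schedule
#'
#' Maps protocol restaging labels to months from the start of induction
#' (R-CHOP). The trial calendar places the end of induction at month 0,
#' high-dose cytarabine consolidation at month 3, autologous transplant at
#' month 6, and the maintenance/follow-up samples M6..M36 at 6-month
#' intervals after transplant. The whole table is a convention and can be
#' replaced wherever a schedule argument is accepted.
#'
#' @return named numeric vector label -> months.
#' @export
default_schedule <- function() {
  c(RCHOP = 0, ARAC = 3, ASCT = 6,
    M6 = 12, M12 = 18, M18 = 24, M24 = 30, M30 = 36, M36 = 42)
}

#' Map a protocol time-point label to months
#'
#' @param label character vector of time-point labels.
#' @param schedule named numeric vector label -> months; defaults to
#'   [default_schedule()].
#' @return numeric vector of months.
#' @export
map_timepoint_to_months <- function(label, schedule = default_schedule()) {
  label <- as.character(label)
  unknown <- setdiff(unique(label), names(schedule))
  if (length(unknown))
    stop_mrdflow("unknown time-point label(s): ",
                 paste(unknown, collapse = ", "),
                 "; known labels: ", paste(names(schedule), collapse = ", "),
                 class = "mrdflow_mapping_error")
  unname(schedule[label])
}

#' Construct a single MRD trajectory
#'
#' One patient-tissue series of (months, encoded log10 MRD) pairs, sorted
#' by time. Duplicate times are resolved conservatively by keeping the
#' worse (higher) MRD level, with a warning.
#'
#' @param patient_id scalar identifier.
#' @param tissue `"BM"` or `"PB"`.
#' @param times numeric months from treatment start.
#' @param values encoded log10 MRD, same length as `times`.
#' @return object of class `mrd_trajectory`.
#' @export
mrd_trajectory <- function(patient_id, tissue, times, values) {
  stopifnot(length(times) == length(values), all(is.finite(values)))
  if (!tissue %in% c("BM", "PB"))
    stop_mrdflow("tissue must be BM or PB, got ", tissue,
                 class = "mrdflow_parse_error")
  if (any(times < 0)) stop_mrdflow("negative observation time",
                                   class = "mrdflow_parse_error")
  o <- order(times, -values)
  times <- times[o]; values <- values[o]
  dup <- duplicated(times)
  if (any(dup)) {
    warning("patient ", patient_id, " (", tissue, "): duplicate times ",
            paste(unique(times[dup]), collapse = ", "),
            "; keeping the higher MRD value", call. = FALSE)
    keep <- !dup  # first occurrence has the higher value by the sort above
    times <- times[keep]; values <- values[keep]
  }
  structure(list(patient_id = as.character(patient_id), tissue = tissue,
                 times = as.numeric(times), values = as.numeric(values)),
            class = "mrd_trajectory")
}

#' Assemble a cohort from trajectories and clinical records
#'
#' @param trajectories list of [mrd_trajectory()] objects.
#' @param clinical optional data frame with columns `patient_id`,
#'   `ttp_months` (> 0), `event` (0/1) and optionally `arm`.
#' @return object of class `mrd_cohort`.
#' @export
mrd_cohort <- function(trajectories, clinical = NULL) {
  stopifnot(is.list(trajectories),
            all(vapply(trajectories, inherits, TRUE, "mrd_trajectory")))
  if (!is.null(clinical)) {
    clinical <- as.data.frame(clinical)
    need <- c("patient_id", "ttp_months", "event")
    miss <- setdiff(need, names(clinical))
    if (length(miss))
      stop_mrdflow("clinical table missing column(s): ",
                   paste(miss, collapse = ", "),
                   class = "mrdflow_parse_error")
    clinical$patient_id <- as.character(clinical$patient_id)
    if (anyDuplicated(clinical$patient_id))
      stop_mrdflow("duplicated patient_id in clinical table",
                   class = "mrdflow_parse_error")
    if (any(clinical$ttp_months <= 0))
      stop_mrdflow("ttp_months must be positive", class = "mrdflow_parse_error")
    if (!all(clinical$event %in% c(0, 1)))
      stop_mrdflow("event must be 0/1", class = "mrdflow_parse_error")
    if (!"arm" %in% names(clinical)) clinical$arm <- NA_character_
  }
  structure(list(trajectories = trajectories, clinical = clinical),
            class = "mrd_cohort")
}

#' @export
print.mrd_cohort <- function(x, ...) {
  n <- length(x$trajectories)
  npt <- vapply(x$trajectories, function(tr) length(tr$times), 0L)
  cat("MRD cohort:", n, "trajectories",
      if (n) paste0("(time points per subject: median ", stats::median(npt),
                    ", range ", min(npt), "-", max(npt), ")"), "\n")
  if (!is.null(x$clinical))
    cat("Clinical records:", nrow(x$clinical), "subjects,",
        sum(x$clinical$event), "progression events\n")
  invisible(x)
}

#' Number of trajectories in a cohort
#' @param x an `mrd_cohort`.
#' @param ... ignored.
#' @export
length.mrd_cohort <- function(x) length(x$trajectories)

cohort_ids <- function(cohort)
  vapply(cohort$trajectories, `[[`, "", "patient_id")

#' Keep only trajectories with enough post-baseline time points
#'
#' Inclusion rule for modeling: a trajectory enters the analysis only with
#' at least `min_timepoints` recorded post-baseline measurements (three for
#' bone-marrow series, four for peripheral-blood series in the motivating
#' study). Clinical records of dropped patients are removed as well;
#' trajectory order is preserved.
#'
#' @param cohort an `mrd_cohort`.
#' @param min_timepoints minimum number of measurements (>= 1).
#' @return the filtered `mrd_cohort`.
#' @export
filter_cohort <- function(cohort, min_timepoints) {
  stopifnot(inherits(cohort, "mrd_cohort"), min_timepoints >= 1)
  keep <- vapply(cohort$trajectories,
                 function(tr) length(tr$times) >= min_timepoints, TRUE)
  trs <- cohort$trajectories[keep]
  if (length(trs) == 0)
    warning("no trajectories satisfy min_timepoints = ", min_timepoints,
            call. = FALSE)
  clin <- cohort$clinical
  if (!is.null(clin)) {
    ids <- unique(vapply(trs, `[[`, "", "patient_id"))
    clin <- clin[clin$patient_id %in% ids, , drop = FALSE]
    rownames(clin) <- NULL
  }
  mrd_cohort(trs, clin)
}

#' Read a cohort from long-format CSV tables
#'
#' The measurements table holds one row per MRD determination with columns
#' `patient_id`, `tissue`, `timepoint_label` (optional if `time_months`
#' given), `time_months` (optional if a label is given), `status`
#' (QUANT/PNQ/NEG) and `quant_value` (required for QUANT rows). Rows
#' labeled `BASELINE` (or flagged by a logical `baseline` column) are the
#' diagnostic sample and are dropped: the baseline measurement is not an
#' MRD time point. An optional clinical table supplies `patient_id`,
#' `ttp_months`, `event` and `arm`.
#'
#' @param measurements_path CSV path of measurements.
#' @param clinical_path optional CSV path of clinical records.
#' @param tissue optional `"BM"`/`"PB"` filter; with `NULL` both tissues are
#'   kept (as separate trajectories).
#' @param neg_floor encoding floor for negative samples (see
#'   [encode_mrd_value()]).
#' @param schedule label -> month table for rows without `time_months`.
#' @return an `mrd_cohort`.
#' @export
read_cohort <- function(measurements_path, clinical_path = NULL,
                        tissue = NULL, neg_floor = -7,
                        schedule = default_schedule()) {
  df <- utils::read.csv(measurements_path, stringsAsFactors = FALSE)
  need <- c("patient_id", "tissue", "status")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_mrdflow("measurements CSV missing column(s): ",
                 paste(miss, collapse = ", "), class = "mrdflow_parse_error")
  df$.row <- seq_len(nrow(df)) + 1L  # header is line 1
  if ("baseline" %in% names(df))
    df <- df[!(df$baseline %in% c(TRUE, "TRUE", "true", 1)), , drop = FALSE]
  if ("timepoint_label" %in% names(df))
    df <- df[is.na(df$timepoint_label) | df$timepoint_label != "BASELINE", ,
             drop = FALSE]
  if (!is.null(tissue)) df <- df[df$tissue == tissue, , drop = FALSE]

  bad_status <- !df$status %in% c("QUANT", "PNQ", "NEG")
  if (any(bad_status))
    stop_mrdflow("unparseable status token '", df$status[bad_status][1],
                 "' at CSV line ", df$.row[bad_status][1],
                 class = "mrdflow_parse_error")
  if (!"time_months" %in% names(df)) df$time_months <- NA_real_
  needs_map <- is.na(df$time_months)
  if (any(needs_map)) {
    if (!"timepoint_label" %in% names(df))
      stop_mrdflow("rows without time_months need a timepoint_label ",
                   "(first at CSV line ", df$.row[needs_map][1], ")",
                   class = "mrdflow_parse_error")
    df$time_months[needs_map] <-
      map_timepoint_to_months(df$timepoint_label[needs_map], schedule)
  }
  if (!"quant_value" %in% names(df)) df$quant_value <- NA_real_
  df$log_value <- encode_mrd_value(df$status, df$quant_value, neg_floor)

  key <- interaction(df$patient_id, df$tissue, drop = TRUE)
  trajectories <- lapply(split(df, key), function(d)
    mrd_trajectory(d$patient_id[1], d$tissue[1], d$time_months, d$log_value))
  ord <- order(vapply(trajectories, `[[`, "", "patient_id"),
               vapply(trajectories, `[[`, "", "tissue"))
  trajectories <- unname(trajectories[ord])

  clinical <- if (!is.null(clinical_path))
    utils::read.csv(clinical_path, stringsAsFactors = FALSE)
  mrd_cohort(trajectories, clinical)
}

#' Write a cohort back to CSV
#'
#' Emits the same long measurements format read by [read_cohort()], with
#' deterministic row order (patient_id, tissue, time). Encoded PNQ/NEG
#' levels are written back as status tokens so that a write/read round
#' trip is the identity.
#'
#' @param cohort an `mrd_cohort`.
#' @param measurements_path output CSV path for measurements.
#' @param clinical_path optional output CSV path for clinical records.
#' @param neg_floor the floor used when the cohort was encoded.
#' @return invisibly, the measurements data frame written.
#' @export
write_cohort <- function(cohort, measurements_path, clinical_path = NULL,
                         neg_floor = -7) {
  stopifnot(inherits(cohort, "mrd_cohort"))
  rows <- lapply(cohort$trajectories, function(tr) {
    status <- ifelse(tr$values == neg_floor, "NEG",
                     ifelse(tr$values == -6, "PNQ", "QUANT"))
    data.frame(patient_id = tr$patient_id, tissue = tr$tissue,
               time_months = tr$times, status = status,
               quant_value = ifelse(status == "QUANT", 10^tr$values, NA_real_))
  })
  df <- do.call(rbind, rows)
  df <- df[order(df$patient_id, df$tissue, df$time_months), , drop = FALSE]
  rownames(df) <- NULL
  utils::write.csv(df, measurements_path, row.names = FALSE, na = "")
  if (!is.null(clinical_path) && !is.null(cohort$clinical))
    utils::write.csv(cohort$clinical, clinical_path, row.names = FALSE, na = "")
  invisible(df)
}
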