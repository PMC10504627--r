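# Day-level evaluation of change alarms against risk events. Every monitored
# day of every patient is a data point: an alarm on day d is a true positive
# when a risk event occurs within the next `horizon` days, i.e. in
# (d, d + horizon]; an alarm with no event in that window is a false
# positive; a non-alarm day whose window contains an event is a false
# negative; everything else is a true negative. Monitoring stops at the first
# risk event, so days at or after the event are never evaluated.

#' Day-level confusion counts for one patient
#'
#' @param alarms an `alarm_series` from [detect_alarms()] (burn-in days are
#'   `NA` and excluded from evaluation).
#' @param event_day 0-based day index of the patient's first risk event, or
#'   `NA` if none occurred during monitoring.
#' @param horizon prediction window in days: an alarm at day d predicts an
#'   event in `(d, d + horizon]`. Default 7.
#' @param direction `"forward"` (default) predicts events in
#'   `(d, d + horizon]`; `"backward"` scores an alarm against an event in
#'   `[d - horizon, d)`.
#' @return named integer vector `c(TP, FP, FN, TN)`.
#' @export
label_days <- function(alarms, event_day, horizon = 7,
                       direction = c("forward", "backward")) {
  direction <- match.arg(direction)
  if (horizon <= 0) stop_invalid("horizon must be positive")
  a <- alarms$alarm
  days <- seq_along(a) - 1L               # 0-based
  eval_idx <- !is.na(a)
  if (!is.na(event_day)) {
    if (event_day < alarms$burn_in) {
      warning("risk event during burn-in; patient excluded from evaluation")
      return(c(TP = 0L, FP = 0L, FN = 0L, TN = 0L))
    }
    eval_idx <- eval_idx & days < event_day   # monitoring stops at the event
  }
  d <- days[eval_idx]
  al <- a[eval_idx]
  pos <- if (is.na(event_day)) {
    rep(FALSE, length(d))
  } else if (direction == "forward") {
    event_day > d & event_day <= d + horizon
  } else {
    event_day >= d - horizon & event_day < d
  }
  c(TP = sum(al & pos), FP = sum(al & !pos),
    FN = sum(!al & pos), TN = sum(!al & !pos))
}

#' Pooled ROC curve over a stability-threshold grid
#'
#' Applies the alarm rule at `n_thresholds` equally spaced interior points of
#' (0, 1) (grid `k / (n_thresholds + 1)`), pools day-level confusion counts
#' over all patients at each threshold, and computes the ROC curve and its
#' trapezoidal AUC with anchors at (0,0) and (1,1).
#'
#' @param series_list list of change-probability series (one per patient,
#'   from [change_window_probability()]).
#' @param event_days numeric vector, one entry per patient: 0-based day of
#'   the first risk event or `NA`.
#' @param n_thresholds number of stability thresholds (default 50).
#' @param horizon prediction window in days (default 7).
#' @param burn_in leading days excluded per patient (default 7).
#' @param direction window direction, see [label_days()].
#' @return a `roc_result`: list with `points` (data.frame `tau, FPR, TPR,
#'   TP, FP, FN, TN` sorted by FPR) and `auc`.
#' @export
roc_curve <- function(series_list, event_days, n_thresholds = 50,
                      horizon = 7, burn_in = 7,
                      direction = c("forward", "backward")) {
  direction <- match.arg(direction)
  if (length(series_list) != length(event_days))
    stop_invalid("series_list and event_days lengths differ")
  # Pool day-level values and positive/negative labels once; only the alarm
  # rule depends on the threshold.
  vals <- numeric(0); pos <- logical(0)
  excluded <- 0L
  for (i in seq_along(series_list)) {
    s <- as.vector(series_list[[i]])
    e <- event_days[i]
    days <- seq_along(s) - 1L
    keep <- days >= burn_in
    if (!is.na(e)) {
      if (e < burn_in) { excluded <- excluded + 1L; next }
      keep <- keep & days < e
    }
    d <- days[keep]
    vals <- c(vals, s[keep])
    pos <- c(pos, if (is.na(e)) rep(FALSE, length(d))
             else if (direction == "forward") e > d & e <= d + horizon
             else e >= d - horizon & e < d)
  }
  if (excluded > 0)
    warning(sprintf("%d patient(s) with an event during burn-in excluded",
                    excluded))
  if (!any(pos))
    stop_invalid("degenerate cohort: no positive (pre-event) day to evaluate")
  if (!any(!pos))
    stop_invalid("degenerate cohort: no negative (event-free) day to evaluate")
  taus <- seq_len(n_thresholds) / (n_thresholds + 1)
  n_pos <- sum(pos); n_neg <- sum(!pos)
  counts <- vapply(taus, function(tau) {
    al <- vals > tau
    c(TP = sum(al & pos), FP = sum(al & !pos),
      FN = sum(!al & pos), TN = sum(!al & !pos))
  }, numeric(4))
  tpr <- counts["TP", ] / n_pos
  fpr <- counts["FP", ] / n_neg
  pts <- data.frame(tau = taus, FPR = fpr, TPR = tpr,
                    TP = counts["TP", ], FP = counts["FP", ],
                    FN = counts["FN", ], TN = counts["TN", ])
  pts <- pts[order(pts$FPR, pts$TPR), ]
  fx <- c(0, pts$FPR, 1)
  fy <- c(0, pts$TPR, 1)
  auc <- sum(diff(fx) * (utils::head(fy, -1) + utils::tail(fy, -1)) / 2)
  structure(list(points = pts, auc = auc, horizon = horizon,
                 burn_in = burn_in, direction = direction),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> %d threshold(s), AUC = %.3f\n",
              nrow(x$points), x$auc))
  invisible(x)
}

#' Cohort-level risk-event summary
#'
#' Percentage of patients with a suicide attempt, a psychiatric emergency
#' department visit, and any risk event, rounded to one decimal place (as
#' typically reported). Only the first event per patient counts; monitoring
#' stops there.
#'
#' @param events data.frame with columns `patient_id`, `day`, `type`
#'   (`"suicide_attempt"` or `"ed_visit"`); at most one row per patient is
#'   used (the earliest by `day`).
#' @param n_patients cohort size.
#' @return list with counts and percentages: `n_attempt`, `n_ed`, `n_any`,
#'   `pct_attempt`, `pct_ed`, `pct_any`.
#' @export
cohort_summary <- function(events, n_patients) {
  if (n_patients < 1) stop_invalid("n_patients must be >= 1")
  if (nrow(events) > 0) {
    events <- events[order(events$patient_id, events$day), ]
    events <- events[!duplicated(events$patient_id), ]
  }
  n_attempt <- sum(events$type == "suicide_attempt")
  n_ed <- sum(events$type == "ed_visit")
  n_any <- nrow(events)
  pct <- function(n) round(100 * n / n_patients, 1)
  list(n_attempt = n_attempt, n_ed = n_ed, n_any = n_any,
       pct_attempt = pct(n_attempt), pct_ed = pct(n_ed), pct_any = pct(n_any))
}

#' Write ROC results
#'
#' Writes the threshold grid as CSV and a JSON summary with the AUC.
#'
#' @param roc a `roc_result`.
#' @param csv_path,json_path output paths (either may be `NULL` to skip).
#' @export
write_roc <- function(roc, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path))
    utils::write.csv(roc$points, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(
      list(auc = roc$auc, horizon = roc$horizon, burn_in = roc$burn_in,
           n_thresholds = nrow(roc$points)),
      json_path, auto_unbox = TRUE, digits = NA)
  invisible(roc)
}
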