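# Stability-threshold alarms: a behavioral change is flagged at day d when
# the cumulative probability that a change occurred over the previous w days
# exceeds the threshold. Lower thresholds mean higher detection sensitivity.

#' Raise behavioral-change alarms from a change-probability series
#'
#' An alarm fires on day `d` when the cumulative change probability strictly
#' exceeds the stability threshold `tau`. The first `burn_in` days of the
#' record are excluded (marked `NA`): there the run length is necessarily
#' shorter than the window, the series saturates at 1, and every patient
#' would otherwise alarm on day one.
#'
#' @param series numeric change-probability series in `[0, 1]` (from
#'   [change_window_probability()]).
#' @param tau stability threshold, strictly inside (0, 1).
#' @param burn_in number of leading days excluded from alarms and from
#'   evaluation; defaults to the series' window attribute (7).
#' @return an `alarm_series`: list with `alarm` (logical per day, `NA` during
#'   burn-in), `tau`, `burn_in`.
#' @export
detect_alarms <- function(series, tau, burn_in = NULL) {
  if (!is.numeric(tau) || length(tau) != 1 || tau <= 0 || tau >= 1)
    stop_invalid("stability threshold tau must lie strictly in (0, 1)")
  check_prob(series, "change-probability series")
  if (is.null(burn_in)) {
    burn_in <- attr(series, "window")
    if (is.null(burn_in)) burn_in <- 7L
  }
  alarm <- as.vector(series) > tau
  if (burn_in > 0) alarm[seq_len(min(burn_in, length(alarm)))] <- NA
  structure(list(alarm = alarm, tau = tau, burn_in = as.integer(burn_in)),
            class = "alarm_series")
}

#' @export
print.alarm_series <- function(x, ...) {
  cat(sprintf("<alarm_series> tau = %.3f, %d/%d evaluated day(s) alarmed\n",
              x$tau, sum(x$alarm, na.rm = TRUE), sum(!is.na(x$alarm))))
  invisible(x)
}

#' Write alarms as tidy CSV
#'
#' @param alarms an `alarm_series`.
#' @param patient_id identifier recorded in the output.
#' @param path output CSV path.
#' @export
write_alarms_csv <- function(alarms, patient_id, path) {
  df <- data.frame(patient_id = patient_id,
                   day = seq_along(alarms$alarm) - 1L,
                   alarm = alarms$alarm,
                   threshold = alarms$tau)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
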