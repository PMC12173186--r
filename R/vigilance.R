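#' Yearly pharmacovigilance series
#'
#' National-level yearly counts: adverse-drug-reaction (ADR) reports,
#' serious ADR reports, and new-drug clinical-trial applications and
#' approvals. Any series may be absent (`NA`), but where both are present
#' serious reports cannot exceed total reports and approvals cannot
#' exceed applications.
#'
#' @param df data.frame with column `year` and any of `adr_reports`,
#'   `serious_reports`, `trial_applications`, `trial_approvals`
#' @return a validated `vigilance_series` data.frame
#' @export
as_vigilance_series <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!"year" %in% names(df)) stop_regcap("vigilance series needs a 'year' column")
  cols <- c("adr_reports", "serious_reports", "trial_applications",
            "trial_approvals")
  for (col in cols) if (!col %in% names(df)) df[[col]] <- NA_real_
  df <- df[order(df$year), c("year", cols)]
  for (col in cols) {
    if (any(df[[col]] < 0, na.rm = TRUE))
      stop_regcap("negative count in ", col)
  }
  both <- !is.na(df$serious_reports) & !is.na(df$adr_reports)
  if (any(df$serious_reports[both] > df$adr_reports[both]))
    stop_regcap("serious reports exceed total ADR reports")
  both <- !is.na(df$trial_approvals) & !is.na(df$trial_applications)
  if (any(df$trial_approvals[both] > df$trial_applications[both]))
    stop_regcap("approvals exceed applications")
  structure(df, class = c("vigilance_series", "data.frame"))
}

#' Read a vigilance series from CSV
#' @param path CSV with `year` and count columns
#' @return a `vigilance_series`
#' @export
read_vigilance <- function(path) {
  if (!file.exists(path)) stop_regcap("vigilance file not found: ", path)
  as_vigilance_series(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Clinical-trial approval pass rate
#'
#' Approvals over applications in percent, rounded half-up to 2 decimals
#' (the precision at which published rates print).
#'
#' @param approvals nonnegative approval count(s)
#' @param applications positive application count(s)
#' @return percentage(s) in `[0, 100]`
#' @export
#' @examples
#' pass_rate(879, 1099)  # 79.98
pass_rate <- function(approvals, applications) {
  if (any(applications <= 0)) stop_regcap("applications must be positive")
  if (any(approvals < 0)) stop_regcap("approvals must be nonnegative")
  if (any(approvals > applications))
    stop_regcap("approvals exceed applications")
  round_half_up(100 * approvals / applications, 2)
}

#' Yearly proportion of serious ADR reports
#'
#' Serious reports over total reports in percent, per year, 2 decimals.
#'
#' @param series a `vigilance_series`
#' @return named vector (by year) of percentages
#' @export
serious_proportion <- function(series) {
  series <- as_vigilance_series(series)
  ok <- !is.na(series$serious_reports) & !is.na(series$adr_reports)
  if (any(series$adr_reports[ok] == 0))
    stop_regcap("zero total ADR reports in a year")
  stats::setNames(
    round_half_up(100 * series$serious_reports[ok] / series$adr_reports[ok], 2),
    series$year[ok])
}

#' Year-over-year percentage change of a series
#'
#' `(v_t - v_{t-1}) / v_{t-1} * 100` for each consecutive year pair.
#'
#' @param values numeric series in year order
#' @param years optional year labels (names the result by the later year)
#' @return named vector of percentage changes, 2 decimals
#' @export
yoy_change <- function(values, years = NULL) {
  if (length(values) < 2) stop_regcap("need at least 2 years")
  prev <- values[-length(values)]
  if (any(prev == 0)) stop_regcap("zero previous value")
  chg <- round_half_up(100 * diff(values) / prev, 2)
  if (!is.null(years)) names(chg) <- years[-1]
  chg
}

#' Descriptive pharmacovigilance report
#'
#' Per-year pass rates, serious-report proportions and year-over-year
#' changes of every available series, in one tidy table.
#'
#' @param series a `vigilance_series`
#' @return data.frame keyed by `year` with derived percentage columns
#' @export
vigilance_report <- function(series) {
  series <- as_vigilance_series(series)
  out <- as.data.frame(series)
  ok <- !is.na(series$trial_approvals) & !is.na(series$trial_applications)
  out$pass_rate <- NA_real_
  out$pass_rate[ok] <- pass_rate(series$trial_approvals[ok],
                                 series$trial_applications[ok])
  out$serious_pct <- NA_real_
  oks <- !is.na(series$serious_reports) & !is.na(series$adr_reports)
  if (any(oks)) out$serious_pct[oks] <- serious_proportion(series)
  for (col in c("adr_reports", "serious_reports", "trial_applications",
                "trial_approvals")) {
    v <- series[[col]]
    out[[paste0(col, "_yoy")]] <- NA_real_
    if (sum(!is.na(v)) >= 2 && !anyNA(v) && all(v[-length(v)] != 0))
      out[[paste0(col, "_yoy")]][-1] <- yoy_change(v)
  }
  out
}
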