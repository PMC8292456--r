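# Per-subject ordinary least squares: annual change rate and
# extrapolated level at motor onset.

#' Fit one subject's line: value ~ time
#'
#' Exact closed-form OLS of marker value on the subject's time axis
#' (disease duration for PD, time from baseline for controls). The slope
#' is the subject's annual change rate; the intercept is the
#' extrapolated level at motor onset (PD) or at baseline (controls).
#'
#' @param time Numeric vector of times (years), at least two distinct.
#' @param value Numeric vector of marker values.
#' @return List with `rate` (units/year), `onset_level` (units) and
#'   `n_points`.
#' @examples
#' fit_subject_line(c(1, 3), c(90, 70))   # rate -10, onset level 100
#' @export
fit_subject_line <- function(time, value) {
  ok <- is.finite(time) & is.finite(value)
  time <- time[ok]; value <- value[ok]
  n <- length(time)
  if (n < 2L)
    stop_biotraj("need at least two valid measurements",
                 "biotraj_insufficient_points")
  if (max(time) == min(time))
    stop_biotraj("all measurement times identical",
                 "biotraj_zero_time_variance")
  mx <- mean(time); my <- mean(value)
  dx <- time - mx
  slope <- sum(dx * (value - my)) / sum(dx^2)
  list(rate = slope, onset_level = my - slope * mx, n_points = n)
}

#' Per-subject kinetics for every subject-marker series
#'
#' Applies [fit_subject_line()] to each subject-marker series of a long
#' visit table. The time axis is the `duration_years` column, which
#' holds disease duration for PD subjects and time from baseline for
#' controls. `baseline_level` is the earliest observed value of the
#' series (the level each subject's rate is paired with in the
#' rate-versus-level model).
#'
#' @param visits Long visit table (see [generate_cohort()]).
#' @return Data.frame `subject_id`, `group`, `marker`, `rate`,
#'   `onset_level`, `baseline_level`, `n_points`; degenerate series
#'   (identical times) are dropped and listed in the `exclusions`
#'   attribute with reason `zero_time_variance`.
#' @export
fit_kinetics <- function(visits) {
  req <- c("subject_id", "group", "marker", "duration_years", "value")
  if (!all(req %in% names(visits)))
    stop("visit table must have columns: ", paste(req, collapse = ", "))
  key <- series_key(visits)
  idx <- split(seq_len(nrow(visits)), key)
  out <- vector("list", length(idx))
  excl <- list()
  for (i in seq_along(idx)) {
    rows <- idx[[i]]
    t <- visits$duration_years[rows]
    v <- visits$value[rows]
    fit <- tryCatch(fit_subject_line(t, v), biotraj_error = function(e) e)
    sid <- visits$subject_id[rows[1]]
    mk <- visits$marker[rows[1]]
    if (inherits(fit, "condition")) {
      reason <- if (inherits(fit, "biotraj_zero_time_variance"))
        "zero_time_variance" else "insufficient_points"
      excl[[length(excl) + 1L]] <- data.frame(
        subject_id = sid, marker = mk, reason = reason,
        stringsAsFactors = FALSE)
      next
    }
    first <- rows[which.min(ifelse(is.na(v), Inf, t))]
    out[[i]] <- data.frame(
      subject_id = sid, group = visits$group[rows[1]], marker = mk,
      rate = fit$rate, onset_level = fit$onset_level,
      baseline_level = visits$value[first], n_points = fit$n_points,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(res) <- NULL
  attr(res, "exclusions") <- if (length(excl)) do.call(rbind, excl) else
    data.frame(subject_id = character(), marker = character(),
               reason = character(), stringsAsFactors = FALSE)
  res
}

#' Group anchor level at motor onset
#'
#' The level a group's trajectory is anchored to at time zero: by
#' default the arithmetic mean of the per-subject extrapolated onset
#' levels within the group or stratum (median available).
#'
#' @param kinetics A kinetics table (or subset) from [fit_kinetics()],
#'   or a numeric vector of onset levels.
#' @param stat `"mean"` (default) or `"median"`.
#' @return A single anchor level (marker units).
#' @export
onset_anchor <- function(kinetics, stat = c("mean", "median")) {
  stat <- match.arg(stat)
  x <- if (is.data.frame(kinetics)) kinetics$onset_level else kinetics
  x <- x[is.finite(x)]
  if (length(x) == 0L) stop("no onset levels to anchor on (empty group)")
  if (stat == "mean") mean(x) else median(x)
}
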