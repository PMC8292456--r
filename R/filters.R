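# Cohort inclusion/exclusion rules and stratification.

#' Filter configuration
#'
#' Thresholds and conventions of the cohort filter chain:
#' minimum two measurements per subject-marker series, the hemoglobin
#' cut-off for CSF alpha-synuclein samples (< 200 ng/mL kept, strict),
#' the 3 x IQR rule on PD baseline biomarker levels (strictly beyond the
#' fence excluded), the mean +/- 4 SD rule on PD baseline cognitive
#' scores, and the MoCA (> 25 unimpaired) and amyloid-beta (683.45
#' pg/mL) stratification cut-offs.
#'
#' @param min_measurements Minimum valid measurements per subject-marker
#'   series (default 2).
#' @param hemoglobin_cutoff Samples with hemoglobin at or above this are
#'   dropped for `alpha_syn_marker` (ng/mL).
#' @param iqr_multiplier Baseline fence = Q1 - m*IQR / Q3 + m*IQR.
#' @param cognitive_sd_multiplier Cognitive fence in SD units.
#' @param moca_cutoff MoCA strictly above this is cognitively unimpaired.
#' @param abeta_cutoff Baseline amyloid-beta strictly below this is the
#'   low group; a value exactly at the cut-off goes to the high group.
#' @param quantile_type Quantile convention for Q1/Q3 and knot
#'   percentiles (`type` of [stats::quantile()]; 7 = linear
#'   interpolation, the common default).
#' @param drop_missing_hemoglobin Drop alpha-synuclein samples with
#'   missing hemoglobin instead of retaining them with a warning.
#' @param cognitive_leave_one_out Compute each candidate's mean/SD from
#'   the other subjects (default). With pooled moments that include the
#'   candidate, the largest attainable deviation in a sample of n is
#'   (n-1)/sqrt(n) SDs, so the 4 SD rule could never fire in small
#'   cohorts.
#' @param alpha_syn_marker,abeta_marker,cognitive_markers Marker names
#'   the hemoglobin rule, the amyloid stratification and the cognitive
#'   outlier rule apply to.
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(min_measurements = 2L,
                          hemoglobin_cutoff = 200,
                          iqr_multiplier = 3,
                          cognitive_sd_multiplier = 4,
                          moca_cutoff = 25,
                          abeta_cutoff = 683.45,
                          quantile_type = 7L,
                          drop_missing_hemoglobin = FALSE,
                          cognitive_leave_one_out = TRUE,
                          alpha_syn_marker = "asyn",
                          abeta_marker = "abeta",
                          cognitive_markers = c("moca", "hvlt_dr", "lns")) {
  thresholds <- c(min_measurements, hemoglobin_cutoff, iqr_multiplier,
                  cognitive_sd_multiplier, moca_cutoff, abeta_cutoff)
  if (any(!is.finite(thresholds)) || any(thresholds <= 0))
    stop("all filter thresholds must be positive")
  structure(
    list(min_measurements = as.integer(min_measurements),
         hemoglobin_cutoff = hemoglobin_cutoff,
         iqr_multiplier = iqr_multiplier,
         cognitive_sd_multiplier = cognitive_sd_multiplier,
         moca_cutoff = moca_cutoff, abeta_cutoff = abeta_cutoff,
         quantile_type = as.integer(quantile_type),
         drop_missing_hemoglobin = isTRUE(drop_missing_hemoglobin),
         cognitive_leave_one_out = isTRUE(cognitive_leave_one_out),
         alpha_syn_marker = alpha_syn_marker,
         abeta_marker = abeta_marker,
         cognitive_markers = cognitive_markers),
    class = "filter_config"
  )
}

empty_filter_log <- function() {
  data.frame(subject_id = character(), marker = character(),
             stage = character(), reason = character(),
             detail = character(), stringsAsFactors = FALSE)
}

series_key <- function(visits) paste(visits$subject_id, visits$marker, sep = "\r")

#' Keep subject-marker series with enough measurements
#'
#' A series is retained iff it has at least `min_measurements` valid
#' (non-missing) values.
#'
#' @param visits Long visit table (see [generate_cohort()]).
#' @param min_measurements Minimum number of valid measurements.
#' @return List with `visits` (retained rows) and `log` (one row per
#'   excluded series: `subject_id`, `marker`, `stage`, `reason`,
#'   `detail`).
#' @export
filter_min_visits <- function(visits, min_measurements = 2L) {
  if (nrow(visits) == 0L) {
    warning("empty visit table; nothing to filter")
    return(list(visits = visits, log = empty_filter_log()))
  }
  key <- series_key(visits)
  n_valid <- tapply(!is.na(visits$value), key, sum)
  bad <- names(n_valid)[n_valid < min_measurements]
  log <- empty_filter_log()
  if (length(bad)) {
    parts <- do.call(rbind, strsplit(bad, "\r", fixed = TRUE))
    log <- data.frame(subject_id = parts[, 1], marker = parts[, 2],
                      stage = "min_visits", reason = "insufficient_visits",
                      detail = sprintf("n_valid=%d", as.integer(n_valid[bad])),
                      stringsAsFactors = FALSE)
  }
  list(visits = visits[!(key %in% bad), , drop = FALSE], log = log)
}

#' Drop blood-contaminated alpha-synuclein samples
#'
#' A sample of `marker` is retained iff its hemoglobin is strictly below
#' `cutoff`; the rule is specific to CSF alpha-synuclein, other markers
#' are untouched. Samples with missing hemoglobin are retained with a
#' warning unless `drop_missing = TRUE`. If the hemoglobin column is
#' absent the stage is skipped with a warning (`skipped = TRUE` in the
#' result).
#'
#' @param visits Long visit table.
#' @param cutoff Hemoglobin cut-off (ng/mL).
#' @param marker Marker name the rule applies to.
#' @param drop_missing Drop samples with missing hemoglobin.
#' @return List with `visits`, `log` and `skipped`.
#' @export
filter_hemoglobin <- function(visits, cutoff = 200, marker = "asyn",
                              drop_missing = FALSE) {
  if (!"hemoglobin_ng_ml" %in% names(visits)) {
    warning("no 'hemoglobin_ng_ml' column; hemoglobin filter skipped")
    return(list(visits = visits, log = empty_filter_log(), skipped = TRUE))
  }
  hb <- visits$hemoglobin_ng_ml
  if (any(hb < 0, na.rm = TRUE))
    stop("negative hemoglobin values are invalid")
  is_target <- visits$marker == marker
  drop_high <- is_target & !is.na(hb) & hb >= cutoff
  drop_na <- logical(nrow(visits))
  n_missing <- sum(is_target & is.na(hb))
  if (n_missing > 0L) {
    if (drop_missing) {
      drop_na <- is_target & is.na(hb)
    } else {
      warning(sprintf(
        "%d %s sample(s) have missing hemoglobin; retained", n_missing,
        marker))
    }
  }
  drop <- drop_high | drop_na
  log <- empty_filter_log()
  if (any(drop)) {
    log <- data.frame(
      subject_id = visits$subject_id[drop], marker = visits$marker[drop],
      stage = "hemoglobin",
      reason = ifelse(drop_high[drop], "high_hemoglobin",
                      "missing_hemoglobin"),
      detail = ifelse(drop_high[drop],
                      sprintf("hb=%.1f;visit=%s", hb[drop],
                              visits$visit_label[drop]),
                      sprintf("visit=%s", visits$visit_label[drop])),
      stringsAsFactors = FALSE)
  }
  list(visits = visits[!drop, , drop = FALSE], log = log, skipped = FALSE)
}

baseline_rows <- function(visits) {
  # earliest valid measurement per subject-marker series
  ok <- !is.na(visits$value)
  v <- visits[ok, , drop = FALSE]
  key <- series_key(v)
  ord <- order(key, v$duration_years)
  v <- v[ord, , drop = FALSE]
  v[!duplicated(series_key(v)), , drop = FALSE]
}

#' Exclude series with extreme baseline biomarker levels
#'
#' For each marker, a PD subject's whole series is excluded iff its
#' baseline (earliest) value lies strictly more than
#' `iqr_multiplier` interquartile ranges below the first quartile or
#' above the third quartile of the PD baseline distribution of that
#' marker. With fewer than four baseline values the quartiles are
#' undefined and the marker is left unfiltered with a warning.
#'
#' @param visits Long visit table.
#' @param markers Markers the rule applies to (default: all present).
#' @param iqr_multiplier Fence multiplier.
#' @param quantile_type Quantile convention (see [stats::quantile()]).
#' @param groups Group labels the rule applies to (the published rule
#'   targets PD patients).
#' @return List with `visits` and `log`.
#' @export
filter_baseline_outliers <- function(visits, markers = NULL,
                                     iqr_multiplier = 3,
                                     quantile_type = 7L,
                                     groups = "pd") {
  if (is.null(markers)) markers <- unique(visits$marker)
  log <- empty_filter_log()
  drop_key <- character()
  bl <- baseline_rows(visits)
  bl <- bl[bl$group %in% groups, , drop = FALSE]
  for (m in intersect(markers, unique(bl$marker))) {
    bm <- bl[bl$marker == m, , drop = FALSE]
    if (nrow(bm) < 4L) {
      warning(sprintf(
        "marker '%s': fewer than 4 baseline values, outlier rule skipped", m))
      next
    }
    q <- quantile(bm$value, c(0.25, 0.75), type = quantile_type, names = FALSE)
    iqr <- q[2] - q[1]
    lo <- q[1] - iqr_multiplier * iqr
    hi <- q[2] + iqr_multiplier * iqr
    out <- bm$value < lo | bm$value > hi     # strictly beyond the fence
    if (any(out)) {
      log <- rbind(log, data.frame(
        subject_id = bm$subject_id[out], marker = m,
        stage = "baseline_outlier", reason = "baseline_outlier",
        detail = sprintf("baseline=%.4g;fence=[%.4g,%.4g]",
                         bm$value[out], lo, hi),
        stringsAsFactors = FALSE))
      drop_key <- c(drop_key, paste(bm$subject_id[out], m, sep = "\r"))
    }
  }
  list(visits = visits[!(series_key(visits) %in% drop_key), , drop = FALSE],
       log = log)
}

loo_moments <- function(x) {
  # leave-one-out mean and SD for each element
  n <- length(x)
  s <- sum(x); ss <- sum(x^2)
  mu <- (s - x) / (n - 1)
  var <- pmax((ss - x^2 - (n - 1) * mu^2) / (n - 2), 0)
  list(mean = mu, sd = sqrt(var))
}

#' Exclude series with extreme baseline cognitive scores
#'
#' A PD subject is excluded for a cognitive score iff its baseline value
#' deviates strictly more than `sd_multiplier` standard deviations from
#' the group's baseline mean. By default each candidate is compared
#' against the mean/SD of the *other* subjects (leave-one-out), so a
#' gross outlier cannot mask itself by inflating the pooled SD; with
#' `leave_one_out = FALSE` pooled moments are used. A zero SD excludes
#' exactly the deviating values.
#'
#' @param visits Long visit table.
#' @param markers Cognitive score names.
#' @param sd_multiplier Fence in SD units.
#' @param groups Groups the rule applies to.
#' @param leave_one_out Use leave-one-out moments (default TRUE).
#' @return List with `visits` and `log`.
#' @export
filter_cognitive_outliers <- function(visits,
                                      markers = c("moca", "hvlt_dr", "lns"),
                                      sd_multiplier = 4,
                                      groups = "pd",
                                      leave_one_out = TRUE) {
  log <- empty_filter_log()
  drop_key <- character()
  bl <- baseline_rows(visits)
  bl <- bl[bl$group %in% groups, , drop = FALSE]
  for (m in intersect(markers, unique(bl$marker))) {
    bm <- bl[bl$marker == m, , drop = FALSE]
    if (nrow(bm) < 3L) {
      warning(sprintf(
        "score '%s': fewer than 3 baseline values, outlier rule skipped", m))
      next
    }
    if (leave_one_out) {
      mom <- loo_moments(bm$value)
    } else {
      mom <- list(mean = rep(mean(bm$value), nrow(bm)),
                  sd = rep(sd(bm$value), nrow(bm)))
    }
    dev <- abs(bm$value - mom$mean)
    out <- dev > sd_multiplier * mom$sd     # strict: exactly 4 SD is kept
    if (any(out)) {
      log <- rbind(log, data.frame(
        subject_id = bm$subject_id[out], marker = m,
        stage = "cognitive_outlier", reason = "cognitive_outlier",
        detail = sprintf("score=%.4g;mean=%.4g;sd=%.4g", bm$value[out],
                         mom$mean[out], mom$sd[out]),
        stringsAsFactors = FALSE))
      drop_key <- c(drop_key, paste(bm$subject_id[out], m, sep = "\r"))
    }
  }
  list(visits = visits[!(series_key(visits) %in% drop_key), , drop = FALSE],
       log = log)
}

#' Apply the full filter chain
#'
#' Runs, in order: minimum-measurements, hemoglobin (alpha-synuclein
#' samples), a minimum-measurements recheck (a series that lost samples
#' to the hemoglobin stage may have dropped below the minimum), the
#' 3 x IQR baseline-outlier rule on biomarkers, and the mean +/- 4 SD
#' rule on cognitive scores. Returns the retained visits together with
#' an auditable per-exclusion report and summary counts.
#'
#' @param x A `biotraj_cohort` or a long visit table.
#' @param config A [filter_config()].
#' @return List with `visits`, `report` (exclusion log), `summary`
#'   (per-stage counts) and `skipped_stages`.
#' @export
apply_filters <- function(x, config = filter_config()) {
  visits <- if (inherits(x, "biotraj_cohort")) x$visits else x
  stopifnot(inherits(config, "filter_config"))
  n_series <- function(v) length(unique(series_key(v)))
  input <- list(rows = nrow(visits), series = n_series(visits),
                subjects = length(unique(visits$subject_id)))
  skipped <- character()

  s1 <- filter_min_visits(visits, config$min_measurements)
  s2 <- filter_hemoglobin(s1$visits, config$hemoglobin_cutoff,
                          marker = config$alpha_syn_marker,
                          drop_missing = config$drop_missing_hemoglobin)
  if (isTRUE(s2$skipped)) skipped <- c(skipped, "hemoglobin")
  # recheck: hemoglobin removes individual samples, which can push a
  # series below the minimum
  s2b <- if (nrow(s2$log)) {
    filter_min_visits(s2$visits, config$min_measurements)
  } else {
    list(visits = s2$visits, log = empty_filter_log())
  }
  biomarkers <- setdiff(unique(s2b$visits$marker), config$cognitive_markers)
  s3 <- filter_baseline_outliers(s2b$visits, markers = biomarkers,
                                 iqr_multiplier = config$iqr_multiplier,
                                 quantile_type = config$quantile_type)
  s4 <- filter_cognitive_outliers(s3$visits,
                                  markers = config$cognitive_markers,
                                  sd_multiplier = config$cognitive_sd_multiplier,
                                  leave_one_out = config$cognitive_leave_one_out)

  report <- rbind(s1$log, s2$log, s2b$log, s3$log, s4$log)
  out <- s4$visits
  stage_counts <- list(
    min_visits = sum(report$stage == "min_visits"),
    hemoglobin_samples = sum(report$stage == "hemoglobin"),
    baseline_outlier = sum(report$stage == "baseline_outlier"),
    cognitive_outlier = sum(report$stage == "cognitive_outlier")
  )
  summary <- list(
    input = input,
    output = list(rows = nrow(out), series = n_series(out),
                  subjects = length(unique(out$subject_id))),
    series_excluded = stage_counts$min_visits +
      stage_counts$baseline_outlier + stage_counts$cognitive_outlier,
    stages = stage_counts
  )
  list(visits = out, report = report, summary = summary,
       skipped_stages = skipped)
}

#' Stratify subjects by cognition and amyloid status
#'
#' PD subjects are cognitively unimpaired (`PDCU`) iff baseline MoCA is
#' strictly greater than the cut-off (25), else cognitively impaired
#' (`PDCI`); amyloid status is `low` iff baseline CSF amyloid-beta 1-42
#' is strictly below the cut-off (683.45 pg/mL), else `high` (a value
#' exactly at the cut-off is `high`). Controls carry `control` in both
#' fields. PD subjects with a missing covariate get `NA` for that
#' stratification only and are listed in the `unclassifiable` attribute.
#'
#' @param covariates Subject covariate table with `subject_id`, `group`,
#'   `moca_baseline`, `abeta_baseline`.
#' @param config A [filter_config()].
#' @return Data.frame `subject_id`, `group`, `cognition`
#'   (PDCU/PDCI/control), `abeta` (high/low/control), with attribute
#'   `unclassifiable`.
#' @export
stratify <- function(covariates, config = filter_config()) {
  stopifnot(all(c("subject_id", "group") %in% names(covariates)))
  is_pd <- covariates$group == "pd"
  moca <- covariates$moca_baseline
  abeta <- covariates$abeta_baseline
  cognition <- ifelse(is_pd,
                      ifelse(moca > config$moca_cutoff, "PDCU", "PDCI"),
                      "control")
  abeta_grp <- ifelse(is_pd,
                      ifelse(abeta < config$abeta_cutoff, "low", "high"),
                      "control")
  out <- data.frame(subject_id = covariates$subject_id,
                    group = covariates$group,
                    cognition = cognition, abeta = abeta_grp,
                    stringsAsFactors = FALSE)
  unclass_df <- data.frame(
    subject_id = c(out$subject_id[is_pd & is.na(cognition)],
                   out$subject_id[is_pd & is.na(abeta_grp)]),
    stratification = c(rep("cognition", sum(is_pd & is.na(cognition))),
                       rep("abeta", sum(is_pd & is.na(abeta_grp)))),
    stringsAsFactors = FALSE)
  if (nrow(unclass_df))
    warning(sprintf("%d subject-stratification pair(s) unclassifiable",
                    nrow(unclass_df)))
  attr(out, "unclassifiable") <- unclass_df
  out
}
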