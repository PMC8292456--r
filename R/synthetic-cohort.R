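# Synthetic PPMI-like cohort generation with known ground truth.

# truncated-normal draws by inverse CDF: a fixed number of RNG draws per
# call, so the generator stays reproducible under any configuration
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(pmin(pmax(rep(mean, n), lower), upper))
  p <- runif(n, pnorm(lower, mean, sd), pnorm(upper, mean, sd))
  qnorm(p, mean, sd)
}

visit_label_from_offset <- function(offset) {
  ifelse(offset == 0, "BL", sprintf("M%02d", round(offset * 12)))
}

#' Generate a synthetic longitudinal cohort
#'
#' Simulates a PPMI-like long-format cohort from the known dynamics in a
#' [cohort_config()]. Each PD subject receives an age at motor onset and
#' a baseline disease duration; visit durations are baseline duration
#' plus the schedule offsets (minus dropout, plus optional unscheduled
#' visits); marker values are the subject's truth trajectory evaluated at
#' the visit duration plus i.i.d. Gaussian noise. Controls are indexed by
#' time from baseline. Planted contaminants (blood-contaminated
#' alpha-synuclein samples, extreme baseline outliers) are recorded in a
#' hidden truth table so filter recovery can be verified.
#'
#' @param config A [cohort_config()].
#' @return An object of class `biotraj_cohort`: a list with
#'   * `visits`: long table (`subject_id`, `group`, `marker`,
#'     `visit_label`, `age`, `duration_years`, `value`,
#'     `hemoglobin_ng_ml`). `duration_years` is disease duration for PD
#'     and time from baseline for controls.
#'   * `covariates`: one row per subject (`subject_id`, `group`,
#'     `age_at_baseline`, `age_at_onset`, `baseline_duration_years`,
#'     `moca_baseline`, `abeta_baseline`).
#'   * `truth`: hidden ground truth (`subjects`, `onset_levels`,
#'     `contaminants`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  old_seed <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()),
          add = TRUE)
  set.seed(config$seed)

  markers <- names(config$pd_dynamics)
  sched <- config$visit_schedule
  n_pd <- config$n_pd; n_ct <- config$n_control
  pd_ids <- sprintf("PD%04d", seq_len(n_pd))
  ct_ids <- sprintf("HC%04d", seq_len(n_ct))

  aao <- rtruncnorm(n_pd, config$aao_mean, config$aao_sd,
                    config$aao_range[1], config$aao_range[2])
  bl_dur <- rtruncnorm(n_pd, config$baseline_duration_mean,
                       config$baseline_duration_sd, 0, Inf)
  ct_age <- rtruncnorm(n_ct, config$control_age_mean, config$control_age_sd,
                       config$aao_range[1], config$aao_range[2])

  # per-subject onset levels (single shared rate curve, heterogeneity in x0)
  onset_pd <- lapply(markers, function(m) {
    x0 <- config$pd_dynamics[[m]]$x0 +
      rnorm(n_pd, 0, config$onset_level_sd[[m]])
    if (config$pd_dynamics[[m]]$family == "logistic")
      x0 <- pmax(x0, 1e-6)
    x0
  })
  names(onset_pd) <- markers
  onset_ct <- lapply(markers, function(m) {
    x0 <- config$control_dynamics[[m]]$x0 +
      rnorm(n_ct, 0, config$onset_level_sd[[m]])
    if (config$control_dynamics[[m]]$family == "logistic")
      x0 <- pmax(x0, 1e-6)
    x0
  })
  names(onset_ct) <- markers

  gen_subject <- function(id, group, t0, age0, dyn_list, onset_row) {
    keep <- c(TRUE, runif(length(sched) - 1L) >= config$dropout_prob)
    offs <- sched[keep]
    labs <- visit_label_from_offset(offs)
    if (runif(1) < config$unscheduled_rate) {
      t_un <- round(runif(1, 0.25, max(sched)), 2)
      offs <- c(offs, t_un)
      labs <- c(labs, "UN")
      ord <- order(offs)
      offs <- offs[ord]; labs <- labs[ord]
    }
    nv <- length(offs)
    per_marker <- lapply(markers, function(m) {
      dyn <- dyn_list[[m]]
      dyn$x0 <- onset_row[[m]]
      true_level(dyn, t0 + offs) + rnorm(nv, 0, config$noise_sd[[m]])
    })
    data.frame(
      subject_id = id, group = group,
      marker = rep(markers, each = nv),
      visit_label = rep(labs, times = length(markers)),
      age = rep(age0 + offs, times = length(markers)),
      duration_years = rep(t0 + offs, times = length(markers)),
      value = unlist(per_marker, use.names = FALSE),
      stringsAsFactors = FALSE
    )
  }

  rows <- vector("list", n_pd + n_ct)
  for (i in seq_len(n_pd)) {
    rows[[i]] <- gen_subject(pd_ids[i], "pd", bl_dur[i], aao[i] + bl_dur[i],
                             config$pd_dynamics,
                             lapply(onset_pd, `[`, i))
  }
  for (i in seq_len(n_ct)) {
    rows[[n_pd + i]] <- gen_subject(ct_ids[i], "control", 0, ct_age[i],
                                    config$control_dynamics,
                                    lapply(onset_ct, `[`, i))
  }
  visits <- do.call(rbind, rows)
  rownames(visits) <- NULL

  contaminants <- data.frame(subject_id = character(), marker = character(),
                             visit_label = character(), type = character(),
                             stringsAsFactors = FALSE)

  # hemoglobin for alpha-synuclein samples; a configured fraction is
  # blood-contaminated (>= 200 ng/mL)
  visits$hemoglobin_ng_ml <- NA_real_
  if ("asyn" %in% markers) {
    ia <- which(visits$marker == "asyn")
    contaminated <- runif(length(ia)) < config$hb_high_fraction
    hb_clean <- runif(length(ia), 20, 150)
    hb_high <- runif(length(ia), 210, 500)
    visits$hemoglobin_ng_ml[ia] <- ifelse(contaminated, hb_high, hb_clean)
    if (any(contaminated)) {
      contaminants <- rbind(contaminants, data.frame(
        subject_id = visits$subject_id[ia[contaminated]],
        marker = "asyn",
        visit_label = visits$visit_label[ia[contaminated]],
        type = "high_hemoglobin", stringsAsFactors = FALSE))
    }
  }

  # planted extreme baseline outliers on PD biomarker baselines; cognitive
  # scores are policed by the mean +/- 4 SD rule instead, so they are not
  # planted here
  if (config$outlier_fraction > 0) {
    n_out <- max(1L, round(config$outlier_fraction * n_pd))
    for (m in setdiff(markers, c("moca", "hvlt_dr", "lns"))) {
      victims <- sample(pd_ids, n_out)
      idx <- which(visits$subject_id %in% victims & visits$marker == m &
                     visits$visit_label == "BL")
      # planted at 10x the population onset level: far beyond any
      # plausible 3xIQR fence for markers whose between-subject SD is
      # small relative to the level, whatever the victim's own draw
      visits$value[idx] <- 10 * config$pd_dynamics[[m]]$x0
      contaminants <- rbind(contaminants, data.frame(
        subject_id = visits$subject_id[idx], marker = m,
        visit_label = "BL", type = "baseline_outlier",
        stringsAsFactors = FALSE))
    }
  }

  bl_value <- function(ids, m) {
    if (!m %in% markers) return(rep(NA_real_, length(ids)))
    bl <- visits[visits$marker == m & visits$visit_label == "BL", ]
    bl$value[match(ids, bl$subject_id)]
  }
  covariates <- data.frame(
    subject_id = c(pd_ids, ct_ids),
    group = c(rep("pd", n_pd), rep("control", n_ct)),
    age_at_baseline = c(aao + bl_dur, ct_age),
    age_at_onset = c(aao, rep(NA_real_, n_ct)),
    baseline_duration_years = c(bl_dur, rep(NA_real_, n_ct)),
    moca_baseline = bl_value(c(pd_ids, ct_ids), "moca"),
    abeta_baseline = bl_value(c(pd_ids, ct_ids), "abeta"),
    stringsAsFactors = FALSE
  )

  truth_subjects <- data.frame(
    subject_id = c(pd_ids, ct_ids),
    group = c(rep("pd", n_pd), rep("control", n_ct)),
    age_at_onset = c(aao, rep(NA_real_, n_ct)),
    baseline_duration_years = c(bl_dur, rep(NA_real_, n_ct)),
    stringsAsFactors = FALSE
  )
  truth_onset <- data.frame(
    subject_id = rep(c(pd_ids, ct_ids), times = length(markers)),
    marker = rep(markers, each = n_pd + n_ct),
    onset_level = unlist(lapply(markers, function(m)
      c(onset_pd[[m]], onset_ct[[m]])), use.names = FALSE),
    stringsAsFactors = FALSE
  )

  structure(
    list(visits = visits, covariates = covariates,
         truth = list(subjects = truth_subjects,
                      onset_levels = truth_onset,
                      contaminants = contaminants),
         config = config),
    class = "biotraj_cohort"
  )
}

#' @export
print.biotraj_cohort <- function(x, ...) {
  cat("<biotraj_cohort>", sum(x$covariates$group == "pd"), "PD /",
      sum(x$covariates$group == "control"), "control subjects,",
      nrow(x$visits), "visit rows,",
      length(unique(x$visits$marker)), "markers\n")
  invisible(x)
}

#' Write / read a cohort as plain CSV files
#'
#' `write_cohort()` writes `visits.csv`, `covariates.csv` and (when truth
#' is present) `truth_subjects.csv`, `truth_onset_levels.csv`,
#' `truth_contaminants.csv` into `dir`; `read_cohort()` reads them back.
#'
#' @param cohort A `biotraj_cohort` or a list with at least `visits` and
#'   `covariates`.
#' @param dir Directory (created if missing).
#' @return `write_cohort()` the directory, invisibly; `read_cohort()` a
#'   `biotraj_cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(cohort$visits, file.path(dir, "visits.csv"), row.names = FALSE)
  write.csv(cohort$covariates, file.path(dir, "covariates.csv"),
            row.names = FALSE)
  if (!is.null(cohort$truth)) {
    write.csv(cohort$truth$subjects, file.path(dir, "truth_subjects.csv"),
              row.names = FALSE)
    write.csv(cohort$truth$onset_levels,
              file.path(dir, "truth_onset_levels.csv"), row.names = FALSE)
    write.csv(cohort$truth$contaminants,
              file.path(dir, "truth_contaminants.csv"), row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  visits <- read.csv(file.path(dir, "visits.csv"), stringsAsFactors = FALSE)
  covariates <- read.csv(file.path(dir, "covariates.csv"),
                         stringsAsFactors = FALSE)
  truth <- NULL
  if (file.exists(file.path(dir, "truth_subjects.csv"))) {
    truth <- list(
      subjects = read.csv(file.path(dir, "truth_subjects.csv"),
                          stringsAsFactors = FALSE),
      onset_levels = read.csv(file.path(dir, "truth_onset_levels.csv"),
                              stringsAsFactors = FALSE),
      contaminants = read.csv(file.path(dir, "truth_contaminants.csv"),
                              stringsAsFactors = FALSE)
    )
  }
  structure(list(visits = visits, covariates = covariates, truth = truth),
            class = "biotraj_cohort")
}
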