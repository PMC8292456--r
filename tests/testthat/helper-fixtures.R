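# Fixtures built in code: a hand-crafted 12-subject filter table with
# planted rule violations, and reusable synthetic-cohort configurations.

# 12 PD subjects; markers asyn (3 visits), abeta (2 visits), moca
# (2 visits). Planted violations:
#   S01: single asyn visit                  -> insufficient_visits
#   S02, S03: one asyn sample each with
#             hemoglobin >= 200 ng/mL      -> high_hemoglobin (2 samples)
#   S04: abeta baseline 5000               -> baseline_outlier
#   S05: moca baseline 5                   -> cognitive_outlier
make_filter_fixture <- function() {
  ids <- sprintf("S%02d", 1:12)
  rows <- list()
  add <- function(sid, marker, durations, values, labels, hb = NA_real_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      subject_id = sid, group = "pd", marker = marker,
      visit_label = labels, age = 60 + durations,
      duration_years = durations, value = values,
      hemoglobin_ng_ml = hb, stringsAsFactors = FALSE)
  }
  asyn_base <- seq(1450, 1560, by = 10)    # 12 spread values
  for (i in seq_along(ids)) {
    sid <- ids[i]
    if (sid == "S01") {
      add(sid, "asyn", 2, asyn_base[i], "BL", hb = 50)
    } else {
      hb <- c(50, 60, 70)
      if (sid == "S02") hb[2] <- 250
      if (sid == "S03") hb[3] <- 300
      add(sid, "asyn", c(2, 2.5, 3), asyn_base[i] - c(0, 5, 10),
          c("BL", "M06", "M12"), hb = hb)
    }
    ab <- 900 + 15 * i
    if (sid == "S04") ab <- 5000
    add(sid, "abeta", c(2, 3), c(ab, ab - 20), c("BL", "M12"))
    mo <- c(26, 27, 28, 29)[(i %% 4) + 1]
    if (sid == "S05") mo <- 5
    add(sid, "moca", c(2, 3), c(mo, mo), c("BL", "M12"))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# the end-to-end recovery experiment conditions: 400 PD subjects, truth
# dX/dt = -0.08 (X - 600) from X0 = 1000, measurement noise SD 20, six
# six-monthly visits, baseline duration ~ truncated Normal(2, 2),
# between-subject onset-level SD 150
recovery_config <- function(seed = 42L) {
  cohort_config(
    n_pd = 400L, n_control = 50L,
    pd_dynamics = list(
      abeta = truth_dynamics("exponential_approach", x0 = 1000, k = 0.08,
                             plateau = 600)),
    control_dynamics = list(abeta = truth_dynamics("constant", x0 = 1000)),
    noise_sd = c(abeta = 20), onset_level_sd = c(abeta = 150),
    baseline_duration_mean = 2, baseline_duration_sd = 2,
    visit_schedule = c(0, 0.5, 1, 1.5, 2, 2.5),
    dropout_prob = 0, unscheduled_rate = 0, hb_high_fraction = 0,
    outlier_fraction = 0, seed = seed)
}

# run the recovery experiment; returns the fitted model, trajectory and
# truth comparison
run_recovery <- function(seed = 42L) {
  cohort <- generate_cohort(recovery_config(seed))
  filt <- apply_filters(cohort)
  kin <- fit_kinetics(filt$visits)
  kin_pd <- kin[kin$group == "pd", ]
  model <- fit_rate_model(kin_pd$baseline_level, kin_pd$rate,
                          n_subjects = nrow(kin_pd),
                          marker = "abeta", stratum = "pd")
  traj <- integrate_trajectory(model, anchor = onset_anchor(kin_pd),
                               t_min = -5, t_max = 30, h = 0.01,
                               marker = "abeta", stratum = "pd")
  grid <- traj$time[traj$time >= 0 & traj$time <= 20]
  est <- traj$level[traj$time >= 0 & traj$time <= 20]
  truth <- 600 + 400 * exp(-0.08 * grid)
  list(model = model, traj = traj,
       rmse = sqrt(mean((est - truth)^2)),
       roots = rate_roots(model))
}

# a small, fast cohort for pipeline-level tests
small_cohort_config <- function(seed = 11L, ...) {
  cohort_config(
    n_pd = 60L, n_control = 30L,
    pd_dynamics = default_pd_dynamics()[c("abeta", "nfl", "moca")],
    control_dynamics = default_control_dynamics()[c("abeta", "nfl", "moca")],
    noise_sd = default_noise_sd()[c("abeta", "nfl", "moca")],
    onset_level_sd = default_onset_level_sd()[c("abeta", "nfl", "moca")],
    seed = seed, ...)
}
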