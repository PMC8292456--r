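#' Default ground-truth dynamics for a PD-like synthetic cohort
#'
#' Shapes and scales echo the published baseline means and the reported
#' qualitative dynamics: amyloid-beta and alpha-synuclein decline toward a
#' plateau (negative exponential), the tau species rise slowly toward a
#' plateau, neurofilament light rises along a sigmoid, and cognitive
#' scores decline slowly. Controls sit at a constant level equal to the
#' control baseline mean.
#'
#' @return Named list of [truth_dynamics()] objects, one per marker.
#' @export
default_pd_dynamics <- function() {
  list(
    abeta   = truth_dynamics("exponential_approach", x0 = 916,  k = 0.25, plateau = 800),
    asyn    = truth_dynamics("exponential_approach", x0 = 1529, k = 0.15, plateau = 1100),
    ttau    = truth_dynamics("exponential_approach", x0 = 161,  k = 0.08, plateau = 240),
    ptau    = truth_dynamics("exponential_approach", x0 = 14.2, k = 0.05, plateau = 20),
    nfl     = truth_dynamics("logistic",             x0 = 12.1, k = 0.15, capacity = 32),
    moca    = truth_dynamics("exponential_approach", x0 = 27.1, k = 0.03, plateau = 18),
    hvlt_dr = truth_dynamics("exponential_approach", x0 = 44.8, k = 0.04, plateau = 30),
    lns     = truth_dynamics("exponential_approach", x0 = 10.6, k = 0.04, plateau = 7)
  )
}

#' @rdname default_pd_dynamics
#' @export
default_control_dynamics <- function() {
  list(
    abeta   = truth_dynamics("constant", x0 = 1022.6),
    asyn    = truth_dynamics("constant", x0 = 1701.3),
    ttau    = truth_dynamics("constant", x0 = 192.9),
    ptau    = truth_dynamics("constant", x0 = 17.6),
    nfl     = truth_dynamics("constant", x0 = 12.4),
    moca    = truth_dynamics("constant", x0 = 28.2),
    hvlt_dr = truth_dynamics("constant", x0 = 48.8),
    lns     = truth_dynamics("constant", x0 = 10.9)
  )
}

default_noise_sd <- function() {
  c(abeta = 50, asyn = 75, ttau = 8, ptau = 0.8, nfl = 1.2,
    moca = 1, hvlt_dr = 3, lns = 1)
}

default_onset_level_sd <- function() {
  c(abeta = 400, asyn = 650, ttau = 55, ptau = 5, nfl = 6,
    moca = 1.5, hvlt_dr = 10, lns = 2.5)
}

#' Configuration for a synthetic PPMI-like cohort
#'
#' Bundles every knob of the synthetic-cohort generator. The defaults
#' mimic the published study conditions: 396 PD and 182 control subjects,
#' baseline disease duration ~ truncated Normal(2, 2) years, the
#' BL/6M/.../72M visit schedule (42M is not part of the protocol), and
#' per-visit dropout after baseline.
#'
#' @param n_pd,n_control Subject counts (> 0).
#' @param pd_dynamics,control_dynamics Named lists of [truth_dynamics()],
#'   same marker names in both.
#' @param noise_sd Named numeric, additive Gaussian measurement noise SD
#'   per marker (marker units, >= 0).
#' @param onset_level_sd Named numeric, between-subject SD of the onset
#'   level `x0` per marker (>= 0). Heterogeneity enters only through the
#'   onset level; all subjects share one population rate curve, matching
#'   the estimation method's own assumption.
#' @param baseline_duration_mean,baseline_duration_sd Mean/SD (years) of
#'   PD disease duration at the baseline visit; the draw is truncated at
#'   zero.
#' @param visit_schedule Visit offsets from baseline in years.
#' @param dropout_prob Per-visit probability of a missed visit after
#'   baseline (baseline is always kept).
#' @param unscheduled_rate Probability that a subject contributes one
#'   extra unscheduled ("UN") visit at a uniform time within the
#'   schedule; unscheduled visits are treated identically downstream.
#' @param hb_high_fraction Fraction of alpha-synuclein samples drawn with
#'   hemoglobin >= 200 ng/mL (blood-contaminated; the downstream filter
#'   should remove them).
#' @param outlier_fraction Fraction of PD subjects per biomarker whose
#'   baseline value is planted as an extreme outlier (value scaled by
#'   10), to exercise the 3xIQR filter.
#' @param aao_mean,aao_sd,aao_range Age-at-onset distribution for PD
#'   subjects: Normal truncated to `aao_range`.
#' @param control_age_mean,control_age_sd Baseline-age distribution for
#'   controls (same truncation range as `aao_range`).
#' @param seed Integer RNG seed; identical configs give byte-identical
#'   cohorts.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_pd = 396L,
                          n_control = 182L,
                          pd_dynamics = default_pd_dynamics(),
                          control_dynamics = default_control_dynamics(),
                          noise_sd = default_noise_sd(),
                          onset_level_sd = default_onset_level_sd(),
                          baseline_duration_mean = 2,
                          baseline_duration_sd = 2,
                          visit_schedule = c(0, 0.5, 1, 1.5, 2, 2.5, 3,
                                             4, 4.5, 5, 5.5, 6),
                          dropout_prob = 0.15,
                          unscheduled_rate = 0.05,
                          hb_high_fraction = 0.02,
                          outlier_fraction = 0,
                          aao_mean = 60, aao_sd = 10,
                          aao_range = c(30, 90),
                          control_age_mean = 61, control_age_sd = 11,
                          seed = 20210720L) {
  n_pd <- as.integer(n_pd); n_control <- as.integer(n_control)
  if (n_pd <= 0L || n_control <= 0L)
    stop("subject counts must be positive")
  markers <- names(pd_dynamics)
  if (is.null(markers) || any(!nzchar(markers)))
    stop("'pd_dynamics' must be a named list of truth_dynamics")
  if (!setequal(markers, names(control_dynamics)))
    stop("'pd_dynamics' and 'control_dynamics' must cover the same markers")
  for (d in c(pd_dynamics, control_dynamics))
    if (!inherits(d, "truth_dynamics"))
      stop("every dynamics entry must be a truth_dynamics object")
  noise_sd <- noise_sd[markers]
  onset_level_sd <- onset_level_sd[markers]
  if (anyNA(noise_sd) || anyNA(onset_level_sd))
    stop("'noise_sd' and 'onset_level_sd' must name every marker")
  if (any(noise_sd < 0) || any(onset_level_sd < 0))
    stop("noise and onset-level SDs must be >= 0")
  probs <- c(dropout_prob, unscheduled_rate, hb_high_fraction,
             outlier_fraction)
  if (any(probs < 0) || any(probs > 1))
    stop("probabilities must lie in [0, 1]")
  if (baseline_duration_sd < 0 || aao_sd < 0 || control_age_sd < 0)
    stop("SD parameters must be >= 0")
  if (length(visit_schedule) < 1L || visit_schedule[1] != 0 ||
      is.unsorted(visit_schedule, strictly = TRUE))
    stop("'visit_schedule' must start at 0 and be strictly increasing")
  structure(
    list(n_pd = n_pd, n_control = n_control,
         pd_dynamics = pd_dynamics, control_dynamics = control_dynamics,
         noise_sd = noise_sd, onset_level_sd = onset_level_sd,
         baseline_duration_mean = baseline_duration_mean,
         baseline_duration_sd = baseline_duration_sd,
         visit_schedule = visit_schedule,
         dropout_prob = dropout_prob,
         unscheduled_rate = unscheduled_rate,
         hb_high_fraction = hb_high_fraction,
         outlier_fraction = outlier_fraction,
         aao_mean = aao_mean, aao_sd = aao_sd, aao_range = aao_range,
         control_age_mean = control_age_mean,
         control_age_sd = control_age_sd,
         seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' Read a cohort configuration from YAML
#'
#' Top-level YAML keys mirror the arguments of [cohort_config()];
#' `pd_dynamics`/`control_dynamics` entries are maps with the fields of
#' [truth_dynamics()] (`family`, `x0`, `k`, `plateau`, `capacity`).
#'
#' @param path Path to a YAML file.
#' @return A `cohort_config` object.
#' @export
read_cohort_config <- function(path) {
  raw <- yaml::read_yaml(path)
  for (fld in c("pd_dynamics", "control_dynamics"))
    if (!is.null(raw[[fld]]))
      raw[[fld]] <- lapply(raw[[fld]], function(d) do.call(truth_dynamics, d))
  for (fld in c("noise_sd", "onset_level_sd"))
    if (!is.null(raw[[fld]])) raw[[fld]] <- unlist(raw[[fld]])
  for (fld in c("visit_schedule", "aao_range"))
    if (!is.null(raw[[fld]])) raw[[fld]] <- as.numeric(unlist(raw[[fld]]))
  do.call(cohort_config, raw)
}
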