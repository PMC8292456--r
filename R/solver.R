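# Trajectory integration: modified Euler solution of dX/dt = f(X),
# control anchoring in age space, z-scoring, summary quantities.

#' One modified-Euler (Heun) step
#'
#' Predictor-corrector trapezoidal step
#' `x' = x + (h/2) (f(x) + f(x + h f(x)))`; second-order accurate and
#' exact for constant rate. `midpoint_step()` is the other common
#' "modified Euler" reading, `x' = x + h f(x + (h/2) f(x))`, also second
#' order.
#'
#' @param x Current level.
#' @param h Step (years); negative for backward integration.
#' @param f Rate function of one argument.
#' @return Next level.
#' @export
heun_step <- function(x, h, f) {
  k1 <- f(x)
  x + h / 2 * (k1 + f(x + h * k1))
}

#' @rdname heun_step
#' @export
midpoint_step <- function(x, h, f) {
  x + h * f(x + h / 2 * f(x))
}

# wrap a rate model in a rate-clamping closure: outside the
# extrapolation corridor (fit_range widened by corridor_frac of its
# width on each side) the rate is held at the corridor-edge value, so
# the natural-spline linear tails cannot drive unbounded blow-up; every
# clamp is counted
make_rate_function <- function(model, corridor_frac = 0.25) {
  if (is.function(model))
    return(list(f = model, clamp_count = function() 0L,
                corridor = c(-Inf, Inf)))
  stopifnot(inherits(model, "rate_model"))
  fr <- model$fit_range
  w <- diff(fr)
  lo <- fr[1] - corridor_frac * w
  hi <- fr[2] + corridor_frac * w
  env <- new.env(parent = emptyenv())
  env$n <- 0L
  f <- function(x) {
    if (x < lo || x > hi) {
      env$n <- env$n + 1L
      x <- min(max(x, lo), hi)
    }
    evaluate_rate(model, x)
  }
  list(f = f, clamp_count = function() env$n, corridor = c(lo, hi))
}

#' Integrate a trajectory from an anchor
#'
#' Solves `dX/dt = f(X)` with the modified Euler method, forward from
#' the anchor to `t_max` and backward to `t_min` (the premotor segment
#' is integrated backward from onset). The level at the anchor time
#' equals the anchor exactly. When `model` is a fitted [fit_rate_model()]
#' the rate is clamped at the edges of the extrapolation corridor
#' (`fit_range` widened by `corridor_frac` of its width); clamp events
#' are counted in the diagnostics. Negative levels are allowed but
#' produce a warning.
#'
#' @param model A `rate_model` or a plain rate function of one argument.
#' @param anchor Level at `t_anchor` (marker units).
#' @param t_min,t_max Estimation window in years from motor onset
#'   (default -5 to +30).
#' @param h Integration step in years (> 0; default 0.01).
#' @param t_anchor Anchor time (0 for PD groups; controls are anchored
#'   at their re-indexed median baseline age).
#' @param method `"heun"` (trapezoidal predictor-corrector, default) or
#'   `"midpoint"`.
#' @param corridor_frac Corridor half-widening as a fraction of the
#'   fitting-range width.
#' @param divergence_factor Abort when |level| exceeds this multiple of
#'   max(|anchor|, 1).
#' @return A `biotraj_trajectory`: data.frame `time`, `level` on the
#'   regular grid `t_anchor + k h` covering the window, with attributes
#'   `anchor`, `h`, `method`, `diagnostics` (clamp count, corridor,
#'   negative-level count).
#' @examples
#' tr <- integrate_trajectory(function(x) -0.1 * x, anchor = 100,
#'                            t_min = 0, t_max = 30)
#' max(abs(tr$level - 100 * exp(-0.1 * tr$time)))
#' @export
integrate_trajectory <- function(model, anchor, t_min = -5, t_max = 30,
                                 h = 0.01, t_anchor = 0,
                                 method = c("heun", "midpoint"),
                                 corridor_frac = 0.25,
                                 divergence_factor = 1e6,
                                 marker = NA_character_,
                                 stratum = NA_character_) {
  method <- match.arg(method)
  stopifnot(is.finite(anchor), h > 0, t_min < t_max,
            t_anchor >= t_min - 1e-9, t_anchor <= t_max + 1e-9)
  rf <- make_rate_function(model, corridor_frac)
  f <- rf$f
  step <- if (method == "heun") heun_step else midpoint_step
  bound <- divergence_factor * max(abs(anchor), 1)

  march <- function(n_steps, hh) {
    out <- numeric(n_steps)
    x <- anchor
    for (i in seq_len(n_steps)) {
      fx <- f(x)
      if (!is.finite(fx))
        stop(sprintf(
          "non-finite rate at level %.6g (t = %.3f); integration aborted",
          x, t_anchor + i * hh))
      x <- step(x, hh, f)
      if (!is.finite(x) || abs(x) > bound)
        stop(sprintf(
          "trajectory diverged at t = %.3f (level %.6g); integration aborted",
          t_anchor + i * hh, x))
      out[i] <- x
    }
    out
  }

  n_f <- max(0L, as.integer(ceiling((t_max - t_anchor) / h - 1e-9)))
  n_b <- max(0L, as.integer(ceiling((t_anchor - t_min) / h - 1e-9)))
  fwd <- march(n_f, h)
  bwd <- march(n_b, -h)
  time <- c(t_anchor - h * rev(seq_len(n_b)), t_anchor,
            t_anchor + h * seq_len(n_f))
  level <- c(rev(bwd), anchor, fwd)
  n_neg <- sum(level < 0)
  if (n_neg > 0L)
    warning(sprintf("trajectory reaches negative levels at %d grid point(s)",
                    n_neg))
  structure(
    data.frame(time = time, level = level),
    class = c("biotraj_trajectory", "data.frame"),
    marker = marker, stratum = stratum,
    anchor = list(time = t_anchor, level = anchor),
    h = h, method = method,
    diagnostics = list(n_clamped = rf$clamp_count(),
                       corridor = rf$corridor, n_negative = n_neg)
  )
}

#' @export
print.biotraj_trajectory <- function(x, ...) {
  a <- attr(x, "anchor")
  cat("<biotraj_trajectory>", attr(x, "marker"), "/", attr(x, "stratum"),
      "\n  grid:", nrow(x), "points over [",
      signif(min(x$time), 4), ",", signif(max(x$time), 4),
      "] y; anchor", signif(a$level, 6), "at t =", signif(a$time, 4), "\n")
  invisible(x)
}

#' Control baseline reference
#'
#' Per-marker mean and SD of the control baseline values (used for
#' z-scoring and as the control anchor level), the median control
#' baseline age, and the median PD age at motor onset (used to convert
#' age into disease duration: duration = age - median AAO).
#'
#' @param visits Long visit table.
#' @param covariates Subject covariate table with `age_at_baseline` and
#'   `age_at_onset`.
#' @return An object of class `control_reference`.
#' @export
control_reference <- function(visits, covariates) {
  bl <- baseline_rows(visits)
  bl <- bl[bl$group == "control", , drop = FALSE]
  if (nrow(bl) == 0L) stop("no control baseline measurements")
  stats <- do.call(rbind, lapply(split(bl$value, bl$marker), function(v) {
    data.frame(mean = mean(v), sd = sd(v), n = length(v))
  }))
  stats$marker <- rownames(stats)
  rownames(stats) <- NULL
  ctrl_age <- covariates$age_at_baseline[covariates$group == "control"]
  pd_aao <- covariates$age_at_onset[covariates$group == "pd"]
  structure(
    list(markers = stats[, c("marker", "mean", "sd", "n")],
         median_control_age = median(ctrl_age, na.rm = TRUE),
         median_pd_aao = median(pd_aao, na.rm = TRUE)),
    class = "control_reference"
  )
}

#' @export
print.control_reference <- function(x, ...) {
  cat("<control_reference> median control baseline age",
      signif(x$median_control_age, 4), "y; median PD AAO",
      signif(x$median_pd_aao, 4), "y\n")
  print(x$markers, row.names = FALSE)
  invisible(x)
}

ref_marker_stats <- function(reference, marker) {
  i <- match(marker, reference$markers$marker)
  if (is.na(i))
    stop(sprintf("marker '%s' absent from the control reference", marker))
  reference$markers[i, ]
}

#' Anchor and integrate a control trajectory on the duration axis
#'
#' Controls have no motor onset, so their trajectory is anchored in age
#' space: integration starts at the median control baseline age with the
#' control mean baseline level and the resulting age axis is re-indexed
#' to disease duration via `duration = age - median PD age at onset`, so
#' control and PD trajectories share a common time axis.
#'
#' @param model Control-group `rate_model` for the marker.
#' @param reference A [control_reference()].
#' @param marker Marker name.
#' @inheritParams integrate_trajectory
#' @return A `biotraj_trajectory` on the duration axis
#'   (stratum `"control"`).
#' @export
anchor_control_trajectory <- function(model, reference, marker,
                                      t_min = -5, t_max = 30, h = 0.01,
                                      method = c("heun", "midpoint"),
                                      corridor_frac = 0.25) {
  stopifnot(inherits(reference, "control_reference"))
  if (!is.finite(reference$median_control_age) ||
      !is.finite(reference$median_pd_aao))
    stop("control reference is missing the median ages")
  st <- ref_marker_stats(reference, marker)
  t_anchor <- reference$median_control_age - reference$median_pd_aao
  if (t_anchor < t_min || t_anchor > t_max)
    stop(sprintf(
      "control anchor (duration %.2f y) falls outside the window [%g, %g]",
      t_anchor, t_min, t_max))
  integrate_trajectory(model, anchor = st$mean, t_min = t_min,
                       t_max = t_max, h = h, t_anchor = t_anchor,
                       method = method, corridor_frac = corridor_frac,
                       marker = marker, stratum = "control")
}

#' Convert a trajectory to z-scores
#'
#' `z(t) = (x(t) - mu_c) / sigma_c` with the control *baseline* mean and
#' SD for the marker.
#'
#' @param traj A `biotraj_trajectory`.
#' @param reference A [control_reference()].
#' @param marker Marker name (defaults to the trajectory's own).
#' @return The trajectory with a `z` column added.
#' @export
to_zscores <- function(traj, reference, marker = attr(traj, "marker")) {
  st <- ref_marker_stats(reference, marker)
  if (!is.finite(st$sd) || st$sd <= 0)
    stop(sprintf("control baseline SD for '%s' must be positive", marker))
  traj$z <- (traj$level - st$mean) / st$sd
  traj
}

#' Percent change of a trajectory between two time points
#'
#' `100 (x(t_to) - x(t_from)) / x(t_from)`, the convention used to
#' report overall change over the 30 years after motor onset.
#'
#' @param traj A trajectory data.frame with `time` and `level`.
#' @param t_from,t_to Times in years (must lie within the grid; values
#'   between grid points are linearly interpolated).
#' @return Percent change (single number).
#' @export
percent_change <- function(traj, t_from = 0, t_to = 30) {
  lv <- approx(traj$time, traj$level, xout = c(t_from, t_to), rule = 1)$y
  if (anyNA(lv))
    stop("requested times fall outside the trajectory grid")
  if (lv[1] == 0)
    stop("level at 't_from' is zero; percent change undefined")
  100 * (lv[2] - lv[1]) / lv[1]
}

#' First crossing time of two trajectories (or a constant)
#'
#' The earliest time at which `a - b` changes sign, refined by linear
#' interpolation within the bracketing grid interval. Used for
#' PD-versus-control crossings and for z-score zero crossings
#' (`find_crossing(traj, 0, value = "z")`).
#'
#' @param a Trajectory data.frame.
#' @param b Trajectory data.frame or a single numeric constant.
#' @param value Column compared (`"level"` or `"z"`).
#' @return Crossing time in years, or `numeric(0)` when the curves do
#'   not cross on the common grid.
#' @export
find_crossing <- function(a, b = 0, value = "level") {
  ta <- a$time; va <- a[[value]]
  if (is.data.frame(b)) {
    lo <- max(min(ta), min(b$time))
    hi <- min(max(ta), max(b$time))
    keep <- ta >= lo - 1e-12 & ta <= hi + 1e-12
    ta <- ta[keep]
    d <- va[keep] - approx(b$time, b[[value]], xout = ta, rule = 2)$y
  } else {
    stopifnot(is.numeric(b), length(b) == 1L)
    d <- va - b
  }
  if (length(d) < 2L || all(d == 0)) return(numeric(0))
  zero <- which(d == 0)
  if (length(zero)) return(ta[zero[1]])
  chg <- which(d[-length(d)] * d[-1] < 0)
  if (!length(chg)) return(numeric(0))
  i <- chg[1]
  ta[i] + (ta[i + 1] - ta[i]) * d[i] / (d[i] - d[i + 1])
}
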