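# Modified-Euler integration, anchoring, z-scores, crossings.

test_that("single Heun and midpoint steps match hand calculations", {
  f <- function(x) -x
  expect_equal(heun_step(1, 0.1, f), 0.905)        # 1 + 0.05(-1 - 0.9)
  expect_equal(midpoint_step(1, 0.1, f), 1 - 0.1 * 0.95)
  # exact for constant rate, identity for zero rate
  expect_equal(heun_step(3, 0.25, function(x) 4), 4)
  expect_equal(heun_step(3, 0.25, function(x) 0), 3)
})

test_that("exponential decay is integrated to < 1e-3 relative error", {
  tr <- integrate_trajectory(function(x) -0.1 * x, anchor = 100,
                             t_min = 0, t_max = 30, h = 0.01)
  truth <- 100 * exp(-0.1 * tr$time)
  expect_lt(max(abs(tr$level - truth) / truth), 1e-3)
  expect_equal(tr$level[tr$time == 0], 100)        # anchor exact
  # deSolve cross-check on the same problem
  if (requireNamespace("deSolve", quietly = TRUE)) {
    ref <- deSolve::ode(c(x = 100), seq(0, 30, 1),
                        function(t, y, p) list(-0.1 * y))
    expect_equal(approx(tr$time, tr$level, xout = ref[, 1])$y,
                 unname(ref[, 2]), tolerance = 1e-5)
  }
})

test_that("both schemes converge at second order", {
  f <- function(x) -0.1 * x
  err <- function(h, method) {
    tr <- integrate_trajectory(f, 100, t_min = 0, t_max = 30, h = h,
                               method = method)
    max(abs(tr$level - 100 * exp(-0.1 * tr$time)))
  }
  for (method in c("heun", "midpoint")) {
    ratio <- err(0.01, method) / err(0.005, method)
    expect_gt(ratio, 3.5)
    expect_lt(ratio, 4.5)
  }
})

test_that("constant rate gives an exact line across the whole window", {
  # the premotor half of the line is negative, which is allowed but
  # flagged
  expect_warning(tr <- integrate_trajectory(function(x) 2, anchor = 0),
                 "negative")
  expect_equal(tr$level, 2 * tr$time, tolerance = 1e-9)
  expect_equal(approx(tr$time, tr$level, -5)$y, -10, tolerance = 1e-9)
})

test_that("forward-then-backward integration returns to the anchor", {
  f <- function(x) -0.1 * x
  tr <- integrate_trajectory(f, 100, t_min = 0, t_max = 30, h = 0.01)
  x <- tr$level[nrow(tr)]
  for (i in 1:3000) x <- heun_step(x, -0.01, f)
  expect_lt(abs(x - 100), 1e-3)
})

test_that("trajectories approach a stable root monotonically without crossing", {
  f <- function(x) -0.1 * (x - 600)
  tr <- integrate_trajectory(f, anchor = 1000, t_min = 0, t_max = 30)
  expect_true(all(diff(tr$level) < 0))
  expect_true(all(tr$level > 600))
})

test_that("rates are clamped outside the extrapolation corridor", {
  set.seed(10)
  x <- runif(50, 90, 110)                  # narrow observed range
  m <- fit_rate_model(x, rep(-5, 50), knots = c(92, 100, 108))
  tr <- integrate_trajectory(m, anchor = 100, t_min = 0, t_max = 10)
  diag <- attr(tr, "diagnostics")
  expect_gt(diag$n_clamped, 0)
  # clamped rate stays at the corridor-edge value: linear decline
  late <- tr[tr$time > 5, ]
  expect_equal(diff(late$level), rep(-5 * 0.01, nrow(late) - 1),
               tolerance = 1e-9)
})

test_that("divergent and non-finite dynamics abort with diagnostics", {
  expect_error(integrate_trajectory(function(x) x^2, anchor = 10,
                                    t_min = 0, t_max = 30),
               "diverged")
  expect_error(integrate_trajectory(function(x) NaN, anchor = 1,
                                    t_min = 0, t_max = 1),
               "non-finite")
})

make_reference <- function(mu = 1000, sdv = 100, ctrl_age = 61,
                           pd_aao = 60) {
  structure(list(
    markers = data.frame(marker = "abeta", mean = mu, sd = sdv, n = 50),
    median_control_age = ctrl_age, median_pd_aao = pd_aao),
    class = "control_reference")
}

test_that("control anchoring re-indexes age as duration = age - median AAO", {
  ref <- make_reference(ctrl_age = 61.5, pd_aao = 60)
  set.seed(11)
  x <- runif(60, 800, 1200)
  m0 <- fit_rate_model(x, rep(0, 60) + 1e-14 * x, marker = "abeta")
  tr <- anchor_control_trajectory(m0, ref, "abeta")
  # flat at the control mean
  expect_equal(tr$level, rep(1000, nrow(tr)), tolerance = 1e-9)
  # anchor sits at duration = 61.5 - 60 = 1.5, grid covers the window
  expect_equal(attr(tr, "anchor")$time, 1.5)
  expect_true(any(tr$time == 1.5))
  expect_lte(min(tr$time), -5 + 1e-9)
  expect_gte(max(tr$time), 30 - 1e-9)
  # identical medians put the anchor at duration zero
  tr0 <- anchor_control_trajectory(
    m0, make_reference(ctrl_age = 60, pd_aao = 60), "abeta")
  expect_equal(attr(tr0, "anchor")$time, 0)
})

test_that("a slow linear control drift is recovered on the duration axis", {
  # controls drifting 0.5 units/year, zero noise
  cc <- cohort_config(
    n_pd = 30L, n_control = 40L,
    pd_dynamics = list(abeta = truth_dynamics("exponential_approach",
                                              x0 = 1000, k = 0.1,
                                              plateau = 600)),
    control_dynamics = list(abeta = truth_dynamics(
      "exponential_approach", x0 = 1000, k = 1e-4,
      plateau = 1000 + 0.5 / 1e-4)),
    noise_sd = c(abeta = 0), onset_level_sd = c(abeta = 30),
    dropout_prob = 0, unscheduled_rate = 0, hb_high_fraction = 0,
    seed = 12L)
  co <- generate_cohort(cc)
  kin <- fit_kinetics(co$visits)
  kc <- kin[kin$group == "control", ]
  m <- fit_rate_model(kc$baseline_level, kc$rate, n_subjects = nrow(kc),
                      marker = "abeta", stratum = "control")
  ref <- control_reference(co$visits, co$covariates)
  tr <- anchor_control_trajectory(m, ref, "abeta")
  slope <- coef(lm(level ~ time, tr))[["time"]]
  expect_equal(slope, 0.5, tolerance = 0.02)
})

test_that("z-scores are the level in control-baseline SD units", {
  ref <- make_reference(mu = 1000, sdv = 100)
  tr <- integrate_trajectory(function(x) 0, anchor = 1100, t_min = 0,
                             t_max = 1, marker = "abeta")
  trz <- to_zscores(tr, ref)
  expect_equal(unique(trz$z), 1)
  tr0 <- to_zscores(
    integrate_trajectory(function(x) 0, anchor = 1000, t_min = 0,
                         t_max = 1, marker = "abeta"), ref)
  expect_equal(unique(tr0$z), 0)
  ref0 <- make_reference(sdv = 0)
  expect_error(to_zscores(tr, ref0), "positive")
})

test_that("percent change matches its definition and the truth closed form", {
  tr <- data.frame(time = c(0, 15, 30), level = c(100, 94, 88))
  expect_equal(percent_change(tr), -12)
  flat <- data.frame(time = 0:30, level = rep(7, 31))
  expect_equal(percent_change(flat), 0)
  dyn <- truth_dynamics("exponential_approach", x0 = 1000, k = 0.1,
                        plateau = 600)
  tt <- true_trajectory(dyn, seq(0, 30, 0.5))
  expect_equal(percent_change(tt),
               100 * (600 + 400 * exp(-3) - 1000) / 1000,
               tolerance = 1e-10)
  expect_error(percent_change(flat, 0, 40), "outside")
  expect_error(percent_change(data.frame(time = 0:30, level = 0)),
               "undefined|zero")
})

test_that("crossings are found by linear interpolation, or empty", {
  a <- data.frame(time = 0:10, level = (0:10) - 5)
  expect_equal(find_crossing(a, 0), 5)
  below <- data.frame(time = 0:10, level = rep(-1, 11))
  expect_length(find_crossing(below, 0), 0)
  t <- seq(0, 30, 0.01)
  aexp <- data.frame(time = t, level = 100 * exp(-0.1 * t))
  expect_equal(find_crossing(aexp, 50), 10 * log(2), tolerance = 1e-4)
  # trajectory-vs-trajectory on a common grid
  b <- data.frame(time = t, level = rep(50, length(t)))
  expect_equal(find_crossing(aexp, b), 10 * log(2), tolerance = 1e-4)
  expect_length(find_crossing(b, b), 0)   # identical curves never cross
  # z-column crossing
  az <- data.frame(time = 0:10, level = 1:11, z = (0:10) / 2 - 2.5)
  expect_equal(find_crossing(az, 0, value = "z"), 5)
})
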