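# Inclusion/exclusion rules: boundaries, quantile conventions, the
# full chain on the hand-crafted fixture, idempotency.

mk_visits <- function(subject_id, marker, durations, values, group = "pd",
                      hb = NA_real_) {
  data.frame(subject_id = subject_id, group = group, marker = marker,
             visit_label = visit_labels(durations), age = 60 + durations,
             duration_years = durations, value = values,
             hemoglobin_ng_ml = hb, stringsAsFactors = FALSE)
}
visit_labels <- function(d) sprintf("V%02d", seq_along(d))

test_that("minimum-measurement rule keeps series with >= 2 valid values", {
  v <- rbind(mk_visits("A", "m", c(0, 1), c(10, 11)),
             mk_visits("B", "m", 0, 10),
             mk_visits("C", "m", c(0, 1, 2), c(10, 11, 12)))
  out <- filter_min_visits(v, 2)
  expect_setequal(unique(out$visits$subject_id), c("A", "C"))
  expect_equal(out$log$subject_id, "B")
  expect_equal(out$log$reason, "insufficient_visits")
  # NA values do not count as measurements
  v2 <- mk_visits("D", "m", c(0, 1), c(10, NA))
  expect_equal(nrow(filter_min_visits(v2, 2)$visits), 0)
  expect_warning(filter_min_visits(v[0, ], 2), "empty")
})

test_that("hemoglobin rule is strict, alpha-synuclein-specific", {
  v <- rbind(mk_visits("A", "asyn", c(0, 1, 2), c(1, 2, 3),
                       hb = c(199.9, 200, 50)),
             mk_visits("B", "ttau", 0, 9, hb = 500))
  out <- filter_hemoglobin(v, 200)
  kept <- out$visits
  expect_equal(sum(kept$marker == "asyn"), 2)     # 199.9 and 50 kept
  expect_true(200 %in% v$hemoglobin_ng_ml &&
                !200 %in% kept$hemoglobin_ng_ml)  # exactly 200 excluded
  expect_equal(sum(kept$marker == "ttau"), 1)     # rule not applied
  expect_equal(out$log$reason, "high_hemoglobin")
  expect_error(filter_hemoglobin(mk_visits("A", "asyn", 0, 1, hb = -5)),
               "negative")
  # missing hemoglobin: retained with warning by default, droppable
  vna <- mk_visits("A", "asyn", c(0, 1), c(1, 2), hb = c(NA, 50))
  expect_warning(r <- filter_hemoglobin(vna), "missing")
  expect_equal(nrow(r$visits), 2)
  r2 <- filter_hemoglobin(vna, drop_missing = TRUE)
  expect_equal(nrow(r2$visits), 1)
  # absent column: skipped with warning
  v_nohb <- mk_visits("A", "asyn", c(0, 1), c(1, 2))
  v_nohb$hemoglobin_ng_ml <- NULL
  expect_warning(r3 <- filter_hemoglobin(v_nohb), "skipped")
  expect_true(r3$skipped)
  expect_equal(nrow(r3$visits), 2)
})

test_that("baseline outlier rule matches a quantile oracle and is strict", {
  # {1..100} + 10000 planted baseline values
  vals <- c(1:100, 10000)
  ids <- sprintf("S%03d", seq_along(vals))
  v <- do.call(rbind, lapply(seq_along(vals), function(i)
    mk_visits(ids[i], "abeta", c(0, 1), c(vals[i], vals[i]))))
  out <- filter_baseline_outliers(v, "abeta")
  expect_equal(out$log$subject_id, ids[101])
  expect_equal(out$log$reason, "baseline_outlier")
  # independent oracle: recompute the fence with stats::quantile
  q <- quantile(vals, c(0.25, 0.75), type = 7, names = FALSE)
  fence_hi <- q[2] + 3 * (q[2] - q[1])
  expect_identical(vals > fence_hi | vals < q[1] - 3 * (q[2] - q[1]),
                   ids %in% out$log$subject_id)

  # identical values: IQR 0, any deviating value excluded, ties kept
  vals2 <- c(rep(5, 8), 50)
  v2 <- do.call(rbind, lapply(seq_along(vals2), function(i)
    mk_visits(sprintf("T%02d", i), "m", c(0, 1), rep(vals2[i], 2))))
  out2 <- filter_baseline_outliers(v2, "m")
  expect_equal(out2$log$subject_id, "T09")
  expect_equal(sum(out2$visits$value == 5), 16)

  # fewer than 4 baselines: no filtering, warning
  v3 <- do.call(rbind, lapply(1:3, function(i)
    mk_visits(sprintf("U%d", i), "m", c(0, 1), c(i, i))))
  expect_warning(out3 <- filter_baseline_outliers(v3, "m"), "fewer than 4")
  expect_equal(nrow(out3$visits), nrow(v3))

  # randomized property: exclusions equal the brute-force fence check
  set.seed(7)
  for (rep_i in 1:5) {
    b <- rlnorm(40, 5, 0.4)
    vi <- do.call(rbind, lapply(seq_along(b), function(i)
      mk_visits(sprintf("R%02d", i), "m", c(0, 1), rep(b[i], 2))))
    oi <- filter_baseline_outliers(vi, "m")
    qq <- quantile(b, c(0.25, 0.75), type = 7, names = FALSE)
    iq <- qq[2] - qq[1]
    expected <- which(b < qq[1] - 3 * iq | b > qq[2] + 3 * iq)
    expect_setequal(oi$log$subject_id, sprintf("R%02d", expected))
  }
})

test_that("cognitive outlier rule: exactly one exclusion in a planted normal sample", {
  set.seed(123)
  scores <- c(rnorm(199, 28, 1), 50)
  ids <- sprintf("C%03d", seq_along(scores))
  v <- do.call(rbind, lapply(seq_along(scores), function(i)
    mk_visits(ids[i], "moca", c(0, 1), rep(scores[i], 2))))
  out <- filter_cognitive_outliers(v, "moca")
  expect_equal(out$log$subject_id, ids[200])
  expect_equal(out$log$reason, "cognitive_outlier")
})

test_that("cognitive rule is strict at the 4 SD boundary and handles SD 0", {
  # candidate placed exactly 4 leave-one-out SDs from the rest: kept
  others <- rep(c(-1, 1), 5)
  cand <- 4 * sd(c(others))           # others' mean is 0
  scores <- c(others, cand)
  v <- do.call(rbind, lapply(seq_along(scores), function(i)
    mk_visits(sprintf("B%02d", i), "moca", c(0, 1), rep(scores[i], 2))))
  out <- filter_cognitive_outliers(v, "moca")
  expect_equal(nrow(out$log), 0)

  # SD 0 among the others: only the deviating value is excluded
  scores2 <- c(rep(28, 11), 29)
  v2 <- do.call(rbind, lapply(seq_along(scores2), function(i)
    mk_visits(sprintf("D%02d", i), "moca", c(0, 1), rep(scores2[i], 2))))
  out2 <- filter_cognitive_outliers(v2, "moca")
  expect_equal(out2$log$subject_id, "D12")
  v3 <- do.call(rbind, lapply(1:12, function(i)
    mk_visits(sprintf("E%02d", i), "moca", c(0, 1), c(28, 28))))
  expect_equal(nrow(filter_cognitive_outliers(v3, "moca")$log), 0)
})

test_that("stratification boundaries follow the published cut-offs", {
  cov <- data.frame(
    subject_id = c("P1", "P2", "P3", "P4", "H1"),
    group = c(rep("pd", 4), "control"),
    moca_baseline = c(26, 25, 28, NA, 29),
    abeta_baseline = c(683.45, 683.44, 900, 500, 1000),
    stringsAsFactors = FALSE)
  s <- suppressWarnings(stratify(cov))
  expect_equal(s$cognition[s$subject_id == "P1"], "PDCU")  # 26 > 25
  expect_equal(s$cognition[s$subject_id == "P2"], "PDCI")  # 25 is impaired
  expect_equal(s$abeta[s$subject_id == "P1"], "high")      # cut-off -> high
  expect_equal(s$abeta[s$subject_id == "P2"], "low")       # strictly below
  expect_equal(s$cognition[s$subject_id == "H1"], "control")
  expect_equal(s$abeta[s$subject_id == "H1"], "control")
  expect_true(is.na(s$cognition[s$subject_id == "P4"]))
  expect_equal(attr(s, "unclassifiable")$subject_id, "P4")
})

test_that("the 12-subject fixture yields exactly the planted exclusions", {
  v <- make_filter_fixture()
  res <- apply_filters(v)
  rep <- res$report
  expect_equal(nrow(rep), 5)
  expect_equal(rep$reason[rep$subject_id == "S01"], "insufficient_visits")
  hb <- rep[rep$reason == "high_hemoglobin", ]
  expect_setequal(hb$subject_id, c("S02", "S03"))
  expect_true(all(hb$marker == "asyn"))
  expect_equal(rep$subject_id[rep$reason == "baseline_outlier"], "S04")
  expect_equal(rep$marker[rep$reason == "baseline_outlier"], "abeta")
  expect_equal(rep$subject_id[rep$reason == "cognitive_outlier"], "S05")
  expect_equal(rep$marker[rep$reason == "cognitive_outlier"], "moca")
  # S02/S03 keep their two clean alpha-synuclein samples
  kept <- res$visits
  expect_equal(sum(kept$subject_id == "S02" & kept$marker == "asyn"), 2)
})

test_that("the filter chain is idempotent and its counts reconcile", {
  co <- generate_cohort(cohort_config(
    n_pd = 120L, n_control = 50L, hb_high_fraction = 0.05,
    outlier_fraction = 0.02, seed = 77L))
  once <- apply_filters(co)
  twice <- apply_filters(once$visits)
  expect_identical(once$visits, twice$visits)
  expect_equal(nrow(twice$report), 0)
  # row conservation: removed rows = input - output
  n_removed <- once$summary$input$rows - once$summary$output$rows
  expect_true(n_removed > 0)
  # every removed row is accounted for by a report entry (series rows or
  # individual samples)
  key_in <- paste(co$visits$subject_id, co$visits$marker)
  excl_series <- paste(once$report$subject_id, once$report$marker)[
    once$report$stage != "hemoglobin"]
  n_series_rows <- sum(key_in %in% excl_series)
  n_hb_rows <- sum(once$report$stage == "hemoglobin" &
                     !(paste(once$report$subject_id, once$report$marker)
                       %in% excl_series))
  expect_equal(n_removed, n_series_rows + n_hb_rows)
})
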