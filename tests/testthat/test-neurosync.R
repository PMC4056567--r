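test_that("detection periods follow the offset-to-offset / onset-to-onset rule", {
  ne <- tibble::tibble(onset_s = c(2, 6, 10), offset_s = c(3, 7, 11))
  p <- build_detection_periods(ne)
  expect_equal(nrow(p), 1)
  expect_equal(p$effort, 2L)
  expect_equal(c(p$insp_start_s, p$insp_divider_s, p$insp_end_s), c(3, 6, 7))
  expect_equal(c(p$exp_start_s, p$exp_divider_s, p$exp_end_s), c(6, 7, 10))

  expect_warning(
    p2 <- build_detection_periods(ne[1:2, ]), "at least 3")
  expect_equal(nrow(p2), 0)
})

test_that("regular simulated cycles give equal-length periods", {
  sim <- simulate_psv(sim_spec(n_breaths = 8, seed = 2,
                               neural_ti_cv = 0, neural_te_cv = 0,
                               noise_sd_uV = 0, noise_sd_cmH2O = 0))
  p <- build_detection_periods(detect_neural_events(sim$record))
  len <- p$insp_end_s - p$insp_start_s
  expect_lt(diff(range(len)), 0.03)
})

test_that("trigger and cycle-off errors match the worked examples", {
  expect_equal(trigger_error(0, 2, 3, 2.0), 0)
  expect_equal(trigger_error(0, 2, 3, 1.2), -40)
  expect_equal(trigger_error(0, 2, 3, 2.4), 40)
  expect_equal(cycleoff_error(2, 3, 5, 3.0), 0)
  expect_equal(cycleoff_error(2, 3, 5, 3.8), 40)
  expect_equal(cycleoff_error(2, 3, 5, 2.6), -40)
  # clamping at the period bounds
  expect_equal(cycleoff_error(2, 3, 5, 6.5), 100)
  expect_equal(cycleoff_error(2, 3, 5, 1.0), -100)
  expect_error(trigger_error(3, 2, 5, 2.5), "start < divider")
})

test_that("classification respects the inclusive 33% box and forces asynchrony", {
  ev <- tibble::tibble(
    category = c("paired", "paired", "paired", "eadi_without_assist"),
    trigger_error_pct = c(0, 33, 33.01, -20),
    cycleoff_error_pct = c(0, 33, 0, -20))
  out <- classify_events(ev)
  expect_equal(out$classification,
               c("synchrony", "synchrony", "dyssynchrony", "asynchrony"))
  expect_equal(out$trigger_error_pct[4], 100)
  expect_equal(out$cycleoff_error_pct[4], 100)
})

test_that("the index is the pooled mean of absolute errors", {
  ev <- tibble::tibble(category = c("paired", "paired"),
                       trigger_error_pct = c(-40, 40),
                       cycleoff_error_pct = c(-40, 40))
  expect_equal(neurosync_index(ev), 40)
  ev0 <- dplyr::mutate(ev, trigger_error_pct = 0, cycleoff_error_pct = 0)
  expect_equal(neurosync_index(ev0), 0)
  ev100 <- dplyr::mutate(ev, trigger_error_pct = 100,
                         cycleoff_error_pct = 100)
  expect_equal(neurosync_index(ev100), 100)
  expect_error(neurosync_index(ev[0, ]), "undefined")
  # pooling weighs trigger and cycle-off equally
  ev2 <- tibble::tibble(category = "paired",
                        trigger_error_pct = 60, cycleoff_error_pct = 0)
  expect_equal(neurosync_index(ev2), 30)
})

test_that("pairing assigns interaction categories from period geometry", {
  ne <- tibble::tibble(onset_s = c(2, 6, 10, 14, 18),
                       offset_s = c(3, 7, 11, 15, 19))
  p <- build_detection_periods(ne)
  # one assist per interior effort, overlapping the burst
  vent <- tibble::tibble(onset_s = c(6.1, 10.1, 14.1),
                         offset_s = c(7.2, 11.2, 15.2))
  m <- pair_events(p, vent, ne$onset_s)
  expect_equal(m$category, rep("paired", 3))
  expect_equal(m$neural_id, 2:4)

  # an assist fully inside the expiratory phase (ends before the burst):
  # auto-triggering, not an extreme early trigger
  vent2 <- tibble::tibble(onset_s = c(4.5, 6.1, 10.1, 14.1),
                          offset_s = c(5.3, 7.2, 11.2, 15.2))
  m2 <- pair_events(p, vent2, ne$onset_s)
  expect_equal(m2$category[m2$vent_id == 1], "assist_without_eadi")
  expect_true(is.na(m2$neural_id[m2$vent_id == 1]))

  # an effort with no assist at all is a wasted effort
  vent3 <- tibble::tibble(onset_s = c(6.1, 14.1), offset_s = c(7.2, 15.2))
  m3 <- pair_events(p, vent3, ne$onset_s)
  expect_equal(m3$category[m3$neural_id == 3], "eadi_without_assist")
  expect_true(is.na(m3$vent_id[m3$neural_id == 3]))

  # one assist spanning two neural onsets
  vent4 <- tibble::tibble(onset_s = 5.9, offset_s = 14.5)
  m4 <- pair_events(p, vent4, ne$onset_s)
  expect_equal(m4$category[!is.na(m4$vent_id)],
               "multiple_eadi_during_assist")

  # two burst-overlapping assists in one period: double triggering,
  # each scored separately
  vent5 <- tibble::tibble(onset_s = c(6.05, 6.6, 10.1, 14.1),
                          offset_s = c(6.5, 7.2, 11.2, 15.2))
  m5 <- pair_events(p, vent5, ne$onset_s)
  expect_equal(sum(m5$category == "multiple_assist_during_eadi"), 2)

  # assists before the first period are edge events, excluded but counted
  vent6 <- tibble::tibble(onset_s = c(2.1, 6.1, 10.1, 14.1),
                          offset_s = c(3.1, 7.2, 11.2, 15.2))
  m6 <- pair_events(p, vent6, ne$onset_s)
  expect_equal(attr(m6, "n_edge_vent"), 1)
  expect_false(1 %in% m6$vent_id)
})

test_that("quadrant assignment matches the sign pattern of the errors", {
  ev <- tibble::tibble(
    category = rep("paired", 4),
    trigger_error_pct = c(-40, 40, 40, -40),
    cycleoff_error_pct = c(-40, -40, 40, 40))
  ev <- classify_events(ev)
  q <- ventsync:::quadrant_of(ev$cycleoff_error_pct, ev$trigger_error_pct)
  expect_equal(q, c("lower_left", "upper_left", "upper_right",
                    "lower_right"))
})

test_that("full analysis recovers near-zero index on perfect interaction", {
  sim <- simulate_psv(sim_spec(n_breaths = 15, seed = 4,
                               trigger_delay_s = 0, trigger_delay_sd_s = 0,
                               cycleoff_delay_s = 0, cycleoff_delay_sd_s = 0,
                               noise_sd_uV = 0, noise_sd_cmH2O = 0))
  res <- neurosync(sim$record)
  expect_lt(res$index_pct, 5)
  expect_true(all(res$events$classification == "synchrony"))
})

test_that("suppressing every assist yields a 100% index", {
  sim <- simulate_psv(sim_spec(n_breaths = 12, seed = 8, p_wasted = 1,
                               noise_sd_uV = 0, noise_sd_cmH2O = 0))
  res <- neurosync(sim$record)
  expect_equal(res$index_pct, 100)
  expect_true(all(res$events$category == "eadi_without_assist"))
})

test_that("the index is invariant under time shift and dilation", {
  sim <- simulate_psv(sim_spec(n_breaths = 12, seed = 6,
                               noise_sd_uV = 0, noise_sd_cmH2O = 0))
  base <- neurosync(sim$record)$index_pct

  shifted <- sim$record
  shifted$time_s <- shifted$time_s + 100
  expect_equal(neurosync(shifted)$index_pct, base, tolerance = 1e-9)

  dilated <- sim$record
  dilated$time_s <- dilated$time_s * 1.5
  attr(dilated, "sample_rate_hz") <- attr(sim$record, "sample_rate_hz") / 1.5
  expect_equal(neurosync(dilated)$index_pct, base, tolerance = 0.6)
})

test_that("growing trigger delays strictly grow the index (noiseless)", {
  idx <- vapply(c(0.05, 0.15, 0.25, 0.35), function(d) {
    sim <- simulate_psv(sim_spec(n_breaths = 12, seed = 21,
                                 trigger_delay_s = d, trigger_delay_sd_s = 0,
                                 cycleoff_delay_s = 0, cycleoff_delay_sd_s = 0,
                                 noise_sd_uV = 0, noise_sd_cmH2O = 0))
    neurosync(sim$record)$index_pct
  }, numeric(1))
  expect_true(all(diff(idx) > 0))
})

test_that("constant delays reproduce the analytic error on every breath", {
  d <- 0.27
  sim <- simulate_psv(sim_spec(n_breaths = 12, seed = 31,
                               neural_ti_cv = 0, neural_te_cv = 0,
                               trigger_delay_s = d, trigger_delay_sd_s = 0,
                               cycleoff_delay_s = 0, cycleoff_delay_sd_s = 0,
                               noise_sd_uV = 0, noise_sd_cmH2O = 0))
  res <- neurosync(sim$record)
  ev <- res$events[res$events$category == "paired", ]
  analytic <- 100 * d / 0.9           # late segment = neural Ti
  # within two samples' worth of percent
  tol <- 100 * 2 * 0.01 / 0.9
  expect_true(all(abs(ev$trigger_error_pct - analytic) < tol))
  expect_true(all(abs(ev$cycleoff_error_pct) < 100 * 2 * 0.01 / 1.6))
})

test_that("tidy and glance expose the event table and the summary row", {
  sim <- simulate_psv(sim_spec(n_breaths = 8, seed = 13,
                               noise_sd_uV = 0, noise_sd_cmH2O = 0))
  res <- neurosync(sim$record)
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("category", "trigger_error_pct", "classification")
                  %in% names(td)))
  gl <- glance(res)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$index_pct, res$index_pct)
  expect_equal(gl$n_events, nrow(td))
})
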