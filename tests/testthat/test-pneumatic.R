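test_that("double triggering needs a short gap and a patient-triggered first cycle", {
  br <- tibble::tibble(ti_s = c(1, 1), te_s = c(0.3, NA),
                       patient_triggered = c(TRUE, TRUE))
  expect_equal(detect_double_trigger(br), 1)
  br$patient_triggered[1] <- FALSE
  expect_equal(detect_double_trigger(br), 0)
  br$patient_triggered[1] <- TRUE
  br$te_s[1] <- 0.6                      # 0.6 > 0.5 * mean Ti
  expect_equal(detect_double_trigger(br), 0)
})

test_that("short and prolonged cycles are judged against the record mean Ti", {
  mk <- function(ti) tibble::tibble(ti_s = ti, te_s = NA,
                                    patient_triggered = TRUE)
  expect_equal(classify_cycles(mk(c(1, 1, 1, 0.4))),
               list(short = 1L, prolonged = 0L))
  # mean 1.375 makes 2.5 fall below the doubled mean: nothing prolonged
  expect_equal(classify_cycles(mk(c(1, 1, 1, 2.5))),
               list(short = 0L, prolonged = 0L))
  expect_equal(classify_cycles(mk(rep(1, 5))),
               list(short = 0L, prolonged = 0L))
})

test_that("the pneumatic asynchrony index uses breaths plus ineffective efforts", {
  counts <- list(ineffective = 0, double_trigger = 0, auto_trigger = 0,
                 short_cycle = 0, prolonged_cycle = 0, total_breaths = 100)
  expect_equal(asynchrony_index(counts), 0)
  counts$ineffective <- 10
  counts$total_breaths <- 90
  expect_equal(asynchrony_index(counts), 10)
  counts$total_breaths <- 0
  counts$ineffective <- 0
  expect_error(asynchrony_index(counts), "no breaths")
})

test_that("ineffective efforts are found only as unanswered expiratory dips", {
  sim <- simulate_psv(sim_spec(n_breaths = 25, seed = 14, p_wasted = 0.25,
                               noise_sd_uV = 0, noise_sd_cmH2O = 0))
  vent <- detect_vent_events(sim$record)
  ineff <- detect_ineffective(sim$record, vent)
  truth_wasted <- sim$truth$slots[sim$truth$slots$category == "wasted", ]
  expect_equal(nrow(ineff), nrow(truth_wasted))
  # each detection sits near a true wasted-effort dip (placed 0.1 s after
  # the neural onset), and inside an expiratory window
  for (tt in ineff$time_s) {
    expect_true(min(abs(truth_wasted$on_s + 0.1 - tt)) < 0.35)
  }
  # a triggered breath's dip is not ineffective: none detected without
  # wasted efforts
  sim0 <- simulate_psv(sim_spec(n_breaths = 15, seed = 14,
                                noise_sd_uV = 0, noise_sd_cmH2O = 0))
  expect_equal(nrow(detect_ineffective(sim0$record,
                                       detect_vent_events(sim0$record))), 0)
})

test_that("sub-threshold dips are not ineffective efforts", {
  sim <- simulate_psv(sim_spec(n_breaths = 20, seed = 15, p_wasted = 0.3,
                               dip_cmH2O = 0.3,
                               noise_sd_uV = 0, noise_sd_cmH2O = 0))
  vent <- detect_vent_events(sim$record)
  expect_equal(nrow(detect_ineffective(sim$record, vent)), 0)
})

test_that("ineffective detection without a flow channel points to the EAdi route", {
  rec <- as_waveform(data.frame(eadi_uV = rep(0, 300),
                                paw_cmH2O = rep(5, 300)))
  expect_error(detect_ineffective(rec, tibble::tibble()), "EAdi")
})

test_that("auto-triggered assists lack the pre-trigger dip", {
  sim <- simulate_psv(sim_spec(n_breaths = 30, seed = 16, p_auto = 0.2,
                               noise_sd_uV = 0, noise_sd_cmH2O = 0))
  vent <- detect_vent_events(sim$record)
  at <- detect_autotrigger(sim$record, vent)
  n_auto_truth <- sum(sim$truth$slots$category == "auto")
  expect_equal(nrow(at), n_auto_truth)
  # patient-triggered breaths all carry the dip
  br <- pneumatic_breaths(sim$record, vent)
  expect_equal(sum(!br$patient_triggered), n_auto_truth)
})

test_that("the EAdi-verified fraction equals the asynchrony fraction absent double triggers", {
  sim <- simulate_psv(sim_spec(n_breaths = 30, seed = 17, p_wasted = 0.2,
                               p_auto = 0.1,
                               noise_sd_uV = 0, noise_sd_cmH2O = 0))
  res <- neurosync(sim$record)
  expect_equal(sum(res$events$category == "multiple_assist_during_eadi"), 0)
  frac_async <- 100 * sum(res$events$classification == "asynchrony") /
    nrow(res$events)
  expect_equal(ai_colombo(res$events), frac_async)
  # and with all events paired inside the box it is zero
  sim0 <- simulate_psv(sim_spec(n_breaths = 10, seed = 18,
                                noise_sd_uV = 0, noise_sd_cmH2O = 0))
  res0 <- neurosync(sim0$record)
  expect_equal(ai_colombo(res0$events), 0)
  expect_error(ai_colombo(res0$events[0, ]), "no events")
})

test_that("double triggers raise the EAdi-verified fraction above the asynchrony fraction", {
  sim <- simulate_psv(sim_spec(n_breaths = 30, seed = 19, p_double = 0.3,
                               noise_sd_uV = 0, noise_sd_cmH2O = 0))
  res <- neurosync(sim$record)
  n_dt_events <- sum(res$events$category == "multiple_assist_during_eadi")
  expect_gt(n_dt_events, 0)
  frac_async <- 100 * sum(res$events$classification == "asynchrony") /
    nrow(res$events)
  expect_gte(ai_colombo(res$events), frac_async)
  # pneumatic view agrees there are double triggers
  vent <- detect_vent_events(sim$record)
  br <- pneumatic_breaths(sim$record, vent)
  expect_equal(detect_double_trigger(br),
               sum(sim$truth$slots$category == "double"))
})

test_that("pneumatic counts integrate into the asynchrony index on one record", {
  sim <- simulate_psv(sim_spec(n_breaths = 30, seed = 20, p_wasted = 0.15,
                               p_auto = 0.1,
                               noise_sd_uV = 0, noise_sd_cmH2O = 0))
  vent <- detect_vent_events(sim$record)
  counts <- asynchrony_counts(sim$record, vent)
  sl <- table(sim$truth$slots$category)
  expect_equal(counts$ineffective, unname(sl["wasted"]))
  expect_equal(counts$auto_trigger, unname(sl["auto"]))
  ai <- asynchrony_index(counts)
  expect_gt(ai, 0)
  expect_lte(ai, 100)
})
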