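make_record <- function(eadi, paw = rep(5, length(eadi)), fs = 100) {
  as_waveform(tibble::tibble(time_s = (seq_along(eadi) - 1) / fs,
                             eadi_uV = eadi, paw_cmH2O = paw))
}

triangular <- function(t, start, peak_t, end, amp) {
  up <- pmax(pmin((t - start) / (peak_t - start), 1), 0)
  down <- pmax(pmin((end - t) / (end - peak_t), 1), 0)
  amp * pmin(up, down) * (t >= start & t <= end)
}

test_that("constant-zero EAdi yields no neural events", {
  rec <- make_record(rep(0, 1000))
  expect_equal(nrow(detect_neural_events(rec)), 0)
})

test_that("a single triangular burst gives the expected onset and offset", {
  t <- seq(0, 5, by = 0.01)
  rec <- make_record(triangular(t, 1, 2, 3, 10))
  ev <- detect_neural_events(rec)
  expect_equal(nrow(ev), 1)
  # onset at the foot of the rise
  expect_equal(ev$onset_s, 1.00)
  expect_equal(ev$onset_amplitude_uV, 0)
  expect_equal(ev$peak_uV, 10)
  # offset at the first sample below 70% of the 10 uV peak on the descent
  idx_off <- which(t > 2 & rec$eadi_uV < 7)[1]
  expect_equal(ev$offset_s, t[idx_off])
  # and the oracle agrees exactly
  ref <- ref_detect_neural(rec)
  expect_equal(ev$onset_s, ref$onset_s)
  expect_equal(ev$offset_s, ref$offset_s)
})

test_that("two separated bursts give two non-overlapping events", {
  t <- seq(0, 10, by = 0.01)
  x <- triangular(t, 1, 2, 3, 8) + triangular(t, 5, 6, 7, 12)
  ev <- detect_neural_events(make_record(x))
  expect_equal(nrow(ev), 2)
  expect_true(all(diff(ev$onset_s) > 0))
  expect_true(ev$offset_s[1] < ev$onset_s[2])
  expect_equal(ev$onset_s, c(1, 5))
})

test_that("records shorter than 3 samples are rejected", {
  rec <- suppressWarnings(
    as_waveform(data.frame(eadi_uV = c(0, 1), paw_cmH2O = c(5, 5))))
  expect_error(detect_neural_events(rec), "3 samples")
  expect_error(detect_vent_events(rec), "3 samples")
})

test_that("constant-PEEP pressure yields no ventilator events", {
  rec <- make_record(rep(0, 800), paw = rep(5, 800))
  expect_equal(nrow(detect_vent_events(rec)), 0)
})

test_that("a square pressurization is detected with PEEP and peak", {
  t <- seq(0, 6, by = 0.01)
  paw <- 5 + 12 * pmin(pmax((t - 2) / 0.05, 0), 1) * (t < 3)
  rec <- make_record(rep(0, length(t)), paw = paw)
  ev <- detect_vent_events(rec)
  expect_equal(nrow(ev), 1)
  expect_lt(abs(ev$onset_s - 2.00), 0.011)
  expect_equal(ev$peep_cmH2O, 5)
  expect_equal(ev$peak_paw_cmH2O, 17)
  expect_gt(ev$offset_s, 2.9)
})

test_that("pressure rises at or below the 3 cmH2O threshold are ignored", {
  t <- seq(0, 6, by = 0.01)
  mk <- function(amp) make_record(rep(0, length(t)),
                                  paw = 5 + amp * (t >= 2 & t < 3))
  expect_equal(nrow(detect_vent_events(mk(2.5))), 0)
  expect_equal(nrow(detect_vent_events(mk(3.0))), 0)   # strict >
  expect_equal(nrow(detect_vent_events(mk(3.1))), 1)
})

test_that("ventilator detection is invariant to a PEEP shift", {
  sim <- simulate_psv(sim_spec(n_breaths = 10, seed = 5,
                               noise_sd_uV = 0, noise_sd_cmH2O = 0))
  rec2 <- sim$record
  rec2$paw_cmH2O <- rec2$paw_cmH2O + 7.5
  a <- detect_vent_events(sim$record)
  b <- detect_vent_events(rec2)
  expect_equal(b$onset_s, a$onset_s)
  expect_equal(b$offset_s, a$offset_s)
  expect_equal(b$peep_cmH2O, a$peep_cmH2O + 7.5)
  expect_equal(b$area_cmH2Os, a$area_cmH2Os, tolerance = 1e-8)
})

test_that("raising the trigger threshold never increases the event count", {
  for (seed in 1:15) {
    rec <- random_record(seed, n = 1200)
    counts <- vapply(c(0.25, 0.5, 1.0), function(th) {
      nrow(detect_neural_events(rec, ns_config(
        eadi_trigger_threshold_uV = th)))
    }, numeric(1))
    expect_true(all(diff(counts) <= 0),
                info = paste("seed", seed, ":",
                             paste(counts, collapse = " ")))
  }
})

test_that("defragmentation drops strictly sub-minimum areas and is idempotent", {
  neural <- tibble::tibble(
    onset_s = c(1, 3, 5), offset_s = c(2, 4, 6),
    onset_amplitude_uV = 0, peak_uV = 5,
    area_uVs = c(0.10, 0.15, 0.30), merged = FALSE)
  vent <- tibble::tibble(
    onset_s = c(1, 3, 5), offset_s = c(2, 4, 6),
    peep_cmH2O = 5, peak_paw_cmH2O = 17,
    area_cmH2Os = c(1.49, 1.5, 1.51), merged = FALSE)
  d <- defragment(neural, vent)
  expect_equal(d$neural$area_uVs, c(0.15, 0.30))   # 0.10 removed, 0.15 kept
  expect_equal(d$vent$area_cmH2Os, c(1.5, 1.51))   # 1.49 removed
  d2 <- defragment(d$neural, d$vent)
  expect_identical(d2, d)
  # disabled defragmentation is a no-op
  off <- defragment(neural, vent, ns_config(defrag_enabled = FALSE))
  expect_identical(off$neural, neural)
  expect_identical(off$vent, vent)
})

test_that("events_from_annotations pairs cursors and handles stragglers", {
  ann <- annotation_set(eadi_on_s = c(1, 3, 5), eadi_off_s = c(2, 4, 6),
                        ps_on_s = c(1.1, 3.1), ps_off_s = c(2.1, 4.1))
  ev <- events_from_annotations(ann)
  expect_equal(nrow(ev$neural), 3)
  expect_equal(nrow(ev$vent), 2)
  expect_true(all(is.na(ev$neural$area_uVs)))

  odd <- annotation_set(eadi_on_s = c(1, 3), eadi_off_s = 2)
  expect_warning(ev2 <- events_from_annotations(odd), "unpaired")
  expect_equal(nrow(ev2$neural), 1)

  bad <- annotation_set(eadi_on_s = c(1, 3, 5), eadi_off_s = 2)
  expect_error(events_from_annotations(bad), "cannot pair")
})

test_that("annotated events on a noiseless simulation match detection", {
  sim <- simulate_psv(sim_spec(n_breaths = 10, seed = 9,
                               noise_sd_uV = 0, noise_sd_cmH2O = 0))
  man <- events_from_annotations(sim$truth$annotations, sim$record)
  auto <- detect_neural_events(sim$record)
  expect_equal(nrow(man$neural), nrow(auto))
  expect_true(all(abs(man$neural$onset_s - auto$onset_s) <= 0.0100001))
  autov <- detect_vent_events(sim$record)
  expect_equal(nrow(man$vent), nrow(autov))
  expect_true(all(abs(man$vent$onset_s - autov$onset_s) <= 0.0100001))
  # waveform-derived amplitudes are populated
  expect_true(all(is.finite(man$neural$peak_uV)))
  expect_true(all(is.finite(man$vent$area_cmH2Os)))
})
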