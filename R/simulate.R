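#' Simulation parameters for pressure-support ventilation
#'
#' Defines a synthetic record of assisted breathing: EAdi bursts on a tonic
#' baseline, square pressurizations above PEEP with a finite rise time, a
#' pre-trigger airway-pressure dip for patient-triggered breaths, and flow
#' from single-compartment respiratory mechanics. Interaction failures are
#' injected per breath with probabilities `p_wasted` (neural effort without
#' assist), `p_auto` (assist without neural effort, no dip) and `p_double`
#' (two assists during one effort). Timing errors are controlled by the
#' trigger and cycle-off delay distributions; delays may be negative.
#'
#' Defaults emulate a typical adult on pressure support: neural inspiratory
#' time 0.9 s, expiratory time 1.6 s, EAdi peaks around 12 uV on a 0.5 uV
#' tonic baseline, PEEP 5 cmH2O, 12 cmH2O of support, trigger delay
#' 100 +/- 20 ms, cycle-off delay 150 +/- 30 ms, and mild measurement noise.
#'
#' @param n_breaths Number of breath slots.
#' @param neural_ti_s,neural_ti_cv Mean neural inspiratory time (EAdi_ON to
#'   EAdi_OFF, s) and its coefficient of variation.
#' @param neural_te_s,neural_te_cv Mean neural expiratory time (EAdi_OFF to
#'   next EAdi_ON, s) and CV.
#' @param eadi_peak_uV,eadi_peak_cv Mean burst peak (uV) and CV.
#' @param eadi_tonic_uV Tonic EAdi baseline (uV).
#' @param burst_shape `"triangular"` (linear rise) or `"raised-cosine"`.
#'   The decay past the peak is linear in both, so the 70%-of-peak crossing
#'   falls exactly at the intended EAdi_OFF.
#' @param trigger_delay_s,trigger_delay_sd_s Assist-onset delay relative to
#'   EAdi_ON: mean and SD (s); negative means early triggering.
#' @param cycleoff_delay_s,cycleoff_delay_sd_s Assist-termination delay
#'   relative to EAdi_OFF: mean and SD (s).
#' @param p_wasted,p_auto,p_double Per-breath failure probabilities; their
#'   sum must not exceed 1.
#' @param peep_cmH2O,ps_level_cmH2O PEEP and the support level above PEEP.
#' @param rise_time_s Pressurization rise time (s).
#' @param dip_cmH2O Depth of the pre-trigger pressure dip; 0.7 by default so
#'   it exceeds the 0.5 cmH2O pneumatic detection threshold.
#' @param resistance_cmH2O_per_Lps,compliance_L_per_cmH2O Single-compartment
#'   mechanics for the flow channel.
#' @param pmus_gain_cmH2O_per_uV Muscle pressure generated per uV of EAdi
#'   above the tonic level.
#' @param noise_sd_uV,noise_sd_cmH2O Gaussian measurement noise SDs. Both
#'   channels carry band-limited noise (80 ms moving average for the EAdi
#'   RMS envelope, 50 ms for the transducer-filtered pressure); EAdi is
#'   clipped at zero after adding noise.
#' @param sample_rate_hz Samples per second (default 100).
#' @param seed Integer seed; the whole record is reproducible given the
#'   seed. Per-breath draws occur in a fixed order (inspiratory time,
#'   expiratory time, peak, category uniform, trigger delay, cycle-off
#'   delay), followed by the channel noise vectors.
#' @return A list of class `sim_spec`.
#' @export
sim_spec <- function(n_breaths = 30,
                     neural_ti_s = 0.9, neural_ti_cv = 0.08,
                     neural_te_s = 1.6, neural_te_cv = 0.08,
                     eadi_peak_uV = 12, eadi_peak_cv = 0.15,
                     eadi_tonic_uV = 0.5,
                     burst_shape = c("triangular", "raised-cosine"),
                     trigger_delay_s = 0.10, trigger_delay_sd_s = 0.02,
                     cycleoff_delay_s = 0.15, cycleoff_delay_sd_s = 0.03,
                     p_wasted = 0, p_auto = 0, p_double = 0,
                     peep_cmH2O = 5, ps_level_cmH2O = 12,
                     rise_time_s = 0.15, dip_cmH2O = 0.7,
                     resistance_cmH2O_per_Lps = 12,
                     compliance_L_per_cmH2O = 0.04,
                     pmus_gain_cmH2O_per_uV = 0.3,
                     noise_sd_uV = 0.2, noise_sd_cmH2O = 0.1,
                     sample_rate_hz = 100, seed = 1L) {
  spec <- list(
    n_breaths = as.integer(n_breaths),
    neural_ti_s = neural_ti_s, neural_ti_cv = neural_ti_cv,
    neural_te_s = neural_te_s, neural_te_cv = neural_te_cv,
    eadi_peak_uV = eadi_peak_uV, eadi_peak_cv = eadi_peak_cv,
    eadi_tonic_uV = eadi_tonic_uV,
    burst_shape = match.arg(burst_shape),
    trigger_delay_s = trigger_delay_s,
    trigger_delay_sd_s = trigger_delay_sd_s,
    cycleoff_delay_s = cycleoff_delay_s,
    cycleoff_delay_sd_s = cycleoff_delay_sd_s,
    p_wasted = p_wasted, p_auto = p_auto, p_double = p_double,
    peep_cmH2O = peep_cmH2O, ps_level_cmH2O = ps_level_cmH2O,
    rise_time_s = rise_time_s, dip_cmH2O = dip_cmH2O,
    resistance_cmH2O_per_Lps = resistance_cmH2O_per_Lps,
    compliance_L_per_cmH2O = compliance_L_per_cmH2O,
    pmus_gain_cmH2O_per_uV = pmus_gain_cmH2O_per_uV,
    noise_sd_uV = noise_sd_uV, noise_sd_cmH2O = noise_sd_cmH2O,
    sample_rate_hz = sample_rate_hz, seed = as.integer(seed))
  validate_sim_spec(spec)
  structure(spec, class = "sim_spec")
}

validate_sim_spec <- function(spec) {
  p <- c(spec$p_wasted, spec$p_auto, spec$p_double)
  if (any(p < 0) || any(p > 1) || sum(p) > 1) {
    stop("failure probabilities must lie in [0,1] and sum to at most 1",
         call. = FALSE)
  }
  pos <- c("neural_ti_s", "neural_te_s", "eadi_peak_uV", "ps_level_cmH2O",
           "rise_time_s", "resistance_cmH2O_per_Lps",
           "compliance_L_per_cmH2O", "sample_rate_hz")
  for (f in pos) {
    if (!(spec[[f]] > 0)) stop("`", f, "` must be > 0", call. = FALSE)
  }
  cvs <- c("neural_ti_cv", "neural_te_cv", "eadi_peak_cv", "noise_sd_uV",
           "noise_sd_cmH2O", "trigger_delay_sd_s", "cycleoff_delay_sd_s")
  for (f in cvs) {
    if (spec[[f]] < 0) stop("`", f, "` must be >= 0", call. = FALSE)
  }
  if (spec$n_breaths < 1L) stop("`n_breaths` must be >= 1", call. = FALSE)
  invisible(spec)
}

rtrunc_norm <- function(n, mean, sd, lower) {
  x <- stats::rnorm(n, mean, sd)
  pmax(x, lower)
}

# Double-trigger geometry (fractions of the neural inspiratory time): the
# first assist cycles off at 55% of the effort, the second re-triggers at
# 70% and cycles off with the usual cycle-off delay. The first cycle is kept
# long enough that its pressurization area stays clearly above the
# defragmentation minimum.
DT_OFF1_FRAC <- 0.55
DT_ON2_FRAC <- 0.70

#' Simulate a pressure-support ventilation record with ground truth
#'
#' Builds the EAdi, airway pressure and flow channels implied by a
#' [sim_spec()], together with the true event times, per-breath categories,
#' true timing errors and the true NeuroSync index (computed from the true
#' event times with the same pooled-mean definition used by the analyzer).
#'
#' @param spec A [sim_spec()].
#' @return A list of class `psv_sim`: `record` (a `waveform_df`), `truth`
#'   (list with `neural` and `vent` event tibbles, per-slot `slots` tibble,
#'   `annotations`, the scored `result`, and `true_index_pct`) and `spec`.
#' @export
#' @examples
#' sim <- simulate_psv(sim_spec(n_breaths = 5, seed = 7))
#' sim$truth$true_index_pct
simulate_psv <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  validate_sim_spec(spec)
  set.seed(spec$seed)
  nb <- spec$n_breaths
  fs <- spec$sample_rate_hz
  dt <- 1 / fs
  tonic <- spec$eadi_tonic_uV
  peep <- spec$peep_cmH2O

  # per-breath draws in fixed, documented order
  slots <- vector("list", nb)
  # neural onsets (and burst peaks, below) are snapped to the sample grid so
  # the intended event times are exactly representable in the record
  on_grid <- function(x) round(x * fs) / fs
  t_cursor <- 1.0
  for (i in seq_len(nb)) {
    ti <- rtrunc_norm(1, spec$neural_ti_s, spec$neural_ti_cv * spec$neural_ti_s,
                      0.3 * spec$neural_ti_s)
    te <- rtrunc_norm(1, spec$neural_te_s, spec$neural_te_cv * spec$neural_te_s,
                      max(0.8 * ti, 0.3 * spec$neural_te_s))
    peak <- rtrunc_norm(1, spec$eadi_peak_uV,
                        spec$eadi_peak_cv * spec$eadi_peak_uV,
                        max(0.2 * spec$eadi_peak_uV, tonic + 1))
    u <- stats::runif(1)
    d_tr <- stats::rnorm(1, spec$trigger_delay_s, spec$trigger_delay_sd_s)
    d_cy <- stats::rnorm(1, spec$cycleoff_delay_s, spec$cycleoff_delay_sd_s)
    category <- if (u < spec$p_wasted) {
      "wasted"
    } else if (u < spec$p_wasted + spec$p_auto) {
      "auto"
    } else if (u < spec$p_wasted + spec$p_auto + spec$p_double) {
      "double"
    } else {
      "normal"
    }
    slots[[i]] <- tibble::tibble(
      breath = i, category = category, on_s = on_grid(t_cursor), ti_s = ti,
      te_s = te, peak_uV = peak, trigger_delay_s = d_tr,
      cycleoff_delay_s = d_cy)
    t_cursor <- t_cursor + ti + te
  }
  slots <- dplyr::bind_rows(slots)

  t_end <- t_cursor + 1.0
  n <- ceiling(t_end * fs) + 1L
  t <- (seq_len(n) - 1L) * dt
  eadi <- rep(tonic, n)
  paw <- rep(peep, n)

  put_burst <- function(on, ti, peak) {
    t_pk <- on_grid(on + 0.75 * ti)
    t_off <- on + ti
    slope <- 0.3 * peak / (t_off - t_pk)
    rise_idx <- which(t >= on & t < t_pk)
    if (spec$burst_shape == "triangular") {
      v <- tonic + (peak - tonic) * (t[rise_idx] - on) / (t_pk - on)
    } else {
      v <- tonic + (peak - tonic) *
        (1 - cos(pi * (t[rise_idx] - on) / (t_pk - on))) / 2
    }
    eadi[rise_idx] <<- pmax(eadi[rise_idx], v)
    dec_end <- t_pk + (peak - tonic) / slope
    dec_idx <- which(t >= t_pk & t <= dec_end)
    eadi[dec_idx] <<- pmax(eadi[dec_idx],
                           pmax(peak - slope * (t[dec_idx] - t_pk), tonic))
  }

  put_assist <- function(ps_on, ps_off, with_dip) {
    bottom <- peep
    if (with_dip) {
      dip_start <- max(ps_on - 0.15, 0)
      bottom <- peep - spec$dip_cmH2O
      idx <- which(t >= dip_start & t < ps_on)
      if (length(idx)) {
        paw[idx] <<- pmin(paw[idx], peep - spec$dip_cmH2O *
                            (t[idx] - dip_start) / (ps_on - dip_start))
      }
    }
    ridx <- which(t >= ps_on & t < ps_on + spec$rise_time_s & t <= ps_off)
    if (length(ridx)) {
      paw[ridx] <<- bottom + (peep + spec$ps_level_cmH2O - bottom) *
        (t[ridx] - ps_on) / spec$rise_time_s
    }
    pidx <- which(t >= ps_on + spec$rise_time_s & t <= ps_off)
    if (length(pidx)) paw[pidx] <<- peep + spec$ps_level_cmH2O
  }

  put_dip <- function(tc) {
    half <- 0.15
    idx <- which(t >= tc - half & t <= tc + half)
    if (length(idx)) {
      paw[idx] <<- pmin(paw[idx],
                        peep - spec$dip_cmH2O *
                          (1 - abs(t[idx] - tc) / half))
    }
  }

  neural_rows <- list()
  vent_rows <- list()
  for (i in seq_len(nb)) {
    s <- slots[i, ]
    on <- s$on_s; ti <- s$ti_s; off <- on + ti
    if (s$category != "auto") put_burst(on, ti, s$peak_uV)
    if (s$category == "normal") {
      ps_on <- on + s$trigger_delay_s
      ps_off <- max(off + s$cycleoff_delay_s, ps_on + 0.2)
      put_assist(ps_on, ps_off, with_dip = TRUE)
      vent_rows[[length(vent_rows) + 1L]] <-
        tibble::tibble(breath = i, onset_s = ps_on, offset_s = ps_off)
    } else if (s$category == "auto") {
      ps_on <- on + max(s$trigger_delay_s, 0)
      ps_off <- max(off + s$cycleoff_delay_s, ps_on + 0.2)
      put_assist(ps_on, ps_off, with_dip = FALSE)
      vent_rows[[length(vent_rows) + 1L]] <-
        tibble::tibble(breath = i, onset_s = ps_on, offset_s = ps_off)
    } else if (s$category == "double") {
      ps_on1 <- on + s$trigger_delay_s
      ps_off1 <- on + DT_OFF1_FRAC * ti
      ps_on2 <- on + DT_ON2_FRAC * ti
      ps_off2 <- max(off + s$cycleoff_delay_s, ps_on2 + 0.2)
      put_assist(ps_on1, ps_off1, with_dip = TRUE)
      put_assist(ps_on2, ps_off2, with_dip = TRUE)
      vent_rows[[length(vent_rows) + 1L]] <-
        tibble::tibble(breath = i, onset_s = c(ps_on1, ps_on2),
                       offset_s = c(ps_off1, ps_off2))
    } else { # wasted: effort with a pneumatic signature but no assist
      put_dip(on + 0.1)
    }
    if (s$category != "auto") {
      neural_rows[[length(neural_rows) + 1L]] <- tibble::tibble(
        breath = i, onset_s = on, offset_s = off,
        onset_amplitude_uV = tonic, peak_uV = s$peak_uV)
    }
  }
  if (!length(neural_rows)) {
    truth_neural <- tibble::tibble(
      breath = integer(), onset_s = numeric(), offset_s = numeric(),
      onset_amplitude_uV = numeric(), peak_uV = numeric())
  } else {
    truth_neural <- dplyr::bind_rows(neural_rows)
  }
  truth_vent <- if (length(vent_rows)) {
    dplyr::arrange(dplyr::bind_rows(vent_rows), .data$onset_s)
  } else {
    tibble::tibble(breath = integer(), onset_s = numeric(),
                   offset_s = numeric())
  }

  # analytic burst area above the onset amplitude, for defragmentation
  truth_neural$area_uVs <- with(truth_neural, {
    rise <- 0.5 * (peak_uV - tonic) * 0.75 * (offset_s - onset_s)
    dec <- 0.25 * (offset_s - onset_s) *
      ((peak_uV - tonic) + pmax(0.7 * peak_uV - tonic, 0)) / 2
    rise + dec
  })
  truth_neural$merged <- FALSE
  if (nrow(truth_vent)) {
    truth_vent$peep_cmH2O <- peep
    truth_vent$peak_paw_cmH2O <- peep + spec$ps_level_cmH2O
    # trapezoidal pressurization: the linear rise contributes half its span
    truth_vent$area_cmH2Os <- spec$ps_level_cmH2O *
      pmax(truth_vent$offset_s - truth_vent$onset_s - spec$rise_time_s / 2, 0)
    truth_vent$merged <- FALSE
  } else {
    truth_vent <- tibble::tibble(
      breath = integer(), onset_s = numeric(), offset_s = numeric(),
      peep_cmH2O = numeric(), peak_paw_cmH2O = numeric(),
      area_cmH2Os = numeric(), merged = logical())
  }

  # flow from single-compartment mechanics driven by assist + muscle pressure
  pmus <- spec$pmus_gain_cmH2O_per_uV * (eadi - tonic)
  pdrive <- (paw - peep) + pmus
  vol <- numeric(n)
  flow <- numeric(n)
  rc <- spec$resistance_cmH2O_per_Lps
  cl <- spec$compliance_L_per_cmH2O
  for (k in seq_len(n - 1L)) {
    flow[k] <- (pdrive[k] - vol[k] / cl) / rc
    vol[k + 1L] <- max(vol[k] + dt * flow[k], 0)
  }
  flow[n] <- (pdrive[n] - vol[n] / cl) / rc

  if (spec$noise_sd_uV > 0) {
    # EAdi is an RMS envelope: its noise is band-limited, not white.
    # Moving average over ~80 ms, scaled to keep the requested SD.
    w <- max(1L, round(0.08 * fs))
    raw <- stats::rnorm(n + w - 1L)
    sm <- as.numeric(stats::filter(raw, rep(1, w) / sqrt(w), sides = 1))
    sm <- sm[w:(n + w - 1L)]
    eadi_out <- pmax(eadi + spec$noise_sd_uV * sm, 0)
  } else {
    eadi_out <- eadi
  }
  if (spec$noise_sd_cmH2O > 0) {
    # ventilator pressure is transducer-filtered: band-limited noise (~50 ms)
    w2 <- max(1L, round(0.05 * fs))
    raw2 <- stats::rnorm(n + w2 - 1L)
    sm2 <- as.numeric(stats::filter(raw2, rep(1, w2) / sqrt(w2), sides = 1))
    paw_out <- paw + spec$noise_sd_cmH2O * sm2[w2:(n + w2 - 1L)]
  } else {
    paw_out <- paw
  }

  record <- as_waveform(tibble::tibble(
    time_s = t, eadi_uV = eadi_out, paw_cmH2O = paw_out, flow_Lps = flow),
    sample_rate_hz = fs)

  ann <- annotation_set(
    eadi_on_s = truth_neural$onset_s, eadi_off_s = truth_neural$offset_s,
    ps_on_s = truth_vent$onset_s, ps_off_s = truth_vent$offset_s,
    analyst_id = "ground_truth", pass_id = "1")

  truth_result <- neurosync_from_events(
    dplyr::select(truth_neural, -"breath"),
    dplyr::select(truth_vent, -"breath"),
    ns_config())

  structure(list(
    record = record,
    truth = list(neural = truth_neural, vent = truth_vent, slots = slots,
                 annotations = ann, result = truth_result,
                 true_index_pct = truth_result$index_pct),
    spec = spec), class = "psv_sim")
}

#' @export
print.psv_sim <- function(x, ...) {
  cat("<psv_sim> ", x$spec$n_breaths, " breaths, ",
      nrow(x$record), " samples, true index ",
      formatC(x$truth$true_index_pct, digits = 1, format = "f"), "%\n",
      sep = "")
  invisible(x)
}

#' Analytic expected NeuroSync index for a simulation spec
#'
#' Closed-form expectation of the pooled mean absolute error implied by a
#' [sim_spec()], using the mean segment lengths: the early trigger segment
#' is the mean neural expiratory time, the late trigger segment the mean
#' neural inspiratory time (and vice versa for cycle-off). Normal breaths
#' contribute the expected absolute trigger and cycle-off errors (the delay
#' distribution mapped through the piecewise early/late normalization and
#' integrated numerically against the normal density); wasted efforts and
#' auto-triggers contribute 100 and 100; double-triggered breaths contribute
#' both assists' errors at the deterministic re-trigger geometry. Intended
#' for zero-noise specs: with measurement noise the value is approximate and
#' a warning is raised.
#'
#' @param spec A [sim_spec()].
#' @return The expected index in percent.
#' @export
#' @examples
#' expected_index(sim_spec(trigger_delay_s = 0, trigger_delay_sd_s = 0,
#'                         cycleoff_delay_s = 0, cycleoff_delay_sd_s = 0,
#'                         noise_sd_uV = 0, noise_sd_cmH2O = 0)) # 0
expected_index <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  if (spec$noise_sd_uV > 0 || spec$noise_sd_cmH2O > 0) {
    warning("expected_index() assumes a noiseless spec; ",
            "the value is approximate under measurement noise",
            call. = FALSE)
  }
  ti <- spec$neural_ti_s
  te <- spec$neural_te_s
  err_pct <- function(d, early_seg, late_seg) {
    ifelse(d <= 0, pmin(100 * (-d) / early_seg, 100),
           pmin(100 * d / late_seg, 100))
  }
  e_abs <- function(mu, sd, early_seg, late_seg) {
    if (sd == 0) return(err_pct(mu, early_seg, late_seg))
    g <- seq(mu - 8 * sd, mu + 8 * sd, length.out = 4001L)
    w <- stats::dnorm(g, mu, sd)
    sum(err_pct(g, early_seg, late_seg) * w) / sum(w)
  }
  e_tr <- e_abs(spec$trigger_delay_s, spec$trigger_delay_sd_s, te, ti)
  e_cy <- e_abs(spec$cycleoff_delay_s, spec$cycleoff_delay_sd_s, ti, te)
  p_d <- spec$p_double
  p_fail <- spec$p_wasted + spec$p_auto
  p_n <- 1 - p_fail - p_d
  # double-trigger assists: first cycles off early at DT_OFF1_FRAC of the
  # effort (error -100 * (1 - frac)), second triggers late at DT_ON2_FRAC
  cyc1 <- 100 * (1 - DT_OFF1_FRAC)
  trig2 <- 100 * DT_ON2_FRAC
  num <- p_n * (e_tr + e_cy) + p_fail * 200 +
    p_d * (e_tr + cyc1 + trig2 + e_cy)
  den <- p_n * 2 + p_fail * 2 + p_d * 4
  num / den
}
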