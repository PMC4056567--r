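#' @importFrom rlang .data
NULL

# Causal burst scan shared by the neural and ventilator detectors.
#
# State machine over the sample grid:
#   * search: track the running nadir since the last offset (ties move the
#     nadir forward, so on a flat baseline the onset lands at the last
#     baseline sample before the rise). When the signal exceeds
#     nadir + threshold (>= for EAdi, strict > for pressure), the onset is
#     the nadir sample. Crossings within `refractory_s` of the previous
#     offset are ignored.
#   * burst: track the running peak. The offset is the first post-peak
#     sample below the termination level (fraction of peak for EAdi;
#     baseline + fraction * amplitude for pressure). If instead the signal
#     rises by `threshold` above the post-peak local minimum before reaching
#     the termination level (merged bursts), the event is closed at that
#     local minimum and a new onset starts there.
# A burst still open at the end of the record is dropped.
scan_bursts <- function(t, x, threshold, termination_fraction,
                        refractory_s, strict_onset = FALSE,
                        baseline = NULL, backtrack_onset = FALSE) {
  n <- length(x)
  onsets <- integer(); offsets <- integer(); merged <- logical()
  in_burst <- FALSE
  nadir_val <- x[1]; nadir_idx <- 1L
  floor_idx <- 1L
  last_off_t <- -Inf
  peak_val <- NA_real_; peak_idx <- NA_integer_
  postmin_val <- NA_real_; postmin_idx <- NA_integer_
  onset_idx <- NA_integer_
  base_val <- NA_real_

  crosses <- function(v, ref) if (strict_onset) v > ref else v >= ref

  emit <- function(on_i, off_i, was_merged) {
    onsets[[length(onsets) + 1L]] <<- on_i
    offsets[[length(offsets) + 1L]] <<- off_i
    merged[[length(merged) + 1L]] <<- was_merged
  }

  i <- 2L
  while (i <= n) {
    v <- x[i]
    if (!in_burst) {
      if (v <= nadir_val) {
        nadir_val <- v; nadir_idx <- i
      } else if (crosses(v, nadir_val + threshold) &&
                 t[i] - last_off_t >= refractory_s) {
        in_burst <- TRUE
        if (backtrack_onset) {
          # onset at the beginning of the continuous rise: walk back from
          # the crossing to the most recent local minimum (a deep trough
          # earlier in expiration must not pre-date the pressurization)
          j <- i
          while (j - 1L > floor_idx && x[j - 1L] < x[j]) j <- j - 1L
          onset_idx <- j
        } else {
          onset_idx <- nadir_idx
        }
        if (!is.null(baseline)) base_val <- baseline(onset_idx)
        peak_val <- v; peak_idx <- i
        postmin_val <- v; postmin_idx <- i
      }
    } else {
      if (v > peak_val) {
        peak_val <- v; peak_idx <- i
        postmin_val <- v; postmin_idx <- i
      } else {
        lvl <- if (is.null(baseline)) {
          termination_fraction * peak_val
        } else {
          base_val + termination_fraction * (peak_val - base_val)
        }
        if (v < lvl) {
          emit(onset_idx, i, FALSE)
          in_burst <- FALSE
          last_off_t <- t[i]
          floor_idx <- i
          # nadir tracking resumes strictly after the offset sample so the
          # next onset cannot coincide with this offset
          nadir_val <- Inf; nadir_idx <- min(i + 1L, n)
        } else {
          if (v <= postmin_val) {
            postmin_val <- v; postmin_idx <- i
          } else if (crosses(v, postmin_val + threshold)) {
            # merged bursts: close at the inter-burst minimum and reopen at
            # the next sample, keeping event times strictly ordered
            emit(onset_idx, postmin_idx, TRUE)
            floor_idx <- postmin_idx
            onset_idx <- min(postmin_idx + 1L, i)
            if (!is.null(baseline)) base_val <- baseline(onset_idx)
            peak_val <- v; peak_idx <- i
            postmin_val <- v; postmin_idx <- i
          }
        }
      }
    }
    i <- i + 1L
  }
  list(onset_idx = onsets, offset_idx = offsets, merged = merged)
}

trapz_area <- function(t, y) {
  if (length(t) < 2L) return(0)
  pracma::trapz(t, pmax(y, 0))
}

#' Detect neural (EAdi) events
#'
#' Scans the EAdi channel causally: the running nadir since the last offset
#' is tracked, and when the signal rises to `nadir + threshold` an onset
#' (EAdi_ON) is emitted at the nadir the increase started from - the most
#' recent local minimum before the crossing - with its amplitude. The burst peak
#' is then followed, and the offset (EAdi_OFF) is the first post-peak sample
#' where the signal drops below `eadi_termination_fraction` of the peak
#' (default 70%). A burst whose descent never reaches the termination level
#' before the next rise is closed at the inter-burst minimum and flagged
#' `merged`.
#'
#' @param record A `waveform_df` tibble (see [as_waveform()]).
#' @param config An [ns_config()] list.
#' @return A tibble with one row per neural effort: `onset_s`, `offset_s`,
#'   `onset_amplitude_uV`, `peak_uV`, `area_uVs` (trapezoid integral of EAdi
#'   above the onset amplitude, clipped at zero), `merged`.
#' @export
#' @examples
#' rec <- as_waveform(data.frame(
#'   eadi_uV = c(rep(0, 100), seq(0, 10, length.out = 50),
#'               seq(10, 0, length.out = 50), rep(0, 100)),
#'   paw_cmH2O = rep(5, 300)))
#' detect_neural_events(rec)
detect_neural_events <- function(record, config = ns_config()) {
  if (nrow(record) < 3L) {
    stop("record too short for event detection (need >= 3 samples)",
         call. = FALSE)
  }
  t <- record$time_s; x <- record$eadi_uV
  hits <- scan_bursts(t, x,
                      threshold = config$eadi_trigger_threshold_uV,
                      termination_fraction = config$eadi_termination_fraction,
                      refractory_s = config$refractory_s,
                      strict_onset = FALSE,
                      backtrack_onset = TRUE)
  if (!length(hits$onset_idx)) {
    return(tibble::tibble(
      onset_s = numeric(), offset_s = numeric(),
      onset_amplitude_uV = numeric(), peak_uV = numeric(),
      area_uVs = numeric(), merged = logical()))
  }
  out <- purrr::pmap_dfr(hits, function(onset_idx, offset_idx, merged) {
    seg <- onset_idx:offset_idx
    tibble::tibble(
      onset_s = t[onset_idx],
      offset_s = t[offset_idx],
      onset_amplitude_uV = x[onset_idx],
      peak_uV = max(x[seg]),
      area_uVs = trapz_area(t[seg], x[seg] - x[onset_idx]),
      merged = merged
    )
  })
  if (nrow(out)) {
    # a burst must rise at least the trigger threshold above its own onset
    out <- dplyr::filter(
      out, .data$peak_uV >= .data$onset_amplitude_uV +
        config$eadi_trigger_threshold_uV)
  }
  out
}

#' Detect ventilator pressurization events
#'
#' Scans the airway-pressure channel for rises exceeding
#' `paw_rise_threshold_cmH2O` (strict `>`) above the running pre-breath
#' nadir; the onset (PS_ON) is the beginning of the continuous
#' pressurization rise, found by walking back from the threshold crossing to
#' the most recent local pressure minimum (so an expiratory-effort dip
#' earlier in the breath cannot pre-date the assist onset). PEEP is
#' estimated as the median pressure over
#' `peep_window_s` preceding the onset. The offset (PS_OFF) is the first
#' post-peak sample where pressure falls below
#' `PEEP + paw_termination_fraction * (peak - PEEP)`. Detection is relative
#' to the running nadir, so it is invariant to the PEEP level.
#'
#' @inheritParams detect_neural_events
#' @return A tibble with one row per assist: `onset_s`, `offset_s`,
#'   `peep_cmH2O`, `peak_paw_cmH2O`, `area_cmH2Os` (trapezoid integral of
#'   pressure above PEEP, clipped at zero), `merged`.
#' @export
detect_vent_events <- function(record, config = ns_config()) {
  if (nrow(record) < 3L) {
    stop("record too short for event detection (need >= 3 samples)",
         call. = FALSE)
  }
  t <- record$time_s; x <- record$paw_cmH2O
  win <- config$peep_window_s
  baseline <- function(onset_i) {
    lo <- t[onset_i] - win
    idx <- which(t >= lo & t < t[onset_i])
    if (!length(idx)) idx <- onset_i
    stats::median(x[idx])
  }
  hits <- scan_bursts(t, x,
                      threshold = config$paw_rise_threshold_cmH2O,
                      termination_fraction = config$paw_termination_fraction,
                      refractory_s = config$refractory_s,
                      strict_onset = TRUE,
                      baseline = baseline,
                      backtrack_onset = TRUE)
  if (!length(hits$onset_idx)) {
    return(tibble::tibble(
      onset_s = numeric(), offset_s = numeric(), peep_cmH2O = numeric(),
      peak_paw_cmH2O = numeric(), area_cmH2Os = numeric(),
      merged = logical()))
  }
  out <- purrr::pmap_dfr(hits, function(onset_idx, offset_idx, merged) {
    seg <- onset_idx:offset_idx
    peep <- baseline(onset_idx)
    tibble::tibble(
      onset_s = t[onset_idx],
      offset_s = t[offset_idx],
      peep_cmH2O = peep,
      peak_paw_cmH2O = max(x[seg]),
      area_cmH2Os = trapz_area(t[seg], x[seg] - peep),
      merged = merged
    )
  })
  if (nrow(out)) {
    out <- dplyr::filter(
      out, .data$peak_paw_cmH2O - .data$peep_cmH2O >
        config$paw_rise_threshold_cmH2O)
  }
  out
}

#' Remove subventilatory fragments
#'
#' Drops detected neural efforts with burst area strictly below
#' `defrag_eadi_min_area_uVs` (default 0.15 uV*s) and assists with
#' pressurization area strictly below `defrag_paw_min_area_cmH2Os` (default
#' 1.5 cmH2O*s). Events whose area equals the minimum are retained. A no-op
#' when `defrag_enabled` is `FALSE` or when areas are unavailable (`NA`,
#' e.g. annotation-derived events without a waveform).
#'
#' @param neural Tibble from [detect_neural_events()].
#' @param vent Tibble from [detect_vent_events()].
#' @param config An [ns_config()] list.
#' @return A list with elements `neural` and `vent`, filtered, order kept.
#' @export
defragment <- function(neural, vent, config = ns_config()) {
  if (!config$defrag_enabled) return(list(neural = neural, vent = vent))
  if (nrow(neural) && !all(is.na(neural$area_uVs))) {
    neural <- dplyr::filter(
      neural, is.na(.data$area_uVs) |
        .data$area_uVs >= config$defrag_eadi_min_area_uVs)
  }
  if (nrow(vent) && !all(is.na(vent$area_cmH2Os))) {
    vent <- dplyr::filter(
      vent, is.na(.data$area_cmH2Os) |
        .data$area_cmH2Os >= config$defrag_paw_min_area_cmH2Os)
  }
  list(neural = neural, vent = vent)
}

#' Build event tables from manual annotations
#'
#' Pairs consecutive onset/offset cursor times into neural and ventilator
#' events. When onset and offset counts differ by one, the trailing unpaired
#' onset is dropped with a warning; a larger mismatch is an error. Amplitude
#' and area fields are populated from `record` when one is supplied,
#' otherwise left `NA`.
#'
#' @param ann An [annotation_set()].
#' @param record Optional `waveform_df` the annotations refer to.
#' @param config An [ns_config()] list (used for the PEEP window).
#' @return A list with event tibbles `neural` and `vent` shaped like the
#'   output of the automatic detectors.
#' @export
events_from_annotations <- function(ann, record = NULL,
                                    config = ns_config()) {
  stopifnot(inherits(ann, "annotation_set"))
  pair <- function(on, off, what) {
    if (abs(length(on) - length(off)) > 1L) {
      stop("cannot pair ", what, " events: ", length(on), " onsets vs ",
           length(off), " offsets", call. = FALSE)
    }
    m <- min(length(on), length(off))
    if (length(on) > m) {
      warning("dropping trailing unpaired ", what, " onset", call. = FALSE)
    }
    if (length(off) > m) {
      warning("dropping trailing unpaired ", what, " offset", call. = FALSE)
    }
    on <- on[seq_len(m)]; off <- off[seq_len(m)]
    if (m && any(off <= on)) {
      stop(what, " offsets must follow their onsets", call. = FALSE)
    }
    list(on = on, off = off)
  }
  ne <- pair(ann$eadi_on_s, ann$eadi_off_s, "neural")
  ve <- pair(ann$ps_on_s, ann$ps_off_s, "ventilator")

  slice_vals <- function(ch, lo, hi) {
    idx <- which(record$time_s >= lo & record$time_s <= hi)
    record[[ch]][idx]
  }
  neural <- tibble::tibble(
    onset_s = ne$on, offset_s = ne$off,
    onset_amplitude_uV = NA_real_, peak_uV = NA_real_, area_uVs = NA_real_,
    merged = FALSE)
  vent <- tibble::tibble(
    onset_s = ve$on, offset_s = ve$off,
    peep_cmH2O = NA_real_, peak_paw_cmH2O = NA_real_, area_cmH2Os = NA_real_,
    merged = FALSE)

  if (!is.null(record)) {
    t <- record$time_s
    for (i in seq_len(nrow(neural))) {
      y <- slice_vals("eadi_uV", neural$onset_s[i], neural$offset_s[i])
      ts <- t[t >= neural$onset_s[i] & t <= neural$offset_s[i]]
      if (length(y)) {
        neural$onset_amplitude_uV[i] <- y[1]
        neural$peak_uV[i] <- max(y)
        neural$area_uVs[i] <- trapz_area(ts, y - y[1])
      }
    }
    for (i in seq_len(nrow(vent))) {
      on <- vent$onset_s[i]
      widx <- which(t >= on - config$peep_window_s & t < on)
      if (!length(widx)) widx <- which.min(abs(t - on))
      peep <- stats::median(record$paw_cmH2O[widx])
      y <- slice_vals("paw_cmH2O", on, vent$offset_s[i])
      ts <- t[t >= on & t <= vent$offset_s[i]]
      if (length(y)) {
        vent$peep_cmH2O[i] <- peep
        vent$peak_paw_cmH2O[i] <- max(y)
        vent$area_cmH2Os[i] <- trapz_area(ts, y - peep)
      }
    }
  }
  list(neural = neural, vent = vent)
}
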