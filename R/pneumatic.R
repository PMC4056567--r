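#' Per-breath pneumatic timing table
#'
#' Derives the flow/pressure-only view of the record: inspiratory time
#' `ti_s` (PS_ON to PS_OFF), expiratory time `te_s` (PS_OFF to the next
#' PS_ON, `NA` for the final breath) and whether the breath was
#' patient-triggered, i.e. preceded within `dip_window_s` by an airway
#' pressure drop of at least `dip_threshold_cmH2O`.
#'
#' @param record A `waveform_df` tibble.
#' @param vent Tibble of ventilator events ([detect_vent_events()]).
#' @param config An [ns_config()] list.
#' @return A tibble: `onset_s`, `offset_s`, `ti_s`, `te_s`,
#'   `patient_triggered`.
#' @export
pneumatic_breaths <- function(record, vent, config = ns_config()) {
  n <- nrow(vent)
  if (n == 0L) {
    return(tibble::tibble(onset_s = numeric(), offset_s = numeric(),
                          ti_s = numeric(), te_s = numeric(),
                          patient_triggered = logical()))
  }
  t <- record$time_s; paw <- record$paw_cmH2O
  dip <- vapply(vent$onset_s, function(on) {
    idx <- which(t >= on - config$dip_window_s & t <= on)
    if (length(idx) < 2L) return(0)
    max(paw[idx]) - paw[idx[length(idx)]]
  }, numeric(1))
  tibble::tibble(
    onset_s = vent$onset_s,
    offset_s = vent$offset_s,
    ti_s = vent$offset_s - vent$onset_s,
    te_s = c(vent$onset_s[-1] - vent$offset_s[-n], NA_real_),
    patient_triggered = dip >= config$dip_threshold_cmH2O)
}

#' Detect ineffective (wasted) efforts from flow and pressure
#'
#' Scans expiratory windows (between an assist's end and the next assist's
#' start) for an abrupt airway pressure drop of at least
#' `dip_threshold_cmH2O` within `dip_window_s`, coincident with a decrease
#' of the expiratory flow magnitude (signed flow deflecting toward
#' inspiration), and not followed by an assist within `dip_window_s`.
#' Requires a flow channel.
#'
#' @param record A `waveform_df` tibble with `flow_Lps`.
#' @param vent Tibble of ventilator events.
#' @param config An [ns_config()] list.
#' @return A tibble of detected dip times (`time_s`); `nrow()` is the count.
#' @export
detect_ineffective <- function(record, vent, config = ns_config()) {
  if (!"flow_Lps" %in% names(record)) {
    stop("ineffective-effort detection needs a flow channel; ",
         "use the EAdi-based analysis (neurosync()) instead", call. = FALSE)
  }
  t <- record$time_s; paw <- record$paw_cmH2O; flow <- record$flow_Lps
  fs <- sample_rate(record)
  w <- max(1L, round(config$dip_window_s * fs))
  windows <- expiratory_windows(vent, max(t))
  hits <- numeric()
  for (r in seq_len(nrow(windows))) {
    idx <- which(t > windows$start_s[r] & t < windows$end_s[r])
    idx <- idx[idx > w]
    i <- 1L
    while (i <= length(idx)) {
      s <- idx[i]
      drop <- max(paw[(s - w):s]) - paw[s]
      # inspiratory-direction flow deflection: the expiratory flow magnitude
      # falls (signed flow moves toward inspiration) over the dip window
      flow_dec <- flow[s] > flow[s - w]
      if (drop >= config$dip_threshold_cmH2O && flow_dec) {
        followed <- any(vent$onset_s > t[s] &
                          vent$onset_s <= t[s] + config$dip_window_s)
        if (!followed) {
          hits <- c(hits, t[s])
          i <- i + w  # refractory: one detection per dip
          next
        }
      }
      i <- i + 1L
    }
  }
  # keep the deepest sample of each dip: collapse hits closer than window
  if (length(hits) > 1L) {
    keep <- c(TRUE, diff(hits) > config$dip_window_s)
    hits <- hits[keep]
  }
  tibble::tibble(time_s = hits)
}

expiratory_windows <- function(vent, t_end) {
  n <- nrow(vent)
  if (n == 0L) return(tibble::tibble(start_s = 0, end_s = t_end))
  # everything outside an assist is expiration, including the stretch
  # before the first assist
  tibble::tibble(start_s = c(0, vent$offset_s),
                 end_s = c(vent$onset_s, t_end))
}

#' Count auto-triggered assists
#'
#' An assist delivered without a prior airway pressure decrease: no drop of
#' at least `dip_threshold_cmH2O` in the `dip_window_s` preceding PS_ON.
#'
#' @inheritParams detect_ineffective
#' @return A tibble of auto-trigger onset times (`time_s`).
#' @export
detect_autotrigger <- function(record, vent, config = ns_config()) {
  br <- pneumatic_breaths(record, vent, config)
  tibble::tibble(time_s = br$onset_s[!br$patient_triggered])
}

#' Count double-triggered breath pairs
#'
#' Two cycles separated by an expiratory time shorter than half the mean
#' inspiratory time (mean over all breaths in the record), the first cycle
#' being patient-triggered.
#'
#' @param breaths Tibble from [pneumatic_breaths()].
#' @return Number of qualifying pairs.
#' @export
#' @examples
#' br <- tibble::tibble(ti_s = c(1, 1), te_s = c(0.3, NA),
#'                      patient_triggered = c(TRUE, TRUE))
#' detect_double_trigger(br) # 1
detect_double_trigger <- function(breaths) {
  if (nrow(breaths) < 2L) return(0L)
  mean_ti <- mean(breaths$ti_s)
  te <- breaths$te_s[-nrow(breaths)]
  first_pt <- breaths$patient_triggered[-nrow(breaths)]
  sum(!is.na(te) & te < 0.5 * mean_ti & first_pt)
}

#' Classify short and prolonged cycles
#'
#' Short: inspiratory time strictly less than half the mean inspiratory
#' time. Prolonged: strictly greater than twice the mean. The mean is taken
#' over all breaths in the record.
#'
#' @param breaths Tibble from [pneumatic_breaths()].
#' @return A named list: `short`, `prolonged`.
#' @export
classify_cycles <- function(breaths) {
  if (nrow(breaths) < 2L) return(list(short = 0L, prolonged = 0L))
  mean_ti <- mean(breaths$ti_s)
  list(short = sum(breaths$ti_s < 0.5 * mean_ti),
       prolonged = sum(breaths$ti_s > 2 * mean_ti))
}

#' Tabulate flow/pressure asynchrony counts
#'
#' Applies all pneumatic definitions (ineffective triggering,
#' double-triggering, auto-triggering, short and prolonged cycles) to one
#' record.
#'
#' @inheritParams detect_ineffective
#' @return A one-row tibble of counts plus `total_breaths`.
#' @export
asynchrony_counts <- function(record, vent, config = ns_config()) {
  breaths <- pneumatic_breaths(record, vent, config)
  cyc <- classify_cycles(breaths)
  ineff <- if ("flow_Lps" %in% names(record)) {
    nrow(detect_ineffective(record, vent, config))
  } else {
    NA_integer_
  }
  tibble::tibble(
    ineffective = ineff,
    double_trigger = detect_double_trigger(breaths),
    auto_trigger = nrow(detect_autotrigger(record, vent, config)),
    short_cycle = cyc$short,
    prolonged_cycle = cyc$prolonged,
    total_breaths = nrow(breaths))
}

#' Pneumatic asynchrony index
#'
#' `AI = 100 * (ineffective + double + auto + short + prolonged) /
#' (total ventilator cycles + ineffective efforts)`, the classical
#' flow/pressure asynchrony index.
#'
#' @param counts One-row tibble from [asynchrony_counts()] (or any list with
#'   the same fields).
#' @return The index in percent.
#' @export
#' @examples
#' asynchrony_index(list(ineffective = 10, double_trigger = 0,
#'                       auto_trigger = 0, short_cycle = 0,
#'                       prolonged_cycle = 0, total_breaths = 90)) # 10
asynchrony_index <- function(counts) {
  ineff <- ifelse(is.na(counts$ineffective), 0L, counts$ineffective)
  denom <- counts$total_breaths + ineff
  if (denom <= 0) {
    stop("asynchrony index undefined: no breaths", call. = FALSE)
  }
  100 * (ineff + counts$double_trigger + counts$auto_trigger +
           counts$short_cycle + counts$prolonged_cycle) / denom
}

#' EAdi-verified asynchrony fraction
#'
#' The fraction of interaction events that are asynchronies when verified
#' against the EAdi signal: wasted efforts, assists without EAdi, multiple
#' EAdi during one assist, plus double-trigger pairs (each group of k
#' assists sharing one neural effort contributes k - 1 pairs).
#'
#' @param events Scored matched-event tibble (from a [neurosync()] result).
#' @return The fraction in percent.
#' @export
ai_colombo <- function(events) {
  if (nrow(events) == 0L) {
    stop("EAdi-verified asynchrony fraction undefined: no events",
         call. = FALSE)
  }
  n_async <- sum(events$category %in% ASYNC_CATEGORIES)
  dt <- events[events$category == "multiple_assist_during_eadi", ]
  dt_pairs <- if (nrow(dt)) {
    sum(pmax(table(dt$neural_id) - 1L, 0L))
  } else {
    0L
  }
  100 * (n_async + dt_pairs) / nrow(events)
}
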