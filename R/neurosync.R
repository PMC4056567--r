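#' Build neural detection periods
#'
#' For every interior neural effort i (the first and last efforts lack a
#' complete period and are excluded), the inspiratory detection period runs
#' from the previous effort's termination (EAdi_OFF, i-1) to this effort's
#' termination (EAdi_OFF, i), divided into early and late segments at the
#' onset EAdi_ON, i. The expiratory detection period runs from EAdi_ON, i to
#' the next onset EAdi_ON, i+1, divided at EAdi_OFF, i.
#'
#' @param neural Tibble of neural events ([detect_neural_events()]).
#' @return A tibble with one row per interior effort: `effort` (row index
#'   into `neural`), `insp_start_s`, `insp_divider_s`, `insp_end_s`,
#'   `exp_start_s`, `exp_divider_s`, `exp_end_s`. Fewer than 3 efforts give
#'   an empty tibble with a warning.
#' @export
#' @examples
#' ne <- tibble::tibble(onset_s = c(2, 6, 10), offset_s = c(3, 7, 11))
#' build_detection_periods(ne)
build_detection_periods <- function(neural) {
  empty <- tibble::tibble(
    effort = integer(), insp_start_s = numeric(), insp_divider_s = numeric(),
    insp_end_s = numeric(), exp_start_s = numeric(), exp_divider_s = numeric(),
    exp_end_s = numeric())
  n <- nrow(neural)
  if (n < 3L) {
    warning("need at least 3 neural efforts to build detection periods",
            call. = FALSE)
    return(empty)
  }
  i <- 2:(n - 1L)
  tibble::tibble(
    effort = i,
    insp_start_s = neural$offset_s[i - 1L],
    insp_divider_s = neural$onset_s[i],
    insp_end_s = neural$offset_s[i],
    exp_start_s = neural$onset_s[i],
    exp_divider_s = neural$offset_s[i],
    exp_end_s = neural$onset_s[i + 1L])
}

#' Signed trigger error
#'
#' Position of the assist onset (PS_ON) within the neural inspiratory
#' detection period, expressed as a signed percentage of the early or late
#' segment. PS_ON at the divider (EAdi_ON) gives 0%; earlier onsets map to
#' (-100, 0) as a fraction of the early segment, later ones to (0, 100] as a
#' fraction of the late segment. Values are clamped to [-100, 100].
#'
#' @param insp_start_s Period start (previous EAdi_OFF), seconds.
#' @param insp_divider_s Period divider (EAdi_ON), seconds.
#' @param insp_end_s Period end (EAdi_OFF), seconds.
#' @param ps_on_s Assist onset time, seconds. All arguments vectorized.
#' @return Signed error in percent.
#' @export
#' @examples
#' trigger_error(0, 2, 3, 1.2) # early triggering: -40
trigger_error <- function(insp_start_s, insp_divider_s, insp_end_s, ps_on_s) {
  signed_segment_error(insp_start_s, insp_divider_s, insp_end_s, ps_on_s)
}

#' Signed cycle-off error
#'
#' Position of the assist termination (PS_OFF) within the neural expiratory
#' detection period, divided at EAdi_OFF: early terminations map to
#' (-100, 0) of the early segment, late ones to (0, 100] of the late
#' segment. A PS_OFF beyond the period end (the next EAdi_ON) clamps to
#' +100; one before the period start clamps to -100.
#'
#' @param exp_start_s Period start (EAdi_ON), seconds.
#' @param exp_divider_s Period divider (EAdi_OFF), seconds.
#' @param exp_end_s Period end (next EAdi_ON), seconds.
#' @param ps_off_s Assist termination time, seconds. All vectorized.
#' @return Signed error in percent.
#' @export
#' @examples
#' cycleoff_error(2, 3, 5, 3.8) # late cycling-off: +40
cycleoff_error <- function(exp_start_s, exp_divider_s, exp_end_s, ps_off_s) {
  signed_segment_error(exp_start_s, exp_divider_s, exp_end_s, ps_off_s)
}

signed_segment_error <- function(start, divider, end, at) {
  stopifnot(all(start < divider), all(divider < end))
  early <- -100 * (divider - at) / (divider - start)
  late <- 100 * (at - divider) / (end - divider)
  err <- ifelse(at <= divider, early, late)
  pmin(pmax(err, -100), 100)
}

#' Pair ventilator events with neural detection periods
#'
#' Assigns each assist to the effort whose inspiratory detection period
#' contains its onset (half-open interval `(insp_start, insp_end]`, so an
#' onset exactly at the period start belongs to the earlier effort) and
#' derives the interaction category of every event:
#'
#' * `paired` - exactly one assist in the period, overlapping the burst.
#' * `multiple_assist_during_eadi` - two or more burst-overlapping assists
#'   in one period (double triggering); each is scored separately.
#' * `multiple_eadi_during_assist` - one assist spanning two or more neural
#'   onsets between its PS_ON and PS_OFF (asynchrony).
#' * `assist_without_eadi` - an assist ending before the neural onset of
#'   the effort it nominally pairs with, i.e. no overlap with any burst
#'   (auto-triggering; asynchrony).
#' * `eadi_without_assist` - an interior effort with no assist (wasted
#'   effort; asynchrony).
#'
#' Assists whose onset falls outside every period (possible only at the
#' record edges) are excluded and counted in the `n_edge_vent` attribute.
#'
#' @param periods Tibble from [build_detection_periods()].
#' @param vent Tibble of ventilator events ([detect_vent_events()]).
#' @param neural_onsets Optional vector of all neural onset times, used to
#'   count onsets spanned by an assist; defaults to the onsets recoverable
#'   from `periods`.
#' @return A tibble of matched events: `neural_id` (row in the neural event
#'   table, `NA` for assists without efforts), `vent_id` (row in `vent`,
#'   `NA` for wasted efforts), `category`. Attribute `n_edge_vent` counts
#'   excluded edge assists.
#' @export
pair_events <- function(periods, vent, neural_onsets = NULL) {
  if (is.null(neural_onsets)) {
    neural_onsets <- unique(c(periods$insp_divider_s,
                              periods$exp_end_s[nrow(periods)]))
  }
  empty <- tibble::tibble(neural_id = integer(), vent_id = integer(),
                          category = character(), onset_s = numeric())
  if (nrow(periods) == 0L) {
    out <- empty
    attr(out, "n_edge_vent") <- nrow(vent)
    return(out)
  }

  rows <- list()
  assist_effort <- rep(NA_integer_, nrow(vent))   # period row, not effort id
  assist_cat <- rep(NA_character_, nrow(vent))
  for (j in seq_len(nrow(vent))) {
    on <- vent$onset_s[j]; off <- vent$offset_s[j]
    k <- which(on > periods$insp_start_s & on <= periods$insp_end_s)
    if (!length(k)) next                      # record edge, excluded
    k <- k[1]
    assist_effort[j] <- k
    n_spanned <- sum(neural_onsets > on & neural_onsets < off)
    if (n_spanned >= 2) {
      assist_cat[j] <- "multiple_eadi_during_assist"
    } else if (off <= periods$insp_divider_s[k]) {
      assist_cat[j] <- "assist_without_eadi"
    } else {
      assist_cat[j] <- "candidate"
    }
  }
  # double triggering: >= 2 burst-overlapping assists in one period
  cand <- which(assist_cat == "candidate")
  if (length(cand)) {
    tab <- table(assist_effort[cand])
    multi <- as.integer(names(tab)[tab >= 2])
    assist_cat[cand] <- ifelse(assist_effort[cand] %in% multi,
                               "multiple_assist_during_eadi", "paired")
  }

  for (j in seq_len(nrow(vent))) {
    if (is.na(assist_cat[j])) next
    k <- assist_effort[j]
    rows[[length(rows) + 1L]] <- tibble::tibble(
      neural_id = if (assist_cat[j] == "assist_without_eadi") NA_integer_
                  else periods$effort[k],
      vent_id = j,
      category = assist_cat[j],
      onset_s = vent$onset_s[j])
  }

  # efforts consumed by an assist: their own candidate/multiple assist, or
  # a spanning multiple_eadi_during_assist burst
  consumed <- periods$effort[assist_effort[
    !is.na(assist_cat) & assist_cat != "assist_without_eadi"]]
  span <- which(assist_cat == "multiple_eadi_during_assist")
  for (j in span) {
    hit <- periods$insp_divider_s > vent$onset_s[j] &
      periods$insp_divider_s < vent$offset_s[j]
    consumed <- c(consumed, periods$effort[hit])
  }
  wasted <- setdiff(periods$effort, consumed)
  for (e in wasted) {
    rows[[length(rows) + 1L]] <- tibble::tibble(
      neural_id = e, vent_id = NA_integer_,
      category = "eadi_without_assist",
      onset_s = periods$insp_divider_s[periods$effort == e])
  }

  out <- if (length(rows)) {
    dplyr::arrange(dplyr::bind_rows(rows), .data$onset_s)
  } else {
    empty
  }
  attr(out, "n_edge_vent") <- sum(is.na(assist_cat))
  out
}

ASYNC_CATEGORIES <- c("eadi_without_assist", "assist_without_eadi",
                      "multiple_eadi_during_assist")

score_events <- function(matched, periods, vent) {
  if (nrow(matched) == 0L) {
    matched$trigger_error_pct <- numeric()
    matched$cycleoff_error_pct <- numeric()
    return(matched)
  }
  trig <- cyc <- rep(100, nrow(matched))
  finite <- matched$category %in% c("paired", "multiple_assist_during_eadi")
  for (i in which(finite)) {
    p <- periods[periods$effort == matched$neural_id[i], ]
    v <- vent[matched$vent_id[i], ]
    trig[i] <- trigger_error(p$insp_start_s, p$insp_divider_s, p$insp_end_s,
                             v$onset_s)
    cyc[i] <- cycleoff_error(p$exp_start_s, p$exp_divider_s, p$exp_end_s,
                             v$offset_s)
  }
  matched$trigger_error_pct <- trig
  matched$cycleoff_error_pct <- cyc
  matched
}

#' Classify scored events
#'
#' Events in the asynchrony categories (wasted efforts, assists without
#' EAdi, multiple EAdi during one assist) are `asynchrony` with both errors
#' forced to 100%. Otherwise an event is `synchrony` when both absolute
#' errors are at most `sync_box_limit_pct` (inclusive, default 33%), else
#' `dyssynchrony` - including large negative trigger errors, kept finite for
#' symmetry of the display.
#'
#' @param events Scored matched-event tibble (with `trigger_error_pct` and
#'   `cycleoff_error_pct`).
#' @param config An [ns_config()] list.
#' @return `events` with a `classification` column.
#' @export
classify_events <- function(events, config = ns_config()) {
  box <- config$sync_box_limit_pct
  is_async <- events$category %in% ASYNC_CATEGORIES
  events$trigger_error_pct[is_async] <- 100
  events$cycleoff_error_pct[is_async] <- 100
  events$classification <- dplyr::case_when(
    is_async ~ "asynchrony",
    abs(events$trigger_error_pct) <= box &
      abs(events$cycleoff_error_pct) <= box ~ "synchrony",
    TRUE ~ "dyssynchrony")
  events
}

#' NeuroSync index
#'
#' The pooled mean of the absolute trigger and cycle-off errors over all
#' events, in percent: 0 is perfect interaction, 100 complete asynchrony.
#' Asynchronous events contribute 100 and 100.
#'
#' @param events Scored matched-event tibble.
#' @return The index in percent.
#' @export
#' @examples
#' ev <- tibble::tibble(category = "paired",
#'                      trigger_error_pct = c(-40, 40),
#'                      cycleoff_error_pct = c(-40, 40))
#' neurosync_index(ev) # 40
neurosync_index <- function(events) {
  if (nrow(events) == 0L) {
    stop("NeuroSync index is undefined for an empty event list",
         call. = FALSE)
  }
  mean(c(abs(events$trigger_error_pct), abs(events$cycleoff_error_pct)))
}

quadrant_of <- function(cycleoff, trigger) {
  dplyr::case_when(
    cycleoff >= 0 & trigger >= 0 ~ "upper_right",
    cycleoff < 0 & trigger >= 0 ~ "upper_left",
    cycleoff < 0 & trigger < 0 ~ "lower_left",
    TRUE ~ "lower_right")
}

#' Score paired neural and ventilator event tables
#'
#' Runs the scoring half of the pipeline on already-detected (or manually
#' annotated) event tables: detection periods, pairing, signed errors,
#' classification and the NeuroSync index.
#'
#' @param neural,vent Event tibbles shaped like the detector outputs.
#' @param config An [ns_config()] list.
#' @return A `neurosync` object; see [neurosync()].
#' @export
neurosync_from_events <- function(neural, vent, config = ns_config()) {
  periods <- if (nrow(neural) >= 3L) build_detection_periods(neural) else
    suppressWarnings(build_detection_periods(neural))
  matched <- pair_events(periods, vent, neural_onsets = neural$onset_s)
  events <- score_events(matched, periods, vent)
  events <- classify_events(events, config)

  cats <- c("paired", "multiple_assist_during_eadi", ASYNC_CATEGORIES)
  category_counts <- tibble::tibble(
    category = cats,
    n = vapply(cats, function(cc) sum(events$category == cc), integer(1)))
  cls <- c("synchrony", "dyssynchrony", "asynchrony")
  classification_counts <- tibble::tibble(
    classification = cls,
    n = vapply(cls, function(cc) sum(events$classification == cc),
               integer(1)))
  finite <- events$category %in% c("paired", "multiple_assist_during_eadi")
  quads <- c("upper_right", "upper_left", "lower_left", "lower_right")
  qf <- if (any(finite)) {
    q <- quadrant_of(events$cycleoff_error_pct[finite],
                     events$trigger_error_pct[finite])
    tibble::tibble(quadrant = quads,
                   fraction = vapply(quads, function(qq) mean(q == qq),
                                     numeric(1)))
  } else {
    tibble::tibble(quadrant = quads, fraction = rep(0, 4))
  }

  structure(list(
    events = events,
    index_pct = if (nrow(events)) neurosync_index(events) else NA_real_,
    category_counts = category_counts,
    classification_counts = classification_counts,
    quadrant_fractions = qf,
    n_neural = nrow(neural),
    n_vent = nrow(vent),
    n_edge_vent = attr(matched, "n_edge_vent"),
    n_edge_efforts = if (nrow(neural) >= 3L) 2L else nrow(neural),
    config = config
  ), class = "neurosync")
}

#' Analyze a waveform record for patient-ventilator interaction
#'
#' The full pipeline: detect neural and ventilator events, remove
#' subventilatory fragments, build detection periods, pair events, compute
#' signed trigger and cycle-off errors, classify each event and compute the
#' NeuroSync index. Deterministic for a fixed record and configuration.
#'
#' When `annotations` are supplied the cursor times replace automatic
#' detection (the manual variant of the index); amplitudes and areas are
#' read off the waveform so defragmentation still applies.
#'
#' @param record A `waveform_df` tibble.
#' @param config An [ns_config()] list.
#' @param annotations Optional [annotation_set()] of manual event times.
#' @return An object of class `neurosync`: a list with the scored `events`
#'   tibble, `index_pct`, `category_counts`, `classification_counts`,
#'   `quadrant_fractions`, and bookkeeping counts (`n_neural`, `n_vent`,
#'   `n_edge_vent`).
#' @export
#' @examples
#' sim <- simulate_psv(sim_spec(n_breaths = 8, seed = 1))
#' res <- neurosync(sim$record)
#' res$index_pct
neurosync <- function(record, config = ns_config(), annotations = NULL) {
  if (is.null(annotations)) {
    neural <- detect_neural_events(record, config)
    vent <- detect_vent_events(record, config)
  } else {
    ev <- events_from_annotations(annotations, record, config)
    neural <- ev$neural
    vent <- ev$vent
  }
  d <- defragment(neural, vent, config)
  neurosync_from_events(d$neural, d$vent, config)
}

#' @export
print.neurosync <- function(x, ...) {
  cat("<neurosync> ", nrow(x$events), " events, index ",
      ifelse(is.na(x$index_pct), "NA",
             formatC(x$index_pct, digits = 1, format = "f")), "%\n", sep = "")
  cc <- x$classification_counts
  cat("  ", paste(sprintf("%s: %d", cc$classification, cc$n),
                  collapse = "  "), "\n")
  invisible(x)
}

#' Tidy a NeuroSync result into its per-event table
#' @param x A `neurosync` object.
#' @param ... Unused.
#' @return The scored events tibble.
#' @export
tidy.neurosync <- function(x, ...) x$events

#' One-row summary of a NeuroSync result
#' @param x A `neurosync` object.
#' @param ... Unused.
#' @return A one-row tibble: index, event counts and classification
#'   fractions.
#' @export
glance.neurosync <- function(x, ...) {
  n <- nrow(x$events)
  cc <- stats::setNames(x$classification_counts$n,
                        x$classification_counts$classification)
  tibble::tibble(
    index_pct = x$index_pct,
    n_events = n,
    n_neural = x$n_neural,
    n_vent = x$n_vent,
    pct_synchrony = if (n) 100 * cc[["synchrony"]] / n else NA_real_,
    pct_dyssynchrony = if (n) 100 * cc[["dyssynchrony"]] / n else NA_real_,
    pct_asynchrony = if (n) 100 * cc[["asynchrony"]] / n else NA_real_)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
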