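#' Coerce a data frame to a validated waveform record
#'
#' A waveform record is a tibble with columns `time_s`, `eadi_uV`,
#' `paw_cmH2O` and optionally `flow_Lps`, on a strictly increasing uniform
#' time grid. Column names are matched case-insensitively. If no time column
#' is present a grid is synthesized at `sample_rate_hz`. Negative EAdi
#' samples (noise on a rectified magnitude signal) are clipped to zero with
#' a message reporting how many were affected.
#'
#' @param df A data frame with at least EAdi and airway-pressure columns.
#' @param sample_rate_hz Sampling rate used to synthesize a time grid when
#'   the input has no `time_s` column. Default 100.
#' @return A tibble of class `waveform_df` with attribute `sample_rate_hz`.
#' @export
#' @examples
#' as_waveform(data.frame(eadi_uV = c(0, 1, 2), paw_cmH2O = c(5, 5, 5)))
as_waveform <- function(df, sample_rate_hz = 100) {
  stopifnot(is.data.frame(df))
  canonical <- c(time_s = "time_s", eadi_uv = "eadi_uV",
                 paw_cmh2o = "paw_cmH2O", flow_lps = "flow_Lps")
  idx <- match(tolower(names(df)), names(canonical))
  names(df)[!is.na(idx)] <- canonical[idx[!is.na(idx)]]

  for (ch in c("eadi_uV", "paw_cmH2O")) {
    if (!ch %in% names(df)) {
      stop("waveform file is missing required channel `", ch, "`",
           call. = FALSE)
    }
  }
  n <- nrow(df)
  if (n < 2L) stop("waveform record needs at least 2 samples", call. = FALSE)

  if (!"time_s" %in% names(df)) {
    df$time_s <- (seq_len(n) - 1) / sample_rate_hz
  } else {
    dt <- diff(df$time_s)
    if (any(dt <= 0)) {
      stop("time grid is not strictly increasing at sample ",
           which(dt <= 0)[1] + 1L, call. = FALSE)
    }
    dt0 <- dt[1]
    bad <- which(abs(dt - dt0) > 1e-6 * max(dt0, 1e-12))
    if (length(bad)) {
      stop(sprintf(
        "non-uniform sampling: spacing %.6g s at sample %d differs from %.6g s",
        dt[bad[1]], bad[1] + 1L, dt0), call. = FALSE)
    }
    sample_rate_hz <- 1 / dt0
  }

  n_neg <- sum(df$eadi_uV < 0)
  if (n_neg > 0) {
    message("clipped ", n_neg, " negative EAdi sample",
            if (n_neg > 1) "s", " to 0")
    df$eadi_uV <- pmax(df$eadi_uV, 0)
  }

  keep <- intersect(c("time_s", "eadi_uV", "paw_cmH2O", "flow_Lps"), names(df))
  out <- tibble::as_tibble(df[keep])
  attr(out, "sample_rate_hz") <- sample_rate_hz
  class(out) <- c("waveform_df", class(out))
  out
}

#' Read a waveform record from delimited text
#'
#' Accepts comma- or tab-delimited text with a header row naming the
#' channels (`time_s`, `eadi_uV`, `paw_cmH2O`, optional `flow_Lps`, any
#' case). Records without a `time_s` column are placed on an implied uniform
#' grid at `sample_rate_hz`.
#'
#' @inheritParams as_waveform
#' @param path Path to the file.
#' @return A `waveform_df` tibble; see [as_waveform()].
#' @export
read_waveform <- function(path, sample_rate_hz = 100) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_delim(path, delim = detect_delim(path),
                          show_col_types = FALSE, progress = FALSE)
  as_waveform(df, sample_rate_hz = sample_rate_hz)
}

#' Write a waveform record to delimited text
#'
#' @param record A `waveform_df` tibble.
#' @param path Output path; comma-delimited with a header row.
#' @return `record`, invisibly.
#' @export
write_waveform <- function(record, path) {
  readr::write_csv(tibble::as_tibble(unclass_waveform(record)), path)
  invisible(record)
}

unclass_waveform <- function(record) {
  class(record) <- setdiff(class(record), "waveform_df")
  record
}

detect_delim <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) && grepl("\t", first, fixed = TRUE)) "\t" else ","
}

#' Sampling rate of a waveform record
#' @param record A `waveform_df` tibble.
#' @return Samples per second.
#' @export
sample_rate <- function(record) {
  sr <- attr(record, "sample_rate_hz")
  if (is.null(sr)) sr <- 1 / (record$time_s[2] - record$time_s[1])
  sr
}

#' Construct a manual-annotation event set
#'
#' Holds cursor-placed event times: neural onsets (`eadi_on_s`), neural
#' terminations (`eadi_off_s`), assist onsets (`ps_on_s`) and assist
#' terminations (`ps_off_s`), each strictly increasing.
#'
#' @param eadi_on_s,eadi_off_s,ps_on_s,ps_off_s Numeric vectors of event
#'   times in seconds.
#' @param analyst_id,pass_id Labels identifying the analyst and the analysis
#'   pass (first/second).
#' @return A list of class `annotation_set`.
#' @export
annotation_set <- function(eadi_on_s = numeric(), eadi_off_s = numeric(),
                           ps_on_s = numeric(), ps_off_s = numeric(),
                           analyst_id = "unknown", pass_id = "1") {
  out <- list(eadi_on_s = as.numeric(eadi_on_s),
              eadi_off_s = as.numeric(eadi_off_s),
              ps_on_s = as.numeric(ps_on_s),
              ps_off_s = as.numeric(ps_off_s),
              analyst_id = analyst_id, pass_id = pass_id)
  for (k in c("eadi_on_s", "eadi_off_s", "ps_on_s", "ps_off_s")) {
    v <- out[[k]]
    if (anyNA(v)) stop("annotation list `", k, "` contains NA", call. = FALSE)
    if (length(v) > 1 && any(diff(v) <= 0)) {
      stop("annotation list `", k, "` is not strictly increasing",
           call. = FALSE)
    }
  }
  structure(out, class = "annotation_set")
}

#' Read manual annotations from delimited text
#'
#' Expects columns `kind` (one of `eadi_on`, `eadi_off`, `ps_on`, `ps_off`)
#' and `time_s`, with optional `analyst_id` and `pass_id`. An empty file is a
#' valid, empty annotation set. Times must already be sorted within each
#' kind; unsorted input is a validation error.
#'
#' @param path Path to the file.
#' @return An `annotation_set`.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0L) return(annotation_set())
  df <- readr::read_delim(path, delim = detect_delim(path),
                          show_col_types = FALSE, progress = FALSE)
  if (nrow(df) == 0L) return(annotation_set())
  if (!all(c("kind", "time_s") %in% names(df))) {
    stop("annotation file needs `kind` and `time_s` columns", call. = FALSE)
  }
  bad <- setdiff(unique(df$kind), c("eadi_on", "eadi_off", "ps_on", "ps_off"))
  if (length(bad)) stop("unknown annotation kind: ", bad[1], call. = FALSE)
  grab <- function(k) df$time_s[df$kind == k]
  annotation_set(
    eadi_on_s = grab("eadi_on"), eadi_off_s = grab("eadi_off"),
    ps_on_s = grab("ps_on"), ps_off_s = grab("ps_off"),
    analyst_id = if ("analyst_id" %in% names(df) && nrow(df))
      as.character(df$analyst_id[1]) else "unknown",
    pass_id = if ("pass_id" %in% names(df) && nrow(df))
      as.character(df$pass_id[1]) else "1"
  )
}

#' Write manual annotations to delimited text
#'
#' @param ann An `annotation_set`.
#' @param path Output path; comma-delimited `kind,time_s,analyst_id,pass_id`.
#' @return `ann`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  stopifnot(inherits(ann, "annotation_set"))
  kinds <- c("eadi_on", "eadi_off", "ps_on", "ps_off")
  df <- purrr::map_dfr(kinds, function(k) {
    tibble::tibble(kind = k, time_s = ann[[paste0(k, "_s")]])
  })
  df$analyst_id <- ann$analyst_id
  df$pass_id <- ann$pass_id
  readr::write_csv(df, path)
  invisible(ann)
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("<annotation_set> analyst:", x$analyst_id, " pass:", x$pass_id, "\n")
  cat(sprintf("  eadi_on: %d  eadi_off: %d  ps_on: %d  ps_off: %d\n",
              length(x$eadi_on_s), length(x$eadi_off_s),
              length(x$ps_on_s), length(x$ps_off_s)))
  invisible(x)
}

#' Write a scored result table to delimited text
#'
#' Writes a summary header (index, event counts, one `#`-prefixed line per
#' field) followed by the per-event table: event id, category,
#' classification, trigger and cycle-off errors in percent.
#'
#' @param result A `neurosync` result, see [neurosync()].
#' @param path Output path.
#' @return `result`, invisibly.
#' @export
write_results <- function(result, path) {
  stopifnot(inherits(result, "neurosync"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  idx <- if (nrow(result$events) == 0) "" else
    format(result$index_pct, digits = 15)
  writeLines(sprintf("# index_pct: %s", idx), con)
  writeLines(sprintf("# n_events: %d", nrow(result$events)), con)
  cls <- result$classification_counts
  for (i in seq_len(nrow(cls))) {
    writeLines(sprintf("# n_%s: %d", cls$classification[i], cls$n[i]), con)
  }
  ev <- result$events
  ev$event <- seq_len(nrow(ev))
  cols <- c("event", "neural_id", "vent_id", "category", "classification",
            "trigger_error_pct", "cycleoff_error_pct")
  writeLines(sub("\n$", "", readr::format_csv(ev[cols])), con)
  invisible(result)
}

#' Read back a result table written by [write_results()]
#'
#' @param path Path to the file.
#' @return A list with `index_pct`, `n_events`, per-classification counts and
#'   the per-event tibble `events`.
#' @export
read_results <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  parse_hdr <- function(key) {
    ln <- hdr[startsWith(hdr, paste0("# ", key, ":"))]
    if (!length(ln)) return(NA_real_)
    val <- trimws(sub(paste0("# ", key, ":"), "", ln[1], fixed = TRUE))
    if (!nzchar(val)) NA_real_ else as.numeric(val)
  }
  events <- if (length(body) > 1) {
    readr::read_csv(I(paste(body, collapse = "\n")),
                    show_col_types = FALSE, progress = FALSE)
  } else {
    tibble::tibble()
  }
  keys <- sub(":.*$", "", sub("^# ", "", hdr))
  counts <- keys[startsWith(keys, "n_") & keys != "n_events"]
  list(index_pct = parse_hdr("index_pct"),
       n_events = parse_hdr("n_events"),
       classification_counts = stats::setNames(
         vapply(counts, parse_hdr, numeric(1)), sub("^n_", "", counts)),
       events = events)
}
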