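#' Breathing-pattern summary
#'
#' Neural frequency (efforts/min, from EAdi onsets), ventilator frequency
#' (assists/min, from PS onsets), per-breath tidal volumes (trapezoid
#' integral of positive flow during each assist, when flow is present),
#' pressurization amplitudes above PEEP, per-effort EAdi peaks, and binned
#' histograms of each. With two or more events the frequency uses the
#' onset-to-onset span, `60 * (n - 1) / span`, which is unbiased for partial
#' records; with fewer it falls back to count per record minute.
#'
#' @param neural Tibble of neural events.
#' @param vent Tibble of ventilator events.
#' @param record The `waveform_df` the events came from (needed for tidal
#'   volumes and record duration).
#' @param freq_bin_bpm,vt_bin_L,paw_bin_cmH2O,eadi_bin_uV Histogram bin
#'   widths: breaths/min, litres, cmH2O and uV.
#' @return A list of class `breathing_pattern`: scalars `f_n_bpm`,
#'   `f_v_bpm`; vectors `vt_L`, `pv_above_peep_cmH2O`, `eadi_peak_uV`,
#'   `f_n_inst_bpm`, `f_v_inst_bpm` (per-interval instantaneous
#'   frequencies); and a named list `histograms` of `bin_lo`/`bin_hi`/`n`
#'   tibbles.
#' @export
breathing_pattern <- function(neural, vent, record,
                              freq_bin_bpm = 2, vt_bin_L = 0.05,
                              paw_bin_cmH2O = 1, eadi_bin_uV = 1) {
  dur_min <- (max(record$time_s) - min(record$time_s)) / 60
  freq_of <- function(onsets) {
    n <- length(onsets)
    if (n >= 2L) {
      60 * (n - 1) / (onsets[n] - onsets[1])
    } else if (dur_min > 0) {
      n / dur_min
    } else {
      0
    }
  }
  if (nrow(neural) == 0L && nrow(vent) == 0L) {
    warning("no events: breathing pattern is all zeros", call. = FALSE)
  }
  vt <- rep(NA_real_, nrow(vent))
  if ("flow_Lps" %in% names(record) && nrow(vent)) {
    t <- record$time_s
    for (i in seq_len(nrow(vent))) {
      idx <- which(t >= vent$onset_s[i] & t <= vent$offset_s[i])
      if (length(idx) > 1L) {
        vt[i] <- pracma::trapz(t[idx], pmax(record$flow_Lps[idx], 0))
      }
    }
  }
  inst <- function(onsets) if (length(onsets) >= 2L) 60 / diff(onsets)
    else numeric()
  pv <- if (nrow(vent)) vent$peak_paw_cmH2O - vent$peep_cmH2O else numeric()
  pk <- if (nrow(neural)) neural$peak_uV else numeric()

  hist_tbl <- function(x, width) {
    x <- x[is.finite(x)]
    if (!length(x)) {
      return(tibble::tibble(bin_lo = numeric(), bin_hi = numeric(),
                            n = integer()))
    }
    lo <- floor(min(x) / width) * width
    hi <- ceiling(max(x) / width) * width
    if (hi <= lo) hi <- lo + width
    breaks <- seq(lo, hi, by = width)
    cnt <- as.integer(table(cut(x, breaks, include.lowest = TRUE,
                                right = FALSE)))
    tibble::tibble(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1],
                   n = cnt)
  }

  structure(list(
    f_n_bpm = freq_of(neural$onset_s),
    f_v_bpm = freq_of(vent$onset_s),
    f_n_inst_bpm = inst(neural$onset_s),
    f_v_inst_bpm = inst(vent$onset_s),
    vt_L = vt,
    pv_above_peep_cmH2O = pv,
    eadi_peak_uV = pk,
    histograms = list(
      f_n = hist_tbl(inst(neural$onset_s), freq_bin_bpm),
      f_v = hist_tbl(inst(vent$onset_s), freq_bin_bpm),
      vt = hist_tbl(vt, vt_bin_L),
      pv = hist_tbl(pv, paw_bin_cmH2O),
      eadi = hist_tbl(pk, eadi_bin_uV))
  ), class = "breathing_pattern")
}

#' @export
print.breathing_pattern <- function(x, ...) {
  cat(sprintf("<breathing_pattern> F_N %.1f /min, F_V %.1f /min\n",
              x$f_n_bpm, x$f_v_bpm))
  if (any(is.finite(x$vt_L))) {
    cat(sprintf("  mean Vt %.3f L\n", mean(x$vt_L, na.rm = TRUE)))
  }
  invisible(x)
}

#' Intraclass correlation coefficient
#'
#' Two-way ICC from the ANOVA mean squares of a ratings table (rows =
#' analysis units, columns = raters or methods). The default,
#' `"agreement"`/`"single"`, is ICC(2,1): two-way random effects, absolute
#' agreement, single measure - the standard inter-rater reliability form.
#' `type = "consistency"` gives ICC(3,1); `unit = "average"` gives the
#' average-measure versions ICC(2,k) / ICC(3,k).
#'
#' @param ratings A numeric matrix or data frame, at least 2 x 2, no missing
#'   cells.
#' @param type `"agreement"` (absolute agreement) or `"consistency"`.
#' @param unit `"single"` or `"average"` measures.
#' @return The coefficient (a single number in `[-1, 1]`).
#' @export
#' @examples
#' icc(cbind(a = c(1, 2, 3, 4), b = c(1.1, 2.1, 2.9, 4.2)))
icc <- function(ratings, type = c("agreement", "consistency"),
                unit = c("single", "average")) {
  type <- match.arg(type)
  unit <- match.arg(unit)
  m <- as.matrix(ratings)
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("ratings table has missing cells", call. = FALSE)
  n <- nrow(m); k <- ncol(m)
  if (n < 2L || k < 2L) {
    stop("ratings table must be at least 2 x 2", call. = FALSE)
  }
  gm <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  sst <- sum((m - gm)^2)
  ssr <- k * sum((row_m - gm)^2)
  ssc <- n * sum((col_m - gm)^2)
  sse <- sst - ssr - ssc
  if (sst <= .Machine$double.eps * max(1, abs(gm))) {
    stop("ICC undefined: ratings table has zero total variance",
         call. = FALSE)
  }
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (type == "agreement") {
    if (unit == "single") {
      (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
    } else {
      (msr - mse) / (msr + (msc - mse) / n)
    }
  } else {
    if (unit == "single") {
      (msr - mse) / (msr + (k - 1) * mse)
    } else {
      (msr - mse) / msr
    }
  }
}

#' Read a ratings table from delimited text
#'
#' Rows are analysis units, columns raters/methods; the first column may be
#' a unit label (non-numeric), which is dropped.
#'
#' @param path Path to the file.
#' @return A numeric matrix suitable for [icc()].
#' @export
read_ratings <- function(path) {
  df <- readr::read_delim(path, delim = detect_delim(path),
                          show_col_types = FALSE, progress = FALSE)
  num <- vapply(df, is.numeric, logical(1))
  as.matrix(df[num])
}
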