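# Independent reference implementations used as oracles.
#
# ref_detect_neural() / ref_detect_vent() re-implement the detection rules
# as a plain, explicit state machine: running-nadir threshold crossing with
# a refractory period, onset backtracked to the most recent local minimum,
# peak-relative termination, merged-burst closure at the inter-burst
# minimum, and the amplitude post-filters. They are kept deliberately
# simple and separate from the package internals.

ref_scan <- function(t, x, thr, frac, refr, strict, peep_fun = NULL) {
  n <- length(x)
  out <- list()
  phase <- "search"
  nadir <- x[1]
  last_off_time <- -Inf
  floor_i <- 1L
  onset <- peak <- postmin_v <- postmin_i <- base <- NA
  i <- 2L
  while (i <= n) {
    if (phase == "search") {
      if (x[i] <= nadir) {
        nadir <- x[i]
      } else {
        hit <- if (strict) x[i] > nadir + thr else x[i] >= nadir + thr
        if (hit && t[i] - last_off_time >= refr) {
          j <- i
          while (j - 1L > floor_i && x[j - 1L] < x[j]) j <- j - 1L
          onset <- j
          base <- if (is.null(peep_fun)) NA else peep_fun(onset)
          peak <- x[i]
          postmin_v <- x[i]; postmin_i <- i
          phase <- "burst"
        }
      }
    } else {
      if (x[i] > peak) {
        peak <- x[i]
        postmin_v <- x[i]; postmin_i <- i
      } else {
        level <- if (is.null(peep_fun)) frac * peak else
          base + frac * (peak - base)
        rehit <- if (strict) x[i] > postmin_v + thr else
          x[i] >= postmin_v + thr
        if (x[i] < level) {
          out[[length(out) + 1L]] <- c(onset, i, FALSE)
          phase <- "search"
          last_off_time <- t[i]
          floor_i <- i
          nadir <- Inf
        } else if (x[i] <= postmin_v) {
          postmin_v <- x[i]; postmin_i <- i
        } else if (rehit) {
          out[[length(out) + 1L]] <- c(onset, postmin_i, TRUE)
          floor_i <- postmin_i
          onset <- min(postmin_i + 1L, i)
          base <- if (is.null(peep_fun)) NA else peep_fun(onset)
          peak <- x[i]
          postmin_v <- x[i]; postmin_i <- i
        }
      }
    }
    i <- i + 1L
  }
  if (!length(out)) {
    return(data.frame(onset_idx = integer(), offset_idx = integer(),
                      merged = logical()))
  }
  m <- do.call(rbind, out)
  data.frame(onset_idx = m[, 1], offset_idx = m[, 2],
             merged = as.logical(m[, 3]))
}

ref_trapz_pos <- function(t, y) {
  y <- pmax(y, 0)
  if (length(t) < 2L) return(0)
  sum(diff(t) * (head(y, -1) + tail(y, -1)) / 2)
}

ref_detect_neural <- function(record, config = ns_config()) {
  t <- record$time_s; x <- record$eadi_uV
  hits <- ref_scan(t, x, config$eadi_trigger_threshold_uV,
                   config$eadi_termination_fraction, config$refractory_s,
                   strict = FALSE)
  rows <- lapply(seq_len(nrow(hits)), function(r) {
    a <- hits$onset_idx[r]; b <- hits$offset_idx[r]
    data.frame(onset_s = t[a], offset_s = t[b],
               onset_amplitude_uV = x[a], peak_uV = max(x[a:b]),
               area_uVs = ref_trapz_pos(t[a:b], x[a:b] - x[a]),
               merged = hits$merged[r])
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(onset_s = numeric(), offset_s = numeric(),
               onset_amplitude_uV = numeric(), peak_uV = numeric(),
               area_uVs = numeric(), merged = logical())
  df[df$peak_uV >= df$onset_amplitude_uV +
       config$eadi_trigger_threshold_uV, , drop = FALSE]
}

ref_detect_vent <- function(record, config = ns_config()) {
  t <- record$time_s; x <- record$paw_cmH2O
  peep_fun <- function(i) {
    w <- which(t >= t[i] - config$peep_window_s & t < t[i])
    if (!length(w)) w <- i
    median(x[w])
  }
  hits <- ref_scan(t, x, config$paw_rise_threshold_cmH2O,
                   config$paw_termination_fraction, config$refractory_s,
                   strict = TRUE, peep_fun = peep_fun)
  rows <- lapply(seq_len(nrow(hits)), function(r) {
    a <- hits$onset_idx[r]; b <- hits$offset_idx[r]
    peep <- peep_fun(a)
    data.frame(onset_s = t[a], offset_s = t[b], peep_cmH2O = peep,
               peak_paw_cmH2O = max(x[a:b]),
               area_cmH2Os = ref_trapz_pos(t[a:b], x[a:b] - peep),
               merged = hits$merged[r])
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(onset_s = numeric(), offset_s = numeric(),
               peep_cmH2O = numeric(), peak_paw_cmH2O = numeric(),
               area_cmH2Os = numeric(), merged = logical())
  df[df$peak_paw_cmH2O - df$peep_cmH2O > config$paw_rise_threshold_cmH2O, ,
     drop = FALSE]
}

# Random short fixtures exercising bursts, dips, plateaus and noise on both
# channels, for the detector-vs-oracle equivalence checks.
random_record <- function(seed, n = NULL) {
  set.seed(seed)
  if (is.null(n)) n <- sample(300:2000, 1)
  fs <- 100
  t <- (seq_len(n) - 1) / fs
  eadi <- rep(runif(1, 0, 1), n)
  paw <- rep(runif(1, 3, 8), n)
  for (k in seq_len(sample(1:8, 1))) {
    c0 <- runif(1, 0, max(t))
    w <- runif(1, 0.1, 1.5)
    a <- runif(1, 0.2, 15)
    shape <- pmax(1 - abs(t - c0) / w, 0)
    eadi <- eadi + a * shape
  }
  for (k in seq_len(sample(0:6, 1))) {
    c0 <- runif(1, 0, max(t))
    w <- runif(1, 0.2, 1.2)
    a <- runif(1, 1, 15)
    box <- as.numeric(t >= c0 & t <= c0 + w)
    ramp <- pmin((t - c0) / 0.1, 1) * box
    paw <- paw + a * ramp
  }
  for (k in seq_len(sample(0:3, 1))) {
    c0 <- runif(1, 0, max(t))
    paw <- paw - runif(1, 0.3, 1) * pmax(1 - abs(t - c0) / 0.15, 0)
  }
  eadi <- pmax(eadi + rnorm(n, 0, runif(1, 0, 0.3)), 0)
  paw <- paw + rnorm(n, 0, runif(1, 0, 0.3))
  as_waveform(tibble::tibble(time_s = t, eadi_uV = eadi, paw_cmH2O = paw))
}
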