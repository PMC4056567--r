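#' Analysis configuration
#'
#' Bundles every tunable threshold of the event-detection and scoring
#' pipeline. Defaults follow the published automated method: a 0.5 uV EAdi
#' trigger threshold (0.25 and 1.0 uV are the other validated settings), a
#' neural termination level at 70% of the burst peak, a >3 cmH2O
#' pressurization rise, defragmentation area minima of 0.15 uV*s (EAdi) and
#' 1.5 cmH2O*s (pressure), and a +/-33% synchrony box.
#'
#' @param eadi_trigger_threshold_uV Rise above the running EAdi nadir (uV)
#'   that defines a neural onset. Validated settings: 0.25, 0.5 or 1.0.
#' @param eadi_termination_fraction Fraction of the burst peak at which the
#'   neural effort is considered terminated (EAdi_OFF). Default 0.70.
#' @param paw_rise_threshold_cmH2O Pressure rise above the running pre-breath
#'   nadir (cmH2O, strict `>`) that defines a ventilator onset (PS_ON).
#' @param paw_termination_fraction PS_OFF is the first post-peak sample where
#'   pressure falls below PEEP + this fraction of the pressurization
#'   amplitude. Mirrors the neural termination criterion.
#' @param defrag_enabled Remove subventilatory fragments before scoring?
#' @param defrag_eadi_min_area_uVs Minimum EAdi burst area (uV*s) to count as
#'   an effort; strictly smaller bursts are dropped.
#' @param defrag_paw_min_area_cmH2Os Minimum pressurization area (cmH2O*s) to
#'   count as an assist; strictly smaller events are dropped.
#' @param sync_box_limit_pct Half-width of the synchrony box on both error
#'   axes, in percent. Events with both |errors| <= the limit are synchrony.
#' @param refractory_s Minimum time after an offset before a new onset may be
#'   emitted (suppresses single-sample re-triggers).
#' @param peep_window_s Window before PS_ON over which PEEP is estimated as
#'   the median pressure.
#' @param dip_threshold_cmH2O Minimum abrupt pressure drop that marks a
#'   patient effort on the airway pressure signal (pneumatic definitions).
#' @param dip_window_s Look-back / look-ahead window for the pneumatic dip
#'   and triggering checks.
#'
#' @return A list of class `ns_config`.
#' @export
#' @examples
#' ns_config(eadi_trigger_threshold_uV = 0.25)
ns_config <- function(eadi_trigger_threshold_uV = 0.5,
                      eadi_termination_fraction = 0.70,
                      paw_rise_threshold_cmH2O = 3.0,
                      paw_termination_fraction = 0.70,
                      defrag_enabled = TRUE,
                      defrag_eadi_min_area_uVs = 0.15,
                      defrag_paw_min_area_cmH2Os = 1.5,
                      sync_box_limit_pct = 33.0,
                      refractory_s = 0.1,
                      peep_window_s = 0.2,
                      dip_threshold_cmH2O = 0.5,
                      dip_window_s = 0.3) {
  cfg <- list(
    eadi_trigger_threshold_uV = eadi_trigger_threshold_uV,
    eadi_termination_fraction = eadi_termination_fraction,
    paw_rise_threshold_cmH2O = paw_rise_threshold_cmH2O,
    paw_termination_fraction = paw_termination_fraction,
    defrag_enabled = isTRUE(defrag_enabled),
    defrag_eadi_min_area_uVs = defrag_eadi_min_area_uVs,
    defrag_paw_min_area_cmH2Os = defrag_paw_min_area_cmH2Os,
    sync_box_limit_pct = sync_box_limit_pct,
    refractory_s = refractory_s,
    peep_window_s = peep_window_s,
    dip_threshold_cmH2O = dip_threshold_cmH2O,
    dip_window_s = dip_window_s
  )
  validate_config(cfg)
  structure(cfg, class = "ns_config")
}

validate_config <- function(cfg) {
  num <- c("eadi_trigger_threshold_uV", "paw_rise_threshold_cmH2O",
           "defrag_eadi_min_area_uVs", "defrag_paw_min_area_cmH2Os",
           "dip_threshold_cmH2O", "dip_window_s", "peep_window_s")
  for (f in num) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || !(cfg[[f]] > 0)) {
      stop("config field `", f, "` must be a single positive number",
           call. = FALSE)
    }
  }
  for (f in c("eadi_termination_fraction", "paw_termination_fraction")) {
    if (!(cfg[[f]] > 0 && cfg[[f]] < 1)) {
      stop("config field `", f, "` must lie in (0, 1)", call. = FALSE)
    }
  }
  if (!(cfg$sync_box_limit_pct > 0 && cfg$sync_box_limit_pct < 100)) {
    stop("`sync_box_limit_pct` must lie in (0, 100)", call. = FALSE)
  }
  if (!(cfg$refractory_s >= 0)) {
    stop("`refractory_s` must be >= 0", call. = FALSE)
  }
  invisible(cfg)
}

#' Read a flat key = value configuration file
#'
#' Each non-blank, non-comment line has the form `key = value`, with keys
#' named after [ns_config()] arguments. Unknown keys raise an error.
#'
#' @param path Path to the configuration file.
#' @return A list of class `ns_config`.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  args <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("malformed config line: ", ln, call. = FALSE)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (!key %in% names(formals(ns_config))) {
      stop("unknown config key: ", key, call. = FALSE)
    }
    args[[key]] <- if (key == "defrag_enabled") {
      tolower(val) %in% c("true", "1", "yes")
    } else {
      as.numeric(val)
    }
  }
  do.call(ns_config, args)
}

#' @export
print.ns_config <- function(x, ...) {
  cat("<ns_config>\n")
  for (f in names(x)) cat(sprintf("  %-28s %s\n", f, format(x[[f]])))
  invisible(x)
}
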