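#' Classifier configuration
#'
#' Thresholds of the response-type criteria. A trace is *responsive* when its
#' peak output exceeds the detection threshold `theta` (10 pM by default; the
#' value is an operational choice, since physiological nuclear
#' transcription-factor concentrations are not known quantitatively).
#' Responsive traces are then phenotyped on their dynamics over the 10-hour
#' observation window: *sustained* responses reach 90% of their peak within
#' 2 hours and retain it to the end; *transient* responses fall below 10% of
#' peak within 2 hours of stimulation and end below `0.1 * theta`;
#' *oscillatory* responses show at least `min_extra_peaks` further amplitudes
#' above `0.1 * theta` after the initial peak, and are sub-labelled
#' sustained- or dampened-oscillatory depending on whether the fifth
#' amplitude is at least half the second. Anything else is *undefined*.
#'
#' In *series mode* (dose series or protein-concentration scans) the
#' threshold is set per trace to that trace's own peak value, which makes all
#' sub-criteria relative; an absolute floor (`series_floor`, 0.1 pM) still
#' separates numerically-zero traces from responsive ones.
#'
#' @param theta Responsiveness threshold (pM).
#' @param t_fast Fast-response window (s); default 2 h.
#' @param t_end Observation horizon (s); default 10 h.
#' @param t_max Maximal horizon when following slow oscillations (s);
#'   default 100 h.
#' @param sustained_fraction Fraction of peak that must be reached quickly
#'   and retained (default 0.9).
#' @param transient_fraction Fraction of peak below which a transient
#'   response must fall (default 0.1).
#' @param amplitude_floor Minimal oscillation amplitude (pM); default
#'   `0.1 * theta`, recomputed per trace in series mode.
#' @param min_extra_peaks Number of qualifying amplitudes after the initial
#'   peak required to call oscillations (default 4).
#' @param damp_ratio Fifth-to-second amplitude ratio separating sustained
#'   from dampened oscillations (default 0.5).
#' @param series_mode Use the per-trace peak as threshold (see above).
#' @param series_floor Absolute responsiveness floor in series mode (pM).
#' @return A list of class `"tgf_classifier_config"`.
#' @export
classifier_config <- function(theta = 10, t_fast = 7200, t_end = 36000,
                              t_max = 360000, sustained_fraction = 0.9,
                              transient_fraction = 0.1,
                              amplitude_floor = NULL, min_extra_peaks = 4,
                              damp_ratio = 0.5, series_mode = FALSE,
                              series_floor = 0.1) {
  stopifnot(theta > 0, t_fast < t_end, t_end <= t_max,
            sustained_fraction > 0, sustained_fraction < 1,
            transient_fraction > 0, transient_fraction < 1,
            min_extra_peaks >= 1, damp_ratio > 0, series_floor > 0)
  structure(list(theta = theta, t_fast = t_fast, t_end = t_end,
                 t_max = t_max, sustained_fraction = sustained_fraction,
                 transient_fraction = transient_fraction,
                 amplitude_floor = amplitude_floor,
                 min_extra_peaks = min_extra_peaks, damp_ratio = damp_ratio,
                 series_mode = series_mode, series_floor = series_floor),
            class = "tgf_classifier_config")
}

#' The seven response labels
#' @return Character vector of the label vocabulary, in reporting order.
#' @export
response_labels <- function() {
  c("sustained", "transient", "dampened_oscillatory",
    "sustained_oscillatory", "unresponsive", "undefined", "failed")
}

#' Alternating local extrema of a sampled trace
#'
#' Strict local minima and maxima of the sampled series, endpoints excluded.
#' Runs of exactly equal consecutive values (plateaus) are merged and
#' represented by a single extremum at the plateau midpoint.
#'
#' @param trace A `"tgf_trace"` (or any data frame with `time_s`,
#'   `output_pM`).
#' @return Tibble with columns `time_s`, `value`, `type`
#'   (`"min"`/`"max"`), ordered in time and alternating in type.
#' @export
find_extrema <- function(trace) {
  y <- trace$output_pM
  t <- trace$time_s
  r <- rle(y)
  nruns <- length(r$values)
  if (nruns < 3) {
    return(tibble::tibble(time_s = numeric(), value = numeric(),
                          type = character()))
  }
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  mid_t <- (t[starts] + t[ends]) / 2
  v <- r$values
  d1 <- diff(v)[-(nruns - 1L)]     # slope into runs 2..n-1
  d2 <- diff(v)[-1L]               # slope out of runs 2..n-1
  is_max <- d1 > 0 & d2 < 0
  is_min <- d1 < 0 & d2 > 0
  keep <- which(is_max | is_min) + 1L
  tibble::tibble(
    time_s = mid_t[keep],
    value = v[keep],
    type = ifelse(is_max[keep - 1L], "max", "min")
  )
}

# amplitude sequence after the initial peak: for each local maximum after
# the first one reaching theta, its value minus the preceding local minimum
amplitude_sequence <- function(extrema, theta) {
  if (nrow(extrema) == 0) {
    return(tibble::tibble(time_s = numeric(), amplitude = numeric()))
  }
  imax <- which(extrema$type == "max")
  first_peak <- imax[extrema$value[imax] >= theta * (1 - 1e-9)][1]
  if (is.na(first_peak)) {
    return(tibble::tibble(time_s = numeric(), amplitude = numeric()))
  }
  later_max <- imax[imax > first_peak]
  # extrema alternate strictly, so the preceding minimum is the previous row
  amp <- extrema$value[later_max] - extrema$value[later_max - 1L]
  tibble::tibble(time_s = extrema$time_s[later_max], amplitude = amp)
}

#' Classify one response trace
#'
#' Applies the phenotype criteria of [classifier_config()] to a simulated or
#' analytic trace. The trace must cover at least the observation horizon
#' `t_end`; points beyond it (from oscillation-following extensions) enter
#' only the oscillation metrics, while peak/retention/decay criteria are
#' evaluated on the `[0, t_end]` window.
#'
#' Precedence: a failed trace is labelled `failed`; then `unresponsive` if
#' the peak stays below the threshold; then the oscillation test, then
#' sustained, then transient; responsive traces matching no criterion are
#' `undefined`. Numerical ties at the 90%/10% boundaries resolve toward the
#' stricter criterion with a relative tolerance of 1e-9.
#'
#' @param trace A `"tgf_trace"`.
#' @param cfg A [classifier_config()].
#' @return A list of class `"tgf_classification"`: `label`, `Opeak` (pM),
#'   `t_peak90` (s), `Oend` (pM), `theta_used` (pM), `amplitudes` (tibble),
#'   `n_peaks`, `period_s`, `duration_s`.
#' @export
#' @examples
#' tr <- make_trace(fixture_spec("sustained_exponential"))
#' classify_trace(tr)$label
classify_trace <- function(trace, cfg = classifier_config()) {
  stopifnot(inherits(cfg, "tgf_classifier_config"))
  if (!trace_succeeded(trace)) {
    return(new_classification("failed", cfg))
  }
  if (max(trace$time_s) < cfg$t_end) {
    stop("trace must cover the observation horizon t_end")
  }
  in_win <- trace$time_s <= cfg$t_end
  y <- trace$output_pM
  Opeak <- max(y[in_win])
  Oend <- y[which(in_win)[sum(in_win)]]

  theta <- if (cfg$series_mode) max(Opeak, cfg$series_floor) else cfg$theta
  floor_amp <- if (is.null(cfg$amplitude_floor) || cfg$series_mode)
    cfg$transient_fraction * theta else cfg$amplitude_floor

  res <- new_classification("undefined", cfg)
  res$Opeak <- Opeak
  res$Oend <- Oend
  res$theta_used <- theta

  responsive <- if (cfg$series_mode) Opeak >= cfg$series_floor
    else Opeak >= theta * (1 - 1e-9)
  if (!responsive) {
    res$label <- "unresponsive"
    return(res)
  }

  extrema <- find_extrema(trace)
  amps <- amplitude_sequence(extrema, theta)
  res$amplitudes <- amps
  qualifying <- amps$amplitude > floor_amp
  res$n_peaks <- sum(qualifying)
  if (res$n_peaks >= cfg$min_extra_peaks) {
    a2 <- if (nrow(amps) >= 2) amps$amplitude[2] else 0
    a5 <- if (nrow(amps) >= 5) amps$amplitude[5] else 0
    res$label <- if (a5 >= cfg$damp_ratio * a2 * (1 - 1e-9))
      "sustained_oscillatory" else "dampened_oscillatory"
    qt <- amps$time_s[qualifying]
    if (length(qt) >= 2) res$period_s <- stats::median(diff(qt))
    res$duration_s <- max(qt)
    return(res)
  }

  lvl90 <- cfg$sustained_fraction * Opeak
  i90 <- which(in_win & y >= lvl90 * (1 - 1e-9))[1]
  t90 <- trace$time_s[i90]
  res$t_peak90 <- t90
  retained <- all(y[in_win & trace$time_s >= t90] >= lvl90 * (1 - 1e-9))
  if (t90 <= cfg$t_fast && retained) {
    res$label <- "sustained"
    return(res)
  }

  lvl10 <- cfg$transient_fraction * Opeak
  t_peak <- trace$time_s[in_win][which.max(y[in_win])]
  decayed <- any(trace$time_s > t_peak & trace$time_s <= cfg$t_fast &
                   y < lvl10)
  if (decayed && Oend < cfg$transient_fraction * theta) {
    res$label <- "transient"
  }
  res
}

new_classification <- function(label, cfg) {
  structure(list(label = label, Opeak = NA_real_, t_peak90 = NA_real_,
                 Oend = NA_real_, theta_used = NA_real_,
                 amplitudes = tibble::tibble(time_s = numeric(),
                                             amplitude = numeric()),
                 n_peaks = 0L, period_s = NA_real_, duration_s = NA_real_,
                 cfg = cfg),
            class = "tgf_classification")
}

#' @export
print.tgf_classification <- function(x, ...) {
  cat(sprintf("<tgf_classification> %s (Opeak %.4g pM, Oend %.4g pM, %d peaks)\n",
              x$label, x$Opeak, x$Oend, x$n_peaks))
  invisible(x)
}

#' Simulate and classify, following slow oscillations beyond 10 hours
#'
#' Runs [simulate_tgf()] to the observation horizon and classifies the trace.
#' If the amplitude sequence has not decayed below the oscillation floor by
#' the end of the horizon, the simulation is re-run with a doubled horizon
#' (capped at `t_max`, 100 h) until the oscillations have vanished or the cap
#' is reached, so that the period and the sustained/dampened sub-label are
#' never biased by the period length relative to the window.
#'
#' @inheritParams simulate_tgf
#' @param cfg A [classifier_config()].
#' @param keep_trace Attach the (possibly extended) trace as field `trace`.
#' @return A `"tgf_classification"` (see [classify_trace()]).
#' @export
classify_with_extension <- function(params, totals = total_concentrations(),
                                    protocol = protocol_constant(),
                                    cfg = classifier_config(),
                                    keep_trace = FALSE) {
  horizon <- cfg$t_end
  repeat {
    tr <- simulate_tgf(params, totals, protocol, duration_s = horizon)
    res <- classify_trace(tr, cfg)
    if (res$label == "failed") break
    amps <- res$amplitudes
    floor_amp <- cfg$transient_fraction * res$theta_used
    last_alive <- nrow(amps) > 0 &&
      amps$amplitude[nrow(amps)] > floor_amp
    if (!last_alive || horizon >= cfg$t_max) break
    horizon <- min(2 * horizon, cfg$t_max)
  }
  if (keep_trace) res$trace <- tr
  res
}

#' One-row summary of a classification
#'
#' @param x A `"tgf_classification"`.
#' @param ... Unused.
#' @return A one-row tibble with the label and all scalar metrics.
#' @method tidy tgf_classification
#' @export
tidy.tgf_classification <- function(x, ...) {
  tibble::tibble(label = x$label, Opeak = x$Opeak, t_peak90 = x$t_peak90,
                 Oend = x$Oend, theta_used = x$theta_used,
                 n_peaks = x$n_peaks, period_s = x$period_s,
                 duration_s = x$duration_s)
}
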