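# Per-IED temporal and spectral features, 40-s binning, and thermal-phase
# segmentation of temperature traces.

#' Peak-to-peak amplitude of a segment
#'
#' @param segment numeric vector (µV).
#' @return `max(segment) - min(segment)`.
#' @export
p2p <- function(segment) {
  if (length(segment) == 0L) stop("`segment` must be non-empty", call. = FALSE)
  max(segment) - min(segment)
}

#' Negative-peak to peak-to-peak ratio (N/P2P)
#'
#' The segment is centred on its own mean first (the preprocessed signal is
#' zero-mean by construction; centring keeps the feature well defined on
#' arbitrary inputs), then the ratio `|min| / (max - min)` is returned. A
#' constant segment has no defined ratio and yields `NA`.
#'
#' @param segment numeric vector.
#' @return value in `[0, 1]`, or `NA_real_` for a constant segment.
#' @export
negative_ratio <- function(segment) {
  if (length(segment) == 0L) stop("`segment` must be non-empty", call. = FALSE)
  x <- segment - mean(segment)
  rng <- max(x) - min(x)
  if (rng == 0) return(NA_real_)
  abs(min(x)) / rng
}

#' Band-power fraction of a segment
#'
#' Single Hann-tapered periodogram of the full segment (no Welch splitting:
#' on a 300-ms segment it would destroy the 2-8 Hz resolution); the ratio
#' of power in `band` to power in `total_band`, both bands half-open
#' `[low, high)`.
#'
#' @param segment numeric vector.
#' @param fs sampling rate (Hz), >= 600.
#' @param band length-2 band of interest (Hz).
#' @param total_band normalising band (Hz), default 2-300.
#' @return fraction in `[0, 1]`, or `NA_real_` if the total-band power is 0.
#' @export
band_power_ratio <- function(segment, fs, band, total_band = c(2, 300)) {
  stopifnot_scalar_number(fs, "fs", min = 600)
  if (length(band) != 2L || band[1] >= band[2]) {
    stop("`band` must be an increasing length-2 vector", call. = FALSE)
  }
  pg <- hann_periodogram(segment, fs)
  den <- sum(pg$P[pg$f >= total_band[1] & pg$f < total_band[2]])
  if (den == 0) return(NA_real_)
  num <- sum(pg$P[pg$f >= band[1] & pg$f < band[2]])
  num / den
}

# single Hann-tapered periodogram (half spectrum)
hann_periodogram <- function(segment, fs) {
  n <- length(segment)
  if (n < 8L) stop("`segment` too short for a periodogram", call. = FALSE)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1)) # symmetric Hann
  P <- Mod(stats::fft(segment * w))^2
  f <- (seq_len(n) - 1) * fs / n
  half <- f < fs / 2
  list(f = f[half], P = P[half])
}

# band fraction from a precomputed periodogram
band_fraction <- function(pg, band, total_band = c(2, 300)) {
  den <- sum(pg$P[pg$f >= total_band[1] & pg$f < total_band[2]])
  if (den == 0) return(NA_real_)
  sum(pg$P[pg$f >= band[1] & pg$f < band[2]]) / den
}

#' All per-event features of one segment
#'
#' @param segment numeric vector (2-300 Hz filtered, 300 ms).
#' @param fs sampling rate (Hz).
#' @return one-row data frame: `p2p_uv`, `n_over_p2p`, `bp_2_8`, `bp_28_80`.
#' @export
ied_features <- function(segment, fs) {
  pg <- hann_periodogram(segment, fs)
  data.frame(p2p_uv = p2p(segment),
             n_over_p2p = negative_ratio(segment),
             bp_2_8 = band_fraction(pg, c(2, 8)),
             bp_28_80 = band_fraction(pg, c(28, 80)))
}

#' Feature table of a detection result
#'
#' @param detection an [detect_ieds()] result.
#' @return data frame: events with their features.
#' @export
ied_features_table <- function(detection) {
  ev <- detection$events
  if (nrow(ev) == 0L) {
    return(cbind(ev, p2p_uv = numeric(0), n_over_p2p = numeric(0),
                 bp_2_8 = numeric(0), bp_28_80 = numeric(0)))
  }
  feats <- do.call(rbind, lapply(seq_len(nrow(ev)), function(i) {
    ied_features(detection$segments[i, ], detection$fs)
  }))
  cbind(ev, feats)
}

#' IED rate per 40-s bin
#'
#' @param event_times_s numeric vector of event times (s).
#' @param protocol an [build_protocol()] timeline.
#' @param bin_s bin width (s), default 40.
#' @return an object of class `binned_series`: data frame with
#'   `bin_start_s`, `bin_end_s`, `value` (event count).
#' @export
ied_rate <- function(event_times_s, protocol, bin_s = BIN_S) {
  edges <- protocol_bin_edges(protocol, bin_s)
  if (length(event_times_s) > 0 &&
      (any(event_times_s < 0) || any(event_times_s > protocol$duration_s))) {
    stop("event times outside the protocol duration", call. = FALSE)
  }
  counts <- if (length(event_times_s) == 0) {
    rep(0, length(edges) - 1L)
  } else {
    idx <- findInterval(event_times_s, edges, rightmost.closed = TRUE)
    tabulate(idx, nbins = length(edges) - 1L)
  }
  structure(data.frame(bin_start_s = edges[-length(edges)],
                       bin_end_s = edges[-1], value = counts),
            feature = "rate", class = c("binned_series", "data.frame"))
}

#' Per-bin mean of a per-event feature
#'
#' Bins with no events are filled by linear interpolation between the
#' nearest non-empty bins (constant extension at the ends); an entirely
#' empty series is an error.
#'
#' @param event_times_s event times (s).
#' @param values per-event feature values, same length.
#' @param protocol an [build_protocol()] timeline.
#' @param bin_s bin width (s), default 40.
#' @return a `binned_series` data frame (`bin_start_s`, `bin_end_s`,
#'   `value`, `n_events`, `interpolated`).
#' @export
bin_feature <- function(event_times_s, values, protocol, bin_s = BIN_S) {
  if (length(event_times_s) != length(values)) {
    stop("`event_times_s` and `values` must have equal length", call. = FALSE)
  }
  edges <- protocol_bin_edges(protocol, bin_s)
  nb <- length(edges) - 1L
  idx <- findInterval(event_times_s, edges, rightmost.closed = TRUE)
  means <- rep(NA_real_, nb)
  counts <- integer(nb)
  if (length(idx) > 0) {
    agg <- tapply(values, factor(idx, levels = seq_len(nb)), mean)
    means <- as.numeric(agg)
    counts <- as.integer(tabulate(idx, nbins = nb))
  }
  filled <- !is.na(means)
  if (!any(filled)) {
    stop("no analyzable events: every bin is empty", call. = FALSE)
  }
  interp <- !filled
  if (any(interp)) {
    means <- stats::approx(which(filled), means[filled],
                           xout = seq_len(nb), rule = 2)$y
  }
  structure(data.frame(bin_start_s = edges[-length(edges)],
                       bin_end_s = edges[-1], value = means,
                       n_events = counts, interpolated = interp),
            class = c("binned_series", "data.frame"))
}

#' Segment a temperature trace into the three thermal phases
#'
#' Per ON/OFF cycle: the heating-up phase runs from laser onset to the
#' first time the near-sensor temperature reaches baseline +
#' `threshold_frac` x (cycle maximum - baseline); the steady-maximum phase
#' lasts until the temperature first drops below that level after laser
#' OFF; the thermal-drop phase covers the rest of the cycle. Cycles whose
#' elevation stays below `min_rise_c` are flagged undefined.
#'
#' @param trace a [simulate_temperature()] result (or data frame with
#'   `times_s` and `temp_near_c`).
#' @param protocol an [build_protocol()] timeline.
#' @param threshold_frac fraction of the cycle elevation separating
#'   heating-up from steady-maximum (default 0.9).
#' @param min_rise_c minimum cycle elevation (°C) for the phases to be
#'   defined.
#' @return data frame, one row per trial: phase boundary times and a
#'   `defined` flag.
#' @export
segment_thermal_phases <- function(trace, protocol, threshold_frac = 0.9,
                                   min_rise_c = 0.1) {
  if (protocol$n_trials == 0L) {
    stop("protocol has no ON/OFF cycles", call. = FALSE)
  }
  tt <- trace$times_s
  temp <- trace$temp_near_c
  base_sel <- tt < PCTRL_S
  baseline <- if (any(base_sel)) mean(temp[base_sel]) else temp[1]

  ph <- protocol$phases
  out <- lapply(seq_len(protocol$n_trials), function(tr) {
    on_row <- ph[ph$trial == tr & ph$laser_on, ]
    off_row <- ph[ph$trial == tr & !ph$laser_on, ]
    onset <- on_row$start_s
    off_onset <- off_row$start_s
    cyc_end <- off_row$end_s
    sel <- tt >= onset & tt <= cyc_end
    cyc_max <- max(temp[sel])
    if (cyc_max - baseline < min_rise_c) {
      return(data.frame(trial = tr, heating_start_s = NA_real_,
                        heating_end_s = NA_real_, steady_end_s = NA_real_,
                        drop_end_s = NA_real_, defined = FALSE))
    }
    level <- baseline + threshold_frac * (cyc_max - baseline)
    in_on <- which(sel & temp >= level)
    heat_end <- tt[in_on[1]]
    after_off <- which(tt > off_onset & tt <= cyc_end & temp < level)
    steady_end <- if (length(after_off) > 0) tt[after_off[1]] else cyc_end
    data.frame(trial = tr, heating_start_s = onset,
               heating_end_s = heat_end, steady_end_s = steady_end,
               drop_end_s = cyc_end, defined = TRUE)
  })
  do.call(rbind, out)
}
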