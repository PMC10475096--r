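# Synthetic micro-ECoG generator: background model, IED prototypes, and
# protocol-modulated recordings with ground truth.
#
# The generative model is deliberately simple but covers every signal
# component the analysis chain has to cope with: 1/f ("pink") background,
# 50 Hz line interference, a 28-80 Hz gamma-band component whose power is
# boosted during laser-ON, an 80-120 Hz narrowband stimulation artifact
# gated by the laser drive, and IED events from a phase-modulated renewal
# process with a 350 ms hard minimum spacing.

# --- seeded noise generators (spectrally shaped white noise) -----------------

# Gaussian noise with the given folded amplitude spectrum, synthesized
# directly in the frequency domain (one inverse FFT; the spectrum of white
# noise is iid complex Gaussian with Hermitian symmetry).
spectral_noise <- function(n, amp) {
  draws <- stats::rnorm(n)
  X <- complex(length.out = n)
  m <- n %/% 2
  X[1] <- draws[1]
  if (n %% 2 == 0) {
    X[m + 1] <- draws[m + 1]
    ks <- if (m >= 2) 2:m else integer(0)
  } else {
    ks <- if (m >= 1) 2:(m + 1) else integer(0)
  }
  if (length(ks) > 0) {
    X[ks] <- complex(real = draws[ks], imaginary = draws[n + 2 - ks]) /
      sqrt(2)
    X[n + 2 - ks] <- Conj(X[ks])
  }
  Re(stats::fft(X * amp, inverse = TRUE)) / n
}

# folded frequency axis of an n-point transform
folded_freqs <- function(n, fs) {
  f <- (seq_len(n) - 1) * fs / n
  pmin(f, fs - f)
}

pink_amp <- function(n, fs, fmin = 2) {
  amp <- 1 / sqrt(pmax(folded_freqs(n, fs), fmin))
  amp[1] <- 0
  amp
}

band_amp <- function(n, fs, lo, hi) {
  f <- folded_freqs(n, fs)
  as.numeric(f >= lo & f < hi)
}

# 1/f-amplitude noise, flat below fmin, scaled to an exact RMS
pink_noise <- function(n, fs, rms, fmin = 2, amp = NULL) {
  if (is.null(amp)) amp <- pink_amp(n, fs, fmin)
  y <- spectral_noise(n, amp)
  y / stats::sd(y) * rms
}

# noise band-limited to [lo, hi) Hz, exact RMS
band_noise <- function(n, fs, lo, hi, rms, amp = NULL) {
  if (is.null(amp)) amp <- band_amp(n, fs, lo, hi)
  y <- spectral_noise(n, amp)
  s <- stats::sd(y)
  if (s == 0) return(y)
  y / s * rms
}

#' Synthesize an IED waveform prototype
#'
#' 300-ms event templates of the two morphological IED classes: type-1 is
#' biphasic (fast negative spike followed by a slow positive wave,
#' reflecting recruitment of excitatory and inhibitory populations); type-2
#' is a monophasic sharp negative spike (no slow-wave component). Both fast
#' components have a 10 ms full width at half maximum, so the two types
#' carry comparable energy into the 30-300 Hz detection band at equal P2P;
#' they differ by the slow wave and hence by the N/P2P ratio (1.0 for
#' type-2, about 0.74 for type-1). The waveform is scaled so its measured
#' peak-to-peak amplitude equals `p2p_amplitude` exactly.
#'
#' @param type_id 1/2 or `"type1"`/`"type2"`.
#' @param p2p_amplitude requested peak-to-peak amplitude (µV), > 0.
#' @param fs sampling rate in Hz (>= 600).
#' @return numeric vector of length `round(0.3 * fs)`.
#' @export
synth_ied <- function(type_id, p2p_amplitude, fs) {
  if (is.character(type_id)) {
    type_id <- match(match.arg(type_id, c("type1", "type2")),
                     c("type1", "type2"))
  }
  if (!type_id %in% c(1, 2)) stop("`type_id` must be 1 or 2", call. = FALSE)
  if (!is.numeric(p2p_amplitude) || length(p2p_amplitude) != 1L ||
      !is.finite(p2p_amplitude) || p2p_amplitude <= 0) {
    stop("`p2p_amplitude` must be a positive number", call. = FALSE)
  }
  stopifnot_scalar_number(fs, "fs", min = 600)
  n <- round(0.300 * fs)
  t <- (seq_len(n) - 1 - floor(n / 2)) / fs
  s_fast <- 0.010 / (2 * sqrt(2 * log(2))) # FWHM 10 ms
  w <- -exp(-t^2 / (2 * s_fast^2))
  if (type_id == 1) {
    s_slow <- 0.030
    w <- w + 0.35 * exp(-(t - 0.055)^2 / (2 * s_slow^2))
  }
  w / (max(w) - min(w)) * p2p_amplitude
}

#' Thermal-effect model of INM on IEDs and background activity
#'
#' Collects the parameters through which laser-ON phases modulate the
#' synthetic recording. Defaults encode the continuous-wave observations:
#' about 25% P2P suppression beside the optrode (`on_p2p_factor = 0.75`,
#' relaxing to 10% in the furthest group via `group_relief`), a mild
#' increase in IED rate (`on_rate_factor = 1.2`), and a gamma-band
#' background power boost during ON.
#'
#' @param base_rate_hz baseline IED rate per channel (Hz); must stay below
#'   2.5 Hz after ON-modulation so the 350 ms minimum spacing is feasible.
#' @param on_p2p_factor multiplicative P2P factor during laser ON for
#'   Group#1 channels.
#' @param on_rate_factor multiplicative IED-rate factor during laser ON.
#' @param type2_fraction fraction of events of type 2.
#' @param artifact_amp RMS amplitude (µV) of the 80-120 Hz stimulation
#'   artifact present while the laser drive is on.
#' @param gamma_boost multiplicative factor on the 28-80 Hz background
#'   component during laser ON.
#' @param group_relief per-group relief of the ON effect: the effective P2P
#'   factor of group g is `1 - (1 - on_p2p_factor) * group_relief[g]`.
#'   The default `c(1, 0.8, 0.6, 0.4)` maps `on_p2p_factor = 0.75` to
#'   factors 0.75 / 0.80 / 0.85 / 0.90 from Group#1 to Group#4.
#' @return an object of class `effect_model`.
#' @export
effect_model <- function(base_rate_hz = 0.5, on_p2p_factor = 0.75,
                         on_rate_factor = 1.2, type2_fraction = 0.5,
                         artifact_amp = 15, gamma_boost = 1.5,
                         group_relief = c(1, 0.8, 0.6, 0.4)) {
  stopifnot_scalar_number(base_rate_hz, "base_rate_hz", min = 0)
  stopifnot_scalar_number(on_p2p_factor, "on_p2p_factor", min = 1e-9)
  stopifnot_scalar_number(on_rate_factor, "on_rate_factor", min = 1e-9)
  stopifnot_scalar_number(type2_fraction, "type2_fraction", min = 0, max = 1)
  stopifnot_scalar_number(artifact_amp, "artifact_amp", min = 0)
  stopifnot_scalar_number(gamma_boost, "gamma_boost", min = 1e-9)
  if (length(group_relief) != 4L || any(group_relief < 0)) {
    stop("`group_relief` must be 4 non-negative numbers", call. = FALSE)
  }
  if (base_rate_hz * max(on_rate_factor, 1) > 2.5) {
    stop("modulated IED rate above 2.5 Hz conflicts with the 350 ms minimum ",
         "inter-event spacing", call. = FALSE)
  }
  structure(list(base_rate_hz = base_rate_hz,
                 on_p2p_factor = on_p2p_factor,
                 on_rate_factor = on_rate_factor,
                 type2_fraction = type2_fraction,
                 artifact_amp = artifact_amp,
                 gamma_boost = gamma_boost,
                 group_relief = group_relief),
            class = "effect_model")
}

MIN_EVENT_SPACING_S <- 0.35
EDGE_MARGIN_S <- 0.175

# renewal event times with hard dead-time and phase-modulated rate: the gap
# after an event is dead-time + Exp(r) with r chosen so the mean gap is
# 1/rate(t), keeping the realised rate equal to the configured rate.
draw_event_times <- function(protocol, base_rate, on_factor) {
  if (base_rate <= 0) return(numeric(0))
  dur <- protocol$duration_s
  times <- numeric(0)
  t <- EDGE_MARGIN_S
  first <- TRUE
  repeat {
    rate <- base_rate * if (laser_on_at(protocol, t)) on_factor else 1
    mean_gap <- 1 / rate
    r_adj <- 1 / max(mean_gap - MIN_EVENT_SPACING_S, 1e-6)
    gap <- MIN_EVENT_SPACING_S + stats::rexp(1L, rate = r_adj)
    # the first event needs no dead-time before it
    t <- t + if (first) stats::rexp(1L, rate = rate) else gap
    first <- FALSE
    if (t > dur - EDGE_MARGIN_S) break
    times <- c(times, t)
  }
  times
}

#' Simulate a multichannel micro-ECoG recording with ground-truth IEDs
#'
#' Generates `n_channels` of protocol-length surface signal: 1/f background,
#' 50 Hz line noise, a gamma-band (28-80 Hz) component boosted during
#' laser-ON, an 80-120 Hz stimulation artifact gated by the laser drive,
#' and IED events injected at a modulated rate with known times, types and
#' amplitudes. Event P2P amplitude is the channel group's mean amplitude
#' multiplied by the group's ON factor while the laser is on, with no
#' per-event jitter, so ground-truth amplitude ratios between phases are
#' exact by construction.
#'
#' @param protocol an [build_protocol()] timeline.
#' @param effect an [effect_model()].
#' @param n_channels number of channels (>= 1; below 4 all channels are
#'   assigned to Group#1).
#' @param fs sampling rate in Hz (> 600; default 2000 keeps every analysis
#'   band below Nyquist at desk-scale runtimes, configurable up to 20000).
#' @param seed integer seed for reproducibility.
#' @param layout site layout (default [ecog_layout()] of `n_channels`).
#' @param bad_channel_mask logical mask of channels to exclude from groups.
#' @param noise_rms_uv RMS of the 1/f background (µV).
#' @param line_amp_uv amplitude of the 50 Hz line component (µV).
#' @param gamma_rms_uv baseline RMS of the 28-80 Hz component (µV).
#' @param group_p2p_uv mean injected IED P2P per site group (µV, length 4).
#' @return an object of class `ied_recording`: list with `signal`
#'   (channels x samples matrix, µV), `fs`, `protocol`, `layout`,
#'   `channel_groups`, `bad_channel_mask` and `ground_truth` (data frame
#'   with `channel`, `t_center_s`, `type`, `p2p_uV`).
#' @export
simulate_recording <- function(protocol, effect = effect_model(),
                               n_channels = 32, fs = 2000, seed = NULL,
                               layout = NULL, bad_channel_mask = NULL,
                               noise_rms_uv = 35, line_amp_uv = 20,
                               gamma_rms_uv = 6,
                               group_p2p_uv = c(600, 500, 420, 350)) {
  if (!inherits(protocol, "ied_protocol")) {
    stop("`protocol` must be an ied_protocol", call. = FALSE)
  }
  n_channels <- stopifnot_count(n_channels, "n_channels", min = 1L)
  stopifnot_scalar_number(fs, "fs", min = 600 + 1e-9)
  if (length(group_p2p_uv) != 4L || any(group_p2p_uv <= 0)) {
    stop("`group_p2p_uv` must be 4 positive amplitudes", call. = FALSE)
  }
  if (is.null(layout)) layout <- ecog_layout(n_channels)
  if (nrow(layout) != n_channels) {
    stop("`layout` must have one row per channel", call. = FALSE)
  }
  groups <- if (n_channels >= 4L) {
    group_channels(layout, bad_channel_mask)
  } else {
    structure(rep("Group#1", n_channels), names = layout$channel)
  }

  with_seed(seed, {
    n <- round(protocol$duration_s * fs)
    times <- (seq_len(n) - 1) / fs
    on_ind <- laser_on_at(protocol, times)
    drive_ind <- pulse_on_at(protocol, times)
    gamma_gain <- ifelse(on_ind, effect$gamma_boost, 1)

    signal <- matrix(0, nrow = n_channels, ncol = n)
    gt <- vector("list", n_channels)
    seg_half <- floor(round(0.300 * fs) / 2)
    amp_pink <- pink_amp(n, fs)
    amp_gamma <- band_amp(n, fs, 28, 80)
    amp_artifact <- band_amp(n, fs, 80, 120)

    for (ch in seq_len(n_channels)) {
      x <- pink_noise(n, fs, noise_rms_uv, amp = amp_pink) +
        line_amp_uv * sin(2 * pi * 50 * times + stats::runif(1, 0, 2 * pi)) +
        band_noise(n, fs, 28, 80, gamma_rms_uv, amp = amp_gamma) * gamma_gain
      if (effect$artifact_amp > 0) {
        x <- x + band_noise(n, fs, 80, 120, effect$artifact_amp,
                            amp = amp_artifact) * drive_ind
      }

      g_idx <- match(groups[ch], paste0("Group#", 1:4))
      ev_t <- draw_event_times(protocol, effect$base_rate_hz,
                               effect$on_rate_factor)
      if (length(ev_t) > 0 && !is.na(g_idx)) {
        ev_type <- ifelse(stats::runif(length(ev_t)) < effect$type2_fraction,
                          2L, 1L)
        on_factor <- 1 - (1 - effect$on_p2p_factor) *
          effect$group_relief[g_idx]
        ev_on <- laser_on_at(protocol, ev_t)
        ev_p2p <- group_p2p_uv[g_idx] * ifelse(ev_on, on_factor, 1)
        for (k in seq_along(ev_t)) {
          w <- synth_ied(ev_type[k], ev_p2p[k], fs)
          c_idx <- round(ev_t[k] * fs) + 1L
          i0 <- c_idx - seg_half
          idx <- i0:(i0 + length(w) - 1L)
          keep <- idx >= 1L & idx <= n
          x[idx[keep]] <- x[idx[keep]] + w[keep]
        }
        gt[[ch]] <- data.frame(channel = ch, t_center_s = ev_t,
                               type = paste0("type", ev_type),
                               p2p_uV = ev_p2p)
      }
      signal[ch, ] <- x
    }

    ground_truth <- if (all(vapply(gt, is.null, logical(1)))) {
      data.frame(channel = integer(0), t_center_s = numeric(0),
                 type = character(0), p2p_uV = numeric(0))
    } else {
      do.call(rbind, gt[!vapply(gt, is.null, logical(1))])
    }
    rownames(ground_truth) <- NULL

    structure(list(signal = signal, fs = fs, protocol = protocol,
                   layout = layout, channel_groups = groups,
                   bad_channel_mask = bad_channel_mask,
                   effect = effect, ground_truth = ground_truth),
              class = "ied_recording")
  })
}

#' @export
print.ied_recording <- function(x, ...) {
  cat(sprintf(
    "<ied_recording> %d channel(s) x %.1f s at %g Hz, %d ground-truth event(s)\n",
    nrow(x$signal), ncol(x$signal) / x$fs, x$fs, nrow(x$ground_truth)))
  cat("protocol:", x$protocol$isp_id, "pulse",
      x$protocol$pulse_frequency_hz, "Hz,", x$protocol$n_trials, "trial(s)\n")
  invisible(x)
}

#' Export ground-truth events as CSV
#'
#' @param recording an `ied_recording`.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_ground_truth_csv <- function(recording, path) {
  utils::write.csv(recording$ground_truth, path, row.names = FALSE)
  invisible(path)
}
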