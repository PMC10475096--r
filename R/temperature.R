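# Cortical temperature simulation under INM protocols.
#
# First-order exponential relaxation toward a phase asymptote: during
# laser-ON the asymptote is baseline + dTmax (sensor- and pulse-frequency-
# dependent), during OFF it is the baseline. Low-frequency fluctuations are
# added during OFF phases of slow pulsed protocols, mimicking ambient-air
# convection effects visible at low cortical temperatures.

#' Thermal model parameters
#'
#' `delta_t_max_near_c` / `delta_t_max_far_c` are the continuous-wave
#' temperature elevations at the sensors near to and far from the optrode;
#' pulsed protocols scale them down (see [delta_t_scale()]). The default
#' heating constant (25 s) lets a 120-s ON phase reach 99.2% of the
#' asymptote, so the configured maxima are reproduced within 1%.
#'
#' @param delta_t_max_near_c continuous-wave maximum elevation near the
#'   optrode (°C).
#' @param delta_t_max_far_c same, far from the optrode; must not exceed the
#'   near value.
#' @param tau_heat_s heating time constant (s), > 0.
#' @param tau_cool_s cooling time constant (s), >= 0 (0 = instantaneous
#'   return to baseline, a limiting case).
#' @param baseline_c baseline cortical temperature (°C).
#' @param fluctuation_sd_c SD (°C) of the low-frequency OFF-phase
#'   fluctuation added for pulse frequencies in (0, 10] Hz.
#' @return an object of class `thermal_params`.
#' @export
thermal_params <- function(delta_t_max_near_c = 3.0, delta_t_max_far_c = 1.5,
                           tau_heat_s = 25, tau_cool_s = 35,
                           baseline_c = 36.5, fluctuation_sd_c = 0.05) {
  stopifnot_scalar_number(delta_t_max_near_c, "delta_t_max_near_c", min = 0)
  stopifnot_scalar_number(delta_t_max_far_c, "delta_t_max_far_c", min = 0)
  stopifnot_scalar_number(tau_heat_s, "tau_heat_s", min = 1e-9)
  stopifnot_scalar_number(tau_cool_s, "tau_cool_s", min = 0)
  stopifnot_scalar_number(fluctuation_sd_c, "fluctuation_sd_c", min = 0)
  if (delta_t_max_far_c > delta_t_max_near_c) {
    stop("`delta_t_max_far_c` must not exceed `delta_t_max_near_c`",
         call. = FALSE)
  }
  structure(list(delta_t_max_near_c = delta_t_max_near_c,
                 delta_t_max_far_c = delta_t_max_far_c,
                 tau_heat_s = tau_heat_s, tau_cool_s = tau_cool_s,
                 baseline_c = baseline_c,
                 fluctuation_sd_c = fluctuation_sd_c),
            class = "thermal_params")
}

#' Pulse-frequency scaling of the maximal temperature elevation
#'
#' Lookup over the protocol pulse frequencies with linear interpolation elsewhere.
#' Continuous wave (0 Hz) reaches the full elevation; 1 Hz pulsing (50%
#' duty) reaches 1.6/3.0 of it and 1 kHz reaches 1.5/3.0, matching the
#' reported near-sensor maxima of ~3.0, ~1.6 and ~1.5 °C. The 10 and
#' 100 Hz values are log-frequency interpolations between the 1 Hz and
#' 1 kHz endpoints (only the endpoints were reported).
#'
#' @param pulse_frequency_hz pulse frequency in Hz (>= 0).
#' @return scalar scale factor in (0, 1].
#' @export
delta_t_scale <- function(pulse_frequency_hz) {
  stopifnot_scalar_number(pulse_frequency_hz, "pulse_frequency_hz", min = 0)
  freqs <- c(0, 1, 10, 100, 1000)
  # 10/100 Hz: 1.6/3 + (1.5/3 - 1.6/3) * log10(f)/3
  scales <- c(1, 1.6 / 3, 1.6 / 3 - 0.1 / 9, 1.6 / 3 - 0.2 / 9, 1.5 / 3)
  if (pulse_frequency_hz >= 1000) return(scales[5])
  stats::approx(freqs, scales, xout = pulse_frequency_hz)$y
}

#' Simulate cortical temperature during an INM protocol
#'
#' @param protocol an [build_protocol()] timeline.
#' @param params a [thermal_params()].
#' @param seed integer seed (OFF-phase fluctuations are the only random
#'   component).
#' @param sample_rate_hz temperature sampling rate (default 6 Hz, matching
#'   the thermometer logger).
#' @return an object of class `temperature_trace`: data frame with columns
#'   `times_s`, `temp_near_c`, `temp_far_c`, plus attributes
#'   `sample_rate_hz`, `baseline_c` and `protocol`.
#' @export
simulate_temperature <- function(protocol, params = thermal_params(),
                                 seed = NULL, sample_rate_hz = 6) {
  if (!inherits(protocol, "ied_protocol")) {
    stop("`protocol` must be an ied_protocol", call. = FALSE)
  }
  stopifnot_scalar_number(sample_rate_hz, "sample_rate_hz", min = 1e-9)
  dt <- 1 / sample_rate_hz
  times <- seq(0, protocol$duration_s, by = dt)
  scale <- delta_t_scale(protocol$pulse_frequency_hz)
  dt_near <- params$delta_t_max_near_c * scale
  dt_far <- params$delta_t_max_far_c * scale

  relax <- function(dt_max) {
    temp <- numeric(length(times))
    cur <- params$baseline_c
    ph <- protocol$phases
    for (i in seq_len(nrow(ph))) {
      sel <- which(times >= ph$start_s[i] &
                     (times < ph$end_s[i] |
                        (i == nrow(ph) & times <= ph$end_s[i])))
      if (length(sel) == 0) next
      asym <- params$baseline_c + if (ph$laser_on[i]) dt_max else 0
      tau <- if (ph$laser_on[i]) params$tau_heat_s else params$tau_cool_s
      tloc <- times[sel] - ph$start_s[i]
      decay <- if (tau <= 0) 0 else exp(-tloc / tau)
      temp[sel] <- asym + (cur - asym) * decay
      t_end <- ph$end_s[i] - ph$start_s[i]
      cur <- asym + (cur - asym) * (if (tau <= 0) 0 else exp(-t_end / tau))
    }
    temp
  }

  tr <- with_seed(seed, {
    temp_near <- relax(dt_near)
    temp_far <- relax(dt_far)
    f <- protocol$pulse_frequency_hz
    if (params$fluctuation_sd_c > 0 && f > 0 && f <= 10) {
      off <- !laser_on_at(protocol, times) &
        times >= PCTRL_S # fluctuations during OFF phases only
      # smooth (about 5 s kernel) seeded noise, rescaled to the target SD
      raw <- stats::rnorm(length(times))
      k <- stats::dnorm(seq(-3, 3, length.out = 6 * sample_rate_hz + 1))
      sm <- stats::filter(raw, k / sum(k), sides = 2)
      sm[is.na(sm)] <- 0
      sm <- as.numeric(sm)
      if (stats::sd(sm) > 0) {
        sm <- sm / stats::sd(sm) * params$fluctuation_sd_c
      }
      # ambient-air convection matters at low cortical temperatures: weight
      # the fluctuation by how far the trace has relaxed toward baseline
      w_near <- if (dt_near > 0) {
        pmin(pmax(1 - (temp_near - params$baseline_c) / dt_near, 0), 1)
      } else 1
      w_far <- if (dt_far > 0) {
        pmin(pmax(1 - (temp_far - params$baseline_c) / dt_far, 0), 1)
      } else 1
      temp_near <- temp_near + sm * off * w_near
      temp_far <- temp_far + sm * off * w_far
    }
    data.frame(times_s = times, temp_near_c = temp_near,
               temp_far_c = temp_far)
  })
  structure(tr, sample_rate_hz = sample_rate_hz,
            baseline_c = params$baseline_c, protocol = protocol,
            class = c("temperature_trace", "data.frame"))
}
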