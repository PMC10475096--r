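# Infrared stimulation protocol timelines.
#
# Two protocol families are supported: ISP1 (2-min laser ON + 4-min OFF per
# trial) and ISP2 (4-min ON + 4-min OFF), both preceded by a single 2-min
# baseline phase (PCtrl). The laser drive within an ON phase is either
# continuous (pulse frequency 0 Hz) or a square wave at the given pulse
# frequency with a fixed 50% duty cycle.

STUDY_PULSE_FREQS <- c(0, 1, 10, 100, 1000)
PCTRL_S <- 120
OFF_S <- 240
BIN_S <- 40

#' Build an infrared stimulation protocol timeline
#'
#' Constructs the phase timeline of an INM session: one 120-s baseline phase
#' (`PCtrl`) followed by `n_trials` ON/OFF cycles. ISP1 cycles are
#' 120 s ON (`P2ON`) + 240 s OFF (`P4OFF`); ISP2 cycles are 240 s ON
#' (`P4ON`) + 240 s OFF. The timeline is the clock against which recordings,
#' temperature traces and 40-s feature bins are aligned.
#'
#' @param isp_id `"ISP1"` or `"ISP2"`.
#' @param pulse_frequency_hz laser pulse frequency in Hz; 0 means continuous
#'   wave. Protocol-faithful runs use 0, 1, 10, 100 or 1000 Hz; other non-negative
#'   values are accepted but flagged (`study_frequency = FALSE`).
#' @param n_trials number of ON/OFF cycles (>= 0).
#' @return an object of class `ied_protocol`: a list with `isp_id`,
#'   `pulse_frequency_hz`, `n_trials`, `duty_cycle` (fixed 0.5),
#'   `study_frequency`, `duration_s` and `phases` (data frame with columns
#'   `label`, `start_s`, `end_s`, `laser_on`, `trial`).
#' @examples
#' p <- build_protocol("ISP1", 0, 5)
#' p$duration_s # 1920
#' @export
build_protocol <- function(isp_id = c("ISP1", "ISP2"), pulse_frequency_hz = 0,
                           n_trials = 5) {
  isp_id <- match.arg(isp_id)
  stopifnot_scalar_number(pulse_frequency_hz, "pulse_frequency_hz", min = 0)
  n_trials <- stopifnot_count(n_trials, "n_trials")

  on_s <- if (isp_id == "ISP1") 120 else 240
  on_label <- if (isp_id == "ISP1") "P2ON" else "P4ON"

  phases <- data.frame(label = "PCtrl", start_s = 0, end_s = PCTRL_S,
                       laser_on = FALSE, trial = 0L,
                       stringsAsFactors = FALSE)
  t0 <- PCTRL_S
  if (n_trials > 0L) {
    for (tr in seq_len(n_trials)) {
      phases <- rbind(
        phases,
        data.frame(label = c(on_label, "P4OFF"),
                   start_s = c(t0, t0 + on_s),
                   end_s = c(t0 + on_s, t0 + on_s + OFF_S),
                   laser_on = c(TRUE, FALSE), trial = tr,
                   stringsAsFactors = FALSE)
      )
      t0 <- t0 + on_s + OFF_S
    }
  }

  structure(
    list(isp_id = isp_id,
         pulse_frequency_hz = pulse_frequency_hz,
         n_trials = n_trials,
         duty_cycle = 0.5,
         study_frequency = pulse_frequency_hz %in% STUDY_PULSE_FREQS,
         on_s = on_s,
         off_s = OFF_S,
         duration_s = t0,
         phases = phases),
    class = "ied_protocol"
  )
}

#' @export
print.ied_protocol <- function(x, ...) {
  cat(sprintf("<ied_protocol> %s, pulse %g Hz%s, %d trial(s), %g s total\n",
              x$isp_id, x$pulse_frequency_hz,
              if (x$study_frequency) "" else " (non-study frequency)",
              x$n_trials, x$duration_s))
  print(x$phases, row.names = FALSE)
  invisible(x)
}

#' Laser state at given times
#'
#' @param protocol an `ied_protocol`.
#' @param times_s numeric vector of times in seconds.
#' @return logical vector: is the laser-ON phase active at each time
#'   (phase-level; ignores intra-phase pulsing).
#' @export
laser_on_at <- function(protocol, times_s) {
  ph <- protocol$phases
  on <- rep(FALSE, length(times_s))
  for (i in which(ph$laser_on)) {
    on <- on | (times_s >= ph$start_s[i] & times_s < ph$end_s[i])
  }
  on
}

#' Laser drive (pulse-resolved) at given times
#'
#' For continuous-wave protocols this equals [laser_on_at()]; for pulsed
#' protocols the drive is a square wave at `pulse_frequency_hz` with 50%
#' duty cycle, phase-locked to each ON-phase onset.
#'
#' @inheritParams laser_on_at
#' @return logical vector.
#' @export
pulse_on_at <- function(protocol, times_s) {
  on <- laser_on_at(protocol, times_s)
  f <- protocol$pulse_frequency_hz
  if (f == 0) {
    return(on)
  }
  ph <- protocol$phases
  drive <- rep(FALSE, length(times_s))
  for (i in which(ph$laser_on)) {
    sel <- times_s >= ph$start_s[i] & times_s < ph$end_s[i]
    frac <- ((times_s[sel] - ph$start_s[i]) * f) %% 1
    drive[sel] <- frac < protocol$duty_cycle
  }
  drive
}

#' 40-s bin edges tiling a protocol
#'
#' @param protocol an `ied_protocol`.
#' @param bin_s bin width in seconds (default 40).
#' @return numeric vector of bin edges from 0 to the protocol duration.
#' @export
protocol_bin_edges <- function(protocol, bin_s = BIN_S) {
  stopifnot_scalar_number(bin_s, "bin_s", min = 1e-9)
  if (protocol$duration_s %% bin_s > 1e-9) {
    stop("bin width does not tile the protocol duration", call. = FALSE)
  }
  seq(0, protocol$duration_s, by = bin_s)
}

# number of bins in one ON/OFF cycle (9 for ISP1, 12 for ISP2)
cycle_bins <- function(protocol, bin_s = BIN_S) {
  as.integer((protocol$on_s + protocol$off_s) / bin_s)
}

# number of PCtrl bins (3)
pctrl_bins <- function(bin_s = BIN_S) as.integer(PCTRL_S / bin_s)
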