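# Shared fixtures: background generator, event injection, and a naive
# reference detector used as the independent oracle.

FS_TEST <- 2000

# default background model of the benchmark (pink + line + gamma band)
make_background <- function(dur_s, fs = FS_TEST, noise_rms = 35,
                            line_amp = 20, gamma_rms = 6) {
  n <- round(dur_s * fs)
  t <- (seq_len(n) - 1) / fs
  iednm:::pink_noise(n, fs, noise_rms) +
    line_amp * sin(2 * pi * 50 * t + runif(1, 0, 2 * pi)) +
    iednm:::band_noise(n, fs, 28, 80, gamma_rms)
}

inject_events <- function(x, fs, times_s, p2p, types = 2) {
  types <- rep_len(types, length(times_s))
  for (k in seq_along(times_s)) {
    w <- synth_ied(types[k], p2p, fs)
    i0 <- round(times_s[k] * fs) + 1 - floor(length(w) / 2)
    idx <- i0:(i0 + length(w) - 1)
    x[idx] <- x[idx] + w
  }
  x
}

# brute-force reference detector: explicit squaring, sample-by-sample
# local-maxima enumeration, the threshold formula, and a sample-by-sample
# run scan. Single window only (inputs <= window length).
naive_detect <- function(filtered_2_300, fs, config = detector_config()) {
  det_f <- butter_design(config$detect_order, config$detect_band_hz,
                         "pass", fs)
  xd <- filtfilt(det_f, filtered_2_300)
  sq <- xd^2
  n <- length(sq)
  peaks <- c()
  for (i in 2:(n - 1)) {
    if (sq[i] > sq[i - 1] && sq[i] > sq[i + 1]) peaks <- c(peaks, i)
  }
  sigma2 <- median(sq) / 0.4549364
  floor_val <- config$peak_floor_sigma^2 * sigma2
  peaks <- peaks[sq[peaks] > floor_val]
  if (length(peaks) == 0) return(numeric(0))
  thr <- (mean(sq[peaks]) + mean(sq)) / 2
  centers <- c()
  in_run <- FALSE
  run_start <- NA
  run_end <- NA
  merge_n <- round(config$merge_gap_s * fs)
  runs <- list()
  for (i in seq_len(n)) {
    if (sq[i] > thr) {
      if (!in_run) {
        in_run <- TRUE
        run_start <- i
      }
      run_end <- i
    } else if (in_run) {
      in_run <- FALSE
      runs[[length(runs) + 1]] <- c(run_start, run_end)
    }
  }
  if (in_run) runs[[length(runs) + 1]] <- c(run_start, run_end)
  merged <- list()
  for (r in runs) {
    if (length(merged) > 0 &&
        r[1] - merged[[length(merged)]][2] < merge_n) {
      merged[[length(merged)]][2] <- r[2]
    } else {
      merged[[length(merged) + 1]] <- r
    }
  }
  for (r in merged) {
    centers <- c(centers, ((r[1] + r[2]) / 2 - 1) / fs)
  }
  # edge-dropping as in detect_ieds
  seg_half <- floor(round(2 * config$segment_halfwidth_s * fs) / 2)
  keep <- sapply(centers, function(ct) {
    ci <- round(ct * fs) + 1
    ci - seg_half >= 1 &&
      ci - seg_half + round(2 * config$segment_halfwidth_s * fs) - 1 <= n
  })
  centers[keep]
}
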