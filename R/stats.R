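# Baseline-normalised feature arrays X and the trial-similarity statistic.
#
# One X array spans the three PCtrl bins plus one ON/OFF cycle of 40-s
# bins (12 elements for ISP1, 15 for ISP2), normalised so the last PCtrl
# bin equals 1. Similarity of a condition is the mean over rats of the
# Pearson correlation between the grand-average array and each rat's
# trial-average array, with negative correlations truncated to zero.

#' Build a feature array X for one trial
#'
#' Concatenates the three PCtrl bins (shared by all trials of a session)
#' with the bins of the trial's ON/OFF cycle. Length 12 for ISP1, 15 for
#' ISP2.
#'
#' @param binned a `binned_series` (or numeric vector of per-bin values
#'   covering the whole protocol).
#' @param protocol an [build_protocol()] timeline.
#' @param trial_index trial number (1-based).
#' @return numeric vector of class `feature_array` with attributes
#'   `isp_id`, `trial_index`, `pulse_frequency_hz`.
#' @export
build_feature_array <- function(binned, protocol, trial_index) {
  trial_index <- stopifnot_count(trial_index, "trial_index", min = 1L)
  if (trial_index > protocol$n_trials) {
    stop("`trial_index` exceeds the protocol's number of trials",
         call. = FALSE)
  }
  values <- if (is.data.frame(binned)) binned$value else as.numeric(binned)
  np <- pctrl_bins()
  cb <- cycle_bins(protocol)
  need <- np + trial_index * cb
  if (length(values) < need) {
    stop("binned series does not cover trial ", trial_index, call. = FALSE)
  }
  idx <- c(seq_len(np), np + (trial_index - 1L) * cb + seq_len(cb))
  structure(values[idx], isp_id = protocol$isp_id,
            trial_index = trial_index,
            pulse_frequency_hz = protocol$pulse_frequency_hz,
            class = "feature_array")
}

#' Normalise a feature array to its last baseline bin
#'
#' Divides every element by the last PCtrl bin (element 3), which becomes
#' exactly 1. Idempotent.
#'
#' @param x numeric vector (a `feature_array` or plain vector whose third
#'   element is the last PCtrl bin).
#' @return normalised vector with the attributes of `x`.
#' @export
normalize_to_baseline <- function(x) {
  np <- pctrl_bins()
  b <- as.numeric(x)[np]
  if (!is.finite(b) || b == 0) {
    tr <- attr(x, "trial_index")
    stop("last PCtrl bin is zero or missing",
         if (!is.null(tr)) sprintf(" (trial %s)", tr) else "", call. = FALSE)
  }
  out <- as.numeric(x) / b
  attributes(out) <- attributes(x)
  out
}

#' Categorise a similarity coefficient
#'
#' `[0, 0.4)` weak, `[0.4, 0.8)` moderate, `[0.8, 1]` strong.
#'
#' @param rho value in `[0, 1]`.
#' @return `"weak"`, `"moderate"` or `"strong"`.
#' @export
categorize_rho <- function(rho) {
  stopifnot_scalar_number(rho, "rho", min = 0, max = 1)
  if (rho < 0.4) "weak" else if (rho < 0.8) "moderate" else "strong"
}

#' Trial-similarity statistic of a condition
#'
#' For arrays of one condition (same pulse frequency, site group and
#' feature) grouped by rat: the grand average G is the elementwise mean of
#' all arrays; for each rat r, `rho_r = cor(G, mean of rat r's arrays)`
#' (Pearson), negative values truncated to zero; the statistic is the mean
#' of the `rho_r`, the aggregate p-value the mean of the per-rat two-sided
#' correlation-test p-values, and the category follows [categorize_rho()].
#' Rats whose average array (or the grand average) has zero variance are
#' excluded with a warning.
#'
#' @param arrays_by_rat list, one element per rat: a numeric vector, a list
#'   of equal-length numeric vectors, or a trials x bins matrix.
#' @param truncate_negative replace negative per-rat correlations by zero
#'   (reversed changes must lower, not cancel, the similarity). `FALSE` is provided for the monotonicity check.
#' @param leave_one_out exclude the rat under comparison from the grand
#'   average.
#' @param by_trial_pairs correlate every single-trial array (not the rat
#'   average) against the grand average; an alternative reading of
#'   "all pairwise combinations".
#' @return an object of class `similarity_result`: list with `rho`,
#'   `p_value`, `category`, `n_pairs`, `significant` (p < 0.05) and
#'   `per_pair` (data frame of the untruncated/truncated coefficients).
#' @export
similarity_rho <- function(arrays_by_rat, truncate_negative = TRUE,
                           leave_one_out = FALSE, by_trial_pairs = FALSE) {
  if (!is.list(arrays_by_rat) || length(arrays_by_rat) < 2L) {
    stop("need arrays from at least 2 rats", call. = FALSE)
  }
  as_mat <- function(a) {
    if (is.matrix(a)) a
    else if (is.list(a)) do.call(rbind, lapply(a, as.numeric))
    else matrix(as.numeric(a), nrow = 1)
  }
  mats <- lapply(arrays_by_rat, as_mat)
  len <- unique(vapply(mats, ncol, integer(1)))
  if (length(len) != 1L) {
    stop("all arrays must have equal length", call. = FALSE)
  }
  all_mat <- do.call(rbind, mats)
  rat_of_row <- rep(seq_along(mats), vapply(mats, nrow, integer(1)))

  units <- if (by_trial_pairs) {
    lapply(seq_len(nrow(all_mat)), function(i) {
      list(vec = all_mat[i, ], rat = rat_of_row[i])
    })
  } else {
    lapply(seq_along(mats), function(r) {
      list(vec = colMeans(mats[[r]], na.rm = TRUE), rat = r)
    })
  }

  res <- lapply(units, function(u) {
    g <- if (leave_one_out) {
      colMeans(all_mat[rat_of_row != u$rat, , drop = FALSE])
    } else {
      colMeans(all_mat)
    }
    if (stats::sd(u$vec) == 0 || stats::sd(g) == 0) {
      return(NULL)
    }
    ct <- stats::cor.test(g, u$vec, method = "pearson",
                          alternative = "two.sided")
    data.frame(rat = u$rat, r = unname(ct$estimate), p = ct$p.value)
  })
  dropped <- vapply(res, is.null, logical(1))
  if (any(dropped)) {
    warning(sum(dropped), " pair(s) with zero variance excluded",
            call. = FALSE)
  }
  res <- res[!dropped]
  if (length(res) == 0L) {
    stop("all pairs excluded (zero variance everywhere)", call. = FALSE)
  }
  per <- do.call(rbind, res)
  per$r_trunc <- if (truncate_negative) pmax(per$r, 0) else per$r
  rho <- mean(per$r_trunc)
  rho_cat <- min(max(rho, 0), 1) # guard fp noise at the boundaries
  p_val <- mean(per$p)
  structure(list(rho = rho, p_value = p_val,
                 category = categorize_rho(rho_cat),
                 n_pairs = nrow(per),
                 significant = p_val < 0.05,
                 per_pair = per),
            class = "similarity_result")
}

#' @export
print.similarity_result <- function(x, ...) {
  cat(sprintf(
    "<similarity_result> rho = %.3f (%s), p = %.3g%s, n_pairs = %d\n",
    x$rho, x$category, x$p_value,
    if (x$significant) " *" else "", x$n_pairs))
  invisible(x)
}
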