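# Recording-site layout and distance-based channel grouping.

#' Default micro-ECoG array layout
#'
#' Places `n_channels` recording sites on a rectangular grid (4 rows,
#' 0.4 mm pitch) around a central aperture at the origin, mimicking a
#' 32-site surface array with a central insertion hole. Distances from the
#' aperture drive the four-group channel organisation.
#'
#' @param n_channels number of recording sites (>= 1).
#' @param pitch_mm inter-site pitch in millimetres.
#' @return data frame with columns `channel`, `x_mm`, `y_mm`, `dist_mm`.
#' @export
ecog_layout <- function(n_channels = 32, pitch_mm = 0.4) {
  n_channels <- stopifnot_count(n_channels, "n_channels", min = 1L)
  n_rows <- min(4L, n_channels)
  n_cols <- ceiling(n_channels / n_rows)
  idx <- seq_len(n_channels) - 1L
  col <- idx %/% n_rows
  row <- idx %% n_rows
  x <- (col - (n_cols - 1) / 2) * pitch_mm
  y <- (row - (n_rows - 1) / 2) * pitch_mm
  data.frame(channel = seq_len(n_channels),
             x_mm = x, y_mm = y,
             dist_mm = sqrt(x^2 + y^2))
}

#' Group channels by distance from the central aperture
#'
#' The four usable sites nearest the aperture form `Group#1`; the remaining
#' usable sites are split, in order of increasing distance, into `Group#2`
#' to `Group#4` (as equally sized as possible). Ties in distance are broken
#' by channel index, so the grouping is deterministic. Masked (bad) channels
#' belong to no group.
#'
#' @param layout data frame with columns `channel` and `dist_mm` (or a rank
#'   column `dist`), e.g. from [ecog_layout()].
#' @param bad_channel_mask logical vector (length = number of channels);
#'   `TRUE` marks a bad channel to exclude. `NULL` keeps all.
#' @return character vector of length `nrow(layout)`, named by channel:
#'   `"Group#1"` ... `"Group#4"`, `NA` for masked channels.
#' @export
group_channels <- function(layout, bad_channel_mask = NULL) {
  if (!is.data.frame(layout) || is.null(layout$channel)) {
    stop("`layout` must be a data frame with a `channel` column", call. = FALSE)
  }
  dist <- if (!is.null(layout$dist_mm)) layout$dist_mm else layout$dist
  if (is.null(dist)) {
    stop("`layout` must provide `dist_mm` (or `dist`)", call. = FALSE)
  }
  n <- nrow(layout)
  if (is.null(bad_channel_mask)) {
    bad_channel_mask <- rep(FALSE, n)
  }
  if (!is.logical(bad_channel_mask) || length(bad_channel_mask) != n) {
    stop("`bad_channel_mask` must be a logical vector matching the layout",
         call. = FALSE)
  }
  usable <- which(!bad_channel_mask)
  if (length(usable) < 4L) {
    stop("fewer than 4 usable channels; cannot form site groups",
         call. = FALSE)
  }
  ord <- usable[order(dist[usable], layout$channel[usable])]
  groups <- rep(NA_character_, n)
  groups[ord[1:4]] <- "Group#1"
  rest <- ord[-(1:4)]
  if (length(rest) > 0L) {
    sizes <- rep(length(rest) %/% 3L, 3L)
    extra <- length(rest) %% 3L
    if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    gi <- rep(2:4, times = sizes)
    groups[rest] <- paste0("Group#", gi)
  }
  names(groups) <- layout$channel
  groups
}
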