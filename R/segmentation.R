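# Run-length gap statistic on a half-height intensity transect.
#
# A "segment" (inter-fiber gap) is a maximal run of transect pixels whose gray
# value is strictly below 25% of the highest value on the transect and whose
# physical length is at least 15 um. More frequent gaps indicate a more
# fibrillar microarchitecture.

#' Extract the half-height transect of an image
#'
#' Takes the single pixel row at floor(height / 2) (0-based), i.e. the row
#' just below the middle for even heights, spanning the full image width.
#'
#' @param img A [gray_image()] with at least 2 rows.
#' @return A `profile_transect`: `values`, `pixel_size_um`, `excluded`
#'   (logical mask, all FALSE), `row` (0-based row index used).
#' @export
extract_transect <- function(img) {
  h <- nrow(img)
  if (h < 2) stop("image must have at least 2 rows")
  r0 <- h %/% 2
  structure(list(values = as.numeric(unclass(img)[r0 + 1, ]),
                 pixel_size_um = pixel_size(img),
                 excluded = rep(FALSE, ncol(img)),
                 row = r0),
            class = "profile_transect")
}

#' Mark transect positions as excluded (e.g. imaging artifacts)
#'
#' Excluded positions participate neither in the transect maximum nor in any
#' run; a run of sub-threshold pixels is broken by an excluded position.
#'
#' @param t A `profile_transect`.
#' @param ranges List of length-2 integer vectors `c(start, end)` (1-based,
#'   inclusive), or a single such vector.
#' @return The transect with an updated exclusion mask.
#' @export
apply_exclusion <- function(t, ranges) {
  if (is.numeric(ranges)) ranges <- list(ranges)
  n <- length(t$values)
  for (r in ranges) {
    stopifnot(length(r) == 2)
    if (r[1] < 1 || r[2] > n || r[1] > r[2])
      stop("exclusion range out of transect bounds")
    t$excluded[r[1]:r[2]] <- TRUE
  }
  t
}

#' Count qualifying low-intensity gaps along a transect
#'
#' The threshold is `threshold_frac` times the maximum gray value over
#' non-excluded positions. A qualifying gap is a maximal run of consecutive
#' non-excluded positions with value strictly below the threshold whose
#' physical length (`pixels * pixel_size_um`) is at least `min_len_um`.
#' Runs touching the image edges count (configurable).
#'
#' @param t A `profile_transect`.
#' @param threshold_frac Fraction of the maximum (default 0.25).
#' @param min_len_um Minimum physical gap length in um (default 15).
#' @param count_edges Count runs touching the transect ends (default TRUE).
#' @return A `segmentation_result`: `gap_count`, `gap_spans` (data frame
#'   `start_px`, `end_px`, `start_um`, `end_um`, `length_um`),
#'   `threshold_value`, `excluded_positions`.
#' @export
count_segments <- function(t, threshold_frac = 0.25, min_len_um = 15,
                           count_edges = TRUE) {
  ok <- !t$excluded
  if (!any(ok)) stop("all transect positions are excluded")
  thr <- threshold_frac * max(t$values[ok])
  ps <- t$pixel_size_um
  low <- ok & (t$values < thr)
  r <- rle(low)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & (r$lengths * ps >= min_len_um)
  if (!count_edges) {
    keep <- keep & starts > 1 & ends < length(low)
  }
  spans <- data.frame(start_px = starts[keep], end_px = ends[keep])
  spans$start_um <- (spans$start_px - 1) * ps
  spans$end_um <- spans$end_px * ps
  spans$length_um <- (spans$end_px - spans$start_px + 1) * ps
  structure(list(gap_count = nrow(spans), gap_spans = spans,
                 threshold_value = thr,
                 excluded_positions = sum(t$excluded)),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("segmentation_result: %d gap(s), threshold %.3g, %d excluded px\n",
              x$gap_count, x$threshold_value, x$excluded_positions))
  invisible(x)
}

#' Average gap counts over replicate images
#'
#' @param results List of `segmentation_result` (or numeric counts).
#' @return List with `mean`, `sd`, `counts`.
#' @export
average_counts <- function(results) {
  if (length(results) == 0) stop("no results to average")
  counts <- vapply(results, function(r)
    if (is.numeric(r)) as.numeric(r) else r$gap_count, 0)
  list(mean = mean(counts), sd = stats::sd(counts), counts = counts)
}
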