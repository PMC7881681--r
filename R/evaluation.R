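#' ROI mean over the valid pixels of a map
#'
#' Arithmetic mean of the map values over the intersection of a region of
#' interest with the map's validity mask. Invalid pixels (failed or
#' out-of-range fits, sub-threshold signal) are excluded, never zero-filled;
#' an ROI containing no valid pixel is an error rather than NaN.
#'
#' @param map A `parameter_map` or `ecv_map`.
#' @param mask Logical matrix congruent with the map grid.
#' @return Scalar mean (ms for T1 maps, fraction for ECV maps).
#' @export
roi_mean <- function(map, mask) {
  grid <- map_grid(map)
  if (!is.logical(mask) || !identical(dim(mask), dim(grid)))
    stop("`mask` must be a logical matrix congruent with the map")
  sel <- mask & map$valid
  if (!any(sel)) stop("ROI contains no valid pixel")
  mean(grid[sel])
}

#' Bland-Altman agreement between paired measurements
#'
#' Computes the mean difference and 95% limits of agreement between two sets
#' of paired measurements: with \eqn{d_i = x_i - y_i},
#' `mean_diff = mean(d)` and `loa = mean_diff +/- 1.96 * sd(d)` using the
#' sample (n-1) standard deviation. The limits are symmetric about the mean
#' difference by construction; swapping `x` and `y` negates all three
#' statistics.
#'
#' @param x,y Numeric vectors of equal length >= 2 (e.g. per-subject
#'   myocardial ROI-mean T1 from two calculation methods).
#' @return An object of class `agreement_stats` with `mean_diff`, `loa_low`,
#'   `loa_high`, `sd_diff` and `n`.
#' @examples
#' bland_altman(c(950, 960, 955), c(951, 958, 957))
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have the same length")
  if (length(x) < 2L) stop("at least 2 pairs are required")
  d <- x - y
  m <- mean(d)
  s <- stats::sd(d)
  structure(list(mean_diff = m, loa_low = m - 1.96 * s, loa_high = m + 1.96 * s,
                 sd_diff = s, n = length(d)),
            class = "agreement_stats")
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf(
    "Bland-Altman (n = %d): mean difference %.3f, 95%% limits of agreement [%.3f, %.3f]\n",
    x$n, x$mean_diff, x$loa_low, x$loa_high))
  invisible(x)
}

#' Method-agreement report over a set of map pairs
#'
#' Convenience wrapper reproducing the usual evaluation procedure: for each
#' subject, the ROI mean of two T1 maps is computed over the same mask, and
#' the per-subject means are compared by Bland-Altman analysis.
#'
#' @param maps_x,maps_y Lists of `parameter_map`s of equal length (one pair
#'   per subject).
#' @param masks A single logical matrix, or a list of masks (one per subject).
#' @return A list: `per_subject` data frame of paired ROI means and
#'   `agreement` ([bland_altman()] result).
#' @export
roi_agreement <- function(maps_x, maps_y, masks) {
  if (length(maps_x) != length(maps_y))
    stop("`maps_x` and `maps_y` must have the same length")
  if (is.matrix(masks)) masks <- rep(list(masks), length(maps_x))
  mx <- mapply(roi_mean, maps_x, masks)
  my <- mapply(roi_mean, maps_y, masks)
  list(per_subject = data.frame(subject = seq_along(mx), mean_x = mx, mean_y = my,
                                diff = mx - my),
       agreement = bland_altman(mx, my))
}
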