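#' A co-registered TI image stack
#'
#' Holds a rows x cols x N volume of signal values together with the
#' inversion time of each slice. Slices are re-ordered TI-ascending on
#' construction, so downstream code can rely on sorted TIs regardless of
#' acquisition or file order.
#'
#' @param voxels Numeric array, rows x cols x N.
#' @param tis Inversion times in ms, one per slice; distinct and positive.
#' @param protocol Protocol tag: `"pre_5(3)3"`, `"post_4(1)3(1)2"` or
#'   `"custom"`. The canonical pre-contrast scheme has N = 8 slices and the
#'   post-contrast scheme N = 9.
#' @param pixel_spacing In-plane pixel spacing (mm, mm).
#' @param is_magnitude Logical; `TRUE` for magnitude images.
#' @return An object of class `ti_image_stack`.
#' @export
ti_image_stack <- function(voxels, tis,
                           protocol = c("custom", "pre_5(3)3", "post_4(1)3(1)2"),
                           pixel_spacing = c(1, 1), is_magnitude = TRUE) {
  protocol <- match.arg(protocol)
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3L)
    stop("`voxels` must be a rows x cols x N array")
  tis <- as.numeric(tis)
  if (dim(voxels)[3] != length(tis))
    stop("number of slices must match the number of inversion times")
  if (any(tis <= 0) || anyDuplicated(tis))
    stop("inversion times must be distinct and positive")
  if (protocol == "pre_5(3)3" && length(tis) != 8L)
    stop("the 5(3)3 protocol has 8 TI images")
  if (protocol == "post_4(1)3(1)2" && length(tis) != 9L)
    stop("the 4(1)3(1)2 protocol has 9 TI images")
  ord <- order(tis)
  structure(list(voxels = voxels[, , ord, drop = FALSE], tis = tis[ord],
                 protocol = protocol, pixel_spacing = as.numeric(pixel_spacing),
                 is_magnitude = isTRUE(is_magnitude)),
            class = "ti_image_stack")
}

#' @export
print.ti_image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("ti_image_stack: %d x %d x %d [%s], TI %g..%g ms\n",
              d[1], d[2], d[3], x$protocol, min(x$tis), max(x$tis)))
  invisible(x)
}

# Extract one pixel's series from a stack.
pixel_series <- function(stack, row, col) {
  ti_series(stack$tis, stack$voxels[row, col, ], stack$is_magnitude)
}

new_parameter_map <- function(t1, rss, valid, flip_count, method, threshold,
                              clamp_limit, tis, pixel_spacing) {
  structure(list(t1 = t1, rss = rss, valid = valid, flip_count = flip_count,
                 method = method, threshold = threshold,
                 clamp_limit = clamp_limit, tis = tis,
                 pixel_spacing = pixel_spacing),
            class = "parameter_map")
}

#' @export
print.parameter_map <- function(x, ...) {
  cat(sprintf("parameter_map [%s]: %d x %d, %d valid pixels",
              x$method, nrow(x$t1), ncol(x$t1), sum(x$valid)))
  if (any(x$valid))
    cat(sprintf(", T1 %.0f..%.0f ms", min(x$t1[x$valid]), max(x$t1[x$valid])))
  cat("\n")
  invisible(x)
}

#' Pixel-wise T1 map computation
#'
#' Fits every pixel whose maximum signal across TIs exceeds `threshold` with
#' the chosen method and assembles the Look-Locker-corrected T1 values into a
#' map. Pixels below threshold, non-converged fits, non-positive T1 and (when
#' `clamp_limit` is set) T1 above the limit are marked invalid — invalid
#' pixels carry `NA` rather than a clipped value so that ROI statistics never
#' mix in failed fits. The result is identical for any worker count: rows are
#' distributed over workers in static chunks, and each pixel's fit depends
#' only on its own samples.
#'
#' @param stack A [ti_image_stack].
#' @param method `"RD"` (reduced-dimension search, initialisation-free) or
#'   `"LM"` (Levenberg-Marquardt with polarity sweep).
#' @param threshold Signal level; pixels whose maximum signal does not exceed
#'   it are skipped. Default 0 fits every non-air pixel; raising it excludes
#'   background and shortens computation.
#' @param workers Number of parallel workers (forked; 1 = serial).
#' @param clamp_limit Optional upper T1 limit in ms (e.g. 3000 pre-contrast,
#'   1500 post-contrast); out-of-range fits are marked invalid.
#' @param init,flip_policy Passed to [fit_lm()] (LM method only). `init`
#'   defaults to the empirical pre-contrast start `(350, 0.001, -150)`; pass
#'   `relaxation_params(350, 0.005, -150)` for post-contrast series.
#' @param search,n_candidates Passed to [fit_rd()] (RD method only).
#' @return A `parameter_map` with matrices `t1`, `rss`, `flip_count`, logical
#'   `valid`, and the settings used.
#' @export
compute_t1_map <- function(stack, method = c("RD", "LM"), threshold = 0,
                           workers = 1L, clamp_limit = NULL,
                           init = relaxation_params(350, 0.001, -150),
                           flip_policy = "full_sweep",
                           search = rd_search(), n_candidates = 4L) {
  stopifnot(inherits(stack, "ti_image_stack"))
  method <- match.arg(method)
  d <- dim(stack$voxels)
  if (d[1] == 0L || d[2] == 0L) stop("empty stack")
  nr <- d[1]; nc <- d[2]

  grid <- if (method == "RD")
    rd_grid(stack$tis, search$t1star_range, search$n_grid) else NULL

  fit_row <- function(r) {
    t1 <- rss <- rep(NA_real_, nc)
    fc <- rep(NA_integer_, nc)
    ok <- rep(FALSE, nc)
    for (cl in seq_len(nc)) {
      sig <- stack$voxels[r, cl, ]
      if (max(sig) <= threshold) next
      series <- ti_series(stack$tis, sig, stack$is_magnitude)
      fit <- if (method == "RD") {
        fit_rd(series, search = search, n_candidates = n_candidates, grid = grid)
      } else {
        fit_lm(series, init = init, flip_policy = flip_policy,
               n_candidates = n_candidates)
      }
      if (!fit$converged) next
      if (!is.null(clamp_limit) && fit$t1_ms > clamp_limit) next
      t1[cl] <- fit$t1_ms; rss[cl] <- fit$rss; fc[cl] <- fit$flip_count
      ok[cl] <- TRUE
    }
    list(t1 = t1, rss = rss, fc = fc, ok = ok)
  }

  rows <- seq_len(nr)
  res <- if (workers > 1L) {
    parallel::mclapply(rows, fit_row, mc.cores = workers,
                       mc.preschedule = TRUE)
  } else {
    lapply(rows, fit_row)
  }

  t1 <- do.call(rbind, lapply(res, `[[`, "t1"))
  rss <- do.call(rbind, lapply(res, `[[`, "rss"))
  fc <- do.call(rbind, lapply(res, `[[`, "fc"))
  valid <- do.call(rbind, lapply(res, `[[`, "ok"))
  new_parameter_map(t1, rss, valid, fc, method, threshold,
                    clamp_limit, stack$tis, stack$pixel_spacing)
}

#' Per-pixel fit report with curve samples for plotting
#'
#' Fits a single pixel and returns, alongside the fit, the observed samples
#' and a dense sampling of the fitted relaxation curve over `[0, max TI]` —
#' the file-based analogue of clicking a pixel in an interactive viewer.
#'
#' @param stack A [ti_image_stack].
#' @param row,col Pixel indices (1-based, row-major).
#' @param method `"RD"` or `"LM"`.
#' @param n_curve Number of curve samples.
#' @param ... Passed to [fit_rd()] / [fit_lm()].
#' @return A list of class `pixel_report`: `fit` (a `fit_result`), `samples`
#'   (data frame of TI, observed signal and restored sign) and `curve` (data
#'   frame of t and fitted signal; `NULL` for non-converged fits).
#' @export
fit_pixel_report <- function(stack, row, col, method = c("RD", "LM"),
                             n_curve = 200L, ...) {
  stopifnot(inherits(stack, "ti_image_stack"))
  method <- match.arg(method)
  d <- dim(stack$voxels)
  if (row < 1L || row > d[1] || col < 1L || col > d[2])
    stop(sprintf("pixel (%d, %d) out of bounds for a %d x %d map",
                 row, col, d[1], d[2]))
  series <- pixel_series(stack, row, col)
  fit <- if (method == "RD") fit_rd(series, ...) else fit_lm(series, ...)
  signs <- if (fit$converged)
    sign_vector(fit$flip_count, length(series$tis)) else rep(1, length(series$tis))
  curve <- NULL
  if (fit$converged) {
    t <- seq(0, max(series$tis), length.out = n_curve)
    curve <- data.frame(t = t, signal = relaxation_signal(fit$params, t))
  }
  structure(list(fit = fit, row = row, col = col,
                 samples = data.frame(ti = series$tis,
                                      signal = series$signals,
                                      sign = signs),
                 curve = curve),
            class = "pixel_report")
}

#' @export
print.pixel_report <- function(x, ...) {
  cat(sprintf("pixel_report (%d, %d):\n", x$row, x$col))
  print(x$fit)
  invisible(x)
}

#' Plot a per-pixel fit report
#'
#' Draws the sign-restored samples and the fitted relaxation curve.
#'
#' @param x A `pixel_report` from [fit_pixel_report()].
#' @param ... Passed to [graphics::plot()].
#' @export
plot.pixel_report <- function(x, ...) {
  y <- x$samples$sign * x$samples$signal
  graphics::plot(x$samples$ti, y, xlab = "TI (ms)", ylab = "signal",
                 pch = 19, ...)
  if (!is.null(x$curve))
    graphics::lines(x$curve$t, x$curve$signal, col = "blue")
  if (x$fit$converged)
    graphics::legend("bottomright", bty = "n", legend = sprintf(
      "%s: T1 = %.1f ms, flips = %d", x$fit$method, x$fit$t1_ms,
      x$fit$flip_count))
  invisible(x)
}
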