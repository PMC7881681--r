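map_grid <- function(map) {
  if (inherits(map, "parameter_map")) map$t1
  else if (inherits(map, "ecv_map")) map$ecv
  else stop("`map` must be a parameter_map or an ecv_map")
}

map_sidecar <- function(map) {
  base <- list(package = "molliT1",
               version = as.character(utils::packageVersion("molliT1")),
               written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  if (inherits(map, "parameter_map")) {
    c(base, list(kind = "t1_map", method = map$method, tis_ms = map$tis,
                 threshold = map$threshold,
                 clamp_limit_ms = if (is.null(map$clamp_limit)) NA else map$clamp_limit,
                 pixel_spacing_mm = map$pixel_spacing))
  } else {
    c(base, list(kind = "ecv_map", hct = map$hct,
                 blood_t1_pre_ms = map$blood_t1_pre,
                 blood_t1_post_ms = map$blood_t1_post, band = map$band))
  }
}

#' Export a parameter or ECV map
#'
#' Writes the map in one of three formats. `"nifti"` stores the grid as
#' 64-bit float NIfTI-1 (bit-exact on round-trip; invalid pixels are NaN),
#' `"csv"` writes one row per pixel with `row, col, value, rss, valid`
#' (`rss` is empty for ECV maps), and `"png"` renders a preview with a
#' colour scale bar (invalid pixels blank). Every call also writes a JSON
#' sidecar `<path>.json` recording the settings needed to recompute the map
#' (TIs, method, threshold, clamp limit, package version).
#'
#' @param map A `parameter_map` from [compute_t1_map()] or an `ecv_map` from
#'   [compute_ecv_map()].
#' @param path Output file path (extension as appropriate for the format).
#' @param format `"nifti"`, `"csv"` or `"png"`.
#' @param range Display range for `"png"`; defaults to the valid data range.
#' @return Invisibly, `path`.
#' @export
write_map <- function(map, path, format = c("nifti", "csv", "png"),
                      range = NULL) {
  format <- match.arg(format)
  grid <- map_grid(map)
  switch(format,
    nifti = {
      grid[is.na(grid)] <- NaN   # invalid pixels are stored as IEEE NaN
      img <- RNifti::asNifti(grid)
      sp <- if (inherits(map, "parameter_map")) map$pixel_spacing else c(1, 1)
      RNifti::pixdim(img) <- sp
      RNifti::writeNifti(img, path, datatype = "double")
    },
    csv = {
      idx <- expand.grid(row = seq_len(nrow(grid)), col = seq_len(ncol(grid)))
      df <- data.frame(idx, value = grid[as.matrix(idx)],
                       rss = if (inherits(map, "parameter_map"))
                         map$rss[as.matrix(idx)] else NA_real_,
                       valid = map$valid[as.matrix(idx)])
      df <- df[order(df$row, df$col), ]
      utils::write.csv(df, path, row.names = FALSE, na = "")
    },
    png = write_map_png(grid, map$valid, path, range)
  )
  jsonlite::write_json(map_sidecar(map), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

write_map_png <- function(grid, valid, path, range = NULL) {
  vals <- grid[valid]
  if (is.null(range))
    range <- if (length(vals)) base::range(vals) else c(0, 1)
  if (range[1] == range[2]) range <- range + c(-0.5, 0.5)
  pal <- grDevices::hcl.colors(256, "viridis")
  grDevices::png(path, width = max(360, 100 + 6 * ncol(grid)),
                 height = max(280, 40 + 6 * nrow(grid)), res = 96)
  on.exit(grDevices::dev.off())
  graphics::layout(matrix(1:2, 1, 2), widths = c(5, 1))
  graphics::par(mar = c(0.5, 0.5, 0.5, 0.5))
  # image() draws x along rows; rotate so the map appears in display orientation
  z <- t(grid[nrow(grid):1, , drop = FALSE])
  zv <- t(valid[nrow(valid):1, , drop = FALSE])
  z[!zv] <- NA
  graphics::image(z, zlim = range, col = pal, axes = FALSE, useRaster = TRUE)
  graphics::par(mar = c(0.5, 0.5, 0.5, 2.5))
  graphics::image(x = 1, y = seq(range[1], range[2], length.out = 256),
                  z = matrix(seq(range[1], range[2], length.out = 256), 1),
                  zlim = range, col = pal, axes = FALSE, xlab = "", ylab = "")
  graphics::axis(4, las = 1)
  invisible(path)
}

#' Read back a NIfTI map grid
#'
#' Convenience reader returning the value grid written by
#' [write_map()] with `format = "nifti"` as a plain matrix (NaN where the
#' map was invalid).
#'
#' @param path NIfTI file path.
#' @return Numeric matrix.
#' @export
read_map_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  matrix(as.vector(img), dim(img)[1], dim(img)[2])
}
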