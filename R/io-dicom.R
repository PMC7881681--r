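# Minimal DICOM I/O for single-frame magnitude TI images.
#
# Only the explicit-VR little-endian transfer syntax (1.2.840.10008.1.2.1) is
# supported, and only the attributes the T1 pipeline needs are interpreted:
# InversionTime (0018,0082), Rows/Columns (0028,0010/0011), PixelSpacing
# (0028,0030), RescaleIntercept/Slope (0028,1052/1053) and 16-bit unsigned
# PixelData (7FE0,0010). Everything else is skipped by length. This is
# deliberately narrow: no installed R package parses DICOM, and the pipeline
# contract needs exactly these tags.

dcm_tag <- function(group, element) sprintf("%04X,%04X", group, element)

.dcm_long_vrs <- c("OB", "OW", "OF", "OD", "SQ", "UT", "UN")

read_dicom_elements <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 140L || rawToChar(raw[129:132]) != "DICM")
    stop(sprintf("'%s' is not a DICOM file (missing DICM marker)", basename(path)))
  pos <- 133L
  elems <- list()
  n <- length(raw)
  while (pos + 7L <= n) {
    group <- readBin(raw[pos:(pos + 1L)], "integer", size = 2, signed = FALSE,
                     endian = "little")
    element <- readBin(raw[(pos + 2L):(pos + 3L)], "integer", size = 2,
                       signed = FALSE, endian = "little")
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (vr %in% .dcm_long_vrs) {
      len <- readBin(raw[(pos + 8L):(pos + 11L)], "integer", size = 4,
                     endian = "little")
      body <- pos + 12L
    } else {
      len <- readBin(raw[(pos + 6L):(pos + 7L)], "integer", size = 2,
                     signed = FALSE, endian = "little")
      body <- pos + 8L
    }
    if (len < 0L || body + len - 1L > n)
      stop(sprintf("corrupt element %s in '%s'", dcm_tag(group, element),
                   basename(path)))
    elems[[dcm_tag(group, element)]] <-
      list(vr = vr, value = if (len > 0L) raw[body:(body + len - 1L)] else raw(0))
    pos <- body + len
  }
  elems
}

dcm_string <- function(elems, tag) {
  e <- elems[[tag]]
  if (is.null(e)) return(NULL)
  trimws(rawToChar(e$value))
}

dcm_numeric <- function(elems, tag) {
  s <- dcm_string(elems, tag)
  if (is.null(s) || !nzchar(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]])
}

dcm_us <- function(elems, tag) {
  e <- elems[[tag]]
  if (is.null(e)) return(NULL)
  readBin(e$value, "integer", n = length(e$value) %/% 2L, size = 2,
          signed = FALSE, endian = "little")
}

read_dicom_ti_image <- function(path) {
  elems <- read_dicom_elements(path)
  ts <- dcm_string(elems, dcm_tag(0x0002, 0x0010))
  if (!is.null(ts) && ts != "1.2.840.10008.1.2.1")
    stop(sprintf("'%s': unsupported transfer syntax %s", basename(path), ts))
  ti <- dcm_numeric(elems, dcm_tag(0x0018, 0x0082))
  if (is.null(ti))
    stop(sprintf("'%s' lacks the InversionTime attribute", basename(path)))
  rows <- dcm_us(elems, dcm_tag(0x0028, 0x0010))
  cols <- dcm_us(elems, dcm_tag(0x0028, 0x0011))
  if (is.null(rows) || is.null(cols))
    stop(sprintf("'%s' lacks Rows/Columns", basename(path)))
  spacing <- dcm_numeric(elems, dcm_tag(0x0028, 0x0030))
  if (is.null(spacing)) spacing <- c(1, 1)
  intercept <- dcm_numeric(elems, dcm_tag(0x0028, 0x1052))
  slope <- dcm_numeric(elems, dcm_tag(0x0028, 0x1053))
  px <- dcm_us(elems, dcm_tag(0x7FE0, 0x0010))
  if (is.null(px))
    stop(sprintf("'%s' lacks PixelData", basename(path)))
  if (length(px) != rows * cols)
    stop(sprintf("'%s': PixelData length does not match Rows x Columns",
                 basename(path)))
  img <- matrix(as.numeric(px), rows, cols, byrow = TRUE)
  if (!is.null(slope)) img <- img * slope
  if (!is.null(intercept)) img <- img + intercept
  list(ti = ti, image = img, spacing = spacing)
}

#' Read a MOLLI TI image series from a DICOM directory
#'
#' Reads every `.dcm` file in `path`, sorts the images by their InversionTime
#' attribute and assembles a magnitude [ti_image_stack]. The result is
#' independent of filesystem enumeration order. Rescale slope/intercept, when
#' present, are applied on read. Directories mixing matrix sizes or repeating
#' an inversion time (e.g. several slices in one folder) are rejected with a
#' message naming the offending file rather than guessed at.
#'
#' @param path Directory containing exactly one single-slice MOLLI series.
#' @param protocol Protocol tag for the stack; `"auto"` labels stacks of 8
#'   TIs as `pre_5(3)3`, of 9 as `post_4(1)3(1)2`, anything else as custom.
#' @return A [ti_image_stack] with TIs strictly ascending.
#' @export
read_ti_series <- function(path, protocol = "auto") {
  if (!dir.exists(path)) stop(sprintf("no such directory: '%s'", path))
  files <- sort(list.files(path, pattern = "\\.dcm$", ignore.case = TRUE,
                           full.names = TRUE))
  if (length(files) == 0L)
    stop(sprintf("no DICOM (.dcm) files found in '%s'", path))
  imgs <- lapply(files, read_dicom_ti_image)

  dims <- vapply(imgs, function(x) dim(x$image), integer(2))
  if (any(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1]))
    stop(sprintf("inconsistent matrix dimensions: '%s' is %dx%d, expected %dx%d",
                 basename(files[which(dims[1, ] != dims[1, 1] |
                                      dims[2, ] != dims[2, 1])[1]]),
                 dims[1, which(dims[1, ] != dims[1, 1])[1]],
                 dims[2, which(dims[2, ] != dims[2, 1])[1]],
                 dims[1, 1], dims[2, 1]))
  tis <- vapply(imgs, `[[`, numeric(1), "ti")
  if (anyDuplicated(tis))
    stop(sprintf("duplicate InversionTime %g ms in '%s'; is this a mixed series?",
                 tis[anyDuplicated(tis)],
                 basename(files[anyDuplicated(tis)])))

  ord <- order(tis)
  voxels <- array(0, c(dims[1, 1], dims[2, 1], length(imgs)))
  for (j in seq_along(ord)) voxels[, , j] <- imgs[[ord[j]]]$image
  if (protocol == "auto")
    protocol <- switch(as.character(length(tis)),
                       "8" = "pre_5(3)3", "9" = "post_4(1)3(1)2", "custom")
  ti_image_stack(voxels, tis[ord], protocol,
                 pixel_spacing = imgs[[1]]$spacing, is_magnitude = TRUE)
}

dcm_element <- function(group, element, vr, value_raw) {
  head <- c(writeBin(as.integer(group), raw(), size = 2, endian = "little"),
            writeBin(as.integer(element), raw(), size = 2, endian = "little"),
            charToRaw(vr))
  if (vr %in% .dcm_long_vrs) {
    c(head, as.raw(c(0, 0)),
      writeBin(length(value_raw), raw(), size = 4, endian = "little"),
      value_raw)
  } else {
    c(head, writeBin(length(value_raw), raw(), size = 2, endian = "little"),
      value_raw)
  }
}

dcm_string_raw <- function(s, pad = charToRaw(" ")) {
  r <- charToRaw(s)
  if (length(r) %% 2L == 1L) r <- c(r, pad)  # even length padding
  r
}

write_dicom_ti_image <- function(img, ti, spacing, path) {
  stopifnot(is.matrix(img))
  px <- as.integer(round(t(img)))   # row-major pixel order
  if (any(px < 0L | px > 65535L))
    stop("pixel values outside the uint16 range; rescale before writing")
  meta <- c(
    dcm_element(0x0002, 0x0010, "UI",
                dcm_string_raw("1.2.840.10008.1.2.1", pad = as.raw(0))))
  meta <- c(dcm_element(0x0002, 0x0000, "UL",
                        writeBin(length(meta), raw(), size = 4, endian = "little")),
            meta)
  body <- c(
    dcm_element(0x0008, 0x0060, "CS", dcm_string_raw("MR")),
    dcm_element(0x0018, 0x0082, "DS", dcm_string_raw(format(ti))),
    dcm_element(0x0028, 0x0002, "US", writeBin(1L, raw(), size = 2, endian = "little")),
    dcm_element(0x0028, 0x0010, "US", writeBin(nrow(img), raw(), size = 2, endian = "little")),
    dcm_element(0x0028, 0x0011, "US", writeBin(ncol(img), raw(), size = 2, endian = "little")),
    dcm_element(0x0028, 0x0030, "DS",
                dcm_string_raw(paste(format(spacing), collapse = "\\"))),
    dcm_element(0x0028, 0x0100, "US", writeBin(16L, raw(), size = 2, endian = "little")),
    dcm_element(0x0028, 0x0101, "US", writeBin(16L, raw(), size = 2, endian = "little")),
    dcm_element(0x0028, 0x0102, "US", writeBin(15L, raw(), size = 2, endian = "little")),
    dcm_element(0x0028, 0x0103, "US", writeBin(0L, raw(), size = 2, endian = "little")),
    dcm_element(0x0028, 0x1052, "DS", dcm_string_raw("0")),
    dcm_element(0x0028, 0x1053, "DS", dcm_string_raw("1")),
    dcm_element(0x7FE0, 0x0010, "OW",
                writeBin(px, raw(), size = 2, endian = "little")))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), meta, body), con)
  invisible(path)
}

#' Write a TI stack as a minimal DICOM series (test fixture)
#'
#' Writes one explicit-VR little-endian DICOM file per TI image, carrying the
#' InversionTime, Rows/Columns, PixelSpacing and 16-bit unsigned PixelData
#' attributes. Pixel values are stored as unsigned 16-bit integers, as
#' clinical magnitude DICOMs are, so voxels must already be integer-valued in
#' `[0, 65535]` (quantise with `round()` first); non-integer input is an
#' error rather than a silent loss of precision. Intended for fixtures and
#' round-trip tests, not for archiving results.
#'
#' @param stack A magnitude [ti_image_stack] with integer-valued voxels.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return Invisibly, the written file paths.
#' @export
write_ti_series_dicom <- function(stack, dir, prefix = "ti") {
  stopifnot(inherits(stack, "ti_image_stack"))
  if (max(abs(stack$voxels - round(stack$voxels))) > 0)
    stop("DICOM fixture writer stores uint16; round() the voxels first")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(stack$tis))
  for (j in seq_along(stack$tis)) {
    paths[j] <- file.path(dir, sprintf("%s_%03d.dcm", prefix, j))
    write_dicom_ti_image(stack$voxels[, , j], stack$tis[j],
                         stack$pixel_spacing, paths[j])
  }
  invisible(paths)
}
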