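#' Construct a fundus image object
#'
#' Wraps an `H x W x 3` array of 8-bit intensities (0..255) together with an
#' image identifier and the scale factor of the working resolution relative
#' to the original resolution (1, or 0.25 after quarter-size reduction).
#' All package coordinates are 0-based `(row, col)`; a pixel lies inside a
#' circle iff its centre is at Euclidean distance <= radius from the circle
#' centre.
#'
#' @param pixels Numeric or integer `H x W x 3` array with values in 0..255.
#' @param image_id Identifier string.
#' @param scale_factor Working/original resolution ratio; 1 or 0.25.
#' @return An `od_image` object.
#' @export
od_image <- function(pixels, image_id = "image", scale_factor = 1) {
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L) {
    abort(sprintf("expected an H x W x 3 array, got %s channel(s)",
                  if (length(dim(pixels)) == 3L) dim(pixels)[3] else 1L),
          class = "od_format_error")
  }
  d <- dim(pixels)
  if (d[1] < 16L || d[2] < 16L) {
    abort("image must be at least 16 x 16 pixels", class = "od_format_error")
  }
  if (!scale_factor %in% c(1, 0.25)) {
    abort("scale_factor must be 1 or 0.25", class = "od_format_error")
  }
  storage.mode(pixels) <- "integer"
  structure(list(pixels = pixels, image_id = as.character(image_id),
                 scale_factor = scale_factor),
            class = "od_image")
}

#' @export
print.od_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<od_image '%s'> %d x %d x 3, 8-bit, scale_factor = %g\n",
              x$image_id, d[1], d[2], x$scale_factor))
  invisible(x)
}

#' @export
dim.od_image <- function(x) dim(x$pixels)

#' Read an 8-bit RGB fundus photograph
#'
#' Loads a PNG, TIFF or JPEG raster as an [od_image] at scale factor 1.
#' Grayscale inputs are rejected (the pipeline is multispectral by design);
#' an alpha channel, if present, is dropped.
#'
#' @param path Path to the raster file.
#' @param image_id Identifier; defaults to the file name without extension.
#' @return An [od_image].
#' @export
od_read_image <- function(path, image_id = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("cannot read '%s': no such file", path), class = "od_io_error")
  }
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e) abort(
                    sprintf("cannot decode '%s': %s", path, conditionMessage(e)),
                    class = "od_io_error"))
  a <- as.array(img)
  if (length(dim(a)) == 2L) {
    abort(sprintf("'%s' is single-channel (grayscale); a 3-channel RGB image is required",
                  path), class = "od_format_error")
  }
  nch <- dim(a)[3]
  if (nch == 4L) a <- a[, , 1:3, drop = FALSE]          # drop alpha
  if (dim(a)[3] != 3L) {
    abort(sprintf("'%s' has %d channel(s); a 3-channel RGB image is required",
                  path, nch), class = "od_format_error")
  }
  # EBImage stores (x = col, y = row); convert to (row, col, channel)
  pixels <- aperm(a, c(2, 1, 3))
  pixels <- round(pixels * 255)
  if (is.null(image_id)) image_id <- sub("\\.[^.]+$", "", basename(path))
  od_image(pixels, image_id = image_id, scale_factor = 1)
}

#' Write an image or mask to disk
#'
#' @param x An [od_image], or a numeric/logical matrix (written as a 0/255
#'   single-channel mask).
#' @param path Output path; the extension selects the format (png/tiff/jpeg).
#' @return `path`, invisibly.
#' @export
od_write_image <- function(x, path) {
  if (inherits(x, "od_image")) {
    a <- aperm(x$pixels, c(2, 1, 3)) / 255
    img <- EBImage::Image(a, colormode = "Color")
  } else {
    img <- EBImage::Image(t(matrix(as.numeric(x != 0), nrow(x), ncol(x))))
  }
  EBImage::writeImage(img, path)
  invisible(path)
}

#' Quarter-size reduction for large images
#'
#' Images with a side longer than `config$downscale_trigger` (default 1000
#' pixels) are reduced to quarter linear size by channel-wise bicubic
#' interpolation, solely to reduce processing time; smaller images pass
#' through unchanged.  The returned image carries `scale_factor = 0.25` so
#' detections can be mapped back to original coordinates.
#'
#' @param image An [od_image] at scale factor 1.
#' @param config An [od_config].
#' @return An [od_image] at working scale.
#' @export
od_downscale <- function(image, config) {
  stopifnot(inherits(image, "od_image"), inherits(config, "od_config"))
  if (image$scale_factor != 1) {
    abort("image is already at working scale", class = "od_format_error")
  }
  d <- dim(image$pixels)
  if (max(d[1:2]) <= config$downscale_trigger) return(image)
  f <- config$downscale_factor
  nr <- round(d[1] * f); nc <- round(d[2] * f)
  out <- array(0L, c(nr, nc, 3L))
  for (ch in 1:3) {
    # bicubic can overshoot: clip back to the 8-bit range
    r <- resize_bicubic(image$pixels[, , ch], nr, nc)
    out[, , ch] <- as.integer(round(pmin(pmax(r, 0), 255)))
  }
  od_image(out, image_id = image$image_id, scale_factor = f)
}
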