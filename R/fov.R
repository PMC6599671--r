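#' Field-of-view mask estimation
#'
#' The illuminated circular field of view (FOV) is separated from the dark
#' surround by two-class Otsu thresholding of a single channel (red by
#' default).  Because the FOV circle may be clipped by the image borders, a
#' circle with diameter equal to the major-axis length of the largest
#' foreground component, centred at the component centroid, completes the
#' mask; the final mask is the union of the component and the (clipped)
#' circle interior.
#'
#' @param image An [od_image].
#' @param channel `"R"`, `"G"` or `"B"`; which channel to threshold.
#' @return An object of class `od_fov`: list with `mask` (logical `H x W`),
#'   `circle_centre` (0-based `(row, col)`), `circle_radius` (pixels).
#' @export
od_fov_mask <- function(image, channel = c("R", "G", "B")) {
  stopifnot(inherits(image, "od_image"))
  channel <- match.arg(channel)
  ch <- image$pixels[, , match(channel, c("R", "G", "B"))]
  h <- tabulate(as.vector(ch) + 1L, nbins = 256L)
  if (sum(h > 0) < 2L) {
    abort("FOV not found: channel has a single intensity level",
          class = "od_fov_error")
  }
  th <- multi_otsu_thresholds(h, k = 1L)$TH
  fg <- ch > th
  if (!any(fg)) {
    abort("FOV not found: empty foreground after Otsu thresholding",
          class = "od_fov_error")
  }
  lab <- label8(fg)
  areas <- tabulate(lab[lab > 0L])
  comp <- lab == which.max(areas)
  ij <- which(comp, arr.ind = TRUE) - 1                # 0-based coords
  ctr <- colMeans(ij)
  major <- major_axis_length(ij)
  radius <- major / 2
  H <- nrow(ch); W <- ncol(ch)
  circ <- circle_mask(H, W, ctr, radius)
  structure(list(mask = comp | circ,
                 circle_centre = unname(ctr),
                 circle_radius = radius),
            class = "od_fov")
}

#' @export
print.od_fov <- function(x, ...) {
  cat(sprintf("<od_fov> %d px, circle centre (%.1f, %.1f) radius %.1f\n",
              sum(x$mask), x$circle_centre[1], x$circle_centre[2],
              x$circle_radius))
  invisible(x)
}

# Major-axis length of a pixel set (regionprops convention: 4 sqrt(lambda_max)
# of the coordinate covariance, +1/12 px for finite pixel size).
major_axis_length <- function(ij) {
  if (nrow(ij) == 1L) return(1)
  cv <- stats::cov(ij) * (nrow(ij) - 1) / nrow(ij) + diag(1 / 12, 2)
  4 * sqrt(max(eigen(cv, symmetric = TRUE, only.values = TRUE)$values))
}

# Logical H x W mask of pixels (0-based centres) within `radius` of `centre`.
circle_mask <- function(H, W, centre, radius) {
  r2 <- (seq_len(H) - 1 - centre[1])^2
  c2 <- (seq_len(W) - 1 - centre[2])^2
  outer(r2, c2, "+") <= radius^2
}

#' Per-channel dynamic-range normalisation
#'
#' Adapts the dynamic range of one channel to the full quantisation interval:
#' \eqn{I_{out} = (I_{in} - \min I) / (\max I - \min I)}, with the minimum and
#' maximum taken over in-FOV pixels only (the dark surround is masked first
#' and would otherwise pin the minimum at 0).  Out-of-FOV pixels are set to 0.
#'
#' @param values Numeric `H x W` matrix of intensities (any range).
#' @param fov An `od_fov` mask for the same geometry.
#' @param channel Channel label (`"R"`, `"G"` or `"B"`), carried along.
#' @return An object of class `od_channel`: `values` in `[0, 1]`, `channel`,
#'   `fov`, and `degenerate` flag (TRUE when the channel was constant inside
#'   the FOV, in which case all values are 0).
#' @export
od_normalize <- function(values, fov, channel = "R") {
  stopifnot(is.matrix(values), inherits(fov, "od_fov"),
            all(dim(values) == dim(fov$mask)))
  if (!any(fov$mask)) abort("empty FOV", class = "od_fov_error")
  v <- values[fov$mask]
  lo <- min(v); hi <- max(v)
  out <- matrix(0, nrow(values), ncol(values))
  degenerate <- hi == lo
  if (!degenerate) {
    out[fov$mask] <- (v - lo) / (hi - lo)
  }
  structure(list(values = out, channel = channel, fov = fov,
                 degenerate = degenerate),
            class = "od_channel")
}

#' @export
print.od_channel <- function(x, ...) {
  cat(sprintf("<od_channel %s> %d x %d, in-FOV range [%.3f, %.3f]%s\n",
              x$channel, nrow(x$values), ncol(x$values),
              min(x$values[x$fov$mask]), max(x$values[x$fov$mask]),
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

# Quantise a [0,1] channel to 256 discrete levels (0..255).
quantize256 <- function(values) {
  q <- floor(values * 255 + 0.5)
  storage.mode(q) <- "integer"
  pmin(pmax(q, 0L), 255L)
}
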