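#' Optic-disc scale Gaussian smoothing
#'
#' Convolves a normalised channel with a truncated Gaussian whose support
#' spans one nominal radius (`x, y` in `[-R_a/2, R_a/2]`, so the kernel side
#' is `R_a + 1` pixels for even `R_a`) and whose scale is `sigma = R_a/4`.
#' The kernel is renormalised to unit sum, so flat regions pass unchanged;
#' structures much smaller than the disc (vessels, exudates, haemorrhages)
#' are blurred away while disc-sized blobs survive.  Borders are handled by
#' mirror reflection.
#'
#' @param channel An [od_channel].
#' @param R_a_work Nominal radius at working scale (pixels, >= 8).
#' @param sigma Gaussian scale; defaults to `R_a_work / 4`.
#' @return The smoothed [od_channel] (out-of-FOV pixels reset to 0).
#' @export
od_gaussian_blur <- function(channel, R_a_work, sigma = R_a_work / 4) {
  stopifnot(inherits(channel, "od_channel"), R_a_work >= 8)
  h <- floor(R_a_work / 2)
  side <- 2L * h + 1L
  if (side > min(dim(channel$values))) {
    abort(sprintf("Gaussian kernel (%d px) exceeds the image", side),
          class = "od_kernel_error")
  }
  x <- seq(-h, h)
  g1 <- exp(-x^2 / (2 * sigma^2))
  kern <- outer(g1, g1)
  kern <- kern / sum(kern)
  out <- convolve_reflect(channel$values, kern)
  out[!channel$fov$mask] <- 0
  channel$values <- pmin(pmax(out, 0), 1)
  channel
}

# 2-D convolution with mirror-reflected borders (via padding + filter2).
convolve_reflect <- function(m, kern) {
  hr <- (nrow(kern) - 1L) %/% 2L
  hc <- (ncol(kern) - 1L) %/% 2L
  ri <- c(rev(seq_len(hr)), seq_len(nrow(m)), nrow(m) + 1 - seq_len(hr))
  ci <- c(rev(seq_len(hc)), seq_len(ncol(m)), ncol(m) + 1 - seq_len(hc))
  pad <- m[ri, ci, drop = FALSE]
  out <- EBImage::filter2(pad, kern, boundary = "circular")
  out[hr + seq_len(nrow(m)), hc + seq_len(ncol(m)), drop = FALSE]
}

#' Maximum-intensity Otsu class of a channel
#'
#' Re-quantises a normalised channel to 256 levels and returns the mask of
#' in-FOV pixels whose level exceeds the last threshold `th_k` (the maximum
#' intensity class).
#'
#' @param channel An [od_channel].
#' @param TH Result of [multi_otsu_thresholds()] (or an integer vector of
#'   thresholds).
#' @return Logical `H x W` mask, with attribute `empty_class = TRUE` when no
#'   in-FOV pixel exceeds `th_k`.
#' @export
max_class_mask <- function(channel, TH) {
  th <- if (is.list(TH)) TH$TH else TH
  q <- quantize256(channel$values)
  mask <- channel$fov$mask & q > th[length(th)]
  if (!any(mask)) {
    warning("empty maximum class", call. = FALSE)
    attr(mask, "empty_class") <- TRUE
  }
  mask
}

#' Multispectral mask combination
#'
#' Combines the per-channel maximum-class masks as
#' `bw_out = bw_R & (bw_G | bw_B)`: the union of the green and blue masks
#' almost always contains the disc, and intersecting with the red mask
#' suppresses rim artefacts and exudates while surviving red-channel
#' saturation (where `bw_R` is a large blob containing the disc).
#'
#' @param bw_R,bw_G,bw_B Logical masks of equal shape.
#' @return Logical mask.
#' @export
combine_masks <- function(bw_R, bw_G, bw_B) {
  stopifnot(all(dim(bw_R) == dim(bw_G)), all(dim(bw_R) == dim(bw_B)))
  out <- bw_R & (bw_G | bw_B)
  attr(out, "empty_class") <- NULL
  out
}

#' Roundness of a binary object
#'
#' `4 * pi * Area / Perimeter^2`: 1 for a continuous circle, `pi/4` for a
#' square.  The perimeter estimator is the 8-connected contour chain length
#' with diagonal steps weighted `sqrt(2)`; discretisation allows values
#' slightly above 1.  A single-pixel object has roundness 1 by convention.
#'
#' @param area Object area in pixels.
#' @param perimeter Contour length in pixels.
#' @return Dimensionless roundness.
#' @export
od_roundness <- function(area, perimeter) {
  stopifnot(all(area >= 1))
  ifelse(perimeter <= 0, 1, 4 * pi * area / perimeter^2)
}

# Chain length of an ordered 8-connected contour (0-based coords, closed).
contour_length <- function(xy) {
  if (nrow(xy) < 2L) return(0)
  xy2 <- rbind(xy, xy[1L, , drop = FALSE])
  sum(sqrt(rowSums(diff(xy2)^2)))
}

#' Measure the connected objects of a labelled mask
#'
#' @param labels Integer label matrix (from 8-connected labelling).
#' @return A tibble with one row per object: `label`, `area`, `perimeter`,
#'   `centroid_row`, `centroid_col` (0-based), `equivalent_radius`
#'   (`sqrt(area/pi)`) and `roundness`.
#' @export
binary_objects <- function(labels) {
  n <- max(labels)
  if (n == 0L) {
    return(tibble(label = integer(), area = numeric(), perimeter = numeric(),
                  centroid_row = numeric(), centroid_col = numeric(),
                  equivalent_radius = numeric(), roundness = numeric()))
  }
  oc <- EBImage::ocontour(labels)
  per <- vapply(oc, contour_length, numeric(1))[seq_len(n)]
  area <- tabulate(labels[labels > 0L], nbins = n)
  idx <- which(labels > 0L, arr.ind = TRUE)
  lab <- labels[labels > 0L]
  cr <- tapply(idx[, 1] - 1, lab, mean)
  cc <- tapply(idx[, 2] - 1, lab, mean)
  tibble(
    label = seq_len(n),
    area = as.numeric(area),
    perimeter = as.numeric(per),
    centroid_row = as.numeric(cr),
    centroid_col = as.numeric(cc),
    equivalent_radius = sqrt(area / pi),
    roundness = od_roundness(area, as.numeric(per))
  )
}

#' Select the disc candidate among binary objects
#'
#' Objects with roundness below `roundness_min` (default 0.6) are discarded;
#' among the survivors the object whose equivalent radius is closest to the
#' nominal radius, `min |sqrt(Area/pi) - R_a|`, is selected.  If no object is
#' round enough the radius criterion is applied to all objects and the
#' fallback path is flagged.  Ties go to the larger object (the disc is a
#' large structure).
#'
#' @param objects Tibble from [binary_objects()].
#' @param R_a_work Nominal radius at working scale.
#' @param roundness_min Roundness cut-off.
#' @return List with `object` (one-row tibble) and `fallback_path`
#'   (`"none"` or `"radius_only"`).
#' @export
select_od_candidate <- function(objects, R_a_work, roundness_min = 0.6) {
  if (nrow(objects) == 0L) {
    abort("no candidate objects", class = "od_roi_error")
  }
  pick <- function(pool) {
    d <- abs(pool$equivalent_radius - R_a_work)
    pool <- pool[d <= min(d) + 1e-9, , drop = FALSE]
    pool[which.max(pool$area), , drop = FALSE]
  }
  pool <- objects[objects$roundness >= roundness_min, , drop = FALSE]
  fallback <- "none"
  if (nrow(pool) == 0L) {
    pool <- objects
    fallback <- "radius_only"
  }
  sel <- pick(pool)
  # radius-consistency override: a vessel-notched disc can fall just below the
  # roundness gate while a small round distractor passes it; if the best object
  # overall is at least twice as close to the nominal radius, prefer it
  if (fallback == "none") {
    sel_all <- pick(objects)
    if (sel_all$label != sel$label &&
        abs(sel_all$equivalent_radius - R_a_work) <
          0.5 * abs(sel$equivalent_radius - R_a_work)) {
      sel <- sel_all
      fallback <- "radius_only"
    }
  }
  list(object = sel, fallback_path = fallback)
}

#' Coarse localisation of the optic-disc region
#'
#' Phase 1 of the pipeline: each channel is normalised, smoothed at disc
#' scale, thresholded with multilevel Otsu (`k` thresholds), and reduced to
#' its maximum intensity class; the three masks are combined as
#' `bw_R & (bw_G | bw_B)`, the 8-connected components are measured, and the
#' disc candidate is selected by roundness and nominal-radius proximity.  If
#' the combined mask is empty, the largest object of `bw_G | bw_B` is used
#' instead (`fallback_path = "union_fallback"`).
#'
#' @param image An [od_image] at working scale.
#' @param fov An `od_fov` for the same geometry.
#' @param config An [od_config].
#' @return An object of class `od_roi`: per-channel masks `bw_R`, `bw_G`,
#'   `bw_B`, combined `bw_out`, `selected` object (tibble row), `centroid`
#'   (0-based working-scale `(row, col)`), `fallback_path`, per-channel
#'   `thresholds`, and the normalised `channels` (before smoothing, reused by
#'   the fine phase).
#' @export
locate_roi <- function(image, fov, config) {
  stopifnot(inherits(image, "od_image"), inherits(fov, "od_fov"),
            inherits(config, "od_config"))
  R_a_work <- working_radius(config, image$scale_factor)
  names_ch <- c("R", "G", "B")
  channels <- lapply(1:3, function(i) {
    od_normalize(matrix(as.numeric(image$pixels[, , i]),
                        nrow(image$pixels), ncol(image$pixels)),
                 fov, channel = names_ch[i])
  })
  names(channels) <- names_ch
  masks <- vector("list", 3L)
  thresholds <- vector("list", 3L)
  for (i in 1:3) {
    blurred <- od_gaussian_blur(channels[[i]], R_a_work,
                                sigma = R_a_work * config$sigma_factor)
    q <- quantize256(blurred$values)
    h <- tabulate(q[fov$mask] + 1L, nbins = 256L)
    th <- tryCatch(multi_otsu_thresholds(h, config$k),
                   od_histogram_error = function(e) NULL)
    thresholds[i] <- list(th)     # [[<- would drop the element when th is NULL
    masks[[i]] <- if (is.null(th)) {
      matrix(FALSE, nrow(q), ncol(q))
    } else {
      suppressWarnings(max_class_mask(blurred, th))
    }
  }
  names(masks) <- names(thresholds) <- names_ch
  bw_out <- combine_masks(masks$R, masks$G, masks$B)
  fallback <- "none"
  labels <- label8(bw_out)
  objects <- binary_objects(labels)
  if (nrow(objects) == 0L) {
    labels <- label8(masks$G | masks$B)
    objects <- binary_objects(labels)
    fallback <- "union_fallback"
    if (nrow(objects) == 0L) {
      abort("ROI not found: no object in any channel combination",
            class = "od_roi_error")
    }
    objects <- objects[which.max(objects$area), , drop = FALSE]
  }
  sel <- select_od_candidate(objects, R_a_work, config$roundness_min)
  if (fallback == "none") fallback <- sel$fallback_path
  structure(
    list(bw_R = masks$R, bw_G = masks$G, bw_B = masks$B, bw_out = bw_out,
         selected = sel$object,
         centroid = c(sel$object$centroid_row, sel$object$centroid_col),
         fallback_path = fallback,
         thresholds = thresholds,
         channels = channels,
         R_a_work = R_a_work),
    class = "od_roi"
  )
}

#' @export
print.od_roi <- function(x, ...) {
  cat(sprintf("<od_roi> centroid (%.1f, %.1f), fallback = %s\n",
              x$centroid[1], x$centroid[2], x$fallback_path))
  invisible(x)
}
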