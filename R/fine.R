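#' Vessel suppression by grayscale closing
#'
#' Retinal vessels are dark curvilinear "gaps" in the retinal background.  A
#' grayscale closing (dilation then erosion) with a disc structuring element
#' of radius `se = 0.15 * R_a_work` — the anatomical vessel-width to
#' disc-diameter ratio — fills structures narrower than the element while
#' preserving the bright disc; a small mean filter (default 3 x 3) then blurs
#' any residual vessel edges.
#'
#' @param channel An [od_channel] (normalised).
#' @param R_a_work Nominal radius at working scale (pixels, >= 8).
#' @param config An [od_config] (supplies `se_factor` and
#'   `mean_filter_size`).
#' @return The filtered [od_channel].
#' @export
suppress_vessels <- function(channel, R_a_work, config = od_config(R_a_work)) {
  stopifnot(inherits(channel, "od_channel"), R_a_work >= 8)
  se_radius <- round(config$se_factor * R_a_work)
  closed <- od_closing(channel$values, se_radius)
  k <- config$mean_filter_size
  mean_kern <- matrix(1 / (k * k), k, k)
  out <- convolve_reflect(closed, mean_kern)
  channel$values <- pmin(pmax(out, 0), 1)
  channel
}

#' Grayscale closing with a disc structuring element
#'
#' Dilation followed by erosion with the same disc element.  Closing is
#' extensive (never decreases intensities), idempotent, and increasing; it
#' fills dark structures narrower than the element diameter while leaving
#' larger bright structures intact.
#'
#' @param values Numeric matrix.
#' @param se_radius Structuring-element radius in pixels (>= 1); the disc
#'   element has diameter `2 * se_radius + 1`.
#' @return The closed matrix.
#' @export
od_closing <- function(values, se_radius) {
  se_radius <- round(se_radius)
  if (se_radius < 1) {
    abort("structuring element smaller than 1 px; use a larger nominal radius",
          class = "od_kernel_error")
  }
  brush <- EBImage::makeBrush(2L * se_radius + 1L, shape = "disc")
  as.matrix(EBImage::closing(values, brush))
}

#' Crop a square window around the coarse centroid
#'
#' Extracts the `2 R_a_work x 2 R_a_work` window centred on the coarse
#' centroid (clipped at the image borders), recording the offset so that
#' detections inside the crop map back to absolute coordinates.
#'
#' @param channel An [od_channel].
#' @param centre 0-based `(row, col)` crop centre.
#' @param R_a_work Nominal radius at working scale.
#' @return An `od_crop`: `values` (matrix), `inside` (logical, crop pixels in
#'   the FOV), `offset` (0-based `(row, col)` of the crop's top-left pixel),
#'   `channel`.
#' @export
crop_square <- function(channel, centre, R_a_work) {
  stopifnot(inherits(channel, "od_channel"))
  H <- nrow(channel$values); W <- ncol(channel$values)
  cr <- round(centre[1]); cc <- round(centre[2])
  if (cr < 0 || cr >= H || cc < 0 || cc >= W) {
    abort("crop centre outside the image", class = "od_crop_error")
  }
  side <- 2L * round(R_a_work)
  r0 <- max(0L, cr - side %/% 2L); r1 <- min(H - 1L, r0 + side - 1L)
  r0 <- max(0L, r1 - side + 1L)
  c0 <- max(0L, cc - side %/% 2L); c1 <- min(W - 1L, c0 + side - 1L)
  c0 <- max(0L, c1 - side + 1L)
  rows <- (r0:r1) + 1L; cols <- (c0:c1) + 1L
  inside <- channel$fov$mask[rows, cols, drop = FALSE]
  if (!any(inside)) {
    abort("crop window entirely outside the FOV", class = "od_crop_error")
  }
  structure(list(values = channel$values[rows, cols, drop = FALSE],
                 inside = inside,
                 offset = c(r0, c0),
                 channel = channel$channel),
            class = "od_crop")
}

#' Shannon entropy of a cropped channel
#'
#' Information content `H = -sum p_i log2(p_i)` over the 256-level intensity
#' histogram of the unmasked crop pixels; empty bins contribute 0.  A
#' saturated (near-constant) channel has low entropy, a well-contrasted one
#' high entropy.
#'
#' @param crop An `od_crop` from [crop_square()].
#' @return Entropy in bits (in `[0, 8]` for 256 levels).
#' @export
shannon_entropy <- function(crop) {
  stopifnot(inherits(crop, "od_crop"), any(crop$inside))
  q <- quantize256(crop$values)[crop$inside]
  p <- tabulate(q + 1L, nbins = 256L)
  p <- p / sum(p)
  p <- p[p > 0]
  max(0, -sum(p * log2(p)))   # guard the -0 of a single-level histogram
}

#' Entropy-based channel arbitration
#'
#' Computes the Shannon entropy of the cropped region in each channel and
#' selects the channel with the greatest information content; in a
#' well-contrasted image this is typically red, while red saturation
#' collapses the red histogram and hands the choice to green or blue.  Ties
#' break in the order R > G > B.
#'
#' @param crops Named list of three `od_crop`s (`R`, `G`, `B`).
#' @return An `od_entropy` report: `H_r`, `H_g`, `H_b` (bits) and
#'   `selected_channel`.
#' @export
select_channel_by_entropy <- function(crops) {
  stopifnot(all(c("R", "G", "B") %in% names(crops)))
  H <- vapply(crops[c("R", "G", "B")], shannon_entropy, numeric(1))
  sel <- c("R", "G", "B")[which.max(H)]   # which.max: first of ties => R > G > B
  structure(list(H_r = unname(H[1]), H_g = unname(H[2]), H_b = unname(H[3]),
                 selected_channel = sel),
            class = "od_entropy")
}

#' @export
print.od_entropy <- function(x, ...) {
  cat(sprintf("<od_entropy> H_r = %.3f, H_g = %.3f, H_b = %.3f bits -> %s\n",
              x$H_r, x$H_g, x$H_b, x$selected_channel))
  invisible(x)
}

# Sobel gradient magnitude.
sobel_magnitude <- function(m) {
  sx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3)
  gx <- convolve_reflect(m, sx)
  gy <- convolve_reflect(m, t(sx))
  sqrt(gx^2 + gy^2)
}

# Integer circle offsets of radius r (unique (dr, dc) pairs).
circle_offsets <- function(r) {
  n <- max(8L, ceiling(2 * pi * r * 1.5))
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  dr <- round(r * sin(th)); dc <- round(r * cos(th))
  unique(cbind(dr, dc))
}

#' Circular Hough transform detection
#'
#' Two-stage circle fit.  (1) Centre: pixels whose Sobel gradient magnitude
#' exceeds the `gradient_quantile` (default 90th percentile over unmasked
#' pixels) vote along full circles in a separate accumulator for every
#' integer radius in `[r_min, r_max]`, with votes weighted by gradient
#' magnitude; each radius's accumulator is smoothed with a small Gaussian
#' (`accumulator_sigma`, default 2 px) and its peak becomes a centre
#' candidate (top three peaks per radius, 5-px non-maximum suppression).
#' Keeping the accumulator radius-resolved stops edge structures at
#' different distances from conspiring at a spurious point.  (2) The
#' candidates (deduplicated within 3 px) are verified with the radial
#' intensity histogram — mean intensity on 1-px rings around each candidate.
#' The winning candidate maximises the disc evidence (mean intensity inside
#' the circle minus the surrounding annulus: the disc is a bright region,
#' and a rim-local score alone can be fooled by half-visible pseudo-circles
#' at the crop border).  Its radius is then the `r` in `[r_min, r_max]`
#' maximising the inward-outward ring-mean contrast, weighted by ring
#' support (the fraction of circumference observed; gated below 0.2), with
#' ties to the smallest radius.  With `radius_rule = "ring_mean"` the radius
#' is instead the first local maximum of the raw radial intensity profile.
#'
#' @param crop An `od_crop`.
#' @param r_min,r_max Radius search band in pixels (`r_min < r_max`).
#' @param config An [od_config] (CHT tunables); the nominal radius is unused
#'   here.
#' @param context Optional [od_channel] covering the full image the crop was
#'   taken from.  When supplied, candidate verification and the radial
#'   profile are measured on it (at absolute coordinates), so that rings
#'   extending past the crop border — inevitable when the disc nearly fills
#'   the crop — are still observed.  The vote accumulation itself stays
#'   inside the crop.
#' @return List with `centre` (0-based `(row, col)` within the crop),
#'   `radius`, `vote` (accumulator peak value of the chosen candidate) and
#'   `failed` (TRUE when no pixel voted, in which case the rest is NA).
#' @export
hough_circle <- function(crop, r_min, r_max,
                         config = od_config(max(8, r_min / 0.95)),
                         context = NULL) {
  stopifnot(inherits(crop, "od_crop"), r_min < r_max)
  H <- nrow(crop$values); W <- ncol(crop$values)
  if (min(H, W) <= 2 * r_min) {
    abort("crop too small for the radius band", class = "od_crop_error")
  }
  r_min <- as.integer(round(r_min)); r_max <- as.integer(round(r_max))
  mag <- sobel_magnitude(crop$values)
  mag[!crop$inside] <- 0
  thr <- quantile(mag[crop$inside], config$gradient_quantile, names = FALSE)
  sel <- crop$inside & mag > thr & mag > 1e-12
  edge <- which(sel, arr.ind = TRUE)
  if (nrow(edge) == 0L) {
    return(list(centre = c(NA_real_, NA_real_), radius = NA_real_,
                vote = NA_real_, failed = TRUE))
  }
  w <- mag[sel]
  s <- config$accumulator_sigma
  hs <- max(1L, ceiling(3 * s))
  g1 <- exp(-(seq(-hs, hs))^2 / (2 * s^2))
  kern <- outer(g1, g1); kern <- kern / sum(kern)
  cand <- matrix(numeric(0), 0L, 3L)             # row, col, vote
  for (r in r_min:r_max) {
    off <- circle_offsets(r)
    m <- nrow(off)
    rr <- rep(edge[, 1], each = m) + off[, 1]
    cc <- rep(edge[, 2], each = m) + off[, 2]
    ww <- rep(w, each = m)
    ok <- rr >= 1L & rr <= H & cc >= 1L & cc <= W
    idx <- rr[ok] + (cc[ok] - 1L) * H
    votes <- rowsum(ww[ok], idx)
    acc <- numeric(H * W)
    acc[as.integer(rownames(votes))] <- votes[, 1L]
    acc_s <- convolve_reflect(matrix(acc, H, W), kern)
    for (j in 1:3) {                     # top peaks, 5-px non-max suppression
      p <- which.max(acc_s)
      v <- acc_s[p]
      if (v <= 0) break
      pr <- (p - 1L) %% H; pc <- (p - 1L) %/% H
      cand <- rbind(cand, c(pr, pc, v))
      acc_s[max(1, pr - 4):min(H, pr + 6), max(1, pc - 4):min(W, pc + 6)] <- 0
    }
  }
  # dedupe candidate centres (3 px), strongest vote first
  keep <- rep(TRUE, nrow(cand))
  for (i in order(-cand[, 3])) {
    if (!keep[i]) next
    d2 <- (cand[, 1] - cand[i, 1])^2 + (cand[, 2] - cand[i, 2])^2
    keep[d2 <= 9 & seq_len(nrow(cand)) != i] <- FALSE
  }
  cand <- cand[keep, , drop = FALSE]
  if (is.null(context)) {
    vvalues <- crop$values; vinside <- crop$inside; voffset <- c(0, 0)
  } else {
    stopifnot(inherits(context, "od_channel"))
    vvalues <- context$values; vinside <- context$fov$mask
    voffset <- crop$offset
  }
  best <- NULL
  for (i in seq_len(nrow(cand))) {
    rc <- ring_profile_score(vvalues, vinside, voffset + cand[i, 1:2],
                             r_min, r_max, config)
    if (is.null(best) || rc$disc_score > best$score) {
      best <- list(centre = cand[i, 1:2], radius = rc$radius,
                   score = rc$disc_score, vote = cand[i, 3])
    }
  }
  if (!is.finite(best$score)) {
    return(list(centre = c(NA_real_, NA_real_), radius = NA_real_,
                vote = NA_real_, failed = TRUE))
  }
  list(centre = as.numeric(best$centre), radius = best$radius,
       vote = best$vote, failed = FALSE)
}

# Radial intensity histogram around a centre.  Returns the radius under the
# configured rule plus two scores: the rim score (support-weighted
# inward-outward ring contrast at the chosen radius) and the disc score
# (mean intensity inside the circle minus the surrounding annulus, the
# bright-region evidence used to arbitrate between centre candidates --
# a rim-local contrast alone can be fooled by half-visible pseudo-circles
# at the crop border).
ring_profile_score <- function(values, inside, centre, r_min, r_max, config) {
  H <- nrow(values); W <- ncol(values)
  d <- sqrt(outer(((seq_len(H) - 1) - centre[1])^2,
                  ((seq_len(W) - 1) - centre[2])^2, "+"))
  ring <- floor(d + 0.5)                 # 1-px rings
  w <- config$ring_width
  rmaxp <- r_max + 2L * w
  keep <- inside & ring <= rmaxp
  sums <- rep(0, rmaxp + 1L)
  count <- rep(0, rmaxp + 1L)
  if (any(keep)) {
    agg <- tapply(values[keep], ring[keep], sum)
    cnt <- tapply(values[keep], ring[keep], length)
    sums[as.integer(names(agg)) + 1L] <- agg
    count[as.integer(names(cnt)) + 1L] <- cnt
  }
  means <- ifelse(count > 0, sums / pmax(count, 1), NA_real_)
  support <- count / (2 * pi * pmax(1, 0:rmaxp))
  rs <- r_min:r_max
  if (config$radius_rule == "ring_mean") {
    prof <- means[rs + 1L]
    loc <- which(diff(sign(diff(c(-Inf, prof, -Inf)))) < 0)
    return(list(radius = as.numeric(rs[loc[1L]]), score = 0, disc_score = 0))
  }
  contrast <- vapply(rs, function(r) {
    inner <- means[pmax(0L, r - w):(r - 1L) + 1L]
    outer_ <- means[(r + 1L):(r + w) + 1L]
    mean(inner, na.rm = TRUE) - mean(outer_, na.rm = TRUE)
  }, numeric(1))
  supp <- vapply(rs, function(r) {
    min(support[(pmax(0L, r - w):(r + w)) + 1L])
  }, numeric(1))
  score <- contrast * sqrt(pmin(1, supp / 0.5))
  score[is.na(score) | supp < 0.2] <- -Inf
  cs <- cumsum(sums); cn <- cumsum(count)
  disc <- vapply(rs, function(r) {
    n_in <- cn[r]                        # pixels with ring <= r - 1
    n_ann <- cn[min(r + 2L * w, rmaxp) + 1L] - cn[r + 1L]
    if (n_in < 0.2 * pi * (r - 1)^2 || n_ann < 30) return(-Inf)
    cs[r] / n_in - (cs[min(r + 2L * w, rmaxp) + 1L] - cs[r + 1L]) / n_ann
  }, numeric(1))
  list(radius = as.numeric(rs[which.max(score)]),   # first of ties = smallest
       score = max(score),
       disc_score = max(disc))
}

#' Detect the optic disc in a colour fundus image
#'
#' Runs the full two-phase pipeline: field-of-view masking, quarter-size
#' reduction of large images, per-channel normalisation, coarse multispectral
#' localisation ([locate_roi()]), vessel suppression by grayscale closing,
#' square cropping around the coarse centroid, entropy-based channel
#' arbitration, and circular Hough transform search in the band
#' `[0.95, 1.3] * R_a`.  Centre and radius are mapped back through the crop
#' offset and the scale factor to original-image coordinates.  If the Hough
#' stage fails (no gradient votes), the coarse centroid with the nominal
#' radius is returned and flagged — the screening use-case prefers a flagged
#' best guess over an error.
#'
#' @param image An [od_image] at original scale.
#' @param config An [od_config]; `nominal_radius` must match the dataset.
#' @return An `od_circle`: `centre` and `radius` in original-scale pixels
#'   (0-based), `centre_work`/`radius_work` at working scale, `channel` used,
#'   `entropies` (`od_entropy`), `accumulator_peak`, `fallback_flags`
#'   (character vector, possibly empty), `coarse` (the `od_roi`),
#'   `scale_factor` and `image_id`.
#' @export
detect_od <- function(image, config) {
  stopifnot(inherits(image, "od_image"), inherits(config, "od_config"))
  work <- od_downscale(image, config)
  fov <- od_fov_mask(work, config$fov_channel)
  roi <- locate_roi(work, fov, config)
  R_a_work <- roi$R_a_work
  flags <- character()
  if (roi$fallback_path != "none") flags <- c(flags, roi$fallback_path)
  suppressed <- lapply(roi$channels, suppress_vessels, R_a_work = R_a_work,
                       config = config)
  crops <- lapply(suppressed, crop_square, centre = roi$centroid,
                  R_a_work = R_a_work)
  ent <- select_channel_by_entropy(crops)
  sel_crop <- crops[[ent$selected_channel]]
  r_min <- max(3L, round(config$r_min_factor * R_a_work))
  r_max <- round(config$r_max_factor * R_a_work)
  cht <- hough_circle(sel_crop, r_min, r_max, config,
                      context = suppressed[[ent$selected_channel]])
  if (cht$failed) {
    flags <- c(flags, "cht_failed")
    centre_work <- roi$centroid
    radius_work <- R_a_work
  } else {
    centre_work <- sel_crop$offset + cht$centre
    radius_work <- cht$radius
  }
  sf <- work$scale_factor
  structure(
    list(centre = centre_work / sf,
         radius = radius_work / sf,
         centre_work = centre_work, radius_work = radius_work,
         channel = ent$selected_channel,
         entropies = ent,
         accumulator_peak = if (cht$failed) NA_real_ else cht$vote,
         fallback_flags = flags,
         coarse = roi,
         scale_factor = sf,
         image_id = image$image_id),
    class = "od_circle"
  )
}

#' @export
print.od_circle <- function(x, ...) {
  cat(sprintf(
    "<od_circle '%s'> centre (%.1f, %.1f), radius %.1f px (original scale)\n",
    x$image_id, x$centre[1], x$centre[2], x$radius))
  cat(sprintf("  channel %s (H_r %.2f, H_g %.2f, H_b %.2f)%s\n",
              x$channel, x$entropies$H_r, x$entropies$H_g, x$entropies$H_b,
              if (length(x$fallback_flags))
                paste0("  flags: ", paste(x$fallback_flags, collapse = ","))
              else ""))
  invisible(x)
}

#' Tidy a detection result
#'
#' @param x An `od_circle`.
#' @param ... Unused.
#' @return One-row tibble: `image_id`, `centre_row`, `centre_col`, `radius`,
#'   `scale_factor`, `channel`, `H_r`, `H_g`, `H_b`, `fallback_flags`.
#' @exportS3Method generics::tidy
tidy.od_circle <- function(x, ...) {
  tibble(image_id = x$image_id,
         centre_row = x$centre[1], centre_col = x$centre[2],
         radius = x$radius, scale_factor = x$scale_factor,
         channel = x$channel,
         H_r = x$entropies$H_r, H_g = x$entropies$H_g, H_b = x$entropies$H_b,
         fallback_flags = paste(x$fallback_flags, collapse = ";"))
}
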