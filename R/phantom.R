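#' Specify a synthetic fundus phantom
#'
#' A phantom emulates the image properties the detection pipeline exploits:
#' a circular illuminated field of view on a dark surround; a bright,
#' roughly circular optic disc whose contrast is strongest in the red
#' channel; smooth low-frequency "choroidal" texture, also strongest in red;
#' dark curvilinear vessels of width 0.15 x the disc diameter radiating from
#' the disc; optional bright exudate distractors; optional red-channel
#' saturation (a wide illumination blob clipped at 255, reproducing
#' overexposure); and Gaussian pixel noise.  It does not attempt
#' photorealism — no physiological vessel branching, no pathology beyond
#' bright blobs.
#'
#' @param seed Integer seed; rendering is bit-deterministic given the spec.
#' @param size `(H, W)` in pixels.
#' @param fov_radius Field-of-view radius (pixels); centred in the image.
#' @param od_centre 0-based `(row, col)`; the disc must lie inside the FOV.
#' @param od_radius Disc radius (pixels).
#' @param od_intensity,background,vessel_intensity Per-channel 8-bit levels
#'   `(R, G, B)`.
#' @param vessel_count Number of vessels.
#' @param vessel_width Width of the widest (main-trunk) stroke; default
#'   `0.15 * 2 * od_radius`, the anatomical main-vessel to disc-diameter
#'   ratio.  Individual vessels are rendered at 0.6-1 x this width.
#' @param cup_radius_factor,cup_boost Optic cup: a paler central region of
#'   radius `cup_radius_factor * od_radius` whose per-channel intensity boost
#'   (levels) is strongest in red, where the cup/rim contrast is most
#'   visible.
#' @param red_saturated Clip the red channel at 255 over a bright region
#'   covering the disc and most of the FOV.
#' @param exudate_count,exudate_radius,exudate_intensity Bright distractor
#'   blobs placed away from the disc.
#' @param noise_sigma Gaussian pixel noise, 8-bit levels.
#' @param illumination_gradient Amplitude (levels) of a linear illumination
#'   ramp across the FOV.
#' @param texture_amplitude Per-channel amplitude of the low-frequency
#'   texture field (levels); red strongest, mimicking choroidal visibility at
#'   long wavelengths.
#' @return An `od_phantom_spec` (named list).
#' @export
phantom_spec <- function(seed = 1L,
                         size = c(512L, 512L),
                         fov_radius = 230,
                         od_centre = c(190, 330),
                         od_radius = 55,
                         od_intensity = c(215, 150, 100),
                         background = c(150, 90, 50),
                         vessel_count = 6L,
                         vessel_width = 0.15 * 2 * od_radius,
                         vessel_intensity = c(135, 35, 15),
                         cup_radius_factor = 0.35,
                         cup_boost = c(14, 7, 2),
                         red_saturated = FALSE,
                         exudate_count = 0L,
                         exudate_radius = 12,
                         exudate_intensity = c(235, 185, 40),
                         noise_sigma = 3,
                         illumination_gradient = 15,
                         texture_amplitude = c(12, 4, 2)) {
  spec <- structure(
    list(seed = as.integer(seed), size = as.integer(size),
         fov_radius = fov_radius,
         fov_centre = (as.integer(size) - 1) / 2,
         od_centre = as.numeric(od_centre), od_radius = od_radius,
         od_intensity = od_intensity, background = background,
         vessel_count = as.integer(vessel_count),
         vessel_width = vessel_width,
         vessel_intensity = vessel_intensity,
         cup_radius_factor = cup_radius_factor,
         cup_boost = cup_boost,
         red_saturated = isTRUE(red_saturated),
         exudate_count = as.integer(exudate_count),
         exudate_radius = exudate_radius,
         exudate_intensity = exudate_intensity,
         noise_sigma = noise_sigma,
         illumination_gradient = illumination_gradient,
         texture_amplitude = texture_amplitude),
    class = "od_phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  d <- sqrt(sum((spec$od_centre - spec$fov_centre)^2))
  if (d + spec$od_radius > spec$fov_radius) {
    abort("optic disc not fully inside the FOV", class = "od_phantom_error")
  }
  if (spec$fov_radius > min(spec$size) / 2) {
    abort("FOV larger than the image", class = "od_phantom_error")
  }
  invisible(spec)
}

# Anti-aliased disc coverage (1 inside, 0 outside, linear over 1 px).
disc_coverage <- function(H, W, centre, radius) {
  d <- sqrt(outer(((seq_len(H) - 1) - centre[1])^2,
                  ((seq_len(W) - 1) - centre[2])^2, "+"))
  pmin(pmax(radius + 0.5 - d, 0), 1)
}

# Smooth low-frequency random field (unit scale), from a coarse grid
# upsampled bicubically.
texture_field <- function(H, W, cell = 32L) {
  g <- matrix(rnorm(ceiling(H / cell + 3) * ceiling(W / cell + 3)),
              ceiling(H / cell + 3))
  resize_bicubic(g, H, W)
}

# Paint soft-edged strokes (max-coverage compositing) along sampled points.
stamp_strokes <- function(cov, points, width) {
  H <- nrow(cov); W <- ncol(cov)
  hw <- width / 2
  span <- ceiling(hw + 1)
  off <- expand.grid(dr = -span:span, dc = -span:span)
  val <- pmin(pmax(hw + 0.5 - sqrt(off$dr^2 + off$dc^2), 0), 1)
  keep <- val > 0
  off <- off[keep, ]; val <- val[keep]
  for (i in seq_len(nrow(points))) {
    rr <- round(points[i, 1]) + 1L + off$dr
    cc <- round(points[i, 2]) + 1L + off$dc
    ok <- rr >= 1L & rr <= H & cc >= 1L & cc <= W
    idx <- rr[ok] + (cc[ok] - 1L) * H
    cov[idx] <- pmax(cov[idx], val[ok])
  }
  cov
}

#' Render a synthetic fundus phantom
#'
#' Deterministic given the spec (including its seed).  Returns the 8-bit RGB
#' image together with exact ground truth: the disc centre, radius and the
#' rasterised disc mask.
#'
#' @param spec An [phantom_spec()].
#' @return List with `image` (an [od_image]), `truth` (an [od_truth]) and
#'   `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "od_phantom_spec"))
  validate_phantom_spec(spec)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(spec$seed)

  H <- spec$size[1]; W <- spec$size[2]
  fov_cov <- disc_coverage(H, W, spec$fov_centre, spec$fov_radius)
  od_cov <- disc_coverage(H, W, spec$od_centre, spec$od_radius)
  cup_cov <- disc_coverage(H, W, spec$od_centre,
                           spec$cup_radius_factor * spec$od_radius)

  # illumination ramp along a random direction, plus shared texture field
  ang <- runif(1, 0, 2 * pi)
  ramp <- (outer((seq_len(H) - 1) - spec$fov_centre[1],
                 (seq_len(W) - 1) - spec$fov_centre[2],
                 function(r, c) r * sin(ang) + c * cos(ang))) / spec$fov_radius
  tex <- texture_field(H, W)

  # vessels: quadratic Bezier strokes leaving the disc centre
  n_v <- spec$vessel_count
  v_ang <- runif(n_v, 0, 2 * pi)
  v_len <- runif(n_v, 0.8, 1.1) * spec$fov_radius
  v_bend <- rnorm(n_v, 0, 0.25)
  v_start <- runif(n_v, 0.2, 0.6) * spec$od_radius
  v_width <- runif(n_v, 0.6, 1) * spec$vessel_width   # one main trunk, thinner branches
  v_width[1] <- spec$vessel_width
  vessel_cov <- matrix(0, H, W)
  for (v in seq_len(n_v)) {
    dir <- c(sin(v_ang[v]), cos(v_ang[v]))
    perp <- c(-dir[2], dir[1])
    # vessels leave the cup margin, not the exact centre: real trunks do not
    # all overlap at one point, which would locally exceed the 0.15 width ratio
    p0 <- spec$od_centre + dir * v_start[v]
    p1 <- p0 + dir * v_len[v] * 0.5 + perp * v_bend[v] * v_len[v]
    p2 <- p0 + dir * v_len[v]
    t <- seq(0, 1, length.out = 300)
    pts <- cbind((1 - t)^2 * p0[1] + 2 * t * (1 - t) * p1[1] + t^2 * p2[1],
                 (1 - t)^2 * p0[2] + 2 * t * (1 - t) * p1[2] + t^2 * p2[2])
    vessel_cov <- stamp_strokes(vessel_cov, pts, v_width[v])
  }
  vessel_cov <- vessel_cov * (fov_cov > 0)

  # exudates: bright blobs away from the disc
  ex_cov <- matrix(0, H, W)
  if (spec$exudate_count > 0) {
    placed <- 0L
    while (placed < spec$exudate_count) {
      p <- spec$fov_centre +
        runif(1, 0.3, 0.85) * spec$fov_radius *
        (function(a) c(sin(a), cos(a)))(runif(1, 0, 2 * pi))
      if (sqrt(sum((p - spec$od_centre)^2)) < 2.5 * spec$od_radius) next
      ex_cov <- pmax(ex_cov, disc_coverage(H, W, p, spec$exudate_radius))
      placed <- placed + 1L
    }
    ex_cov <- ex_cov * (fov_cov > 0)
  }

  sat_blob <- if (spec$red_saturated) {
    bc <- (spec$fov_centre + spec$od_centre) / 2
    sig <- 0.9 * spec$fov_radius
    d2 <- outer(((seq_len(H) - 1) - bc[1])^2, ((seq_len(W) - 1) - bc[2])^2, "+")
    280 * exp(-d2 / (2 * sig^2))
  } else NULL

  px <- array(0, c(H, W, 3))
  for (ch in 1:3) {
    v <- matrix(0, H, W)
    base <- spec$background[ch] +
      spec$illumination_gradient * ramp +
      spec$texture_amplitude[ch] * tex
    v <- base * fov_cov
    v <- v * (1 - od_cov) + (spec$od_intensity[ch] +
                               spec$cup_boost[ch] * cup_cov +
                               spec$texture_amplitude[ch] * tex) * od_cov
    v <- v * (1 - ex_cov) + spec$exudate_intensity[ch] * ex_cov
    v <- v * (1 - vessel_cov) + spec$vessel_intensity[ch] * vessel_cov
    v <- v * (fov_cov > 0)
    if (!is.null(sat_blob)) {
      v <- v + sat_blob * (if (ch == 1) 1 else if (ch == 2) 0.15 else 0.05) *
        (fov_cov > 0)
    }
    v <- v + rnorm(H * W, 0, spec$noise_sigma)
    px[, , ch] <- round(pmin(pmax(v, 0), 255))
  }
  image <- od_image(px, image_id = sprintf("phantom_%06d", spec$seed))
  truth <- od_truth(centre = spec$od_centre,
                    mask = rasterise_circle(H, W, spec$od_centre, spec$od_radius),
                    radius = spec$od_radius,
                    image_id = image$image_id)
  list(image = image, truth = truth, spec = spec)
}

#' Generate a reproducible batch of phantoms
#'
#' Draws `n` phantom specs spanning the image regimes the algorithm must
#' handle — unsaturated, red-saturated, with exudate distractors, and disc
#' near the FOV rim — with per-phantom variation in disc radius, position,
#' vessel count and illumination.  Regime counts are `round(n * mix)`
#' (largest-remainder corrected) and the batch is fully determined by
#' `master_seed`.
#'
#' @param n Number of phantoms.
#' @param master_seed Integer master seed.
#' @param regime_mix Named proportions over
#'   `c("unsaturated", "saturated", "exudate", "rim")`; must sum to 1.
#' @param size,fov_radius,nominal_radius Geometry of the batch; the default
#'   512 x 512 / FOV 230 with nominal disc radius 50 px keeps the disc the
#'   dominant bright structure at a realistic disc-to-FOV ratio.
#' @return A list of length `n`; each element is the [generate_phantom()]
#'   result plus a `regime` label.
#' @export
generate_batch <- function(n, master_seed = 1L,
                           regime_mix = c(unsaturated = 0.3, saturated = 0.5,
                                          exudate = 0.1, rim = 0.1),
                           size = c(512L, 512L), fov_radius = 230,
                           nominal_radius = 50) {
  stopifnot(n >= 1, abs(sum(regime_mix) - 1) < 1e-9)
  regimes <- c("unsaturated", "saturated", "exudate", "rim")
  mix <- setNames(numeric(4), regimes)
  mix[names(regime_mix)] <- regime_mix
  counts <- floor(n * mix)
  rem <- n - sum(counts)
  if (rem > 0) {
    frac <- n * mix - counts
    add <- order(frac, decreasing = TRUE)[seq_len(rem)]
    counts[add] <- counts[add] + 1L
  }
  labels <- rep(regimes, counts)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(as.integer(master_seed %% 100000L) * 17L + 11L)
  labels <- sample(labels)                       # interleave regimes
  fc <- (as.integer(size) - 1) / 2
  out <- vector("list", n)
  for (i in seq_len(n)) {
    r_od <- runif(1, 0.96, 1.24) * nominal_radius
    regime <- labels[i]
    dist <- if (regime == "rim") fov_radius - r_od - 6 else runif(1, 100, 130)
    a <- runif(1, 0, 2 * pi)
    ctr <- fc + dist * c(sin(a), cos(a))
    spec <- phantom_spec(
      seed = as.integer((master_seed %% 1000000L) * 1000L + i),
      size = size, fov_radius = fov_radius,
      od_centre = ctr, od_radius = r_od,
      vessel_count = sample(4:7, 1),
      red_saturated = regime == "saturated",
      exudate_count = if (regime == "exudate") 3L else 0L
    )
    ph <- generate_phantom(spec)
    ph$regime <- regime
    out[[i]] <- ph
  }
  out
}
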