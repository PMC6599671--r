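test_that("closing fills dark strokes and preserves disc-sized structures", {
  se <- 8L
  # dark line of width 2*se - 2 on a bright background is filled
  m <- matrix(0.9, 80, 80)
  m[, 33:(33 + 2 * se - 3)] <- 0.2
  cl <- od_closing(m, se)
  expect_gte(min(cl), 0.9 - 1 / 255)
  # a bright disc of radius 1.5*se survives within one grey level
  m2 <- matrix(0.2, 80, 80)
  disc <- rasterise_circle(80, 80, c(39.5, 39.5), 1.5 * se)
  m2[disc] <- 0.9
  cl2 <- od_closing(m2, se)
  expect_lte(max(abs(cl2[disc] - 0.9)), 1 / 255)

  expect_error(od_closing(m, 0), class = "od_kernel_error")
})

test_that("suppress_vessels leaves constant images unchanged", {
  cfg <- od_config(nominal_radius = 40)
  flat <- as_channel(matrix(0.45, 96, 96))
  out <- suppress_vessels(flat, 40, cfg)
  expect_lt(max(abs(out$values - 0.45)), 1e-9)
})

test_that("cropping records offsets that round-trip exactly", {
  ch <- as_channel(matrix(seq(0, 1, length.out = 200 * 200), 200, 200))
  cr <- crop_square(ch, c(99.5, 99.5), 40)
  expect_equal(dim(cr$values), c(80, 80))
  expect_equal(cr$offset, c(60, 60))
  # a marked pixel inside the crop maps back to its absolute coordinate
  expect_equal(cr$values[13, 27], ch$values[60 + 13, 60 + 27])

  # centre near the border: window clipped, offset still exact
  cr2 <- crop_square(ch, c(5, 10), 40)
  expect_equal(cr2$offset, c(0, 0))
  expect_equal(dim(cr2$values), c(80, 80))
  expect_identical(cr2$values, ch$values[1:80, 1:80])

  expect_error(crop_square(ch, c(500, 500), 40), class = "od_crop_error")
})

test_that("Shannon entropy matches closed forms", {
  expect_equal(shannon_entropy(crop_square(as_channel(matrix(0.5, 32, 32)),
                                           c(15, 15), 16)), 0)
  two <- matrix(rep(c(0, 1), each = 512), 32, 32)
  expect_equal(shannon_entropy(crop_square(as_channel(two), c(15, 15), 16)), 1)
  # exactly uniform over the 256 levels
  u <- matrix(rep(0:255, length.out = 4096) / 255, 64, 64)
  expect_equal(shannon_entropy(crop_square(as_channel(u), c(31, 31), 32)), 8)
})

test_that("entropy is a histogram statistic: permutation invariant", {
  set.seed(21)
  v <- matrix(runif(1024), 32, 32)
  p <- matrix(sample(v), 32, 32)
  h1 <- shannon_entropy(crop_square(as_channel(v), c(15, 15), 16))
  h2 <- shannon_entropy(crop_square(as_channel(p), c(15, 15), 16))
  expect_equal(h1, h2)
})

test_that("channel arbitration selects the highest entropy, ties to red", {
  mk <- function(levels) {
    v <- matrix(rep(seq(0, 1, length.out = levels), length.out = 1024), 32, 32)
    crop_square(as_channel(v), c(15, 15), 16)
  }
  rich <- mk(200); mid <- mk(40); poor <- mk(6)
  e1 <- select_channel_by_entropy(list(R = rich, G = mid, B = poor))
  expect_equal(e1$selected_channel, "R")
  expect_gt(e1$H_r, e1$H_g)
  e2 <- select_channel_by_entropy(list(R = poor, G = rich, B = mid))
  expect_equal(e2$selected_channel, "G")
  e3 <- select_channel_by_entropy(list(R = mid, G = mid, B = mid))
  expect_equal(e3$selected_channel, "R")   # tie-break R > G > B
})

test_that("Hough transform recovers noisy synthetic discs", {
  set.seed(17)
  cfg <- od_config(nominal_radius = 30)
  ok <- 0
  for (i in 1:20) {
    r_true <- runif(1, 0.95, 1.3) * 30
    ctr <- c(60, 60) + runif(2, -3, 3)
    ch <- disc_channel(120, 120, ctr, r_true, noise_sd = 0.05 * 0.5)
    cr <- crop_square(ch, c(60, 60), 60)
    cht <- hough_circle(cr, round(0.95 * 30), round(1.3 * 30), cfg)
    if (!cht$failed &&
        sqrt(sum((cht$centre - ctr)^2)) <= 2 &&
        abs(cht$radius - r_true) <= 2) ok <- ok + 1
  }
  expect_gte(ok, 19)
})

test_that("Hough transform fails cleanly on a constant crop", {
  cr <- crop_square(as_channel(matrix(0.5, 120, 120)), c(60, 60), 60)
  cht <- hough_circle(cr, 28, 39)
  expect_true(cht$failed)
  expect_true(is.na(cht$radius))
})

test_that("the higher-contrast disc wins the accumulator", {
  v <- matrix(0.4, 140, 280)
  v <- v + 0.1 * opticdisc:::disc_coverage(140, 280, c(69.5, 69.5), 32)
  v <- v + 0.4 * opticdisc:::disc_coverage(140, 280, c(69.5, 209.5), 32)
  ch <- as_channel(v)
  cr <- structure(list(values = ch$values, inside = matrix(TRUE, 140, 280),
                       offset = c(0, 0), channel = "R"), class = "od_crop")
  cht <- hough_circle(cr, 30, 36)
  expect_lt(sqrt(sum((cht$centre - c(69.5, 209.5))^2)), 3)
})

test_that("radius stays inside the search band unless the fit failed", {
  cfg <- od_config(nominal_radius = 50)
  for (sd in c(3, 8)) {
    ph <- generate_phantom(phantom_spec(seed = sd, red_saturated = sd %% 2 == 0))
    det <- detect_od(ph$image, cfg)
    if (!"cht_failed" %in% det$fallback_flags) {
      expect_gte(det$radius, 0.95 * 50 - 1)
      expect_lte(det$radius, 1.3 * 50 + 1)
    }
  }
})

test_that("end-to-end: unsaturated phantom found in red, saturated not in red", {
  cfg <- od_config(nominal_radius = 50)
  ph_u <- generate_phantom(phantom_spec(seed = 5))
  det_u <- detect_od(ph_u$image, cfg)
  expect_equal(det_u$channel, "R")
  expect_lt(centre_error(ph_u$truth$centre, det_u$centre,
                         ph_u$truth$radius)$delta_C, 0.3)

  ph_s <- generate_phantom(phantom_spec(seed = 5, red_saturated = TRUE))
  det_s <- detect_od(ph_s$image, cfg)
  expect_true(det_s$channel %in% c("G", "B"))
  expect_lt(centre_error(ph_s$truth$centre, det_s$centre,
                         ph_s$truth$radius)$delta_C, 0.5)

  td <- tidy(det_u)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$channel, "R")
  expect_equal(td$centre_row, det_u$centre[1])
})
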