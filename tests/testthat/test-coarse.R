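test_that("disc-scale Gaussian: unit sum, disc-size selectivity", {
  # constant image passes unchanged (unit-sum kernel)
  const <- as_channel(matrix(0.6, 128, 128))
  out <- od_gaussian_blur(const, 32)
  expect_lt(max(abs(out$values - 0.6)), 1e-9)

  # an isolated small blob is attenuated far more than a disc-sized object
  R <- 40
  blob <- matrix(0, 256, 256); blob[126:128, 126:128] <- 1
  disc <- opticdisc:::disc_coverage(256, 256, c(127.5, 127.5), R)
  b_out <- od_gaussian_blur(as_channel(blob), R)
  d_out <- od_gaussian_blur(as_channel(disc), R)
  expect_gte(max(d_out$values), 3 * max(b_out$values))

  expect_error(od_gaussian_blur(as_channel(matrix(0.5, 20, 20)), 64),
               class = "od_kernel_error")
})

test_that("maximum-class mask follows the last threshold strictly", {
  v <- matrix(0, 10, 10); v[6:10, ] <- 1
  ch <- as_channel(v)
  m <- max_class_mask(ch, list(TH = 0L))
  expect_identical(unname(m), unname(v == 1))

  flat <- as_channel(matrix(0.5, 10, 10))
  expect_warning(m2 <- max_class_mask(flat, list(TH = 128L)))
  expect_false(any(m2))
  expect_true(attr(m2, "empty_class"))
})

test_that("multispectral combination obeys its set identities", {
  set.seed(4)
  A <- matrix(runif(100) > 0.5, 10, 10)
  B <- matrix(runif(100) > 0.5, 10, 10)
  none <- matrix(FALSE, 10, 10)
  all_ <- matrix(TRUE, 10, 10)
  expect_identical(combine_masks(A, B, none), A & B)
  expect_identical(combine_masks(all_, A, B), A | B)   # saturated red
  expect_false(any(combine_masks(none, A, B)))
  # monotonicity: output never exceeds the red mask
  for (i in 1:10) {
    R <- matrix(runif(100) > 0.4, 10, 10)
    expect_lte(sum(combine_masks(R, A, B)), sum(R))
  }
})

test_that("roundness closed forms and the rasterised-disc range", {
  expect_equal(od_roundness(1, 4), pi / 4)           # continuous square side 1
  s <- 17
  expect_equal(od_roundness(s^2, 4 * s), pi / 4)
  expect_equal(od_roundness(pi * 9^2, 2 * pi * 9), 1)  # continuous circle
  expect_equal(od_roundness(1, 0), 1)                  # single pixel convention

  disc <- rasterise_circle(64, 64, c(31.5, 31.5), 20)
  obj <- binary_objects(opticdisc:::label8(disc))
  expect_equal(nrow(obj), 1L)
  expect_gte(obj$roundness, 0.85)
  expect_lte(obj$roundness, 1.1)
  expect_equal(obj$equivalent_radius, sqrt(obj$area / pi))
})

test_that("candidate selection prefers the nominal-radius object", {
  obj <- function(r, round, area = pi * r^2) {
    tibble::tibble(label = NA_integer_, area = area, perimeter = 1,
                   centroid_row = 0, centroid_col = 0,
                   equivalent_radius = r, roundness = round)
  }
  objs <- dplyr::bind_rows(obj(50, 0.9), obj(100, 0.9))
  objs$label <- 1:2
  sel <- select_od_candidate(objs, 50)
  expect_equal(sel$object$equivalent_radius, 50)
  expect_equal(sel$fallback_path, "none")

  lone <- obj(30, 0.3); lone$label <- 1L
  sel2 <- select_od_candidate(lone, 50)
  expect_equal(sel2$fallback_path, "radius_only")

  three <- dplyr::bind_rows(obj(25, 0.7), obj(55, 0.8), obj(150, 0.9))
  three$label <- 1:3
  expect_equal(select_od_candidate(three, 50)$object$equivalent_radius, 55)

  # a notched disc-sized object below the roundness gate beats a small round
  # distractor that is far from the nominal radius
  mix <- dplyr::bind_rows(obj(12, 0.95), obj(42, 0.5))
  mix$label <- 1:2
  sel3 <- select_od_candidate(mix, 50)
  expect_equal(sel3$object$equivalent_radius, 42)
  expect_equal(sel3$fallback_path, "radius_only")

  expect_error(select_od_candidate(obj(1, 1)[0, ], 50), class = "od_roi_error")
})

test_that("coarse localisation lands inside the disc on phantoms", {
  cfg <- od_config(nominal_radius = 50)
  for (sat in c(FALSE, TRUE)) {
    ph <- generate_phantom(phantom_spec(seed = 31, red_saturated = sat))
    fov <- od_fov_mask(ph$image, "R")
    roi <- locate_roi(ph$image, fov, cfg)
    err <- sqrt(sum((roi$centroid - ph$truth$centre)^2))
    expect_lt(err, 0.5 * roi$R_a_work)
    expect_true(fov$mask[round(roi$centroid[1]) + 1, round(roi$centroid[2]) + 1])
  }
})

test_that("a featureless image yields no region of interest", {
  img <- od_image(array(120L, c(64, 64, 3)))
  fov <- full_fov(64, 64)
  expect_error(locate_roi(img, fov, od_config(nominal_radius = 40)),
               class = "od_roi_error")
})

test_that("coarse masks are invariant to a class-preserving intensity shift", {
  cfg <- od_config(nominal_radius = 50)
  ph <- generate_phantom(phantom_spec(seed = 13))
  fov <- od_fov_mask(ph$image, "R")
  # a global +8 shift (clipping-free after capping) is injective on the 256
  # levels, so the dynamic-range normalisation cancels it exactly
  px <- array(pmin(ph$image$pixels, 247L), dim(ph$image$pixels))
  roi1 <- locate_roi(od_image(px), fov, cfg)
  roi2 <- locate_roi(od_image(px + 8L), fov, cfg)
  expect_equal(roi1$centroid, roi2$centroid, tolerance = 1e-9)
  expect_identical(roi1$bw_out, roi2$bw_out)
})
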