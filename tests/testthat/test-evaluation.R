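test_that("equivalent radius closed forms", {
  expect_equal(equivalent_radius(pi), 1)
  expect_equal(equivalent_radius(0), 0)
  expect_equal(equivalent_radius(10000), 56.419, tolerance = 1e-3 / 56)
  expect_error(equivalent_radius(-1), class = "od_metric_error")
})

test_that("normalised centre error and the misdetection boundary", {
  e0 <- centre_error(c(10, 20), c(10, 20), 30)
  expect_equal(e0$delta_C, 0); expect_false(e0$misdetected)
  e1 <- centre_error(c(0, 0), c(3, 4), 10)
  expect_equal(e1$delta_C, 0.5); expect_false(e1$misdetected)
  e2 <- centre_error(c(0, 0), c(0, 12), 10)
  expect_equal(e2$delta_C, 1.2); expect_true(e2$misdetected)
  # the boundary itself counts as misdetection
  expect_true(centre_error(c(0, 0), c(0, 10), 10)$misdetected)
  expect_error(centre_error(c(0, 0), c(1, 1), 0), class = "od_metric_error")
})

test_that("segmentation metrics reproduce the worked contingency values", {
  A <- matrix(FALSE, 20, 50)
  A[2:6, 2:21] <- TRUE                      # |GT| = 100
  m <- segmentation_metrics(A, A)
  expect_equal(unlist(m), c(TPR = 1, FPR = 0, Ac = 1, overlap_pct = 100, dice = 1))

  B <- matrix(FALSE, 20, 50)
  B[10:14, 30:49] <- TRUE                   # disjoint, |MS| = 100
  d <- segmentation_metrics(A, B)
  expect_equal(d$TPR, 0); expect_equal(d$overlap_pct, 0); expect_equal(d$dice, 0)

  C <- matrix(FALSE, 20, 50)
  C[2:6, 12:31] <- TRUE                     # |MS| = 100, |GT & MS| = 50
  w <- segmentation_metrics(A, C)
  expect_equal(w$dice, 0.5)
  expect_equal(w$overlap_pct, 100 * 50 / 150)
  expect_equal(w$TPR, 0.5)
  expect_equal(w$FPR, 50 / 900)
  expect_equal(w$Ac, (50 + 850) / 1000)

  expect_error(segmentation_metrics(matrix(FALSE, 5, 5), matrix(TRUE, 5, 5)),
               class = "od_metric_error")
})

test_that("Dice and Jaccard satisfy their algebraic identity", {
  set.seed(33)
  for (i in 1:30) {
    A <- matrix(runif(900) > 0.6, 30, 30)
    B <- matrix(runif(900) > 0.6, 30, 30)
    if (!any(A)) next
    m <- segmentation_metrics(A, B)
    J <- m$overlap_pct / 100
    expect_gte(m$dice + 1e-12, J)
    expect_equal(m$dice, 2 * J / (1 + J), tolerance = 1e-12)
  }
})

# build masks over a 1 x n strip realising prescribed discordant counts
masks_with_bc <- function(b, c_, n_extra = 10) {
  n <- b + c_ + n_extra
  gt <- matrix(TRUE, 1, n)
  m1 <- gt; m2 <- gt
  if (b > 0) m2[1, seq_len(b)] <- FALSE             # model 1 right, model 2 wrong
  if (c_ > 0) m1[1, b + seq_len(c_)] <- FALSE       # model 1 wrong, model 2 right
  list(gt = gt, m1 = m1, m2 = m2)
}

test_that("mid-p McNemar worked examples", {
  x <- masks_with_bc(0, 0)
  r <- mcnemar_midp(x$gt, x$m1, x$m2)
  expect_equal(r$b, 0); expect_equal(r$c, 0)
  expect_equal(r$midp, 1); expect_equal(r$h, 0L)
  expect_true(r$no_discordance)

  r2 <- mcnemar_midp(masks_with_bc(5, 5)$gt, masks_with_bc(5, 5)$m1,
                     masks_with_bc(5, 5)$m2)
  expect_equal(r2$midp, 1)

  x3 <- masks_with_bc(1, 9)
  r3 <- mcnemar_midp(x3$gt, x3$m1, x3$m2)
  expect_equal(r3$midp, 2 * (11 / 1024 - 5 / 1024), tolerance = 1e-12)
  expect_equal(r3$h, 1L)
  expect_equal(r3$e_1, 9 / 20)
  expect_equal(r3$e_2, 1 / 20)
})

test_that("mid-p McNemar is symmetric and matches direct enumeration", {
  enum_midp <- function(b, c_) {
    n <- b + c_
    if (n == 0) return(1)
    m <- min(b, c_)
    pmf <- choose(n, 0:n) / 2^n
    min(1, 2 * (sum(pmf[seq_len(m + 1)]) - pmf[m + 1] / 2))
  }
  for (b in c(0, 1, 3, 7, 12)) {
    for (c_ in c(0, 2, 5, 11)) {
      x <- masks_with_bc(b, c_)
      r <- mcnemar_midp(x$gt, x$m1, x$m2)
      expect_equal(r$midp, enum_midp(b, c_), tolerance = 1e-12)
      swapped <- mcnemar_midp(x$gt, x$m2, x$m1)
      expect_equal(swapped$midp, r$midp)
      expect_equal(swapped$h, r$h)
      expect_equal(swapped$e_1, r$e_2)
      expect_equal(swapped$e_2, r$e_1)
    }
  }
})

test_that("ground-truth records derive centroid and radius from masks", {
  mk <- rasterise_circle(100, 100, c(49.5, 49.5), 20)
  tr <- od_truth(mask = mk, image_id = "a")
  expect_equal(tr$centre, c(49.5, 49.5), tolerance = 0.01)
  expect_equal(tr$radius, equivalent_radius(sum(mk)))
  expect_error(od_truth(), class = "od_metric_error")
  expect_error(od_truth(centre = c(1, 1)), class = "od_metric_error")
})

test_that("dataset evaluation aggregates exactly like an independent loop", {
  set.seed(55)
  truths <- list(); dets <- list()
  for (i in 1:6) {
    ctr <- c(runif(1, 60, 120), runif(1, 60, 120))
    truths[[i]] <- od_truth(centre = ctr,
                            mask = rasterise_circle(200, 200, ctr, 30),
                            radius = 30, image_id = paste0("img", i))
    off <- if (i == 1) c(45, 0) else c(runif(1, -3, 3), runif(1, -3, 3))
    dets[[i]] <- tibble::tibble(
      image_id = paste0("img", i),
      centre_row = ctr[1] + off[1], centre_col = ctr[2] + off[2],
      radius = 30 + runif(1, -2, 2), scale_factor = 1, channel = "R",
      H_r = 7, H_g = 6, H_b = 5, fallback_flags = "")
  }
  det_tbl <- dplyr::bind_rows(dets)
  ev <- evaluate_dataset(det_tbl, truths)
  expect_equal(nrow(ev), 6)
  expect_equal(sum(ev$misdetected), 1)         # img1 is 45 px = 1.5 radii off
  g <- glance(ev)
  expect_equal(g$misdetection_rate_pct, 100 / 6)
  expect_equal(g$N_R, 6)
  # independent per-image recomputation
  for (i in 1:6) {
    ce <- centre_error(truths[[i]]$centre,
                       c(det_tbl$centre_row[i], det_tbl$centre_col[i]), 30)
    expect_equal(ev$delta_C[ev$image_id == paste0("img", i)], ce$delta_C)
  }
  expect_equal(g$dice_mean, mean(ev$dice[!ev$misdetected]))
})

test_that("perfect detections give a perfect summary", {
  truths <- list(); dets <- list()
  for (i in 1:3) {
    ctr <- c(50 + 10 * i, 80)
    truths[[i]] <- od_truth(centre = ctr,
                            mask = rasterise_circle(160, 160, ctr, 25),
                            image_id = paste0("p", i))
    dets[[i]] <- tibble::tibble(
      image_id = paste0("p", i), centre_row = ctr[1], centre_col = ctr[2],
      radius = truths[[i]]$radius, scale_factor = 1, channel = "G",
      H_r = 1, H_g = 2, H_b = 1, fallback_flags = "")
  }
  ev <- evaluate_dataset(dplyr::bind_rows(dets), truths)
  g <- glance(ev)
  expect_equal(g$misdetection_rate_pct, 0)
  expect_gte(g$dice_mean, 0.99)
  expect_equal(g$delta_C_median, 0)
})

test_that("unmatched image ids are reported, not dropped silently", {
  tr <- list(od_truth(centre = c(10, 10), radius = 5, image_id = "x"))
  det <- tibble::tibble(image_id = "y", centre_row = 1, centre_col = 1,
                        radius = 5, scale_factor = 1, channel = "R",
                        H_r = 1, H_g = 1, H_b = 1, fallback_flags = "")
  expect_warning(ev <- evaluate_dataset(det, tr), "unmatched")
  expect_equal(nrow(ev), 0)
  expect_setequal(attr(ev, "unmatched"), c("x", "y"))
})
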