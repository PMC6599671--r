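#' Equivalent radius of an area
#'
#' Radius of the circle with the same area: `sqrt(area / pi)`.  Used to
#' compare a free-form expert-marked disc with the necessarily circular
#' detection.
#'
#' @param area Area in pixels (>= 0).
#' @return Radius in pixels.
#' @export
equivalent_radius <- function(area) {
  if (any(area < 0)) abort("area must be non-negative", class = "od_metric_error")
  sqrt(area / pi)
}

#' Normalised centre localisation error
#'
#' `delta_C = |C_m - C_a| / R_m`: the Euclidean distance between the marked
#' and detected centres, normalised by the equivalent radius of the marked
#' disc.  `delta_C >= 1` places the detected centre outside the marked disc
#' and counts as a misdetection.
#'
#' @param C_m Ground-truth centre, `(row, col)`.
#' @param C_a Detected centre, `(row, col)`.
#' @param R_m Equivalent radius of the marked disc (> 0).
#' @return List with `delta_C` and logical `misdetected`.
#' @export
centre_error <- function(C_m, C_a, R_m) {
  if (R_m <= 0) abort("R_m must be positive", class = "od_metric_error")
  d <- sqrt(sum((as.numeric(C_m) - as.numeric(C_a))^2)) / R_m
  list(delta_C = d, misdetected = d >= 1)
}

#' Rasterise a circle into a binary mask
#'
#' A pixel belongs to the circle iff its (0-based) centre lies at Euclidean
#' distance <= `radius` from `centre`.
#'
#' @param H,W Mask dimensions.
#' @param centre 0-based `(row, col)`.
#' @param radius Pixels.
#' @return Logical `H x W` matrix.
#' @export
rasterise_circle <- function(H, W, centre, radius) {
  circle_mask(H, W, centre, radius)
}

#' Pixelwise segmentation metrics
#'
#' Contingency metrics of a predicted mask against ground truth: true
#' positive rate `TP / |GT|`, false positive rate `FP / |non-GT|`, accuracy
#' `(TP + TN) / total`, percentage overlap (Jaccard)
#' `100 |GT & MS| / |GT | MS|` and the Dice index
#' `2 |GT & MS| / (|GT| + |MS|)`.
#'
#' @param gt_mask,pred_mask Logical matrices of equal shape; `gt_mask` must
#'   be nonempty.
#' @return One-row tibble: `TPR`, `FPR`, `Ac`, `overlap_pct`, `dice`.
#' @export
segmentation_metrics <- function(gt_mask, pred_mask) {
  stopifnot(all(dim(gt_mask) == dim(pred_mask)))
  gt <- as.logical(gt_mask); ms <- as.logical(pred_mask)
  if (!any(gt)) abort("empty ground-truth mask: TPR undefined",
                      class = "od_metric_error")
  tp <- sum(gt & ms); fp <- sum(!gt & ms)
  tn <- sum(!gt & !ms)
  npos <- sum(gt); nneg <- length(gt) - npos
  uni <- sum(gt | ms)
  tibble(
    TPR = tp / npos,
    FPR = if (nneg > 0) fp / nneg else 0,
    Ac = (tp + tn) / length(gt),
    overlap_pct = if (uni > 0) 100 * tp / uni else 0,
    dice = if (npos + sum(ms) > 0) 2 * tp / (npos + sum(ms)) else 0
  )
}

#' Mid-p McNemar comparison of two segmentations
#'
#' Compares two predicted masks against the same ground truth by classifying
#' every pixel as correct or wrong under each model.  With `b` pixels wrong
#' only under model 2 and `c` wrong only under model 1 (discordant pairs),
#' the mid-p value under `X ~ Binomial(b + c, 1/2)` is
#' `min(1, 2 * (P(X <= min(b, c)) - P(X = min(b, c)) / 2))`; `h = 1` rejects
#' equal accuracy at the 5% level.  Misclassification rates `e_1`, `e_2` are
#' each model's wrong-pixel fraction.
#'
#' @param gt_mask Ground-truth logical matrix.
#' @param mask_1,mask_2 Predicted masks (model 1 and model 2).
#' @return List: `b`, `c`, `midp`, `h`, `e_1`, `e_2`, `no_discordance`.
#' @export
mcnemar_midp <- function(gt_mask, mask_1, mask_2) {
  stopifnot(all(dim(gt_mask) == dim(mask_1)),
            all(dim(gt_mask) == dim(mask_2)))
  gt <- as.logical(gt_mask)
  ok1 <- as.logical(mask_1) == gt
  ok2 <- as.logical(mask_2) == gt
  b <- sum(ok1 & !ok2)
  c_ <- sum(!ok1 & ok2)
  n <- b + c_
  if (n == 0L) {
    midp <- 1
  } else {
    m <- min(b, c_)
    midp <- min(1, 2 * (pbinom(m, n, 0.5) - 0.5 * dbinom(m, n, 0.5)))
  }
  list(b = b, c = c_, midp = midp, h = as.integer(midp < 0.05),
       e_1 = sum(!ok1) / length(gt), e_2 = sum(!ok2) / length(gt),
       no_discordance = n == 0L)
}

#' Ground-truth record for one image
#'
#' Either a hand-marked centre (with the dataset's a-priori radius) or a
#' binary mask (from which the centroid and equivalent radius are derived).
#'
#' @param centre 0-based `(row, col)`, or NULL when a mask is given.
#' @param mask Logical matrix, or NULL when a centre is given.
#' @param radius Equivalent radius `R_m`; mandatory with a centre, derived
#'   from the mask area otherwise.
#' @param image_id Identifier.
#' @return An `od_truth` object.
#' @export
od_truth <- function(centre = NULL, mask = NULL, radius = NULL,
                     image_id = "image") {
  if (is.null(centre) && is.null(mask)) {
    abort("ground truth needs a centre or a mask", class = "od_metric_error")
  }
  if (!is.null(mask)) {
    mask <- mask != 0
    if (!any(mask)) abort("empty ground-truth mask", class = "od_metric_error")
    ij <- which(mask, arr.ind = TRUE) - 1
    if (is.null(centre)) centre <- unname(colMeans(ij))
    if (is.null(radius)) radius <- equivalent_radius(sum(mask))
  }
  if (is.null(radius) || radius <= 0) {
    abort("ground truth needs a positive radius R_m", class = "od_metric_error")
  }
  structure(list(centre = as.numeric(centre), mask = mask,
                 radius = as.numeric(radius),
                 image_id = as.character(image_id)),
            class = "od_truth")
}

#' Evaluate a set of detections against ground truth
#'
#' Produces one evaluation record per image — normalised centre error,
#' misdetection flag, and (when the image geometry is known) the mask
#' metrics of the rasterised detected circle against the ground-truth disc —
#' plus a dataset summary available via [glance()].
#'
#' @param detections List of `od_circle` objects (or a tibble from
#'   [tidy()]-ed detections with the same columns).
#' @param truths List of `od_truth` objects; matched to detections by
#'   `image_id`.
#' @param dim Image dimensions `(H, W)` used to rasterise detections for the
#'   delineation metrics; when NULL and a ground-truth mask is present, the
#'   mask's dimensions are used, otherwise the delineation metrics are NA.
#' @return A tibble of class `od_evaluation` with one row per matched image;
#'   unmatched ids are reported via the `unmatched` attribute and a warning.
#' @export
evaluate_dataset <- function(detections, truths, dim = NULL) {
  det_tbl <- if (inherits(detections, "data.frame")) {
    as_tibble(detections)
  } else {
    dplyr::bind_rows(lapply(detections, tidy))
  }
  truth_ids <- vapply(truths, function(t) t$image_id, character(1))
  unmatched <- c(setdiff(det_tbl$image_id, truth_ids),
                 setdiff(truth_ids, det_tbl$image_id))
  if (length(unmatched)) {
    warning(sprintf("unmatched image ids: %s",
                    paste(unique(unmatched), collapse = ", ")), call. = FALSE)
  }
  ids <- intersect(det_tbl$image_id, truth_ids)
  rows <- lapply(ids, function(id) {
    d <- det_tbl[det_tbl$image_id == id, , drop = FALSE][1L, ]
    tr <- truths[[match(id, truth_ids)]]
    ce <- centre_error(tr$centre, c(d$centre_row, d$centre_col), tr$radius)
    seg <- NULL
    gm <- tr$mask
    dd <- if (!is.null(dim)) dim else if (!is.null(gm)) base::dim(gm) else NULL
    if (!is.null(dd)) {
      if (is.null(gm)) gm <- rasterise_circle(dd[1], dd[2], tr$centre, tr$radius)
      pm <- rasterise_circle(dd[1], dd[2], c(d$centre_row, d$centre_col), d$radius)
      seg <- segmentation_metrics(gm, pm)
    } else {
      seg <- tibble(TPR = NA_real_, FPR = NA_real_, Ac = NA_real_,
                    overlap_pct = NA_real_, dice = NA_real_)
    }
    dplyr::bind_cols(
      tibble(image_id = id, delta_C = ce$delta_C,
             misdetected = ce$misdetected, channel = d$channel,
             fallback_flags = d$fallback_flags),
      seg
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("od_evaluation", class(out))
  attr(out, "unmatched") <- unmatched
  out
}

#' Summarise an evaluation table
#'
#' @param x An `od_evaluation` tibble.
#' @param ... Unused.
#' @return One-row tibble: number of images, misdetection count and rate (%),
#'   channel-usage counts `N_R`/`N_G`/`N_B`, median `delta_C` with quartiles
#'   over non-misdetected images, and mean delineation metrics over
#'   non-misdetected images.
#' @exportS3Method generics::glance
glance.od_evaluation <- function(x, ...) {
  ok <- !x$misdetected
  q <- quantile(x$delta_C[ok], c(0.25, 0.5, 0.75), names = FALSE, na.rm = TRUE)
  tibble(
    n = nrow(x),
    n_misdetected = sum(x$misdetected),
    misdetection_rate_pct = 100 * mean(x$misdetected),
    N_R = sum(x$channel == "R"), N_G = sum(x$channel == "G"),
    N_B = sum(x$channel == "B"),
    delta_C_median = q[2], delta_C_q25 = q[1], delta_C_q75 = q[3],
    TPR_mean = mean(x$TPR[ok]), FPR_mean = mean(x$FPR[ok]),
    Ac_mean = mean(x$Ac[ok]), overlap_pct_mean = mean(x$overlap_pct[ok]),
    dice_mean = mean(x$dice[ok])
  )
}
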