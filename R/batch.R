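#' Detect the optic disc in every image of a directory
#'
#' Runs [detect_od()] over all PNG/TIFF/JPEG files in `input_dir`.  Per-image
#' failures are logged in the manifest and flagged, never aborting the batch.
#'
#' @param input_dir Directory of images.
#' @param config An [od_config].
#' @param output Optional path for the detection CSV (columns `image_id`,
#'   `centre_row`, `centre_col`, `radius`, `scale_factor`, `channel`, `H_r`,
#'   `H_g`, `H_b`, `fallback_flags`).
#' @return A tibble of detections with a `manifest` attribute (tibble:
#'   `image_id`, `path`, `status` ok/fallback/error, `message`, `elapsed`
#'   seconds) and an `exit_status` attribute (0 all ok, 1 partial failures,
#'   2 nothing processed).
#' @export
od_detect_dir <- function(input_dir, config, output = NULL) {
  stopifnot(inherits(config, "od_config"))
  paths <- sort(list.files(input_dir, full.names = TRUE,
                           pattern = "\\.(png|tif|tiff|jpg|jpeg)$",
                           ignore.case = TRUE))
  if (length(paths) == 0L) {
    abort(sprintf("no readable images in '%s'", input_dir),
          class = "od_io_error")
  }
  rows <- list(); man <- list()
  for (p in paths) {
    id <- sub("\\.[^.]+$", "", basename(p))
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch({
      det <- detect_od(od_read_image(p), config)
      rows[[id]] <- tidy(det)
      list(status = if (length(det$fallback_flags)) "fallback" else "ok",
           message = paste(det$fallback_flags, collapse = ";"))
    }, error = function(e) list(status = "error",
                                message = conditionMessage(e)))
    man[[id]] <- tibble(image_id = id, path = p, status = res$status,
                        message = res$message,
                        elapsed = proc.time()[["elapsed"]] - t0)
  }
  detections <- dplyr::bind_rows(rows)
  manifest <- dplyr::bind_rows(man)
  if (!is.null(output)) {
    write.csv(detections, output, row.names = FALSE)
  }
  attr(detections, "manifest") <- manifest
  attr(detections, "exit_status") <-
    if (nrow(detections) == 0L) 2L
    else if (any(manifest$status == "error")) 1L else 0L
  detections
}

#' Evaluate a detection table against ground truth on disk
#'
#' Ground truth is read from `gt_dir`: a `gt_centres.csv` with columns
#' `image_id,row,col` (and optionally `radius`), and/or per-image mask
#' rasters named `<image_id>_mask.png`.  Masks take precedence (centroid and
#' equivalent radius are derived from them); otherwise the CSV radius, or the
#' `default_radius`, normalises the centre error.
#'
#' @param detections Tibble from [od_detect_dir()] (or a CSV path).
#' @param gt_dir Ground-truth directory.
#' @param default_radius Fallback `R_m` when no mask and no per-image radius
#'   is available (the dataset's a-priori nominal radius).
#' @param output_csv,output_json Optional paths for the per-image metrics CSV
#'   and the JSON summary.
#' @return An `od_evaluation` tibble (see [evaluate_dataset()]).
#' @export
od_evaluate_files <- function(detections, gt_dir, default_radius = NULL,
                              output_csv = NULL, output_json = NULL) {
  if (is.character(detections)) {
    detections <- as_tibble(read.csv(detections))
  }
  csv <- file.path(gt_dir, "gt_centres.csv")
  centres <- if (file.exists(csv)) read.csv(csv) else NULL
  masks <- list.files(gt_dir, pattern = "_mask\\.(png|tif|tiff)$",
                      recursive = TRUE, full.names = TRUE)
  if (is.null(centres) && length(masks) == 0L) {
    abort(sprintf("no ground truth in '%s': expected gt_centres.csv or *_mask.png",
                  gt_dir), class = "od_io_error")
  }
  truth_ids <- unique(c(centres$image_id,
                        sub("_mask\\.[^.]+$", "", basename(masks))))
  truths <- lapply(truth_ids, function(id) {
    mp <- masks[sub("_mask\\.[^.]+$", "", basename(masks)) == id]
    mask <- NULL
    if (length(mp)) {
      a <- as.array(EBImage::readImage(mp[1]))
      if (length(dim(a)) == 3L) a <- a[, , 1]
      mask <- t(a) > 0.5
    }
    ctr <- NULL; rad <- NULL
    if (!is.null(centres) && id %in% centres$image_id) {
      rr <- centres[centres$image_id == id, , drop = FALSE][1, ]
      ctr <- c(rr$row, rr$col)
      if ("radius" %in% names(rr) && is.finite(rr$radius)) rad <- rr$radius
    }
    if (is.null(rad) && is.null(mask)) rad <- default_radius
    od_truth(centre = ctr, mask = mask, radius = rad, image_id = id)
  })
  ev <- evaluate_dataset(detections, truths)
  if (!is.null(output_csv)) write.csv(ev, output_csv, row.names = FALSE)
  if (!is.null(output_json)) {
    jsonlite::write_json(as.list(glance(ev)), output_json,
                         auto_unbox = TRUE, digits = NA)
  }
  ev
}

#' Write a phantom dataset to disk
#'
#' Renders a seeded phantom batch into the layout [od_evaluate_files()]
#' reads: `images/<id>.png`, `masks/<id>_mask.png`, `gt_centres.csv` and a
#' JSON spec per image under `specs/`.
#'
#' @param n Number of phantoms.
#' @param seed Master seed.
#' @param output_dir Output directory (created if needed).
#' @param ... Passed to [generate_batch()].
#' @return The ground-truth tibble, invisibly.
#' @export
od_phantom_dataset <- function(n, seed, output_dir, ...) {
  batch <- generate_batch(n, master_seed = seed, ...)
  dir.create(file.path(output_dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(output_dir, "masks"), showWarnings = FALSE)
  dir.create(file.path(output_dir, "specs"), showWarnings = FALSE)
  gt <- lapply(batch, function(ph) {
    id <- ph$image$image_id
    od_write_image(ph$image, file.path(output_dir, "images",
                                       paste0(id, ".png")))
    od_write_image(ph$truth$mask, file.path(output_dir, "masks",
                                            paste0(id, "_mask.png")))
    jsonlite::write_json(
      c(ph$spec[!vapply(ph$spec, is.matrix, logical(1))],
        list(regime = ph$regime)),
      file.path(output_dir, "specs", paste0(id, ".json")),
      auto_unbox = TRUE, digits = NA)
    tibble(image_id = id, row = ph$truth$centre[1], col = ph$truth$centre[2],
           radius = ph$truth$radius, regime = ph$regime)
  })
  gt <- dplyr::bind_rows(gt)
  write.csv(gt, file.path(output_dir, "gt_centres.csv"), row.names = FALSE)
  invisible(gt)
}
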