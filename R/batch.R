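# Batch execution over image sets with a deterministic parallel contract:
# every image derives its RNG seed from the job seed and its own file
# name, so outputs are bit-identical whether the batch runs sequentially
# or on several workers, and regardless of scheduling order.

#' Define a batch job
#'
#' @param images character vector of input image paths.
#' @param kind `"ctmode"`, `"fire"` or `"both"`.
#' @param out_dir output directory (created if needed).
#' @param fire_config a [fire_config()].
#' @param ct_config a [ct_config()].
#' @param boundary_dir optional directory of boundary masks following the
#'   `<basename>_mask.tif` convention.
#' @param roi_file optional JSON ROI file applied to every image.
#' @param jobs worker count (1 = sequential).
#' @param seed job seed.
#' @param write_overlays logical; write overlay/reconstruction TIFFs.
#' @return an object of class `batch_job`.
#' @export
batch_job <- function(images, kind = c("both", "ctmode", "fire"),
                      out_dir, fire_config = fibretrace::fire_config(),
                      ct_config = fibretrace::ct_config(),
                      boundary_dir = NULL, roi_file = NULL,
                      jobs = 1L, seed = 1L, write_overlays = FALSE) {
  kind <- match.arg(kind)
  structure(list(images = images, kind = kind, out_dir = out_dir,
                 fire_config = fire_config, ct_config = ct_config,
                 boundary_dir = boundary_dir, roi_file = roi_file,
                 jobs = as.integer(jobs), seed = as.integer(seed),
                 write_overlays = isTRUE(write_overlays)),
            class = "batch_job")
}

# Analyze one image; returns NULL on success, an error message on failure.
.batch_one <- function(path, job) {
  base <- sub("\\.[^.]+$", "", basename(path))
  img <- read_gray_tiff(path)
  img_seed <- stable_seed(job$seed, basename(path))
  boundary <- NULL
  if (!is.null(job$boundary_dir)) {
    bp <- find_boundary_for(path, job$boundary_dir)
    if (!is.null(bp)) boundary <- load_boundary_mask(bp)
  }
  rois <- if (!is.null(job$roi_file)) load_rois(job$roi_file) else NULL

  if (job$kind %in% c("fire", "both")) {
    fc <- job$fire_config
    fc$seed <- img_seed
    res <- extract_fibers(img, fc)
    dir_f <- file.path(job$out_dir, "ctfire")
    if (!dir.exists(dir_f)) dir.create(dir_f, recursive = TRUE)
    utils::write.csv(res$fibers,
                     file.path(dir_f, paste0(base, "_fibers.csv")),
                     row.names = FALSE)
    utils::write.csv(res$vertices,
                     file.path(dir_f, paste0(base, "_vertices.csv")),
                     row.names = FALSE)
    s <- circular_summary(res$fibers$angle_deg, res$fibers$length)
    utils::write.csv(as.data.frame(s),
                     file.path(dir_f, paste0(base, "_stats.csv")),
                     row.names = FALSE)
    if (job$write_overlays) {
      ov <- render_overlay(img, res$vertices, boundary = boundary,
                           rois = rois)
      write_overlay_tiff(ov, file.path(dir_f, paste0(base, "_overlay.tif")))
    }
  }
  if (job$kind %in% c("ctmode", "both")) {
    res <- analyze_ct(img, job$ct_config, boundary = boundary, rois = rois)
    dir_c <- file.path(job$out_dir, "curvealign")
    if (!dir.exists(dir_c)) dir.create(dir_c, recursive = TRUE)
    utils::write.csv(res$features,
                     file.path(dir_c, paste0(base, "_features.csv")),
                     row.names = FALSE)
    vals <- data.frame(group = res$groups$group,
                       angle_deg = res$groups$angle_deg,
                       magnitude = res$groups$magnitude)
    utils::write.csv(vals, file.path(dir_c, paste0(base, "_values.csv")),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(res$summary),
                     file.path(dir_c, paste0(base, "_stats.csv")),
                     row.names = FALSE)
    utils::write.csv(angle_histogram(res$groups$angle_deg),
                     file.path(dir_c, paste0(base, "_histogram.csv")),
                     row.names = FALSE)
    utils::write.csv(angle_histogram(res$groups$angle_deg, bin_width = 15),
                     file.path(dir_c, paste0(base, "_compass.csv")),
                     row.names = FALSE)
    if (job$write_overlays) {
      ov <- render_overlay(img, res$groups, boundary = boundary,
                           rois = rois)
      write_overlay_tiff(ov, file.path(dir_c, paste0(base, "_overlay.tif")))
      recon <- ifdct(res$pyramid)
      write_gray_tiff(recon, file.path(dir_c, paste0(base, "_recon.tif")),
                      bits = 32)
      amap <- local_alignment_map(res$groups, dim(img),
                                  job$ct_config$heatmap_square_px)
      write_gray_tiff(amap * 255,
                      file.path(dir_c, paste0(base, "_alignmap.tif")))
    }
  }
  NULL
}

#' Run a batch job
#'
#' Processes every image of the job, writing per-image CSV (and optional
#' TIFF) outputs, then combines them with [combine_outputs()]. A failing
#' image is logged and skipped; it does not abort the batch. Outputs are
#' identical for any worker count.
#'
#' @param job a [batch_job()].
#' @return list with `failures` (named character vector of error
#'   messages, empty on full success) and `combined` (the combined
#'   outputs), invisibly.
#' @export
run_batch <- function(job) {
  if (!dir.exists(job$out_dir)) dir.create(job$out_dir, recursive = TRUE)
  log_file <- file.path(job$out_dir, "run_log.txt")
  cat(sprintf("fibretrace batch | kind=%s | %d images | jobs=%d | seed=%d\n",
              job$kind, length(job$images), job$jobs, job$seed),
      file = log_file)
  worker <- function(path) {
    tryCatch({ .batch_one(path, job); NA_character_ },
             error = function(e) conditionMessage(e))
  }
  msgs <- if (job$jobs > 1) {
    unlist(parallel::mclapply(job$images, worker, mc.cores = job$jobs))
  } else {
    vapply(job$images, worker, character(1))
  }
  names(msgs) <- basename(job$images)
  failures <- msgs[!is.na(msgs)]
  for (nm in names(failures)) {
    cat(sprintf("FAILED %s: %s\n", nm, failures[nm]),
        file = log_file, append = TRUE)
  }
  combined <- list()
  fire_dir <- file.path(job$out_dir, "ctfire")
  ct_dir <- file.path(job$out_dir, "curvealign")
  if (dir.exists(fire_dir)) {
    combined$fire <- combine_outputs(fire_dir)
    utils::write.csv(combined$fire$combined,
                     file.path(job$out_dir, "combined_fibers.csv"),
                     row.names = FALSE)
    utils::write.csv(combined$fire$summary,
                     file.path(job$out_dir, "combined_fiber_summary.csv"),
                     row.names = FALSE)
  }
  if (dir.exists(ct_dir)) {
    combined$ct <- combine_outputs(ct_dir, pattern = "_features\\.csv$")
    utils::write.csv(combined$ct$combined,
                     file.path(job$out_dir, "combined_features.csv"),
                     row.names = FALSE)
    utils::write.csv(combined$ct$summary,
                     file.path(job$out_dir, "combined_feature_summary.csv"),
                     row.names = FALSE)
  }
  cat("done\n", file = log_file, append = TRUE)
  invisible(list(failures = failures, combined = combined))
}
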