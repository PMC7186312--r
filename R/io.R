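# Image and table I/O, overlay rendering.

#' Read a grayscale TIFF image
#'
#' Returns the image as a numeric matrix on its native intensity scale
#' (0-255 for 8-bit, 0-65535 for 16-bit, as stored for float). If the
#' file has multiple channels, the first channel is used and a warning is
#' logged.
#'
#' @param path TIFF file path.
#' @return numeric matrix.
#' @export
read_gray_tiff <- function(path) {
  img <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(img)) == 3) {
    warning("multichannel TIFF: using the first channel of ", path)
    img <- img[, , 1]
  }
  storage.mode(img) <- "double"
  img
}

#' Write a grayscale TIFF image
#'
#' @param image numeric matrix. For `bits = 8` or `16`, values are taken
#'   on the 0-255 / 0-65535 scale and clipped; `bits = 32` writes
#'   floating point values rescaled to `[0, 1]` by `max(image)`.
#' @param path output file path.
#' @param bits 8, 16 or 32.
#' @return the path, invisibly.
#' @export
write_gray_tiff <- function(image, path, bits = 8) {
  if (bits == 8) {
    tiff::writeTIFF(clamp(image, 0, 255) / 255, path, bits.per.sample = 8)
  } else if (bits == 16) {
    tiff::writeTIFF(clamp(image, 0, 65535) / 65535, path,
                    bits.per.sample = 16)
  } else {
    mx <- max(image, 1e-12)
    tiff::writeTIFF(clamp(image / mx, 0, 1), path, bits.per.sample = 32)
  }
  invisible(path)
}

# Draw a pixel chain into an RGB array, in place.
.draw_pixels <- function(rgb, pts, color) {
  n1 <- dim(rgb)[1]; n2 <- dim(rgb)[2]
  ok <- pts[, 1] >= 1 & pts[, 1] <= n1 & pts[, 2] >= 1 & pts[, 2] <= n2
  pts <- pts[ok, , drop = FALSE]
  for (ch in 1:3) {
    rgb[cbind(pts[, 1], pts[, 2], ch)] <- color[ch]
  }
  rgb
}

#' Render an analysis overlay
#'
#' Draws orientation ticks (for curvelet groups) or polylines (for
#' fibers) over the grayscale image: objects of interest in green,
#' excluded objects in red, the boundary outline in yellow and ROI
#' rectangles in magenta. Deterministic: identical inputs produce
#' identical pixels.
#'
#' @param image numeric matrix (0-255 scale).
#' @param objects either a group/feature table with `center_row`,
#'   `center_col`, `angle_deg` (ticks) or a fiber vertex table with
#'   `fiber`, `row`, `col` (polylines). May be `NULL`.
#' @param boundary optional [boundary_mask()].
#' @param rois optional list of [roi()] (rectangles drawn).
#' @param statuses optional character vector aligned with objects/fibers;
#'   entries not equal to `"measured"` are drawn in red.
#' @param tick_length tick length in pixels for oriented ticks.
#' @return RGB array (rows x cols x 3, values in `[0, 1]`).
#' @export
render_overlay <- function(image, objects = NULL, boundary = NULL,
                           rois = NULL, statuses = NULL, tick_length = 9) {
  g <- clamp(image / 255, 0, 1)
  rgb <- array(rep(g, 3), dim = c(nrow(image), ncol(image), 3))
  green <- c(0, 1, 0); red <- c(1, 0, 0)
  yellow <- c(1, 1, 0); magenta <- c(1, 0, 1)
  if (!is.null(boundary)) {
    for (o in boundary$outlines) rgb <- .draw_pixels(rgb, o, yellow)
  }
  if (!is.null(rois)) {
    for (rj in rois) {
      if (rj$shape == "rectangle") {
        r0 <- rj$row0 + 1; r1 <- rj$row0 + rj$height
        c0 <- rj$col0 + 1; c1 <- rj$col0 + rj$width
        box <- rbind(pixel_line(r0, c0, r0, c1), pixel_line(r1, c0, r1, c1),
                     pixel_line(r0, c0, r1, c0), pixel_line(r0, c1, r1, c1))
        rgb <- .draw_pixels(rgb, box, magenta)
      }
    }
  }
  if (!is.null(objects) && nrow(objects) > 0) {
    if ("fiber" %in% names(objects)) {
      for (fid in unique(objects$fiber)) {
        v <- objects[objects$fiber == fid, ]
        col <- green
        if (!is.null(statuses) && statuses[match(fid, unique(objects$fiber))]
            != "measured") col <- red
        for (i in seq_len(nrow(v) - 1)) {
          rgb <- .draw_pixels(rgb, pixel_line(v$row[i], v$col[i],
                                              v$row[i + 1], v$col[i + 1]),
                              col)
        }
      }
    } else {
      for (i in seq_len(nrow(objects))) {
        if (is.na(objects$angle_deg[i])) next
        d <- axial_dir(objects$angle_deg[i]) * tick_length / 2
        col <- if (!is.null(statuses) && statuses[i] != "measured") red
        else green
        rgb <- .draw_pixels(rgb, pixel_line(
          objects$center_row[i] - d[1], objects$center_col[i] - d[2],
          objects$center_row[i] + d[1], objects$center_col[i] + d[2]), col)
      }
    }
  }
  rgb
}

#' Write an RGB overlay as TIFF
#'
#' @param rgb RGB array from [render_overlay()].
#' @param path output path.
#' @export
write_overlay_tiff <- function(rgb, path) {
  tiff::writeTIFF(rgb, path, bits.per.sample = 8)
  invisible(path)
}

#' Angle histogram table
#'
#' Fixed-width binning of axial angles for the histogram and compass-plot
#' CSV outputs.
#'
#' @param angles_deg axial angles in degrees.
#' @param bin_width bin width in degrees (must divide 180).
#' @return data frame with `bin_start_deg`, `bin_end_deg`,
#'   `bin_center_deg`, `count`.
#' @export
angle_histogram <- function(angles_deg, bin_width = 10) {
  breaks <- seq(0, 180, by = bin_width)
  a <- fold_axial(angles_deg)
  cut_idx <- pmin(floor(a / bin_width) + 1, length(breaks) - 1)
  counts <- tabulate(cut_idx, nbins = length(breaks) - 1)
  data.frame(bin_start_deg = utils::head(breaks, -1),
             bin_end_deg = utils::tail(breaks, -1),
             bin_center_deg = utils::head(breaks, -1) + bin_width / 2,
             count = counts)
}
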