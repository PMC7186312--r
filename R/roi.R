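# Region-of-interest management: definition, containment filtering and
# intensity statistics.
#
# ROI coordinates are 0-based (row, col) for file interchange, with
# half-open extents for rectangles; internally the package works with
# R's 1-based pixel centers. An import shim accepts 1-based rectangle
# CSVs behind an explicit flag.

#' Define a region of interest
#'
#' @param name ROI name.
#' @param shape `"rectangle"`, `"polygon"` or `"mask"`.
#' @param row0,col0,height,width rectangle definition: 0-based corner and
#'   half-open extents (a pixel with 0-based row r is inside iff
#'   `row0 <= r < row0 + height`).
#' @param rows,cols polygon vertices (0-based pixel coordinates).
#' @param mask logical matrix for mask ROIs.
#' @return an object of class `roi`.
#' @export
roi <- function(name, shape = c("rectangle", "polygon", "mask"),
                row0 = NULL, col0 = NULL, height = NULL, width = NULL,
                rows = NULL, cols = NULL, mask = NULL) {
  shape <- match.arg(shape)
  out <- switch(shape,
    rectangle = {
      if (is.null(row0) || is.null(col0) || is.null(height) ||
          is.null(width)) {
        stop("rectangle ROI needs row0, col0, height, width")
      }
      if (height <= 0 || width <= 0) stop("degenerate rectangle ROI")
      list(name = name, shape = shape, row0 = row0, col0 = col0,
           height = height, width = width)
    },
    polygon = {
      if (is.null(rows) || is.null(cols) || length(rows) != length(cols) ||
          length(rows) < 3) {
        stop("polygon ROI needs >= 3 matching rows/cols vertices")
      }
      list(name = name, shape = shape, rows = rows, cols = cols)
    },
    mask = {
      if (is.null(mask) || !any(mask > 0)) stop("degenerate mask ROI")
      list(name = name, shape = shape, mask = mask > 0)
    })
  class(out) <- "roi"
  out
}

# Is each (1-based) point inside the ROI?
.roi_contains <- function(roi, row, col) {
  r0 <- row - 1   # to 0-based
  c0 <- col - 1
  switch(roi$shape,
    rectangle = r0 >= roi$row0 & r0 < roi$row0 + roi$height &
      c0 >= roi$col0 & c0 < roi$col0 + roi$width,
    polygon = {
      bnd <- cbind(roi$rows, roi$cols)
      if (any(bnd[1, ] != bnd[nrow(bnd), ])) bnd <- rbind(bnd, bnd[1, ])
      as.logical(mgcv::in.out(bnd, cbind(r0, c0)))
    },
    mask = {
      ri <- round(row); ci <- round(col)
      ok <- ri >= 1 & ri <= nrow(roi$mask) & ci >= 1 & ci <= ncol(roi$mask)
      ins <- rep(FALSE, length(row))
      ins[ok] <- roi$mask[cbind(ri[ok], ci[ok])]
      ins
    })
}

#' Filter objects by ROI containment
#'
#' Keeps the rows of an object or feature table whose centers lie inside
#' the ROI (rectangles are half-open, polygons use point-in-polygon
#' containment).
#'
#' @param objects data frame with `center_row`, `center_col` (1-based
#'   pixel coordinates).
#' @param roi a [roi()].
#' @return the subset of `objects` inside the ROI.
#' @export
roi_filter <- function(objects, roi) {
  if (!inherits(roi, "roi")) stop("roi must be constructed with roi()")
  if (nrow(objects) == 0) return(objects)
  keep <- .roi_contains(roi, objects$center_row, objects$center_col)
  objects[keep, , drop = FALSE]
}

# Rasterize an ROI on an image grid; returns logical matrix.
.roi_rasterize <- function(roi, image_dim) {
  n1 <- image_dim[1]; n2 <- image_dim[2]
  if (roi$shape == "mask") {
    m <- matrix(FALSE, n1, n2)
    mr <- min(n1, nrow(roi$mask)); mc <- min(n2, ncol(roi$mask))
    m[seq_len(mr), seq_len(mc)] <- roi$mask[seq_len(mr), seq_len(mc)]
    return(m)
  }
  if (roi$shape == "rectangle") {
    m <- matrix(FALSE, n1, n2)
    rr <- seq_len(n1); cc <- seq_len(n2)
    rin <- (rr - 1) >= roi$row0 & (rr - 1) < roi$row0 + roi$height
    cin <- (cc - 1) >= roi$col0 & (cc - 1) < roi$col0 + roi$width
    m[rin, cin] <- TRUE
    return(m)
  }
  # polygon: test all pixel centers inside the bounding box
  m <- matrix(FALSE, n1, n2)
  r_rng <- clamp(c(floor(min(roi$rows)), ceiling(max(roi$rows))) + 1, 1, n1)
  c_rng <- clamp(c(floor(min(roi$cols)), ceiling(max(roi$cols))) + 1, 1, n2)
  rr <- r_rng[1]:r_rng[2]; cc <- c_rng[1]:c_rng[2]
  pts <- cbind(rep(rr, times = length(cc)), rep(cc, each = length(rr)))
  ins <- .roi_contains(roi, pts[, 1], pts[, 2])
  m[pts[ins, , drop = FALSE]] <- TRUE
  m
}

#' Intensity statistics on, inside or outside an ROI
#'
#' The ROI is rasterized on the image grid; its outline is the layer of
#' ROI pixels with a 4-neighbor outside the ROI (or on the image border),
#' `inside` is the ROI minus the outline, and `outside` is the
#' complement, so the three modes partition the image exactly.
#'
#' @param image numeric matrix.
#' @param roi a [roi()].
#' @param mode `"on-outline"`, `"inside"` or `"outside"`.
#' @return data frame with `mode`, `mean`, `std`, `min`, `max`, `n`;
#'   an empty pixel set yields `NA` statistics with `n = 0`.
#' @export
roi_intensity <- function(image, roi,
                          mode = c("on-outline", "inside", "outside")) {
  mode <- match.arg(mode)
  m <- .roi_rasterize(roi, dim(image))
  if (!any(m)) stop("ROI does not intersect the image")
  n1 <- nrow(m); n2 <- ncol(m)
  shift <- function(mm, dr, dc) {
    out <- matrix(FALSE, n1, n2)
    rs <- seq_len(n1) + dr; cs <- seq_len(n2) + dc
    ok_r <- rs >= 1 & rs <= n1; ok_c <- cs >= 1 & cs <= n2
    out[ok_r, ok_c] <- mm[rs[ok_r], cs[ok_c]]
    out
  }
  interior <- m & shift(m, 1, 0) & shift(m, -1, 0) &
    shift(m, 0, 1) & shift(m, 0, -1)
  # border pixels of the image never have a full 4-neighborhood
  interior[1, ] <- FALSE; interior[n1, ] <- FALSE
  interior[, 1] <- FALSE; interior[, n2] <- FALSE
  outline <- m & !interior
  sel <- switch(mode, `on-outline` = outline, inside = interior,
                outside = !m)
  v <- image[sel]
  if (length(v) == 0) {
    return(data.frame(mode = mode, mean = NA_real_, std = NA_real_,
                      min = NA_real_, max = NA_real_, n = 0L))
  }
  data.frame(mode = mode, mean = mean(v),
             std = if (length(v) > 1) stats::sd(v) else 0,
             min = min(v), max = max(v), n = length(v))
}

#' Read ROI definitions from a JSON file
#'
#' The file holds an array of objects with fields `name`, `shape` and the
#' shape's coordinates (0-based), e.g.
#' `{"name": "a", "shape": "rectangle", "row0": 0, "col0": 0,
#'   "height": 256, "width": 256}` or
#' `{"name": "p", "shape": "polygon", "rows": [...], "cols": [...]}`.
#'
#' @param path JSON file path.
#' @return list of [roi()] objects.
#' @export
load_rois <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.data.frame(j)) {
    j <- lapply(seq_len(nrow(j)), function(i) as.list(j[i, ]))
  }
  lapply(j, function(x) {
    x <- as.list(x)
    x$rows <- unlist(x$rows); x$cols <- unlist(x$cols)
    do.call(roi, x[!vapply(x, is.null, logical(1))])
  })
}

#' Import rectangle ROIs from a CSV table
#'
#' Expects columns `name`, `row0`, `col0`, `height`, `width`. Coordinates
#' are 0-based by default; set `one_based = TRUE` for tables exported by
#' 1-based tools.
#'
#' @param path CSV file path.
#' @param one_based logical; subtract 1 from `row0`/`col0` on import.
#' @return list of [roi()] objects.
#' @export
load_rois_csv <- function(path, one_based = FALSE) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(d)), function(i) {
    off <- if (one_based) 1 else 0
    roi(d$name[i], "rectangle", row0 = d$row0[i] - off,
        col0 = d$col0[i] - off, height = d$height[i], width = d$width[i])
  })
}
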