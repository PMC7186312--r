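# Boundary-relative angle quantification.
#
# A binary mask (e.g. a tumor boundary) is traced into ordered outlines;
# each analyzed object (fiber or curvelet group) is associated with its
# nearest outline point, the local boundary tangent is estimated from a
# window of outline points by principal axis, and the relative angle
# between the object orientation and the tangent is folded into [0, 90]
# degrees. Objects farther than a distance limit, or whose center lies
# inside the mask, are flagged excluded. Squares of a tile map containing
# at least one object with relative angle above a cutoff (default 60
# degrees, the perpendicular-fiber signature) are flagged in a heatmap.

# Moore-neighbor outline tracing of one 8-connected component, starting
# from its lexicographically smallest boundary pixel. Returns an ordered
# matrix of (row, col) outline pixels.
.moore_trace <- function(lab, id) {
  idx <- which(lab == id, arr.ind = TRUE)
  start <- idx[order(idx[, 1], idx[, 2])[1], ]
  n1 <- nrow(lab); n2 <- ncol(lab)
  inside <- function(r, c) r >= 1 && r <= n1 && c >= 1 && c <= n2 &&
    lab[r, c] == id
  # 8-neighborhood in clockwise order starting from W
  moves <- rbind(c(0, -1), c(-1, -1), c(-1, 0), c(-1, 1),
                 c(0, 1), c(1, 1), c(1, 0), c(1, -1))
  if (all(!vapply(seq_len(8), function(k) {
    inside(start[1] + moves[k, 1], start[2] + moves[k, 2])
  }, logical(1)))) {
    return(matrix(start, 1, 2, dimnames = list(NULL, c("row", "col"))))
  }
  path <- list(start)
  cur <- start
  entry <- 1L   # came "from the west"
  first_move <- NA_integer_
  repeat {
    found <- FALSE
    for (s in 0:7) {
      k <- ((entry - 1L + s) %% 8L) + 1L
      r <- cur[1] + moves[k, 1]; c <- cur[2] + moves[k, 2]
      if (inside(r, c)) {
        nxt <- c(r, c)
        # re-enter next search from the neighbor preceding the move
        entry <- ((k - 1L - 2L) %% 8L) + 1L
        if (all(nxt == start) && !is.na(first_move) &&
            length(path) > 2) {
          return(do.call(rbind, path))
        }
        if (is.na(first_move)) first_move <- k
        path[[length(path) + 1L]] <- nxt
        cur <- nxt
        found <- TRUE
        break
      }
    }
    if (!found || length(path) > 4 * (n1 + n2) * 4) {
      return(do.call(rbind, path))
    }
  }
}

#' Construct a boundary mask with traced outlines
#'
#' Binarizes the input (nonzero = inside) and traces the outline of every
#' 8-connected component with Moore neighbor tracing. Components are
#' ordered by size, largest first.
#'
#' @param mask logical or numeric matrix.
#' @return an object of class `boundary_mask`: list with `mask` (logical
#'   matrix) and `outlines` (list of ordered (row, col) matrices).
#' @export
boundary_mask <- function(mask) {
  m <- mask > 0
  if (!any(m)) stop("boundary mask is empty (no foreground pixels)")
  lab <- EBImage::bwlabel(EBImage::Image(m * 1))
  lab <- matrix(as.integer(EBImage::imageData(lab)), nrow(m), ncol(m))
  sizes <- table(lab[lab > 0])
  ids <- as.integer(names(sort(sizes, decreasing = TRUE)))
  outlines <- lapply(ids, function(id) {
    o <- .moore_trace(lab, id)
    colnames(o) <- c("row", "col")
    o
  })
  structure(list(mask = m, outlines = outlines), class = "boundary_mask")
}

#' Load a boundary mask from a TIFF file
#'
#' @param path TIFF path; pixels > 0 are inside the boundary. Raises an
#'   error naming the file if the mask is empty.
#' @return a [boundary_mask()].
#' @export
load_boundary_mask <- function(path) {
  img <- read_gray_tiff(path)
  if (!any(img > 0)) stop("boundary mask is empty: ", path)
  boundary_mask(img)
}

#' Locate the boundary mask that accompanies an image
#'
#' Follows the convention `<image_basename>_mask.tif` inside a `mask/`
#' folder next to the image.
#'
#' @param image_path path of the analyzed image.
#' @param mask_dir override for the mask folder.
#' @return path to the mask file, or `NULL` if absent.
#' @export
find_boundary_for <- function(image_path, mask_dir = NULL) {
  base <- sub("\\.[^.]+$", "", basename(image_path))
  if (is.null(mask_dir)) mask_dir <- file.path(dirname(image_path), "mask")
  p <- file.path(mask_dir, paste0(base, "_mask.tif"))
  if (file.exists(p)) p else NULL
}

#' Local tangent of an outline
#'
#' Axial direction of the principal axis of the outline points within
#' `window` indices of `point_index` (the outline is treated as closed).
#' Outlines shorter than the window are fitted whole.
#'
#' @param outline ordered (row, col) matrix.
#' @param point_index 1-based index into the outline.
#' @param window half-width of the index window (>= 2).
#' @return tangent angle in degrees, `[0, 180)`.
#' @export
boundary_tangent <- function(outline, point_index, window = 5) {
  n <- nrow(outline)
  if (n < 2) return(NA_real_)
  if (n <= 2 * window + 1) {
    pts <- outline
  } else {
    ix <- ((point_index - 1 + seq(-window, window)) %% n) + 1
    pts <- outline[ix, , drop = FALSE]
  }
  ctr <- colMeans(pts)
  X <- sweep(pts, 2, ctr)
  if (nrow(unique(pts)) == 1) return(NA_real_)
  cv <- crossprod(X) / nrow(X)
  e <- eigen(cv, symmetric = TRUE)
  v <- e$vectors[, 1]   # (row, col) principal direction
  axial_angle_deg(v[1], v[2])
}

#' Boundary-relative angles of oriented objects
#'
#' Associates every object with its nearest outline point (Euclidean
#' distance; ties resolved toward the smaller outline index), estimates
#' the boundary tangent there, and reports the axial difference between
#' the object angle and the tangent, folded into `[0, 90]`. Objects
#' beyond `max_distance` are flagged `excluded-too-far`; objects whose
#' center pixel lies inside the mask are flagged `excluded-inside`.
#'
#' @param objects data frame with `id`, `center_row`, `center_col`,
#'   `angle_deg`.
#' @param boundary a [boundary_mask()].
#' @param max_distance distance gate in pixels.
#' @param tangent_window half-width of the tangent window.
#' @return data frame with `id`, `object_angle_deg`, `boundary_row`,
#'   `boundary_col`, `tangent_deg`, `distance_px`, `relative_angle_deg`,
#'   `status`.
#' @export
relative_angles <- function(objects, boundary, max_distance = 150,
                            tangent_window = 5) {
  if (!inherits(boundary, "boundary_mask")) {
    boundary <- boundary_mask(boundary)
  }
  if (length(boundary$outlines) == 0) stop("boundary has no outline")
  all_pts <- do.call(rbind, boundary$outlines)
  comp <- rep(seq_along(boundary$outlines),
              vapply(boundary$outlines, nrow, integer(1)))
  within <- unlist(lapply(boundary$outlines, function(o) seq_len(nrow(o))))
  n <- nrow(objects)
  out <- data.frame(id = objects$id,
                    object_angle_deg = objects$angle_deg,
                    boundary_row = NA_real_, boundary_col = NA_real_,
                    tangent_deg = NA_real_, distance_px = NA_real_,
                    relative_angle_deg = NA_real_,
                    status = rep("measured", n),
                    stringsAsFactors = FALSE)
  if (n == 0) return(out)
  m <- boundary$mask
  for (i in seq_len(n)) {
    d2 <- (all_pts[, 1] - objects$center_row[i])^2 +
      (all_pts[, 2] - objects$center_col[i])^2
    j <- which.min(d2)   # first minimum = smallest outline index
    out$boundary_row[i] <- all_pts[j, 1]
    out$boundary_col[i] <- all_pts[j, 2]
    out$distance_px[i] <- sqrt(d2[j])
    tang <- boundary_tangent(boundary$outlines[[comp[j]]], within[j],
                             tangent_window)
    out$tangent_deg[i] <- tang
    pr <- clamp(round(objects$center_row[i]), 1, nrow(m))
    pc <- clamp(round(objects$center_col[i]), 1, ncol(m))
    if (m[pr, pc]) {
      out$status[i] <- "excluded-inside"
    } else if (out$distance_px[i] > max_distance) {
      out$status[i] <- "excluded-too-far"
    } else if (!is.na(tang) && !is.na(objects$angle_deg[i])) {
      out$relative_angle_deg[i] <-
        axial_diff_deg(objects$angle_deg[i], tang)
    }
  }
  out
}

#' Relative-angle heatmap
#'
#' Tiles the image into squares and flags every square containing at
#' least one measured record with relative angle above the cutoff
#' (default 60 degrees, the perpendicular-orientation signature at tumor
#' boundaries).
#'
#' @param records output of [relative_angles()], carrying the measured
#'   objects' centers as `center_row`/`center_col` columns, or merged with
#'   the object table; if those columns are absent, pass `objects`.
#' @param objects optional object table aligned with `records` (by `id`).
#' @param image_dim `c(rows, cols)`.
#' @param square_size_px tile size (>= 1).
#' @param angle_cutoff_deg cutoff in degrees (default 60).
#' @return binary matrix with one cell per tile (1 = flagged).
#' @export
tacs_heatmap <- function(records, image_dim, square_size_px,
                         angle_cutoff_deg = 60, objects = NULL) {
  if (!("center_row" %in% names(records))) {
    if (is.null(objects)) stop("records lack centers; supply `objects`")
    records <- merge(records, objects[, c("id", "center_row", "center_col")],
                     by = "id", sort = FALSE)
  }
  nt1 <- ceiling(image_dim[1] / square_size_px)
  nt2 <- ceiling(image_dim[2] / square_size_px)
  out <- matrix(0, nt1, nt2)
  hit <- records$status == "measured" &
    !is.na(records$relative_angle_deg) &
    records$relative_angle_deg > angle_cutoff_deg
  if (!any(hit)) return(out)
  ti <- pmin(pmax(ceiling(records$center_row[hit] / square_size_px), 1), nt1)
  tj <- pmin(pmax(ceiling(records$center_col[hit] / square_size_px), 1), nt2)
  out[cbind(ti, tj)] <- 1
  out
}
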