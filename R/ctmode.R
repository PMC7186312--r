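# Curvelet mode: local fiber orientations from grouped curvelet
# coefficients.
#
# Pipeline: forward curvelet transform -> restrict to the scale of
# interest (second finest by default) -> keep the largest-magnitude
# fraction of coefficients -> map them to image-space centers and axial
# angles -> group adjacent curvelets within a radius (single-linkage
# connected components) -> per-group features and circular summary
# statistics. Curvelet angles are weighted by coefficient magnitude,
# since larger coefficients mark stronger edges.

#' Curvelet-mode configuration
#'
#' @param keep_fraction fraction of coefficients kept at the selected
#'   scale (0.001-0.01 is typical; default 0.0035).
#' @param group_radius_px grouping radius in pixels (default 10).
#' @param scale scale selector passed to [select_scale()] (default
#'   `"second_finest"`).
#' @param n_wedges_second_coarsest angular resolution of the transform.
#' @param heatmap_square_px tile size of the local alignment map.
#' @param boundary_max_distance_px distance limit for boundary-relative
#'   measurements (default 150).
#' @param density_radii_px radius ladder for the local density features.
#' @param alignment_neighbors neighbor-count ladder for the local
#'   alignment features.
#' @return an object of class `ct_config`.
#' @export
ct_config <- function(keep_fraction = 0.0035, group_radius_px = 10,
                      scale = "second_finest",
                      n_wedges_second_coarsest = 16L,
                      heatmap_square_px = 32,
                      boundary_max_distance_px = 150,
                      density_radii_px = c(16, 32, 48, 64),
                      alignment_neighbors = c(4, 8, 16)) {
  stopifnot(keep_fraction > 0, keep_fraction <= 1, group_radius_px >= 0,
            heatmap_square_px >= 1)
  cfg <- list(keep_fraction = keep_fraction,
              group_radius_px = group_radius_px,
              scale = scale,
              n_wedges_second_coarsest = as.integer(n_wedges_second_coarsest),
              heatmap_square_px = as.integer(heatmap_square_px),
              boundary_max_distance_px = boundary_max_distance_px,
              density_radii_px = density_radii_px,
              alignment_neighbors = alignment_neighbors)
  class(cfg) <- "ct_config"
  cfg
}

# Union-find with path compression.
.uf_find <- function(parent, i) {
  while (parent[i] != i) {
    parent[i] <- parent[parent[i]]
    i <- parent[i]
  }
  i
}

#' Group adjacent curvelets
#'
#' Single-linkage connected components of the graph joining curvelets at
#' Euclidean distance <= `radius_px`. Each group's representative is the
#' magnitude-weighted centroid and magnitude-weighted axial mean angle of
#' its members. Groups are ordered (and numbered) by their smallest member
#' position, lexicographically by (row, col), which makes the result
#' independent of the input order.
#'
#' @param curvelets data frame with columns `center_row`, `center_col`,
#'   `angle_deg`, `magnitude` (as from [threshold_top_fraction()]).
#' @param radius_px grouping radius in pixels (>= 0); 0 keeps every
#'   curvelet as its own group.
#' @return data frame of groups: `group`, `center_row`, `center_col`,
#'   `angle_deg`, `magnitude` (summed), `n_members`, plus a `membership`
#'   attribute giving each input curvelet's group id.
#' @export
group_curvelets <- function(curvelets, radius_px) {
  n <- nrow(curvelets)
  empty <- data.frame(group = integer(), center_row = numeric(),
                      center_col = numeric(), angle_deg = numeric(),
                      magnitude = numeric(), n_members = integer())
  if (n == 0) {
    attr(empty, "membership") <- integer()
    return(empty)
  }
  parent <- seq_len(n)
  if (radius_px > 0 && n > 1) {
    # spatial binning: only points in the same or adjacent bins can be
    # within the radius
    cell <- max(radius_px, 1e-9)
    bx <- floor(curvelets$center_row / cell)
    by <- floor(curvelets$center_col / cell)
    key <- paste(bx, by)
    bins <- split(seq_len(n), key)
    bin_of <- function(x, y) bins[[paste(x, y)]]
    r2 <- radius_px^2
    for (b in names(bins)) {
      xy <- as.numeric(strsplit(b, " ")[[1]])
      idx <- bins[[b]]
      neigh <- idx
      for (dx in -1:1) for (dy in -1:1) {
        if (dx == 0 && dy == 0) next
        nb <- bin_of(xy[1] + dx, xy[2] + dy)
        if (!is.null(nb)) neigh <- c(neigh, nb)
      }
      for (i in idx) {
        d2 <- (curvelets$center_row[neigh] - curvelets$center_row[i])^2 +
          (curvelets$center_col[neigh] - curvelets$center_col[i])^2
        for (j in neigh[d2 <= r2]) {
          ri <- .uf_find(parent, i)
          rj <- .uf_find(parent, j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
  }
  root <- vapply(seq_len(n), function(i) .uf_find(parent, i), integer(1))
  # canonical ordering: by the smallest member (row, col) of each group
  comp <- split(seq_len(n), root)
  mins <- t(vapply(comp, function(ix) {
    o <- order(curvelets$center_row[ix], curvelets$center_col[ix])[1]
    c(curvelets$center_row[ix[o]], curvelets$center_col[ix[o]])
  }, numeric(2)))
  ord <- order(mins[, 1], mins[, 2])
  comp <- comp[ord]
  membership <- integer(n)
  rows <- lapply(seq_along(comp), function(g) {
    ix <- comp[[g]]
    membership[ix] <<- g
    w <- curvelets$magnitude[ix]
    if (sum(w) == 0) w <- rep(1, length(ix))
    data.frame(group = g,
               center_row = sum(w * curvelets$center_row[ix]) / sum(w),
               center_col = sum(w * curvelets$center_col[ix]) / sum(w),
               angle_deg = axial_mean(curvelets$angle_deg[ix], w),
               magnitude = sum(curvelets$magnitude[ix]),
               n_members = length(ix))
  })
  out <- do.call(rbind, rows)
  attr(out, "membership") <- membership
  out
}

# Per-group neighborhood features: nearest-neighbor distance, local
# density counts at a radius ladder, local alignment over the k nearest
# groups (including the group itself).
.group_features <- function(groups, config) {
  n <- nrow(groups)
  feat <- groups
  radii <- config$density_radii_px
  ks <- config$alignment_neighbors
  for (r in radii) feat[[sprintf("density_r%d", r)]] <- rep(NA_integer_, n)
  for (k in ks) feat[[sprintf("align_n%d", k)]] <- rep(NA_real_, n)
  feat$nearest_neighbor_px <- rep(NA_real_, n)
  if (n < 2) return(feat)
  for (i in seq_len(n)) {
    d <- sqrt((groups$center_row - groups$center_row[i])^2 +
                (groups$center_col - groups$center_col[i])^2)
    d[i] <- Inf
    feat$nearest_neighbor_px[i] <- min(d)
    for (r in radii) {
      feat[[sprintf("density_r%d", r)]][i] <- sum(d <= r)
    }
    ord <- order(d)
    for (k in ks) {
      sel <- c(i, ord[seq_len(min(k, n - 1))])
      feat[[sprintf("align_n%d", k)]][i] <-
        alignment(groups$angle_deg[sel], groups$magnitude[sel])
    }
  }
  feat
}

#' Curvelet-mode analysis of an image
#'
#' Runs the full curvelet-mode pipeline and returns the per-group feature
#' table together with the circular summary of the group orientations
#' (magnitude-weighted). Without a boundary the angles are measured
#' against the absolute image axes; with a boundary mask the features are
#' augmented with the distance to the boundary and the relative angle in
#' `[0, 90]`, and the summary is computed over the measured relative
#' angles.
#'
#' @param image numeric matrix, or a TIFF path readable by
#'   [read_gray_tiff()].
#' @param config a [ct_config()].
#' @param boundary optional boundary mask (matrix or [boundary_mask()]);
#'   must match the image grid.
#' @param rois optional list of ROIs; per-ROI summaries are returned.
#' @return list with `features`, `groups`, `curvelets`, `summary`
#'   (`circ_summary`), `pyramid` (scale-restricted), and optionally
#'   `boundary_records` and `roi_summaries`.
#' @export
analyze_ct <- function(image, config = ct_config(), boundary = NULL,
                       rois = NULL) {
  if (is.character(image)) image <- read_gray_tiff(image)
  pyr <- fdct(image,
              n_wedges_second_coarsest = config$n_wedges_second_coarsest)
  sel <- select_scale(pyr, config$scale)
  curvelets <- threshold_top_fraction(sel, config$keep_fraction)
  groups <- group_curvelets(curvelets, config$group_radius_px)
  features <- .group_features(groups, config)
  boundary_records <- NULL
  if (!is.null(boundary)) {
    if (!inherits(boundary, "boundary_mask")) {
      boundary <- boundary_mask(boundary)
    }
    if (!all(dim(boundary$mask) == dim(image))) {
      stop("boundary mask and image are on different pixel grids")
    }
    objects <- data.frame(id = groups$group,
                          center_row = groups$center_row,
                          center_col = groups$center_col,
                          angle_deg = groups$angle_deg)
    boundary_records <- relative_angles(objects, boundary,
                                        config$boundary_max_distance_px)
    features$distance_to_boundary_px <- boundary_records$distance_px
    features$relative_angle_deg <- boundary_records$relative_angle_deg
    features$boundary_status <- boundary_records$status
    meas <- boundary_records[boundary_records$status == "measured", ]
    summary <- circular_summary(meas$relative_angle_deg)
  } else {
    summary <- circular_summary(groups$angle_deg, groups$magnitude)
  }
  roi_summaries <- NULL
  if (!is.null(rois)) {
    roi_summaries <- lapply(rois, function(roi) {
      sub <- roi_filter(features, roi)
      s <- circular_summary(sub$angle_deg, sub$magnitude)
      cbind(data.frame(roi = roi$name), as.data.frame(s))
    })
    roi_summaries <- do.call(rbind, roi_summaries)
  }
  list(features = features, groups = groups, curvelets = curvelets,
       summary = summary, pyramid = sel,
       boundary_records = boundary_records,
       roi_summaries = roi_summaries)
}

#' Local alignment map
#'
#' Tiles the image into squares and assigns each square the alignment
#' coefficient of the groups whose centers fall inside it
#' (magnitude-weighted); squares without groups are 0.
#'
#' @param groups group table from [group_curvelets()].
#' @param image_dim `c(rows, cols)` of the analyzed image.
#' @param square_size_px tile size in pixels (>= 1).
#' @return numeric matrix with one cell per tile, values in `[0, 1]`.
#' @export
local_alignment_map <- function(groups, image_dim, square_size_px) {
  stopifnot(square_size_px >= 1)
  nt1 <- ceiling(image_dim[1] / square_size_px)
  nt2 <- ceiling(image_dim[2] / square_size_px)
  out <- matrix(0, nt1, nt2)
  if (nrow(groups) == 0) return(out)
  ti <- pmin(pmax(ceiling(groups$center_row / square_size_px), 1), nt1)
  tj <- pmin(pmax(ceiling(groups$center_col / square_size_px), 1), nt2)
  for (cell in split(seq_len(nrow(groups)), paste(ti, tj))) {
    a <- alignment(groups$angle_deg[cell], groups$magnitude[cell])
    if (!is.na(a)) {
      out[ti[cell[1]], tj[cell[1]]] <- a
    }
  }
  out
}
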