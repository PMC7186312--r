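# Individual fiber extraction by distance-transform tracing.
#
# Three stages: (1) nucleation — local maxima of the Euclidean distance
# transform of the foreground that exceed a distance threshold seed the
# tracer; (2) extension — from each nucleation point, branches grow by
# repeatedly stepping to local maximum points (LMPs) of the distance map
# found on the surface of a box whose size is set by the distance value at
# the current tip, with the tip direction updated with memory to prevent
# backtracking; (3) linking — branches that meet at a nucleation point and
# continue nearly straight are joined into fibers, and fibers shorter than
# a minimum length are discarded.
#
# All tie-breaks are lexicographic by (row, col); plateau ties in the
# nucleation search are broken by a seeded, vanishingly small jitter of
# the distance values, so results are deterministic for a given seed and
# identical under parallel and sequential execution.

#' Fiber-extraction configuration
#'
#' @param background_threshold intensity below or at which a pixel is
#'   background (foreground rule is strictly greater). Default 60.
#' @param nucleation_box_radius half-width (pixels) of the box in which a
#'   nucleation point must be the distance-map maximum.
#' @param nucleation_distance_threshold minimum distance value (pixels) at
#'   a nucleation point.
#' @param lmp_distance_threshold minimum distance value (pixels) for an
#'   extension candidate.
#' @param lmp_min_separation of two LMPs closer than this (pixels), only
#'   the one with the larger distance value is kept.
#' @param direction_memory_weight lambda in `[0, 1)`: the tip direction is
#'   `normalize(lambda * old + (1 - lambda) * step)`.
#' @param link_angle_threshold maximum deviation (degrees) from straight
#'   continuation for two branches to be linked.
#' @param tip_spacing number of vertices between a branch end and the
#'   vertex used to compute the end direction.
#' @param min_fiber_length fibers shorter than this (pixels) are discarded.
#'   Default 30.
#' @param seed RNG seed for the nucleation tie-break jitter.
#' @return an object of class `fire_config`.
#' @export
fire_config <- function(background_threshold = 60,
                        nucleation_box_radius = 5,
                        nucleation_distance_threshold = 2,
                        lmp_distance_threshold = 1.5,
                        lmp_min_separation = 3,
                        direction_memory_weight = 0.5,
                        link_angle_threshold = 30,
                        tip_spacing = 3,
                        min_fiber_length = 30,
                        seed = 1L) {
  stopifnot(background_threshold >= 0, nucleation_box_radius >= 1,
            nucleation_distance_threshold >= 0,
            lmp_distance_threshold >= 0, lmp_min_separation >= 0,
            direction_memory_weight >= 0, direction_memory_weight < 1,
            link_angle_threshold >= 0, tip_spacing >= 1,
            min_fiber_length >= 0)
  cfg <- list(background_threshold = background_threshold,
              nucleation_box_radius = as.integer(nucleation_box_radius),
              nucleation_distance_threshold = nucleation_distance_threshold,
              lmp_distance_threshold = lmp_distance_threshold,
              lmp_min_separation = lmp_min_separation,
              direction_memory_weight = direction_memory_weight,
              link_angle_threshold = link_angle_threshold,
              tip_spacing = as.integer(tip_spacing),
              min_fiber_length = min_fiber_length,
              seed = as.integer(seed))
  class(cfg) <- "fire_config"
  cfg
}

#' Binarize an image and compute its Euclidean distance map
#'
#' Foreground is every pixel with intensity strictly greater than the
#' background threshold; the distance map holds, for each foreground
#' pixel, the exact Euclidean distance to the nearest background pixel
#' (zero on background).
#'
#' @param image numeric matrix.
#' @param background_threshold intensity threshold.
#' @return list with `distance` (numeric matrix) and `foreground`
#'   (logical matrix).
#' @export
binarize_and_distance <- function(image, background_threshold) {
  fg <- image > background_threshold
  if (!any(fg)) {
    return(list(distance = matrix(0, nrow(image), ncol(image)),
                foreground = fg))
  }
  dm <- EBImage::distmap(EBImage::Image(fg * 1), metric = "euclidean")
  list(distance = matrix(as.numeric(EBImage::imageData(dm)),
                         nrow(image), ncol(image)),
       foreground = fg)
}

#' Find nucleation points of a distance map
#'
#' A pixel is a nucleation point iff its jittered distance value is the
#' strict maximum over the `(2r+1)^2` box centered on it and its raw
#' distance exceeds the distance threshold. The jitter is a seeded uniform
#' perturbation of relative magnitude below 1e-6 that breaks plateau ties
#' deterministically.
#'
#' @param dmap distance map (matrix or result of
#'   [binarize_and_distance()]).
#' @param box_radius box half-width in pixels (>= 1).
#' @param dist_threshold minimum raw distance value.
#' @param seed RNG seed for the jitter.
#' @return data frame with columns `id`, `row`, `col`, `distance`, ordered
#'   lexicographically by (row, col).
#' @export
find_nucleation_points <- function(dmap, box_radius, dist_threshold,
                                   seed = 1L) {
  if (is.list(dmap)) dmap <- dmap$distance
  set.seed(as.integer(seed))
  jit <- dmap * (1 + matrix(stats::runif(length(dmap)), nrow(dmap)) * 1e-6)
  mx <- box_max_filter(jit, as.integer(box_radius))
  is_np <- (jit == mx) & (dmap > dist_threshold)
  idx <- which(is_np, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    return(data.frame(id = integer(), row = integer(), col = integer(),
                      distance = numeric()))
  }
  ord <- order(idx[, 1], idx[, 2])
  idx <- idx[ord, , drop = FALSE]
  data.frame(id = seq_len(nrow(idx)), row = idx[, 1], col = idx[, 2],
             distance = dmap[idx])
}

# Pixels on the surface (square ring) of the box of half-width r around
# (row, col), clipped to the image; ordered by angle around the center.
.box_ring <- function(row, col, r, n1, n2) {
  rr <- (row - r):(row + r)
  cc <- (col - r):(col + r)
  ring <- rbind(
    cbind(rep(row - r, length(cc)), cc),
    cbind(rep(row + r, length(cc)), cc),
    cbind(rr[-c(1, length(rr))], rep(col - r, length(rr) - 2)),
    cbind(rr[-c(1, length(rr))], rep(col + r, length(rr) - 2)))
  keep <- ring[, 1] >= 1 & ring[, 1] <= n1 & ring[, 2] >= 1 & ring[, 2] <= n2
  ring <- ring[keep, , drop = FALSE]
  if (nrow(ring) == 0) return(ring)
  ang <- atan2(ring[, 1] - row, ring[, 2] - col)
  ring[order(ang, ring[, 1], ring[, 2]), , drop = FALSE]
}

# LMPs on the ring: circular local maxima of the distance values along the
# angular ordering, above the threshold, then thinned so that no two kept
# LMPs are closer than min_sep (larger distance wins, lexicographic ties).
.ring_lmps <- function(dmap, ring, lmp_threshold, min_sep) {
  if (nrow(ring) == 0) return(ring[0, , drop = FALSE])
  v <- dmap[ring]
  n <- length(v)
  if (n == 1) {
    keep <- v > lmp_threshold
    return(ring[keep, , drop = FALSE])
  }
  nxt <- c(2:n, 1)
  prv <- c(n, 1:(n - 1))
  is_max <- v >= v[nxt] & v >= v[prv] & v > lmp_threshold
  # collapse plateaus: keep the lexicographically smallest pixel of runs
  cand <- which(is_max)
  if (length(cand) == 0) return(ring[0, , drop = FALSE])
  pts <- ring[cand, , drop = FALSE]
  vals <- v[cand]
  ord <- order(-vals, pts[, 1], pts[, 2])
  pts <- pts[ord, , drop = FALSE]
  vals <- vals[ord]
  kept <- rep(TRUE, nrow(pts))
  for (i in seq_len(nrow(pts))) {
    if (!kept[i]) next
    if (i < nrow(pts)) {
      for (j in (i + 1):nrow(pts)) {
        if (kept[j] &&
            sum((pts[i, ] - pts[j, ])^2) < min_sep^2) {
          kept[j] <- FALSE
        }
      }
    }
  }
  pts <- pts[kept, , drop = FALSE]
  pts[order(pts[, 1], pts[, 2]), , drop = FALSE]
}

#' Extend branches from nucleation points
#'
#' From each nucleation point, one branch starts per initial LMP found on
#' the surface of the box whose half-width is the (ceiling of the)
#' distance value at the point. At each subsequent step, candidate LMPs on
#' the tip's box surface that oppose the tip direction (negative dot
#' product) are discarded to prevent backtracking, the most aligned
#' candidate is chosen, and the tip direction is updated as
#' `lambda * old + (1 - lambda) * step` (normalized). A branch terminates
#' when no admissible LMP remains (`no-LMP`), when the step lands within
#' the nucleation box radius of another nucleation point
#' (`reached-nucleation-point`, recording that point's id and snapping the
#' final vertex to it), or at the image border (`image-edge`). Extensions
#' from distinct nucleation points are independent.
#'
#' @param points nucleation data frame from [find_nucleation_points()].
#' @param dmap distance map (matrix or list from
#'   [binarize_and_distance()]).
#' @param config a [fire_config()].
#' @return list of branches: `list(vertices, origin, terminal,
#'   terminated_reason, tip_direction)` where `terminal` is the id of the
#'   nucleation point reached, or `NA`.
#' @export
extend_branches <- function(points, dmap, config) {
  if (is.list(dmap) && !is.matrix(dmap)) dmap <- dmap$distance
  n1 <- nrow(dmap); n2 <- ncol(dmap)
  lam <- config$direction_memory_weight
  branches <- list()
  if (nrow(points) == 0) return(branches)
  np_mat <- as.matrix(points[, c("row", "col")])
  for (pi in seq_len(nrow(points))) {
    p <- c(points$row[pi], points$col[pi])
    r0 <- max(1L, as.integer(ceiling(dmap[p[1], p[2]])))
    ring <- .box_ring(p[1], p[2], r0, n1, n2)
    lmps <- .ring_lmps(dmap, ring, config$lmp_distance_threshold,
                       config$lmp_min_separation)
    if (nrow(lmps) == 0) {
      branches[[length(branches) + 1L]] <-
        list(vertices = matrix(p, 1, 2, dimnames = list(NULL, c("row", "col"))),
             origin = points$id[pi], terminal = NA_integer_,
             terminated_reason = "no-LMP",
             tip_direction = c(NA_real_, NA_real_))
      next
    }
    for (li in seq_len(nrow(lmps))) {
      start_dir <- lmps[li, ] - p
      nd <- sqrt(sum(start_dir^2))
      if (nd < 1e-9) next
      branches[[length(branches) + 1L]] <-
        .grow_branch(p, lmps[li, ], start_dir / nd, points$id[pi],
                     np_mat, points$id, dmap, config)
    }
  }
  branches
}

.grow_branch <- function(origin_pos, first_vertex, dir0, origin_id,
                         np_mat, np_ids, dmap, config) {
  n1 <- nrow(dmap); n2 <- ncol(dmap)
  lam <- config$direction_memory_weight
  verts <- rbind(origin_pos, first_vertex)
  tipdir <- dir0
  reason <- "no-LMP"
  terminal <- NA_integer_
  max_steps <- 4 * (n1 + n2)
  for (step in seq_len(max_steps)) {
    tip <- verts[nrow(verts), ]
    # terminated at another nucleation point?
    d2 <- (np_mat[, 1] - tip[1])^2 + (np_mat[, 2] - tip[2])^2
    near <- which(d2 <= config$nucleation_box_radius^2 &
                    np_ids != origin_id)
    if (length(near) > 0) {
      j <- near[which.min(d2[near])]
      if (sum((np_mat[j, ] - tip)^2) > 1e-9) {
        verts <- rbind(verts, np_mat[j, ])
      }
      terminal <- np_ids[j]
      reason <- "reached-nucleation-point"
      break
    }
    if (tip[1] <= 1 || tip[1] >= n1 || tip[2] <= 1 || tip[2] >= n2) {
      reason <- "image-edge"
      break
    }
    r <- max(1L, as.integer(ceiling(dmap[tip[1], tip[2]])))
    ring <- .box_ring(tip[1], tip[2], r, n1, n2)
    lmps <- .ring_lmps(dmap, ring, config$lmp_distance_threshold,
                       config$lmp_min_separation)
    if (nrow(lmps) == 0) break
    steps <- sweep(lmps, 2, tip)
    norms <- sqrt(rowSums(steps^2))
    ok <- norms > 1e-9
    dots <- rowSums(sweep(steps, 1, norms, "/") *
                      matrix(tipdir, nrow(steps), 2, byrow = TRUE))
    ok <- ok & dots > 0
    if (!any(ok)) break
    cand <- which(ok)
    best <- cand[order(-dots[cand], lmps[cand, 1], lmps[cand, 2])[1]]
    newv <- lmps[best, ]
    # cycle guard
    if (any(verts[, 1] == newv[1] & verts[, 2] == newv[2])) break
    stepdir <- steps[best, ] / norms[best]
    tipdir <- lam * tipdir + (1 - lam) * stepdir
    tipdir <- tipdir / sqrt(sum(tipdir^2))
    verts <- rbind(verts, newv)
  }
  dimnames(verts) <- list(NULL, c("row", "col"))
  list(vertices = verts, origin = origin_id, terminal = terminal,
       terminated_reason = reason, tip_direction = tipdir)
}

# Direction at a chain end, pointing INTO the end vertex, computed over
# `spacing` vertices back along the chain.
.end_dir <- function(verts, end = c("first", "last"), spacing) {
  n <- nrow(verts)
  if (end == "first") {
    a <- verts[min(n, 1 + spacing), ]
    b <- verts[1, ]
  } else {
    a <- verts[max(1, n - spacing), ]
    b <- verts[n, ]
  }
  d <- b - a
  nd <- sqrt(sum(d^2))
  if (nd < 1e-9) c(NA_real_, NA_real_) else d / nd
}

#' Link branches into fibers
#'
#' Branches (and partially linked fibers) that are incident to the same
#' nucleation point are joined when their directions continue nearly
#' straight through the point: the angle between the inward end direction
#' of one and the reversed inward direction of the other, each computed
#' over `tip_spacing` vertices, must deviate from straight continuation by
#' at most `link_angle_threshold` degrees. Nucleation points are processed
#' in id order; at each point, admissible pairs are linked
#' best-aligned-first until none remain, and a linked pair leaves the pool
#' as a single longer fiber that may keep linking at its other ends.
#' Unlinked branches become single-branch fibers. Fibers shorter than
#' `min_fiber_length` are discarded.
#'
#' @param branches branch list from [extend_branches()].
#' @param config a [fire_config()].
#' @param dmap optional distance map used to attach per-vertex radii.
#' @return data frames: `fibers` (id, length, width, straightness,
#'   angle_deg, n_vertices) and `vertices` (fiber, vertex, row, col,
#'   radius), as a list.
#' @export
link_branches <- function(branches, config, dmap = NULL) {
  if (is.list(dmap) && !is.matrix(dmap)) dmap <- dmap$distance
  # drop degenerate single-vertex branches
  branches <- Filter(function(b) nrow(b$vertices) >= 2, branches)
  # delete duplicated branches: a branch from nucleation point a to b and
  # one from b to a trace the same path; keep the one with the smaller
  # origin id (both kept if only one direction was traced)
  if (length(branches) > 1) {
    keys <- vapply(branches, function(b) {
      paste(b$origin, b$terminal)
    }, character(1))
    rev_keys <- vapply(branches, function(b) {
      paste(b$terminal, b$origin)
    }, character(1))
    drop <- vapply(seq_along(branches), function(i) {
      b <- branches[[i]]
      !is.na(b$terminal) && b$terminal < b$origin &&
        rev_keys[i] %in% keys
    }, logical(1))
    branches <- branches[!drop]
  }
  chains <- lapply(branches, function(b) {
    list(vertices = b$vertices,
         ends = c(b$origin, b$terminal))  # NA if free end
  })
  all_nps <- sort(unique(stats::na.omit(
    unlist(lapply(chains, function(ch) ch$ends)))))
  spacing <- config$tip_spacing
  for (np in all_nps) {
    repeat {
      inc <- list()
      for (ci in seq_along(chains)) {
        ch <- chains[[ci]]
        if (is.null(ch)) next
        for (e in 1:2) {
          if (!is.na(ch$ends[e]) && ch$ends[e] == np) {
            inc[[length(inc) + 1L]] <- list(chain = ci, end = e)
          }
        }
      }
      if (length(inc) < 2) break
      # inward directions at this nucleation point
      dirs <- lapply(inc, function(x) {
        ch <- chains[[x$chain]]
        .end_dir(ch$vertices, if (x$end == 1) "first" else "last", spacing)
      })
      best <- NULL
      best_dev <- Inf
      for (i in seq_len(length(inc) - 1)) {
        for (j in (i + 1):length(inc)) {
          if (inc[[i]]$chain == inc[[j]]$chain) next
          u <- dirs[[i]]; v <- dirs[[j]]
          if (any(is.na(u)) || any(is.na(v))) next
          # straight continuation: u and -v aligned
          dev <- acos(clamp(sum(u * -v), -1, 1)) * 180 / pi
          if (dev < best_dev - 1e-12) {
            best_dev <- dev
            best <- c(i, j)
          }
        }
      }
      if (is.null(best) || best_dev > config$link_angle_threshold) break
      a <- inc[[best[1]]]; b <- inc[[best[2]]]
      ca <- chains[[a$chain]]; cb <- chains[[b$chain]]
      # orient A to end at np, B to start at np
      va <- ca$vertices; ea <- ca$ends
      if (a$end == 1) { va <- va[nrow(va):1, , drop = FALSE]; ea <- rev(ea) }
      vb <- cb$vertices; eb <- cb$ends
      if (b$end == 2) { vb <- vb[nrow(vb):1, , drop = FALSE]; eb <- rev(eb) }
      if (all(abs(va[nrow(va), ] - vb[1, ]) < 1e-9)) {
        vb <- vb[-1, , drop = FALSE]
      }
      merged <- list(vertices = rbind(va, vb), ends = c(ea[1], eb[2]))
      chains[[a$chain]] <- merged
      chains[[b$chain]] <- NULL
    }
  }
  chains <- Filter(Negate(is.null), chains)

  fib_rows <- list()
  vert_rows <- list()
  fid <- 0L
  for (ch in chains) {
    v <- ch$vertices
    seg <- diff(v)
    len <- sum(sqrt(rowSums(seg^2)))
    if (len < config$min_fiber_length) next
    fid <- fid + 1L
    radius <- if (!is.null(dmap)) {
      dmap[cbind(clamp(round(v[, 1]), 1, nrow(dmap)),
                 clamp(round(v[, 2]), 1, ncol(dmap)))]
    } else rep(NA_real_, nrow(v))
    ee <- v[nrow(v), ] - v[1, ]
    fib_rows[[fid]] <- data.frame(
      id = fid, length = len,
      width = 2 * mean(radius),
      straightness = min(sqrt(sum(ee^2)) / len, 1),
      angle_deg = axial_angle_deg(ee[1], ee[2]),
      n_vertices = nrow(v))
    vert_rows[[fid]] <- data.frame(fiber = fid, vertex = seq_len(nrow(v)),
                                   row = v[, 1], col = v[, 2],
                                   radius = radius)
  }
  fibers_out <- if (fid > 0) do.call(rbind, fib_rows) else NULL
  verts_out <- if (fid > 0) do.call(rbind, vert_rows) else NULL
  if (!is.null(fibers_out)) rownames(fibers_out) <- NULL
  if (!is.null(verts_out)) rownames(verts_out) <- NULL
  list(fibers = if (fid > 0) fibers_out else
         data.frame(id = integer(), length = numeric(), width = numeric(),
                    straightness = numeric(), angle_deg = numeric(),
                    n_vertices = integer()),
       vertices = if (fid > 0) verts_out else
         data.frame(fiber = integer(), vertex = integer(), row = numeric(),
                    col = numeric(), radius = numeric()))
}

#' Extract individual fibers from an image
#'
#' Full pipeline: binarize and distance-transform, find nucleation points,
#' extend branches, link them into fibers, and measure per-fiber length,
#' width (twice the mean vertex radius), straightness and axial angle.
#' Deterministic given the config seed.
#'
#' @param image numeric matrix (grayscale, 0-255 scale).
#' @param config a [fire_config()].
#' @return list with `fibers` and `vertices` data frames (see
#'   [link_branches()]) plus `nucleation` and `distance`.
#' @export
extract_fibers <- function(image, config = fire_config()) {
  bd <- binarize_and_distance(image, config$background_threshold)
  nps <- find_nucleation_points(bd$distance, config$nucleation_box_radius,
                                config$nucleation_distance_threshold,
                                seed = config$seed)
  branches <- extend_branches(nps, bd$distance, config)
  out <- link_branches(branches, config, dmap = bd$distance)
  out$nucleation <- nps
  out$distance <- bd$distance
  out
}
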