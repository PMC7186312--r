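# Programmatic fixtures shared across the test files.

# A straight line of given axial angle through the image center, dilated
# to `width` pixels.
make_line_image <- function(n, angle_deg, width = 3, value = 255,
                            length_frac = 0.8) {
  img <- matrix(0, n, n)
  ctr <- (n + 1) / 2
  d <- axial_dir(angle_deg)
  half <- n * length_frac / 2
  p0 <- c(ctr, ctr) - half * d
  p1 <- c(ctr, ctr) + half * d
  fibretrace:::.stamp_segment(img, p0, p1, width) * (value / 255)
}

# Solid disk mask/image.
make_disk <- function(n, center, radius, value = 1) {
  R <- matrix(seq_len(n), n, n)
  C <- matrix(seq_len(n), n, n, byrow = TRUE)
  ((R - center[1])^2 + (C - center[2])^2 <= radius^2) * value
}

# Brute-force exact Euclidean distance map (O(N^2), small images only).
brute_distance <- function(fg) {
  bgi <- which(!fg, arr.ind = TRUE)
  out <- matrix(0, nrow(fg), ncol(fg))
  fgi <- which(fg, arr.ind = TRUE)
  for (k in seq_len(nrow(fgi))) {
    out[fgi[k, 1], fgi[k, 2]] <-
      sqrt(min((bgi[, 1] - fgi[k, 1])^2 + (bgi[, 2] - fgi[k, 2])^2))
  }
  out
}

# Brute-force single-linkage components: transitive closure of the
# pairwise distance <= radius relation.
brute_components <- function(pts, radius) {
  n <- nrow(pts)
  adj <- as.matrix(stats::dist(pts)) <= radius
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      nb <- which(adj[i, ])
      m <- min(comp[nb])
      if (m < comp[i]) { comp[comp == comp[i]] <- m; changed <- TRUE }
    }
    if (!changed) break
  }
  match(comp, sort(unique(comp)))
}

# Brute-force ray-casting point-in-polygon.
brute_pip <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((vy[i] > py) != (vy[j] > py)) {
      xint <- (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i]
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

# Small, fast generator config for unit tests.
tiny_generator_config <- function(...) {
  generator_config(image_width = 128, image_height = 128, n_fibers = 5,
                   length = dist_spec("gaussian", mean = 40, sd = 0),
                   edge_buffer_px = 8, ...)
}
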