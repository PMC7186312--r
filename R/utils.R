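# Shared low-level helpers: angle conventions, hashing, line rasterization.
#
# Angle convention used throughout the package: the image row axis points
# down, angles are measured counterclockwise (as displayed) from the +x
# (column) axis in degrees, and all fiber / curvelet angles are axial,
# i.e. defined modulo 180 degrees.

#' Fold angles into the axial range [0, 180)
#'
#' @param angle_deg numeric vector of angles in degrees.
#' @return angles folded into `[0, 180)`.
#' @export
fold_axial <- function(angle_deg) angle_deg %% 180

#' Axial angle of a displacement vector
#'
#' Converts a displacement in image coordinates (rows grow downwards) to an
#' axial orientation in degrees, measured counterclockwise from the +column
#' axis as the image is displayed. A horizontal structure has angle 0, a
#' vertical one 90.
#'
#' @param drow,dcol displacement components in pixels (row, column).
#' @return angle in degrees, in `[0, 180)`.
#' @export
axial_angle_deg <- function(drow, dcol) {
  fold_axial(atan2(-drow, dcol) * 180 / pi)
}

#' Unit direction vector of an axial angle
#'
#' Inverse of [axial_angle_deg()]: returns the (drow, dcol) unit vector of a
#' given axial orientation (one of the two antipodal representatives).
#'
#' @param angle_deg axial angle in degrees.
#' @return numeric vector `c(drow, dcol)`.
#' @export
axial_dir <- function(angle_deg) {
  th <- angle_deg * pi / 180
  c(-sin(th), cos(th))
}

#' Axial difference between two angles
#'
#' @param a,b angles in degrees (axial).
#' @return difference in degrees, in `[0, 90]`.
#' @export
axial_diff_deg <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

# Deterministic 31-multiplier string hash folded with a base seed; used to
# derive per-image RNG seeds that do not depend on scheduling order.
# Kept below 2^31 - 1 so the result is a valid R integer seed.
stable_seed <- function(seed, name) {
  h <- as.numeric(seed) %% 2147483647
  for (ch in utf8ToInt(as.character(name))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

# Integer pixel chain between two points (Bresenham-like via dense
# parameter sampling; deterministic). Returns a matrix with columns row, col.
pixel_line <- function(r0, c0, r1, c1) {
  n <- max(abs(r1 - r0), abs(c1 - c0), 1)
  t <- seq(0, 1, length.out = ceiling(n) + 1)
  cbind(row = round(r0 + t * (r1 - r0)), col = round(c0 + t * (c1 - c0)))
}

# Running maximum of a vector over a centered window of half-width `r`
# (window size 2r+1), computed with vectorized shifts. Values beyond the
# edges are treated as -Inf.
running_max <- function(x, r) {
  n <- length(x)
  out <- x
  if (r < 1) return(out)
  for (s in 1:r) {
    out <- pmax(out,
                c(x[-seq_len(s)], rep(-Inf, s)),
                c(rep(-Inf, s), x[seq_len(n - s)]))
  }
  out
}

# 2-D separable maximum filter over a (2r+1) x (2r+1) box.
box_max_filter <- function(m, r) {
  m1 <- apply(m, 2, running_max, r = r)
  t(apply(t(m1), 2, running_max, r = r))
}

# Clamp helper.
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
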