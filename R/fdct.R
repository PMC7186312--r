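# Fast discrete curvelet transform (frequency-wedge variant).
#
# The transform tiles the 2-D frequency plane with smooth windows whose
# squares form an exact partition of unity: a low-pass block at the
# coarsest scale, dyadic coronae split into angular wedges at the
# intermediate scales, and an isotropic ring at the finest scale. Each
# wedge band is extracted on the rectangular frequency block that bounds
# its support and inverse-transformed with a unitary FFT, which yields
# complex coefficients on a regular spatial lattice. Because the squared
# windows sum to one and each block FFT is unitary, the frame is tight:
# energy is conserved exactly and the adjoint is an exact inverse.
#
# Window design: the radial window of each corona rises on
# [rho_{j-1}, rho_j] and falls on [rho_j, rho_{j+1}] with dyadic knots
# rho_j = rho_top * 2^(j - J), i.e. it is supported on (rho_j/2, 2*rho_j) --
# one octave each side of its center. The angular window of a wedge spans
# one wedge spacing each side of its center direction. Rising and falling
# edges are complementary C-infinity steps with squares summing to one.
#
# Wedge counts are a multiple of 4 and double every second scale
# (parabolic scaling); antipodal wedges of a real image carry complex
# conjugate coefficients, which the extraction preserves exactly by
# indexing the antipodal block as the negated partner block.

# C-infinity step pair: .ct_fall() goes 1 -> 0 on [0,1], .ct_rise() is its
# mirror, and .ct_fall(x)^2 + .ct_rise(x)^2 == 1 pointwise.
.ct_fall_raw <- function(x) {
  r <- numeric(length(x))
  r[x <= 0] <- 1
  i <- x > 0 & x < 1
  if (any(i)) r[i] <- exp(1 - 1 / (1 - exp(1 - 1 / x[i])))
  r
}

.ct_fall <- function(x) {
  f <- .ct_fall_raw(x)
  g <- .ct_fall_raw(1 - x)
  f / sqrt(f^2 + g^2)
}

.ct_rise <- function(x) .ct_fall(1 - x)

# Cache of transform plans, keyed by image shape and parameters.
.fdct_cache <- new.env(parent = emptyenv())

# Signed frequency indices of an N-point DFT in "shifted" order
# -floor(N/2) .. ceil(N/2)-1, as a plain ascending integer sequence.
.freq_axis <- function(n) seq.int(-floor(n / 2), ceiling(n / 2) - 1)

#' Default number of curvelet scales for an image size
#'
#' @param n1,n2 image dimensions in pixels.
#' @return integer number of scales, at least 3.
#' @export
fdct_n_scales <- function(n1, n2) {
  max(3L, as.integer(ceiling(log2(min(n1, n2)) - 3)))
}

# Number of wedges per scale: `n_wedges_coarse` at the second-coarsest
# wedge-bearing scale, doubling every second scale. Scale 1 (coarsest) and
# scale J (finest ring) are isotropic.
.wedges_per_scale <- function(n_scales, n_wedges_coarse) {
  w <- integer(n_scales)
  w[1] <- 1L
  if (n_scales >= 3) {
    for (s in 2:(n_scales - 1)) {
      w[s] <- as.integer(n_wedges_coarse * 2^floor((s - 2) / 2))
    }
  }
  w[n_scales] <- 1L
  w
}

# Build (and cache) the transform plan: for every (scale, wedge) the
# bounding frequency block, the window restricted to it, the unshifted FFT
# index vectors, the lattice sign, and the wedge's ridge angle.
.fdct_plan <- function(n1, n2, n_scales, n_wedges_coarse) {
  key <- sprintf("%dx%d_s%d_w%d", n1, n2, n_scales, n_wedges_coarse)
  if (!is.null(.fdct_cache[[key]])) return(.fdct_cache[[key]])

  f1 <- .freq_axis(n1)
  f2 <- .freq_axis(n2)
  a1 <- f1 / n1                      # normalized row frequencies
  a2 <- f2 / n2
  R <- sqrt(outer(a1^2, a2^2, "+"))  # normalized radius, max 1/sqrt(2)
  PHI <- atan2(outer(a1, rep(1, n2)), outer(rep(1, n1), a2))

  rho_top <- 0.48
  rho <- rho_top * 2^(seq_len(n_scales) - n_scales)  # rho[j], j = 1..J

  radial_band <- function(s) {
    if (s == 1) {
      B <- matrix(1, n1, n2)
      i <- R > rho[1]
      B[i] <- .ct_fall((R[i] - rho[1]) / (rho[2] - rho[1]))
      B
    } else if (s == n_scales) {
      B <- matrix(1, n1, n2)
      i <- R < rho[s]
      B[i] <- .ct_rise((R[i] - rho[s - 1]) / (rho[s] - rho[s - 1]))
      B[R <= rho[s - 1]] <- 0
      B
    } else {
      B <- matrix(0, n1, n2)
      i <- R > rho[s - 1] & R <= rho[s]
      B[i] <- .ct_rise((R[i] - rho[s - 1]) / (rho[s] - rho[s - 1]))
      i <- R > rho[s] & R < rho[s + 1]
      B[i] <- .ct_fall((R[i] - rho[s]) / (rho[s + 1] - rho[s]))
      B
    }
  }

  wedges_ct <- .wedges_per_scale(n_scales, n_wedges_coarse)
  support_tol <- 1e-14

  make_block <- function(win_full, sign, ridge_angle, scale, wedge) {
    sup <- which(win_full > support_tol, arr.ind = TRUE)
    i1 <- min(sup[, 1]); i2 <- max(sup[, 1])
    j1 <- min(sup[, 2]); j2 <- max(sup[, 2])
    fr <- f1[i1:i2]           # signed frequency rows of the block
    fc <- f2[j1:j2]
    if (sign < 0) { fr <- -fr; fc <- -fc }
    list(
      scale = scale, wedge = wedge,
      win = win_full[i1:i2, j1:j2, drop = FALSE],
      freq_r = fr, freq_c = fc,       # signed frequencies, extraction order
      idx_r = (fr %% n1) + 1L,        # unshifted FFT array indices
      idx_c = (fc %% n2) + 1L,
      L1 = i2 - i1 + 1L, L2 = j2 - j1 + 1L,
      sign = sign,
      angle_deg = ridge_angle
    )
  }

  blocks <- list()
  for (s in seq_len(n_scales)) {
    B <- radial_band(s)
    W <- wedges_ct[s]
    if (W == 1L) {
      blocks[[length(blocks) + 1L]] <- make_block(B, 1L, NA_real_, s, 1L)
      next
    }
    delta <- 2 * pi / W
    half <- W %/% 2L
    part_block <- vector("list", half)
    for (l in seq_len(half)) {
      phi_l <- (l - 1) * delta
      u <- ((PHI - phi_l + pi) %% (2 * pi) - pi) / delta
      A <- matrix(0, n1, n2)
      i <- u > -1 & u <= 0
      A[i] <- .ct_rise(u[i] + 1)
      i <- u > 0 & u < 1
      A[i] <- .ct_fall(u[i])
      # ridge angle: perpendicular to the wedge's central frequency
      # direction; central direction phi_l has (row, col) components
      # (sin(phi_l), cos(phi_l)), so the spatial ridge angle is
      ridge <- fold_axial(atan2(cos(phi_l), sin(phi_l)) * 180 / pi)
      blk <- make_block(B * A, 1L, ridge, s, l)
      part_block[[l]] <- blk
      blocks[[length(blocks) + 1L]] <- blk
    }
    # Antipodal partners: same window values, frequency block negated
    # element-wise in the same extraction order. This makes antipodal
    # coefficients of a real image exact complex conjugates at mirrored
    # lattice positions.
    for (l in seq_len(half)) {
      p <- part_block[[l]]
      blk <- p
      blk$wedge <- l + half
      blk$sign <- -1L
      blk$freq_r <- -p$freq_r
      blk$freq_c <- -p$freq_c
      blk$idx_r <- (blk$freq_r %% n1) + 1L
      blk$idx_c <- (blk$freq_c %% n2) + 1L
      blocks[[length(blocks) + 1L]] <- blk
    }
  }

  plan <- list(n1 = n1, n2 = n2, n_scales = n_scales,
               n_wedges_coarse = n_wedges_coarse,
               wedges_per_scale = sapply(seq_len(n_scales), function(s) {
                 sum(vapply(blocks, function(b) b$scale == s, logical(1)))
               }),
               blocks = blocks, key = key)
  .fdct_cache[[key]] <- plan
  plan
}

#' Forward fast discrete curvelet transform
#'
#' Decomposes a 2-D grayscale image into complex curvelet coefficients
#' organized by scale and angular wedge. The transform is a tight frame:
#' total coefficient energy equals image energy, and [ifdct()] inverts it
#' exactly (up to floating-point rounding).
#'
#' @param image numeric matrix (2-D grayscale image), minimum dimension 32.
#' @param n_scales number of scales (>= 3); default
#'   `ceil(log2(min(dim)) - 3)` and at least 3.
#' @param n_wedges_second_coarsest wedges at the second-coarsest
#'   wedge-bearing scale; must be a multiple of 4. Default 16.
#' @return an object of class `coef_pyramid`: a list of scales, each a list
#'   of complex coefficient matrices (one per wedge), with metadata
#'   attributes. Scale 1 is the coarsest (isotropic low-pass), the last
#'   scale is an isotropic fine ring; intermediate scales carry wedges.
#' @export
fdct <- function(image, n_scales = NULL, n_wedges_second_coarsest = 16L) {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop("image must be a 2-D numeric matrix")
  }
  n1 <- nrow(image); n2 <- ncol(image)
  if (min(n1, n2) < 32) stop("image too small: minimum dimension is 32")
  if (is.null(n_scales)) n_scales <- fdct_n_scales(n1, n2)
  n_scales <- as.integer(n_scales)
  if (n_scales < 3) stop("n_scales must be at least 3")
  if (n_wedges_second_coarsest %% 4 != 0 || n_wedges_second_coarsest < 8) {
    stop("n_wedges_second_coarsest must be a multiple of 4 (>= 8)")
  }
  plan <- .fdct_plan(n1, n2, n_scales, as.integer(n_wedges_second_coarsest))

  X <- stats::fft(image) / sqrt(n1 * n2)  # unitary forward FFT
  scales <- lapply(seq_len(n_scales), function(s) list())
  for (b in plan$blocks) {
    Y <- X[b$idx_r, b$idx_c, drop = FALSE] * b$win
    coef <- stats::fft(Y, inverse = TRUE) / sqrt(b$L1 * b$L2)
    scales[[b$scale]][[b$wedge]] <- coef
  }
  structure(scales,
            class = "coef_pyramid",
            shape = c(n1, n2),
            n_scales = n_scales,
            n_wedges_coarse = as.integer(n_wedges_second_coarsest),
            plan_key = plan$key)
}

.pyramid_plan <- function(pyramid) {
  sh <- attr(pyramid, "shape")
  .fdct_plan(sh[1], sh[2], attr(pyramid, "n_scales"),
             attr(pyramid, "n_wedges_coarse"))
}

#' Inverse fast discrete curvelet transform
#'
#' Exact inverse of [fdct()] for a full pyramid; for a pyramid with scales
#' or coefficients zeroed out (e.g. after [select_scale()]) it returns the
#' corresponding partial reconstruction.
#'
#' @param pyramid a `coef_pyramid` from [fdct()].
#' @return numeric matrix with the original image shape.
#' @export
ifdct <- function(pyramid) {
  if (!inherits(pyramid, "coef_pyramid")) {
    stop("pyramid must be a coef_pyramid (missing shape metadata)")
  }
  sh <- attr(pyramid, "shape")
  n1 <- sh[1]; n2 <- sh[2]
  plan <- .pyramid_plan(pyramid)
  X <- matrix(0 + 0i, n1, n2)
  for (b in plan$blocks) {
    coef <- pyramid[[b$scale]][[b$wedge]]
    Y <- stats::fft(coef) / sqrt(b$L1 * b$L2)
    X[b$idx_r, b$idx_c] <- X[b$idx_r, b$idx_c] + Y * b$win
  }
  Re(stats::fft(X, inverse = TRUE)) / sqrt(n1 * n2)
}

#' Total coefficient energy of a pyramid
#'
#' @param pyramid a `coef_pyramid`.
#' @return sum of squared coefficient magnitudes.
#' @export
pyramid_energy <- function(pyramid) {
  sum(vapply(pyramid, function(s) {
    sum(vapply(s, function(w) sum(Mod(w)^2), numeric(1)))
  }, numeric(1)))
}

# Resolve a scale selector ("second_finest", "finest", "coarsest" or an
# integer index) against a pyramid.
.resolve_scale <- function(pyramid, which) {
  J <- attr(pyramid, "n_scales")
  if (is.character(which)) {
    which <- match.arg(which, c("second_finest", "finest", "coarsest"))
    s <- switch(which, second_finest = J - 1L, finest = J, coarsest = 1L)
  } else {
    s <- as.integer(which)
  }
  if (s < 1 || s > J) stop("scale selector out of range: ", s)
  s
}

#' Restrict a pyramid to one scale
#'
#' Returns a pyramid whose coefficients outside the selected scale are set
#' to zero. The default selects the second-finest scale, the scale at which
#' oriented edge content is analyzed. Idempotent.
#'
#' @param pyramid a `coef_pyramid`.
#' @param which scale selector: `"second_finest"` (default), `"finest"`,
#'   `"coarsest"`, or an integer scale index (1 = coarsest).
#' @return a `coef_pyramid` of the same shape.
#' @export
select_scale <- function(pyramid, which = "second_finest") {
  s <- .resolve_scale(pyramid, which)
  out <- pyramid
  for (j in seq_along(out)) {
    if (j != s) {
      out[[j]] <- lapply(out[[j]], function(w) w * 0)
    }
  }
  attr(out, "selected_scale") <- s
  out
}

# Spatial lattice of a wedge block: coefficient (k1, k2) (0-based indices
# into the block matrix) sits at image position (sign*k*N/L mod N) + 1.
.block_centers <- function(b, n1, n2) {
  k1 <- seq_len(b$L1) - 1L
  k2 <- seq_len(b$L2) - 1L
  rows <- ((b$sign * k1 * n1 / b$L1) %% n1) + 1
  cols <- ((b$sign * k2 * n2 / b$L2) %% n2) + 1
  list(rows = rows, cols = cols)
}

#' Image-space geometry of one curvelet coefficient
#'
#' Maps a coefficient index (scale, wedge, lattice position) to its spatial
#' center in image coordinates and its axial ridge orientation. The ridge
#' angle is perpendicular to the wedge's central frequency direction,
#' folded into `[0, 180)`; the isotropic coarsest/finest scales have `NA`
#' angle.
#'
#' @param index list with fields `scale`, `wedge`, `k1`, `k2` (`k1`, `k2`
#'   are 0-based lattice indices).
#' @param pyramid a `coef_pyramid`.
#' @return one-row data frame with `center_row`, `center_col` (pixels,
#'   1-based), `angle_deg`, `magnitude`, `scale`, `wedge`, `k1`, `k2`.
#' @export
curvelet_geometry <- function(index, pyramid) {
  plan <- .pyramid_plan(pyramid)
  sh <- attr(pyramid, "shape")
  b <- Find(function(bb) bb$scale == index$scale && bb$wedge == index$wedge,
            plan$blocks)
  if (is.null(b)) stop("no such (scale, wedge) in pyramid")
  if (index$k1 < 0 || index$k1 >= b$L1 || index$k2 < 0 || index$k2 >= b$L2) {
    stop("lattice position out of range")
  }
  ctr <- .block_centers(b, sh[1], sh[2])
  mag <- Mod(pyramid[[b$scale]][[b$wedge]][index$k1 + 1L, index$k2 + 1L])
  data.frame(center_row = ctr$rows[index$k1 + 1L],
             center_col = ctr$cols[index$k2 + 1L],
             angle_deg = b$angle_deg,
             magnitude = mag,
             scale = b$scale, wedge = b$wedge,
             k1 = index$k1, k2 = index$k2)
}

#' Keep the largest coefficients at one scale
#'
#' Selects the `keep_fraction` largest-magnitude coefficients at the
#' pyramid's selected scale (typically after [select_scale()]) and returns
#' them as curvelets with image-space geometry attached. Exactly
#' `ceil(keep_fraction * N)` coefficients are returned, where `N` is the
#' total number of coefficients at the scale, except that exact-zero
#' coefficients are never returned (a blank scale yields an empty table).
#' Ties in magnitude are broken by (wedge, k1, k2) lexicographic order for
#' cross-platform determinism.
#'
#' @param pyramid a `coef_pyramid` restricted to one scale.
#' @param keep_fraction fraction of coefficients to keep, in (0, 1].
#' @param scale optional explicit scale index; default: the scale recorded
#'   by [select_scale()], or the unique nonzero scale.
#' @return data frame of curvelets ordered by decreasing magnitude with
#'   columns `center_row`, `center_col`, `angle_deg`, `magnitude`, `scale`,
#'   `wedge`, `k1`, `k2`.
#' @export
threshold_top_fraction <- function(pyramid, keep_fraction, scale = NULL) {
  if (!is.numeric(keep_fraction) || keep_fraction <= 0 || keep_fraction > 1) {
    stop("keep_fraction must lie in (0, 1]")
  }
  if (is.null(scale)) scale <- attr(pyramid, "selected_scale")
  if (is.null(scale)) {
    nz <- which(vapply(pyramid, function(s) {
      any(vapply(s, function(w) any(w != 0), logical(1)))
    }, logical(1)))
    if (length(nz) != 1) {
      stop("pyramid is not restricted to one scale; call select_scale() ",
           "first or pass `scale`")
    }
    scale <- nz
  }
  s <- .resolve_scale(pyramid, scale)
  plan <- .pyramid_plan(pyramid)
  sh <- attr(pyramid, "shape")
  blocks <- Filter(function(b) b$scale == s, plan$blocks)

  tabs <- lapply(blocks, function(b) {
    coef <- pyramid[[b$scale]][[b$wedge]]
    ctr <- .block_centers(b, sh[1], sh[2])
    k1 <- rep(seq_len(b$L1) - 1L, times = b$L2)
    k2 <- rep(seq_len(b$L2) - 1L, each = b$L1)
    data.frame(center_row = rep(ctr$rows, times = b$L2),
               center_col = rep(ctr$cols, each = b$L1),
               angle_deg = b$angle_deg,
               magnitude = as.vector(Mod(coef)),
               scale = s, wedge = b$wedge, k1 = k1, k2 = k2)
  })
  tab <- do.call(rbind, tabs)
  n_total <- nrow(tab)
  n_keep <- min(ceiling(keep_fraction * n_total), sum(tab$magnitude > 0))
  if (n_keep == 0) return(tab[0, ])
  ord <- order(-tab$magnitude, tab$wedge, tab$k1, tab$k2)
  out <- tab[ord[seq_len(n_keep)], ]
  rownames(out) <- NULL
  out
}
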