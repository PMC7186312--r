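# Synthetic fiber image generator with per-fiber ground truth.
#
# Fibers are built from user-specified distributions of length, starting
# width and straightness. End-to-end directions are drawn from an axial
# von Mises model and then calibrated so that every generated image's
# fiber population has exactly the requested mean orientation and
# alignment coefficient. Paths between the two endpoints are constructed
# by recursive bridging: the midpoint of a gap of m segments is sampled
# uniformly from the intersection of the two regions reachable in
# ceil(m/2) and floor(m/2) exact-length steps from the current endpoints,
# and the process recurses until every segment is determined. Segment
# lengths are exact, so contour length equals n_segments * segment_length
# and the chord length divided by the contour length equals the drawn
# straightness by construction. Optional smoothing (bubble, swap, spline)
# and rendering degradations (rescale, downsample, blur, noise, distance
# filter, threshold, normalize) mimic real micrographs.

# --- distributions -------------------------------------------------------

#' Distribution specification for fiber properties
#'
#' @param kind `"gaussian"`, `"uniform"` or `"piecewise_linear"`.
#' @param mean,sd Gaussian parameters; `sd = 0` is allowed and gives a
#'   point mass at `mean`.
#' @param min,max uniform bounds (`min < max`).
#' @param x,y knots of a piecewise linear density: `x` strictly
#'   increasing, `y` nonnegative with positive total area.
#' @return an object of class `dist_spec`.
#' @export
dist_spec <- function(kind = c("gaussian", "uniform", "piecewise_linear"),
                      mean = NULL, sd = NULL, min = NULL, max = NULL,
                      x = NULL, y = NULL) {
  kind <- match.arg(kind)
  spec <- switch(kind,
    gaussian = {
      if (is.null(mean) || is.null(sd)) stop("gaussian needs mean and sd")
      if (sd < 0) stop("sd must be >= 0")
      list(kind = kind, mean = mean, sd = sd)
    },
    uniform = {
      if (is.null(min) || is.null(max)) stop("uniform needs min and max")
      if (min >= max) stop("uniform requires min < max")
      list(kind = kind, min = min, max = max)
    },
    piecewise_linear = {
      if (is.null(x) || is.null(y)) stop("piecewise_linear needs x and y")
      if (length(x) != length(y) || length(x) < 2) {
        stop("piecewise_linear needs matching x, y with >= 2 knots")
      }
      if (any(diff(x) <= 0)) stop("knot x values must be strictly increasing")
      if (any(y < 0)) stop("density values must be nonnegative")
      area <- sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
      if (area <= 0) stop("piecewise density must have positive area")
      list(kind = kind, x = x, y = y)
    })
  class(spec) <- "dist_spec"
  spec
}

#' Draw samples from a `dist_spec`
#'
#' @param spec a [dist_spec()].
#' @param n number of draws.
#' @return numeric vector of length `n`.
#' @export
draw_dist <- function(spec, n) {
  if (!inherits(spec, "dist_spec")) stop("spec must be a dist_spec")
  switch(spec$kind,
    gaussian = if (spec$sd == 0) rep(spec$mean, n) else
      stats::rnorm(n, spec$mean, spec$sd),
    uniform = stats::runif(n, spec$min, spec$max),
    piecewise_linear = .draw_piecewise(spec, n))
}

# Inverse-CDF sampling of a piecewise linear density.
.draw_piecewise <- function(spec, n) {
  x <- spec$x; y <- spec$y
  seg_area <- diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2
  cum <- c(0, cumsum(seg_area))
  total <- cum[length(cum)]
  u <- stats::runif(n) * total
  seg <- findInterval(u, cum, rightmost.closed = TRUE)
  seg <- pmin(pmax(seg, 1L), length(seg_area))
  res <- numeric(n)
  for (i in seq_len(n)) {
    s <- seg[i]
    a <- u[i] - cum[s]                     # area to cover inside segment s
    x0 <- x[s]; x1 <- x[s + 1]; y0 <- y[s]; y1 <- y[s + 1]
    w <- x1 - x0
    slope <- (y1 - y0) / w
    if (abs(slope) < 1e-12) {
      res[i] <- x0 + if (y0 > 0) a / y0 else w / 2
    } else {
      # solve y0*t + slope*t^2/2 = a for t in [0, w]
      disc <- y0^2 + 2 * slope * a
      t <- (-y0 + sqrt(max(disc, 0))) / slope
      res[i] <- x0 + clamp(t, 0, w)
    }
  }
  res
}

# --- generator configuration --------------------------------------------

#' Synthetic fiber generator configuration
#'
#' All user-tunable parameters of the generator. Lengths and widths are in
#' pixels, angles in degrees (axial convention). The smoothing defaults
#' (one bubble pass, swap rate 1, spline ratio 2) are applied in the order
#' bubble, swap, spline. Rendering operations are applied, each only if
#' enabled, in the order rescale, downsample, blur, noise, distance
#' filter, threshold, normalize.
#'
#' @param image_width,image_height canvas size in pixels.
#' @param n_images number of images in a dataset.
#' @param n_fibers fibers per image.
#' @param mean_angle_deg population mean orientation, degrees in `[0,180)`.
#' @param alignment target alignment coefficient in `[0, 1]`; each image's
#'   fiber directions are calibrated so the sample alignment matches it
#'   exactly (targets below 0.02 fall back to uniform directions).
#' @param length,width,straightness [dist_spec()] objects for the drawn
#'   fiber properties; straightness draws are clipped to `(0, 1]`.
#' @param segment_length_px length of each fiber segment, pixels.
#' @param width_change_px maximum per-segment width delta, pixels.
#' @param edge_buffer_px margin that no fiber vertex may enter.
#' @param bubble_passes,swap_rate,spline_ratio smoothing parameters; a
#'   value of 0 disables the corresponding method (`spline_ratio` 0 or 1
#'   disables resampling).
#' @param rescale intensity scale factor (`NULL` disables).
#' @param downsample integer pooling factor (`NULL`/1 disables).
#' @param blur_sigma Gaussian blur sigma in pixels (0 disables).
#' @param noise_level background mean count for Poisson noise (0 disables);
#'   with `noise_model = "gaussian"` it is the additive noise sd instead.
#' @param noise_model `"poisson"` (photon-count-like) or `"gaussian"`.
#' @param distance_falloff exponent of the distance filter (0 disables).
#' @param threshold intensity cutoff; pixels below are zeroed (0 disables).
#' @param normalize logical; stretch the final image to `[0, 255]`.
#' @param seed integer RNG seed; image `i` of a dataset uses a seed derived
#'   deterministically from (`seed`, `i`).
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(image_width = 512, image_height = 512,
                             n_images = 1, n_fibers = 30,
                             mean_angle_deg = 90, alignment = 0.2,
                             length = dist_spec("gaussian", mean = 60, sd = 0),
                             width = dist_spec("gaussian", mean = 5, sd = 0),
                             straightness = dist_spec("gaussian", mean = 1, sd = 0),
                             segment_length_px = 4,
                             width_change_px = 0.2,
                             edge_buffer_px = 10,
                             bubble_passes = 1, swap_rate = 1,
                             spline_ratio = 2,
                             rescale = NULL, downsample = NULL,
                             blur_sigma = 0, noise_level = 0,
                             noise_model = c("poisson", "gaussian"),
                             distance_falloff = 0, threshold = 0,
                             normalize = FALSE, seed = 1L) {
  noise_model <- match.arg(noise_model)
  if (alignment < 0 || alignment > 1) stop("alignment must lie in [0, 1]")
  if (edge_buffer_px < 0 ||
      2 * edge_buffer_px >= min(image_width, image_height)) {
    stop("edge buffer must be nonnegative and smaller than half the image")
  }
  if (segment_length_px <= 0) stop("segment_length_px must be positive")
  cfg <- list(image_width = image_width, image_height = image_height,
              n_images = n_images, n_fibers = n_fibers,
              mean_angle_deg = fold_axial(mean_angle_deg),
              alignment = alignment,
              length = length, width = width, straightness = straightness,
              segment_length_px = segment_length_px,
              width_change_px = width_change_px,
              edge_buffer_px = edge_buffer_px,
              bubble_passes = bubble_passes, swap_rate = swap_rate,
              spline_ratio = spline_ratio,
              rescale = rescale, downsample = downsample,
              blur_sigma = blur_sigma, noise_level = noise_level,
              noise_model = noise_model,
              distance_falloff = distance_falloff, threshold = threshold,
              normalize = normalize, seed = as.integer(seed))
  class(cfg) <- "generator_config"
  cfg
}

#' Validation presets: straight and curvy fiber datasets
#'
#' The packaged validation conditions: 512 x 512 images of 30 fibers with
#' mean angle 90 degrees, alignment coefficient 0.2, fiber length 60 px,
#' width 5.0 px, edge buffer 10 px, Poisson noise with background level 50,
#' all three smoothing methods at their defaults, and straightness 1
#' (straight preset) or 0.92 (curvy preset).
#'
#' @param n_images number of images.
#' @param seed RNG seed.
#' @return a [generator_config()].
#' @export
straight_validation_config <- function(n_images = 100, seed = 1L) {
  generator_config(n_images = n_images, noise_level = 50, seed = seed)
}

#' @rdname straight_validation_config
#' @export
curvy_validation_config <- function(n_images = 100, seed = 1L) {
  generator_config(n_images = n_images, noise_level = 50,
                   straightness = dist_spec("gaussian", mean = 0.92, sd = 0),
                   seed = seed)
}

# --- population sampling -------------------------------------------------

#' Sample a fiber population for one image
#'
#' Draws lengths, widths and straightness i.i.d. from their distributions
#' (truncated to positive values; straightness clipped to (0, 1]) and
#' directions from an axial von Mises distribution whose concentration
#' matches the target alignment. The drawn directions are then calibrated
#' (deviations scaled about the sample mean and recentered) so that the
#' sample's axial mean equals `mean_angle_deg` and its alignment equals
#' the target exactly.
#'
#' @param config a [generator_config()].
#' @param n number of fibers (default `config$n_fibers`).
#' @return data frame with columns `length`, `width`, `straightness`,
#'   `direction_deg`.
#' @export
sample_fiber_population <- function(config, n = config$n_fibers) {
  draw_pos <- function(spec, n, lo = 1e-6) {
    v <- draw_dist(spec, n)
    for (k in 1:50) {
      bad <- v <= lo
      if (!any(bad)) break
      v[bad] <- draw_dist(spec, sum(bad))
    }
    pmax(v, lo)
  }
  len <- draw_pos(config$length, n, lo = config$segment_length_px / 2)
  wid <- draw_pos(config$width, n, lo = 0.5)
  str <- clamp(draw_pos(config$straightness, n), 1e-3, 1)
  dir <- .sample_directions(n, config$mean_angle_deg, config$alignment)
  data.frame(length = len, width = wid, straightness = str,
             direction_deg = dir)
}

# Axial direction sampler with exact sample-level calibration.
.sample_directions <- function(n, mean_deg, align) {
  mu2 <- 2 * mean_deg * pi / 180
  if (align >= 1) return(rep(fold_axial(mean_deg), n))
  if (align < 0.02 || n < 2) {
    # targets indistinguishable from isotropy: plain uniform draws
    return(fold_axial(stats::runif(n, 0, 180)))
  }
  kappa <- vm_concentration(align)
  phi <- rvonmises(n, mu2, kappa)          # doubled angles
  m <- atan2(mean(sin(phi)), mean(cos(phi)))
  delta <- (phi - m + pi) %% (2 * pi) - pi # deviations about sample mean
  resultant <- function(s) {
    Mod(mean(exp(1i * s * delta)))
  }
  # R(0) = 1 and R oscillates as s grows: scan a fine grid for the first
  # crossing below the target, then refine with uniroot
  s_grid <- seq(0, 256, length.out = 8193)
  vals <- vapply(s_grid, resultant, numeric(1))
  k <- which(vals <= align)[1]
  s <- if (is.na(k)) {
    s_grid[which.min(vals)]   # degenerate sample: best reachable
  } else if (k == 1) {
    0
  } else {
    stats::uniroot(function(s) resultant(s) - align,
                   c(s_grid[k - 1], s_grid[k]), tol = 1e-12)$root
  }
  phi2 <- s * delta + mu2
  m2 <- atan2(mean(sin(phi2)), mean(cos(phi2)))
  phi3 <- phi2 + (mu2 - m2)                # exact mean, alignment unchanged
  fold_axial(phi3 / 2 * 180 / pi)
}

# --- recursive bridging --------------------------------------------------

#' Build a fiber path by recursive disk-intersection bridging
#'
#' Constructs a path of `n_segments` segments of exact length `seg_len`
#' between two fixed endpoints. The midpoint of a gap of `m` segments is
#' sampled uniformly from the intersection of the regions reachable in
#' `ceil(m/2)` and `floor(m/2)` steps from its endpoints (disks for two or
#' more steps, circles for exactly one), and the construction recurses
#' until all vertices are placed.
#'
#' @param start,end numeric `c(row, col)` endpoints.
#' @param n_segments number of segments (>= 1).
#' @param seg_len exact segment length in pixels.
#' @return matrix of `n_segments + 1` vertices (columns `row`, `col`).
#' @export
bridge_path <- function(start, end, n_segments, seg_len) {
  d <- sqrt(sum((end - start)^2))
  if (d > n_segments * seg_len + 1e-9) {
    stop("endpoints not reachable: distance exceeds n_segments * seg_len")
  }
  if (n_segments == 1 && abs(d - seg_len) > 1e-6) {
    stop("a single segment requires the endpoints to be seg_len apart")
  }
  mids <- .bridge(start, end, n_segments, seg_len)
  path <- do.call(rbind, c(list(start), mids, list(end)))
  dimnames(path) <- list(NULL, c("row", "col"))
  path
}

.bridge <- function(p, q, m, L) {
  if (m <= 1) return(list())
  ml <- ceiling(m / 2)
  mr <- floor(m / 2)
  M <- .sample_midpoint(p, q, ml, mr, L)
  c(.bridge(p, M, ml, L), list(M), .bridge(M, q, mr, L))
}

.sample_midpoint <- function(p, q, ml, mr, L) {
  d <- sqrt(sum((q - p)^2))
  u <- if (d > 1e-12) (q - p) / d else c(1, 0)
  perp <- c(-u[2], u[1])
  if (ml >= 2 && mr >= 2) {
    R1 <- ml * L; R2 <- mr * L
    if (d >= R1 + R2 - 1e-9) {
      return(p + u * R1 * d / (R1 + R2))   # degenerate lens: touching point
    }
    # uniform rejection from the bounding box of the lens
    lo <- pmax(p - R1, q - R2)
    hi <- pmin(p + R1, q + R2)
    for (it in 1:10000) {
      M <- c(stats::runif(1, lo[1], hi[1]), stats::runif(1, lo[2], hi[2]))
      if (sum((M - p)^2) <= R1^2 && sum((M - q)^2) <= R2^2) return(M)
    }
    return((p + q) / 2)
  }
  if (ml == 1 && mr == 1) {
    # two circles of radius L: at most two intersection points
    h2 <- L^2 - (d / 2)^2
    h <- sqrt(max(h2, 0))
    side <- if (stats::runif(1) < 0.5) 1 else -1
    return((p + q) / 2 + side * h * perp)
  }
  # ml == 2, mr == 1 (m == 3): M on the circle of radius L around q,
  # constrained to the disk of radius 2L around p
  cos_lim <- (d^2 + L^2 - (2 * L)^2) / (2 * d * L)
  alpha <- acos(clamp(cos_lim, -1, 1))
  gamma <- stats::runif(1, -alpha, alpha)
  dir_pq <- -u                              # from q toward p
  rot <- c(cos(gamma) * dir_pq[1] - sin(gamma) * dir_pq[2],
           sin(gamma) * dir_pq[1] + cos(gamma) * dir_pq[2])
  q + L * rot
}

# --- width variation -----------------------------------------------------

#' Per-segment width sequence
#'
#' The width changes from segment to segment by a uniformly distributed
#' delta in `[-max_delta, +max_delta]`, floored at 0.5 px.
#'
#' @param start_width starting width in pixels (> 0).
#' @param n_segments number of segments.
#' @param max_delta maximum absolute per-segment change, pixels.
#' @return numeric vector of `n_segments` widths.
#' @export
vary_width <- function(start_width, n_segments, max_delta) {
  if (start_width <= 0) stop("start_width must be positive")
  w <- numeric(n_segments)
  w[1] <- max(start_width, 0.5)
  if (n_segments > 1) {
    for (i in 2:n_segments) {
      w[i] <- max(0.5, w[i - 1] + stats::runif(1, -max_delta, max_delta))
    }
  }
  w
}

# --- smoothing -----------------------------------------------------------

#' Smooth a fiber path
#'
#' Three methods, all preserving the endpoints exactly:
#' * `bubble`: sweeps over the path and swaps adjacent segment displacement
#'   vectors whenever the swap reduces the total turning angle at the
#'   affected joints (`passes` sweeps). Preserves the multiset of segment
#'   vectors, hence contour length and the end-to-end vector.
#' * `swap`: performs `rate * n_segments` random transpositions of segment
#'   displacement vectors. Same invariants as bubble.
#' * `spline`: fits interpolating cubic splines to the vertices
#'   (chord-length parameterization) and resamples to
#'   `ratio * n_points` points.
#'
#' @param path vertex matrix (columns row, col), at least 3 vertices.
#' @param method `"bubble"`, `"swap"` or `"spline"`.
#' @param passes bubble sweeps.
#' @param rate average swaps per segment.
#' @param ratio spline resampling ratio (> 0).
#' @return smoothed vertex matrix.
#' @export
smooth_path <- function(path, method = c("bubble", "swap", "spline"),
                        passes = 1, rate = 1, ratio = 2) {
  method <- match.arg(method)
  if (nrow(path) < 3) stop("path must have at least 3 vertices")
  switch(method,
    bubble = .smooth_bubble(path, passes),
    swap = .smooth_swap(path, rate),
    spline = .smooth_spline(path, ratio))
}

.segs <- function(path) diff(path)

.rebuild <- function(start, segs) {
  out <- apply(rbind(start, segs), 2, cumsum)
  dimnames(out) <- list(NULL, c("row", "col"))
  out
}

.turn_cost <- function(a, b) {
  # angle between consecutive segment vectors, radians in [0, pi]
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na < 1e-12 || nb < 1e-12) return(0)
  acos(clamp(sum(a * b) / (na * nb), -1, 1))
}

.smooth_bubble <- function(path, passes) {
  if (passes < 1) return(path)
  s <- .segs(path)
  m <- nrow(s)
  for (p in seq_len(passes)) {
    if (m < 2) break
    for (i in seq_len(m - 1)) {
      before <- 0; after <- 0
      if (i > 1) {
        before <- before + .turn_cost(s[i - 1, ], s[i, ])
        after <- after + .turn_cost(s[i - 1, ], s[i + 1, ])
      }
      if (i + 2 <= m) {
        before <- before + .turn_cost(s[i + 1, ], s[i + 2, ])
        after <- after + .turn_cost(s[i, ], s[i + 2, ])
      }
      if (after < before - 1e-12) {
        tmp <- s[i, ]; s[i, ] <- s[i + 1, ]; s[i + 1, ] <- tmp
      }
    }
  }
  .rebuild(path[1, ], s)
}

.smooth_swap <- function(path, rate) {
  s <- .segs(path)
  m <- nrow(s)
  n_swaps <- round(rate * m)
  if (m >= 2 && n_swaps > 0) {
    for (k in seq_len(n_swaps)) {
      ij <- sample.int(m, 2)
      tmp <- s[ij[1], ]; s[ij[1], ] <- s[ij[2], ]; s[ij[2], ] <- tmp
    }
  }
  .rebuild(path[1, ], s)
}

.smooth_spline <- function(path, ratio) {
  if (ratio <= 0) stop("spline ratio must be positive")
  n_new <- max(3, round(ratio * nrow(path)))
  t <- c(0, cumsum(sqrt(rowSums(.segs(path)^2))))
  tt <- seq(0, t[length(t)], length.out = n_new)
  fr <- stats::splinefun(t, path[, 1], method = "natural")
  fc <- stats::splinefun(t, path[, 2], method = "natural")
  out <- cbind(row = fr(tt), col = fc(tt))
  out[1, ] <- path[1, ]
  out[n_new, ] <- path[nrow(path), ]
  out
}

# --- fiber construction --------------------------------------------------

# Measure ground truth from a vertex chain.
.measure_path <- function(path, widths) {
  seg_len <- sqrt(rowSums(.segs(path)^2))
  len <- sum(seg_len)
  ee <- path[nrow(path), ] - path[1, ]
  ee_d <- sqrt(sum(ee^2))
  list(length = len,
       width = mean(widths),
       straightness = if (len > 0) min(ee_d / len, 1) else 1,
       angle_deg = axial_angle_deg(ee[1], ee[2]),
       n_vertices = nrow(path))
}

#' Generate the fibers of one synthetic image
#'
#' Samples the population, builds each fiber by recursive bridging, applies
#' the configured smoothing methods, and returns both the fiber geometry
#' and the per-fiber ground-truth table (measured from the final vertices,
#' so the stored length/straightness/angle are exactly self-consistent).
#'
#' @param config a [generator_config()].
#' @param image_index 1-based image index; combined with `config$seed` to
#'   seed this image's RNG stream deterministically.
#' @return list with `fibers` (list of `list(vertices, widths)`) and
#'   `table` (ground-truth data frame with columns `fiber`, `length`,
#'   `width`, `straightness`, `angle_deg`, `n_vertices`).
#' @export
generate_fibers <- function(config, image_index = 1) {
  set.seed(stable_seed(config$seed, paste0("image", image_index)))
  pop <- sample_fiber_population(config)
  L <- config$segment_length_px
  buf <- config$edge_buffer_px
  lo <- c(buf, buf)
  hi <- c(config$image_height - buf, config$image_width - buf)
  fibers <- vector("list", nrow(pop))
  rows <- vector("list", nrow(pop))
  for (i in seq_len(nrow(pop))) {
    n_seg <- max(1, round(pop$length[i] / L))
    contour <- n_seg * L
    chord <- pop$straightness[i] * contour
    if (n_seg == 1) chord <- contour
    dirv <- axial_dir(pop$direction_deg[i])
    path <- NULL
    for (try in 1:100) {
      ctr <- c(stats::runif(1, lo[1], hi[1]), stats::runif(1, lo[2], hi[2]))
      p0 <- ctr - dirv * chord / 2
      p1 <- ctr + dirv * chord / 2
      if (any(p0 < lo) || any(p0 > hi) || any(p1 < lo) || any(p1 > hi)) next
      cand <- bridge_path(p0, p1, n_seg, L)
      if (all(cand[, 1] >= lo[1]) && all(cand[, 1] <= hi[1]) &&
          all(cand[, 2] >= lo[2]) && all(cand[, 2] <= hi[2])) {
        path <- cand
        break
      }
    }
    if (is.null(path)) {
      ctr <- (lo + hi) / 2
      path <- bridge_path(ctr - dirv * chord / 2, ctr + dirv * chord / 2,
                          n_seg, L)
      path[, 1] <- clamp(path[, 1], lo[1], hi[1])
      path[, 2] <- clamp(path[, 2], lo[2], hi[2])
    }
    widths <- vary_width(pop$width[i], n_seg, config$width_change_px)
    if (nrow(path) >= 3) {
      if (config$bubble_passes > 0) {
        path <- .smooth_bubble(path, config$bubble_passes)
      }
      if (config$swap_rate > 0) path <- .smooth_swap(path, config$swap_rate)
      if (config$spline_ratio > 0 && config$spline_ratio != 1) {
        path <- .smooth_spline(path, config$spline_ratio)
        widths <- stats::approx(seq_along(widths), widths,
                                xout = seq(1, length(widths),
                                           length.out = nrow(path) - 1),
                                rule = 2)$y
      }
      path[, 1] <- clamp(path[, 1], lo[1], hi[1])
      path[, 2] <- clamp(path[, 2], lo[2], hi[2])
    }
    gt <- .measure_path(path, widths)
    fibers[[i]] <- list(vertices = path, widths = widths)
    rows[[i]] <- data.frame(fiber = i, length = gt$length, width = gt$width,
                            straightness = gt$straightness,
                            angle_deg = gt$angle_deg,
                            n_vertices = gt$n_vertices)
  }
  list(fibers = fibers, table = do.call(rbind, rows))
}

# --- rendering -----------------------------------------------------------

# Stamp one segment as a line dilated to its width (foreground 255).
.stamp_segment <- function(img, p0, p1, width) {
  half <- max(width / 2, 0.5)
  n1 <- nrow(img); n2 <- ncol(img)
  r0 <- max(1L, floor(min(p0[1], p1[1]) - half))
  r1 <- min(n1, ceiling(max(p0[1], p1[1]) + half))
  c0 <- max(1L, floor(min(p0[2], p1[2]) - half))
  c1 <- min(n2, ceiling(max(p0[2], p1[2]) + half))
  if (r0 > r1 || c0 > c1) return(img)
  rr <- r0:r1; cc <- c0:c1
  R <- matrix(rr, length(rr), length(cc))
  C <- matrix(cc, length(rr), length(cc), byrow = TRUE)
  v <- p1 - p0
  vv <- sum(v^2)
  if (vv < 1e-12) {
    D2 <- (R - p0[1])^2 + (C - p0[2])^2
  } else {
    t <- clamp(((R - p0[1]) * v[1] + (C - p0[2]) * v[2]) / vv, 0, 1)
    D2 <- (R - (p0[1] + t * v[1]))^2 + (C - (p0[2] + t * v[2]))^2
  }
  sub <- img[rr, cc]
  sub[D2 <= half^2] <- 255
  img[rr, cc] <- sub
  img
}

#' Render fibers into an image
#'
#' Stamps every fiber segment as a line dilated to its width (foreground
#' 255, background 0, 8-bit scale), then applies the enabled rendering
#' operations in order: rescale, downsample (mean pooling), Gaussian blur,
#' noise, distance filter, threshold, normalize. With Poisson noise the
#' pixel value is replaced by a Poisson draw with mean
#' `intensity + noise_level`, clipped to `[0, 255]`, so the background mean
#' equals `noise_level`.
#'
#' @param fibers fiber list from [generate_fibers()].
#' @param config a [generator_config()].
#' @return numeric matrix (image on the 0-255 scale).
#' @export
render_fibers <- function(fibers, config) {
  img <- matrix(0, config$image_height, config$image_width)
  for (f in fibers) {
    v <- f$vertices
    for (i in seq_len(nrow(v) - 1)) {
      w <- f$widths[min(i, length(f$widths))]
      img <- .stamp_segment(img, v[i, ], v[i + 1, ], w)
    }
  }
  if (!is.null(config$rescale)) {
    img <- clamp(img * config$rescale, 0, 255)
  }
  if (!is.null(config$downsample) && config$downsample > 1) {
    k <- as.integer(config$downsample)
    n1 <- (nrow(img) %/% k) * k; n2 <- (ncol(img) %/% k) * k
    img <- img[seq_len(n1), seq_len(n2)]
    img <- .mean_pool(img, k)
  }
  if (config$blur_sigma > 0) {
    img <- .gauss_blur(img, config$blur_sigma)
  }
  if (config$noise_level > 0) {
    if (config$noise_model == "poisson") {
      img <- matrix(stats::rpois(length(img), lambda = img + config$noise_level),
                    nrow(img), ncol(img))
    } else {
      img <- img + stats::rnorm(length(img), 0, config$noise_level)
    }
    img <- clamp(img, 0, 255)
  }
  if (config$distance_falloff > 0) {
    dm <- binarize_and_distance(img, 0)$distance
    mx <- max(dm)
    if (mx > 0) img <- img * (dm / mx)^config$distance_falloff
  }
  if (config$threshold > 0) {
    img[img < config$threshold] <- 0
  }
  if (isTRUE(config$normalize)) {
    rng <- range(img)
    if (diff(rng) > 0) img <- (img - rng[1]) / diff(rng) * 255
  }
  img
}

.mean_pool <- function(img, k) {
  n1 <- nrow(img) %/% k; n2 <- ncol(img) %/% k
  dim(img) <- c(k, n1, k, n2)
  apply(img, c(2, 4), mean)
}

.gauss_blur <- function(img, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  kx <- stats::dnorm(-r:r, sd = sigma)
  kx <- kx / sum(kx)
  pad <- function(m, r) {
    m[c(rep(1, r), seq_len(nrow(m)), rep(nrow(m), r)), ]
  }
  conv_rows <- function(m) {
    mp <- pad(m, r)
    out <- matrix(0, nrow(m), ncol(m))
    for (s in -r:r) {
      out <- out + kx[s + r + 1] * mp[(r + 1 + s):(r + nrow(m) + s), ]
    }
    out
  }
  t(conv_rows(t(conv_rows(img))))
}

#' Generate a synthetic dataset
#'
#' Produces `config$n_images` images and their ground-truth tables. Fully
#' deterministic for a given config (each image derives its own RNG stream
#' from `config$seed` and the image index, so results do not depend on
#' evaluation order).
#'
#' @param config a [generator_config()].
#' @param out_dir optional output directory; if given, each image is
#'   written as an 8-bit TIFF (`image_###.tif`) with a ground-truth CSV
#'   (`image_###_truth.csv`), plus a dataset-level `truth_summary.csv`.
#' @param render logical; `FALSE` skips image rendering (ground truth only).
#' @return list with `images` (list of matrices or `NULL`s),
#'   `ground_truth` (combined data frame with an `image` column), and
#'   `summary` (per-image means).
#' @export
generate_dataset <- function(config, out_dir = NULL, render = TRUE) {
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  images <- vector("list", config$n_images)
  tabs <- vector("list", config$n_images)
  for (i in seq_len(config$n_images)) {
    gen <- generate_fibers(config, i)
    tab <- gen$table
    tab$image <- i
    tabs[[i]] <- tab[, c("image", setdiff(names(tab), "image"))]
    if (render) {
      images[[i]] <- render_fibers(gen$fibers, config)
      if (!is.null(out_dir)) {
        write_gray_tiff(images[[i]],
                        file.path(out_dir, sprintf("image_%03d.tif", i)))
        utils::write.csv(tabs[[i]],
                         file.path(out_dir, sprintf("image_%03d_truth.csv", i)),
                         row.names = FALSE)
      }
    }
  }
  gt <- do.call(rbind, tabs)
  summ <- do.call(rbind, lapply(split(gt, gt$image), function(d) {
    data.frame(image = d$image[1], n_fibers = nrow(d),
               mean_length = mean(d$length), mean_width = mean(d$width),
               mean_straightness = mean(d$straightness),
               mean_angle_deg = axial_mean(d$angle_deg, d$length),
               alignment = alignment(d$angle_deg))
  }))
  rownames(summ) <- NULL
  if (!is.null(out_dir)) {
    utils::write.csv(summ, file.path(out_dir, "truth_summary.csv"),
                     row.names = FALSE)
  }
  list(images = images, ground_truth = gt, summary = summ)
}

# --- JSON configuration interchange --------------------------------------

#' Read or write a generator configuration as JSON
#'
#' The generator is configured through a JSON document whose fields mirror
#' the arguments of [generator_config()]; distributions are objects such as
#' `{"kind": "gaussian", "mean": 60, "sd": 0}`.
#'
#' @param path JSON file path.
#' @return [read_generator_config()] returns a `generator_config`.
#' @export
read_generator_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_spec <- function(x) {
    if (is.null(x)) return(NULL)
    do.call(dist_spec, as.list(x))
  }
  args <- j
  for (f in c("length", "width", "straightness")) {
    if (!is.null(args[[f]])) args[[f]] <- as_spec(args[[f]])
  }
  do.call(generator_config, args)
}

#' @rdname read_generator_config
#' @param config a [generator_config()].
#' @export
write_generator_config <- function(config, path) {
  out <- unclass(config)
  for (f in c("length", "width", "straightness")) {
    out[[f]] <- unclass(out[[f]])
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
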