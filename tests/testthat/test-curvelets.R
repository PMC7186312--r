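# Curvelet transform: frame properties, selection, thresholding, geometry.

test_that("transform of the zero image is zero and inverts to zero", {
  z <- matrix(0, 64, 64)
  p <- fdct(z)
  expect_equal(pyramid_energy(p), 0)
  expect_equal(ifdct(p), z)
})

test_that("round trip and energy conservation hold across sizes", {
  set.seed(2)
  for (d in list(c(32, 32), c(64, 64), c(96, 128), c(45, 45), c(256, 256))) {
    x <- matrix(rnorm(d[1] * d[2]), d[1], d[2])
    p <- fdct(x)
    expect_lt(sqrt(sum((ifdct(p) - x)^2) / sum(x^2)), 1e-6)
    expect_lt(abs(pyramid_energy(p) - sum(x^2)) / sum(x^2), 1e-6)
  }
})

test_that("antipodal wedges of a real image are complex conjugates", {
  set.seed(3)
  x <- matrix(rnorm(64 * 64), 64, 64)
  p <- fdct(x)
  J <- attr(p, "n_scales")
  for (s in 2:(J - 1)) {
    W <- length(p[[s]])
    for (l in seq_len(W / 2)) {
      c1 <- p[[s]][[l]]
      c2 <- p[[s]][[l + W / 2]]
      L1 <- nrow(c1); L2 <- ncol(c1)
      mir <- Conj(c1[c(1, L1:2), c(1, L2:2)])
      expect_lt(max(Mod(c2 - mir)) / max(Mod(c1)), 1e-8)
    }
  }
})

test_that("wedge counts are multiples of 4 and double every second scale", {
  p <- fdct(matrix(rnorm(256 * 256), 256, 256))
  J <- attr(p, "n_scales")
  W <- vapply(p, length, integer(1))
  expect_equal(W[1], 1)       # isotropic coarsest
  expect_equal(W[J], 1)       # isotropic finest ring
  inner <- W[2:(J - 1)]
  expect_true(all(inner %% 4 == 0))
  expect_equal(inner, 16 * 2^floor((seq_along(inner) - 1) / 2))
})

test_that("invalid inputs are rejected", {
  expect_error(fdct(array(0, c(4, 4, 2))), "matrix")
  expect_error(fdct(matrix(0, 16, 16)), "too small")
  expect_error(fdct(matrix(0, 64, 64), n_scales = 2), "at least 3")
  expect_error(fdct(matrix(0, 64, 64), n_wedges_second_coarsest = 10),
               "multiple of 4")
  expect_error(ifdct(list()), "coef_pyramid")
})

test_that("select_scale is idempotent and per-scale selections partition", {
  set.seed(5)
  x <- matrix(rnorm(64 * 64), 64, 64)
  p <- fdct(x)
  J <- attr(p, "n_scales")
  s1 <- select_scale(p)                      # default: second finest
  nz <- which(vapply(s1, function(sc) {
    any(vapply(sc, function(w) any(w != 0), logical(1)))
  }, logical(1)))
  expect_equal(nz, J - 1L)
  s2 <- select_scale(s1, "second_finest")
  expect_equal(unclass(s2), unclass(s1))     # idempotent
  expect_error(select_scale(p, J + 1), "out of range")
  # partition: per-scale reconstructions sum to the image
  tot <- Reduce(`+`, lapply(seq_len(J), function(j) {
    ifdct(select_scale(p, j))
  }))
  expect_lt(sqrt(sum((tot - x)^2) / sum(x^2)), 1e-10)
})

test_that("thresholding keeps ceil(fraction * N) and matches a full sort", {
  set.seed(6)
  x <- matrix(rnorm(64 * 64), 64, 64)
  p <- select_scale(fdct(x))
  s <- attr(p, "selected_scale")
  n_total <- sum(vapply(p[[s]], length, integer(1)))
  for (f in c(0.0035, 0.01, 0.3)) {
    cv <- threshold_top_fraction(p, f)
    expect_equal(nrow(cv), ceiling(f * n_total))
    # brute-force oracle: full sort of all magnitudes at the scale
    mags <- sort(unlist(lapply(p[[s]], Mod)), decreasing = TRUE)
    expect_equal(sort(cv$magnitude, decreasing = TRUE),
                 mags[seq_len(nrow(cv))], tolerance = 1e-12)
  }
  # keep everything
  cv_all <- threshold_top_fraction(p, 1)
  expect_equal(nrow(cv_all), n_total)
  # blank scale -> empty table
  z <- select_scale(fdct(matrix(0, 64, 64)))
  expect_equal(nrow(threshold_top_fraction(z, 0.5)), 0)
})

test_that("wedge geometry: vertical frequency direction means ridge angle 0", {
  p <- fdct(matrix(rnorm(64 * 64), 64, 64))
  plan <- fibretrace:::.pyramid_plan(p)
  # wedge whose central frequency direction points straight down the row
  # axis (phi = pi/2) has a horizontal ridge
  b <- Find(function(b) b$scale == 2 && !is.na(b$angle_deg) &&
              abs(b$angle_deg - 0) < 1e-9, plan$blocks)
  expect_false(is.null(b))
  # lattice origin: k = (0,0) maps to pixel (1,1) (image-coordinate origin)
  g <- curvelet_geometry(list(scale = 2, wedge = 1, k1 = 0, k2 = 0), p)
  expect_equal(g$center_row, 1)
  expect_equal(g$center_col, 1)
  expect_error(
    curvelet_geometry(list(scale = 2, wedge = 1, k1 = -1, k2 = 0), p),
    "out of range")
})

test_that("oriented lines land in the nearest wedge (modal angle)", {
  for (ang in c(0, 30, 75, 120, 165)) {
    img <- make_line_image(128, ang)
    p <- select_scale(fdct(img))
    cv <- threshold_top_fraction(p, 0.005)
    agg <- tapply(cv$magnitude, cv$angle_deg, sum)
    modal <- as.numeric(names(agg)[which.max(agg)])
    # scale 3 of 4 at this size has 16 wedges: half-width 11.25 degrees
    expect_lte(axial_diff_deg(modal, ang), 11.25)
  }
})

test_that("rotating a line by one wedge increment shifts the modal wedge", {
  p0 <- select_scale(fdct(make_line_image(128, 45)))
  cv0 <- threshold_top_fraction(p0, 0.005)
  step <- 180 / 16  # axial wedge spacing at 16 wedges
  p1 <- select_scale(fdct(make_line_image(128, 45 + step)))
  cv1 <- threshold_top_fraction(p1, 0.005)
  modal <- function(cv) {
    agg <- tapply(cv$magnitude, cv$angle_deg, sum)
    as.numeric(names(agg)[which.max(agg)])
  }
  expect_lte(axial_diff_deg(modal(cv1), modal(cv0) + step), step)
})

test_that("keeping only the finest scale isolates edge content", {
  set.seed(8)
  img <- make_line_image(64, 30) + matrix(rnorm(64 * 64, 0, 5), 64, 64)
  p <- fdct(img)
  fine <- ifdct(select_scale(p, "finest"))
  expect_gt(sum(fine^2), 0)
  expect_lt(sum(fine^2), sum(img^2))
})
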