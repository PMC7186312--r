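# Synthetic fiber generator.

test_that("distribution specs validate and sample correctly", {
  expect_error(dist_spec("uniform", min = 5, max = 5), "min < max")
  expect_error(dist_spec("gaussian", mean = 1, sd = -1), ">= 0")
  expect_error(dist_spec("piecewise_linear", x = c(1, 0), y = c(1, 1)),
               "increasing")
  set.seed(1)
  # point mass
  expect_equal(draw_dist(dist_spec("gaussian", mean = 6, sd = 0), 5),
               rep(6, 5))
  # uniform bounds
  u <- draw_dist(dist_spec("uniform", min = 2, max = 4), 1e4)
  expect_true(all(u >= 2 & u <= 4))
  expect_equal(mean(u), 3, tolerance = 0.05)
  # triangular density via piecewise linear: mean = (0+1+1)/3 for the
  # right-triangle density on [0, 1]
  tri <- draw_dist(dist_spec("piecewise_linear", x = c(0, 1), y = c(0, 2)),
                   2e4)
  expect_equal(mean(tri), 2 / 3, tolerance = 0.02)
})

test_that("direction sampling hits the mean and alignment targets exactly", {
  set.seed(2)
  # degenerate concentration
  d1 <- fibretrace:::.sample_directions(20, 37, 1)
  expect_true(all(d1 == 37))
  # exact calibration at n = 30
  d2 <- fibretrace:::.sample_directions(30, 90, 0.2)
  expect_equal(alignment(d2), 0.2, tolerance = 1e-9)
  expect_lt(axial_diff_deg(axial_mean(d2), 90), 1e-6)
  # near-zero target falls back to uniform draws
  d3 <- fibretrace:::.sample_directions(1e4, 90, 0)
  expect_lt(alignment(d3), 0.05)
})

test_that("recursive bridging respects reach disks and exact segments", {
  set.seed(3)
  # the printed example: 16 unit segments between (0,0) and (10,0)
  p <- bridge_path(c(0, 0), c(10, 0), 16, 1)
  expect_equal(nrow(p), 17)
  seg <- sqrt(rowSums(diff(p)^2))
  expect_true(all(abs(seg - 1) < 1e-9))        # exact unit steps
  # straightness forced by endpoints and segment count: 10/16
  expect_equal(10 / sum(seg), 0.625, tolerance = 1e-9)
  # the first midpoint (vertex 9) lies in both radius-8 reach disks
  mid <- p[9, ]
  expect_lte(sqrt(sum((mid - c(0, 0))^2)), 8 + 1e-9)
  expect_lte(sqrt(sum((mid - c(10, 0))^2)), 8 + 1e-9)
  # degenerate: taut chord gives the exactly collinear path
  q <- bridge_path(c(0, 0), c(12, 0), 3, 4)
  expect_true(all(abs(q[, 2]) < 1e-9))
  expect_equal(q[, 1], c(0, 4, 8, 12), tolerance = 1e-9)
  # unreachable endpoints rejected
  expect_error(bridge_path(c(0, 0), c(20, 0), 4, 1), "not reachable")
})

test_that("width variation is floored and mean-preserving", {
  set.seed(4)
  expect_equal(vary_width(5, 10, 0), rep(5, 10))
  w <- replicate(200, vary_width(5, 15, 0.2))
  expect_true(all(w >= 0.5))
  expect_equal(mean(w), 5, tolerance = 0.05)
  # floor is binding for thin fibers with large deltas
  w2 <- replicate(200, vary_width(0.6, 50, 1))
  expect_true(all(w2 >= 0.5))
  expect_error(vary_width(0, 5, 0.1), "positive")
})

test_that("smoothing methods preserve endpoints and their invariants", {
  set.seed(5)
  path <- bridge_path(c(20, 20), c(20, 60), 16, 4)
  ends <- path[c(1, nrow(path)), ]
  contour <- function(p) sum(sqrt(rowSums(diff(p)^2)))
  # bubble fixpoint on a monotone-turning path
  t <- seq(0, pi / 2, length.out = 10)
  arc <- cbind(row = 50 - 30 * sin(t), col = 20 + 30 * cos(t))
  expect_equal(smooth_path(arc, "bubble", passes = 3), arc,
               tolerance = 1e-12)
  # bubble and swap preserve endpoints, contour length and segment
  # multiset
  for (m in c("bubble", "swap")) {
    sm <- smooth_path(path, m, passes = 2, rate = 2)
    expect_equal(sm[c(1, nrow(sm)), ], ends, tolerance = 1e-9)
    expect_equal(contour(sm), contour(path), tolerance = 1e-9)
    expect_equal(
      sort(round(sqrt(rowSums(diff(sm)^2)), 9)),
      sort(round(sqrt(rowSums(diff(path)^2)), 9)))
  }
  # spline: point count ratio, endpoints, bounded deviation
  p17 <- bridge_path(c(30, 10), c(50, 60), 16, 4)
  sp <- smooth_path(p17, "spline", ratio = 2)
  expect_equal(nrow(sp), 34)
  expect_equal(sp[c(1, nrow(sp)), ], p17[c(1, nrow(p17)), ],
               tolerance = 1e-9)
  # max deviation from the original polyline stays below one segment
  devs <- apply(sp, 1, function(pt) {
    min(sqrt((p17[, 1] - pt[1])^2 + (p17[, 2] - pt[2])^2))
  })
  expect_lt(max(devs), 4)
  expect_error(smooth_path(p17, "spline", ratio = 0), "positive")
})

test_that("ground truth is self-consistent with the stored vertices", {
  cfg <- tiny_generator_config(seed = 6)
  gen <- generate_fibers(cfg, 1)
  for (i in seq_along(gen$fibers)) {
    v <- gen$fibers[[i]]$vertices
    seg <- sqrt(rowSums(diff(v)^2))
    len <- sum(seg)
    ee <- sqrt(sum((v[nrow(v), ] - v[1, ])^2))
    expect_equal(len, gen$table$length[i], tolerance = 1e-6)
    expect_equal(min(ee / len, 1), gen$table$straightness[i],
                 tolerance = 1e-6)
    d <- v[nrow(v), ] - v[1, ]
    expect_lt(axial_diff_deg(axial_angle_deg(d[1], d[2]),
                             gen$table$angle_deg[i]), 1e-6)
    # buffer respected
    expect_true(all(v >= cfg$edge_buffer_px - 1e-9))
    expect_true(all(v[, 1] <= cfg$image_height - cfg$edge_buffer_px + 1e-9))
    expect_true(all(v[, 2] <= cfg$image_width - cfg$edge_buffer_px + 1e-9))
  }
})

test_that("rendering stamps the configured ribbon width and noise floor", {
  cfg <- generator_config(image_width = 128, image_height = 128,
                          n_fibers = 1, mean_angle_deg = 0, alignment = 1,
                          length = dist_spec("gaussian", mean = 60, sd = 0),
                          width_change_px = 0, bubble_passes = 0,
                          swap_rate = 0, spline_ratio = 0, seed = 7)
  gen <- generate_fibers(cfg, 1)
  img <- render_fibers(gen$fibers, cfg)
  # profile across the horizontal ribbon: measured width 5 +/- 1
  per_col <- colSums(img > 0)
  expect_equal(median(per_col[per_col > 0]), 5, tolerance = 1)
  # zero noise level leaves the render untouched
  img2 <- render_fibers(gen$fibers, cfg)
  expect_identical(img, img2)
  # Poisson noise raises the background to ~noise_level
  cfg$noise_level <- 50
  set.seed(1)
  img3 <- render_fibers(gen$fibers, cfg)
  expect_equal(mean(img3[img == 0]), 50, tolerance = 2)
})

test_that("datasets are reproducible and recover population targets", {
  cfg <- tiny_generator_config(n_images = 3, seed = 8)
  d1 <- generate_dataset(cfg, render = TRUE)
  d2 <- generate_dataset(cfg, render = TRUE)
  expect_identical(d1$images, d2$images)        # bit-identical
  expect_identical(d1$ground_truth, d2$ground_truth)
  # per-image calibrated targets
  expect_true(all(abs(d1$summary$alignment - cfg$alignment) < 1e-6))
  # population recovery over many fibers (t-test fails to reject)
  cfg2 <- generator_config(n_images = 10, n_fibers = 30,
                           length = dist_spec("gaussian", mean = 60, sd = 6),
                           width = dist_spec("gaussian", mean = 5, sd = 0.5),
                           straightness = dist_spec("gaussian", mean = 0.92,
                                                    sd = 0.02),
                           seed = 9)
  d3 <- generate_dataset(cfg2, render = FALSE)
  gt <- d3$ground_truth
  expect_gt(stats::t.test(gt$width, mu = 5)$p.value, 0.05)
  expect_equal(mean(gt$straightness), 0.92, tolerance = 0.02)
  expect_equal(mean(gt$length), 60, tolerance = 3)
})

test_that("generator configs survive a JSON round trip", {
  cfg <- curvy_validation_config(n_images = 2, seed = 3)
  f <- tempfile(fileext = ".json")
  write_generator_config(cfg, f)
  cfg2 <- read_generator_config(f)
  expect_equal(cfg2$straightness$mean, 0.92)
  expect_equal(cfg2$noise_level, 50)
  expect_equal(cfg2$n_images, 2L)
  # identical datasets from the round-tripped config
  g1 <- generate_fibers(cfg, 1)
  g2 <- generate_fibers(cfg2, 1)
  expect_equal(g1$table, g2$table)
  unlink(f)
})
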