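# Distance-transform fiber tracing.

test_that("distance map matches geometry and a brute-force oracle", {
  # all-background image
  z <- binarize_and_distance(matrix(0, 32, 32), 60)
  expect_equal(max(z$distance), 0)
  # solid disk of radius 10: max distance ~10 at the center
  disk <- make_disk(64, c(32, 32), 10, value = 255)
  bd <- binarize_and_distance(disk, 60)
  expect_equal(max(bd$distance), 10, tolerance = 0.5)
  expect_equal(which(bd$distance == max(bd$distance), arr.ind = TRUE)[1, ],
               c(row = 32, col = 32))
  expect_true(all(bd$distance[disk == 0] == 0))
  # random blob vs O(N^2) nearest-background search
  set.seed(12)
  img <- matrix(0, 48, 48)
  img[12:30, 8:40] <- 255 * (matrix(runif(19 * 33), 19, 33) > 0.3)
  bd2 <- binarize_and_distance(img, 60)
  expect_equal(bd2$distance, brute_distance(img > 60), tolerance = 1e-6)
})

test_that("nucleation points are box maxima above the distance threshold", {
  # empty map -> none
  expect_equal(nrow(find_nucleation_points(matrix(0, 32, 32), 5, 2)), 0)
  # single disk, threshold below its radius -> exactly the center
  disk <- make_disk(64, c(30, 35), 9, value = 255)
  bd <- binarize_and_distance(disk, 60)
  np <- find_nucleation_points(bd$distance, 5, 2, seed = 1)
  expect_equal(nrow(np), 1)
  expect_equal(c(np$row, np$col), c(30, 35))
  # straight ribbon: points on the medial axis, separated by > box radius
  img <- matrix(0, 64, 64); img[29:35, 6:58] <- 255
  bd2 <- binarize_and_distance(img, 60)
  np2 <- find_nucleation_points(bd2$distance, 5, 2, seed = 3)
  expect_true(all(np2$row == 32))                 # medial axis row
  expect_true(all(diff(sort(np2$col)) > 5))
  # brute-force box-maximum oracle (same jitter stream)
  set.seed(3)
  jit <- bd2$distance *
    (1 + matrix(runif(length(bd2$distance)), 64) * 1e-6)
  ora <- which(apply(expand.grid(r = 1:64, c = 1:64), 1, function(p) {
    r <- p[1]; c <- p[2]
    if (bd2$distance[r, c] <= 2) return(FALSE)
    box <- jit[max(1, r - 5):min(64, r + 5), max(1, c - 5):min(64, c + 5)]
    jit[r, c] == max(box)
  }))
  expect_equal(sort((np2$col - 1) * 64 + np2$row), sort(ora))
})

test_that("branch extension follows a ribbon in both directions", {
  img <- matrix(0, 64, 64); img[29:35, 6:58] <- 255
  bd <- binarize_and_distance(img, 60)
  np <- find_nucleation_points(bd$distance, 5, 2, seed = 1)
  mid <- np[which.min(abs(np$col - 32)), ]
  cfg <- fire_config()
  br <- extend_branches(mid, bd$distance, cfg)
  expect_equal(length(br), 2)
  dirs <- sapply(br, function(b) {
    v <- b$vertices
    d <- v[nrow(v), ] - v[1, ]
    atan2(-d[1], d[2]) * 180 / pi
  })
  # one branch toward 0 degrees, one toward 180
  expect_lt(min(abs(dirs - 0), abs(abs(dirs) - 180)), 10)
  expect_true(any(abs(dirs) < 10) && any(abs(abs(dirs) - 180) < 10))
  # vertices stay on the foreground
  for (b in br) {
    expect_true(all(bd$distance[round(b$vertices)] > 0))
  }
})

test_that("an isolated dot below the LMP threshold yields no branches", {
  img <- matrix(0, 64, 64); img[30:31, 30:31] <- 255
  bd <- binarize_and_distance(img, 60)
  np <- find_nucleation_points(bd$distance, 5, 0.5, seed = 1)
  cfg <- fire_config()
  br <- extend_branches(np, bd$distance, cfg)
  expect_true(all(vapply(br, function(b) {
    b$terminated_reason == "no-LMP"
  }, logical(1))))
})

test_that("an L-shaped ribbon is traced along both legs near the skeleton", {
  img <- matrix(0, 96, 96)
  img[45:51, 10:80] <- 255   # horizontal leg
  img[10:51, 74:80] <- 255   # vertical leg
  out <- extract_fibers(img, fire_config(min_fiber_length = 20))
  expect_gte(nrow(out$fibers), 2)
  # every vertex within 2.5 px of one of the two medial axes
  v <- out$vertices
  d_h <- abs(v$row - 48)
  d_v <- abs(v$col - 77)
  expect_true(all(pmin(d_h, d_v) <= 2.5))
})

test_that("linking joins collinear branches and splits right angles", {
  cfg <- fire_config(min_fiber_length = 0, tip_spacing = 2)
  mkbranch <- function(verts, origin, terminal = NA_integer_) {
    list(vertices = verts, origin = origin, terminal = terminal,
         terminated_reason = "no-LMP", tip_direction = c(0, 1))
  }
  np <- c(50, 50)
  right <- mkbranch(cbind(row = rep(50, 6), col = seq(50, 75, 5)), 1L)
  left <- mkbranch(cbind(row = rep(50, 6), col = seq(50, 25, -5)), 1L)
  up <- mkbranch(cbind(row = seq(50, 25, -5), col = rep(50, 6)), 1L)
  # two collinear branches -> one fiber through both
  out <- link_branches(list(right, left), cfg)
  expect_equal(nrow(out$fibers), 1)
  expect_equal(out$fibers$length, 50, tolerance = 1e-6)
  # 90-degree pair with 30-degree threshold -> two fibers
  out2 <- link_branches(list(right, up), cfg)
  expect_equal(nrow(out2$fibers), 2)
  # three branches: the most collinear pair links, the third stays single
  out3 <- link_branches(list(right, up, left), cfg)
  expect_equal(nrow(out3$fibers), 2)
  expect_equal(sort(out3$fibers$length), c(25, 50), tolerance = 1e-6)
})

test_that("blank images give an empty fiber table", {
  out <- extract_fibers(matrix(0, 64, 64), fire_config())
  expect_equal(nrow(out$fibers), 0)
  expect_equal(nrow(out$vertices), 0)
})

test_that("a rendered single fiber is recovered with its angle", {
  for (ang in c(20, 90, 140)) {
    cfg <- generator_config(image_width = 192, image_height = 192,
                            n_fibers = 1, mean_angle_deg = ang,
                            alignment = 1,
                            length = dist_spec("gaussian", mean = 90, sd = 0))
    gen <- generate_fibers(cfg, 1)
    img <- render_fibers(gen$fibers, cfg)
    out <- extract_fibers(img, fire_config())
    expect_gte(nrow(out$fibers), 1)
    main <- out$fibers[which.max(out$fibers$length), ]
    expect_lte(axial_diff_deg(main$angle_deg, gen$table$angle_deg), 5)
    expect_gt(main$length, 60)
    expect_true(all(out$fibers$straightness <= 1 &
                      out$fibers$straightness > 0))
    expect_true(all(out$fibers$width > 0))
  }
})

test_that("extraction is deterministic and vertices stay off background", {
  cfg <- straight_validation_config(n_images = 1, seed = 77)
  gen <- generate_fibers(cfg, 1)
  img <- render_fibers(gen$fibers, cfg)
  fc <- fire_config(seed = 5)
  a <- extract_fibers(img, fc)
  b <- extract_fibers(img, fc)
  expect_identical(a$fibers, b$fibers)
  expect_identical(a$vertices, b$vertices)
  dm <- a$distance
  expect_true(all(dm[cbind(round(a$vertices$row),
                           round(a$vertices$col))] > 0))
})

test_that("extraction biases run in the documented directions", {
  # on noisy validation-style images: summed extracted length does not
  # exceed summed true length, and mean extracted width is not below the
  # stamped width
  cfg <- straight_validation_config(n_images = 2, seed = 31)
  lens <- c(); widths <- c(); true_len <- c(); true_wid <- c()
  for (i in 1:2) {
    gen <- generate_fibers(cfg, i)
    img <- render_fibers(gen$fibers, cfg)
    out <- extract_fibers(img, fire_config())
    lens <- c(lens, sum(out$fibers$length))
    widths <- c(widths, mean(out$fibers$width))
    true_len <- c(true_len, sum(gen$table$length))
    true_wid <- c(true_wid, mean(gen$table$width))
  }
  expect_lte(sum(lens), sum(true_len))
  expect_gte(mean(widths), mean(true_wid))
})
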