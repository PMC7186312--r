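# Boundary tracing, relative angles, heatmap, ROI tools.

test_that("outline tracing covers frames, circles and multiple blobs", {
  # full-frame mask: outline = image border
  full <- matrix(1, 32, 32)
  b <- boundary_mask(full)
  expect_equal(length(b$outlines), 1)
  o <- b$outlines[[1]]
  expect_true(all(o[, 1] %in% c(1, 32) | o[, 2] %in% c(1, 32)))
  expect_gte(nrow(o), 2 * 32 + 2 * 30 - 4)
  # filled circle: one outline whose pixel count matches the digital
  # perimeter (foreground pixels 4-adjacent to background), itself within
  # 15% of the Euclidean circumference 2*pi*r
  circ <- make_disk(128, c(64, 64), 30)
  b2 <- boundary_mask(circ)
  expect_equal(length(b2$outlines), 1)
  fg <- circ > 0
  shift <- function(m, dr, dc) {
    out <- matrix(FALSE, nrow(m), ncol(m))
    rs <- seq_len(nrow(m)) + dr; cs <- seq_len(ncol(m)) + dc
    okr <- rs >= 1 & rs <= nrow(m); okc <- cs >= 1 & cs <= ncol(m)
    out[okr, okc] <- m[rs[okr], cs[okc]]
    out
  }
  digital_perimeter <- sum(fg & !(shift(fg, 1, 0) & shift(fg, -1, 0) &
                                    shift(fg, 0, 1) & shift(fg, 0, -1)))
  expect_equal(nrow(b2$outlines[[1]]), digital_perimeter, tolerance = 0.10)
  expect_equal(digital_perimeter, 2 * pi * 30, tolerance = 0.15)
  # two blobs -> two outlines, ordered by size
  two <- make_disk(96, c(25, 25), 12) + make_disk(96, c(70, 70), 6)
  b3 <- boundary_mask(two)
  expect_equal(length(b3$outlines), 2)
  expect_gt(nrow(b3$outlines[[1]]), nrow(b3$outlines[[2]]))
  # empty mask errors
  expect_error(boundary_mask(matrix(0, 16, 16)), "empty")
})

test_that("boundary tangents match analytic directions", {
  # straight vertical boundary
  m <- matrix(0, 64, 64); m[, 1:30] <- 1
  b <- boundary_mask(m)
  o <- b$outlines[[1]]
  edge_idx <- which(o[, 2] == 30 & o[, 1] > 10 & o[, 1] < 54)[1]
  expect_lte(axial_diff_deg(boundary_tangent(o, edge_idx, 5), 90), 1)
  # circle: horizontal tangent at the topmost point
  circ <- make_disk(128, c(64, 64), 30)
  oc <- boundary_mask(circ)$outlines[[1]]
  top <- which.min(oc[, 1])
  expect_lte(axial_diff_deg(boundary_tangent(oc, top, 5), 0), 5)
  # two-point outline: the chord direction
  two_pts <- cbind(row = c(10, 12), col = c(10, 12))
  expect_equal(boundary_tangent(two_pts, 1, 5),
               axial_angle_deg(2, 2))
})

test_that("relative angles hit exact values on a straight boundary", {
  m <- matrix(0, 128, 128); m[, 1:20] <- 1   # vertical boundary at col 20
  b <- boundary_mask(m)
  objects <- data.frame(
    id = 1:4,
    center_row = c(64, 64, 64, 30),
    center_col = c(60, 60, 120, 15),
    angle_deg = c(90, 0, 90, 45))
  rec <- relative_angles(objects, b, max_distance = 60)
  # parallel to the boundary -> 0; perpendicular -> 90
  expect_equal(rec$relative_angle_deg[1], 0, tolerance = 1)
  expect_equal(rec$relative_angle_deg[2], 90, tolerance = 1)
  # beyond the distance gate
  expect_equal(rec$status[3], "excluded-too-far")
  # center inside the mask
  expect_equal(rec$status[4], "excluded-inside")
  expect_true(all(rec$relative_angle_deg >= 0 &
                    rec$relative_angle_deg <= 90, na.rm = TRUE))
})

test_that("distance gating excludes a fiber at 200 px under a 150 px limit", {
  m <- matrix(0, 300, 300); m[, 1:10] <- 1
  b <- boundary_mask(m)
  obj <- data.frame(id = 1, center_row = 150, center_col = 210,
                    angle_deg = 45)
  rec <- relative_angles(obj, b, max_distance = 150)
  expect_equal(rec$status, "excluded-too-far")
  rec2 <- relative_angles(obj, b, max_distance = 250)
  expect_equal(rec2$status, "measured")
})

test_that("shrinking the distance gate never adds measured records", {
  set.seed(31)
  m <- matrix(0, 200, 200); m[80:120, 80:120] <- 1
  b <- boundary_mask(m)
  obj <- data.frame(id = 1:50, center_row = runif(50, 1, 200),
                    center_col = runif(50, 1, 200),
                    angle_deg = runif(50, 0, 180))
  counts <- sapply(c(150, 100, 50, 20), function(d) {
    sum(relative_angles(obj, b, d)$status == "measured")
  })
  expect_true(all(diff(counts) <= 0))
})

test_that("relative angles are invariant to flipping fiber or tangent", {
  m <- matrix(0, 128, 128); m[, 1:20] <- 1
  b <- boundary_mask(m)
  for (a in c(10, 50, 85)) {
    o1 <- data.frame(id = 1, center_row = 64, center_col = 60,
                     angle_deg = a)
    o2 <- o1; o2$angle_deg <- fold_axial(a + 180)
    r1 <- relative_angles(o1, b, 100)$relative_angle_deg
    r2 <- relative_angles(o2, b, 100)$relative_angle_deg
    expect_equal(r1, r2, tolerance = 1e-9)
  }
})

test_that("the heatmap flags exactly the perpendicular patch tiles", {
  recs <- data.frame(id = 1:3, status = "measured",
                     relative_angle_deg = c(0, 75, 30),
                     center_row = c(10, 70, 100),
                     center_col = c(10, 70, 100))
  hm <- tacs_heatmap(recs, c(128, 128), 32)
  expect_equal(sum(hm), 1)
  expect_equal(hm[3, 3], 1)     # the 75-degree record's tile
  # all parallel records -> nothing flagged
  recs$relative_angle_deg <- 5
  expect_equal(sum(tacs_heatmap(recs, c(128, 128), 32)), 0)
  # constructed scene: perpendicular patch flags its own tiles only
  m <- matrix(0, 256, 256); m[, 1:16] <- 1
  b <- boundary_mask(m)
  obj <- rbind(
    data.frame(id = 1:4, center_row = c(40, 44, 48, 52),
               center_col = 40, angle_deg = 0),     # perpendicular patch
    data.frame(id = 5:8, center_row = c(200, 204, 208, 212),
               center_col = 40, angle_deg = 90))    # parallel patch
  rec <- merge(relative_angles(obj, b, 150), obj, by = "id")
  hm2 <- tacs_heatmap(rec, c(256, 256), 64)
  expect_equal(which(hm2 == 1), which(matrix(seq_len(16), 4)[1, 1] == 1:16))
})

test_that("ROI filtering matches half-open rectangles and an oracle", {
  set.seed(32)
  obj <- data.frame(center_row = runif(500, 1, 100),
                    center_col = runif(500, 1, 100),
                    angle_deg = runif(500, 0, 180))
  # whole-image ROI is the identity
  whole <- roi("all", "rectangle", row0 = 0, col0 = 0,
               height = 100, width = 100)
  expect_equal(nrow(roi_filter(obj, whole)), nrow(obj))
  # half-open rectangle
  r <- roi("r", "rectangle", row0 = 10, col0 = 20, height = 30, width = 40)
  sub <- roi_filter(obj, r)
  keep <- (obj$center_row - 1) >= 10 & (obj$center_row - 1) < 40 &
    (obj$center_col - 1) >= 20 & (obj$center_col - 1) < 60
  expect_equal(nrow(sub), sum(keep))
  # polygon containment vs brute-force ray casting
  vx <- c(10, 80, 70, 40, 15); vy <- c(20, 15, 70, 90, 55)
  p <- roi("p", "polygon", rows = vx, cols = vy)
  pts <- data.frame(center_row = runif(1000, 1, 100),
                    center_col = runif(1000, 1, 100))
  got <- fibretrace:::.roi_contains(p, pts$center_row, pts$center_col)
  want <- mapply(function(r0, c0) brute_pip(r0, c0, vx, vy),
                 pts$center_row - 1, pts$center_col - 1)
  expect_gte(mean(got == want), 0.995)  # disagreement only on edges
  expect_error(roi("bad", "rectangle", row0 = 0, col0 = 0,
                   height = 0, width = 5), "degenerate")
})

test_that("ROI intensity modes partition the image", {
  img <- matrix(7, 64, 64)
  r <- roi("d", "rectangle", row0 = 10, col0 = 10, height = 20, width = 20)
  modes <- c("on-outline", "inside", "outside")
  stats <- lapply(modes, function(m) roi_intensity(img, r, m))
  # constant image: means equal the constant
  for (s in stats) expect_equal(s$mean, 7)
  # partition: counts sum to the pixel count
  expect_equal(sum(vapply(stats, function(s) s$n, numeric(1))), 64 * 64)
  # bright disk inside a disk-matched ROI
  img2 <- make_disk(64, c(32, 32), 10, value = 200) + 20
  rd <- roi("disk", "mask", mask = make_disk(64, c(32, 32), 12) > 0)
  expect_gt(roi_intensity(img2, rd, "inside")$mean,
            roi_intensity(img2, rd, "outside")$mean)
})

test_that("ROI JSON and CSV loaders round-trip definitions", {
  f <- tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(list(
    list(name = "a", shape = "rectangle", row0 = 0, col0 = 0,
         height = 256, width = 256),
    list(name = "p", shape = "polygon", rows = c(1, 50, 25),
         cols = c(1, 1, 40))), auto_unbox = TRUE), f)
  rois <- load_rois(f)
  expect_equal(length(rois), 2)
  expect_equal(rois[[1]]$height, 256)
  expect_equal(rois[[2]]$shape, "polygon")
  unlink(f)
  fc <- tempfile(fileext = ".csv")
  write.csv(data.frame(name = "r1", row0 = 1, col0 = 1, height = 10,
                       width = 10), fc, row.names = FALSE)
  r1 <- load_rois_csv(fc, one_based = TRUE)[[1]]
  expect_equal(r1$row0, 0)
  unlink(fc)
})
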