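test_that("an image without nucleus pixels raises NoNucleus", {
  expect_error(find_contour(suite()$all_background$cls),
               class = "nucshell_no_nucleus")
  expect_error(estimate_geometry(suite()$all_background$cls),
               class = "nucshell_no_nucleus")
})

test_that("row scanning finds the per-row nucleus extremes", {
  fx <- suite()$axis_aligned # a=100, b=50, center (201, 193)
  ct <- find_contour(fx$cls)
  mid <- ct[ct$y == 193, ]
  expect_lte(abs(mid$left - 101), 1)
  expect_lte(abs(mid$right - 301), 1)
  # scanning property: contour pixels are foreground, nothing foreground
  # before them in the scan
  lab <- unclass(fx$cls)
  for (y in c(150, 193, 230)) {
    l <- ct$left[y]; r <- ct$right[y]
    expect_true(lab[y, l] %in% c(1L, 2L))
    expect_true(lab[y, r] %in% c(1L, 2L))
    if (l > 1) expect_true(all(!lab[y, 1:(l - 1)] %in% c(1L, 2L)))
    if (r < ncol(lab)) expect_true(all(!lab[y, (r + 1):ncol(lab)] %in% c(1L, 2L)))
  }
  # probe pixels on the rim count as boundary
  lab2 <- lab
  lab2[193, 95:100] <- 2L
  ct2 <- find_contour(label_grid(lab2))
  expect_identical(ct2$left[193], 95L)
})

test_that("degenerate contours are handled: one pixel, two pixels", {
  ct <- find_contour(suite()$one_pixel$cls)
  expect_identical(ct$left[4], 7L)
  expect_identical(ct$right[4], 7L)
  expect_true(all(is.na(ct$left[-4])))
  box <- bounding_box(ct)
  expect_equal(box$left, c(x = 7, y = 4))
  expect_equal(box$right, c(x = 7, y = 4))
  expect_equal(initial_midpoint(box), c(x = 7, y = 4))
  expect_error(major_axis(ct, initial_midpoint(box)),
               class = "nucshell_degenerate")

  m <- matrix(0L, 8, 12)
  m[2, 3] <- 1L; m[6, 9] <- 1L
  box2 <- bounding_box(find_contour(label_grid(m)))
  expect_equal(box2$left[["x"]], 3)
  expect_equal(box2$right[["x"]], 9)
  expect_equal(box2$top[["y"]], 2)
  expect_equal(box2$bottom[["y"]], 6)
})

test_that("bounding box and initial midpoint follow the contour extremes", {
  fx <- suite()$axis_aligned
  box <- bounding_box(find_contour(fx$cls))
  expect_equal(box$left, c(x = 101, y = 193), tolerance = 0.011)
  expect_equal(box$right, c(x = 301, y = 193), tolerance = 0.011)
  expect_lte(abs(box$top[["y"]] - 143), 1)
  expect_lte(abs(box$bottom[["y"]] - 243), 1)
  expect_equal(initial_midpoint(box), c(x = 201, y = 193), tolerance = 0.01)
  # pure arithmetic on a constructed box
  box3 <- list(top = c(x = 2, y = 0), bottom = c(x = 2, y = 5),
               left = c(x = 0, y = 3), right = c(x = 5, y = 2))
  expect_equal(initial_midpoint(box3), c(x = 2.5, y = 2.5))
})

test_that("major axis spans the long diameter and respects rotation", {
  fx <- suite()$axis_aligned
  ct <- find_contour(fx$cls)
  mpt0 <- initial_midpoint(bounding_box(ct))
  maj <- major_axis(ct, mpt0)
  len <- sqrt(sum((maj$majpt1 - maj$majpt2)^2))
  expect_lte(abs(len - 200), 2)

  rot <- suite()$rotated_30
  ctr <- find_contour(rot$cls)
  majr <- major_axis(ctr, initial_midpoint(bounding_box(ctr)))
  ang <- atan2(majr$majpt2[["y"]] - majr$majpt1[["y"]],
               majr$majpt2[["x"]] - majr$majpt1[["x"]])
  expect_lte(axis_angle_diff_deg(ang, 30 * pi / 180), 2)

  circ <- suite()$circle
  ctc <- find_contour(circ$cls)
  majc <- major_axis(ctc, initial_midpoint(bounding_box(ctc)))
  expect_lte(abs(sqrt(sum((majc$majpt1 - majc$majpt2)^2)) - 160), 2)
})

test_that("refine_midpoint is the endpoint average and recovers the center", {
  expect_equal(refine_midpoint(c(x = 300, y = 150), c(x = 100, y = 150)),
               c(x = 200, y = 150))
  expect_equal(refine_midpoint(c(x = 0, y = 0), c(x = 10, y = 20)),
               c(x = 5, y = 10))
  expect_error(refine_midpoint(c(x = 1, y = 1), c(x = 1, y = 1)),
               class = "nucshell_degenerate")
  g <- estimate_geometry(suite()$rotated_30$cls)
  truth <- suite()$rotated_30$truth$geometry
  expect_lte(abs(g$mpt[["x"]] - truth$mpt[["x"]]), 1)
  expect_lte(abs(g$mpt[["y"]] - truth$mpt[["y"]]), 1)
})

test_that("minor axis is the perpendicular chord through the midpoint", {
  fx <- suite()$axis_aligned
  ct <- find_contour(fx$cls)
  mins <- minor_axis(ct, c(x = 201, y = 193), 0)
  expect_lte(abs(mins$minpt1[["x"]] - 201), 1)
  expect_lte(abs(abs(mins$minpt1[["y"]] - 193) - 50), 1)
  b <- sqrt(sum((mins$minpt1 - mins$minpt2)^2)) / 2
  expect_lte(abs(b - 50), 1)
  expect_error(minor_axis(ct, c(x = 5, y = 5), 0),
               class = "nucshell_geometry_error")
})

test_that("estimate_geometry recovers generator parameters", {
  fx <- make_nucleus_image(nucleus_spec(
    width = 281, height = 281, a = 120, b = 60, theta = 40 * pi / 180, seed = 9
  ))
  g <- estimate_geometry(fx$cls)
  expect_lte(abs(g$a - 120), 2)
  expect_lte(abs(g$b - 60), 2)
  expect_lte(axis_angle_diff_deg(g$theta, 40 * pi / 180), 2)
  # axis invariants
  expect_gte(g$a, g$b)
  expect_lte(abs(sqrt(sum((g$majpt1 - g$majpt2)^2)) - 2 * g$a), 1)
  expect_lte(abs(sqrt(sum((g$minpt1 - g$minpt2)^2)) - 2 * g$b), 1)

  gc <- estimate_geometry(suite()$circle$cls)
  expect_gte(gc$a / gc$b, 0.98)
  expect_lte(gc$a / gc$b, 1.02)

  g2 <- estimate_geometry(suite()$axis_aligned$cls)
  expect_gte(g2$a / g2$b, 1.9)
  expect_lte(g2$a / g2$b, 2.1)
})

test_that("parameter recovery holds across random ellipses", {
  for (case in random_ellipse_suite(n = 25, seed = 5)) {
    g <- estimate_geometry(case$fx$cls)
    expect_lte(abs(g$a - case$a), 0.02 * case$a + 2)
    expect_lte(abs(g$b - case$b), 0.02 * case$b + 2)
    if (case$a / case$b >= 1.3) {
      expect_lte(axis_angle_diff_deg(g$theta, case$theta), 2)
    }
  }
})

test_that("rotating the image by 90 degrees rotates theta and keeps the axes", {
  fx <- suite()$rotated_30
  g <- estimate_geometry(fx$cls)
  px <- unclass(fx$grid)
  h <- dim(px)[1]; w <- dim(px)[2]
  rot <- array(0, dim = c(w, h, 3))
  for (ch in 1:3) rot[, , ch] <- t(px[h:1, , ch]) # 90 deg clockwise
  g2 <- estimate_geometry(classify_grid(pixel_grid(rot)))
  expect_lte(axis_angle_diff_deg(g2$theta, g$theta + pi / 2), 2)
  expect_lte(abs(g2$a - g$a), 1)
  expect_lte(abs(g2$b - g$b), 1)
})
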