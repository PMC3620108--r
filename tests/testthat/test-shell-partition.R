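test_that("shell_radii implements the equal-area construction", {
  r <- shell_radii(100, 50, 5)
  expect_equal(r$a_k, c(44.721, 63.246, 77.460, 89.443), tolerance = 1e-4)
  expect_equal(r$b_k, r$a_k / 2)
  # areas of the concentric ellipses are k/N of the total
  expect_equal(pi * r$a_k * r$b_k, (1:4) / 5 * pi * 100 * 50)
  # constant aspect, strictly increasing
  expect_true(all(diff(r$a_k) > 0))
  expect_equal(r$a_k / r$b_k, rep(2, 4))

  expect_identical(nrow(shell_radii(80, 40, 1)), 0L)
  expect_equal(shell_radii(10, 10, 2)$a_k, 10 / sqrt(2), tolerance = 1e-9)
  expect_error(shell_radii(100, 50, 0), "positive")
  expect_error(shell_radii(50, 100, 5), "a >= b")
})

test_that("normalized_coord measures position in the axis frame", {
  geom <- structure(
    list(mpt = c(x = 200, y = 150), a = 100, b = 50, theta = 0),
    class = "nucleus_geometry"
  )
  expect_equal(normalized_coord(200, 150, geom), 0)
  expect_equal(normalized_coord(200 + sqrt(0.2) * 100, 150, geom), 0.2)
  expect_equal(normalized_coord(300, 150, geom), 1)
  expect_equal(normalized_coord(200, 100, geom), 1)
  # recovered geometry places its own major endpoint at e = 1
  g <- estimate_geometry(suite()$rotated_30$cls)
  expect_lte(abs(normalized_coord(g$majpt1[["x"]], g$majpt1[["y"]], g) - 1), 0.05)
  # rotation invariance: e depends only on the axis-frame position
  geom_r <- structure(
    list(mpt = c(x = 200, y = 150), a = 100, b = 50, theta = pi / 3),
    class = "nucleus_geometry"
  )
  r <- sqrt(0.2) * 100
  p <- c(200 + r * cos(pi / 3), 150 + r * sin(pi / 3))
  expect_equal(normalized_coord(p[1], p[2], geom_r), 0.2)
})

test_that("assign_shell maps e to shells, periphery = 1 and center = N", {
  expect_identical(assign_shell(0.05, TRUE, 5), 5L)
  expect_identical(assign_shell(1.3, TRUE, 5), 1L)  # irregular outer shell
  expect_identical(assign_shell(0.5, TRUE, 5), 3L)  # ceil(2.5) = 3
  expect_identical(assign_shell(0, TRUE, 5), 5L)
  # boundary e = k/N belongs to the inner ring
  expect_identical(assign_shell(0.2, TRUE, 5), 5L)
  expect_identical(assign_shell(0.4, TRUE, 5), 4L)
  expect_true(is.na(assign_shell(0.5, FALSE, 5)))
  # monotone: shell number never increases as e grows in [0, 1]
  e <- sort(runif(200))
  s <- assign_shell(e, TRUE, 7)
  expect_true(all(diff(s) <= 0))
})

test_that("count_shells yields near-equal areas on a plain ellipse", {
  fx <- suite()$axis_aligned
  ct <- find_contour(fx$cls)
  cnt <- count_shells(fx$cls, ct, fx$truth$geometry, 5)
  tot <- sum(cnt$n_total)
  expect_identical(tot, sum(ct$right - ct$left + 1L, na.rm = TRUE))
  expect_true(all(abs(cnt$n_total - tot / 5) <= 0.02 * tot / 5))
  expect_identical(cnt$n_total, cnt$n_nucleus + cnt$n_probe + cnt$n_other)
})

test_that("a uniform probe wash spreads its share evenly across shells", {
  fx <- suite()$uniform_wash
  ct <- find_contour(fx$cls)
  prof <- shell_profile(count_shells(fx$cls, ct, fx$truth$geometry, 5))
  expect_true(all(abs(prof$share_probe - 20) <= 2))
  expect_equal(sum(prof$share_probe), 100, tolerance = 1e-9)
  # within-shell percentages sum to 100 in every shell
  expect_true(all(abs(prof$pct_nucleus + prof$pct_probe + prof$pct_other - 100)
                  <= 0.1))
})

test_that("a central probe disk lands entirely in the innermost shells", {
  fx <- make_nucleus_image(nucleus_spec(
    width = 261, height = 181, a = 100, b = 50,
    blobs = tibble::tibble(u = 0, angle = 0, radius = 30), seed = 2
  ))
  ct <- find_contour(fx$cls)
  prof <- shell_profile(count_shells(fx$cls, ct, fx$truth$geometry, 5))
  expect_equal(sum(prof$share_probe[4:5]), 100, tolerance = 1e-9)
  expect_equal(prof$share_probe[1], 0)
  expect_equal(prof$share_probe[2], 0)
})

test_that("every nucleus-region pixel is assigned exactly one shell", {
  fx <- suite()$rotated_30
  ct <- find_contour(fx$cls)
  g <- estimate_geometry(fx$cls, ct)
  cnt <- count_shells(fx$cls, ct, g, 5)
  region <- sum(ct$right - ct$left + 1L, na.rm = TRUE)
  expect_identical(sum(cnt$n_total), region)
  # no labeled pixel sits on a row the contour calls empty
  lab <- unclass(fx$cls)
  empty_rows <- which(is.na(ct$left))
  expect_true(all(!lab[empty_rows, ] %in% c(1L, 2L)))
})

test_that("background inside the contour is tallied as other", {
  lab <- matrix(0L, 21, 21)
  lab[5:17, 5:17] <- 1L
  lab[11, 11] <- 0L # interior hole in background color
  cls <- label_grid(lab)
  ct <- find_contour(cls)
  g <- estimate_geometry(cls, ct)
  cnt <- count_shells(cls, ct, g, 3)
  expect_identical(sum(cnt$n_other), 1L)
  expect_identical(sum(cnt$n_total), 13L * 13L)
})

test_that("count_shells rejects a midpoint outside the contour", {
  fx <- suite()$circle
  ct <- find_contour(fx$cls)
  g <- estimate_geometry(fx$cls, ct)
  g$mpt <- c(x = 3, y = 3)
  expect_error(count_shells(fx$cls, ct, g, 5), class = "nucshell_geometry_error")
})

test_that("shell_profile computes both normalizations", {
  cnt <- tibble::tibble(
    shell = 1:5,
    n_nucleus = c(100L, 90L, 90L, 100L, 100L),
    n_probe = c(0L, 10L, 10L, 0L, 0L),
    n_other = 0L,
    n_total = 100L
  )
  prof <- shell_profile(cnt)
  expect_equal(prof$pct_probe, c(0, 10, 10, 0, 0))
  expect_equal(prof$share_probe, c(0, 50, 50, 0, 0))

  zero <- dplyr::mutate(cnt, n_probe = 0L, n_nucleus = 100L)
  expect_warning(pz <- shell_profile(zero), "no probe")
  expect_equal(pz$share_probe, rep(0, 5))
  expect_error(shell_profile(cnt[0, ]), "empty")
})

test_that("the published worked example's percentages are reproduced", {
  # printed per-shell counts of the reference sample nucleus
  cnt <- tibble::tibble(
    shell = 1:5,
    n_nucleus = c(12207L, 10936L, 11015L, 11483L, 11406L),
    n_probe = c(10L, 1192L, 1221L, 716L, 653L),
    n_other = c(0L, 0L, 0L, 5L, 34L)
  )
  cnt$n_total <- cnt$n_nucleus + cnt$n_probe + cnt$n_other
  expect_identical(cnt$n_total, c(12217L, 12128L, 12236L, 12204L, 12093L))
  prof <- shell_profile(cnt)
  expect_equal(round(prof$pct_probe[2], 1), 9.8)
  expect_equal(round(prof$pct_probe, 1), c(0.1, 9.8, 10.0, 5.9, 5.4))
  expect_equal(round(prof$pct_nucleus, 1), c(99.9, 90.2, 90.0, 94.1, 94.3))
})
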