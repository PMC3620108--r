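#' Trace the nucleus contour by row scanning
#'
#' For every image row, scans from the left and from the right until the
#' first nucleus or probe pixel is met (a probe blob touching the nuclear rim
#' counts as boundary). Rows with no such pixel carry `NA` on both sides.
#' Concavities are bridged — the contour records only the per-row extremes,
#' so interior holes count as nucleus area.
#'
#' @param cls A `class_grid` (ideally after [remove_smudges()]).
#' @return A `nucleus_contour`: tibble with columns `y` (1..H), `left`,
#'   `right` (x of the outermost nucleus/probe pixel, `NA` when the row is
#'   empty).
#' @export
find_contour <- function(cls) {
  stopifnot(inherits(cls, "class_grid"))
  h <- nrow(cls); w <- ncol(cls)
  fg <- cls == CLS_NUCLEUS | cls == CLS_PROBE
  idx <- which(fg)
  if (length(idx) == 0) {
    abort("no nucleus or probe pixel found in image", class = "nucshell_no_nucleus")
  }
  ys <- ((idx - 1L) %% h) + 1L
  xs <- ((idx - 1L) %/% h) + 1L
  left <- rep(NA_integer_, h)
  right <- rep(NA_integer_, h)
  mn <- tapply(xs, ys, min)
  mx <- tapply(xs, ys, max)
  rows <- as.integer(names(mn))
  left[rows] <- as.integer(mn)
  right[rows] <- as.integer(mx)
  structure(
    tibble(y = seq_len(h), left = left, right = right),
    class = c("nucleus_contour", "tbl_df", "tbl", "data.frame"),
    width = w
  )
}

# fast accessors used by the geometry marchers
contour_spans <- function(contour) {
  list(left = contour$left, right = contour$right, h = nrow(contour))
}

# Vectorized interior test: a (sub-pixel) point is inside the nucleus region
# iff its nearest row has a contour span covering its nearest column.
in_contour <- function(x, y, spans) {
  ry <- as.integer(round(y))
  rx <- round(x)
  ok <- ry >= 1 & ry <= spans$h
  res <- logical(length(x))
  if (any(ok)) {
    l <- spans$left[ry[ok]]
    r <- spans$right[ry[ok]]
    res[ok] <- !is.na(l) & rx[ok] >= l & rx[ok] <= r
  }
  res
}

#' Bounding box of the nucleus contour
#'
#' Extreme points of the contour: `top`/`bottom` are the first/last occupied
#' rows (x at the midpoint of that row's span), `left`/`right` the global
#' horizontal extremes with their rows.
#'
#' @param contour A `nucleus_contour`.
#' @return A list with elements `top`, `bottom`, `left`, `right`, each a
#'   named numeric `c(x =, y =)`.
#' @export
bounding_box <- function(contour) {
  occ <- which(!is.na(contour$left))
  if (length(occ) == 0) {
    abort("empty contour", class = "nucshell_no_nucleus")
  }
  y_top <- occ[1]; y_bot <- occ[length(occ)]
  l <- contour$left[occ]; r <- contour$right[occ]
  i_l <- occ[which.min(l)]
  i_r <- occ[which.max(r)]
  pt <- function(x, y) c(x = as.numeric(x), y = as.numeric(y))
  list(
    top = pt((contour$left[y_top] + contour$right[y_top]) / 2, y_top),
    bottom = pt((contour$left[y_bot] + contour$right[y_bot]) / 2, y_bot),
    left = pt(min(l), i_l),
    right = pt(max(r), i_r)
  )
}

#' Initial midpoint from the bounding box
#'
#' The first midpoint estimate: `((right_x + left_x)/2, (top_y + bottom_y)/2)`,
#' kept as real numbers.
#'
#' @param box A bounding box from [bounding_box()].
#' @return Named numeric `c(x =, y =)`.
#' @export
initial_midpoint <- function(box) {
  c(x = (box$right["x"][[1]] + box$left["x"][[1]]) / 2,
    y = (box$top["y"][[1]] + box$bottom["y"][[1]]) / 2)
}

# Sub-pixel vertex localization. The raster contour is flat near an ellipse
# vertex: the literal farthest pixel can sit several degrees off the true
# vertex while being farther by under half a pixel. Fit distance-to-midpoint
# against angle with a quadratic over the near-vertex arc and take its apex.
# Falls back to the seed pixel when the arc is too short or not locally
# concave (e.g. a circle, where any diameter is acceptable).
locate_vertex <- function(px, py, mpt, seed_pt, window = 15 * pi / 180) {
  phi0 <- atan2(seed_pt[2] - mpt[2], seed_pt[1] - mpt[1])
  for (pass in 1:2) {
    dphi <- atan2(py - mpt[2], px - mpt[1]) - phi0
    dphi <- atan2(sin(dphi), cos(dphi)) # wrap to (-pi, pi]
    arc <- abs(dphi) <= window
    if (sum(arc) < 6) return(seed_pt)
    d <- sqrt((px[arc] - mpt[1])^2 + (py[arc] - mpt[2])^2)
    psi <- dphi[arc]
    fit <- stats::lm.fit(cbind(1, psi, psi^2), d)
    c1 <- fit$coefficients[2]; c2 <- fit$coefficients[3]
    if (!is.finite(c2) || c2 >= -1e-6) return(seed_pt)
    shift <- -c1 / (2 * c2)
    shift <- max(min(shift, window), -window)
    phi0 <- phi0 + shift
    if (abs(shift) < 1e-4) break
  }
  dv <- fit$coefficients[1] + c1 * shift + c2 * shift^2
  c(x = unname(mpt[1] + dv * cos(phi0)), y = unname(mpt[2] + dv * sin(phi0)))
}

# March from an interior start point along `dir` (unit vector) in 0.25-px
# steps; return the last point still inside the contour region.
march_to_boundary <- function(start, dir, spans, step = 0.25) {
  tmax <- spans$h + length(spans$left) + max(abs(spans$right), na.rm = TRUE)
  tt <- seq(0, tmax, by = step)
  xs <- start[1] + tt * dir[1]
  ys <- start[2] + tt * dir[2]
  inside <- in_contour(xs, ys, spans)
  if (!inside[1]) {
    abort("march start point lies outside the nucleus contour",
          class = "nucshell_geometry_error")
  }
  last <- which(!inside)[1]
  if (is.na(last)) last <- length(tt) + 1L
  i <- last - 1L
  c(x = xs[i], y = ys[i])
}

#' Major axis endpoints
#'
#' The first endpoint is the contour point farthest from the midpoint (ties
#' broken toward smallest y, then smallest x); the line through the midpoint
#' is then extended to the opposite side of the perimeter in 0.25-px steps,
#' and the last interior point is the second endpoint.
#'
#' Because the contour is an integer raster and an ellipse is flat near its
#' vertex, the literal farthest pixel can sit several degrees off the true
#' vertex while being farther by under half a pixel. By default the endpoint
#' is therefore the centroid of the near-maximal contour arc — all contour
#' points within 1 px of the maximum distance and within 20 degrees (about
#' the midpoint) of the farthest pixel — which is the sub-pixel estimate of
#' the same vertex. Set `stabilize = FALSE` for the raw farthest pixel.
#'
#' @param contour A `nucleus_contour`.
#' @param mpt Midpoint `c(x, y)`.
#' @param stabilize Use the near-maximal arc centroid (default) instead of
#'   the single farthest pixel.
#' @return List with `majpt1`, `majpt2` (named numeric points).
#' @export
major_axis <- function(contour, mpt, stabilize = TRUE) {
  occ <- !is.na(contour$left)
  px <- c(contour$left[occ], contour$right[occ])
  py <- c(contour$y[occ], contour$y[occ])
  u <- !duplicated(cbind(px, py))
  px <- px[u]; py <- py[u]
  if (length(px) < 2) {
    abort("contour is degenerate (fewer than 2 distinct points)",
          class = "nucshell_degenerate")
  }
  d2 <- (px - mpt[1])^2 + (py - mpt[2])^2
  ord <- order(-d2, py, px)
  majpt1 <- c(x = as.numeric(px[ord[1]]), y = as.numeric(py[ord[1]]))
  if (stabilize) {
    majpt1 <- locate_vertex(px, py, mpt, majpt1)
  }
  v <- c(mpt[1] - majpt1[1], mpt[2] - majpt1[2])
  nv <- sqrt(sum(v^2))
  if (nv == 0) {
    abort("midpoint coincides with the farthest contour point",
          class = "nucshell_degenerate")
  }
  spans <- contour_spans(contour)
  majpt2 <- march_to_boundary(unname(mpt), v / nv, spans)
  list(majpt1 = majpt1, majpt2 = c(x = majpt2[["x"]], y = majpt2[["y"]]))
}

#' Refined midpoint
#'
#' The arithmetic midpoint of the two major-axis endpoints; used because a
#' real nucleus is rarely a perfect ellipse, so the bounding-box midpoint is
#' only a first guess.
#'
#' @param majpt1,majpt2 Major-axis endpoints.
#' @return Named numeric `c(x =, y =)`.
#' @export
refine_midpoint <- function(majpt1, majpt2) {
  if (all(abs(majpt1 - majpt2) < 1e-12)) {
    abort("major-axis endpoints coincide", class = "nucshell_degenerate")
  }
  c(x = (majpt1[["x"]] + majpt2[["x"]]) / 2,
    y = (majpt1[["y"]] + majpt2[["y"]]) / 2)
}

#' Minor axis endpoints
#'
#' Marches from the refined midpoint perpendicular to the major axis, in both
#' directions, to the two perimeter intersections. The semi-minor length is
#' half the chord even when the chord is asymmetric about the midpoint.
#'
#' @param contour A `nucleus_contour`.
#' @param mpt Refined midpoint (must lie inside the contour).
#' @param theta Major-axis angle (radians).
#' @return List with `minpt1`, `minpt2`.
#' @export
minor_axis <- function(contour, mpt, theta) {
  spans <- contour_spans(contour)
  dir <- c(cos(theta + pi / 2), sin(theta + pi / 2))
  p1 <- march_to_boundary(unname(mpt), dir, spans)
  p2 <- march_to_boundary(unname(mpt), -dir, spans)
  list(minpt1 = c(x = p1[["x"]], y = p1[["y"]]),
       minpt2 = c(x = p2[["x"]], y = p2[["y"]]))
}

#' Estimate nucleus geometry from a classified image
#'
#' Runs the full geometric chain: contour scan, bounding box, initial
#' midpoint, major axis, refined midpoint, minor axis. The semi-axes are half
#' the endpoint distances; `theta` is the major-axis angle in `[0, pi)`.
#' When rasterization noise on a near-circular nucleus makes the perpendicular
#' chord marginally longer than the major chord, axes are swapped so that
#' `a >= b` always holds.
#'
#' @param cls A `class_grid` (ideally smudge-cleaned).
#' @param contour Optional precomputed `nucleus_contour`.
#' @return A `nucleus_geometry`: list with `mpt`, `majpt1`, `majpt2`,
#'   `minpt1`, `minpt2`, semi-axes `a`, `b`, and `theta` (radians).
#' @export
estimate_geometry <- function(cls, contour = NULL) {
  if (is.null(contour)) contour <- find_contour(cls)
  box <- bounding_box(contour)
  mpt0 <- initial_midpoint(box)
  maj <- major_axis(contour, mpt0)
  mpt <- refine_midpoint(maj$majpt1, maj$majpt2)
  dvec <- maj$majpt2 - maj$majpt1
  theta <- atan2(dvec[["y"]], dvec[["x"]]) %% pi
  mins <- minor_axis(contour, mpt, theta)
  a <- sqrt(sum((maj$majpt1 - maj$majpt2)^2)) / 2
  b <- sqrt(sum((mins$minpt1 - mins$minpt2)^2)) / 2
  majpt1 <- maj$majpt1; majpt2 <- maj$majpt2
  minpt1 <- mins$minpt1; minpt2 <- mins$minpt2
  if (b > a) {
    tmp <- a; a <- b; b <- tmp
    tmp <- majpt1; majpt1 <- minpt1; minpt1 <- tmp
    tmp <- majpt2; majpt2 <- minpt2; minpt2 <- tmp
    theta <- (theta + pi / 2) %% pi
  }
  if (b <= 0) {
    abort("degenerate nucleus: zero minor axis", class = "nucshell_degenerate")
  }
  structure(
    list(mpt = mpt, majpt1 = majpt1, majpt2 = majpt2,
         minpt1 = minpt1, minpt2 = minpt2, a = a, b = b, theta = theta),
    class = "nucleus_geometry"
  )
}

#' @export
print.nucleus_geometry <- function(x, ...) {
  cat(sprintf(
    "<nucleus_geometry> center (%.1f, %.1f), a = %.1f px, b = %.1f px, theta = %.1f deg\n",
    x$mpt[1], x$mpt[2], x$a, x$b, x$theta * 180 / pi
  ))
  invisible(x)
}

#' Tidy a nucleus geometry into a one-row tibble
#'
#' @param x A `nucleus_geometry`.
#' @param ... Unused.
#' @return A one-row tibble with midpoint, semi-axes, orientation (degrees)
#'   and axis endpoints.
#' @export
tidy.nucleus_geometry <- function(x, ...) {
  tibble(
    mpt_x = x$mpt[["x"]], mpt_y = x$mpt[["y"]],
    a = x$a, b = x$b, theta_deg = x$theta * 180 / pi,
    majpt1_x = x$majpt1[["x"]], majpt1_y = x$majpt1[["y"]],
    majpt2_x = x$majpt2[["x"]], majpt2_y = x$majpt2[["y"]],
    minpt1_x = x$minpt1[["x"]], minpt1_y = x$minpt1[["y"]],
    minpt2_x = x$minpt2[["x"]], minpt2_y = x$minpt2[["y"]]
  )
}
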