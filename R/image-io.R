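#' Pixel grid constructor
#'
#' Wraps an H x W x 3 numeric array (channels in `[0, 1]`, rows = y from the
#' top, columns = x from the left) as a `pixel_grid`. Images smaller than
#' 3 x 3 are rejected: they cannot hold a nucleus plus a background margin.
#'
#' @param px Numeric array, dimensions `c(H, W, 3)`, values in `[0, 1]`.
#' @return A `pixel_grid`.
#' @export
pixel_grid <- function(px) {
  if (!is.array(px) || length(dim(px)) != 3 || dim(px)[3] != 3) {
    abort("`px` must be an H x W x 3 array")
  }
  if (dim(px)[1] < 3 || dim(px)[2] < 3) {
    abort("image too small: width and height must both be >= 3 pixels")
  }
  if (anyNA(px) || min(px) < 0 || max(px) > 1) {
    abort("pixel channels must lie in [0, 1]")
  }
  structure(px, class = "pixel_grid")
}

#' @export
print.pixel_grid <- function(x, ...) {
  cat("<pixel_grid> ", dim(x)[2], "x", dim(x)[1], " (W x H), RGB in [0,1]\n",
      sep = "")
  invisible(x)
}

#' Image width and height
#'
#' @param grid A `pixel_grid` or `class_grid`.
#' @return Named integer vector `c(w = , h = )`.
#' @export
grid_dim <- function(grid) {
  d <- dim(grid)
  c(w = as.integer(d[2]), h = as.integer(d[1]))
}

#' Read a nucleus image into a pixel grid
#'
#' Decodes a PNG, JPEG or TIFF raster into an H x W x 3 array with channels
#' normalized to `[0, 1]`. Palettized/16-bit images are scaled on decode; an
#' alpha channel is composited over `alpha_background`; grayscale images are
#' rejected because the method needs three distinguishable color classes.
#' GIF is not supported by the available decoders.
#'
#' @param path Path to the image file.
#' @param alpha_background RGB triplet used to flatten an alpha channel.
#' @return A `pixel_grid`.
#' @export
read_nucleus_image <- function(path, alpha_background = c(1, 1, 1)) {
  if (!file.exists(path)) {
    abort(sprintf("image file not found: %s", path))
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "gif") {
    abort(sprintf("GIF input is not supported (no decoder available): %s", path))
  }
  img <- tryCatch(
    suppressWarnings(EBImage::readImage(path)),
    error = function(e) abort(sprintf("cannot decode image %s: %s", path,
                                      conditionMessage(e)))
  )
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 2) {
    abort(sprintf(
      "grayscale image rejected (%s): three distinguishable colors required",
      path
    ))
  }
  nch <- dim(a)[3]
  # EBImage stores (x, y, channel); convert to (y, x, channel)
  a <- aperm(a, c(2, 1, 3))
  if (nch >= 4) {
    alpha <- a[, , 4]
    rgb <- a[, , 1:3, drop = FALSE]
    for (ch in 1:3) {
      rgb[, , ch] <- rgb[, , ch] * alpha + alpha_background[ch] * (1 - alpha)
    }
    a <- rgb
  } else if (nch == 3) {
    a <- a[, , 1:3, drop = FALSE]
  } else {
    abort(sprintf("unsupported channel count (%d) in %s", nch, path))
  }
  a[a < 0] <- 0
  a[a > 1] <- 1
  pixel_grid(a)
}

#' Write a pixel grid as a PNG image
#'
#' @param grid A `pixel_grid`.
#' @param path Output path (PNG).
#' @return `path`, invisibly.
#' @export
write_image <- function(grid, path) {
  stopifnot(inherits(grid, "pixel_grid"))
  a <- aperm(unclass(grid), c(2, 1, 3))
  img <- EBImage::Image(a, colormode = "Color")
  EBImage::writeImage(img, path)
  invisible(path)
}

set_pixels <- function(px, x, y, col) {
  d <- dim(px)
  x <- round(x); y <- round(y)
  keep <- x >= 1 & x <= d[2] & y >= 1 & y <= d[1]
  x <- x[keep]; y <- y[keep]
  if (length(x)) {
    for (ch in 1:3) px[cbind(y, x, ch)] <- col[ch]
  }
  px
}

# Default annotation colors; shells run center -> periphery as in the
# published renderings (yellow, green, magenta, blue, aqua).
annotation_colors <- function(n_shells = 5) {
  base <- list(
    contour = c(1, 1, 0),
    major_axis = c(0, 1, 0),
    minor_axis = c(0, 0, 1)
  )
  ramp <- grDevices::colorRamp(
    c("yellow", "green", "magenta", "blue", "cyan")
  )(seq(0, 1, length.out = max(n_shells, 2)))[seq_len(n_shells), , drop = FALSE] / 255
  base$shells <- lapply(seq_len(n_shells), function(i) as.numeric(ramp[i, ]))
  base
}

#' Write an annotated diagnostic image
#'
#' Renders the computed contour (yellow), major axis (green), minor axis
#' (blue) and the boundaries of the N concentric equal-area ellipses (one
#' distinct color per shell, from center outward) on top of the input image,
#' and writes the result as PNG. The input grid is never modified.
#'
#' @param grid A `pixel_grid`.
#' @param path Output PNG path.
#' @param contour Optional `nucleus_contour` (see [find_contour()]).
#' @param geometry Optional `nucleus_geometry` (see [estimate_geometry()]).
#' @param n_shells Number of shells whose boundaries to draw (requires
#'   `geometry`); use 0 to skip shells.
#' @param colors Color set from [annotation_colors()].
#' @return `path`, invisibly.
#' @export
write_annotated <- function(grid, path, contour = NULL, geometry = NULL,
                            n_shells = 0,
                            colors = annotation_colors(max(n_shells, 1))) {
  stopifnot(inherits(grid, "pixel_grid"))
  px <- unclass(grid)
  d <- dim(px)
  if (n_shells > 0) {
    if (is.null(geometry)) abort("shell annotation requires `geometry`")
    # boundary ellipses at e = k/N, k = 1..N (k = N is the fitted ellipse)
    for (k in seq_len(n_shells)) {
      s <- sqrt(k / n_shells)
      a <- geometry$a * s; b <- geometry$b * s
      tt <- seq(0, 2 * pi, length.out = max(64, ceiling(8 * pi * a)))
      ex <- a * cos(tt); ey <- b * sin(tt)
      xr <- geometry$mpt[1] + ex * cos(geometry$theta) - ey * sin(geometry$theta)
      yr <- geometry$mpt[2] + ex * sin(geometry$theta) + ey * cos(geometry$theta)
      px <- set_pixels(px, xr, yr, colors$shells[[k]])
    }
  }
  if (!is.null(contour)) {
    cc <- contour[!is.na(contour$left), ]
    px <- set_pixels(px, c(cc$left, cc$right), c(cc$y, cc$y), colors$contour)
  }
  if (!is.null(geometry)) {
    seg <- function(p1, p2) {
      n <- max(2, ceiling(2 * sqrt(sum((p2 - p1)^2))))
      list(x = seq(p1[1], p2[1], length.out = n),
           y = seq(p1[2], p2[2], length.out = n))
    }
    s1 <- seg(geometry$majpt1, geometry$majpt2)
    px <- set_pixels(px, s1$x, s1$y, colors$major_axis)
    s2 <- seg(geometry$minpt1, geometry$minpt2)
    px <- set_pixels(px, s2$x, s2$y, colors$minor_axis)
  }
  write_image(pixel_grid(px), path)
}
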