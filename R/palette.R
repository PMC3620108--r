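#' Reference color palette for pixel classification
#'
#' Defines the three reference colors that must be distinguishable in a
#' 2D-FISH image — background, nucleus counterstain and chromosome probe —
#' together with a per-channel tolerance. A pixel matches a class when every
#' RGB channel lies within `tolerance` of that class's reference color; with
#' the defaults, `[0.9, 0.1, 0.1]` is still probe (red) just as `[1, 0, 0]` is.
#'
#' Construction fails if any two reference colors could both match one pixel,
#' i.e. if all three channel intervals of one color overlap those of another
#' under the given tolerance — classification must be unambiguous.
#'
#' @param background,nucleus,probe RGB triplets in `[0, 1]`. Defaults follow
#'   the usual 2D-FISH rendering: white background, blue (DAPI) nucleus,
#'   red probe.
#' @param tolerance Per-channel maximum absolute deviation, in `(0, 0.5)`.
#' @return An object of class `fish_palette`.
#' @examples
#' pal <- fish_palette()
#' classify_pixel(c(0.9, 0.1, 0.1), pal) # "probe"
#' @export
fish_palette <- function(background = c(1, 1, 1),
                         nucleus = c(0, 0, 1),
                         probe = c(1, 0, 0),
                         tolerance = 0.15) {
  check_rgb <- function(x, what) {
    if (!is.numeric(x) || length(x) != 3 || anyNA(x) || any(x < 0) || any(x > 1)) {
      abort(sprintf("`%s` must be an RGB triplet with channels in [0, 1]", what))
    }
    as.numeric(x)
  }
  background <- check_rgb(background, "background")
  nucleus <- check_rgb(nucleus, "nucleus")
  probe <- check_rgb(probe, "probe")
  if (!is.numeric(tolerance) || length(tolerance) != 1 ||
      !is.finite(tolerance) || tolerance <= 0 || tolerance >= 0.5) {
    abort("`tolerance` must be a single number in (0, 0.5)")
  }
  refs <- list(background = background, nucleus = nucleus, probe = probe)
  pairs <- utils::combn(names(refs), 2, simplify = FALSE)
  for (p in pairs) {
    # two classes are ambiguous iff every channel interval pair overlaps
    if (all(abs(refs[[p[1]]] - refs[[p[2]]]) <= 2 * tolerance)) {
      abort(sprintf(
        "palette colors `%s` and `%s` are not mutually exclusive at tolerance %.3g",
        p[1], p[2], tolerance
      ))
    }
  }
  structure(
    list(background = background, nucleus = nucleus, probe = probe,
         tolerance = tolerance),
    class = "fish_palette"
  )
}

#' @export
print.fish_palette <- function(x, ...) {
  fmt <- function(v) paste0("[", paste(format(v, digits = 3), collapse = ", "), "]")
  cat("<fish_palette>\n",
      "  background ", fmt(x$background), "\n",
      "  nucleus    ", fmt(x$nucleus), "\n",
      "  probe      ", fmt(x$probe), "\n",
      "  tolerance  ", format(x$tolerance), "\n", sep = "")
  invisible(x)
}

#' Classify a single RGB triplet
#'
#' Returns the class whose reference color matches the pixel within the
#' palette tolerance on every channel, or `"other"` when none matches.
#' Palette construction guarantees at most one class can match.
#'
#' @param rgb Numeric RGB triplet in `[0, 1]`.
#' @param palette A [fish_palette()].
#' @return One of `"background"`, `"nucleus"`, `"probe"`, `"other"`.
#' @export
classify_pixel <- function(rgb, palette = fish_palette()) {
  stopifnot(is.numeric(rgb), length(rgb) == 3)
  tol <- palette$tolerance
  for (lbl in c("probe", "nucleus", "background")) {
    if (all(abs(rgb - palette[[lbl]]) <= tol)) return(lbl)
  }
  "other"
}

#' Classify every pixel of an image
#'
#' Vectorized [classify_pixel()] over a pixel grid: each pixel is labeled
#' background, nucleus, probe or other by the palette's RGB ranges.
#'
#' @param grid A `pixel_grid` from [read_nucleus_image()] or
#'   [make_nucleus_image()].
#' @param palette A [fish_palette()].
#' @return A `class_grid`: an integer H x W matrix with levels attribute;
#'   use [class_counts()] or `class_label()` codes 0..3 for
#'   background/nucleus/probe/other.
#' @export
classify_grid <- function(grid, palette = fish_palette()) {
  stopifnot(inherits(grid, "pixel_grid"))
  px <- unclass(grid)
  tol <- palette$tolerance
  match_class <- function(ref) {
    abs(px[, , 1] - ref[1]) <= tol &
      abs(px[, , 2] - ref[2]) <= tol &
      abs(px[, , 3] - ref[3]) <= tol
  }
  lbl <- matrix(CLS_OTHER, nrow = dim(px)[1], ncol = dim(px)[2])
  lbl[match_class(palette$background)] <- CLS_BACKGROUND
  lbl[match_class(palette$nucleus)] <- CLS_NUCLEUS
  lbl[match_class(palette$probe)] <- CLS_PROBE
  structure(lbl, class = "class_grid", levels = CLASS_LEVELS)
}

#' Tally pixel classes in a class grid
#'
#' @param cls A `class_grid`.
#' @return A tibble with columns `class` and `n`.
#' @export
class_counts <- function(cls) {
  stopifnot(inherits(cls, "class_grid"))
  tb <- tabulate(as.integer(cls) + 1L, nbins = 4L)
  tibble(class = CLASS_LEVELS, n = tb)
}

#' @export
print.class_grid <- function(x, ...) {
  cat("<class_grid> ", ncol(x), "x", nrow(x), " (W x H)\n", sep = "")
  print(class_counts(x))
  invisible(x)
}
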