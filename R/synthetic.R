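#' Specification of a synthetic 2D-FISH-like nucleus image
#'
#' Describes an elliptical nucleus at arbitrary orientation with probe signal
#' placed at controlled normalized radial positions, plus optional off-nucleus
#' smudges — everything needed to emulate a flattened 2D-FISH nucleus with a
#' known answer. Rendering is deterministic given `seed`.
#'
#' @param width,height Image size in pixels.
#' @param center Nucleus center `c(x, y)`; defaults to the image center.
#' @param a,b True semi-axes in pixels (`a >= b > 0`).
#' @param theta True orientation of the major axis, radians.
#' @param blobs Probe blobs: a data frame with columns `u` (normalized radial
#'   position of the blob center, in `[0, 1)`), `angle` (radians, position
#'   around the ellipse) and `radius` (pixels). Blob pixels are clipped to the
#'   nucleus.
#' @param wash_density If non-`NULL`, each nucleus pixel is independently
#'   recolored as probe with this probability. Either a single number (a
#'   uniform probe wash) or a function of the normalized elliptical coordinate
#'   `e` returning per-pixel probabilities — e.g. a density decreasing in `e`
#'   emulates an interior-localized (gene-rich, chromosome-19-like) territory,
#'   an increasing one a peripheral (chromosome-18-like) territory.
#' @param smudges Off-nucleus artifacts: data frame with columns `x`, `y`
#'   (center, must lie outside the nucleus) and `radius` (pixels), drawn in
#'   the probe color.
#' @param palette A [fish_palette()] supplying the three colors.
#' @param margin Minimum background margin (pixels) required between the
#'   nucleus and the image border.
#' @param seed RNG seed for the wash.
#' @return A `nucleus_spec` list.
#' @export
nucleus_spec <- function(width = 301, height = 301,
                         center = c(x = (width + 1) / 2, y = (height + 1) / 2),
                         a = 100, b = 60, theta = 0,
                         blobs = NULL, wash_density = NULL, smudges = NULL,
                         palette = fish_palette(), margin = 7, seed = 1) {
  if (a < b || b <= 0) abort("true semi-axes must satisfy a >= b > 0")
  # extent of a rotated ellipse along x / y
  ext_x <- sqrt((a * cos(theta))^2 + (b * sin(theta))^2)
  ext_y <- sqrt((a * sin(theta))^2 + (b * cos(theta))^2)
  if (center[1] - ext_x < margin + 1 || center[1] + ext_x > width - margin ||
      center[2] - ext_y < margin + 1 || center[2] + ext_y > height - margin) {
    abort("nucleus does not fit inside the image with the required background margin")
  }
  if (!is.null(blobs)) {
    blobs <- as_tibble(blobs)
    stopifnot(all(c("u", "angle", "radius") %in% names(blobs)))
    if (any(blobs$u < 0 | blobs$u >= 1)) {
      abort("blob radial positions `u` must lie in [0, 1)")
    }
  }
  if (!is.null(smudges)) {
    smudges <- as_tibble(smudges)
    stopifnot(all(c("x", "y", "radius") %in% names(smudges)))
  }
  structure(
    list(width = width, height = height,
         center = c(x = unname(center[1]), y = unname(center[2])),
         a = a, b = b, theta = theta,
         blobs = blobs, wash_density = wash_density, smudges = smudges,
         palette = palette, margin = margin, seed = seed),
    class = "nucleus_spec"
  )
}

# geometry object carrying the generator's exact parameters, so the same
# shell-assignment code can be evaluated against the truth
true_geometry <- function(spec) {
  ct <- cos(spec$theta); st <- sin(spec$theta)
  maj1 <- c(x = spec$center[["x"]] - spec$a * ct, y = spec$center[["y"]] - spec$a * st)
  maj2 <- c(x = spec$center[["x"]] + spec$a * ct, y = spec$center[["y"]] + spec$a * st)
  min1 <- c(x = spec$center[["x"]] - spec$b * st * -1, y = spec$center[["y"]] - spec$b * ct)
  min2 <- c(x = spec$center[["x"]] + spec$b * st * -1, y = spec$center[["y"]] + spec$b * ct)
  structure(
    list(mpt = spec$center, majpt1 = maj1, majpt2 = maj2,
         minpt1 = min1, minpt2 = min2,
         a = spec$a, b = spec$b, theta = spec$theta %% pi),
    class = "nucleus_geometry"
  )
}

with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Render a synthetic nucleus image with exact ground truth
#'
#' Rasterizes the nucleus with the centers-in convention (a pixel belongs to
#' the ellipse iff its center satisfies `e <= 1` under the true geometry),
#' overdraws probe blobs and/or a uniform probe wash, adds off-nucleus
#' smudges, and computes exact per-shell, per-class pixel counts by brute
#' force against the TRUE geometry — so geometry-recovery error and counting
#' error can be measured separately downstream.
#'
#' @param spec A [nucleus_spec()].
#' @param n_shells Number of shells used for the ground-truth tally.
#' @return List with `grid` (a `pixel_grid`), `cls` (the exactly drawn
#'   `class_grid`), `truth` (list: `geometry` — a `nucleus_geometry` holding
#'   the true parameters, `counts` — a `shell_counts` tibble from the true
#'   geometry, `n_smudge_px` — pixels drawn as smudges) and `spec`.
#' @export
make_nucleus_image <- function(spec, n_shells = 5) {
  stopifnot(inherits(spec, "nucleus_spec"))
  w <- spec$width; h <- spec$height
  pal <- spec$palette
  geom <- true_geometry(spec)
  xs <- matrix(rep(seq_len(w), each = h), nrow = h)
  ys <- matrix(rep(seq_len(h), times = w), nrow = h)
  e <- matrix(normalized_coord(as.vector(xs), as.vector(ys), geom), nrow = h)
  lab <- matrix(CLS_BACKGROUND, h, w)
  lab[e <= 1] <- CLS_NUCLEUS

  if (!is.null(spec$wash_density)) {
    nuc_idx <- which(lab == CLS_NUCLEUS)
    prob <- if (is.function(spec$wash_density)) {
      p <- spec$wash_density(e[nuc_idx])
      if (any(p < 0 | p > 1)) abort("wash density function must return probabilities")
      p
    } else spec$wash_density
    pick <- with_local_seed(spec$seed,
      nuc_idx[runif(length(nuc_idx)) < prob])
    lab[pick] <- CLS_PROBE
  }
  if (!is.null(spec$blobs)) {
    ct <- cos(spec$theta); st <- sin(spec$theta)
    for (i in seq_len(nrow(spec$blobs))) {
      bl <- spec$blobs[i, ]
      ex <- spec$a * bl$u * cos(bl$angle)
      ey <- spec$b * bl$u * sin(bl$angle)
      cx <- spec$center[["x"]] + ex * ct - ey * st
      cy <- spec$center[["y"]] + ex * st + ey * ct
      hit <- (xs - cx)^2 + (ys - cy)^2 <= bl$radius^2 & e <= 1
      lab[hit] <- CLS_PROBE
    }
  }
  n_smudge <- 0L
  if (!is.null(spec$smudges)) {
    for (i in seq_len(nrow(spec$smudges))) {
      sm <- spec$smudges[i, ]
      if (normalized_coord(sm$x, sm$y, geom) <= 1) {
        abort("smudge center lies inside the nucleus")
      }
      hit <- (xs - sm$x)^2 + (ys - sm$y)^2 <= sm$radius^2 & e > 1
      n_smudge <- n_smudge + sum(hit)
      lab[hit] <- CLS_PROBE
    }
  }

  px <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) {
    m <- matrix(pal$background[ch], h, w)
    m[lab == CLS_NUCLEUS] <- pal$nucleus[ch]
    m[lab == CLS_PROBE] <- pal$probe[ch]
    px[, , ch] <- m
  }

  # brute-force ground truth from the true geometry; smudges excluded (they
  # are outside the nucleus region by construction)
  inside <- e <= 1 # truth region: the true ellipse
  shell <- assign_shell(as.vector(e), as.vector(inside), n_shells)
  lv <- as.vector(lab)
  truth_tal <- function(code) {
    sel <- lv == code & !is.na(shell)
    tabulate(shell[sel], nbins = n_shells)
  }
  counts <- tibble(
    shell = seq_len(n_shells),
    n_nucleus = truth_tal(CLS_NUCLEUS),
    n_probe = truth_tal(CLS_PROBE), # smudge pixels have NA shells, so excluded
    n_other = rep(0L, n_shells)
  )
  counts$n_total <- counts$n_nucleus + counts$n_probe + counts$n_other
  class(counts) <- c("shell_counts", class(counts))

  list(
    grid = pixel_grid(px),
    cls = structure(lab, class = "class_grid", levels = CLASS_LEVELS),
    truth = list(geometry = geom, counts = counts, n_smudge_px = n_smudge),
    spec = spec
  )
}

#' Canonical synthetic test cases
#'
#' A named collection of rendered fixtures with ground truth, covering the
#' situations the analysis must handle: axis-aligned and rotated ellipses, a
#' circle, an interior probe blob, a peripheral probe ring, a uniform wash, a
#' smudged image with its clean twin, a large-smudge escape case, a one-pixel
#' degenerate nucleus and an all-background image.
#'
#' @param seed Base RNG seed.
#' @return Named list; each regular element is the list returned by
#'   [make_nucleus_image()]. The degenerate entries (`one_pixel`,
#'   `all_background`) carry `grid` and `cls` only.
#' @export
fixture_suite <- function(seed = 42) {
  pal <- fish_palette()
  out <- list()
  out$axis_aligned <- make_nucleus_image(nucleus_spec(
    width = 401, height = 385, a = 100, b = 50, theta = 0, seed = seed
  ))
  out$rotated_30 <- make_nucleus_image(nucleus_spec(
    width = 301, height = 301, a = 100, b = 50, theta = 30 * pi / 180,
    seed = seed + 1
  ))
  out$circle <- make_nucleus_image(nucleus_spec(
    width = 221, height = 221, a = 80, b = 80, seed = seed + 2
  ))
  out$interior_blob <- make_nucleus_image(nucleus_spec(
    width = 301, height = 241, a = 110, b = 70,
    blobs = tibble(u = 0.1, angle = 0.4, radius = 10), seed = seed + 3
  ))
  out$peripheral_ring <- make_nucleus_image(nucleus_spec(
    width = 301, height = 241, a = 110, b = 70,
    blobs = tibble(u = 0.93, angle = seq(0, 2 * pi, length.out = 9)[1:8],
                   radius = 5),
    seed = seed + 4
  ))
  out$uniform_wash <- make_nucleus_image(nucleus_spec(
    width = 281, height = 241, a = 100, b = 70, theta = 0.3,
    wash_density = 0.3, seed = seed + 5
  ))
  clean_spec <- nucleus_spec(
    width = 301, height = 261, a = 100, b = 60, theta = 20 * pi / 180,
    blobs = tibble(u = 0.5, angle = 1.0, radius = 8), seed = seed + 6
  )
  out$smudge_clean_twin <- make_nucleus_image(clean_spec)
  smudged_spec <- clean_spec
  smudged_spec$smudges <- tibble(x = c(20, 280), y = c(20, 240),
                                 radius = c(1.6, 1.6))
  out$smudged <- make_nucleus_image(smudged_spec)
  large_spec <- clean_spec
  large_spec$smudges <- tibble(x = 25, y = 230, radius = 9)
  out$large_smudge <- make_nucleus_image(large_spec)

  one_px_lab <- matrix(CLS_BACKGROUND, 11, 11)
  one_px_lab[4, 7] <- CLS_NUCLEUS # (x = 7, y = 4)
  px <- array(1, dim = c(11, 11, 3))
  for (ch in 1:3) px[4, 7, ch] <- pal$nucleus[ch]
  out$one_pixel <- list(
    grid = pixel_grid(px),
    cls = structure(one_px_lab, class = "class_grid", levels = CLASS_LEVELS)
  )
  out$all_background <- list(
    grid = pixel_grid(array(1, dim = c(9, 9, 3))),
    cls = structure(matrix(CLS_BACKGROUND, 9, 9),
                    class = "class_grid", levels = CLASS_LEVELS)
  )
  out
}

#' Write a fixture directory for end-to-end runs
#'
#' Emits the [fixture_suite()] images as PNG files plus a ground-truth JSON
#' and a batch list file, ready for the command-line `run` subcommand.
#'
#' @param outdir Output directory (created if missing).
#' @param seed Base RNG seed.
#' @return Path of the batch list file, invisibly.
#' @export
write_fixture_suite <- function(outdir, seed = 42) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    abort("writing fixtures requires the jsonlite package")
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  suite <- fixture_suite(seed)
  paths <- character(0)
  truth <- list()
  for (nm in names(suite)) {
    p <- file.path(outdir, paste0(nm, ".png"))
    write_image(suite[[nm]]$grid, p)
    paths <- c(paths, p)
    if (!is.null(suite[[nm]]$truth)) {
      tr <- suite[[nm]]$truth
      truth[[nm]] <- list(
        a = tr$geometry$a, b = tr$geometry$b,
        theta = tr$geometry$theta,
        center = as.list(tr$geometry$mpt),
        counts = as.data.frame(tr$counts)
      )
    }
  }
  jsonlite::write_json(truth, file.path(outdir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  listfile <- file.path(outdir, "images.txt")
  writeLines(c("# synthetic fixture suite", paths), listfile)
  invisible(listfile)
}
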