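#' Semi-axes of the equal-area concentric ellipses
#'
#' The nucleus of semi-axes `A`, `B` (area `pi*A*B`) is split into `N`
#' concentric shells of equal area by `N - 1` interior ellipses that keep the
#' aspect ratio `A/B`: ellipse `k` has area `k/N * pi*A*B`, giving semi-axes
#' `a_k = A*sqrt(k/N)`, `b_k = B*sqrt(k/N)`. The outermost shell is bounded by
#' the true contour and is irregular, which avoids any erosion/smoothing of
#' the nuclear periphery.
#'
#' @param a,b Semi-major and semi-minor axis lengths (pixels), `a >= b > 0`.
#' @param n_shells Number of shells `N >= 1`.
#' @return Tibble with columns `k` (1..N-1), `a_k`, `b_k`; zero rows for
#'   `N = 1` (the whole nucleus is one irregular shell).
#' @examples
#' shell_radii(100, 50, 5)
#' @export
shell_radii <- function(a, b, n_shells = 5) {
  if (!is.numeric(n_shells) || length(n_shells) != 1 || n_shells < 1 ||
      n_shells != round(n_shells)) {
    abort("`n_shells` must be a positive integer")
  }
  if (!is.numeric(a) || !is.numeric(b) || a < b || b <= 0) {
    abort("semi-axes must satisfy a >= b > 0")
  }
  k <- seq_len(n_shells - 1)
  tibble(k = k, a_k = a * sqrt(k / n_shells), b_k = b * sqrt(k / n_shells))
}

#' Normalized elliptical coordinate
#'
#' Rotates a point into the nucleus axis frame about the midpoint and returns
#' `e = (x'/A)^2 + (y'/B)^2`. `e = 0` at the center, `e = 1` on the fitted
#' ellipse; `e <= k/N` selects the k-th concentric equal-area ellipse.
#'
#' @param x,y Point coordinates (vectorized).
#' @param geometry A `nucleus_geometry`.
#' @return Numeric vector of `e` values (`>= 0`).
#' @export
normalized_coord <- function(x, y, geometry) {
  dx <- x - geometry$mpt[["x"]]
  dy <- y - geometry$mpt[["y"]]
  ct <- cos(geometry$theta); st <- sin(geometry$theta)
  xp <- ct * dx + st * dy
  yp <- -st * dx + ct * dy
  (xp / geometry$a)^2 + (yp / geometry$b)^2
}

#' Shell number of a point
#'
#' Maps the normalized coordinate to a shell, numbered 1 = periphery up to
#' `N` = center (the interior-most shell). Points inside the contour but
#' outside the largest full ellipse (`e > 1`) fall in the irregular outermost
#' shell 1; points outside the contour get `NA`. A boundary value
#' `e = k/N` belongs to the inner ring.
#'
#' @param e Normalized coordinate(s) from [normalized_coord()].
#' @param inside_contour Logical, whether each point lies in the nucleus
#'   region (recycled).
#' @param n_shells Number of shells.
#' @return Integer shell numbers (1..N) or `NA`.
#' @export
assign_shell <- function(e, inside_contour = TRUE, n_shells = 5) {
  stopifnot(all(e >= 0, na.rm = TRUE))
  m <- pmin(pmax(ceiling(e * n_shells), 1), n_shells)
  shell <- as.integer(n_shells - m + 1L)
  shell[!rep_len(inside_contour, length(e))] <- NA_integer_
  shell
}

#' Count pixels per shell and color class
#'
#' Sweeps every pixel of the nucleus region (columns between the row's
#' contour extremes), assigns it a shell via the normalized elliptical
#' coordinate, and tallies nucleus / probe / other pixels. Background-colored
#' pixels inside the contour land in `other` — they are unrecognized content
#' within the nucleus region.
#'
#' @param cls A `class_grid`.
#' @param contour The matching `nucleus_contour`.
#' @param geometry The matching `nucleus_geometry`.
#' @param n_shells Number of shells (default 5).
#' @return A `shell_counts` tibble: columns `shell` (1 = periphery ...
#'   N = center), `n_nucleus`, `n_probe`, `n_other`, `n_total`.
#' @export
count_shells <- function(cls, contour, geometry, n_shells = 5) {
  stopifnot(inherits(cls, "class_grid"))
  spans <- contour_spans(contour)
  if (!in_contour(geometry$mpt[["x"]], geometry$mpt[["y"]], spans)) {
    abort("geometry midpoint lies outside the contour",
          class = "nucshell_geometry_error")
  }
  occ <- which(!is.na(contour$left))
  lens <- contour$right[occ] - contour$left[occ] + 1L
  ys <- rep.int(occ, lens)
  xs <- sequence(lens, from = contour$left[occ])
  e <- normalized_coord(xs, ys, geometry)
  shell <- assign_shell(e, TRUE, n_shells)
  lab <- cls[cbind(ys, xs)]
  # background inside the contour is unrecognized content -> other
  lab[lab == CLS_BACKGROUND] <- CLS_OTHER
  tal <- function(code) {
    tabulate(shell[lab == code], nbins = n_shells)
  }
  out <- tibble(
    shell = seq_len(n_shells),
    n_nucleus = tal(CLS_NUCLEUS),
    n_probe = tal(CLS_PROBE),
    n_other = tal(CLS_OTHER)
  )
  out$n_total <- out$n_nucleus + out$n_probe + out$n_other
  class(out) <- c("shell_counts", class(out))
  out
}

#' Per-shell percentages from shell counts
#'
#' Two normalizations are computed for each class:
#' * `pct_*` — within-shell percentage, `100 * n_class(s) / n_total(s)`
#'   (the per-shell composition);
#' * `share_*` — share of the class total, `100 * n_class(s) / sum(n_class)`
#'   (how the class distributes across shells; used for the radial
#'   localization histograms).
#'
#' With equal-area shells the two rank shells identically for the probe.
#' When no probe pixel exists all probe shares are set to 0 with a warning.
#'
#' @param counts A `shell_counts` tibble from [count_shells()].
#' @return A `shell_profile` tibble: the counts plus `pct_nucleus`,
#'   `pct_probe`, `pct_other`, `share_nucleus`, `share_probe`, `share_other`.
#' @export
shell_profile <- function(counts) {
  if (nrow(counts) == 0 || sum(counts$n_total) == 0) {
    abort("empty shell counts", class = "nucshell_geometry_error")
  }
  pct <- function(n, d) ifelse(d > 0, 100 * n / d, 0)
  share <- function(n, what) {
    tot <- sum(n)
    if (tot == 0) {
      if (what == "probe") {
        warn("no probe pixels found; probe shares reported as 0")
      }
      return(rep(0, length(n)))
    }
    100 * n / tot
  }
  out <- mutate(
    counts,
    pct_nucleus = pct(.data$n_nucleus, .data$n_total),
    pct_probe = pct(.data$n_probe, .data$n_total),
    pct_other = pct(.data$n_other, .data$n_total),
    share_nucleus = share(.data$n_nucleus, "nucleus"),
    share_probe = share(.data$n_probe, "probe"),
    share_other = share(.data$n_other, "other")
  )
  class(out) <- unique(c("shell_profile", class(out)))
  out
}
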