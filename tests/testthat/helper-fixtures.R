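# Shared fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

suite <- function() {
  if (is.null(.fixture_env$suite)) .fixture_env$suite <- fixture_suite(seed = 42)
  .fixture_env$suite
}

# Random-ellipse recovery suite shared by the equal-area and geometry
# acceptance checks: 50 ellipses, semi-major 40-150 px, aspect 1-3, uniform
# orientation, sub-pixel random centers.
random_ellipse_suite <- function(n = 50, seed = 1, a_range = c(40, 150),
                                 aspect_range = c(1, 3)) {
  key <- paste("ell", n, seed, paste(a_range, collapse = "-"),
               paste(aspect_range, collapse = "-"), sep = "_")
  if (!is.null(.fixture_env[[key]])) return(.fixture_env[[key]])
  set.seed(seed)
  cases <- vector("list", n)
  for (i in seq_len(n)) {
    a <- runif(1, a_range[1], a_range[2])
    b <- a / runif(1, aspect_range[1], aspect_range[2])
    th <- runif(1, 0, pi)
    w <- ceiling(2 * a) + 24
    ctr <- c(w / 2 + runif(1, -0.5, 0.5), w / 2 + runif(1, -0.5, 0.5))
    fx <- make_nucleus_image(nucleus_spec(
      width = w, height = w, center = ctr, a = a, b = b, theta = th, seed = i
    ))
    cases[[i]] <- list(a = a, b = b, theta = th, fx = fx)
  }
  .fixture_env[[key]] <- cases
  cases
}

# class_grid built directly from an integer label matrix (0 = background,
# 1 = nucleus, 2 = probe, 3 = other)
label_grid <- function(m) {
  structure(m, class = "class_grid",
            levels = c("background", "nucleus", "probe", "other"))
}

# smallest angular distance between two axis orientations (mod 180 degrees)
axis_angle_diff_deg <- function(t1, t2) {
  abs((((t1 - t2) * 180 / pi + 90) %% 180) - 90)
}
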