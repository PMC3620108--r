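#' Analysis configuration
#'
#' Bundles every tunable of the per-image pipeline. Defaults reproduce the
#' reference settings: 5 equal-area shells, smudge radius 5 px, white/blue/red
#' palette with tolerance 0.15.
#'
#' @param shells Number of concentric equal-area shells, `N >= 1`.
#' @param palette A [fish_palette()].
#' @param smudge_radius Isolation-circle radius `r` for [remove_smudges()].
#' @param smudge_mode `"pixel"`, `"component"`, or `"off"`.
#' @param annotate Write an annotated PNG beside the results for each image.
#' @param write_cleaned Write the smudge-cleaned image beside the results.
#' @return A `run_config` list.
#' @export
run_config <- function(shells = 5, palette = fish_palette(),
                       smudge_radius = 5,
                       smudge_mode = c("pixel", "component", "off"),
                       annotate = FALSE, write_cleaned = FALSE) {
  smudge_mode <- match.arg(smudge_mode)
  if (shells < 1 || shells != round(shells)) abort("`shells` must be >= 1")
  if (smudge_radius < 1) abort("`smudge_radius` must be >= 1")
  structure(
    list(shells = as.integer(shells), palette = palette,
         smudge_radius = as.integer(smudge_radius), smudge_mode = smudge_mode,
         annotate = annotate, write_cleaned = write_cleaned),
    class = "run_config"
  )
}

#' Analyze one nucleus image
#'
#' The full per-image chain: load (unless a `pixel_grid` is given), classify
#' by color, remove off-nucleus smudges, estimate contour and axes, partition
#' into equal-area shells and tally. Any stage failure is captured into the
#' record's `status`; nothing escapes, so batch runs never abort.
#'
#' @param image A file path or a `pixel_grid`.
#' @param config A [run_config()].
#' @param id Identifier used in outputs (defaults to the path or
#'   `"<in-memory>"`).
#' @param outdir Directory for optional annotated/cleaned images.
#' @return A `nucleus_record` list: `id`, `status` (`"ok"` or `"error"`),
#'   `error` (message or `NA`), `geometry`, `profile` (a `shell_profile`
#'   tibble), `smudges_removed`, `residual_components`.
#' @export
process_image <- function(image, config = run_config(),
                          id = NULL, outdir = NULL) {
  if (is.null(id)) {
    id <- if (is.character(image)) image else "<in-memory>"
  }
  rec <- list(id = id, status = "ok", error = NA_character_,
              geometry = NULL, profile = NULL,
              smudges_removed = NA_integer_, residual_components = NA_integer_)
  result <- tryCatch({
    grid <- if (is.character(image)) {
      read_nucleus_image(image, alpha_background = config$palette$background)
    } else image
    cls <- classify_grid(grid, config$palette)
    residual <- 0L
    removed <- 0L
    if (config$smudge_mode != "off") {
      cleaned <- withCallingHandlers(
        remove_smudges(grid, cls, radius = config$smudge_radius,
                       mode = config$smudge_mode,
                       background = config$palette$background),
        nucshell_large_smudge = function(w) invokeRestart("muffleWarning")
      )
      grid <- cleaned$grid
      cls <- cleaned$cls
      removed <- cleaned$removed
      residual <- cleaned$residual_components
    }
    contour <- find_contour(cls)
    geometry <- estimate_geometry(cls, contour)
    counts <- count_shells(cls, contour, geometry, config$shells)
    profile <- shell_profile(counts)
    if (!is.null(outdir)) {
      stem <- tools::file_path_sans_ext(basename(id))
      if (isTRUE(config$annotate)) {
        write_annotated(grid, file.path(outdir, paste0(stem, "_annotated.png")),
                        contour = contour, geometry = geometry,
                        n_shells = config$shells)
      }
      if (isTRUE(config$write_cleaned)) {
        write_image(grid, file.path(outdir, paste0(stem, "_cleaned.png")))
      }
    }
    list(geometry = geometry, profile = profile, removed = removed,
         residual = residual)
  }, error = function(e) e)
  if (inherits(result, "error")) {
    rec$status <- "error"
    rec$error <- conditionMessage(result)
  } else {
    rec$geometry <- result$geometry
    rec$profile <- result$profile
    rec$smudges_removed <- result$removed
    rec$residual_components <- result$residual
  }
  structure(rec, class = "nucleus_record")
}

#' @export
print.nucleus_record <- function(x, ...) {
  cat("<nucleus_record> ", x$id, " [", x$status, "]\n", sep = "")
  if (x$status == "ok") {
    print(x$geometry)
    print(as_tibble(x$profile))
  } else {
    cat("  error: ", x$error, "\n", sep = "")
  }
  invisible(x)
}

#' Read a batch list file
#'
#' One image path per line; blank lines and `#` comments are ignored. A line
#' may carry an explicit group as `path,group`; otherwise the group is the
#' image's parent directory name (samples are conventionally grouped by
#' chromosome in per-chromosome directories).
#'
#' @param listfile Path to the list file.
#' @return Tibble with columns `path`, `group`.
#' @export
read_image_list <- function(listfile) {
  if (!file.exists(listfile)) abort(sprintf("list file not found: %s", listfile))
  lines <- trimws(readLines(listfile, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) abort("list file contains no image paths")
  has_group <- grepl(",", lines, fixed = TRUE)
  path <- ifelse(has_group, sub(",.*$", "", lines), lines)
  group <- ifelse(has_group, sub("^[^,]*,", "", lines), basename(dirname(path)))
  group[!nzchar(group) | group == "."] <- "all"
  tibble(path = trimws(path), group = trimws(group))
}

#' Run the pipeline over a batch of images
#'
#' Processes every image with [process_image()] and collects per-image
#' geometry and shell profiles; failures are recorded per image, never fatal.
#'
#' @param images Character vector of paths, a data frame with columns
#'   `path`/`group`, or a list of `pixel_grid`s.
#' @param config A [run_config()].
#' @param groups Optional group label per image (recycled); defaults to the
#'   parent directory for paths, `"all"` otherwise.
#' @param outdir Directory for optional per-image diagnostic images.
#' @return A `nucshell_batch`: list with `images` (one row per image:
#'   id, group, status, error, smudge counts, geometry columns), `profiles`
#'   (long tibble, one row per ok image x shell) and `summary` (from
#'   [aggregate_profiles()], `NULL` when no image succeeded).
#' @export
run_batch <- function(images, config = run_config(), groups = NULL,
                      outdir = NULL) {
  if (is.data.frame(images)) {
    stopifnot("path" %in% names(images))
    groups <- if ("group" %in% names(images)) images$group else groups
    images <- images$path
  }
  n <- length(images)
  if (n == 0) abort("no images to process")
  if (is.null(groups)) {
    groups <- if (is.character(images)) basename(dirname(images)) else "all"
    groups[!nzchar(groups) | groups == "."] <- "all"
  }
  groups <- rep_len(as.character(groups), n)
  ids <- if (is.character(images)) images else sprintf("image_%03d", seq_len(n))

  records <- vector("list", n)
  for (i in seq_len(n)) {
    img <- if (is.character(images)) images[i] else images[[i]]
    records[[i]] <- process_image(img, config, id = ids[i], outdir = outdir)
  }

  img_rows <- purrr::map2_dfr(records, groups, function(r, g) {
    geo <- if (is.null(r$geometry)) {
      tibble(mpt_x = NA_real_, mpt_y = NA_real_, a = NA_real_, b = NA_real_,
             theta_deg = NA_real_)
    } else {
      tidy(r$geometry)[, c("mpt_x", "mpt_y", "a", "b", "theta_deg")]
    }
    dplyr::bind_cols(
      tibble(image = r$id, group = g, status = r$status, error = r$error,
             smudges_removed = r$smudges_removed,
             residual_components = r$residual_components),
      geo
    )
  })
  prof_rows <- purrr::map2_dfr(records, groups, function(r, g) {
    if (is.null(r$profile)) return(NULL)
    dplyr::bind_cols(tibble(image = r$id, group = g), as_tibble(r$profile))
  })
  if (nrow(prof_rows) == 0) {
    prof_rows <- tibble(image = character(), group = character())
  }
  summary <- if (nrow(prof_rows) > 0) aggregate_profiles(prof_rows) else NULL
  structure(
    list(images = img_rows, profiles = prof_rows, summary = summary,
         config = config),
    class = "nucshell_batch"
  )
}

#' Aggregate shell profiles across nuclei
#'
#' Per group and shell: mean and standard error of the mean (SEM = sample
#' standard deviation with the n-1 denominator, divided by sqrt(n)) of the
#' probe share-of-total percentage and, in parallel, of the within-shell
#' probe percentage. Only successfully processed images contribute. Before
#' aggregating, each image's probe shares are checked to sum to 100 (when any
#' probe pixel exists).
#'
#' @param profiles Long profile tibble (columns `image`, `group`, `shell`,
#'   `share_probe`, `pct_probe`), e.g. `tidy()` of a `nucshell_batch`.
#' @return Tibble with columns `group`, `shell`, `n`, `mean_share_probe`,
#'   `sem_share_probe`, `mean_pct_probe`, `sem_pct_probe`.
#' @export
aggregate_profiles <- function(profiles) {
  if (is.null(profiles) || nrow(profiles) == 0) {
    abort("no successful image records to aggregate")
  }
  if (!"group" %in% names(profiles)) profiles$group <- "all"
  sums <- profiles %>%
    group_by(.data$image) %>%
    summarise(s = sum(.data$share_probe), .groups = "drop")
  bad <- abs(sums$s - 100) > 1e-9 & sums$s != 0
  if (any(bad)) {
    abort(sprintf("probe shares of image %s do not sum to 100",
                  sums$image[which(bad)[1]]))
  }
  sem <- function(x) {
    if (length(x) < 2) {
      warn("SEM undefined for a single image; reported as 0")
      return(0)
    }
    stats::sd(x) / sqrt(length(x))
  }
  profiles %>%
    group_by(.data$group, .data$shell) %>%
    summarise(
      n = dplyr::n(),
      mean_share_probe = mean(.data$share_probe),
      sem_share_probe = sem(.data$share_probe),
      mean_pct_probe = mean(.data$pct_probe),
      sem_pct_probe = sem(.data$pct_probe),
      .groups = "drop"
    ) %>%
    arrange(.data$group, .data$shell)
}

#' @export
print.nucshell_batch <- function(x, ...) {
  ok <- sum(x$images$status == "ok")
  cat("<nucshell_batch> ", nrow(x$images), " image(s), ", ok, " ok, ",
      nrow(x$images) - ok, " failed\n", sep = "")
  if (!is.null(x$summary)) print(x$summary)
  invisible(x)
}

#' Tidy a batch result into the long per-image, per-shell table
#'
#' @param x A `nucshell_batch`.
#' @param ... Unused.
#' @return The long profile tibble (one row per ok image x shell).
#' @export
tidy.nucshell_batch <- function(x, ...) x$profiles

#' One-row-per-group overview of a batch
#'
#' @param x A `nucshell_batch`.
#' @param ... Unused.
#' @return Tibble with `group`, `n_images`, `n_ok`, `n_failed`.
#' @export
glance.nucshell_batch <- function(x, ...) {
  x$images %>%
    group_by(.data$group) %>%
    summarise(
      n_images = dplyr::n(),
      n_ok = sum(.data$status == "ok"),
      n_failed = sum(.data$status != "ok"),
      .groups = "drop"
    )
}

#' Write batch results to disk
#'
#' Emits `results.csv` (per image x shell, with geometry and status columns),
#' `summary.csv` (per group x shell mean and SEM), a spreadsheet `results.xls`
#' with both tables, one histogram PNG per group (mean probe share per shell
#' with SEM error bars) and `run.log`.
#'
#' @param batch A `nucshell_batch`.
#' @param outdir Output directory (created if missing).
#' @return Character vector of files written, invisibly.
#' @export
write_results <- function(batch, outdir) {
  stopifnot(inherits(batch, "nucshell_batch"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(outdir, 2) != 0) {
    abort(sprintf("output directory is not writable: %s", outdir))
  }
  files <- character(0)

  per_image <- left_join(batch$images, batch$profiles,
                         by = c("image", "group"))
  f <- file.path(outdir, "results.csv")
  write.csv(per_image, f, row.names = FALSE)
  files <- c(files, f)

  if (!is.null(batch$summary)) {
    f <- file.path(outdir, "summary.csv")
    write.csv(batch$summary, f, row.names = FALSE)
    files <- c(files, f)
  }

  f <- file.path(outdir, "results.xls")
  tabs <- list(results = per_image)
  if (!is.null(batch$summary)) tabs$summary <- batch$summary
  write_xls(tabs, f)
  files <- c(files, f)

  if (!is.null(batch$summary)) {
    for (g in unique(batch$summary$group)) {
      p <- plot_shell_profile(batch$summary[batch$summary$group == g, ]) +
        ggplot2::ggtitle(g)
      f <- file.path(outdir, paste0("histogram_",
                                    gsub("[^A-Za-z0-9_.-]", "_", g), ".png"))
      ggplot2::ggsave(f, p, width = 5, height = 4, dpi = 120)
      files <- c(files, f)
    }
  }

  f <- file.path(outdir, "run.log")
  ok <- sum(batch$images$status == "ok")
  cfg <- batch$config
  writeLines(c(
    sprintf("nucshell %s", as.character(utils::packageVersion("nucshell"))),
    sprintf("date: %s", format(Sys.time())),
    sprintf("shells: %d", cfg$shells),
    sprintf("smudge radius: %d, mode: %s", cfg$smudge_radius, cfg$smudge_mode),
    sprintf("palette tolerance: %g", cfg$palette$tolerance),
    sprintf("images: %d ok, %d failed", ok, nrow(batch$images) - ok),
    "",
    sprintf("%s\t%s\t%s", batch$images$image, batch$images$status,
            ifelse(is.na(batch$images$error), "", batch$images$error))
  ), f)
  files <- c(files, f)
  invisible(files)
}
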