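#' Hair-coverage percentages from tile counts
#'
#' `perc_hair = 100 * hair / (hair + nohair)`: the proportion of leaf tiles
#' classified as hairy, with background tiles excluded from the
#' denominator. When an image contributes no leaf tiles at all the
#' percentage is undefined and reported as `NA` (with a warning), never as
#' a silent zero.
#'
#' @param back,hair,nohair Non-negative tile counts.
#' @param quiet Suppress the no-leaf-tiles warning.
#' @return Named numeric vector `c(perc_hair, perc_nohair)`.
#' @examples
#' compute_percentages(106, 100, 300) # perc_hair = 25
#' @export
compute_percentages <- function(back, hair, nohair, quiet = FALSE) {
  back <- unname(back)
  hair <- unname(hair)
  nohair <- unname(nohair)
  counts <- c(back, hair, nohair)
  if (any(is.na(counts)) || any(counts < 0)) abort("counts must be non-negative")
  denom <- hair + nohair
  if (denom == 0) {
    if (!quiet) warn("no leaf tiles: hair percentage undefined (NA)")
    return(c(perc_hair = NA_real_, perc_nohair = NA_real_))
  }
  ph <- 100 * hair / denom
  c(perc_hair = ph, perc_nohair = 100 - ph)
}

#' Classify one disc image with the two-stage cascade
#'
#' Slices the image on its tile grid, scores every tile with the stage-1
#' classifier (background vs leaf disc), and sends only the tiles that
#' passed stage 1 to the stage-2 classifier (leaf without hair vs leaf
#' with hair) — background tiles never reach stage 2. Counts are
#' aggregated into the per-image result row and every tile keeps its
#' stage probabilities.
#'
#' @param image `(H, W, 3)` array in 0..255, or a file path.
#' @param model1 Trained stage-1 classifier (positive class = leaf disc).
#' @param model2 Trained stage-2 classifier (positive class = leaf hair).
#' @param grid Optional [grid_spec()]; computed from the image size and
#'   `tile_width`/`tile_height` when `NULL`. A note is emitted for
#'   non-nominal (not 2752 x 2208) image sizes.
#' @param image_id Name recorded in the result row.
#' @param threshold Decision threshold for both stages (boundary to the
#'   positive class).
#' @param tile_width,tile_height Tile size when `grid` is `NULL`.
#' @return A `leafhair_disc` list: `result` (one-row tibble `img_name`,
#'   `back`, `hair`, `nohair`, `perc_hair`, `perc_nohair`), `labels`
#'   (per-tile tibble with `row`, `col`, `label`, `stage1_prob`,
#'   `stage2_prob`), and `grid`.
#' @export
classify_disc <- function(image, model1, model2, grid = NULL,
                          image_id = "image", threshold = 0.5,
                          tile_width = 119, tile_height = 100) {
  if (is.character(image)) {
    if (image_id == "image") image_id <- sub("\\.[^.]+$", "", basename(image))
    image <- read_disc_image(image)
  }
  check_image_array(image)
  d <- dim(image)
  if (is.null(grid)) grid <- grid_spec(d[2], d[1], tile_width, tile_height)
  if (d[2] != 2752 || d[1] != 2208) {
    inform(sprintf(
      "non-nominal image size %d x %d: grid recomputed (%d tiles)",
      d[2], d[1], grid$n_tiles
    ))
  }
  tiles <- slice_image(image, grid, image_id = image_id)
  p1 <- predict(model1, tiles)
  is_leaf <- binarize(p1, threshold) == 1L
  p2 <- rep(NA_real_, nrow(tiles))
  label <- rep("BACKGROUND", nrow(tiles))
  if (any(is_leaf)) {
    p2[is_leaf] <- predict(model2, tiles[is_leaf, ])
    label[is_leaf] <- ifelse(binarize(p2[is_leaf], threshold) == 1L,
      "LEAF_HAIR", "LEAF_NO_HAIR"
    )
  }
  counts <- c(
    back = sum(label == "BACKGROUND"),
    hair = sum(label == "LEAF_HAIR"),
    nohair = sum(label == "LEAF_NO_HAIR")
  )
  perc <- compute_percentages(counts[["back"]], counts[["hair"]], counts[["nohair"]])
  structure(
    list(
      result = tibble::tibble(
        img_name = image_id,
        back = counts[["back"]], hair = counts[["hair"]], nohair = counts[["nohair"]],
        perc_hair = perc[["perc_hair"]], perc_nohair = perc[["perc_nohair"]]
      ),
      labels = tibble::tibble(
        image_id = image_id, row = tiles$row, col = tiles$col,
        label = label, stage1_prob = p1, stage2_prob = p2
      ),
      grid = grid
    ),
    class = "leafhair_disc"
  )
}

#' @export
print.leafhair_disc <- function(x, ...) {
  r <- x$result
  cat(sprintf(
    "<leafhair_disc> %s: %d background / %d hair / %d no-hair tiles; hair coverage %s\n",
    r$img_name, r$back, r$hair, r$nohair,
    ifelse(is.na(r$perc_hair), "NA", sprintf("%.2f%%", r$perc_hair))
  ))
  invisible(x)
}

#' @method tidy leafhair_disc
#' @export
tidy.leafhair_disc <- function(x, ...) x$labels

#' @method glance leafhair_disc
#' @export
glance.leafhair_disc <- function(x, ...) x$result

#' Render the annotated slice map of a classified disc
#'
#' Copies the input image and outlines every `LEAF_HAIR` tile in pure red
#' (255, 0, 0) and every `BACKGROUND` tile in pure blue (0, 0, 255);
#' `LEAF_NO_HAIR` tiles stay unmarked. Outlines are drawn inside the tile
#' bounding box, so pixels strictly interior to a tile (and the untiled
#' right/bottom margin) are untouched and output dimensions equal input
#' dimensions.
#'
#' @param image `(H, W, 3)` array in 0..255.
#' @param labels Per-tile label tibble from [classify_disc()] (columns
#'   `row`, `col`, `label`).
#' @param grid The matching [grid_spec()].
#' @param outline Outline width in pixels.
#' @return The annotated `(H, W, 3)` array.
#' @export
render_slice_map <- function(image, labels, grid, outline = 3) {
  check_image_array(image)
  stopifnot(inherits(grid, "leafhair_grid"))
  key <- labels$row * grid$n_cols + labels$col
  if (!setequal(key, 0:(grid$n_tiles - 1L)) || anyDuplicated(key) > 0) {
    abort("labels must cover the grid exactly once", class = "leafhair_incomplete_cover")
  }
  out <- image
  colours <- list(LEAF_HAIR = c(255, 0, 0), BACKGROUND = c(0, 0, 255))
  for (i in seq_len(nrow(labels))) {
    col3 <- colours[[labels$label[i]]]
    if (is.null(col3)) next
    x0 <- labels$col[i] * grid$tile_width
    y0 <- labels$row[i] * grid$tile_height
    ys <- (y0 + 1):(y0 + grid$tile_height)
    xs <- (x0 + 1):(x0 + grid$tile_width)
    bh <- ys[c(seq_len(outline), grid$tile_height - seq_len(outline) + 1L)]
    bw <- xs[c(seq_len(outline), grid$tile_width - seq_len(outline) + 1L)]
    for (ch in 1:3) {
      out[bh, xs, ch] <- col3[ch]
      out[ys, bw, ch] <- col3[ch]
    }
  }
  out
}

results_timestamp <- function() format(Sys.time(), "%Y%m%d-%H%M%S")

# Pick a path that never overwrites: append -1, -2, ... if taken.
fresh_path <- function(dir, stem, ext) {
  path <- file.path(dir, paste0(stem, ext))
  k <- 0
  while (file.exists(path)) {
    k <- k + 1
    path <- file.path(dir, paste0(stem, "-", k, ext))
  }
  path
}

#' Write the batch results table
#'
#' CSV with header `img_name,back,hair,nohair,perc_hair,perc_nohair`, one
#' row per image, percentages with two decimals and `NA` for undefined
#' values. The file name carries a timestamp
#' (`results_YYYYMMDD-HHMMSS.csv`) and an existing file is never
#' overwritten.
#'
#' @param results Tibble of per-image result rows (as produced by
#'   [classify_disc()] / [run_directory()]).
#' @param output_dir Output directory (created if missing).
#' @param timestamp Timestamp string; defaults to the current time.
#' @return The CSV file path.
#' @export
write_results_csv <- function(results, output_dir, timestamp = results_timestamp()) {
  if (is.null(results) || nrow(results) == 0) abort("no results to write")
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  path <- fresh_path(output_dir, paste0("results_", timestamp), ".csv")
  fmt <- function(x) ifelse(is.na(x), "NA", sprintf("%.2f", x))
  out <- tibble::tibble(
    img_name = results$img_name,
    back = results$back, hair = results$hair, nohair = results$nohair,
    perc_hair = fmt(results$perc_hair), perc_nohair = fmt(results$perc_nohair)
  )
  readr::write_csv(out, path)
  path
}

#' Classify every disc image in a directory
#'
#' Runs the cascade over each readable `.jpg`/`.jpeg`/`.png` image (sorted
#' lexicographically for a deterministic row order), writes a timestamped
#' results CSV and one annotated slice map per image, and logs one line
#' per image to the console and a run log file. Unreadable images are
#' skipped with a warning and recorded as failures; the batch continues.
#'
#' @param input_dir Directory with disc images (must contain at least one).
#' @param output_dir Output directory for CSV, maps and the run log.
#' @param model1,model2 Trained cascade stage classifiers.
#' @param threshold Decision threshold for both stages.
#' @param tile_width,tile_height Tile size in pixels.
#' @param write_maps Render and save slice maps (JPG quality 95).
#' @return A `leafhair_batch` list: `results` tibble, `csv_path`,
#'   `map_paths`, `failures` (character vector of failed file names), and
#'   `log_path`.
#' @export
run_directory <- function(input_dir, output_dir, model1, model2,
                          threshold = 0.5, tile_width = 119, tile_height = 100,
                          write_maps = TRUE) {
  if (!dir.exists(input_dir)) abort(sprintf("input directory not found: %s", input_dir))
  files <- sort(list.files(input_dir, pattern = "\\.(jpg|jpeg|png)$", ignore.case = TRUE))
  if (length(files) == 0) abort(sprintf("no images found in %s", input_dir))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  ts <- results_timestamp()
  log_path <- fresh_path(output_dir, paste0("run_", ts), ".log")
  log_line <- function(msg) {
    inform(msg)
    cat(msg, "\n", file = log_path, append = TRUE)
  }
  log_line(sprintf(
    "batch start: %d image(s) in %s; threshold %.2f; tile %d x %d",
    length(files), input_dir, threshold, tile_width, tile_height
  ))
  results <- list()
  map_paths <- character(0)
  failures <- character(0)
  for (f in files) {
    id <- sub("\\.[^.]+$", "", f)
    res <- tryCatch(
      {
        img <- read_disc_image(file.path(input_dir, f))
        disc <- classify_disc(img, model1, model2,
          image_id = id, threshold = threshold,
          tile_width = tile_width, tile_height = tile_height
        )
        if (write_maps) {
          map <- render_slice_map(img, disc$labels, disc$grid)
          mp <- fresh_path(output_dir, sprintf("%s_map_%s", id, ts), ".jpg")
          write_disc_image(map, mp, quality = 95)
          map_paths <- c(map_paths, mp)
        }
        r <- disc$result
        log_line(sprintf(
          "%s: back=%d hair=%d nohair=%d perc_hair=%s",
          f, r$back, r$hair, r$nohair,
          ifelse(is.na(r$perc_hair), "NA", sprintf("%.2f", r$perc_hair))
        ))
        r
      },
      error = function(e) {
        warn(sprintf("skipping %s: %s", f, conditionMessage(e)))
        log_line(sprintf("%s: FAILED (%s)", f, conditionMessage(e)))
        failures <<- c(failures, f)
        NULL
      }
    )
    if (!is.null(res)) results[[f]] <- res
  }
  results <- dplyr::bind_rows(results)
  csv_path <- NULL
  if (nrow(results) > 0) {
    csv_path <- write_results_csv(results, output_dir, timestamp = ts)
    log_line(sprintf("results written to %s", csv_path))
  } else {
    warn("no image classified successfully; no results CSV written")
  }
  structure(
    list(
      results = results, csv_path = csv_path, map_paths = map_paths,
      failures = failures, log_path = log_path
    ),
    class = "leafhair_batch"
  )
}

#' @export
print.leafhair_batch <- function(x, ...) {
  cat(sprintf(
    "<leafhair_batch> %d image(s) classified, %d failed\n",
    nrow(x$results), length(x$failures)
  ))
  if (!is.null(x$csv_path)) cat("  results:", x$csv_path, "\n")
  invisible(x)
}

#' @method glance leafhair_batch
#' @export
glance.leafhair_batch <- function(x, ...) x$results
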