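#' Fixed-grid geometry for slicing a leaf-disc image
#'
#' Computes the tile grid used to chop a disc photomicrograph into
#' classification units. Tiles are laid out from the top-left corner;
#' `n_cols = floor(image_width / tile_width)` and
#' `n_rows = floor(image_height / tile_height)`. Remainder pixels on the
#' right and bottom margins are excluded from every tile (never padded),
#' so a nominal 2752 x 2208 image with the default 119 x 100 tile yields
#' exactly 23 x 22 = 506 slices.
#'
#' All coordinates in this package are 0-based with half-open pixel boxes
#' `(x0, y0, x1, y1)`: x grows rightward, y downward, and tiles are
#' traversed row-major from the top-left.
#'
#' @param image_width,image_height Image size in pixels (positive integers).
#' @param tile_width,tile_height Tile size in pixels; defaults 119 x 100.
#' @return A `leafhair_grid` object: a list with fields `image_width`,
#'   `image_height`, `tile_width`, `tile_height`, `n_cols`, `n_rows`,
#'   `n_tiles`.
#' @examples
#' grid_spec(2752, 2208)$n_tiles  # 506
#' @export
grid_spec <- function(image_width, image_height,
                      tile_width = 119, tile_height = 100) {
  dims <- c(image_width, image_height, tile_width, tile_height)
  if (any(dims != floor(dims)) || any(dims <= 0)) {
    abort("grid dimensions must be positive integers", class = "leafhair_invalid_geometry")
  }
  if (tile_width > image_width || tile_height > image_height) {
    abort("tile larger than image", class = "leafhair_invalid_geometry")
  }
  n_cols <- image_width %/% tile_width
  n_rows <- image_height %/% tile_height
  structure(
    list(
      image_width = as.integer(image_width), image_height = as.integer(image_height),
      tile_width = as.integer(tile_width), tile_height = as.integer(tile_height),
      n_cols = as.integer(n_cols), n_rows = as.integer(n_rows),
      n_tiles = as.integer(n_cols * n_rows)
    ),
    class = "leafhair_grid"
  )
}

#' @export
print.leafhair_grid <- function(x, ...) {
  cat(sprintf(
    "<leafhair_grid> %d x %d px, %d x %d tiles -> %d cols x %d rows = %d slices\n",
    x$image_width, x$image_height, x$tile_width, x$tile_height,
    x$n_cols, x$n_rows, x$n_tiles
  ))
  invisible(x)
}

#' Pixel bounding boxes of every tile of a grid
#'
#' @param grid A [grid_spec()] object.
#' @return A tibble with 0-based `row`, `col` and half-open pixel bounds
#'   `x0`, `y0`, `x1`, `y1`, in row-major order (top-left tile first).
#' @export
tile_bboxes <- function(grid) {
  stopifnot(inherits(grid, "leafhair_grid"))
  rows <- rep(seq_len(grid$n_rows) - 1L, each = grid$n_cols)
  cols <- rep(seq_len(grid$n_cols) - 1L, times = grid$n_rows)
  tibble::tibble(
    row = rows, col = cols,
    x0 = cols * grid$tile_width, y0 = rows * grid$tile_height,
    x1 = (cols + 1L) * grid$tile_width, y1 = (rows + 1L) * grid$tile_height
  )
}

check_image_array <- function(image) {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L) {
    abort("image must be an (H, W, 3) RGB array", class = "leafhair_invalid_geometry")
  }
  invisible(image)
}

#' Slice a disc image into its grid of tiles
#'
#' Cuts the image into `grid$n_tiles` non-overlapping tiles in row-major
#' order. Pixel content of every tile equals the crop of the source image at
#' its recorded bounding box; right/bottom remainder pixels are dropped.
#'
#' @param image An `(H, W, 3)` numeric array with values in 0..255 (see
#'   [read_disc_image()]).
#' @param grid A [grid_spec()] whose image dimensions match `image`.
#' @param image_id Identifier recorded with every tile (used in file names
#'   and result tables).
#' @return A tibble with columns `image_id`, `row`, `col`, `x0`, `y0`,
#'   `x1`, `y1` and a `pixels` list-column of `(tile_height, tile_width, 3)`
#'   arrays.
#' @export
slice_image <- function(image, grid, image_id = "image") {
  check_image_array(image)
  stopifnot(inherits(grid, "leafhair_grid"))
  d <- dim(image)
  if (d[1] != grid$image_height || d[2] != grid$image_width) {
    abort(
      sprintf(
        "image is %d x %d but grid expects %d x %d",
        d[2], d[1], grid$image_width, grid$image_height
      ),
      class = "leafhair_invalid_geometry"
    )
  }
  bb <- tile_bboxes(grid)
  bb$pixels <- purrr::pmap(
    list(bb$x0, bb$y0, bb$x1, bb$y1),
    function(x0, y0, x1, y1) image[(y0 + 1):y1, (x0 + 1):x1, , drop = FALSE]
  )
  dplyr::bind_cols(tibble::tibble(image_id = image_id), bb)
}

#' Reassemble tiles into the tiled region of the source image
#'
#' Inverse of [slice_image()] restricted to the tiled region: the output is
#' a `(n_rows * tile_height, n_cols * tile_width, 3)` array, and
#' `reassemble(slice_image(img, g), g)` is bit-identical to the
#' corresponding crop of `img`. Input order is irrelevant; tiles are placed
#' by their `(row, col)` keys.
#'
#' @param tiles A tibble as returned by [slice_image()].
#' @param grid The matching [grid_spec()].
#' @return An RGB array covering the tiled region.
#' @export
reassemble <- function(tiles, grid) {
  stopifnot(inherits(grid, "leafhair_grid"))
  key <- tiles$row * grid$n_cols + tiles$col
  expected <- 0:(grid$n_tiles - 1L)
  if (nrow(tiles) != grid$n_tiles || !setequal(key, expected) || anyDuplicated(key) > 0) {
    abort("tiles must cover every (row, col) of the grid exactly once",
      class = "leafhair_incomplete_cover"
    )
  }
  out <- array(0, c(grid$n_rows * grid$tile_height, grid$n_cols * grid$tile_width, 3L))
  for (i in seq_len(nrow(tiles))) {
    r <- tiles$row[i]
    co <- tiles$col[i]
    out[
      (r * grid$tile_height + 1):((r + 1) * grid$tile_height),
      (co * grid$tile_width + 1):((co + 1) * grid$tile_width),
    ] <- tiles$pixels[[i]]
  }
  out
}

#' Quadrant train/test split of a tile grid
#'
#' Implements the disc-level hold-out in which one quarter of each image is
#' reserved for testing and the remaining three quarters are used for
#' training. A tile belongs to the test quadrant iff its bounding-box
#' centre lies inside that quadrant of the tiled region (boundaries at half
#' the tiled width/height; centres exactly on a boundary fall in the
#' east/south half). With an odd column count the split cannot be exactly
#' 25%; the centre rule keeps it within one tile row/column of a quarter.
#'
#' @param grid A [grid_spec()].
#' @param test_quadrant One of `"NE"`, `"NW"`, `"SE"`, `"SW"`.
#' @return A tibble with `row`, `col` (0-based), `partition` (`"TRAIN"` or
#'   `"TEST"`) and `test_quadrant`.
#' @export
quadrant_split <- function(grid, test_quadrant = c("NE", "NW", "SE", "SW")) {
  stopifnot(inherits(grid, "leafhair_grid"))
  test_quadrant <- match.arg(test_quadrant)
  bb <- tile_bboxes(grid)
  cx <- (bb$x0 + bb$x1) / 2
  cy <- (bb$y0 + bb$y1) / 2
  east <- cx >= grid$n_cols * grid$tile_width / 2
  south <- cy >= grid$n_rows * grid$tile_height / 2
  in_test <- switch(test_quadrant,
    NE = east & !south,
    NW = !east & !south,
    SE = east & south,
    SW = !east & south
  )
  tibble::tibble(
    row = bb$row, col = bb$col,
    partition = ifelse(in_test, "TEST", "TRAIN"),
    test_quadrant = test_quadrant
  )
}

#' Export tiles as image files with a coordinate manifest
#'
#' Writes each tile as `<image_id>_r<row>_c<col>.jpg` plus a sidecar
#' manifest CSV (`image_id,row,col,x0,y0,x1,y1`) preserving the 0-based
#' half-open pixel coordinates of every slice.
#'
#' @param tiles Tibble from [slice_image()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest path.
#' @export
write_tiles <- function(tiles, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(nrow(tiles))) {
    path <- file.path(dir, sprintf(
      "%s_r%d_c%d.jpg",
      tiles$image_id[i], tiles$row[i], tiles$col[i]
    ))
    write_disc_image(tiles$pixels[[i]], path)
  }
  manifest <- file.path(dir, "tile_manifest.csv")
  readr::write_csv(
    dplyr::select(tiles, "image_id", "row", "col", "x0", "y0", "x1", "y1"),
    manifest
  )
  invisible(manifest)
}
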