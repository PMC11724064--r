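test_that("grid arithmetic reproduces the nominal 506-slice layout", {
  g <- grid_spec(2752, 2208, 119, 100)
  expect_equal(g$n_cols, 23L)
  expect_equal(g$n_rows, 22L)
  expect_equal(g$n_tiles, 506L)

  expect_equal(grid_spec(119, 100, 119, 100)$n_tiles, 1L)

  g2 <- grid_spec(250, 230, 119, 100)
  expect_equal(c(g2$n_cols, g2$n_rows, g2$n_tiles), c(2L, 2L, 4L))
})

test_that("degenerate grid geometry is rejected", {
  expect_error(grid_spec(100, 100, 119, 100), class = "leafhair_invalid_geometry")
  expect_error(grid_spec(200, 90, 119, 100), class = "leafhair_invalid_geometry")
  expect_error(grid_spec(200.5, 100, 119, 100), class = "leafhair_invalid_geometry")
  expect_error(grid_spec(0, 100, 119, 100), class = "leafhair_invalid_geometry")
})

test_that("grid matches brute-force enumeration of non-overlapping boxes", {
  set.seed(11)
  for (rep in 1:20) {
    iw <- sample(20:400, 1)
    ih <- sample(20:400, 1)
    tw <- sample(5:iw, 1)
    th <- sample(5:ih, 1)
    g <- grid_spec(iw, ih, tw, th)
    # brute force: place boxes left to right, top to bottom
    n_boxes <- 0
    y0 <- 0
    while (y0 + th <= ih) {
      x0 <- 0
      while (x0 + tw <= iw) {
        n_boxes <- n_boxes + 1
        x0 <- x0 + tw
      }
      y0 <- y0 + th
    }
    expect_equal(g$n_tiles, n_boxes)
    # discarded margin
    expect_equal(iw - g$n_cols * tw, iw %% tw)
    expect_equal(ih - g$n_rows * th, ih %% th)
  }
})

test_that("slicing covers the image row-major with exact crops", {
  img <- make_test_image(230, 250)
  g <- grid_spec(250, 230, 119, 100)
  tiles <- slice_image(img, g, image_id = "t")
  expect_equal(nrow(tiles), 4L)
  # row-major from the top-left
  expect_equal(tiles$row, c(0L, 0L, 1L, 1L))
  expect_equal(tiles$col, c(0L, 1L, 0L, 1L))
  expect_equal(unlist(tiles[1, c("x0", "y0", "x1", "y1")], use.names = FALSE),
    c(0L, 0L, 119L, 100L))
  for (i in seq_len(nrow(tiles))) {
    crop <- img[(tiles$y0[i] + 1):tiles$y1[i], (tiles$x0[i] + 1):tiles$x1[i], ]
    expect_identical(tiles$pixels[[i]], crop)
  }
  # single-tile identity
  one <- slice_image(make_test_image(100, 119), grid_spec(119, 100))
  expect_identical(one$pixels[[1]], make_test_image(100, 119))
  # dimension mismatch
  expect_error(slice_image(img, grid_spec(300, 230, 119, 100)),
    class = "leafhair_invalid_geometry")
})

test_that("nominal-size slicing yields 506 tiles with the documented corner boxes", {
  img <- make_test_image(2208, 2752)
  tiles <- slice_image(img, grid_spec(2752, 2208))
  expect_equal(nrow(tiles), 506L)
  expect_equal(unlist(tiles[1, c("x0", "y0", "x1", "y1")], use.names = FALSE),
    c(0L, 0L, 119L, 100L))
  last <- tiles[nrow(tiles), ]
  expect_equal(unlist(last[c("x0", "y0", "x1", "y1")], use.names = FALSE),
    c(2618L, 2100L, 2737L, 2200L))
})

test_that("slice -> reassemble round trip is bit-exact on the tiled region", {
  set.seed(21)
  for (rep in 1:5) {
    ih <- sample(30:180, 1)
    iw <- sample(30:180, 1)
    th <- sample(7:ih, 1)
    tw <- sample(7:iw, 1)
    img <- array(runif(ih * iw * 3, 0, 255), c(ih, iw, 3))
    g <- grid_spec(iw, ih, tw, th)
    tiles <- slice_image(img, g)
    back <- reassemble(tiles, g)
    expect_identical(back, img[seq_len(g$n_rows * th), seq_len(g$n_cols * tw), , drop = FALSE])
    # order independence: permuted tiles give the same raster
    perm <- tiles[sample(nrow(tiles)), ]
    expect_identical(reassemble(perm, g), back)
  }
})

test_that("reassembly rejects incomplete or duplicated covers", {
  img <- make_test_image(230, 250)
  g <- grid_spec(250, 230, 119, 100)
  tiles <- slice_image(img, g)
  expect_error(reassemble(tiles[-1, ], g), class = "leafhair_incomplete_cover")
  dup <- tiles
  dup$row[2] <- 0L
  dup$col[2] <- 0L
  expect_error(reassemble(dup, g), class = "leafhair_incomplete_cover")
})

test_that("quadrant split holds out about a quarter by tile centre", {
  g <- grid_spec(2752, 2208, 119, 100)
  for (q in c("NE", "NW", "SE", "SW")) {
    s <- quadrant_split(g, q)
    expect_equal(nrow(s), 506L)
    n_test <- sum(s$partition == "TEST")
    expect_true(n_test %in% c(11 * 11, 11 * 12, 12 * 11, 12 * 12))
    expect_setequal(s$partition, c("TRAIN", "TEST"))
    # within one tile row/col of 25%
    expect_lt(abs(n_test / 506 - 0.25), 0.05)
  }
  # 2x2 grid: exactly one test tile, and the four quadrants partition it
  g2 <- grid_spec(238, 200, 119, 100)
  picked <- vapply(c("NE", "NW", "SE", "SW"), function(q) {
    s <- quadrant_split(g2, q)
    expect_equal(sum(s$partition == "TEST"), 1L)
    which(s$partition == "TEST")
  }, integer(1))
  expect_setequal(picked, 1:4)
})

test_that("exported tiles carry a coordinate manifest", {
  dir <- withr::local_tempdir()
  img <- make_test_image(230, 250)
  tiles <- slice_image(img, grid_spec(250, 230, 119, 100), image_id = "discA")
  manifest <- write_tiles(tiles, dir)
  expect_true(file.exists(file.path(dir, "discA_r0_c0.jpg")))
  expect_true(file.exists(file.path(dir, "discA_r1_c1.jpg")))
  m <- readr::read_csv(manifest, show_col_types = FALSE)
  expect_equal(nrow(m), 4L)
  expect_named(m, c("image_id", "row", "col", "x0", "y0", "x1", "y1"))
  expect_equal(m$x1 - m$x0, rep(119L, 4))
})
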