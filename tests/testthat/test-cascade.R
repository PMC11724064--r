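test_that("hair percentage excludes background from the denominator", {
  p <- compute_percentages(106, 100, 300)
  expect_equal(p[["perc_hair"]], 25)
  expect_equal(p[["perc_nohair"]], 75)
  expect_equal(compute_percentages(0, 506, 0)[["perc_hair"]], 100)
  expect_warning(p0 <- compute_percentages(506, 0, 0), "undefined")
  expect_true(all(is.na(p0)))
  expect_error(compute_percentages(-1, 2, 3))
  # perc_hair + perc_nohair is always 100 when defined
  set.seed(2)
  for (i in 1:20) {
    cts <- sample(0:500, 3)
    if (cts[2] + cts[3] == 0) next
    p <- compute_percentages(cts[1], cts[2], cts[3])
    expect_equal(sum(p), 100)
  }
})

test_that("the cascade conserves tile counts and skips stage 2 for background", {
  mods <- tiny_models()
  d <- generate_disc(synthetic_disc_spec(hair_density = 0.5, seed = 301, small = TRUE))
  disc <- suppressMessages(classify_disc(d$image, mods$m1, mods$m2, image_id = "s1"))
  r <- disc$result
  expect_equal(r$back + r$hair + r$nohair, disc$grid$n_tiles)
  if (!is.na(r$perc_hair)) expect_equal(r$perc_hair + r$perc_nohair, 100)
  lab <- disc$labels
  expect_equal(nrow(lab), disc$grid$n_tiles)
  # stage-2 probability present iff the tile passed stage 1
  expect_true(all(is.na(lab$stage2_prob[lab$label == "BACKGROUND"])))
  expect_true(all(!is.na(lab$stage2_prob[lab$label != "BACKGROUND"])))
  expect_true(all(lab$stage1_prob >= 0 & lab$stage1_prob <= 1))
})

test_that("a zero-density disc yields zero hair and an all-agar image yields NA", {
  mods <- tiny_models()
  d0 <- generate_disc(synthetic_disc_spec(hair_density = 0, seed = 302, small = TRUE))
  r0 <- suppressMessages(classify_disc(d0$image, mods$m1, mods$m2))$result
  expect_equal(r0$hair, 0)
  expect_equal(r0$perc_hair, 0)

  agar <- generate_disc(synthetic_disc_spec(
    hair_density = 0.5, disc_radius = 0,
    seed = 303, small = TRUE
  ))
  suppressMessages(suppressWarnings(
    ra <- classify_disc(agar$image, mods$m1, mods$m2)$result
  ))
  expect_equal(ra$back, 25)
  expect_true(is.na(ra$perc_hair))
})

test_that("hair percentage is invariant to adding pure-agar margin", {
  mods <- tiny_models()
  spec <- synthetic_disc_spec(hair_density = 0.75, seed = 304, small = TRUE)
  d <- generate_disc(spec)
  base <- suppressMessages(classify_disc(d$image, mods$m1, mods$m2))$result
  # pad one tile column (right) and one tile row (bottom) with noisy agar;
  # top-left alignment keeps every original tile bbox identical
  H <- dim(d$image)[1]
  W <- dim(d$image)[2]
  padded <- array(0, c(H + 100, W + 119, 3))
  set.seed(304)
  for (ch in 1:3) {
    padded[, , ch] <- spec$agar_color[ch] + rnorm((H + 100) * (W + 119), 0, spec$noise_sd)
  }
  padded[1:H, 1:W, ] <- d$image
  pres <- suppressMessages(classify_disc(padded, mods$m1, mods$m2))$result
  n_leaf <- base$hair + base$nohair
  expect_lte(abs(pres$perc_hair - base$perc_hair), 100 / n_leaf)
})

test_that("slice maps outline hair in red and background in blue, leaving interiors intact", {
  mods <- tiny_models()
  d <- generate_disc(synthetic_disc_spec(hair_density = 1, seed = 305, small = TRUE))
  disc <- suppressMessages(classify_disc(d$image, mods$m1, mods$m2))
  map <- render_slice_map(d$image, disc$labels, disc$grid)
  expect_equal(dim(map), dim(d$image))

  g <- disc$grid
  count_boxes <- function(map, rgb) {
    hits <- 0
    for (i in seq_len(nrow(disc$labels))) {
      x0 <- disc$labels$col[i] * g$tile_width
      y0 <- disc$labels$row[i] * g$tile_height
      px <- map[y0 + 1, x0 + 1, ] # outline corner pixel
      if (all(px == rgb)) hits <- hits + 1
    }
    hits
  }
  expect_equal(count_boxes(map, c(255, 0, 0)), disc$result$hair)
  expect_equal(count_boxes(map, c(0, 0, 255)), disc$result$back)

  # interior pixels (inside the 3-px outline) are untouched
  interior <- map[5:96, 5:115, ]
  expect_identical(interior, d$image[5:96, 5:115, ])

  # an all-background label map paints every tile blue and none red
  all_bg <- disc$labels
  all_bg$label <- "BACKGROUND"
  map_bg <- render_slice_map(d$image, all_bg, g)
  expect_equal(count_boxes(map_bg, c(0, 0, 255)), g$n_tiles)
  expect_equal(count_boxes(map_bg, c(255, 0, 0)), 0)
})

test_that("results CSV follows the published schema and never overwrites", {
  dir <- withr::local_tempdir()
  res <- tibble::tibble(
    img_name = c("img7", "img8", "img9"),
    back = c(106L, 506L, 0L), hair = c(100L, 0L, 506L), nohair = c(300L, 0L, 0L),
    perc_hair = c(25, NA, 100), perc_nohair = c(75, NA, 0)
  )
  p1 <- write_results_csv(res, dir, timestamp = "20250101-120000")
  expect_match(basename(p1), "^results_20250101-120000\\.csv$")
  lines <- readLines(p1)
  expect_equal(length(lines), 4L) # header + 3 rows
  expect_equal(lines[1], "img_name,back,hair,nohair,perc_hair,perc_nohair")
  expect_match(lines[2], "img7,106,100,300,25.00,75.00", fixed = TRUE)
  expect_match(lines[3], "NA,NA", fixed = TRUE)
  p2 <- write_results_csv(res, dir, timestamp = "20250101-120000")
  expect_false(p1 == p2) # rerun creates a fresh file
  expect_error(write_results_csv(res[0, ], dir))
})

test_that("directory runs classify every readable image and log failures", {
  mods <- tiny_models()
  ind <- withr::local_tempdir()
  outd <- withr::local_tempdir()
  for (i in 1:2) {
    d <- generate_disc(synthetic_disc_spec(
      hair_density = c(0, 1)[i],
      seed = 400 + i, small = TRUE
    ))
    write_disc_image(d$image, file.path(ind, sprintf("disc%d.jpg", i)))
  }
  writeLines("not an image", file.path(ind, "broken.jpg"))
  suppressMessages(suppressWarnings(
    batch <- run_directory(ind, outd, mods$m1, mods$m2)
  ))
  expect_equal(nrow(batch$results), 2L)
  expect_equal(batch$failures, "broken.jpg")
  expect_equal(batch$results$img_name, c("disc1", "disc2")) # lexicographic order
  expect_true(all(batch$results$back + batch$results$hair + batch$results$nohair == 25))
  expect_true(file.exists(batch$csv_path))
  expect_equal(length(batch$map_paths), 2L)
  expect_true(file.exists(batch$log_path))
  expect_error(run_directory(withr::local_tempdir(), outd, mods$m1, mods$m2))

  # rerunning gives identical numeric content (timestamps aside)
  suppressMessages(suppressWarnings(
    batch2 <- run_directory(ind, outd, mods$m1, mods$m2, write_maps = FALSE)
  ))
  expect_equal(batch2$results, batch$results)
})
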