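#' Specification of a synthetic leaf-disc image
#'
#' Parameters of the built-in generator that emulates the imaging setup the
#' cascade is trained for: a noisy agar background, a circular green leaf
#' disc (anti-aliased edge, low-frequency lamina mottling), and bright,
#' low-saturation hair strokes (random walks, 2-4 px wide) confined to the
#' disc, at a controllable density. The same spec and seed always produce a
#' bit-identical image and ground truth.
#'
#' Per-tile ground truth is derived from the very masks used for rendering:
#' a tile is `BACKGROUND` when less than `background_tile_threshold` (50%)
#' of its pixels lie in the disc mask; a leaf tile is `LEAF_HAIR` when at
#' least `hair_tile_threshold` (2%) of its pixels are hair-stroke pixels.
#'
#' @param image_width,image_height Image size in pixels. The default
#'   2752 x 2208 matches the nominal photomicrograph; `small = TRUE`
#'   switches to 688 x 552 (a 5 x 5 grid of 119 x 100 tiles) for fast
#'   experimentation.
#' @param tile_width,tile_height Tile size used for ground-truth labels.
#' @param hair_density Fraction in `[0, 1]` scaling the number of hair
#'   strokes (`rho`).
#' @param n_strokes_max Hair-tuft count at `hair_density = 1`; the default
#'   (one tuft per tile's worth of disc area) makes expected tile coverage
#'   rise steadily across the whole density range, reaching a woolly
#'   70-80% of leaf tiles at full density.
#' @param disc_center `(x, y)` pixel centre of the disc; default image
#'   centre.
#' @param disc_radius Disc radius in pixels; default 42% of the shorter
#'   image edge (the disc nearly fills the frame height, as in the
#'   photomicrographs). `0` renders pure agar.
#' @param agar_color,leaf_color,hair_color RGB triplets in 0..255.
#' @param noise_sd Per-pixel Gaussian noise (RGB units).
#' @param lighting_jitter Fraction: global brightness factor drawn
#'   uniformly from `1 +/- lighting_jitter`, emulating day-to-day lighting
#'   differences.
#' @param background_tile_threshold,hair_tile_threshold Ground-truth rules
#'   (see above).
#' @param seed Integer seed driving all stochastic choices.
#' @param small Convenience switch for the 688 x 552 size.
#' @return A `leafhair_synth_spec` object.
#' @export
synthetic_disc_spec <- function(image_width = 2752, image_height = 2208,
                                tile_width = 119, tile_height = 100,
                                hair_density = 0.5, n_strokes_max = NULL,
                                disc_center = NULL, disc_radius = NULL,
                                agar_color = c(205, 200, 188),
                                leaf_color = c(74, 112, 58),
                                hair_color = c(242, 240, 235),
                                noise_sd = 6, lighting_jitter = 0.05,
                                background_tile_threshold = 0.5,
                                hair_tile_threshold = 0.02,
                                seed = 1, small = FALSE) {
  if (small) {
    image_width <- 688
    image_height <- 552
  }
  if (hair_density < 0 || hair_density > 1) abort("hair_density must be in [0, 1]")
  if (is.null(disc_center)) disc_center <- c(image_width / 2, image_height / 2)
  if (is.null(disc_radius)) disc_radius <- 0.42 * min(image_width, image_height)
  if (is.null(n_strokes_max)) {
    # one tuft per tile's worth of disc area at full density: expected
    # coverage then rises steadily over the whole density grid instead of
    # saturating below rho = 1
    n_strokes_max <- max(1L, round(pi * disc_radius^2 / (tile_width * tile_height)))
  }
  structure(
    list(
      image_width = as.integer(image_width), image_height = as.integer(image_height),
      tile_width = as.integer(tile_width), tile_height = as.integer(tile_height),
      hair_density = hair_density, n_strokes_max = as.integer(n_strokes_max),
      disc_center = disc_center, disc_radius = disc_radius,
      agar_color = agar_color, leaf_color = leaf_color, hair_color = hair_color,
      noise_sd = noise_sd, lighting_jitter = lighting_jitter,
      background_tile_threshold = background_tile_threshold,
      hair_tile_threshold = hair_tile_threshold,
      seed = as.integer(seed)
    ),
    class = "leafhair_synth_spec"
  )
}

# Rasterise one hair tuft: a curved random walk plus parallel companion
# filaments (each 2-4 px wide), mimicking the woolly texture of trichome
# mats rather than isolated hairs. Returns an integer matrix of stamped
# pixel coordinates (1-based, rows = (y, x)).
stroke_pixels <- function(cx, cy, radius, W, H) {
  r0 <- radius * sqrt(runif(1)) * 0.95
  th0 <- runif(1, 0, 2 * pi)
  x <- cx + r0 * cos(th0)
  y <- cy + r0 * sin(th0)
  len <- max(8L, round(runif(1, 0.2, 0.45) * radius))
  dir <- runif(1, 0, 2 * pi)
  turns <- cumsum(c(0, rnorm(len - 1, 0, 0.08)))
  xs0 <- x + cumsum(cos(dir + turns))
  ys0 <- y + cumsum(sin(dir + turns))
  # companion filaments offset perpendicular to the walk direction
  n_fil <- sample(2:4, 1)
  perp <- dir + pi / 2
  lanes <- seq(-(n_fil - 1) / 2, (n_fil - 1) / 2) * runif(1, 2.5, 4)
  xs <- as.numeric(outer(xs0, lanes * cos(perp), "+"))
  ys <- as.numeric(outer(ys0, lanes * sin(perp), "+"))
  inside <- (xs - cx)^2 + (ys - cy)^2 < (radius - 1)^2
  xs <- xs[inside]
  ys <- ys[inside]
  if (length(xs) == 0) {
    return(matrix(integer(0), ncol = 2))
  }
  wd <- sample(2:4, 1)
  off <- expand.grid(dx = -wd:wd, dy = -wd:wd)
  off <- off[off$dx^2 + off$dy^2 <= (wd / 2)^2 + 0.5, , drop = FALSE]
  px <- as.integer(round(rep(xs, each = nrow(off))) + off$dx)
  py <- as.integer(round(rep(ys, each = nrow(off))) + off$dy)
  keep <- px >= 1 & px <= W & py >= 1 & py <= H
  cbind(py[keep], px[keep])
}

#' Generate a synthetic leaf-disc image with per-tile ground truth
#'
#' Renders the image described by a [synthetic_disc_spec()] and derives the
#' tile-level truth (`BACKGROUND` / `LEAF_NO_HAIR` / `LEAF_HAIR`) from the
#' same disc and hair masks used for rendering, plus the true hair-coverage
#' percentage computed by the cascade's own formula
#' (`100 * hair / (hair + nohair)`, `NA` when the disc contributes no leaf
#' tiles).
#'
#' @param spec A [synthetic_disc_spec()].
#' @param image_id Identifier attached to the truth table.
#' @return A `leafhair_synth_disc`: list with `image` (`(H, W, 3)` array,
#'   0..255), `truth` (tibble `image_id`, `row`, `col`, `true_label`,
#'   `disc_frac`, `hair_frac`), `grid`, `true_perc_hair`, `counts`, and
#'   `spec`.
#' @export
generate_disc <- function(spec, image_id = sprintf("synthetic_disc_seed%d", spec$seed)) {
  stopifnot(inherits(spec, "leafhair_synth_spec"))
  withr::with_seed(spec$seed, {
    W <- spec$image_width
    H <- spec$image_height
    cx <- spec$disc_center[1]
    cy <- spec$disc_center[2]
    r <- spec$disc_radius

    dist <- sqrt(outer((seq_len(H) - 0.5 - cy)^2, (seq_len(W) - 0.5 - cx)^2, "+"))
    alpha <- pmin(pmax(r + 0.5 - dist, 0), 1) # anti-aliased disc coverage
    disc_mask <- alpha >= 0.5

    # lamina mottling: two low-frequency waves with random phase
    xg <- matrix(seq_len(W), H, W, byrow = TRUE)
    yg <- matrix(seq_len(H), H, W)
    mottle <- 6 * sin(2 * pi * xg / (W / runif(1, 3, 6)) + runif(1, 0, 2 * pi)) +
      5 * sin(2 * pi * yg / (H / runif(1, 3, 6)) + runif(1, 0, 2 * pi))

    hair_mask <- matrix(FALSE, H, W)
    n_strokes <- round(spec$hair_density * spec$n_strokes_max)
    if (r > 0 && n_strokes > 0) {
      for (s in seq_len(n_strokes)) {
        px <- stroke_pixels(cx, cy, r, W, H)
        if (nrow(px) > 0) hair_mask[px] <- TRUE
      }
    }
    hair_mask <- hair_mask & disc_mask

    img <- array(0, c(H, W, 3L))
    light <- 1 + spec$lighting_jitter * runif(1, -1, 1)
    for (ch in 1:3) {
      agar <- spec$agar_color[ch] + matrix(rnorm(H * W, 0, spec$noise_sd), H, W)
      leaf <- spec$leaf_color[ch] + mottle + matrix(rnorm(H * W, 0, spec$noise_sd), H, W)
      plane <- agar * (1 - alpha) + leaf * alpha
      if (any(hair_mask)) {
        hv <- spec$hair_color[ch] + rnorm(sum(hair_mask), 0, spec$noise_sd / 2)
        plane[hair_mask] <- 0.15 * plane[hair_mask] + 0.85 * hv
      }
      img[, , ch] <- pmin(pmax(plane * light, 0), 255)
    }

    grid <- grid_spec(W, H, spec$tile_width, spec$tile_height)
    bb <- tile_bboxes(grid)
    disc_frac <- numeric(nrow(bb))
    hair_frac <- numeric(nrow(bb))
    for (i in seq_len(nrow(bb))) {
      ys <- (bb$y0[i] + 1):bb$y1[i]
      xs <- (bb$x0[i] + 1):bb$x1[i]
      disc_frac[i] <- mean(disc_mask[ys, xs])
      hair_frac[i] <- mean(hair_mask[ys, xs])
    }
    true_label <- ifelse(
      disc_frac < spec$background_tile_threshold, "BACKGROUND",
      ifelse(hair_frac >= spec$hair_tile_threshold, "LEAF_HAIR", "LEAF_NO_HAIR")
    )
    counts <- c(
      back = sum(true_label == "BACKGROUND"),
      hair = sum(true_label == "LEAF_HAIR"),
      nohair = sum(true_label == "LEAF_NO_HAIR")
    )
    perc <- compute_percentages(counts["back"], counts["hair"], counts["nohair"], quiet = TRUE)
    structure(
      list(
        image = img,
        truth = dplyr::bind_cols(
          tibble::tibble(image_id = image_id),
          bb[c("row", "col")],
          tibble::tibble(true_label = true_label, disc_frac = disc_frac, hair_frac = hair_frac)
        ),
        grid = grid,
        true_perc_hair = perc[["perc_hair"]],
        counts = counts,
        spec = spec
      ),
      class = "leafhair_synth_disc"
    )
  })
}

#' @export
print.leafhair_synth_disc <- function(x, ...) {
  cat(sprintf(
    "<leafhair_synth_disc> %d x %d px, rho = %.2f, true hair coverage = %s\n",
    x$spec$image_width, x$spec$image_height, x$spec$hair_density,
    ifelse(is.na(x$true_perc_hair), "NA (no leaf tiles)", sprintf("%.2f%%", x$true_perc_hair))
  ))
  invisible(x)
}

#' Generate labeled tile manifests for both cascade stages
#'
#' Builds `n_discs` synthetic discs with hair densities cycled over
#' `density_grid`, labels every tile from the generator's ground truth, and
#' splits tiles into train/test partitions by holding out one random
#' quadrant per disc (the three-quarters/one-quarter disc-level split).
#' The stage-1 manifest labels tiles `BACKGROUND` (0) vs any leaf tile (1);
#' the stage-2 manifest is restricted to leaf tiles, labeled
#' `LEAF_NO_HAIR` (0) vs `LEAF_HAIR` (1).
#'
#' @param n_discs Number of discs (>= 1).
#' @param density_grid Non-empty vector of hair densities in `[0, 1]`.
#' @param seed Integer seed; disc `i` uses `seed + i` for its rendering
#'   stream.
#' @param resize_to Optional square edge: store tile pixels already resized
#'   (saves memory when tiles feed straight into training).
#' @param ... Passed to [synthetic_disc_spec()] (e.g. `small = TRUE`).
#' @return List with tibbles `cnn1` and `cnn2` (columns `image_id`, `row`,
#'   `col`, `partition`, `label`, `pixels`) and `discs` (per-disc
#'   `image_id`, `hair_density`, `true_perc_hair`, `test_quadrant`).
#' @export
generate_training_sets <- function(n_discs, density_grid = c(0, 0.25, 0.5, 0.75, 1),
                                   seed = 1708, resize_to = NULL, ...) {
  if (length(density_grid) == 0) abort("density_grid must be non-empty")
  if (n_discs < 1) abort("n_discs must be >= 1")
  quads <- withr::with_seed(seed, sample(c("NE", "NW", "SE", "SW"), n_discs, replace = TRUE))
  densities <- rep_len(density_grid, n_discs)
  cnn1 <- vector("list", n_discs)
  cnn2 <- vector("list", n_discs)
  discs <- vector("list", n_discs)
  for (i in seq_len(n_discs)) {
    spec <- synthetic_disc_spec(hair_density = densities[i], seed = seed + i, ...)
    id <- sprintf("disc%03d", i)
    d <- generate_disc(spec, image_id = id)
    tiles <- slice_image(d$image, d$grid, image_id = id)
    if (!is.null(resize_to)) {
      tiles$pixels <- lapply(tiles$pixels, nn_resize_bilinear, oh = resize_to, ow = resize_to)
    }
    split <- quadrant_split(d$grid, quads[i])
    tl <- dplyr::inner_join(tiles, d$truth[c("row", "col", "true_label")], by = c("row", "col"))
    tl <- dplyr::inner_join(tl, split[c("row", "col", "partition")], by = c("row", "col"))
    cnn1[[i]] <- dplyr::mutate(
      tl[c("image_id", "row", "col", "partition", "pixels")],
      label = as.integer(tl$true_label != "BACKGROUND")
    )
    leaf <- tl[tl$true_label != "BACKGROUND", , drop = FALSE]
    cnn2[[i]] <- dplyr::mutate(
      leaf[c("image_id", "row", "col", "partition", "pixels")],
      label = as.integer(leaf$true_label == "LEAF_HAIR")
    )
    discs[[i]] <- tibble::tibble(
      image_id = id, hair_density = densities[i],
      true_perc_hair = d$true_perc_hair, test_quadrant = quads[i]
    )
  }
  list(
    cnn1 = dplyr::bind_rows(cnn1),
    cnn2 = dplyr::bind_rows(cnn2),
    discs = dplyr::bind_rows(discs)
  )
}

#' Write a batch of synthetic discs to disk
#'
#' Renders `n` discs (densities cycled over `densities`), writing each
#' image as JPG plus a per-tile truth CSV
#' (`img_name,row,col,true_label`) and a per-disc summary CSV
#' (`img_name,true_perc_hair`).
#'
#' @param out_dir Output directory.
#' @param n Number of discs.
#' @param densities Density grid.
#' @param seed Integer seed.
#' @param ... Passed to [synthetic_disc_spec()] (e.g. `small = TRUE`).
#' @return Invisibly, the per-disc summary tibble.
#' @export
write_synthetic_set <- function(out_dir, n = 20, densities = c(0, 0.25, 0.5, 0.75, 1),
                                seed = 1708, ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dens <- rep_len(densities, n)
  truth_rows <- vector("list", n)
  summary_rows <- vector("list", n)
  for (i in seq_len(n)) {
    id <- sprintf("disc%03d", i)
    d <- generate_disc(
      synthetic_disc_spec(hair_density = dens[i], seed = seed + i, ...),
      image_id = id
    )
    write_disc_image(d$image, file.path(out_dir, paste0(id, ".jpg")))
    truth_rows[[i]] <- dplyr::mutate(
      d$truth[c("image_id", "row", "col", "true_label")],
      img_name = .data$image_id, .keep = "unused", .before = 1
    )
    summary_rows[[i]] <- tibble::tibble(
      img_name = id, hair_density = dens[i], true_perc_hair = d$true_perc_hair
    )
  }
  readr::write_csv(dplyr::bind_rows(truth_rows), file.path(out_dir, "truth_tiles.csv"))
  summary <- dplyr::bind_rows(summary_rows)
  readr::write_csv(summary, file.path(out_dir, "truth_summary.csv"))
  invisible(summary)
}
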