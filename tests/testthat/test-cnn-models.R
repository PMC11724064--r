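test_that("default classifier follows the printed width sequence", {
  spec <- classifier_spec()
  expect_equal(spec$entry_widths, c(32L, 64L))
  expect_equal(spec$middle_widths, c(128L, 256L, 512L, 728L))
  expect_equal(spec$final_width, 1024L)
  expect_equal(spec$input_size, 112L)
  m <- build_classifier(classifier_spec(input_size = 16), seed = 1)
  p <- m$params
  expect_equal(dim(p[["c1.w"]])[4], 32L)
  expect_equal(dim(p[["c2.w"]])[4], 64L)
  expect_equal(
    vapply(1:4, function(k) dim(p[[sprintf("bk%d.s1pw", k)]])[4], integer(1)),
    c(128L, 256L, 512L, 728L)
  )
  expect_equal(dim(p[["fin.pw"]])[4], 1024L)
  expect_equal(dim(p[["out.w"]]), c(1024L, 1L))
})

test_that("invalid classifier specs are rejected", {
  expect_error(classifier_spec(dropout_rate = 1.5))
  expect_error(classifier_spec(entry_widths = c(64, 32)))
  expect_error(classifier_spec(middle_widths = c(128, 128)))
  expect_error(training_config(learning_rate = 0))
  expect_error(training_config(epochs = 0))
})

test_that("select_epoch matches a brute-force argmin with earliest tie-break", {
  h <- tibble::tibble(train_accuracy = c(0.90, 0.99), val_accuracy = c(0.89, 0.93))
  expect_equal(select_epoch(h), 1L)
  const <- tibble::tibble(train_accuracy = rep(0.8, 5), val_accuracy = rep(0.8, 5))
  expect_equal(select_epoch(const), 1L)
  single <- tibble::tibble(train_accuracy = 0.7, val_accuracy = 0.9)
  expect_equal(select_epoch(single), 1L)
  expect_error(select_epoch(tibble::tibble(train_accuracy = numeric(), val_accuracy = numeric())))

  set.seed(31)
  for (rep in 1:50) {
    n <- sample(1:30, 1)
    h <- tibble::tibble(train_accuracy = runif(n), val_accuracy = runif(n))
    gap <- abs(h$train_accuracy - h$val_accuracy)
    brute <- which(gap == min(gap))[1] # scan, earliest minimum
    expect_equal(select_epoch(h), brute)
  }
})

test_that("binarize thresholds with the boundary in the positive class", {
  expect_equal(binarize(0.7, 0.5), 1L)
  expect_equal(binarize(0.5, 0.5), 1L)
  expect_equal(binarize(0.49, 0.5), 0L)
  expect_equal(binarize(c(0, 1, 0.5)), c(0L, 1L, 1L))
  expect_error(binarize(0.5, 1.2))
  expect_error(binarize(1.4, 0.5))
})

test_that("rotation augmentation preserves labels and composes correctly", {
  tiles <- tibble::tibble(
    pixels = list(make_test_image(10, 12), make_test_image(10, 12) * 0.5),
    label = c(0L, 1L)
  )
  aug <- augment_tiles(tiles, input_size = 16)
  expect_equal(nrow(aug), 2L * 3L) # n tiles x k variants
  expect_equal(aug$label, rep(c(0L, 1L), each = 3))

  # 180-degree rotation is an involution
  sq <- augment_tiles(tiles[1, ], input_size = 16, rotations = 180)$pixels[[1]]
  back <- augment_tiles(list(sq), input_size = 16, rotations = 180)$pixels[[1]]
  orig <- asNamespace("leafhair")$nn_resize_bilinear(tiles$pixels[[1]], 16, 16)
  expect_equal(back, orig, tolerance = 1e-12)

  # four quarter turns return to the original
  r <- orig
  for (i in 1:4) r <- augment_tiles(list(r), input_size = 16, rotations = 90)$pixels[[1]]
  expect_equal(r, orig, tolerance = 1e-12)

  # constant-colour tile is rotation-invariant
  flat <- array(42, c(16, 16, 3))
  for (v in augment_tiles(list(flat), input_size = 16)$pixels) {
    expect_equal(v, flat, tolerance = 1e-12)
  }
})

test_that("training records per-epoch history and rejects degenerate datasets", {
  sets <- tiny_models()$sets
  tr <- dplyr::filter(sets$cnn1, partition == "TRAIN")[1:40, ]
  te <- dplyr::filter(sets$cnn1, partition == "TEST")[1:20, ]
  m <- build_classifier(tiny_spec(), seed = 5)
  cfg <- training_config(epochs = 1, seed = 5)
  mt <- train_classifier(m, tr, te, cfg)
  expect_equal(nrow(mt$history), 1L)
  expect_true(all(mt$history$val_accuracy >= 0 & mt$history$val_accuracy <= 1))
  expect_equal(mt$selected_epoch, 1L)

  one_class <- dplyr::filter(tr, label == 1)
  expect_error(train_classifier(m, one_class, te, cfg),
    class = "leafhair_degenerate_dataset")
})

test_that("the same seed and data reproduce an identical history", {
  sets <- tiny_models()$sets
  tr <- dplyr::filter(sets$cnn1, partition == "TRAIN")[1:40, ]
  te <- dplyr::filter(sets$cnn1, partition == "TEST")[1:16, ]
  cfg <- training_config(epochs = 2, seed = 77)
  m_a <- train_classifier(build_classifier(tiny_spec(), seed = 77), tr, te, cfg)
  m_b <- train_classifier(build_classifier(tiny_spec(), seed = 77), tr, te, cfg)
  expect_identical(m_a$history, m_b$history)
  expect_identical(m_a$params, m_b$params)
})

test_that("a saved model reloads with bit-identical predictions", {
  m <- tiny_models()$m1
  tiles <- tiny_models()$sets$cnn1$pixels[1:5]
  path <- withr::local_tempfile(fileext = ".rds")
  save_classifier(m, path)
  m2 <- load_classifier(path)
  expect_identical(predict(m, tiles), predict(m2, tiles))
})

test_that("tidy/glance/history export expose the training record", {
  m <- tiny_models()$m1
  h <- tidy(m)
  expect_named(h, c("epoch", "train_accuracy", "val_accuracy", "train_loss", "val_loss"))
  g <- glance(m)
  expect_equal(g$epochs, nrow(h))
  expect_equal(g$val_accuracy_selected, h$val_accuracy[m$selected_epoch])
  path <- withr::local_tempfile(fileext = ".csv")
  write_history_csv(m, path)
  csv <- readr::read_csv(path, show_col_types = FALSE)
  expect_named(csv, c("epoch", "train_acc", "val_acc", "train_loss", "val_loss"))
  expect_equal(nrow(csv), nrow(h))
  expect_s3_class(autoplot(m), "ggplot")
})

test_that("validation accuracy does not degrade with more training data on average", {
  # monotonicity-on-average over seeds, on the separable stage-1 task
  sets <- tiny_models()$sets
  tr <- dplyr::filter(sets$cnn1, partition == "TRAIN")
  te <- dplyr::filter(sets$cnn1, partition == "TEST")
  accs <- sapply(c(101, 202, 303), function(seed) {
    small_idx <- withr::with_seed(seed, sample(nrow(tr), 24))
    cfg <- training_config(epochs = 3, seed = seed)
    m_small <- train_classifier(
      build_classifier(tiny_spec(), seed = seed), tr[small_idx, ], te, cfg
    )
    m_large <- train_classifier(
      build_classifier(tiny_spec(), seed = seed), tr, te, cfg
    )
    c(
      small = m_small$history$val_accuracy[nrow(m_small$history)],
      large = m_large$history$val_accuracy[nrow(m_large$history)]
    )
  })
  expect_gte(mean(accs["large", ]), mean(accs["small", ]))
})
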