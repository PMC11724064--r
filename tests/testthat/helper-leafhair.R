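# Shared fixtures. Everything is generated in code at test time; the tiny
# cascade models are trained once per run and memoised.

fixture_env <- new.env(parent = emptyenv())

# A deterministic RGB test image (smooth gradients, no randomness).
make_test_image <- function(height, width) {
  y <- matrix(seq_len(height), height, width)
  x <- matrix(seq_len(width), height, width, byrow = TRUE)
  img <- array(0, c(height, width, 3))
  img[, , 1] <- (x %% 251)
  img[, , 2] <- (y %% 241)
  img[, , 3] <- ((x + y) %% 253)
  img
}

tiny_spec <- function(dropout_rate = 0, positive_class = "pos",
                      negative_class = "neg") {
  classifier_spec(
    input_size = 16, entry_widths = c(2, 3), middle_widths = c(4, 6),
    final_width = 8, dropout_rate = dropout_rate,
    positive_class = positive_class, negative_class = negative_class
  )
}

# Small-width cascade trained on a handful of small synthetic discs; good
# enough to separate the synthetic classes, cheap enough for unit tests.
tiny_models <- function() {
  if (!is.null(fixture_env$models)) {
    return(fixture_env$models)
  }
  sets <- generate_training_sets(24,
    density_grid = c(0, 0.5, 1), seed = 99,
    resize_to = 32, small = TRUE
  )
  spec1 <- classifier_spec(
    input_size = 32, entry_widths = c(8, 12),
    middle_widths = c(16, 24), final_width = 32, dropout_rate = 0.5,
    positive_class = "leaf disc", negative_class = "background"
  )
  spec2 <- classifier_spec(
    input_size = 32, entry_widths = c(8, 12),
    middle_widths = c(16, 24), final_width = 32, dropout_rate = 0.2,
    positive_class = "leaf hair", negative_class = "leaf no hair"
  )
  cfg <- training_config(epochs = 10, learning_rate = 0.003, seed = 99)
  m1 <- train_classifier(
    build_classifier(spec1, seed = 99),
    dplyr::filter(sets$cnn1, partition == "TRAIN"),
    dplyr::filter(sets$cnn1, partition == "TEST"), cfg
  )
  m2 <- train_classifier(
    build_classifier(spec2, seed = 99),
    dplyr::filter(sets$cnn2, partition == "TRAIN"),
    dplyr::filter(sets$cnn2, partition == "TEST"), cfg
  )
  fixture_env$models <- list(m1 = m1, m2 = m2, sets = sets)
  fixture_env$models
}
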