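#' Reduced-scale reference experiment on synthetic discs
#'
#' Runs the package's complete workflow at the scale used throughout its
#' documentation: generate small synthetic discs, train both cascade
#' stages, then classify a fresh density-spanning validation batch and
#' score it against the generator's ground truth.
#'
#' The defaults define the reference conditions: `n_train_discs` small
#' (688 x 552, 5 x 5 grid) discs with hair densities cycled over
#' `train_densities` give about 1,500 stage-1 tiles; the quadrant hold-out
#' supplies the validation split; stage 1 trains for `epochs[1]` epochs and
#' stage 2 for `epochs[2]` (the background/leaf task converges within two
#' to three epochs; the hair/no-hair task improves through most of the
#' longer schedule);
#' Adam with learning rate 0.001, batch size 32, binary cross-entropy,
#' 64 x 64 network inputs. Validation uses `n_val` fresh discs, four per
#' density in `val_densities`. One integer seed drives every stochastic
#' choice.
#'
#' @param seed Integer seed for generation, initialisation and training.
#' @param n_train_discs Number of training discs.
#' @param train_densities Hair densities cycled over the training discs.
#' @param epochs Length-2 integer vector: training epochs for stage 1 and
#'   stage 2.
#' @param n_val Number of fresh validation discs.
#' @param val_densities Densities cycled over the validation discs.
#' @param input_size Square network input edge in pixels.
#' @param verbose Print per-epoch training lines.
#' @return A list: `model1`, `model2` (trained classifiers),
#'   `validation` (per-disc tibble with `image_id`, `hair_density`,
#'   `true_perc_hair`, `perc_hair`), and `metrics` (list with
#'   `val_accuracy_stage1`, `val_accuracy_stage2` — validation accuracy in
#'   percent at the selected epoch —, `pearson_r`, `pearson_p`, `rmse`,
#'   `n_val`).
#' @export
run_reference_experiment <- function(seed = 1708,
                                     n_train_discs = 60,
                                     train_densities = c(0, 0.5, 1),
                                     epochs = c(3L, 8L),
                                     n_val = 20,
                                     val_densities = c(0, 0.25, 0.5, 0.75, 1),
                                     input_size = 64,
                                     verbose = FALSE) {
  sets <- generate_training_sets(
    n_train_discs,
    density_grid = train_densities,
    seed = seed, resize_to = input_size, small = TRUE
  )
  tr1 <- dplyr::filter(sets$cnn1, .data$partition == "TRAIN")
  te1 <- dplyr::filter(sets$cnn1, .data$partition == "TEST")
  tr2 <- dplyr::filter(sets$cnn2, .data$partition == "TRAIN")
  te2 <- dplyr::filter(sets$cnn2, .data$partition == "TEST")

  m1 <- build_classifier(
    classifier_spec(
      input_size = input_size, dropout_rate = 0.5,
      positive_class = "leaf disc", negative_class = "background"
    ),
    seed = seed
  )
  m1 <- train_classifier(m1, tr1, te1,
    training_config(epochs = epochs[1], seed = seed),
    verbose = verbose
  )
  m2 <- build_classifier(
    classifier_spec(
      input_size = input_size, dropout_rate = 0.2,
      positive_class = "leaf hair", negative_class = "leaf no hair"
    ),
    seed = seed
  )
  m2 <- train_classifier(m2, tr2, te2,
    training_config(epochs = epochs[2], seed = seed),
    verbose = verbose
  )

  dens <- rep_len(val_densities, n_val)
  dens <- sort(dens)
  val <- vector("list", n_val)
  for (i in seq_len(n_val)) {
    id <- sprintf("val%02d", i)
    d <- generate_disc(
      synthetic_disc_spec(hair_density = dens[i], seed = seed + 1000 + i, small = TRUE),
      image_id = id
    )
    disc <- suppressMessages(classify_disc(d$image, m1, m2, image_id = id))
    val[[i]] <- tibble::tibble(
      image_id = id, hair_density = dens[i],
      true_perc_hair = d$true_perc_hair,
      perc_hair = disc$result$perc_hair,
      back = disc$result$back, hair = disc$result$hair, nohair = disc$result$nohair,
      n_tiles = disc$grid$n_tiles
    )
  }
  val <- dplyr::bind_rows(val)
  ok <- !is.na(val$perc_hair) & !is.na(val$true_perc_hair)
  pr <- pearson_r(val$perc_hair[ok], val$true_perc_hair[ok])
  list(
    model1 = m1, model2 = m2, validation = val,
    metrics = list(
      val_accuracy_stage1 = 100 * m1$history$val_accuracy[m1$selected_epoch],
      val_accuracy_stage2 = 100 * m2$history$val_accuracy[m2$selected_epoch],
      pearson_r = pr$r, pearson_p = pr$p_value,
      rmse = rmse(val$perc_hair[ok], val$true_perc_hair[ok]),
      n_val = sum(ok),
      n_tiles_stage1 = nrow(sets$cnn1),
      n_tiles_stage2 = nrow(sets$cnn2)
    )
  )
}
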