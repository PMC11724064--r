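#' Specification of one binary slice classifier
#'
#' Describes the separable-convolution residual network used by both cascade
#' stages: a rescaling layer (RGB 0..255 to 0..1), two entry convolution
#' blocks (widths 32 and 64, each conv + batch norm + ReLU), four middle
#' residual blocks with separable convolutions of widths 128, 256, 512 and
#' 728 (each: ReLU, separable conv, batch norm, ReLU, separable conv, batch
#' norm, max pool, plus a 1x1 projection of the block input summed back in),
#' a final separable convolution of width 1024 with batch norm and ReLU,
#' global average pooling, dropout, and a 1-unit sigmoid output. Stage 1
#' uses dropout 0.5 ("background" vs "leaf disc"); stage 2 uses dropout 0.2
#' ("leaf no hair" vs "leaf hair").
#'
#' Kernel conventions (fixed here, configurable only through the widths):
#' 3x3 kernels with "same" padding everywhere; the first entry conv has
#' stride 2; middle-block max pooling is 3x3 stride 2 "same"; the residual
#' projection is a 1x1 conv with stride 2.
#'
#' @param input_size Square network input edge in pixels (tiles are
#'   bilinearly resized to `input_size x input_size` before the forward
#'   pass). Default 112.
#' @param entry_widths Two increasing entry-block conv widths.
#' @param middle_widths Increasing separable-conv widths of the residual
#'   blocks.
#' @param final_width Width of the last separable convolution.
#' @param dropout_rate Dropout fraction applied after global pooling.
#' @param positive_class,negative_class Names for sigmoid output 1 and 0.
#' @param bn_momentum,bn_eps Batch-normalisation running-moment momentum and
#'   variance floor. The momentum default (0.9) keeps inference statistics
#'   close to the batch statistics within the short training schedules this
#'   package targets.
#' @return A `leafhair_classifier_spec` object.
#' @export
classifier_spec <- function(input_size = 112,
                            entry_widths = c(32, 64),
                            middle_widths = c(128, 256, 512, 728),
                            final_width = 1024,
                            dropout_rate = 0.5,
                            positive_class = "leaf disc",
                            negative_class = "background",
                            bn_momentum = 0.9, bn_eps = 1e-3) {
  if (dropout_rate < 0 || dropout_rate > 1) abort("dropout_rate must be in [0, 1]")
  if (length(entry_widths) != 2 || any(diff(entry_widths) <= 0)) {
    abort("entry_widths must be two strictly increasing widths")
  }
  if (length(middle_widths) < 1 || any(diff(middle_widths) <= 0)) {
    abort("middle_widths must be strictly increasing")
  }
  if (input_size < 8) abort("input_size must be at least 8 pixels")
  structure(
    list(
      input_size = as.integer(input_size),
      entry_widths = as.integer(entry_widths),
      middle_widths = as.integer(middle_widths),
      final_width = as.integer(final_width),
      dropout_rate = dropout_rate,
      positive_class = positive_class,
      negative_class = negative_class,
      bn_momentum = bn_momentum, bn_eps = bn_eps
    ),
    class = "leafhair_classifier_spec"
  )
}

#' Training hyper-parameters
#'
#' Adam with learning rate 0.001 on binary cross-entropy, the settings used
#' for both cascade stages. One integer seed controls weight
#' initialisation, shuffling, dropout masks and augmentation.
#'
#' @param learning_rate Adam learning rate (> 0).
#' @param epochs Number of training epochs (>= 1); each epoch is
#'   checkpointed.
#' @param batch_size Minibatch size.
#' @param seed Integer seed for all stochastic choices.
#' @param augmentation If `TRUE`, training tiles are augmented with
#'   90/180/270 degree rotations (applied after the resize to the square
#'   network input).
#' @return A `leafhair_training_config` object.
#' @export
training_config <- function(learning_rate = 0.001, epochs = 30,
                            batch_size = 32, seed = 1708,
                            augmentation = FALSE) {
  if (learning_rate <= 0) abort("learning_rate must be > 0")
  if (epochs < 1) abort("epochs must be >= 1")
  structure(
    list(
      learning_rate = learning_rate, epochs = as.integer(epochs),
      batch_size = as.integer(batch_size), seed = as.integer(seed),
      augmentation = isTRUE(augmentation)
    ),
    class = "leafhair_training_config"
  )
}

#' Build an untrained slice classifier
#'
#' Initialises the network of [classifier_spec()] with Glorot-uniform
#' weights (batch-norm scale 1 / shift 0, biases 0).
#'
#' @param spec A [classifier_spec()].
#' @param seed Integer seed for weight initialisation.
#' @return A `leafhair_classifier` object (untrained).
#' @export
build_classifier <- function(spec, seed = 1708) {
  stopifnot(inherits(spec, "leafhair_classifier_spec"))
  init <- withr::with_seed(seed, nn_init_params(spec))
  structure(
    list(
      spec = spec, params = init$params, state = init$state,
      trained = FALSE, history = NULL, selected_epoch = NULL,
      final_params = NULL, final_state = NULL,
      metadata = list(created_at = format(Sys.time()), init_seed = seed)
    ),
    class = "leafhair_classifier"
  )
}

#' @export
print.leafhair_classifier <- function(x, ...) {
  cat(sprintf(
    "<leafhair_classifier> %s vs %s; widths [%s]; dropout %.2f; input %dx%d\n",
    x$spec$negative_class, x$spec$positive_class,
    paste(c(x$spec$entry_widths, x$spec$middle_widths, x$spec$final_width), collapse = ", "),
    x$spec$dropout_rate, x$spec$input_size, x$spec$input_size
  ))
  if (x$trained) {
    cat(sprintf(
      "  trained %d epochs; selected epoch %d (val accuracy %.4f)\n",
      nrow(x$history), x$selected_epoch,
      x$history$val_accuracy[x$selected_epoch]
    ))
  } else {
    cat("  untrained\n")
  }
  invisible(x)
}

# Normalise tile input: a tibble with a `pixels` list-column (and optional
# `label`), a plain list of (H, W, 3) arrays, or a pre-stacked 4-d array.
as_tile_list <- function(tiles) {
  if (is.data.frame(tiles)) {
    return(tiles$pixels)
  }
  if (is.array(tiles) && length(dim(tiles)) == 4) {
    return(lapply(seq_len(dim(tiles)[4]), function(i) tiles[, , , i, drop = TRUE]))
  }
  tiles
}

tile_labels_from <- function(tiles, labels) {
  if (is.null(labels) && is.data.frame(tiles) && "label" %in% names(tiles)) {
    labels <- tiles$label
  }
  if (is.null(labels)) abort("labels are required (a `label` column or the labels argument)")
  labels <- as.numeric(labels)
  if (!all(labels %in% c(0, 1))) abort("labels must be binary 0/1")
  labels
}

rot90_stack <- function(x) {
  # one quarter-turn of every (C, H, W, N) slice; square inputs only
  aperm(x, c(1, 3, 2, 4))[, dim(x)[3]:1, , , drop = FALSE]
}

# Fingerprint a stacked tile array + labels so model metadata records what
# the classifier was trained on.
dataset_fingerprint <- function(x, y) {
  sprintf(
    "n=%d;pos=%d;pixsum=%.3f", length(y), sum(y == 1),
    sum(x[seq(1, length(x), by = max(1L, length(x) %/% 1000L))])
  )
}

#' Train a slice classifier
#'
#' Runs minibatch Adam on binary cross-entropy for `config$epochs` epochs.
#' Tiles are bilinearly resized to the square network input before the
#' forward pass (identically at train and inference time). Every epoch is
#' checkpointed and a history row (train/validation accuracy and loss) is
#' recorded; after training, the weights of the epoch selected by
#' [select_epoch()] (smallest train-validation accuracy gap) become the
#' deployed weights, with the final epoch retained alongside.
#'
#' Training accuracy/loss are running epoch averages over minibatches (the
#' value seen while the weights move); validation metrics are computed with
#' frozen weights and batch-norm running moments after each epoch.
#'
#' @param model An untrained [build_classifier()] model.
#' @param train_tiles,val_tiles Labeled tiles: a tibble with `pixels` and
#'   `label` columns (as produced by [generate_training_sets()]), or a list
#'   of `(H, W, 3)` arrays with labels passed separately.
#' @param config A [training_config()].
#' @param train_labels,val_labels Binary 0/1 labels when not supplied as a
#'   `label` column.
#' @param checkpoint_dir Optional directory; per-epoch checkpoints are
#'   written there as `epoch_NN.rds` plus a `selected.rds` copy.
#' @param verbose Print one line per epoch.
#' @return The trained `leafhair_classifier`.
#' @export
train_classifier <- function(model, train_tiles, val_tiles,
                             config = training_config(),
                             train_labels = NULL, val_labels = NULL,
                             checkpoint_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "leafhair_classifier"))
  stopifnot(inherits(config, "leafhair_training_config"))
  y_tr <- tile_labels_from(train_tiles, train_labels)
  y_va <- tile_labels_from(val_tiles, val_labels)
  if (length(y_tr) == 0 || length(y_va) == 0) abort("empty tile set")
  if (length(unique(y_tr)) < 2) {
    abort("training set contains a single class", class = "leafhair_degenerate_dataset")
  }
  spec <- model$spec
  x_tr <- nn_stack_tiles(as_tile_list(train_tiles), spec$input_size)
  x_va <- nn_stack_tiles(as_tile_list(val_tiles), spec$input_size)

  if (config$augmentation) {
    xs <- list(x_tr)
    r <- x_tr
    for (i in 1:3) {
      r <- rot90_stack(r)
      xs[[i + 1]] <- r
    }
    x_tr <- array(unlist(xs), c(dim(x_tr)[1:3], dim(x_tr)[4] * 4L))
    y_tr <- rep(y_tr, 4L)
  }

  params <- model$params
  state <- model$state
  opt <- nn_adam_init(params)
  n <- length(y_tr)
  bs <- min(config$batch_size, n)
  history <- vector("list", config$epochs)
  checkpoints <- vector("list", config$epochs)
  if (!is.null(checkpoint_dir)) dir.create(checkpoint_dir, showWarnings = FALSE, recursive = TRUE)

  withr::with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1, n, by = bs)
      loss_sum <- 0
      acc_sum <- 0
      for (s in starts) {
        idx <- ord[s:min(s + bs - 1, n)]
        xb <- x_tr[, , , idx, drop = FALSE]
        yb <- y_tr[idx]
        mask <- NULL
        if (spec$dropout_rate > 0) {
          mask <- matrix(
            (runif(spec$final_width * length(idx)) >= spec$dropout_rate) /
              (1 - spec$dropout_rate),
            spec$final_width, length(idx)
          )
        }
        fw <- nn_forward(params, state, xb, spec,
          training = TRUE,
          dropout_mask = mask, keep_cache = TRUE
        )
        state <- fw$state
        loss_sum <- loss_sum + nn_bce(fw$prob, yb) * length(idx)
        acc_sum <- acc_sum + sum((fw$prob >= 0.5) == (yb == 1))
        dlogit <- (fw$prob - yb) / length(idx)
        grads <- nn_backward(params, spec, fw$cache, dlogit, dropout_mask = mask)
        step <- nn_adam_step(params, grads, opt, lr = config$learning_rate)
        params <- step$params
        opt <- step$opt
      }
      val <- nn_eval(params, state, x_va, y_va, spec, batch_size = max(bs, 64L))
      history[[epoch]] <- tibble::tibble(
        epoch = epoch,
        train_accuracy = acc_sum / n, val_accuracy = val$accuracy,
        train_loss = loss_sum / n, val_loss = val$loss
      )
      checkpoints[[epoch]] <- list(params = params, state = state)
      if (!is.null(checkpoint_dir)) {
        saveRDS(checkpoints[[epoch]], file.path(checkpoint_dir, sprintf("epoch_%02d.rds", epoch)))
      }
      if (verbose) {
        inform(sprintf(
          "epoch %2d/%d  acc %.4f  val_acc %.4f  loss %.4f  val_loss %.4f",
          epoch, config$epochs, acc_sum / n, val$accuracy, loss_sum / n, val$loss
        ))
      }
    }
  })

  history <- dplyr::bind_rows(history)
  sel <- select_epoch(history)
  model$params <- checkpoints[[sel]]$params
  model$state <- checkpoints[[sel]]$state
  model$final_params <- params
  model$final_state <- state
  model$history <- history
  model$selected_epoch <- sel
  model$trained <- TRUE
  model$metadata$trained_at <- format(Sys.time())
  model$metadata$seed <- config$seed
  model$metadata$config <- unclass(config)
  model$metadata$dataset <- dataset_fingerprint(x_tr, y_tr)
  model$metadata$class_coding <- c(`0` = spec$negative_class, `1` = spec$positive_class)
  if (!is.null(checkpoint_dir)) {
    saveRDS(checkpoints[[sel]], file.path(checkpoint_dir, "selected.rds"))
  }
  model
}

nn_eval <- function(params, state, x, y, spec, batch_size = 64L) {
  n <- dim(x)[4]
  probs <- numeric(n)
  for (s in seq(1, n, by = batch_size)) {
    idx <- s:min(s + batch_size - 1, n)
    fw <- nn_forward(params, state, x[, , , idx, drop = FALSE], spec, training = FALSE)
    probs[idx] <- fw$prob
  }
  list(
    accuracy = mean((probs >= 0.5) == (y == 1)),
    loss = nn_bce(probs, y),
    prob = probs
  )
}

#' Select the deployment epoch from a training history
#'
#' Returns the (1-based) epoch with the smallest absolute difference
#' between training and validation accuracy; ties go to the earliest epoch.
#'
#' @param history A data frame with `train_accuracy` and `val_accuracy`
#'   columns (one row per epoch), or a trained classifier.
#' @return Integer epoch index.
#' @export
select_epoch <- function(history) {
  if (inherits(history, "leafhair_classifier")) history <- history$history
  if (is.null(history) || nrow(history) == 0) abort("empty training history")
  gap <- abs(history$train_accuracy - history$val_accuracy)
  which.min(gap) # which.min takes the earliest on ties
}

#' Predict tile probabilities
#'
#' Forward pass in inference mode (batch-norm running moments, no dropout)
#' using the checkpoint-selected weights. Tiles are resized exactly as
#' during training.
#'
#' @param object A trained `leafhair_classifier`.
#' @param tiles Tiles in any form accepted by [train_classifier()].
#' @param which `"selected"` (default) or `"final"` epoch weights.
#' @param batch_size Inference batch size.
#' @param ... Unused.
#' @return Numeric vector of probabilities in `[0, 1]`, one per tile
#'   (probability of the spec's positive class).
#' @export
predict.leafhair_classifier <- function(object, tiles, which = c("selected", "final"),
                                        batch_size = 64L, ...) {
  which <- match.arg(which)
  if (!object$trained) abort("classifier is not trained")
  tl <- as_tile_list(tiles)
  if (length(tl) == 0) {
    return(numeric(0))
  }
  x <- nn_stack_tiles(tl, object$spec$input_size)
  params <- if (which == "final") object$final_params else object$params
  state <- if (which == "final") object$final_state else object$state
  n <- dim(x)[4]
  probs <- numeric(n)
  for (s in seq(1, n, by = batch_size)) {
    idx <- s:min(s + batch_size - 1, n)
    fw <- nn_forward(params, state, x[, , , idx, drop = FALSE], object$spec, training = FALSE)
    probs[idx] <- fw$prob
  }
  probs
}

#' Threshold a probability into a binary label
#'
#' Label 1 iff `p >= threshold`; the boundary belongs to the positive
#' class. Default threshold 0.5.
#'
#' @param p Probabilities in `[0, 1]`.
#' @param threshold Decision threshold in `[0, 1]`.
#' @return Integer 0/1 vector.
#' @export
binarize <- function(p, threshold = 0.5) {
  if (threshold < 0 || threshold > 1) abort("threshold must be in [0, 1]")
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("probabilities must be in [0, 1]")
  as.integer(p >= threshold)
}

#' Rotation augmentation of labeled tiles
#'
#' Returns the 90/180/270-degree rotations of each tile (computed after
#' resizing to a square), with labels preserved and optional multiplicative
#' brightness jitter.
#'
#' @param tiles A tibble with `pixels` (and optionally `label`) or a list
#'   of `(H, W, 3)` arrays.
#' @param input_size Square size tiles are resized to before rotation.
#' @param rotations Subset of `c(90, 180, 270)` degrees.
#' @param brightness_jitter Fraction `j`: each variant is scaled by a
#'   factor drawn uniformly from `[1 - j, 1 + j]` (clipped to 0..255).
#' @param seed Optional seed for the jitter draws.
#' @return A tibble with `pixels`, `label` (if present) and `rotation`.
#' @export
augment_tiles <- function(tiles, input_size = 112, rotations = c(90, 180, 270),
                          brightness_jitter = 0, seed = NULL) {
  stopifnot(all(rotations %in% c(90, 180, 270)))
  tl <- as_tile_list(tiles)
  labels <- if (is.data.frame(tiles) && "label" %in% names(tiles)) tiles$label else NULL
  sq <- lapply(tl, function(t) {
    if (dim(t)[1] != input_size || dim(t)[2] != input_size) {
      nn_resize_bilinear(t, input_size, input_size)
    } else {
      t
    }
  })
  rot1 <- function(a) aperm(a, c(2, 1, 3))[dim(a)[2]:1, , , drop = FALSE]
  rot <- function(a, deg) {
    for (i in seq_len(deg / 90)) a <- rot1(a)
    a
  }
  jitter_fun <- function(a) {
    if (brightness_jitter <= 0) {
      return(a)
    }
    f <- runif(1, 1 - brightness_jitter, 1 + brightness_jitter)
    pmin(pmax(a * f, 0), 255)
  }
  build <- function() {
    out <- purrr::map(seq_along(sq), function(i) {
      purrr::map(rotations, function(deg) jitter_fun(rot(sq[[i]], deg)))
    })
    tibble::tibble(
      pixels = purrr::flatten(out),
      label = if (is.null(labels)) NA else rep(labels, each = length(rotations)),
      rotation = rep(rotations, times = length(sq))
    )
  }
  res <- if (is.null(seed)) build() else withr::with_seed(seed, build())
  if (is.null(labels)) res$label <- NULL
  res
}

#' Save / load a trained classifier
#'
#' Serialises the full model (weights of the selected and final epochs,
#' batch-norm state, history, metadata); reloading reproduces bit-identical
#' predictions.
#'
#' @param model A `leafhair_classifier`.
#' @param path File path (`.rds`).
#' @return `save_classifier` returns `path` invisibly; `load_classifier`
#'   returns the model.
#' @export
save_classifier <- function(model, path) {
  stopifnot(inherits(model, "leafhair_classifier"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "leafhair_classifier")) abort("not a saved leafhair classifier")
  model
}

#' Export a training history as CSV
#'
#' Writes `epoch,train_acc,val_acc,train_loss,val_loss` rows.
#'
#' @param model A trained classifier.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_history_csv <- function(model, path) {
  h <- model$history
  readr::write_csv(
    tibble::tibble(
      epoch = h$epoch, train_acc = h$train_accuracy, val_acc = h$val_accuracy,
      train_loss = h$train_loss, val_loss = h$val_loss
    ),
    path
  )
  invisible(path)
}

#' @method tidy leafhair_classifier
#' @export
tidy.leafhair_classifier <- function(x, ...) {
  if (is.null(x$history)) {
    return(tibble::tibble(
      epoch = integer(), train_accuracy = numeric(), val_accuracy = numeric(),
      train_loss = numeric(), val_loss = numeric()
    ))
  }
  x$history
}

#' @method glance leafhair_classifier
#' @export
glance.leafhair_classifier <- function(x, ...) {
  if (!x$trained) {
    return(tibble::tibble(trained = FALSE))
  }
  sel <- x$selected_epoch
  tibble::tibble(
    trained = TRUE,
    epochs = nrow(x$history),
    selected_epoch = sel,
    train_accuracy_selected = x$history$train_accuracy[sel],
    val_accuracy_selected = x$history$val_accuracy[sel],
    val_accuracy_final = x$history$val_accuracy[nrow(x$history)],
    val_loss_final = x$history$val_loss[nrow(x$history)],
    positive_class = x$spec$positive_class,
    negative_class = x$spec$negative_class
  )
}

#' Training-history curves
#'
#' Accuracy and loss per epoch for train and validation sets, with the
#' selected epoch marked.
#'
#' @param object A trained `leafhair_classifier`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot leafhair_classifier
#' @export
autoplot.leafhair_classifier <- function(object, ...) {
  h <- tidy(object)
  long <- tidyr::pivot_longer(h, -"epoch", names_to = "series", values_to = "value")
  long$metric <- ifelse(grepl("loss", long$series), "loss", "accuracy")
  long$set <- ifelse(grepl("^val", long$series), "validation", "training")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value, colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL)
  if (!is.null(object$selected_epoch)) {
    p <- p + ggplot2::geom_vline(xintercept = object$selected_epoch, linetype = "dashed")
  }
  p
}
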