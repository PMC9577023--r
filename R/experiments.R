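# Experiment harness: configuration, training under the three dropout
# conditions (none / standard Bernoulli / FBM fibers), per-epoch metric
# trajectories, and multi-seed condition comparison.
#
# Architecture note: the droppable layers are the two hidden fully
# connected ReLU layers (widths N^2), which carry the Euclidean grid; the
# raw inputs and the output units are never masked. Fibers in the two
# hidden layers form independent populations.

#' Experiment configuration
#'
#' All hyperparameters of one training run. Benchmark defaults are provided
#' by [regression_config()] (1 -> 100 -> 100 -> 1, MSE, Adam lr 0.01,
#' 50 epochs x 50 single-sample mini-batches) and [classification_config()]
#' (784 -> 1024 -> 1024 -> 10, cross-entropy, Adam lr 1e-4, 100 epochs x 16
#' mini-batches of 64).
#'
#' @param task `"regression"` or `"classification"`.
#' @param layer_sizes Integer vector input, hidden..., output. The hidden
#'   layers are the droppable ones; for FBM mode each hidden width must be
#'   a perfect square N^2 (the grid side).
#' @param lr Adam learning rate.
#' @param epochs Training epochs.
#' @param batches_per_epoch Mini-batches (training iterations) per epoch.
#' @param batch_size Nominal samples per mini-batch (documentation of the
#'   design; actual chunk sizes come from the split).
#' @param batch_mode `"split"`: the shuffled training set is partitioned
#'   into `batches_per_epoch` nearly equal chunks, one Adam step per chunk.
#'   `"full"`: every iteration is an Adam step on the entire training set
#'   (`batches_per_epoch` steps per epoch). The regression benchmark uses
#'   `"full"`, which is what actually drives the training loss below the
#'   noise floor and produces the overfitting the dropout conditions are
#'   meant to suppress; dropout masks and fiber windows still advance once
#'   per iteration in both modes.
#' @param mode Dropout condition: `"none"`, `"standard"`, or `"fbm"`.
#' @param target_rate Drop probability for standard mode; calibration
#'   target / nominal rate for FBM mode.
#' @param n_fibers Fibers per droppable layer in FBM mode (e.g. 12 for the
#'   regression benchmark, 60 for the image benchmark). If `NULL`,
#'   calibrated to `target_rate` at run time.
#' @param window_len,shift,hurst,sigma,dt Fiber/FBM parameters (defaults
#'   L = s = 50, H = 0.9, sigma = 1, dt = 1/500).
#' @param rescale If `TRUE`, inverted-dropout scaling 1/(1 - target_rate)
#'   is applied to kept units in both dropout modes (default `FALSE`:
#'   plain zeroing, symmetric across conditions).
#' @param seed Master seed; all run randomness (weight init, shuffling,
#'   masks, fibers) derives from it.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(task = c("regression", "classification"),
                              layer_sizes,
                              lr, epochs, batches_per_epoch, batch_size,
                              batch_mode = c("split", "full"),
                              mode = c("none", "standard", "fbm"),
                              target_rate = 0.2, n_fibers = NULL,
                              window_len = 50L, shift = 50L, hurst = 0.9,
                              sigma = 1, dt = 1 / 500, rescale = FALSE,
                              seed = NULL) {
  task <- match.arg(task)
  mode <- match.arg(mode)
  batch_mode <- match.arg(batch_mode)
  if (length(layer_sizes) < 3L)
    stop_field("layer_sizes", "need at least input, one hidden, output")
  layer_sizes <- as.integer(layer_sizes)
  if (any(layer_sizes < 1L))
    stop_field("layer_sizes", "all layer sizes must be positive")
  for (nm in c("epochs", "batches_per_epoch", "batch_size")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 1 ||
        v != round(v))
      stop_field(nm, "must be a single positive integer")
  }
  if (!is.numeric(lr) || length(lr) != 1L || lr <= 0)
    stop_field("lr", "must be a single positive number")
  if (!is.numeric(target_rate) || target_rate < 0 || target_rate > 1)
    stop_field("target_rate", "must lie in [0, 1]")
  hidden <- layer_sizes[-c(1L, length(layer_sizes))]
  if (mode == "fbm") {
    sides <- sqrt(hidden)
    if (any(sides != round(sides)))
      stop_field("layer_sizes",
                 "hidden layer widths must be perfect squares (N^2) for FBM mode")
    if (!is.null(n_fibers) && (n_fibers < 1 || n_fibers != round(n_fibers)))
      stop_field("n_fibers", "must be a positive integer or NULL")
  }
  structure(
    list(task = task, layer_sizes = layer_sizes,
         loss = if (task == "regression") "mse" else "cross_entropy",
         lr = lr, epochs = as.integer(epochs),
         batches_per_epoch = as.integer(batches_per_epoch),
         batch_size = as.integer(batch_size), batch_mode = batch_mode,
         mode = mode,
         target_rate = target_rate,
         n_fibers = if (is.null(n_fibers)) NULL else as.integer(n_fibers),
         window_len = as.integer(window_len), shift = as.integer(shift),
         hurst = hurst, sigma = sigma, dt = dt, rescale = isTRUE(rescale),
         seed = seed),
    class = "experiment_config"
  )
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf(
    "%s experiment: layers %s, %s dropout%s, lr %g, %d epochs x %d batches\n",
    x$task, paste(x$layer_sizes, collapse = "-"), x$mode,
    if (x$mode == "fbm" && !is.null(x$n_fibers))
      sprintf(" (n = %d fibers/layer)", x$n_fibers) else "",
    x$lr, x$epochs, x$batches_per_epoch))
  invisible(x)
}

#' Benchmark regression configuration
#'
#' 1 input, two hidden ReLU layers of 100 neurons (10 x 10 grids), 1
#' output; MSE loss, Adam lr 0.01, 50 epochs of 50 single-sample
#' mini-batches; FBM mode uses 12 fibers per layer (H = 0.9, L = s = 50,
#' dt = 1/500).
#'
#' @param mode Dropout condition.
#' @param seed Master seed.
#' @param ... Overrides passed to [experiment_config()].
#' @return An `experiment_config`.
#' @export
regression_config <- function(mode = c("none", "standard", "fbm"),
                              seed = NULL, ...) {
  mode <- match.arg(mode)
  args <- list(task = "regression", layer_sizes = c(1L, 100L, 100L, 1L),
               lr = 0.01, epochs = 50L, batches_per_epoch = 50L,
               batch_size = 50L, batch_mode = "full", mode = mode,
               target_rate = 0.2,
               n_fibers = if (mode == "fbm") 12L else NULL, seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(experiment_config, args)
}

#' Benchmark classification configuration
#'
#' 784 inputs (28 x 28 images), two hidden ReLU layers of 1,024 neurons
#' (32 x 32 grids), 10 outputs; cross-entropy, Adam lr 1e-4, 100 epochs of
#' 16 mini-batches of 64; FBM mode uses 60 fibers per layer.
#'
#' @inheritParams regression_config
#' @return An `experiment_config`.
#' @export
classification_config <- function(mode = c("none", "standard", "fbm"),
                                  seed = NULL, ...) {
  mode <- match.arg(mode)
  args <- list(task = "classification",
               layer_sizes = c(784L, 1024L, 1024L, 10L),
               lr = 1e-4, epochs = 100L, batches_per_epoch = 16L,
               batch_size = 64L, mode = mode, target_rate = 0.2,
               n_fibers = if (mode == "fbm") 60L else NULL, seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(experiment_config, args)
}

# Coerce a dataset half (train or test) into X (features x n), Y (targets
# for the loss), labels (1-based ints, classification only).
prepare_xy <- function(config, part, name) {
  if (config$task == "regression") {
    if (!inherits(part, "regression_data"))
      stop_field(name, "regression runs need regression_data (see make_regression_split)")
    list(X = matrix(part$x, nrow = 1L), Y = matrix(part$y, nrow = 1L),
         labels = NULL)
  } else {
    if (!inherits(part, "image_data"))
      stop_field(name, "classification runs need image_data")
    d <- dim(part$images)
    n_feat <- d[1] * d[2]
    if (n_feat != config$layer_sizes[1])
      stop_field(name, sprintf("images have %d pixels but the network expects %d inputs",
                               n_feat, config$layer_sizes[1]))
    X <- matrix(part$images, nrow = n_feat)
    list(X = X, Y = NULL, labels = as.integer(part$labels) + 1L)
  }
}

# keep-multiplier vectors (one per hidden layer) for the current iteration
iteration_masks <- function(config, hidden_sizes, fiber_sets, grids, iter0) {
  scale <- if (config$rescale) 1 / (1 - config$target_rate) else 1
  lapply(seq_along(hidden_sizes), function(l) {
    mask <- switch(config$mode,
      none = return(NULL),
      standard = standard_dropout_mask(hidden_sizes[l], config$target_rate),
      fbm = mask_from_points(grids[[l]],
                             active_points(fiber_sets[[l]], iter0)))
    as.numeric(!mask$dropped) * scale
  })
}

#' Run one training experiment
#'
#' Trains the configured feed-forward network on `data$train` under the
#' configured dropout condition and records per-epoch training loss,
#' testing loss, testing accuracy (classification) and the generalization
#' gap (testing loss minus training loss). Dropout masks are rebuilt at
#' every mini-batch iteration; in FBM mode each hidden layer carries an
#' independent fiber population that advances one window per iteration and
#' branches at each epoch end. Fully reproducible under `config$seed`.
#'
#' @param config An [experiment_config()].
#' @param data List with `train` and `test` parts ([make_regression_split()],
#'   [make_glyph_split()], or [load_mnist()]).
#' @return An object of class `fbm_run` with `metrics` (data frame: epoch,
#'   train_loss, test_loss, accuracy, gap), `condition`, `config`, and the
#'   trained `net`.
#' @export
run_experiment <- function(config, data) {
  stopifnot(inherits(config, "experiment_config"))
  if (!is.list(data) || is.null(data$train) || is.null(data$test))
    stop_field("data", "must be a list with 'train' and 'test' parts")
  train <- prepare_xy(config, data$train, "data$train")
  test <- prepare_xy(config, data$test, "data$test")
  n_train <- ncol(train$X)
  if (config$batch_mode == "split" && n_train < config$batches_per_epoch)
    stop_field("data$train",
               sprintf("%d samples cannot fill %d mini-batches", n_train,
                       config$batches_per_epoch))

  hidden_sizes <- config$layer_sizes[-c(1L, length(config$layer_sizes))]
  seed <- config$seed
  net <- mlp_init(config$layer_sizes, derive_seed(seed, "init"))
  opt <- adam_init(net)

  grids <- NULL; fparams <- NULL
  if (config$mode == "fbm") {
    grids <- lapply(sqrt(hidden_sizes), neuron_grid)
    n_fib <- config$n_fibers
    fparams <- lapply(seq_along(hidden_sizes), function(l) {
      fiber_params(n_fibers = if (is.null(n_fib)) 1L else n_fib,
                   iters_per_epoch = config$batches_per_epoch,
                   window_len = config$window_len, shift = config$shift,
                   hurst = config$hurst, sigma = config$sigma,
                   dt = config$dt)
    })
    if (is.null(n_fib)) {
      n_fib <- calibrate_fiber_count(grids[[1]], fparams[[1]],
                                     config$target_rate,
                                     seed = derive_seed(seed, "calib"))
      config$n_fibers <- as.integer(n_fib)
      fparams <- lapply(fparams, function(p)
        fiber_params(n_fibers = as.integer(n_fib),
                     iters_per_epoch = p$iters_per_epoch,
                     window_len = p$window_len, shift = p$shift,
                     hurst = p$fbm$hurst, sigma = p$fbm$sigma,
                     dt = p$fbm$dt))
    }
  }

  eval_metrics <- function(net) {
    f_tr <- mlp_forward(net, train$X)
    f_te <- mlp_forward(net, test$X)
    if (config$task == "regression") {
      tr <- mlp_loss(f_tr$out, train$Y, "mse")$value
      te <- mlp_loss(f_te$out, test$Y, "mse")$value
      acc <- NA_real_
    } else {
      tr <- mlp_loss(f_tr$out, train$labels, "cross_entropy")$value
      lte <- mlp_loss(f_te$out, test$labels, "cross_entropy")
      te <- lte$value
      acc <- mean(max.col(t(f_te$out)) == test$labels)
    }
    c(train_loss = tr, test_loss = te, accuracy = acc)
  }

  metrics <- matrix(NA_real_, config$epochs, 3L,
                    dimnames = list(NULL, c("train_loss", "test_loss",
                                            "accuracy")))
  run_body <- function() {
    fiber_sets <- if (config$mode == "fbm")
      lapply(seq_along(grids), function(l)
        init_fibers(fparams[[l]], derive_seed(seed, "fibers", l)))
    else NULL
    for (epoch in seq_len(config$epochs)) {
      batches <- if (config$batch_mode == "full") {
        rep(list(seq_len(n_train)), config$batches_per_epoch)
      } else {
        order <- sample.int(n_train)
        split(order, cut(seq_len(n_train), config$batches_per_epoch,
                         labels = FALSE))
      }
      if (config$mode == "fbm" && epoch > 1L)
        fiber_sets <- lapply(fiber_sets, branch_epoch)
      for (i in seq_len(config$batches_per_epoch)) {
        idx <- batches[[i]]
        masks <- if (config$mode == "none") NULL
                 else iteration_masks(config, hidden_sizes, fiber_sets,
                                      grids, i - 1L)
        Xb <- train$X[, idx, drop = FALSE]
        fwd <- mlp_forward(net, Xb, masks = masks, training = TRUE)
        l <- if (config$task == "regression")
          mlp_loss(fwd$out, train$Y[, idx, drop = FALSE], "mse")
        else
          mlp_loss(fwd$out, train$labels[idx], "cross_entropy")
        grads <- mlp_backward(net, fwd, l$grad, masks = masks)
        upd <- adam_step(net, grads, opt, config$lr)
        net <<- upd$net
        opt <<- upd$state
      }
      metrics[epoch, ] <<- eval_metrics(net)
    }
  }
  with_seed(derive_seed(seed, "train-loop"), run_body())

  md <- as.data.frame(metrics)
  md <- cbind(epoch = seq_len(config$epochs), md)
  md$gap <- md$test_loss - md$train_loss
  structure(
    list(metrics = md, condition = config$mode, config = config, net = net,
         task = config$task, seed = seed),
    class = "fbm_run"
  )
}

#' @export
print.fbm_run <- function(x, ...) {
  fin <- x$metrics[nrow(x$metrics), ]
  cat(sprintf("%s run (%s dropout), %d epochs\n", x$task, x$condition,
              nrow(x$metrics)))
  cat(sprintf(
    "  final: train loss %.4f, test loss %.4f, gap %.4f%s\n",
    fin$train_loss, fin$test_loss, fin$gap,
    if (!is.na(fin$accuracy)) sprintf(", accuracy %.3f", fin$accuracy)
    else ""))
  invisible(x)
}

#' Predict from a trained run
#'
#' @param object An `fbm_run`.
#' @param newdata For regression, a numeric vector of x values; for
#'   classification, a 28 x 28 x n image array or an `image_data` object.
#' @param type For classification, `"class"` (0-based labels) or `"prob"`.
#' @param ... Unused.
#' @return Predictions (numeric vector, labels, or probability matrix).
#' @export
predict.fbm_run <- function(object, newdata, type = c("class", "prob"),
                            ...) {
  type <- match.arg(type)
  if (object$task == "regression") {
    out <- mlp_forward(object$net, matrix(as.numeric(newdata), nrow = 1L))
    return(as.numeric(out$out))
  }
  if (inherits(newdata, "image_data")) newdata <- newdata$images
  X <- matrix(newdata, nrow = object$config$layer_sizes[1])
  out <- mlp_forward(object$net, X)$out
  if (type == "class") return(max.col(t(out)) - 1L)
  ex <- exp(sweep(out, 2L, apply(out, 2L, max)))
  t(sweep(ex, 2L, colSums(ex), "/"))
}

#' @export
plot.fbm_run <- function(x, ...) {
  m <- x$metrics
  graphics::matplot(m$epoch, cbind(m$train_loss, m$test_loss, m$gap),
                    type = "l", lty = 1, col = c("black", "red", "blue"),
                    xlab = "epoch", ylab = "loss", ...)
  graphics::legend("topright", c("train", "test", "gap"), lty = 1,
                   col = c("black", "red", "blue"), bty = "n")
  invisible(x)
}

#' Compare the three dropout conditions over multiple seeds
#'
#' Runs the same experiment under each dropout condition for `n_seeds`
#' seeds (conditions share seeds, hence weight initialization and batch
#' order), and summarizes per-epoch mean and SD trajectories plus the
#' final-epoch generalization gaps.
#'
#' @param config An [experiment_config()]; its `mode` is overridden per
#'   condition, everything else is held identical.
#' @param data Train/test data list as for [run_experiment()], or a
#'   function of one integer seed returning such a list — then every seed
#'   replicate draws its own dataset (the full experiment, data included,
#'   is replicated; conditions within a seed still share the data).
#' @param n_seeds Number of independent seeds (>= 1).
#' @param modes Conditions to compare.
#' @return An object of class `fbm_comparison`: `final` (data frame of
#'   final-epoch metrics per seed and condition), `trajectories` (per-epoch
#'   mean/sd per condition), `runs` (nested list), `config`.
#' @export
compare_conditions <- function(config, data, n_seeds = 10L,
                               modes = c("none", "standard", "fbm")) {
  stopifnot(inherits(config, "experiment_config"), n_seeds >= 1L)
  modes <- match.arg(modes, several.ok = TRUE)
  base_seed <- if (is.null(config$seed)) 1L else config$seed
  datasets <- lapply(seq_len(n_seeds), function(s) {
    if (is.function(data)) data(derive_seed(base_seed, "data", s)) else data
  })
  runs <- list()
  final <- list()
  for (mode in modes) {
    runs[[mode]] <- vector("list", n_seeds)
    for (s in seq_len(n_seeds)) {
      cfg <- config
      cfg$mode <- mode
      if (mode != "fbm") cfg$n_fibers <- NULL
      cfg$seed <- derive_seed(base_seed, "compare", s)
      r <- run_experiment(cfg, datasets[[s]])
      runs[[mode]][[s]] <- r
      fin <- r$metrics[nrow(r$metrics), ]
      final[[length(final) + 1L]] <- cbind(condition = mode, seed_index = s,
                                           fin)
    }
  }
  final <- do.call(rbind, final)
  traj <- do.call(rbind, lapply(modes, function(mode) {
    ms <- lapply(runs[[mode]], `[[`, "metrics")
    ep <- ms[[1]]$epoch
    agg <- function(col) {
      v <- sapply(ms, `[[`, col)
      if (is.null(dim(v))) v <- matrix(v, nrow = 1L)
      cbind(rowMeans(v), apply(v, 1L, stats::sd))
    }
    out <- data.frame(condition = mode, epoch = ep)
    for (col in c("train_loss", "test_loss", "accuracy", "gap")) {
      a <- agg(col)
      out[[paste0(col, "_mean")]] <- a[, 1]
      out[[paste0(col, "_sd")]] <- a[, 2]
    }
    out
  }))
  structure(list(final = final, trajectories = traj, runs = runs,
                 config = config, n_seeds = n_seeds),
            class = "fbm_comparison")
}

#' @export
print.fbm_comparison <- function(x, ...) {
  cat(sprintf("Dropout-condition comparison: %d seeds per condition\n",
              x$n_seeds))
  med <- stats::aggregate(gap ~ condition, data = x$final, FUN = stats::median)
  names(med)[2] <- "median_final_gap"
  print(med, row.names = FALSE)
  invisible(x)
}

#' @export
plot.fbm_comparison <- function(x, ...) {
  cols <- c(none = "red", standard = "darkgreen", fbm = "blue")
  tr <- x$trajectories
  modes <- unique(tr$condition)
  rng <- range(tr$gap_mean, na.rm = TRUE)
  graphics::plot(NULL, xlim = range(tr$epoch), ylim = rng, xlab = "epoch",
                 ylab = "generalization gap", ...)
  for (m in modes) {
    d <- tr[tr$condition == m, ]
    graphics::lines(d$epoch, d$gap_mean, col = cols[[m]], lwd = 2)
  }
  graphics::legend("topleft", modes, col = cols[modes], lwd = 2, bty = "n")
  invisible(x)
}
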