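# Experiment harness: configuration contracts, determinism, architecture
# fidelity, training behavior on both tasks, exports.

quick_reg_cfg <- function(mode, seed = 1, ...) {
  regression_config(mode, seed = seed, epochs = 3L, ...)
}

test_that("configuration contracts reject invalid setups before training", {
  expect_error(regression_config("none", batches_per_epoch = 0L),
               "batches_per_epoch")
  expect_error(regression_config("none", epochs = 0L), "epochs")
  # FBM mode needs perfect-square hidden widths to carry the grid
  expect_error(experiment_config("regression", c(1L, 90L, 90L, 1L),
                                 lr = 0.01, epochs = 1L,
                                 batches_per_epoch = 1L, batch_size = 1L,
                                 mode = "fbm"), "perfect squares")
  # dataset/architecture mismatch caught before any training
  dat <- make_glyph_split(2, 2, seed = 1)
  expect_error(run_experiment(quick_reg_cfg("none"), dat),
               "regression_data")
  small <- classification_config("none", layer_sizes = c(100L, 16L, 10L),
                                 lr = 1e-3, epochs = 1L,
                                 batches_per_epoch = 2L, batch_size = 10L)
  expect_error(run_experiment(small, dat), "784|inputs")
  # too few samples for the requested mini-batch count (split mode)
  tiny <- make_regression_split(5, 5, seed = 2)
  expect_error(
    run_experiment(regression_config("none", epochs = 1L,
                                     batch_mode = "split"), tiny),
    "mini-batches")
})

test_that("runs are reproducible under a fixed seed, all conditions", {
  dat <- make_regression_split(seed = 31)
  for (mode in c("none", "standard", "fbm")) {
    r1 <- run_experiment(quick_reg_cfg(mode, seed = 32), dat)
    r2 <- run_experiment(quick_reg_cfg(mode, seed = 32), dat)
    expect_identical(r1$metrics, r2$metrics)
    r3 <- run_experiment(quick_reg_cfg(mode, seed = 33), dat)
    expect_false(identical(r1$metrics$train_loss, r3$metrics$train_loss))
  }
})

test_that("gap equals testing minus training loss at every epoch", {
  dat <- make_regression_split(seed = 41)
  r <- run_experiment(quick_reg_cfg("standard", seed = 42), dat)
  expect_equal(r$metrics$gap, r$metrics$test_loss - r$metrics$train_loss)
  expect_true(all(is.na(r$metrics$accuracy)))
})

test_that("only the hidden layers are droppable and full masking blanks them", {
  ns <- asNamespace("fbmdropout")
  cfg <- quick_reg_cfg("standard")
  masks <- ns$iteration_masks(cfg, c(100L, 100L), NULL, NULL, 0L)
  expect_length(masks, 2L)  # one keep-vector per hidden layer, none else
  # with every hidden unit dropped the network output cannot depend on x
  net <- ns$mlp_init(c(1L, 9L, 9L, 1L), seed = 5)
  dead <- list(rep(0, 9), rep(0, 9))
  out <- ns$mlp_forward(net, matrix(c(-1, 0, 1), 1), masks = dead,
                        training = TRUE)$out
  expect_equal(max(out) - min(out), 0)
})

test_that("the no-dropout regression run overfits the training points", {
  dat <- make_regression_split(seed = 103)
  r <- run_experiment(regression_config("none", seed = 3), dat)
  m <- r$metrics
  # training loss sinks below the 0.09 noise floor ...
  expect_lt(m$train_loss[50], 0.07)
  # ... while testing loss rises after an early minimum
  expect_lt(which.min(m$test_loss), 50)
  expect_gt(m$test_loss[50], min(m$test_loss) + 0.01)
  expect_gt(m$gap[50], 0)
})

test_that("FBM dropout bounds the gap on a paired short comparison", {
  # one paired seed at the benchmark configuration: the fiber condition
  # must not overfit harder than no dropout
  dat <- make_regression_split(seed = 71)
  r_none <- run_experiment(regression_config("none", seed = 72), dat)
  r_fbm <- run_experiment(regression_config("fbm", seed = 72), dat)
  expect_gt(r_none$metrics$gap[50], r_fbm$metrics$gap[50])
})

test_that("a small network learns the glyph classes without dropout", {
  dat <- make_glyph_split(50, 50, seed = 5)
  cfg <- classification_config("none", seed = 9,
                               layer_sizes = c(784L, 64L, 64L, 10L),
                               lr = 1e-3, epochs = 40L,
                               batches_per_epoch = 10L, batch_size = 50L)
  r <- run_experiment(cfg, dat)
  expect_gt(r$metrics$accuracy[40], 0.9)
  # predictions come back as 0-based labels
  pred <- predict(r, dat$test)
  expect_true(all(pred %in% 0:9))
  expect_gt(mean(pred == dat$test$labels), 0.9)
  probs <- predict(r, dat$test, type = "prob")
  expect_equal(rowSums(probs), rep(1, 500), tolerance = 1e-12)
})

test_that("FBM classification trains with per-layer independent fibers", {
  dat <- make_glyph_split(20, 20, seed = 6)
  cfg <- classification_config("fbm", seed = 10,
                               layer_sizes = c(784L, 64L, 64L, 10L),
                               lr = 1e-3, epochs = 12L,
                               batches_per_epoch = 10L, batch_size = 20L,
                               n_fibers = 12L)
  r <- run_experiment(cfg, dat)
  expect_equal(nrow(r$metrics), 12L)
  expect_gt(r$metrics$accuracy[12], 0.5)
  expect_identical(r$condition, "fbm")
})

test_that("condition comparison pairs seeds and aggregates trajectories", {
  cmp <- compare_conditions(quick_reg_cfg("fbm", seed = 51),
                            function(s) make_regression_split(seed = s),
                            n_seeds = 2, modes = c("none", "fbm"))
  expect_setequal(unique(cmp$final$condition), c("none", "fbm"))
  expect_equal(nrow(cmp$final), 4L)
  expect_equal(nrow(cmp$trajectories), 2L * 3L)
  # stored runs are faithful re-runnable records
  r <- cmp$runs$fbm[[1]]
  redo <- run_experiment(r$config, make_regression_split(
    seed = fbmdropout:::derive_seed(51, "data", 1)))
  expect_identical(r$metrics, redo$metrics)
})

test_that("runs and comparisons export to CSV/JSON and configs to YAML", {
  tmp <- withr::local_tempdir()
  dat <- make_regression_split(seed = 61)
  r <- run_experiment(quick_reg_cfg("standard", seed = 62), dat)
  csv <- file.path(tmp, "run.csv")
  write_run_csv(r, csv)
  df <- read.csv(csv)
  expect_named(df, c("epoch", "condition", "train_loss", "test_loss",
                     "accuracy", "gap"))
  expect_equal(df$gap, r$metrics$gap)

  js <- file.path(tmp, "run.json")
  write_run_json(r, js)
  obj <- jsonlite::read_json(js)
  expect_identical(obj$condition, "standard")
  expect_equal(obj$final$generalization_gap, r$metrics$gap[3])

  cmp <- compare_conditions(quick_reg_cfg("none", seed = 63), dat,
                            n_seeds = 2, modes = "none")
  write_comparison(cmp, file.path(tmp, "cmp"))
  expect_true(all(file.exists(file.path(tmp, "cmp",
                                        c("trajectories.csv", "final.csv",
                                          "summary.json")))))

  yml <- file.path(tmp, "cfg.yaml")
  writeLines(c("task: regression",
               "layer_sizes: [1, 100, 100, 1]",
               "lr: 0.01", "epochs: 2", "batches_per_epoch: 50",
               "batch_size: 50", "batch_mode: full",
               "mode: fbm", "n_fibers: 12", "seed: 7"), yml)
  cfg <- read_experiment_config(yml)
  expect_s3_class(cfg, "experiment_config")
  expect_identical(cfg$mode, "fbm")
  expect_identical(cfg$n_fibers, 12L)
  writeLines(c("task: regression", "nonsense: 1"), yml)
  expect_error(read_experiment_config(yml), "unknown config keys")
})
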