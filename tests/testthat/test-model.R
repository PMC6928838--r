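# Model unit tests run on 24 px tiles with a reduced architecture so each
# fit takes seconds; the full-scale behavior is exercised in the
# acceptance suite.

fit_tiny <- function(n_per = 6, epochs = 2, seed = 1, lr = 1e-3, ts = 24,
                     max_steps = NULL, init = NULL, tileset_seed = 1) {
  set <- synth_tileset(rep(class_codes(), each = n_per), ts,
                       seed = tileset_seed)
  cfg <- training_config(epochs = epochs, learning_rate = lr, seed = seed,
                         max_steps = max_steps)
  list(fit = patch_cnn(set$manifest, tiles = set$tiles, config = cfg,
                       architecture = tiny_arch(), init = init),
       set = set)
}

test_that("the forward pass meets the shape and normalization contract", {
  r <- fit_tiny(epochs = 1, lr = 0)
  fit <- r$fit
  expect_s3_class(fit, "patch_cnn")
  expect_equal(fit$tile_size, 24)
  logit <- predict(fit, r$set$tiles[1:3], type = "logit")
  expect_equal(dim(logit), c(3, 8))
  prob <- predict(fit, r$set$tiles[1:5], type = "prob")
  expect_equal(unname(rowSums(prob)), rep(1, 5), tolerance = 1e-6)
  expect_true(all(prob >= 0))
  # argmax invariant under softmax
  expect_equal(apply(logit, 1, which.max),
               apply(predict(fit, r$set$tiles[1:3], type = "prob"), 1,
                     which.max))
  cls <- predict(fit, r$set$tiles[1:5])
  expect_true(all(cls %in% class_codes()))
})

test_that("initialization and training are deterministic under a seed", {
  a <- fit_tiny(epochs = 2, seed = 5)$fit
  b <- fit_tiny(epochs = 2, seed = 5)$fit
  expect_identical(coef(a), coef(b))
  expect_identical(a$history, b$history)
  c2 <- fit_tiny(epochs = 2, seed = 6)$fit
  expect_false(identical(coef(a), coef(c2)))
  # same seed: identical initial parameters (lr 0 keeps them at init)
  i1 <- fit_tiny(epochs = 1, lr = 0, seed = 9)$fit
  i2 <- fit_tiny(epochs = 1, lr = 0, seed = 9)$fit
  expect_identical(coef(i1), coef(i2))
})

test_that("history bookkeeping follows epochs and max_steps", {
  expect_equal(nrow(fit_tiny(epochs = 1)$fit$history), 1)
  expect_equal(nrow(fit_tiny(epochs = 3)$fit$history), 3)
  expect_error(training_config(epochs = 0), "epochs")
  # a max_steps cap stops mid-epoch: 48 tiles / batch 20 = 3 steps/epoch
  capped <- fit_tiny(epochs = 10, max_steps = 4)$fit
  expect_equal(nrow(capped$history), 2)
})

test_that("zero learning rate leaves warm-started parameters unchanged", {
  base <- fit_tiny(epochs = 2, seed = 3)
  again <- retrain(base$fit, base$set$manifest, tiles = base$set$tiles,
                   config = training_config(epochs = 1, learning_rate = 0,
                                            seed = 3))
  expect_identical(coef(base$fit), coef(again))
  # with a positive rate the parameters do move, from the warm start
  moved <- retrain(base$fit, base$set$manifest, tiles = base$set$tiles,
                   config = training_config(epochs = 1, learning_rate = 1e-3,
                                            seed = 3))
  expect_false(identical(coef(base$fit), coef(moved)))
})

test_that("a forced constant output layer predicts one class everywhere", {
  r <- fit_tiny(epochs = 1, lr = 0)
  fit <- r$fit
  last <- length(fit$layers)
  fit$layers[[last]]$W[] <- 0
  fit$layers[[last]]$b <- c(0, 0, 0, 0, 0, 10, 0, 0) # favor class 6 = DC
  expect_equal(unique(predict(fit, r$set$tiles)), "DC")
})

test_that("analytic gradients match finite differences", {
  layers <- terrapatch:::.build_network(tiny_arch(), 16, 8, seed = 3)
  X <- terrapatch:::with_seed(4, matrix(stats::runif(16 * 16 * 3 * 4), ncol = 4))
  y <- c(1, 3, 5, 8)
  fw <- terrapatch:::.forward(layers, X, keep_cache = TRUE)
  sm <- terrapatch:::.softmax_xent(fw$out, y)
  grads <- terrapatch:::.backward(layers, fw$caches, sm$dlogits)
  loss_at <- function(ls) {
    terrapatch:::.softmax_xent(terrapatch:::.forward(ls, X)$out, y)$loss
  }
  eps <- 1e-6
  set.seed(8)
  for (i in seq_along(layers)) {
    if (is.null(grads[[i]])) next
    for (k in sample(length(layers[[i]]$W), 5)) {
      l2 <- layers
      l2[[i]]$W[k] <- l2[[i]]$W[k] + eps
      num <- (loss_at(l2) - sm$loss) / eps
      expect_equal(grads[[i]]$W[k], num, tolerance = 1e-3)
    }
  }
})

test_that("training learns separable synthetic textures", {
  # balanced manifest, modest epochs: training accuracy must be high
  # because the textures are separable by construction
  r <- fit_tiny(n_per = 20, epochs = 25, seed = 1)
  expect_gte(utils::tail(r$fit$history$accuracy, 1), 0.95)
  expect_lte(utils::tail(r$fit$history$loss, 1), r$fit$history$loss[1])
})

test_that("checkpoints round-trip with a JSON sidecar", {
  r <- fit_tiny(epochs = 1)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(r$fit, path)
  expect_true(file.exists(paste0(path, ".json")))
  back <- load_model(path)
  expect_identical(coef(back), coef(r$fit))
  expect_identical(predict(back, r$set$tiles[1:3]),
                   predict(r$fit, r$set$tiles[1:3]))
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  expect_equal(side$tile_size, 24)
  expect_equal(side$class_order, class_codes())
  expect_error(load_model(file.path(tempdir(), "nope.rds")), "missing")
})

test_that("configs validate inputs and round-trip through YAML", {
  cfg <- training_config()
  expect_equal(cfg$batch_size, 20L)
  expect_equal(cfg$epochs, 200L)
  expect_equal(cfg$learning_rate, 1e-2)
  expect_equal(cfg$optimizer, "adam")
  expect_equal(cfg$loss, "cross_entropy")
  expect_equal(cfg$regularization, "none")
  expect_equal(cfg$pooling, "max")
  expect_equal(cfg$output_transfer, "linear")
  expect_error(training_config(batch_size = 0), "batch_size")
  expect_error(training_config(learning_rate = -1), "learning_rate")
  path <- withr::local_tempfile(fileext = ".yaml")
  write_training_config(training_config(epochs = 7, seed = 42), path)
  cfg2 <- read_training_config(path)
  expect_equal(cfg2$epochs, 7L)
  expect_equal(cfg2$seed, 42L)
})

test_that("size mismatches and bad labels error clearly", {
  r <- fit_tiny(epochs = 1)
  wrong <- synth_tileset(c("H", "D"), 32, seed = 2)
  expect_error(predict(r$fit, wrong$tiles), "size mismatch")
  mf <- wrong$manifest
  mf$class_code <- c("H", "D")
  expect_error(patch_cnn(mf[0, ], config = training_config(epochs = 1)),
               "empty")
  expect_error(patch_cnn(mf, config = training_config(epochs = 1)),
               "unreadable tile")
})
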