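#' Fit the eight-class terrain patch classifier
#'
#' Trains a small convolutional network (see [default_architecture()]) that
#' maps square RGB patches to the eight terrain classes. Pixel values are
#' scaled to `[0, 1]`; the output layer is linear and class probabilities
#' are obtained by softmax at prediction time (the softmax is folded into
#' the cross-entropy loss during training). Training is deterministic for a
#' given configuration seed: initialization and the per-epoch shuffling of
#' mini-batches both derive from it.
#'
#' Tiles can come from disk (the manifest's `tile_path` column, PNG files)
#' or be supplied in memory via `tiles`, aligned row-by-row with the
#' manifest — the form returned by [synth_scene()] and [synth_tileset()].
#'
#' Passing a fitted model as `init` warm-starts training from that model's
#' parameters without reinitialization (the optimizer state starts fresh);
#' this is the retraining workflow for adapting a classifier to a new
#' terrain, also available as [retrain()].
#'
#' @param manifest A labeled `patch_manifest` (see [manifest()]).
#' @param tiles Optional list of in-memory tiles aligned with the manifest.
#' @param config A [training_config()].
#' @param architecture Layer specification list; defaults to
#'   [default_architecture()].
#' @param init Optional fitted `patch_cnn` to warm-start from.
#' @param verbose Print per-epoch progress.
#' @return An object of class `patch_cnn` with components `layers` (fitted
#'   parameters and geometry), `architecture`, `class_order`, `tile_size`,
#'   `config` and `history` (data frame of per-epoch loss and training
#'   accuracy).
#' @seealso [predict.patch_cnn()], [retrain()], [evaluate_classifier()]
#' @examples
#' set <- synth_tileset(rep(class_codes(), each = 6), tile_size = 24, seed = 1)
#' cfg <- training_config(epochs = 2, learning_rate = 1e-3, seed = 1)
#' fit <- patch_cnn(set$manifest, tiles = set$tiles, config = cfg,
#'                  architecture = default_architecture(c(8, 16), dense_units = 32))
#' fit$history
#' @export
patch_cnn <- function(manifest, tiles = NULL, config = training_config(),
                      architecture = NULL, init = NULL, verbose = FALSE) {
  if (nrow(manifest) == 0) stop("manifest is empty", call. = FALSE)
  .check_codes(manifest$class_code)
  class_order <- class_codes()
  X <- .load_tile_matrix(manifest, tiles)
  tile_size <- as.integer(sqrt(nrow(X) / 3))
  y <- match(manifest$class_code, class_order)

  if (!is.null(init)) {
    if (!inherits(init, "patch_cnn")) stop("init must be a patch_cnn",
                                           call. = FALSE)
    if (init$tile_size != tile_size) {
      stop("init model expects ", init$tile_size, " px tiles, data has ",
           tile_size, " px", call. = FALSE)
    }
    layers <- init$layers
    architecture <- init$architecture
  } else {
    architecture <- architecture %||% default_architecture()
    layers <- .build_network(architecture, tile_size,
                             n_classes = length(class_order),
                             seed = derive_seed(config$seed, 17L))
  }

  w <- if (config$class_weights) {
    freq <- tabulate(y, length(class_order))
    wc <- ifelse(freq > 0, sum(freq) / (sum(freq > 0) * pmax(freq, 1)), 0)
    wc[y]
  }

  n <- ncol(X)
  opt <- .adam_state(layers)
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        accuracy = numeric(0))
  steps <- 0L
  done <- FALSE
  for (ep in seq_len(config$epochs)) {
    ord <- with_seed(derive_seed(config$seed, 23L, ep), sample.int(n))
    ep_loss <- 0; ep_hits <- 0; ep_n <- 0
    for (start in seq(1, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1, n)]
      Xb <- X[, idx, drop = FALSE]
      yb <- y[idx]
      fw <- .forward(layers, Xb, keep_cache = TRUE)
      sm <- .softmax_xent(fw$out, yb, if (!is.null(w)) w[idx])
      if (!is.finite(sm$loss)) {
        stop("training diverged (non-finite loss) at epoch ", ep,
             call. = FALSE)
      }
      ep_loss <- ep_loss + sm$loss * length(idx)
      ep_hits <- ep_hits + sum(max.col(t(fw$out), ties.method = "first") == yb)
      ep_n <- ep_n + length(idx)
      if (config$learning_rate > 0) {
        grads <- .backward(layers, fw$caches, sm$dlogits)
        opt <- .adam_step(layers, grads, opt, config$learning_rate)
        layers <- opt$layers
      }
      steps <- steps + 1L
      if (!is.null(config$max_steps) && steps >= config$max_steps) {
        done <- TRUE
        break
      }
    }
    history <- rbind(history, data.frame(
      epoch = ep, loss = ep_loss / ep_n, accuracy = ep_hits / ep_n))
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f  accuracy %.4f", ep,
                      ep_loss / ep_n, ep_hits / ep_n))
    }
    if (done) break
  }

  structure(list(
    layers = layers, architecture = architecture, class_order = class_order,
    tile_size = tile_size, config = config, history = history,
    n_train = n, call = match.call()
  ), class = "patch_cnn")
}

#' Continue training a fitted classifier on new data
#'
#' Warm-starts from the fitted model's parameters (no reinitialization) and
#' continues training on a new manifest — the workflow for adapting the
#' classifier to a different terrain with a modest amount of new labels.
#'
#' @param model A fitted `patch_cnn`.
#' @inheritParams patch_cnn
#' @return A new fitted `patch_cnn`.
#' @export
retrain <- function(model, manifest, tiles = NULL,
                    config = model$config, verbose = FALSE) {
  patch_cnn(manifest, tiles = tiles, config = config, init = model,
            verbose = verbose)
}

# Stack tiles (from memory or PNG files) into the (D x N) input matrix,
# scaled to [0, 1].
.load_tile_matrix <- function(manifest, tiles = NULL) {
  n <- nrow(manifest)
  if (!is.null(tiles)) {
    if (length(tiles) != n) {
      stop("tiles must align with the manifest (", n, " records)",
           call. = FALSE)
    }
    px1 <- tiles[[1]]$pixels
  } else {
    missing <- !file.exists(manifest$tile_path)
    if (any(missing)) {
      stop("unreadable tile: ", manifest$tile_path[which(missing)[1]],
           call. = FALSE)
    }
    px1 <- png::readPNG(manifest$tile_path[1])
  }
  d <- dim(px1)
  if (d[1] != d[2]) stop("tiles must be square", call. = FALSE)
  X <- matrix(0, d[1] * d[2] * 3, n)
  for (i in seq_len(n)) {
    px <- if (!is.null(tiles)) tiles[[i]]$pixels else
      png::readPNG(manifest$tile_path[i])
    if (length(dim(px)) == 3 && dim(px)[3] > 3) px <- px[, , 1:3]
    if (max(px) > 1) px <- px / 255
    if (!all(dim(px)[1:2] == d[1:2])) {
      stop("tile size mismatch at record ", i, call. = FALSE)
    }
    X[, i] <- as.vector(px[, , 1:3])
  }
  X
}

.softmax_xent <- function(logits, y, w = NULL) {
  B <- ncol(logits)
  Z <- sweep(logits, 2, apply(logits, 2, max))
  P <- exp(Z)
  P <- sweep(P, 2, colSums(P), "/")
  picked <- P[cbind(y, seq_len(B))]
  wts <- if (is.null(w)) rep(1, B) else w
  loss <- -sum(wts * log(pmax(picked, 1e-12))) / sum(wts)
  dZ <- P
  dZ[cbind(y, seq_len(B))] <- dZ[cbind(y, seq_len(B))] - 1
  dZ <- sweep(dZ, 2, wts, "*") / sum(wts)
  list(loss = loss, dlogits = dZ, probs = P)
}

.adam_state <- function(layers) {
  ms <- lapply(layers, function(ly) {
    if (!is.null(ly$W)) list(mW = ly$W * 0, vW = ly$W * 0,
                             mb = ly$b * 0, vb = ly$b * 0)
  })
  list(layers = layers, m = ms, t = 0L)
}

.adam_step <- function(layers, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  t <- opt$t + 1L
  for (i in seq_along(layers)) {
    if (is.null(grads[[i]])) next
    st <- opt$m[[i]]
    st$mW <- beta1 * st$mW + (1 - beta1) * grads[[i]]$W
    st$vW <- beta2 * st$vW + (1 - beta2) * grads[[i]]$W^2
    st$mb <- beta1 * st$mb + (1 - beta1) * grads[[i]]$b
    st$vb <- beta2 * st$vb + (1 - beta2) * grads[[i]]$b^2
    mhW <- st$mW / (1 - beta1^t); vhW <- st$vW / (1 - beta2^t)
    mhb <- st$mb / (1 - beta1^t); vhb <- st$vb / (1 - beta2^t)
    layers[[i]]$W <- layers[[i]]$W - lr * mhW / (sqrt(vhW) + eps)
    layers[[i]]$b <- layers[[i]]$b - lr * mhb / (sqrt(vhb) + eps)
    opt$m[[i]] <- st
  }
  opt$layers <- layers
  opt$t <- t
  opt
}

#' Predict terrain classes for tiles
#'
#' Runs the forward pass and returns, per tile, the argmax class (ties
#' broken toward the lowest index in the canonical class order), the full
#' softmax probability vector, or the raw logits.
#'
#' @param object A fitted `patch_cnn`.
#' @param tiles A list of tiles, a `patch_manifest` (tiles read from
#'   `tile_path`), or a `H x W x 3` array / list thereof.
#' @param type `"class"` (default), `"prob"`, `"logit"`, or `"both"`
#'   (a list with `class` and `prob`).
#' @param batch_size Forward-pass batch size.
#' @param ... Unused.
#' @return A character vector, a numeric matrix (`n x 8`, columns named by
#'   class), or a list, per `type`.
#' @export
predict.patch_cnn <- function(object, tiles, type = c("class", "prob",
                                                      "logit", "both"),
                              batch_size = 64L, ...) {
  type <- match.arg(type)
  X <- if (is.data.frame(tiles)) {
    .load_tile_matrix(tiles)
  } else if (is.array(tiles) && length(dim(tiles)) == 3) {
    .load_tile_matrix(data.frame(row = 1), tiles = list(list(pixels = tiles)))
  } else {
    .load_tile_matrix(data.frame(row = seq_along(tiles)), tiles = tiles)
  }
  expect_d <- object$tile_size^2 * 3
  if (nrow(X) != expect_d) {
    stop("tile size mismatch: model expects ", object$tile_size, " px tiles",
         call. = FALSE)
  }
  n <- ncol(X)
  L <- length(object$class_order)
  logits <- matrix(0, n, L, dimnames = list(NULL, object$class_order))
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    out <- .forward(object$layers, X[, idx, drop = FALSE])$out
    logits[idx, ] <- t(out)
  }
  if (type == "logit") return(logits)
  Z <- exp(logits - apply(logits, 1, max))
  prob <- Z / rowSums(Z)
  cls <- object$class_order[max.col(prob, ties.method = "first")]
  switch(type,
         class = cls,
         prob = prob,
         both = list(class = cls, prob = prob))
}

#' @export
print.patch_cnn <- function(x, ...) {
  cat("<patch_cnn> 8-class terrain patch classifier\n")
  cat(sprintf("  input: %d x %d px RGB; classes: %s\n", x$tile_size,
              x$tile_size, paste(x$class_order, collapse = " ")))
  cat(sprintf("  trained %d epochs on %d tiles; final loss %.4f, accuracy %.3f\n",
              nrow(x$history), x$n_train,
              utils::tail(x$history$loss, 1),
              utils::tail(x$history$accuracy, 1)))
  invisible(x)
}

#' @export
summary.patch_cnn <- function(object, ...) {
  n_par <- sum(vapply(object$layers, function(ly) {
    if (is.null(ly$W)) 0 else length(ly$W) + length(ly$b)
  }, numeric(1)))
  desc <- vapply(object$layers, function(ly) {
    switch(ly$type,
           conv = sprintf("conv %dx, %d params", ly$filters,
                          length(ly$W) + length(ly$b)),
           pool = "max-pool 2x2",
           relu = "relu",
           dense = sprintf("dense %d units%s", length(ly$b),
                           if (isTRUE(ly$output)) " (linear output)" else ""))
  }, character(1))
  structure(list(model = object, n_par = n_par, layer_desc = desc),
            class = "summary.patch_cnn")
}

#' @export
print.summary.patch_cnn <- function(x, ...) {
  print(x$model)
  cat(sprintf("  %d trainable parameters\n  layers:\n", x$n_par))
  cat(paste0("    ", seq_along(x$layer_desc), ". ", x$layer_desc,
             collapse = "\n"), "\n")
  invisible(x)
}

#' @export
coef.patch_cnn <- function(object, ...) {
  params <- lapply(object$layers, function(ly) {
    if (!is.null(ly$W)) list(W = ly$W, b = ly$b)
  })
  params[!vapply(params, is.null, logical(1))]
}

#' Plot training history
#'
#' Draws per-epoch training loss and accuracy curves.
#'
#' @param x A fitted `patch_cnn`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.patch_cnn <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(h$epoch, h$loss, type = "l", xlab = "epoch",
                 ylab = "training loss", main = "loss", ...)
  graphics::plot(h$epoch, h$accuracy, type = "l", ylim = c(0, 1),
                 xlab = "epoch", ylab = "training accuracy",
                 main = "accuracy", ...)
  invisible(x)
}

#' Save and load classifier checkpoints
#'
#' The model is serialized with [saveRDS()]; a JSON sidecar
#' (`<path>.json`) records the class order, tile size and training
#' configuration for inspection without loading the checkpoint.
#'
#' @param model A fitted `patch_cnn`.
#' @param path Checkpoint file path (e.g. `model.rds`).
#' @return `load_model()` returns the `patch_cnn`.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  side <- list(class_order = model$class_order, tile_size = model$tile_size,
               config = unclass(model$config),
               epochs_trained = nrow(model$history))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("missing checkpoint: ", path, call. = FALSE)
  m <- readRDS(path)
  if (!inherits(m, "patch_cnn")) stop("not a patch_cnn checkpoint: ", path,
                                      call. = FALSE)
  m
}
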