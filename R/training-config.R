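#' Training configuration
#'
#' Hyperparameters of the patch classifier. The defaults reproduce the
#' reference acquisition campaign's training profile: mini-batches of 20,
#' 200 epochs, ReLU activations, softmax cross-entropy loss, Adam with
#' learning rate 1e-2, no regularization, max pooling, and a linear
#' ("pureline") output transfer with probabilities obtained by softmax at
#' prediction time.
#'
#' `epochs` counts full passes over the training set. For the alternative
#' literal reading of an iteration budget as optimizer steps, set
#' `max_steps`: training then stops after that many mini-batch updates
#' regardless of `epochs`.
#'
#' Note that Adam at learning rate 1e-2 is an aggressive setting for
#' convolutional networks and can be unstable on small datasets; 1e-3 is a
#' robust choice for experiments on synthetic scenes (see the package
#' vignette).
#'
#' @param batch_size Mini-batch size (>= 1).
#' @param epochs Number of passes over the training data (>= 1).
#' @param learning_rate Adam step size (>= 0; a rate of exactly zero leaves
#'   parameters untouched, which is occasionally useful to re-evaluate a
#'   model through the training path).
#' @param optimizer Only `"adam"` is implemented.
#' @param loss Only `"cross_entropy"` is implemented.
#' @param activation Hidden activation; only `"relu"` is implemented.
#' @param regularization Only `"none"` is implemented.
#' @param pooling Only `"max"` is implemented.
#' @param output_transfer Only `"linear"` is implemented.
#' @param seed Integer seed controlling initialization and batch order.
#' @param max_steps Optional cap on total optimizer steps.
#' @param class_weights If `TRUE`, weight the loss of each class inversely
#'   to its training frequency (off by default).
#' @return An object of class `training_config`.
#' @export
training_config <- function(batch_size = 20L, epochs = 200L,
                            learning_rate = 1e-2, optimizer = "adam",
                            loss = "cross_entropy", activation = "relu",
                            regularization = "none", pooling = "max",
                            output_transfer = "linear", seed = 1L,
                            max_steps = NULL, class_weights = FALSE) {
  if (batch_size < 1) stop("batch_size must be >= 1", call. = FALSE)
  if (epochs < 1) stop("epochs must be >= 1", call. = FALSE)
  if (learning_rate < 0) stop("learning_rate must be >= 0", call. = FALSE)
  optimizer <- match.arg(optimizer, "adam")
  loss <- match.arg(loss, "cross_entropy")
  activation <- match.arg(activation, "relu")
  regularization <- match.arg(regularization, "none")
  pooling <- match.arg(pooling, "max")
  output_transfer <- match.arg(output_transfer, "linear")
  structure(list(
    batch_size = as.integer(batch_size), epochs = as.integer(epochs),
    learning_rate = learning_rate, optimizer = optimizer, loss = loss,
    activation = activation, regularization = regularization,
    pooling = pooling, output_transfer = output_transfer,
    seed = as.integer(seed),
    max_steps = if (!is.null(max_steps)) as.integer(max_steps),
    class_weights = isTRUE(class_weights)
  ), class = "training_config")
}

#' @export
print.training_config <- function(x, ...) {
  cat("<training_config>\n")
  cat(sprintf("  batch size      %d\n", x$batch_size))
  cat(sprintf("  epochs          %d%s\n", x$epochs,
              if (!is.null(x$max_steps)) sprintf(" (max %d steps)", x$max_steps)
              else ""))
  cat(sprintf("  learning rate   %g\n", x$learning_rate))
  cat(sprintf("  optimizer/loss  %s / %s\n", x$optimizer, x$loss))
  cat(sprintf("  activation      %s, pooling %s, output %s\n",
              x$activation, x$pooling, x$output_transfer))
  cat(sprintf("  regularization  %s\n", x$regularization))
  cat(sprintf("  seed            %d\n", x$seed))
  invisible(x)
}

#' Read and write training configurations as YAML
#'
#' @param config A [training_config()].
#' @param path YAML file path.
#' @return `read_training_config()` returns a `training_config`.
#' @export
write_training_config <- function(config, path) {
  x <- unclass(config)
  x <- x[!vapply(x, is.null, logical(1))]
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_training_config
#' @export
read_training_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(training_config, x)
}
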