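# Vectorized neural-network engine.
#
# Feature maps are stored column-major as flat vectors of length H*W*C with
# index (c-1)*H*W + (x-1)*H + y, so an H x W x 3 tile array flattens to the
# input layout with a plain as.vector(). A mini-batch is a (D x B) matrix.
# Convolutions are "valid" (no padding), stride 1, computed through a
# precomputed im2col index map; pooling is 2x2 max with stride 2, dropping
# odd trailing rows/columns. All of this is deliberately plain matrix
# algebra so training is bit-reproducible given a seed on a single thread.

# --- layer geometry ---------------------------------------------------------

.conv_geometry <- function(H, W, C, k) {
  Hp <- H - k + 1L; Wp <- W - k + 1L
  if (Hp < 1 || Wp < 1) {
    stop("convolution kernel larger than its input (", H, "x", W, ")",
         call. = FALSE)
  }
  P <- Hp * Wp
  y0 <- rep(seq_len(Hp), times = Wp)
  x0 <- rep(seq_len(Wp), each = Hp)
  K <- k * k * C
  Cmat <- matrix(0L, K, P)
  r <- 1L
  for (ch in seq_len(C)) {
    for (dx in 0:(k - 1L)) {
      for (dy in 0:(k - 1L)) {
        Cmat[r, ] <- (ch - 1L) * H * W + (x0 + dx - 1L) * H + (y0 + dy)
        r <- r + 1L
      }
    }
  }
  list(Cmat = Cmat, K = K, P = P, Hp = Hp, Wp = Wp)
}

.pool_geometry <- function(H, W, C) {
  H2 <- H %/% 2L; W2 <- W %/% 2L
  if (H2 < 1 || W2 < 1) stop("input too small to pool", call. = FALSE)
  y <- rep(seq_len(H2) * 2L - 1L, times = W2)
  x <- rep(seq_len(W2) * 2L - 1L, each = H2)
  base <- lapply(list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L)),
                 function(d) (x + d[2] - 1L) * H + (y + d[1]))
  per_ch <- H2 * W2
  idx <- lapply(base, function(b) {
    as.vector(outer(b, (seq_len(C) - 1L) * H * W, "+"))
  })
  list(idx = idx, H2 = H2, W2 = W2, n_out = per_ch * C)
}

# Glorot-uniform initial weights.
.glorot <- function(nr, nc, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

#' Default network architecture
#'
#' The classifier is a small convolutional feature extractor followed by a
#' multilayer-perceptron head: three convolution blocks (3x3 kernels with
#' 32, 64 and 128 filters, ReLU activation, each followed by 2x2 max
#' pooling), a flatten, one fully connected ReLU layer of 128 units, and a
#' fully connected output layer with identity (linear) transfer whose
#' logits are turned into class probabilities by a softmax at prediction
#' time (the softmax is folded into the cross-entropy loss during
#' training). Any alternative stack of `conv`/`pool`/`dense` specs can be
#' supplied to [patch_cnn()] instead.
#'
#' @param filters Filter counts of the convolution blocks.
#' @param kernel Convolution kernel edge (pixels).
#' @param dense_units Units of the hidden fully connected layer.
#' @return A list of layer specifications.
#' @export
default_architecture <- function(filters = c(32, 64, 128), kernel = 3,
                                 dense_units = 128) {
  c(
    unlist(lapply(filters, function(f) {
      list(list(type = "conv", filters = f, kernel = kernel),
           list(type = "relu"),
           list(type = "pool"))
    }), recursive = FALSE),
    list(list(type = "dense", units = dense_units),
         list(type = "relu"))
  )
}

# Instantiate layers (geometry + initial parameters) for a given input size.
.build_network <- function(arch, tile_size, n_classes, seed) {
  H <- W <- as.integer(tile_size); C <- 3L
  flat <- NULL # becomes the vector length once spatial structure is dropped
  layers <- list()
  with_seed(seed, {
    for (spec in arch) {
      if (spec$type == "conv") {
        if (!is.null(flat)) stop("conv layer after dense is not supported",
                                 call. = FALSE)
        g <- .conv_geometry(H, W, C, as.integer(spec$kernel))
        F_ <- as.integer(spec$filters)
        layers[[length(layers) + 1L]] <- list(
          type = "conv", geom = g, filters = F_, d_in = H * W * C,
          W = .glorot(g$K, F_, g$K, F_ * spec$kernel^2), b = rep(0, F_)
        )
        H <- g$Hp; W <- g$Wp; C <- F_
      } else if (spec$type == "pool") {
        if (!is.null(flat)) stop("pool layer after dense is not supported",
                                 call. = FALSE)
        g <- .pool_geometry(H, W, C)
        layers[[length(layers) + 1L]] <- list(type = "pool", geom = g)
        H <- g$H2; W <- g$W2
      } else if (spec$type == "relu") {
        layers[[length(layers) + 1L]] <- list(type = "relu")
      } else if (spec$type == "dense") {
        d_in <- flat %||% (H * W * C)
        u <- as.integer(spec$units)
        layers[[length(layers) + 1L]] <- list(
          type = "dense", W = .glorot(d_in, u, d_in, u), b = rep(0, u)
        )
        flat <- u
      } else {
        stop("unknown layer type: ", spec$type, call. = FALSE)
      }
    }
    d_in <- flat %||% (H * W * C)
    layers[[length(layers) + 1L]] <- list(
      type = "dense", W = .glorot(d_in, n_classes, d_in, n_classes),
      b = rep(0, n_classes), output = TRUE
    )
  })
  layers
}

# --- forward / backward -----------------------------------------------------

.forward <- function(layers, X, keep_cache = FALSE) {
  caches <- if (keep_cache) vector("list", length(layers))
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    if (ly$type == "conv") {
      g <- ly$geom; B <- ncol(X)
      M <- X[as.vector(g$Cmat), , drop = FALSE]
      dim(M) <- c(g$K, g$P * B)
      Z <- crossprod(ly$W, M) + ly$b
      dim(Z) <- c(ly$filters, g$P, B)
      Z <- aperm(Z, c(2, 1, 3))
      dim(Z) <- c(g$P * ly$filters, B)
      if (keep_cache) caches[[i]] <- list(M = M, B = B)
      X <- Z
    } else if (ly$type == "relu") {
      if (keep_cache) caches[[i]] <- X > 0
      X <- X * (X > 0)
    } else if (ly$type == "pool") {
      g <- ly$geom
      x1 <- X[g$idx[[1]], , drop = FALSE]; x2 <- X[g$idx[[2]], , drop = FALSE]
      x3 <- X[g$idx[[3]], , drop = FALSE]; x4 <- X[g$idx[[4]], , drop = FALSE]
      Y <- pmax(x1, x2, x3, x4)
      if (keep_cache) {
        caches[[i]] <- list(x = list(x1, x2, x3, x4), Y = Y, d_in = nrow(X))
      }
      X <- Y
    } else { # dense
      if (keep_cache) caches[[i]] <- X
      X <- crossprod(ly$W, X) + ly$b
    }
  }
  list(out = X, caches = caches)
}

# Backpropagate dOut; returns per-layer parameter gradients.
.backward <- function(layers, caches, dOut) {
  grads <- vector("list", length(layers))
  dX <- dOut
  for (i in rev(seq_along(layers))) {
    ly <- layers[[i]]
    if (ly$type == "conv") {
      g <- ly$geom; cache <- caches[[i]]; B <- cache$B
      dim(dX) <- c(g$P, ly$filters, B)
      dZ <- aperm(dX, c(2, 1, 3))
      dim(dZ) <- c(ly$filters, g$P * B)
      grads[[i]] <- list(W = tcrossprod(cache$M, dZ), b = rowSums(dZ))
      if (i == 1L) break # no gradient needed w.r.t. the image input
      dM <- ly$W %*% dZ
      dim(dM) <- c(g$K * g$P, B)
      rs <- rowsum(dM, as.vector(g$Cmat))
      dX <- matrix(0, ly$d_in, B)
      dX[as.integer(rownames(rs)), ] <- rs
    } else if (ly$type == "relu") {
      dX <- dX * caches[[i]]
    } else if (ly$type == "pool") {
      g <- ly$geom; cache <- caches[[i]]
      dIn <- matrix(0, cache$d_in, ncol(dX))
      taken <- matrix(FALSE, nrow(dX), ncol(dX))
      for (j in 1:4) {
        m <- (cache$x[[j]] == cache$Y) & !taken
        taken <- taken | m
        dIn[g$idx[[j]], ] <- dX * m
      }
      dX <- dIn
    } else { # dense
      Xin <- caches[[i]]
      grads[[i]] <- list(W = tcrossprod(Xin, dX), b = rowSums(dX))
      dX <- ly$W %*% dX
    }
  }
  grads
}
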