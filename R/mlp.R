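#' Forward pass of the multi-layer perceptron
#'
#' The per-class MLP is a 5:3:1 feed-forward network on the SWeeP vector:
#' two tanh hidden layers of 5 and 3 units and a single logistic output
#' unit, so every score lies strictly in (0, 1). The pass is a pure
#' function of `(model, x)`.
#'
#' @param model An `mlp_model` from [train_mlp()].
#' @param x Numeric vector of length `d_in`, or an `n x d_in` matrix.
#' @return Numeric vector of scores in (0, 1), one per input row.
#' @export
forward_mlp <- function(model, x) {
  stopifnot(inherits(model, "mlp_model"))
  X <- as_input_matrix(x, model$layer_sizes[1L])
  H <- X
  n_aff <- length(model$weights)
  for (l in seq_len(n_aff)) {
    Z <- H %*% model$weights[[l]] +
      matrix(model$biases[[l]], nrow(H), length(model$biases[[l]]), byrow = TRUE)
    H <- if (l < n_aff) tanh(Z) else stats::plogis(Z)
  }
  as.numeric(H)
}

as_input_matrix <- function(x, d_in) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  if (ncol(x) != d_in) {
    stop("input has ", ncol(x), " features but the model expects ", d_in)
  }
  if (!all(is.finite(x))) stop("input contains non-finite values")
  x
}

#' Train a binary MLP classifier
#'
#' Fits the 5:3:1 perceptron (tanh hidden, logistic output) on positive and
#' negative SWeeP vectors by full-batch Adam minimization of binary
#' cross-entropy. Inputs are standardized per feature during optimization
#' and the standardization is folded into the first affine layer of the
#' returned model, so [forward_mlp()] is exactly the documented
#' logistic(affine(tanh(affine(tanh(affine(x)))))) composition on raw
#' vectors. Training is deterministic given the seed (the only randomness
#' is the weight initialization).
#'
#' @param pos,neg Numeric matrices of positive/negative training vectors
#'   (rows are sequences).
#' @param epochs Full-batch epochs (default 300).
#' @param learning_rate Adam step size (default 0.01).
#' @param seed Integer seed for weight initialization.
#' @param hidden Hidden layer sizes (default `c(5, 3)`).
#' @param weight_decay L2 penalty on the weights (not biases), default
#'   1e-3; keeps the network's response far from the training data close
#'   to its bias, which suppresses spurious high scores on unrelated
#'   sequences.
#' @param min_positives Minimum number of positive rows (default 10).
#' @return An object of class `mlp_model`: list with `layer_sizes`,
#'   `weights`, `biases`, `seed`, `architecture = "mlp"` and `loss_trace`
#'   (cross-entropy recorded every 10 epochs).
#' @export
train_mlp <- function(pos, neg, epochs = 300L, learning_rate = 0.01,
                      seed = 1L, hidden = c(5L, 3L), weight_decay = 1e-3,
                      min_positives = 10L) {
  pos <- as.matrix(pos); neg <- as.matrix(neg)
  if (nrow(pos) < min_positives) {
    stop("too few positive vectors: ", nrow(pos), " < ", min_positives)
  }
  if (nrow(neg) < 1L) stop("at least one negative vector is required")
  if (ncol(pos) != ncol(neg)) stop("pos and neg must have the same width")
  X <- rbind(pos, neg)
  if (!all(is.finite(X))) stop("training vectors contain non-finite values")
  y <- c(rep(1, nrow(pos)), rep(0, nrow(neg)))
  d_in <- ncol(X)
  n <- nrow(X)

  mu <- colMeans(X)
  sdv <- sqrt(pmax(colMeans(X^2) - mu^2, 0))
  sdv[sdv < 1e-8] <- 1
  Xs <- sweep(sweep(X, 2L, mu, "-"), 2L, sdv, "/")

  sizes <- c(d_in, as.integer(hidden), 1L)
  n_aff <- length(sizes) - 1L
  init <- with_rng(seed, {
    lapply(seq_len(n_aff), function(l) {
      sd0 <- sqrt(2 / (sizes[l] + sizes[l + 1L]))
      matrix(stats::rnorm(sizes[l] * sizes[l + 1L], sd = sd0),
             sizes[l], sizes[l + 1L])
    })
  })
  W <- init
  b <- lapply(seq_len(n_aff), function(l) numeric(sizes[l + 1L]))

  # Adam state
  mW <- lapply(W, function(w) w * 0); vW <- mW
  mb <- lapply(b, function(x) x * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  loss_trace <- numeric(0)

  for (epoch in seq_len(epochs)) {
    # forward
    A <- vector("list", n_aff + 1L)  # activations; A[[1]] = input
    A[[1L]] <- Xs
    for (l in seq_len(n_aff)) {
      Z <- A[[l]] %*% W[[l]] +
        matrix(b[[l]], n, sizes[l + 1L], byrow = TRUE)
      A[[l + 1L]] <- if (l < n_aff) tanh(Z) else stats::plogis(Z)
    }
    p <- as.numeric(A[[n_aff + 1L]])
    if (epoch %% 10L == 0L || epoch == epochs || epoch == 1L) {
      pc <- pmin(pmax(p, 1e-12), 1 - 1e-12)
      loss_trace <- c(loss_trace, -mean(y * log(pc) + (1 - y) * log(1 - pc)))
      names(loss_trace)[length(loss_trace)] <- as.character(epoch)
    }
    # backward
    delta <- matrix((p - y) / n, ncol = 1L)
    for (l in rev(seq_len(n_aff))) {
      gW <- crossprod(A[[l]], delta) + weight_decay * W[[l]]
      gb <- colSums(delta)
      if (l > 1L) {
        delta <- (delta %*% t(W[[l]])) * (1 - A[[l]]^2)
      }
      # Adam update
      mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
      vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
      mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
      vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
      mhW <- mW[[l]] / (1 - beta1^epoch); vhW <- vW[[l]] / (1 - beta2^epoch)
      mhb <- mb[[l]] / (1 - beta1^epoch); vhb <- vb[[l]] / (1 - beta2^epoch)
      W[[l]] <- W[[l]] - learning_rate * mhW / (sqrt(vhW) + eps)
      b[[l]] <- b[[l]] - learning_rate * mhb / (sqrt(vhb) + eps)
    }
  }

  # fold the standardization into the first affine layer:
  # ((x - mu)/sd) W1 + b1 == x (W1/sd) + (b1 - (mu/sd) W1)
  b[[1L]] <- as.numeric(b[[1L]] - (mu / sdv) %*% W[[1L]])
  W[[1L]] <- W[[1L]] / sdv

  structure(
    list(
      layer_sizes = sizes,
      weights = W,
      biases = b,
      seed = as.integer(seed),
      architecture = "mlp",
      loss_trace = loss_trace
    ),
    class = "mlp_model"
  )
}

#' @export
print.mlp_model <- function(x, ...) {
  cat("MLP classifier: layers ", paste(x$layer_sizes, collapse = ":"),
      " (tanh hidden, logistic output), seed ", x$seed, "\n", sep = "")
  invisible(x)
}
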