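#' Forward pass of the radial basis function network
#'
#' Each of the (by default 51) basis units computes a Gaussian response
#' `exp(-||x - center_j||^2 / (2 width_j^2))` — exactly 1 when the input
#' coincides with the center — and the logistic output unit combines them
#' linearly: `score = logistic(bias + sum_j w_j basis_j)`. Far from every
#' center the score tends to `logistic(bias)`.
#'
#' @param model An `rbf_model` from [train_rbf()].
#' @param x Numeric vector of length `d_in`, or an `n x d_in` matrix.
#' @return Numeric vector of scores in (0, 1), one per input row.
#' @export
forward_rbf <- function(model, x) {
  stopifnot(inherits(model, "rbf_model"))
  X <- as_input_matrix(x, ncol(model$centers))
  Phi <- rbf_design(X, model$centers, model$widths)
  as.numeric(stats::plogis(model$bias + Phi %*% model$output_weights))
}

# Gaussian design matrix: n x k basis activations.
rbf_design <- function(X, centers, widths) {
  n <- nrow(X); k <- nrow(centers)
  d2 <- matrix(rowSums(X^2), n, k) +
    matrix(rowSums(centers^2), n, k, byrow = TRUE) -
    2 * X %*% t(centers)
  d2 <- pmax(d2, 0)
  exp(sweep(d2, 2L, 2 * widths^2, "/") * -1)
}

#' Train a binary RBF classifier
#'
#' Centers are chosen by seeded k-means over the pooled training vectors;
#' each width is the Euclidean distance from its center to the nearest
#' other center (floored at 1e-6), so basis functions tile the data at the
#' local cluster scale. The output layer is a ridge-regularized logistic
#' regression on the basis activations. If fewer training vectors (or
#' distinct vectors) than requested basis functions are available, the
#' basis count is reduced to fit with a warning. Deterministic given the
#' seed.
#'
#' @param pos,neg Numeric matrices of positive/negative training vectors.
#' @param n_basis Number of Gaussian basis functions (default 51).
#' @param seed Integer seed for the k-means initialization.
#' @param lambda Ridge penalty of the logistic output layer (default 0.01).
#' @param min_positives Minimum number of positive rows (default 10).
#' @return An object of class `rbf_model`: list with `centers` (k x d_in),
#'   `widths` (k), `output_weights` (k), `bias`, `n_basis_requested`,
#'   `seed`, `architecture = "rbf"`.
#' @export
train_rbf <- function(pos, neg, n_basis = 51L, seed = 1L, lambda = 0.01,
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

  U <- unique(X)
  k <- as.integer(n_basis)
  if (k > nrow(U)) {
    warning("reducing RBF basis count from ", k, " to ", nrow(U),
            " (training set has only that many distinct vectors)",
            call. = FALSE)
    k <- nrow(U)
  }
  centers <- if (k == nrow(U)) {
    # every distinct training vector becomes a center; k-means is a no-op
    unname(U)
  } else {
    km <- with_rng(seed, {
      init <- U[sample.int(nrow(U), k), , drop = FALSE]
      stats::kmeans(X, centers = init, iter.max = 100L)
    })
    unname(km$centers)
  }

  if (k >= 2L) {
    D <- as.matrix(stats::dist(centers))
    diag(D) <- Inf
    widths <- apply(D, 1L, min)
  } else {
    # single center: use the mean distance of the data to it
    widths <- mean(sqrt(rowSums(sweep(X, 2L, centers[1L, ], "-")^2)))
  }
  widths <- pmax(widths, 1e-6)

  Phi <- rbf_design(X, centers, widths)
  if (k >= 2L) {
    lam_seq <- sort(unique(c(1, 0.1, lambda)), decreasing = TRUE)
    fit <- glmnet::glmnet(Phi, y, family = "binomial", alpha = 0,
                          lambda = lam_seq, standardize = FALSE)
    cf <- as.numeric(stats::coef(fit, s = lambda))
  } else {
    g <- stats::glm(y ~ Phi, family = stats::binomial())
    cf <- as.numeric(stats::coef(g))
    cf[is.na(cf)] <- 0
  }

  structure(
    list(
      centers = centers,
      widths = as.numeric(widths),
      output_weights = cf[-1L],
      bias = cf[1L],
      n_basis_requested = as.integer(n_basis),
      seed = as.integer(seed),
      architecture = "rbf"
    ),
    class = "rbf_model"
  )
}

#' @export
print.rbf_model <- function(x, ...) {
  cat("RBF classifier: ", nrow(x$centers), " Gaussian basis functions on ",
      ncol(x$centers), " features, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# Architecture-dispatching score helper used by evaluation and prediction.
score_model <- function(model, x) {
  if (inherits(model, "mlp_model")) {
    forward_mlp(model, x)
  } else if (inherits(model, "rbf_model")) {
    forward_rbf(model, x)
  } else {
    stop("unknown model class: ", paste(class(model), collapse = "/"))
  }
}
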