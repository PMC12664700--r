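zero_mlp <- function(sizes) {
  n_aff <- length(sizes) - 1
  structure(
    list(
      layer_sizes = sizes,
      weights = lapply(seq_len(n_aff), function(l) matrix(0, sizes[l], sizes[l + 1])),
      biases = lapply(seq_len(n_aff), function(l) numeric(sizes[l + 1])),
      seed = 0L, architecture = "mlp", loss_trace = NULL
    ),
    class = "mlp_model"
  )
}

test_that("all-zero weights score exactly 0.5 and scores stay in (0,1)", {
  m <- zero_mlp(c(4L, 5L, 3L, 1L))
  expect_identical(forward_mlp(m, c(1, -2, 3, 100)), 0.5)
  withr::with_seed(3, {
    m2 <- train_mlp(matrix(rnorm(40), 10), matrix(rnorm(40), 10),
                    epochs = 20, seed = 1)
    x <- matrix(rnorm(200) * 50, 50, 4)
    s <- forward_mlp(m2, x)
    expect_true(all(s > 0 & s < 1))
  })
})

test_that("forward pass matches a hand-computed toy network", {
  # 2-input net, hidden sizes 2 and 1: arithmetic done with plain scalar ops
  m <- zero_mlp(c(2L, 2L, 1L, 1L))
  m$weights[[1]] <- matrix(c(0.5, -0.3, 0.1, 0.8), 2, 2)
  m$biases[[1]] <- c(0.05, -0.1)
  m$weights[[2]] <- matrix(c(1.2, -0.7), 2, 1)
  m$biases[[2]] <- 0.2
  m$weights[[3]] <- matrix(-1.5, 1, 1)
  m$biases[[3]] <- 0.3
  x <- c(0.4, -1.1)
  h1a <- tanh(0.5 * 0.4 + (-0.3) * (-1.1) + 0.05)
  h1b <- tanh(0.1 * 0.4 + 0.8 * (-1.1) - 0.1)
  h2 <- tanh(1.2 * h1a - 0.7 * h1b + 0.2)
  expected <- 1 / (1 + exp(-(-1.5 * h2 + 0.3)))
  expect_equal(forward_mlp(m, x), expected, tolerance = 1e-12)
})

test_that("dimension mismatch and non-finite input are rejected", {
  m <- zero_mlp(c(4L, 5L, 3L, 1L))
  expect_error(forward_mlp(m, c(1, 2, 3)), "expects")
  expect_error(forward_mlp(m, c(1, 2, NA, 4)), "non-finite")
})

test_that("training separates two Gaussian clouds", {
  cl <- gaussian_clouds(n_per = 50, d = 16)
  split <- stratified_split(cl$pos, cl$neg, 0.7, seed = 2)
  m <- train_mlp(split$train_pos, split$train_neg, seed = 5)
  rep <- evaluate_model(m, split$test_pos, split$test_neg)
  expect_gte(rep$accuracy, 0.95)
  # loss decreases over recorded checkpoints (full-batch, small tolerance)
  expect_lt(tail(m$loss_trace, 1), m$loss_trace[1])
  expect_true(all(diff(m$loss_trace) < 1e-2))
})

test_that("indistinguishable classes bound held-out accuracy at chance", {
  # positives and negatives drawn i.i.d. from one distribution: no signal
  withr::with_seed(8, {
    pos <- matrix(rnorm(200 * 8), 200, 8)
    neg <- matrix(rnorm(200 * 8), 200, 8)
    split <- stratified_split(pos, neg, 0.7, seed = 3)
    m <- train_mlp(split$train_pos, split$train_neg, seed = 5, epochs = 100)
    rep <- evaluate_model(m, split$test_pos, split$test_neg)
    expect_gte(rep$accuracy, 0.35)
    expect_lte(rep$accuracy, 0.65)
  })
})

test_that("training is deterministic given the seed and needs positives", {
  cl <- gaussian_clouds(n_per = 15, d = 6)
  m1 <- train_mlp(cl$pos, cl$neg, seed = 9, epochs = 50)
  m2 <- train_mlp(cl$pos, cl$neg, seed = 9, epochs = 50)
  m3 <- train_mlp(cl$pos, cl$neg, seed = 10, epochs = 50)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$biases, m2$biases)
  expect_false(identical(m1$weights, m3$weights))
  expect_error(train_mlp(cl$pos[1:5, ], cl$neg, seed = 1), "too few positive")
  bad <- cl$pos; bad[1, 1] <- Inf
  expect_error(train_mlp(bad, cl$neg, seed = 1), "non-finite")
})
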