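test_that("confusion matrices tally truth/prediction pairs", {
  labels <- c("A", "B", "C")
  truth <- c(s1 = "A", s2 = "A", s3 = "B")
  pred <- c(s1 = "A", s2 = "B", s3 = "B")
  M <- build_confusion(truth, pred, labels)
  expect_identical(M["A", "A"], 1L)
  expect_identical(M["A", "B"], 1L)
  expect_identical(M["B", "B"], 1L)
  expect_identical(sum(M), 3L)
  # row sums = truth frequencies
  expect_identical(unname(rowSums(M)), c(2, 1, 0))
  # all correct -> diagonal
  Md <- build_confusion(truth, truth, labels)
  expect_identical(sum(Md) - sum(diag(Md)), 0L)
  # id mismatch and foreign labels are errors
  expect_error(build_confusion(truth, pred[-1], labels), "identical id sets")
  expect_error(build_confusion(truth, c(s1 = "Z", pred[-1]), labels),
               "outside the label set")
})

test_that("per-class one-vs-rest metrics match hand arithmetic", {
  labels <- c("pos", "neg")
  M <- matrix(c(8L, 2L, 2L, 18L), 2, 2, byrow = TRUE,
              dimnames = list(truth = labels, prediction = labels))
  class(M) <- c("multiclass_confusion", class(M))
  pc <- per_class_metrics(M)
  p1 <- pc[pc$class == "pos", ]
  expect_equal(p1$precision, 0.8)
  expect_equal(p1$sensitivity, 0.8)
  expect_equal(p1$f1, 0.8)
  expect_equal(p1$accuracy, 26 / 30)
  # diagonal confusion -> all metrics 1
  tr <- c(a = "pos", b = "neg")
  Md <- build_confusion(tr, tr, labels)
  pcd <- per_class_metrics(Md)
  expect_true(all(pcd[, c("accuracy", "sensitivity", "precision", "f1")] == 1))
})

test_that("absent classes are flagged and excluded from macro means", {
  labels <- c("A", "B", "ghost")
  truth <- c(s1 = "A", s2 = "B", s3 = "A")
  pred <- c(s1 = "A", s2 = "B", s3 = "B")
  M <- build_confusion(truth, pred, labels)
  pc <- per_class_metrics(M)
  expect_false(pc$evaluated[pc$class == "ghost"])
  sm <- evaluation_summary(M)
  kept <- pc[pc$evaluated, ]
  expect_equal(unname(sm$macro["f1"]), mean(kept$f1))
  expect_equal(unname(sm$macro["accuracy"]), mean(kept$accuracy))
})

test_that("label permutation permutes per-class rows, macro unchanged", {
  withr::with_seed(17, {
    labels <- c("A", "B", "C", "D")
    ids <- sprintf("s%03d", 1:200)
    truth <- setNames(sample(labels, 200, TRUE), ids)
    pred <- truth
    flip <- sample(200, 50)
    pred[flip] <- sample(labels, 50, TRUE)
    M1 <- build_confusion(truth, pred, labels)
    perm <- c("C", "A", "D", "B")
    M2 <- build_confusion(truth, pred, perm)
    pc1 <- per_class_metrics(M1)
    pc2 <- per_class_metrics(M2)
    expect_identical(pc1[match(perm, pc1$class), "f1"], pc2$f1)
    s1 <- evaluation_summary(M1); s2 <- evaluation_summary(M2)
    expect_equal(s1$macro, s2$macro)
  })
})

test_that("class correlation matches the textbook formula and edge cases", {
  expect_equal(class_correlation(c(1, 2, 3), c(1, 2, 3)), 1.0)
  expect_equal(class_correlation(c(1, 2, 3), c(3, 2, 1)), -1.0)
  x <- c(10, 20, 30, 40); y <- c(12, 18, 33, 37)
  # independent oracle: explicit sum formula
  n <- 4
  r_oracle <- (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  expect_equal(class_correlation(x, y), r_oracle, tolerance = 1e-12)
  # symmetry and positive-scale invariance
  expect_equal(class_correlation(x, y), class_correlation(y, x))
  expect_equal(class_correlation(x * 7, y), class_correlation(x, y * 0.1))
  # degenerate inputs
  expect_warning(cc <- class_correlation(c(2, 2, 2), y[1:3]), "undefined")
  expect_true(is.na(cc))
  expect_error(class_correlation(1, 2), "at least 2")
  expect_error(class_correlation(x, y[1:3]), "same length")
})

test_that("summary aggregates can exclude the non-Nif background class", {
  labels <- c("NifH", "NifD", "non-Nif")
  ids <- sprintf("q%02d", 1:60)
  truth <- setNames(rep(labels, each = 20), ids)
  pred <- truth
  pred[c(1, 21, 41)] <- c("NifD", "non-Nif", "NifH")
  M <- build_confusion(truth, pred, labels)
  sm <- evaluation_summary(M, exclude = "non-Nif")
  pc <- sm$per_class
  nif_rows <- pc[pc$class != "non-Nif", ]
  expect_equal(unname(sm$macro["sensitivity"]), mean(nif_rows$sensitivity))
  expect_identical(sm$excluded, "non-Nif")
})
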