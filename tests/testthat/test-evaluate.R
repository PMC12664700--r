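score_matrix <- function(scores) matrix(scores, ncol = 1)

test_that("evaluate_model reproduces hand-computed confusion arithmetic", {
  # monotone_model predicts positive exactly when the feature is >= 0
  m <- monotone_model()
  # positives: 8 above, 2 below; negatives: 2 above, 18 below
  pos <- score_matrix(c(rep(2, 8), rep(-2, 2)))
  neg <- score_matrix(c(rep(2, 2), rep(-2, 18)))
  rep <- evaluate_model(m, pos, neg, threshold = 0.5)
  expect_identical(c(rep$tp, rep$fp, rep$fn, rep$tn), c(8L, 2L, 2L, 18L))
  expect_equal(rep$precision, 0.8)
  expect_equal(rep$sensitivity, 0.8)
  expect_equal(rep$f1, 0.8)
  expect_equal(rep$accuracy, 26 / 30)
  expect_length(rep$undefined, 0)
})

test_that("perfect and degenerate classifiers hit the documented edges", {
  m <- monotone_model()
  perfect <- evaluate_model(m, score_matrix(rep(1, 5)),
                            score_matrix(rep(-1, 5)))
  expect_equal(unlist(perfect[c("accuracy", "sensitivity", "precision", "f1")]),
               c(accuracy = 1, sensitivity = 1, precision = 1, f1 = 1))
  # everything below threshold: sensitivity 0, precision undefined -> 0
  allneg <- evaluate_model(m, score_matrix(rep(-1, 4)),
                           score_matrix(rep(-1, 6)))
  expect_equal(allneg$sensitivity, 0)
  expect_equal(allneg$precision, 0)
  expect_true(all(c("precision", "f1") %in% allneg$undefined))
  expect_error(evaluate_model(m, score_matrix(numeric(0)),
                              score_matrix(1)), "non-empty")
})

test_that("metrics are exactly recomputable from the stored counts", {
  m <- monotone_model()
  withr::with_seed(13, {
    for (i in 1:10) {
      pos <- score_matrix(rnorm(20))
      neg <- score_matrix(rnorm(30))
      r <- evaluate_model(m, pos, neg)
      expect_identical(r$tp + r$fn, 20L)
      expect_identical(r$fp + r$tn, 30L)
      expect_equal(r$accuracy, (r$tp + r$tn) / 50)
      if (r$tp + r$fn > 0) expect_equal(r$sensitivity, r$tp / (r$tp + r$fn))
      if (r$tp + r$fp > 0) expect_equal(r$precision, r$tp / (r$tp + r$fp))
      if (r$precision + r$sensitivity > 0) {
        expect_equal(r$f1, 2 * r$precision * r$sensitivity /
                       (r$precision + r$sensitivity))
      }
    }
  })
})

fake_candidate <- function(arch, f1, acc) {
  list(
    model = structure(list(architecture = arch, seed = 1L), class = paste0(arch, "_model")),
    report = structure(
      list(architecture = arch, seed = 1L, threshold = 0.5,
           tp = 1L, fp = 0L, tn = 1L, fn = 0L,
           accuracy = acc, sensitivity = 1, precision = 1, f1 = f1,
           undefined = character(0)),
      class = "training_report"
    )
  )
}

test_that("selection takes the highest F1, then accuracy, then MLP first", {
  a <- fake_candidate("mlp", 0.90, 0.95)
  b <- fake_candidate("rbf", 0.95, 0.80)
  expect_identical(select_best(list(a, b))$report$f1, 0.95)

  c1 <- fake_candidate("rbf", 0.90, 0.85)
  c2 <- fake_candidate("mlp", 0.90, 0.92)
  expect_identical(select_best(list(c1, c2))$report$accuracy, 0.92)

  d1 <- fake_candidate("rbf", 0.90, 0.90)
  d2 <- fake_candidate("mlp", 0.90, 0.90)
  expect_identical(select_best(list(d1, d2))$report$architecture, "mlp")
  # invariant to candidate order apart from the documented tie-breaks
  expect_identical(select_best(list(d2, d1))$report$architecture, "mlp")
  expect_identical(select_best(list(b, a))$report$f1, 0.95)
  expect_error(select_best(list()), "at least one")
})
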