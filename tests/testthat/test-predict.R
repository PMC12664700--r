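test_that("score_all produces per-class forward passes under one fingerprint", {
  tr <- small_trained()
  S <- score_all(tr$X, tr$bundle)
  expect_identical(dim(S), c(nrow(tr$X), length(tr$bundle$models)))
  expect_true(all(S > 0 & S < 1))
  expect_identical(colnames(S), intersect(tr$bundle$registry,
                                          names(tr$bundle$models)))
  # per-class composition contract
  for (cls in colnames(S)) {
    direct <- niffindr:::score_model(tr$bundle$models[[cls]]$model, tr$X)
    expect_identical(unname(S[, cls]), direct)
  }
  expect_identical(S, score_all(tr$X, tr$bundle))
  # fingerprint mismatch is a hard error
  X2 <- tr$X
  fp <- attr(X2, "fingerprint"); fp$projection_seed <- 9999L
  attr(X2, "fingerprint") <- fp
  expect_error(score_all(X2, tr$bundle), "fingerprint")
  attr(X2, "fingerprint") <- NULL
  expect_error(score_all(X2, tr$bundle), "no fingerprint")
})

test_that("label assignment follows threshold, argmax and registry ties", {
  S <- rbind(
    a = c(NifH = 0.2, NifD = 0.2, NifK = 0.2),
    b = c(NifH = 0.9, NifD = 0.6, NifK = 0.1),
    c = c(NifH = 0.1, NifD = 0.8, NifK = 0.8)
  )
  # NifD comes before NifK in the column order, so the tie goes to NifD
  pred <- assign_labels(S, threshold = 0.5)
  expect_identical(pred$assigned_label, c("non-Nif", "NifH", "NifD"))
  expect_identical(pred$assigned_score, c(NA, 0.9, 0.8))
  expect_identical(pred$sequence_id, c("a", "b", "c"))
  expect_identical(pred$NifK, unname(S[, "NifK"]))
})

test_that("raising the threshold never increases assignments", {
  tr <- small_trained()
  S <- score_all(tr$X, tr$bundle)
  n_assigned <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(th) {
    sum(assign_labels(S, th)$assigned_label != "non-Nif")
  }, numeric(1))
  expect_true(all(diff(n_assigned) <= 0))
})

test_that("write_outputs filters the FASTA, covers the table, round-trips", {
  tr <- small_trained()
  pred <- nif_predict(tr$bench$records, tr$bundle)
  prefix <- file.path(withr::local_tempdir(), "scan")
  paths <- write_outputs(tr$bench$records, pred, prefix,
                         fingerprint = tr$bundle$fingerprint, threshold = 0.5)
  hits <- pred$assigned_label != "non-Nif"
  expect_gt(sum(hits), 0)

  out_fa <- read_fasta(paths[["fasta"]])
  expect_identical(nrow(out_fa), sum(hits))
  # residues byte-identical to the inputs
  expect_identical(out_fa$seq,
                   tr$bench$records$seq[match(out_fa$id, tr$bench$records$id)])
  # header format contract
  i <- which(hits)[1]
  expect_match(
    out_fa$desc[out_fa$id == pred$sequence_id[i]],
    sprintf("\\[NifFinder=%s score=%.4f\\]$", pred$assigned_label[i],
            pred$assigned_score[i])
  )

  tab <- read.delim(paths[["table"]], stringsAsFactors = FALSE)
  expect_identical(nrow(tab), nrow(tr$bench$records))
  expect_setequal(tab$sequence_id, tr$bench$records$id)

  expect_error(write_outputs(tr$bench$records[-1, ], pred, prefix),
               "cover exactly")
})

test_that("synthetic families are recovered end-to-end", {
  tr <- small_trained()
  pred <- nif_predict(tr$bench$records, tr$bundle)
  truth <- tr$bench$truth[pred$sequence_id]
  acc <- mean(pred$assigned_label == unname(truth))
  # miniature fixture; the full-scale recovery gate is in the acceptance suite
  expect_gte(acc, 0.8)
  # prediction is deterministic
  pred2 <- nif_predict(tr$bench$records, tr$bundle)
  expect_identical(pred, pred2)
})

test_that("bundles round-trip through disk with identical predictions", {
  tr <- small_trained()
  dir <- withr::local_tempdir()
  save_bundle(tr$bundle, dir)
  back <- load_bundle(dir)
  expect_identical(back$registry, tr$bundle$registry)
  expect_identical(unclass(back$fingerprint), unclass(tr$bundle$fingerprint))
  for (cls in names(tr$bundle$models)) {
    expect_identical(back$models[[cls]]$report, tr$bundle$models[[cls]]$report)
  }
  S1 <- score_all(tr$X, tr$bundle)
  S2 <- score_all(tr$X, back)
  expect_identical(S1, S2)
  # saving the loaded bundle again is byte-identical
  dir2 <- withr::local_tempdir()
  save_bundle(back, dir2)
  f1 <- file.path(dir, "manifest.yaml"); f2 <- file.path(dir2, "manifest.yaml")
  expect_identical(readLines(f1), readLines(f2))
})
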