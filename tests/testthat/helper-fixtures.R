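# Shared fixtures and independent oracles for the test suite.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Random canonical protein sequence.
random_protein <- function(len, alphabet = AA20) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# Brute-force spaced-word oracle: enumerate every window with plain
# substr() calls, no shared code with the implementation.
oracle_words <- function(sequence, pattern) {
  sequence <- toupper(sequence)
  take <- which(strsplit(pattern, "")[[1]] == "1")  # 1-based offsets
  m <- nchar(pattern)
  L <- nchar(sequence)
  words <- character(0)
  if (L < m) return(words)
  for (p in 0:(L - m)) {
    w <- ""
    ok <- TRUE
    for (o in take) {
      ch <- substr(sequence, p + o, p + o)
      if (!ch %in% AA20) { ok <- FALSE; break }
      w <- paste0(w, ch)
    }
    if (ok) words <- c(words, w)
  }
  words
}

# Brute-force dense HDV from the word list (base-20 index arithmetic done
# independently of word_index()).
oracle_dense_hdv <- function(sequence, pattern, mode) {
  words <- oracle_words(sequence, pattern)
  k <- sum(strsplit(pattern, "")[[1]] == "1")
  v <- numeric(20^k)
  for (w in words) {
    idx <- 0
    for (j in seq_len(nchar(w))) {
      idx <- idx * 20 + (match(substr(w, j, j), AA20) - 1)
    }
    if (mode == "occurrence") v[idx + 1] <- 1 else v[idx + 1] <- v[idx + 1] + 1
  }
  v
}

dense_hdv <- function(h) {
  v <- numeric(h$dim)
  v[h$index + 1] <- h$value
  v
}

# Two well-separated Gaussian clouds for classifier tests.
gaussian_clouds <- function(n_per = 50, d = 16, sep = 4, seed = 42) {
  withr::with_seed(seed, {
    list(
      pos = matrix(rnorm(n_per * d, mean = sep / 2), n_per, d),
      neg = matrix(rnorm(n_per * d, mean = -sep / 2), n_per, d)
    )
  })
}

# Small synthetic benchmark + matching low-dimensional config for fast
# end-to-end pipeline tests (full-size runs live in the acceptance tests).
small_benchmark <- function(n_families = 3, n_per = 30, seed = 7) {
  specs <- lapply(seq_len(n_families), function(i) {
    family_spec(nif_registry()[i], n = n_per, length_mean = 150,
                length_jitter = 10, n_motifs = 3, motif_length = 20)
  })
  generate_benchmark(specs, background_ratio = 2, seed = seed)
}

small_config <- function(...) {
  run_config(d_low = 96L, mlp_epochs = 200L, rbf_n_basis = 12L, ...)
}

# A hand-built bundle around the small benchmark, memoized per session.
.test_env <- new.env()
small_trained <- function() {
  if (is.null(.test_env$bundle)) {
    bench <- small_benchmark()
    cfg <- small_config()
    X <- vectorize_batch(bench$records, mask = cfg$mask, mode = cfg$hdv_mode,
                         d_low = cfg$d_low, projection_seed = cfg$projection_seed)
    .test_env$bundle <- train_all_classes(X, bench$truth,
                                          registry = nif_registry(),
                                          config = cfg)
    .test_env$bench <- bench
    .test_env$X <- X
  }
  list(bundle = .test_env$bundle, bench = .test_env$bench, X = .test_env$X)
}

# A 1-feature MLP that is strictly increasing in its input with
# score >= 0.5 exactly when the feature is >= 0; lets tests construct
# exact confusion outcomes from plain numbers.
monotone_model <- function() {
  structure(
    list(
      layer_sizes = c(1L, 1L, 1L, 1L),
      weights = list(matrix(1), matrix(1), matrix(10)),
      biases = list(0, 0, 0),
      seed = 0L, architecture = "mlp", loss_trace = NULL
    ),
    class = "mlp_model"
  )
}

# Candidate with a fixed report, for exercising the selection rule.
fake_acceptance_candidate <- function(arch, f1, acc) {
  list(
    model = structure(list(architecture = arch, seed = 1L),
                      class = paste0(arch, "_model")),
    report = structure(
      list(architecture = arch, seed = 1L, threshold = 0.5,
           tp = 1L, fp = 0L, tn = 1L, fn = 0L,
           accuracy = acc, sensitivity = 1, precision = 1, f1 = f1,
           undefined = character(0)),
      class = "training_report"
    )
  )
}
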