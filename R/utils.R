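`%||%` <- function(a, b) if (is.null(a)) b else a

# Seeded evaluation with a pinned RNG kind, restoring the caller's RNG state.
# All reproducibility contracts in the package route through this helper so
# that "same seed" means the same thing in every function.
with_rng <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (abs(seed) >= 2^31) {
    stop("seed must be a 32-bit integer (|seed| < 2^31)")
  }
  withr::with_seed(
    as.integer(seed), code,
    .rng_kind = "Mersenne-Twister",
    .rng_normal_kind = "Inversion",
    .rng_sample_kind = "Rejection"
  )
}

# Deterministic per-class / per-stage seed derivation, kept well below 2^31.
derive_seed <- function(base, i) {
  s <- (as.numeric(base) %% 1000003) * 2039 + as.numeric(i)
  as.integer(s %% 2147483647)
}

# Jaccard similarity of two character sets (assumed unique elements).
jaccard_similarity <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0L) return(1)
  length(intersect(a, b)) / u
}

# Write/read numeric matrices as plain text with full double precision
# (17 significant digits round-trip doubles exactly).
write_num_matrix <- function(x, path) {
  x <- as.matrix(x)
  lines <- apply(x, 1L, function(r) {
    paste(formatC(r, digits = 17, format = "g"), collapse = "\t")
  })
  writeLines(lines, path)
  invisible(path)
}

read_num_matrix <- function(path) {
  lines <- readLines(path)
  rows <- lapply(strsplit(lines, "\t", fixed = TRUE), as.numeric)
  matrix(unlist(rows), nrow = length(rows), byrow = TRUE)
}

# Binary confusion counts -> the standard metric quadruple. Zero-denominator
# ratios are reported as 0 and named in the `undefined` flag so F1 stays
# defined (documented degenerate-case rule).
metrics_from_counts <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  total <- tp + fp + tn + fn
  undefined <- character(0)
  ratio <- function(num, den, what) {
    if (den == 0) {
      undefined <<- c(undefined, what)
      0
    } else {
      num / den
    }
  }
  accuracy <- ratio(tp + tn, total, "accuracy")
  sensitivity <- ratio(tp, tp + fn, "sensitivity")
  precision <- ratio(tp, tp + fp, "precision")
  f1 <- if (precision + sensitivity == 0) {
    undefined <- c(undefined, "f1")
    0
  } else {
    2 * precision * sensitivity / (precision + sensitivity)
  }
  list(
    tp = as.integer(tp), fp = as.integer(fp),
    tn = as.integer(tn), fn = as.integer(fn),
    accuracy = accuracy, sensitivity = sensitivity,
    precision = precision, f1 = f1,
    undefined = undefined
  )
}
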