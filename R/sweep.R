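#' Enumerate spaced words of a sequence
#'
#' Slides the mask along the sequence, one candidate window per start
#' position `p` in `[0, L - span]`, and reads the residues at the mask's
#' `1` positions. Windows containing any residue outside the 20-letter
#' canonical alphabet are skipped rather than guessed at; sequences shorter
#' than the mask span yield an empty result.
#'
#' @param sequence Amino-acid string (upper-cased internally).
#' @param mask A `spaced_word_mask` or mask pattern string.
#' @param alphabet An [amino_alphabet()].
#' @return Character vector of `weight`-letter words, ordered by window
#'   start position.
#' @examples
#' enumerate_spaced_words("ACDEF", "11011")  # "ACEF"
#' @export
enumerate_spaced_words <- function(sequence, mask,
                                   alphabet = amino_alphabet()) {
  mask <- as_mask(mask)
  codes <- encode_sequence(sequence, alphabet)
  M <- window_code_matrix(codes, mask)
  if (nrow(M) == 0L) return(character(0))
  apply(M, 1L, function(r) paste(alphabet$letters[r + 1L], collapse = ""))
}

# All valid windows as a matrix of 0-based letter codes (one row per
# window, columns follow take_positions). Invalid windows are dropped.
window_code_matrix <- function(codes, mask) {
  L <- length(codes)
  n <- L - mask$span + 1L
  k <- mask$weight
  if (n < 1L) return(matrix(integer(0), nrow = 0L, ncol = k))
  M <- matrix(0L, nrow = n, ncol = k)
  for (j in seq_len(k)) {
    M[, j] <- codes[seq_len(n) + mask$take_positions[j]]
  }
  M[rowSums(is.na(M)) == 0L, , drop = FALSE]
}

#' Canonical index of a spaced word
#'
#' Encodes a k-letter word as its base-20 positional code with the leftmost
#' letter most significant, a bijection between the `20^k` possible words
#' and the integers `[0, 20^k)`. This fixes which coordinate of the
#' high-dimensional word vector each spaced word occupies.
#'
#' @param word Character vector of words over the canonical alphabet (all
#'   the same length k).
#' @param alphabet An [amino_alphabet()].
#' @return Numeric vector of 0-based indices (numeric because `20^k` can
#'   exceed the 32-bit integer range for long words).
#' @examples
#' word_index("AAAC")  # 1
#' @export
word_index <- function(word, alphabet = amino_alphabet()) {
  stopifnot(is.character(word))
  if (length(word) == 0L) return(numeric(0))
  k <- unique(nchar(word))
  if (length(k) != 1L || k < 1L) stop("all words must have the same positive length")
  vapply(word, function(w) {
    codes <- encode_sequence(w, alphabet)
    if (anyNA(codes)) {
      stop("word contains letters outside the alphabet: ", w)
    }
    idx <- 0
    for (c0 in codes) idx <- idx * 20 + c0
    idx
  }, numeric(1), USE.NAMES = FALSE)
}

# Row indices from a window code matrix, vectorized (0-based).
codes_to_indices <- function(M) {
  if (nrow(M) == 0L) return(numeric(0))
  idx <- as.numeric(M[, 1L])
  if (ncol(M) > 1L) {
    for (j in 2:ncol(M)) idx <- idx * 20 + M[, j]
  }
  idx
}

#' Build the high-dimensional spaced-word vector of a sequence
#'
#' The pre-projection stage of the SWeeP encoding: a sparse vector over all
#' `20^k` possible spaced words. In `"occurrence"` mode (the default) each
#' observed word contributes a 1 regardless of multiplicity; in `"count"`
#' mode entries accumulate word multiplicities, so the entry total equals
#' the number of valid windows. A sequence with no valid window (shorter
#' than the mask span, or every window touched by a non-canonical residue)
#' yields the all-zero vector with a warning rather than an error, so
#' whole-proteome scans are never aborted by one degenerate record.
#'
#' @param sequence Amino-acid string.
#' @param mask A `spaced_word_mask` or pattern string.
#' @param alphabet An [amino_alphabet()].
#' @param mode `"occurrence"` (binary) or `"count"`.
#' @param sequence_id Optional id used in warnings.
#' @return An object of class `hdv`: list with `dim` (`20^k`), `index`
#'   (0-based sorted indices of nonzero entries), `value`, `mode`,
#'   `n_windows` (candidate windows) and `n_valid` (windows kept).
#' @examples
#' h <- build_hdv("AAAAA", "11011")
#' h$index  # 0
#' @export
build_hdv <- function(sequence, mask, alphabet = amino_alphabet(),
                      mode = c("occurrence", "count"), sequence_id = NULL) {
  mode <- match.arg(mode)
  mask <- as_mask(mask)
  codes <- encode_sequence(sequence, alphabet)
  n_windows <- max(0L, length(codes) - mask$span + 1L)
  idx0 <- codes_to_indices(window_code_matrix(codes, mask))
  if (length(idx0) == 0L) {
    warning("sequence ", if (!is.null(sequence_id)) sequence_id else "",
            " has no valid spaced-word window; emitting a zero vector",
            call. = FALSE)
    index <- numeric(0)
    value <- numeric(0)
  } else if (mode == "occurrence") {
    index <- sort(unique(idx0))
    value <- rep(1, length(index))
  } else {
    r <- rle(sort(idx0))
    index <- r$values
    value <- as.numeric(r$lengths)
  }
  structure(
    list(
      dim = 20^mask$weight,
      index = index,
      value = value,
      mode = mode,
      n_windows = n_windows,
      n_valid = length(idx0)
    ),
    class = "hdv"
  )
}

#' @export
print.hdv <- function(x, ...) {
  cat("Sparse spaced-word vector: dim ", format(x$dim, big.mark = ","),
      ", ", length(x$index), " nonzero (", x$mode, " mode), ",
      x$n_valid, "/", x$n_windows, " windows valid\n", sep = "")
  invisible(x)
}

# Dense numeric expansion, for small dims only (tests, oracles).
as_dense <- function(hdv) {
  stopifnot(inherits(hdv, "hdv"))
  v <- numeric(hdv$dim)
  v[hdv$index + 1] <- hdv$value
  v
}
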