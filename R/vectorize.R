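#' Vectorization fingerprint
#'
#' The tuple of parameters that fully determines a SWeeP encoding: mask
#' pattern, occurrence/count mode, both dimensions, projection seed and
#' generation method. Models are only valid against vectors produced under
#' the fingerprint they were trained with, so the fingerprint travels with
#' every vector matrix and model bundle and is compared (hard error on
#' mismatch) at prediction time.
#'
#' @param mask A `spaced_word_mask` or pattern string.
#' @param mode `"occurrence"` or `"count"`.
#' @param d_low Projected dimension.
#' @param projection_seed Seed of the projection matrix.
#' @param method Projection generation scheme label.
#' @return A list of class `sweep_fingerprint`.
#' @export
sweep_fingerprint <- function(mask = "11011", mode = "occurrence",
                              d_low = 1369L, projection_seed = 1369L,
                              method = "gaussian-orthonormal") {
  mask <- as_mask(mask)
  structure(
    list(
      mask = mask$pattern,
      mode = match.arg(mode, c("occurrence", "count")),
      d_hi = 20^mask$weight,
      d_low = as.integer(d_low),
      projection_seed = as.integer(projection_seed),
      method = method
    ),
    class = "sweep_fingerprint"
  )
}

fingerprints_match <- function(a, b) {
  identical(unclass(a), unclass(b))
}

#' @export
print.sweep_fingerprint <- function(x, ...) {
  cat("SWeeP fingerprint: mask ", x$mask, ", ", x$mode, " mode, ",
      format(x$d_hi, big.mark = ","), " -> ", x$d_low,
      " (projection seed ", x$projection_seed, ")\n", sep = "")
  invisible(x)
}

#' Vectorize a batch of protein records
#'
#' Converts FASTA records into an `n x d_low` matrix of SWeeP vectors, one
#' row per record in input order, all under a single projection. Degenerate
#' sequences (no valid spaced-word window) produce zero rows and a
#' consolidated warning naming the affected ids; an empty record set is an
#' error.
#'
#' @param records A data frame with columns `id` and `seq` (as returned by
#'   [read_fasta()]).
#' @param mask Mask pattern or `spaced_word_mask` (default `"11011"`).
#' @param mode `"occurrence"` (default) or `"count"`.
#' @param d_low Projected dimension (default 1369).
#' @param projection_seed Seed for [make_projection()] (default 1369).
#' @param projection Optional pre-built `sweep_projection`; must match the
#'   mask and `d_low`.
#' @param alphabet An [amino_alphabet()].
#' @param cache Passed to [make_projection()].
#' @return Numeric matrix with rownames set to record ids and attribute
#'   `fingerprint` (a [sweep_fingerprint()]).
#' @export
vectorize_batch <- function(records, mask = "11011",
                            mode = c("occurrence", "count"),
                            d_low = 1369L, projection_seed = 1369L,
                            projection = NULL, alphabet = amino_alphabet(),
                            cache = TRUE) {
  mode <- match.arg(mode)
  records <- validate_records(records)
  if (nrow(records) == 0L) stop("no records to vectorize (empty FASTA?)")
  mask <- as_mask(mask)
  d_hi <- 20^mask$weight
  if (is.null(projection)) {
    projection <- make_projection(d_hi, d_low, projection_seed, cache = cache)
  } else {
    stopifnot(inherits(projection, "sweep_projection"))
    if (attr(projection, "d_hi") != d_hi || attr(projection, "d_low") != d_low) {
      stop("supplied projection does not match mask weight / d_low")
    }
    projection_seed <- attr(projection, "seed")
  }

  X <- matrix(0, nrow = nrow(records), ncol = d_low)
  degenerate <- character(0)
  for (i in seq_len(nrow(records))) {
    h <- withCallingHandlers(
      build_hdv(records$seq[i], mask, alphabet, mode,
                sequence_id = records$id[i]),
      warning = function(w) {
        degenerate <<- c(degenerate, records$id[i])
        invokeRestart("muffleWarning")
      }
    )
    X[i, ] <- project_hdv(h, projection)
  }
  if (length(degenerate) > 0L) {
    warning(length(degenerate), " sequence(s) had no valid spaced-word ",
            "window and were encoded as zero vectors: ",
            paste(utils::head(degenerate, 5L), collapse = ", "),
            if (length(degenerate) > 5L) ", ..." else "",
            call. = FALSE)
  }
  rownames(X) <- records$id
  attr(X, "fingerprint") <- sweep_fingerprint(
    mask, mode, d_low, projection_seed, attr(projection, "method")
  )
  X
}

# Subset a vector matrix by rows while keeping the fingerprint attribute
# (plain `[` drops it).
subset_vectors <- function(X, rows) {
  fp <- attr(X, "fingerprint")
  Y <- X[rows, , drop = FALSE]
  attr(Y, "fingerprint") <- fp
  Y
}
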