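# In-session memoization of projection matrices (the default 160000 x 1369
# matrix costs ~1-2 min to build; every caller in one session shares it).
.proj_cache <- new.env(parent = emptyenv())

#' Generate the seeded orthonormal projection matrix
#'
#' The SWeeP projection maps the sparse `20^k`-dimensional spaced-word
#' vector to a short dense vector (1369 coordinates by default). The matrix
#' is a deterministic function of `(d_hi, d_low, seed)`: standard-normal
#' entries drawn from a pinned, seeded generator, followed by column
#' orthonormalization, so regeneration with the same parameters is
#' bitwise-identical. Orthonormalization iterates `W <- W R^-1` with
#' `R = chol(W'W)` until `max|W'W - I| < 1e-9` (at most three passes; one
#' suffices for random matrices with `d_hi >> d_low`).
#'
#' Vectors, trained models and predictions are only comparable when they
#' share one projection, so results are memoized in-session and optionally
#' persisted to a disk cache keyed by the parameters.
#'
#' @param d_hi Number of rows, `20^k` for mask weight k.
#' @param d_low Number of columns (projected dimension), default 1369.
#' @param seed Integer seed, default 1369.
#' @param cache Persist/reuse the matrix on disk (in-session memoization is
#'   always on).
#' @param cache_dir Cache directory; defaults to the user cache dir for the
#'   package. Cache failures fall back silently to regeneration.
#' @return A numeric `d_hi x d_low` matrix of class `sweep_projection` with
#'   attributes `d_hi`, `d_low`, `seed`, `method`.
#' @examples
#' W <- make_projection(400, 16, seed = 7, cache = FALSE)
#' max(abs(crossprod(W) - diag(16)))  # < 1e-8
#' @export
make_projection <- function(d_hi, d_low = 1369L, seed = 1369L,
                            cache = TRUE, cache_dir = NULL) {
  stopifnot(is.numeric(d_hi), length(d_hi) == 1L, d_hi >= 1,
            is.numeric(d_low), length(d_low) == 1L, d_low >= 1)
  d_hi <- round(d_hi)
  d_low <- as.integer(d_low)
  if (d_low > d_hi) {
    stop("d_low (", d_low, ") must not exceed d_hi (", d_hi, ")")
  }
  key <- sprintf("gaussortho_%.0f_%d_%d", d_hi, d_low, as.integer(seed))
  if (!is.null(.proj_cache[[key]])) return(.proj_cache[[key]])

  path <- NULL
  if (isTRUE(cache)) {
    dir <- cache_dir %||% tools::R_user_dir("niffindr", "cache")
    ok <- tryCatch({
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      TRUE
    }, error = function(e) FALSE)
    if (ok) path <- file.path(dir, paste0(key, ".rds"))
    if (!is.null(path) && file.exists(path)) {
      W <- tryCatch(readRDS(path), error = function(e) NULL)
      if (!is.null(W)) {
        .proj_cache[[key]] <- W
        return(W)
      }
    }
  }

  W <- with_rng(seed, matrix(stats::rnorm(d_hi * d_low), nrow = d_hi, ncol = d_low))
  for (pass in 1:3) {
    G <- crossprod(W)
    if (max(abs(G - diag(d_low))) < 1e-9) break
    R <- chol(G)
    W <- W %*% backsolve(R, diag(d_low))
  }
  attr(W, "d_hi") <- d_hi
  attr(W, "d_low") <- d_low
  attr(W, "seed") <- as.integer(seed)
  attr(W, "method") <- "gaussian-orthonormal"
  class(W) <- c("sweep_projection", class(W))

  if (!is.null(path)) {
    tryCatch({
      tmp <- paste0(path, ".tmp", Sys.getpid())
      saveRDS(W, tmp, compress = FALSE)
      file.rename(tmp, path)
    }, error = function(e) invisible(NULL))
  }
  .proj_cache[[key]] <- W
  W
}

#' @export
print.sweep_projection <- function(x, ...) {
  cat("SWeeP projection matrix: ", format(attr(x, "d_hi"), big.mark = ","),
      " x ", attr(x, "d_low"), " (seed ", attr(x, "seed"), ", ",
      attr(x, "method"), ")\n", sep = "")
  invisible(x)
}

#' Project a high-dimensional word vector
#'
#' Computes `t(h) %*% W` sparsely, touching only the rows of `W` that
#' correspond to nonzero entries of the word vector; the result equals the
#' dense matrix product to within 1e-10.
#'
#' @param hdv An [build_hdv()] result.
#' @param projection A [make_projection()] matrix with matching `d_hi`.
#' @return Numeric vector of length `d_low` (the SWeeP vector).
#' @export
project_hdv <- function(hdv, projection) {
  stopifnot(inherits(hdv, "hdv"), inherits(projection, "sweep_projection"))
  if (hdv$dim != attr(projection, "d_hi")) {
    stop("dimension mismatch: hdv dim ", format(hdv$dim, big.mark = ","),
         " vs projection rows ", format(attr(projection, "d_hi"), big.mark = ","))
  }
  d_low <- attr(projection, "d_low")
  if (length(hdv$index) == 0L) return(numeric(d_low))
  rows <- projection[hdv$index + 1, , drop = FALSE]
  colSums(rows * hdv$value)
}
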