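#' Parse a spaced-word mask
#'
#' A spaced-word mask is a binary pattern slid along a protein sequence:
#' positions marked `1` are read, positions marked `0` are skipped, so each
#' window of `span` residues yields a word of `weight` letters. The default
#' mask used throughout the package is `"11011"` (span 5, weight 4).
#'
#' @param pattern Character scalar over `{'1','0'}`, starting and ending
#'   with `'1'`.
#' @return An object of class `spaced_word_mask`: a list with `pattern`,
#'   `take_positions` (0-based offsets of the `1` positions), `span` (pattern
#'   length, often written m) and `weight` (number of `1`s, often written k).
#' @examples
#' m <- parse_mask("11011")
#' m$take_positions  # 0 1 3 4
#' @export
parse_mask <- function(pattern) {
  if (!is.character(pattern) || length(pattern) != 1L || is.na(pattern)) {
    stop("mask pattern must be a single character string")
  }
  if (!nzchar(pattern)) stop("mask pattern must be non-empty")
  chars <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  if (any(!chars %in% c("0", "1"))) {
    stop("mask pattern may only contain '0' and '1', got: ", pattern)
  }
  if (!any(chars == "1")) stop("mask pattern must contain at least one '1'")
  if (chars[1L] != "1" || chars[length(chars)] != "1") {
    stop("mask pattern must start and end with '1', got: ", pattern)
  }
  take <- which(chars == "1") - 1L
  structure(
    list(
      pattern = pattern,
      take_positions = take,
      span = length(chars),
      weight = length(take)
    ),
    class = "spaced_word_mask"
  )
}

as_mask <- function(mask) {
  if (inherits(mask, "spaced_word_mask")) mask else parse_mask(mask)
}

#' @export
print.spaced_word_mask <- function(x, ...) {
  cat("Spaced-word mask \"", x$pattern, "\": span ", x$span,
      ", weight ", x$weight, "\n", sep = "")
  invisible(x)
}
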