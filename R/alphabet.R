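#' Canonical amino-acid alphabet
#'
#' The 20 canonical amino-acid one-letter codes in alphabetical order
#' (`ACDEFGHIKLMNPQRSTVWY`), together with the letter-to-index map used to
#' encode spaced words. The ordering is fixed: spaced-word indices, and
#' therefore SWeeP vectors, are only comparable between runs that share it.
#' Residue codes outside this alphabet (B, J, O, U, X, Z, gaps, `*`) are not
#' encoded; windows containing them are skipped during vectorization.
#'
#' @return An object of class `amino_alphabet`: a list with `letters`
#'   (ordered character vector of length 20) and `index` (named integer
#'   vector mapping letter to 0-based index).
#' @examples
#' aa <- amino_alphabet()
#' aa$letters
#' aa$index[["C"]]
#' @export
amino_alphabet <- function() {
  letters20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "", fixed = TRUE)[[1L]]
  structure(
    list(
      letters = letters20,
      index = stats::setNames(seq_along(letters20) - 1L, letters20)
    ),
    class = "amino_alphabet"
  )
}

#' @export
print.amino_alphabet <- function(x, ...) {
  cat("Amino-acid alphabet (", length(x$letters), " letters): ",
      paste(x$letters, collapse = ""), "\n", sep = "")
  invisible(x)
}

# Encode a sequence as 0-based alphabet indices; NA marks non-canonical
# residues. Input is upper-cased here, the single case-handling point.
encode_sequence <- function(sequence, alphabet = amino_alphabet()) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  unname(alphabet$index[chars])
}
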