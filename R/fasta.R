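#' Read a protein FASTA file
#'
#' Lenient multi-record FASTA reader (wrapped lines, CRLF and trailing
#' blank lines are tolerated). The record id is the first
#' whitespace-delimited token of the header; the full header is kept as the
#' description. Duplicate ids are deduplicated with a numeric suffix
#' (`seq1`, `seq1_2`, ...) and a warning, so downstream tables stay keyed
#' by unique ids.
#'
#' @param path Path to a FASTA file.
#' @return A data frame with columns `id`, `desc`, `seq` (one row per
#'   record, input order preserved).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(
    Biostrings::readAAStringSet(path),
    error = function(e) {
      stop("failed to parse FASTA file ", path, ": ", conditionMessage(e),
           call. = FALSE)
    }
  )
  if (length(set) == 0L) stop("FASTA file contains no records: ", path)
  desc <- names(set)
  seqs <- unname(as.character(set))
  if (any(!nzchar(seqs))) {
    stop("FASTA file contains record(s) with empty residues: ",
         paste(utils::head(desc[!nzchar(seqs)], 3L), collapse = ", "))
  }
  id <- sub("\\s.*$", "", desc)
  if (any(!nzchar(id))) stop("FASTA file contains record(s) with empty ids")
  if (anyDuplicated(id)) {
    dup <- unique(id[duplicated(id)])
    warning("duplicate record id(s) deduplicated with a suffix: ",
            paste(utils::head(dup, 5L), collapse = ", "), call. = FALSE)
    counts <- new.env(parent = emptyenv())
    id <- vapply(id, function(x) {
      n <- (counts[[x]] %||% 0L) + 1L
      counts[[x]] <- n
      if (n == 1L) x else paste0(x, "_", n)
    }, character(1), USE.NAMES = FALSE)
  }
  data.frame(id = id, desc = desc, seq = seqs, stringsAsFactors = FALSE)
}

#' Write protein records to FASTA
#'
#' @param records Data frame with columns `id`, `seq` and optionally
#'   `desc` (used as the full header when present).
#' @param path Output path.
#' @param width Residues per line.
#' @return The path, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  records <- validate_records(records)
  x <- Biostrings::AAStringSet(records$seq)
  names(x) <- if ("desc" %in% names(records)) records$desc else records$id
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

validate_records <- function(records) {
  if (!is.data.frame(records) || !all(c("id", "seq") %in% names(records))) {
    stop("records must be a data frame with columns 'id' and 'seq'")
  }
  if (anyDuplicated(records$id)) {
    stop("record ids must be unique (read_fasta deduplicates them)")
  }
  records
}

#' Read a truth table
#'
#' Tab-delimited two-column table mapping sequence id to class label (or
#' `"non-Nif"`). A header line is optional and detected by its field names
#' (`id`/`sequence_id` and `label`/`class`).
#'
#' @param path Path to a TSV file.
#' @return Named character vector of labels keyed by sequence id.
#' @export
read_truth <- function(path) {
  if (!file.exists(path)) stop("truth table not found: ", path)
  tab <- utils::read.delim(path, header = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("truth table must have two tab-delimited columns")
  first <- tolower(trimws(unlist(tab[1L, 1:2])))
  if (first[1L] %in% c("id", "sequence_id", "seqid") &&
      first[2L] %in% c("label", "class", "nif_class")) {
    tab <- tab[-1L, , drop = FALSE]
  }
  if (nrow(tab) == 0L) stop("truth table has no data rows")
  truth <- stats::setNames(trimws(tab[[2L]]), trimws(tab[[1L]]))
  if (anyDuplicated(names(truth))) {
    stop("truth table has duplicate sequence ids")
  }
  truth
}

#' Write a truth table
#'
#' @param truth Named character vector (id -> label).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_truth <- function(truth, path) {
  stopifnot(is.character(truth), !is.null(names(truth)))
  utils::write.table(
    data.frame(id = names(truth), label = unname(truth)),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
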