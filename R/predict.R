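#' Score vectors against every trained class model
#'
#' Applies each class's selected classifier to every SWeeP vector,
#' producing the full `n_sequences x n_classes` score matrix. The vector
#' matrix's fingerprint must match the bundle's: mixing projections would
#' silently corrupt every score, so a mismatch is a hard error.
#'
#' @param vectors Matrix from [vectorize_batch()] (with fingerprint).
#' @param bundle A `model_bundle`.
#' @return Numeric matrix of scores in (0, 1); rownames are sequence ids,
#'   colnames the trained class labels in registry order.
#' @export
score_all <- function(vectors, bundle) {
  stopifnot(inherits(bundle, "model_bundle"))
  fp <- attr(vectors, "fingerprint")
  if (is.null(fp)) stop("vectors carry no fingerprint; use vectorize_batch()")
  if (!fingerprints_match(fp, bundle$fingerprint)) {
    stop("vectorization fingerprint does not match the bundle's; ",
         "vectors and models must share mask, mode, dimensions and ",
         "projection seed")
  }
  classes <- intersect(bundle$registry, names(bundle$models))
  S <- matrix(NA_real_, nrow = nrow(vectors), ncol = length(classes),
              dimnames = list(rownames(vectors), classes))
  for (cls in classes) {
    S[, cls] <- score_model(bundle$models[[cls]]$model, vectors)
  }
  S
}

#' Assign a class label per sequence from the score matrix
#'
#' A sequence is assigned the highest-scoring class provided that score
#' reaches the threshold; exact ties go to the earlier registry label
#' (column order). With no score at or above the threshold the sequence is
#' categorized `"non-Nif"` and its assigned score is `NA`. Raising the
#' threshold can only shrink the set of assigned sequences.
#'
#' @param score_matrix Matrix from [score_all()].
#' @param threshold Decision threshold (default 0.5).
#' @return A data frame of class `prediction_table`: `sequence_id`,
#'   `assigned_label`, `assigned_score`, then one score column per class.
#' @export
assign_labels <- function(score_matrix, threshold = 0.5) {
  S <- as.matrix(score_matrix)
  if (!all(is.finite(S))) stop("score matrix contains non-finite values")
  if (is.null(colnames(S))) stop("score matrix must have class colnames")
  best <- apply(S, 1L, which.max)   # first maximum = earlier registry label
  best_score <- S[cbind(seq_len(nrow(S)), best)]
  assigned <- best_score >= threshold
  out <- data.frame(
    sequence_id = rownames(S) %||% as.character(seq_len(nrow(S))),
    assigned_label = ifelse(assigned, colnames(S)[best], "non-Nif"),
    assigned_score = ifelse(assigned, best_score, NA_real_),
    stringsAsFactors = FALSE
  )
  out <- cbind(out, as.data.frame(S, stringsAsFactors = FALSE))
  rownames(out) <- NULL
  class(out) <- c("prediction_table", class(out))
  out
}

#' Write prediction outputs
#'
#' Emits the two standard outputs of a scan: a labeled FASTA holding only
#' the sequences assigned a Nif class, each original header suffixed with
#' `" [NifFinder=<label> score=<score, 4 decimals>]"`, and a TSV table
#' with one row for every input sequence (including non-Nif ones) listing
#' the assignment and all per-class scores. A YAML sidecar records the
#' threshold and fingerprint when supplied.
#'
#' @param records Input FASTA records (`id`, `desc`, `seq`).
#' @param predictions A `prediction_table` covering exactly these ids.
#' @param prefix Output path prefix; writes `<prefix>.nif.fasta`,
#'   `<prefix>.predictions.tsv` and `<prefix>.run.yaml`.
#' @param fingerprint Optional `sweep_fingerprint` for the sidecar.
#' @param threshold Optional threshold for the sidecar.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_outputs <- function(records, predictions, prefix,
                          fingerprint = NULL, threshold = NULL) {
  records <- validate_records(records)
  if (!setequal(records$id, predictions$sequence_id) ||
      nrow(records) != nrow(predictions)) {
    stop("predictions must cover exactly the input record ids")
  }
  predictions <- predictions[match(records$id, predictions$sequence_id), ,
                             drop = FALSE]
  fasta_path <- paste0(prefix, ".nif.fasta")
  table_path <- paste0(prefix, ".predictions.tsv")
  sidecar_path <- paste0(prefix, ".run.yaml")

  hit <- predictions$assigned_label != "non-Nif"
  out_records <- records[hit, , drop = FALSE]
  if (nrow(out_records) > 0L) {
    out_records$desc <- sprintf(
      "%s [NifFinder=%s score=%.4f]",
      if ("desc" %in% names(out_records)) out_records$desc else out_records$id,
      predictions$assigned_label[hit],
      predictions$assigned_score[hit]
    )
    write_fasta(out_records, fasta_path)
  } else {
    writeLines(character(0), fasta_path)
  }
  utils::write.table(predictions, table_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sidecar <- list(
    n_input = nrow(records),
    n_assigned = sum(hit)
  )
  if (!is.null(threshold)) sidecar$threshold <- threshold
  if (!is.null(fingerprint)) sidecar$fingerprint <- unclass(fingerprint)
  yaml::write_yaml(sidecar, sidecar_path, precision = 17L)
  invisible(c(fasta = fasta_path, table = table_path, sidecar = sidecar_path))
}

#' Predict Nif classes for a FASTA file or record set
#'
#' End-to-end scan: vectorize the input under the bundle's fingerprint,
#' score every sequence against every class model, assign labels by
#' thresholded argmax and optionally write the labeled FASTA and
#' prediction table.
#'
#' @param input Path to a protein FASTA file, or a records data frame.
#' @param bundle A `model_bundle` (from [train_all_classes()] or
#'   [load_bundle()]).
#' @param threshold Decision threshold (default: the bundle's).
#' @param output_prefix If non-NULL, outputs are written via
#'   [write_outputs()].
#' @return The `prediction_table`, invisibly when writing outputs.
#' @export
nif_predict <- function(input, bundle, threshold = NULL,
                        output_prefix = NULL) {
  stopifnot(inherits(bundle, "model_bundle"))
  threshold <- threshold %||% bundle$threshold %||% 0.5
  records <- if (is.character(input)) read_fasta(input) else validate_records(input)
  fp <- bundle$fingerprint
  X <- vectorize_batch(records, mask = fp$mask, mode = fp$mode,
                       d_low = fp$d_low, projection_seed = fp$projection_seed)
  S <- score_all(X, bundle)
  pred <- assign_labels(S, threshold)
  if (!is.null(output_prefix)) {
    write_outputs(records, pred, output_prefix,
                  fingerprint = fp, threshold = threshold)
    return(invisible(pred))
  }
  pred
}
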