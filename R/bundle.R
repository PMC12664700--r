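#' Save a model bundle to disk
#'
#' Writes a portable, text-only bundle: a `manifest.yaml` listing the
#' registry, vectorization fingerprint, per-class selection results and
#' skipped classes, plus one directory per trained class holding a
#' `metadata.yaml` and the weight arrays as full-precision TSV files.
#' Everything needed to reproduce or audit the bundle is human-readable;
#' no timestamps are written, so identical training runs produce
#' byte-identical bundles.
#'
#' @param bundle A `model_bundle` from [train_all_classes()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "model_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    format = "niffindr-bundle-1",
    registry = as.list(bundle$registry),
    fingerprint = unclass(bundle$fingerprint),
    threshold = bundle$threshold,
    classes = lapply(unname(bundle$models), function(m) {
      list(
        class_name = m$class_name,
        architecture = m$model$architecture,
        decision_threshold = m$decision_threshold,
        report = report_to_list(m$report)
      )
    }),
    skipped = if (nrow(bundle$skipped) > 0L) {
      lapply(seq_len(nrow(bundle$skipped)), function(i) {
        list(class = bundle$skipped$class[i], reason = bundle$skipped$reason[i])
      })
    } else {
      list()
    }
  )
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"),
                   precision = 17L)
  for (m in bundle$models) {
    cdir <- file.path(dir, m$class_name)
    dir.create(cdir, showWarnings = FALSE)
    save_class_model(m, cdir)
  }
  invisible(dir)
}

report_to_list <- function(r) {
  list(
    architecture = r$architecture, seed = r$seed, threshold = r$threshold,
    tp = r$tp, fp = r$fp, tn = r$tn, fn = r$fn,
    accuracy = r$accuracy, sensitivity = r$sensitivity,
    precision = r$precision, f1 = r$f1,
    undefined = as.list(r$undefined)
  )
}

list_to_report <- function(x) {
  structure(
    list(
      architecture = x$architecture, seed = as.integer(x$seed),
      threshold = x$threshold,
      tp = as.integer(x$tp), fp = as.integer(x$fp),
      tn = as.integer(x$tn), fn = as.integer(x$fn),
      accuracy = x$accuracy, sensitivity = x$sensitivity,
      precision = x$precision, f1 = x$f1,
      undefined = as.character(unlist(x$undefined))
    ),
    class = "training_report"
  )
}

save_class_model <- function(m, cdir) {
  model <- m$model
  if (model$architecture == "mlp") {
    meta <- list(
      architecture = "mlp",
      layer_sizes = as.list(model$layer_sizes),
      seed = model$seed
    )
    for (l in seq_along(model$weights)) {
      write_num_matrix(model$weights[[l]],
                       file.path(cdir, sprintf("W%d.tsv", l)))
      write_num_matrix(matrix(model$biases[[l]], nrow = 1L),
                       file.path(cdir, sprintf("b%d.tsv", l)))
    }
  } else {
    meta <- list(
      architecture = "rbf",
      n_basis = nrow(model$centers),
      n_basis_requested = model$n_basis_requested,
      seed = model$seed
    )
    write_num_matrix(model$centers, file.path(cdir, "centers.tsv"))
    write_num_matrix(matrix(model$widths, nrow = 1L),
                     file.path(cdir, "widths.tsv"))
    write_num_matrix(matrix(c(model$bias, model$output_weights), nrow = 1L),
                     file.path(cdir, "output.tsv"))
  }
  yaml::write_yaml(meta, file.path(cdir, "metadata.yaml"), precision = 17L)
}

#' Load a model bundle from disk
#'
#' Inverse of [save_bundle()]; weight arrays round-trip exactly (they are
#' written with 17 significant digits).
#'
#' @param dir Bundle directory.
#' @return A `model_bundle`.
#' @export
load_bundle <- function(dir) {
  mpath <- file.path(dir, "manifest.yaml")
  if (!file.exists(mpath)) stop("not a model bundle (no manifest.yaml): ", dir)
  manifest <- yaml::read_yaml(mpath)
  if (!identical(manifest$format, "niffindr-bundle-1")) {
    stop("unsupported bundle format: ", manifest$format %||% "<missing>")
  }
  fp <- structure(
    list(
      mask = manifest$fingerprint$mask,
      mode = manifest$fingerprint$mode,
      d_hi = as.numeric(manifest$fingerprint$d_hi),
      d_low = as.integer(manifest$fingerprint$d_low),
      projection_seed = as.integer(manifest$fingerprint$projection_seed),
      method = manifest$fingerprint$method
    ),
    class = "sweep_fingerprint"
  )
  models <- list()
  for (cl in manifest$classes) {
    cdir <- file.path(dir, cl$class_name)
    model <- load_class_model(cdir)
    models[[cl$class_name]] <- structure(
      list(
        class_name = cl$class_name,
        model = model,
        decision_threshold = cl$decision_threshold,
        report = list_to_report(cl$report),
        fingerprint = fp
      ),
      class = "trained_class_model"
    )
  }
  skipped <- if (length(manifest$skipped) > 0L) {
    data.frame(
      class = vapply(manifest$skipped, `[[`, character(1), "class"),
      reason = vapply(manifest$skipped, `[[`, character(1), "reason"),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(class = character(0), reason = character(0))
  }
  structure(
    list(
      registry = as.character(unlist(manifest$registry)),
      models = models,
      fingerprint = fp,
      threshold = manifest$threshold,
      config = NULL,
      skipped = skipped
    ),
    class = "model_bundle"
  )
}

load_class_model <- function(cdir) {
  meta <- yaml::read_yaml(file.path(cdir, "metadata.yaml"))
  if (meta$architecture == "mlp") {
    sizes <- as.integer(unlist(meta$layer_sizes))
    n_aff <- length(sizes) - 1L
    W <- lapply(seq_len(n_aff), function(l) {
      read_num_matrix(file.path(cdir, sprintf("W%d.tsv", l)))
    })
    b <- lapply(seq_len(n_aff), function(l) {
      as.numeric(read_num_matrix(file.path(cdir, sprintf("b%d.tsv", l))))
    })
    structure(
      list(layer_sizes = sizes, weights = W, biases = b,
           seed = as.integer(meta$seed), architecture = "mlp",
           loss_trace = NULL),
      class = "mlp_model"
    )
  } else if (meta$architecture == "rbf") {
    centers <- read_num_matrix(file.path(cdir, "centers.tsv"))
    widths <- as.numeric(read_num_matrix(file.path(cdir, "widths.tsv")))
    out <- as.numeric(read_num_matrix(file.path(cdir, "output.tsv")))
    structure(
      list(centers = centers, widths = widths,
           output_weights = out[-1L], bias = out[1L],
           n_basis_requested = as.integer(meta$n_basis_requested),
           seed = as.integer(meta$seed), architecture = "rbf"),
      class = "rbf_model"
    )
  } else {
    stop("unknown architecture in ", cdir, ": ", meta$architecture)
  }
}
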