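#' Greedy k-mer redundancy filter
#'
#' Reduces near-duplicate sequences before training by greedy incremental
#' clustering on k-mer sets: each record joins the best-matching existing
#' cluster whose founder it resembles at Jaccard similarity >= the
#' threshold, otherwise it founds a new cluster; one representative (the
#' longest member, ties to the earliest) is kept per cluster. This is a
#' deliberately simple, deterministic filter in the spirit of similarity
#' clustering at a 0.5 threshold — not a reimplementation of any specific
#' clustering tool — and is deterministic given the input order.
#'
#' @param records Data frame with columns `id`, `seq`.
#' @param similarity_threshold Jaccard threshold in `[0, 1]` (default 0.5).
#' @param word_size k-mer length (default 4).
#' @return The subset of `records` kept as representatives, one per
#'   cluster, in cluster-founding order.
#' @export
reduce_redundancy <- function(records, similarity_threshold = 0.5,
                              word_size = 4L) {
  records <- validate_records(records)
  if (nrow(records) == 0L) stop("no records to filter")
  word_size <- as.integer(word_size)
  kmer_set <- function(s) {
    s <- toupper(s)
    L <- nchar(s)
    if (L < word_size) return(s)
    unique(substring(s, seq_len(L - word_size + 1L),
                     seq_len(L - word_size + 1L) + word_size - 1L))
  }
  sets <- lapply(records$seq, kmer_set)
  founder_sets <- list()      # k-mer set of each cluster founder
  members <- list()           # row indices per cluster
  for (i in seq_len(nrow(records))) {
    if (length(founder_sets) > 0L) {
      sims <- vapply(founder_sets, jaccard_similarity, numeric(1), b = sets[[i]])
      best <- which.max(sims)
    } else {
      sims <- numeric(0)
    }
    if (length(sims) > 0L && sims[best] >= similarity_threshold) {
      members[[best]] <- c(members[[best]], i)
    } else {
      founder_sets[[length(founder_sets) + 1L]] <- sets[[i]]
      members[[length(members) + 1L]] <- i
    }
  }
  reps <- vapply(members, function(idx) {
    idx[which.max(nchar(records$seq[idx]))]
  }, integer(1))
  records[reps, , drop = FALSE]
}

#' Sample a negative training set
#'
#' Draws `round(ratio * n_pos)` negatives uniformly without replacement
#' from the pool — the default ratio 2 yields the standard 1:2
#' positive:negative balance. A pool smaller than the request is used in
#' full with a warning. Deterministic given the seed.
#'
#' @param neg_pool Numeric matrix of candidate negative vectors (rows).
#' @param n_pos Number of positives the set is balanced against.
#' @param ratio Negatives per positive (default 2).
#' @param seed Integer seed.
#' @return Row subset of `neg_pool`.
#' @export
assemble_negatives <- function(neg_pool, n_pos, ratio = 2, seed = 1L) {
  neg_pool <- as.matrix(neg_pool)
  if (nrow(neg_pool) == 0L) stop("negative pool is empty")
  stopifnot(is.numeric(n_pos), n_pos >= 1)
  n_take <- round(ratio * n_pos)
  if (n_take < 1L) n_take <- 1L
  if (nrow(neg_pool) < n_take) {
    warning("negative pool (", nrow(neg_pool), ") smaller than requested ",
            n_take, "; using the whole pool", call. = FALSE)
    return(neg_pool)
  }
  idx <- with_rng(seed, sort(sample.int(nrow(neg_pool), n_take)))
  neg_pool[idx, , drop = FALSE]
}

#' Stratified train/test split
#'
#' Splits positives and negatives independently at `train_fraction`
#' (floor on the training side, remainder to test, with at least one
#' vector in each partition), so the class balance is preserved on both
#' sides. Partitions are disjoint and exhaustive; deterministic given the
#' seed.
#'
#' @param pos,neg Numeric matrices (>= 2 rows each).
#' @param train_fraction Training share in (0, 1) (default 0.7).
#' @param seed Integer seed.
#' @return List with `train_pos`, `test_pos`, `train_neg`, `test_neg`.
#' @export
stratified_split <- function(pos, neg, train_fraction = 0.7, seed = 1L) {
  pos <- as.matrix(pos); neg <- as.matrix(neg)
  stopifnot(train_fraction > 0, train_fraction < 1)
  if (nrow(pos) < 2L || nrow(neg) < 2L) {
    stop("each class needs at least 2 vectors to split")
  }
  take <- function(n) {
    n_train <- max(1L, min(n - 1L, floor(train_fraction * n)))
    n_train
  }
  idx <- with_rng(seed, {
    list(pos = sample.int(nrow(pos)), neg = sample.int(nrow(neg)))
  })
  np <- take(nrow(pos)); nn <- take(nrow(neg))
  list(
    train_pos = pos[sort(idx$pos[seq_len(np)]), , drop = FALSE],
    test_pos = pos[sort(idx$pos[-seq_len(np)]), , drop = FALSE],
    train_neg = neg[sort(idx$neg[seq_len(nn)]), , drop = FALSE],
    test_neg = neg[sort(idx$neg[-seq_len(nn)]), , drop = FALSE]
  )
}

#' Train one selected classifier per Nif class
#'
#' The full training orchestration: vectorize all records under one
#' projection, then for every registry class with enough positives
#' assemble a negative set (drawn half from the non-Nif background pool
#' and half from other Nif classes, so classifiers learn both the
#' Nif/non-Nif and the inter-class boundaries), split 70/30 stratified,
#' train both the MLP and the RBF, evaluate on the held-out partition and
#' keep the better model by F1-then-accuracy. Classes with fewer than
#' `min_positives` labeled sequences are skipped with a logged reason.
#' Fully deterministic given the configuration seeds.
#'
#' @param records Data frame of FASTA records (`id`, `seq`), or a
#'   pre-vectorized matrix from [vectorize_batch()].
#' @param truth Named character vector mapping every record id to a
#'   registry label or `"non-Nif"`.
#' @param registry Ordered class labels (default [nif_registry()]).
#' @param config A [run_config()].
#' @param projection Optional pre-built projection passed through to
#'   [vectorize_batch()].
#' @return An object of class `model_bundle`: list with `registry`,
#'   `models` (named list of `trained_class_model`), `fingerprint`,
#'   `threshold`, `config` and `skipped` (data frame of class, reason).
#' @export
train_all_classes <- function(records, truth, registry = nif_registry(),
                              config = run_config(), projection = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(names(truth)) || anyDuplicated(names(truth))) {
    stop("truth must be a named vector with unique ids")
  }
  bad <- setdiff(unique(truth), c(registry, "non-Nif"))
  if (length(bad) > 0L) {
    stop("truth labels outside registry: ", paste(bad, collapse = ", "))
  }

  if (is.matrix(records)) {
    X <- records
    if (is.null(attr(X, "fingerprint"))) {
      stop("pre-vectorized input must carry a fingerprint attribute")
    }
  } else {
    X <- vectorize_batch(records, mask = config$mask, mode = config$hdv_mode,
                         d_low = config$d_low,
                         projection_seed = config$projection_seed,
                         projection = projection)
  }
  ids <- rownames(X)
  missing <- setdiff(ids, names(truth))
  if (length(missing) > 0L) {
    stop("truth is missing ", length(missing), " record id(s), e.g. ",
         paste(utils::head(missing, 3L), collapse = ", "))
  }
  labels <- unname(truth[ids])
  fp <- attr(X, "fingerprint")

  models <- list()
  skipped <- data.frame(class = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  for (ci in seq_along(registry)) {
    cls <- registry[ci]
    pos_rows <- which(labels == cls)
    if (length(pos_rows) == 0L) {
      skipped <- rbind(skipped, data.frame(class = cls, reason = "no labeled sequences"))
      next
    }
    if (length(pos_rows) < config$min_positives) {
      skipped <- rbind(skipped, data.frame(
        class = cls,
        reason = sprintf("only %d positives (< %d)", length(pos_rows),
                         config$min_positives)
      ))
      next
    }
    pos <- subset_vectors(X, pos_rows)
    bg_rows <- which(labels == "non-Nif")
    other_rows <- which(labels != cls & labels != "non-Nif")
    n_pos <- length(pos_rows)
    seed_c <- derive_seed(config$training_seed, ci)

    ratio_bg <- config$negative_ratio * config$background_fraction
    ratio_other <- config$negative_ratio - ratio_bg
    neg_parts <- list()
    short <- 0
    if (ratio_bg > 0 && length(bg_rows) > 0L) {
      want <- round(ratio_bg * n_pos)
      got <- min(want, length(bg_rows))
      short <- short + (want - got)
      if (got > 0L) {
        neg_parts$bg <- suppressWarnings(assemble_negatives(
          X[bg_rows, , drop = FALSE], n_pos, ratio = ratio_bg,
          seed = derive_seed(seed_c, 1L)
        ))
      }
    } else {
      short <- short + round(ratio_bg * n_pos)
    }
    if (ratio_other > 0 || short > 0) {
      want_other <- round(ratio_other * n_pos) + short
      if (length(other_rows) > 0L && want_other > 0) {
        neg_parts$other <- suppressWarnings(assemble_negatives(
          X[other_rows, , drop = FALSE], n_pos,
          ratio = want_other / n_pos, seed = derive_seed(seed_c, 2L)
        ))
      }
    }
    neg <- do.call(rbind, unname(neg_parts))
    if (is.null(neg) || nrow(neg) < 2L) {
      skipped <- rbind(skipped, data.frame(class = cls, reason = "no negative pool"))
      next
    }
    n_target <- round(config$negative_ratio * n_pos)
    if (nrow(neg) < n_target) {
      warning("class ", cls, ": only ", nrow(neg), " negatives available ",
              "(wanted ", n_target, ")", call. = FALSE)
    }

    split <- stratified_split(pos, neg, config$train_fraction,
                              seed = derive_seed(seed_c, 3L))
    # the class-level gate is on labeled sequences; after the 70/30 split
    # the trainers see proportionally fewer positives
    min_train_pos <- max(2L, as.integer(floor(config$min_positives *
                                                config$train_fraction)))
    mlp <- train_mlp(split$train_pos, split$train_neg,
                     epochs = config$mlp_epochs,
                     learning_rate = config$mlp_learning_rate,
                     seed = derive_seed(seed_c, 4L),
                     hidden = config$mlp_hidden,
                     weight_decay = config$mlp_weight_decay,
                     min_positives = min_train_pos)
    rbf <- train_rbf(split$train_pos, split$train_neg,
                     n_basis = config$rbf_n_basis,
                     seed = derive_seed(seed_c, 5L),
                     lambda = config$rbf_lambda,
                     min_positives = min_train_pos)
    cands <- list(
      list(model = mlp,
           report = evaluate_model(mlp, split$test_pos, split$test_neg,
                                   config$threshold)),
      list(model = rbf,
           report = evaluate_model(rbf, split$test_pos, split$test_neg,
                                   config$threshold))
    )
    best <- select_best(cands)
    models[[cls]] <- structure(
      list(
        class_name = cls,
        model = best$model,
        decision_threshold = config$threshold,
        report = best$report,
        fingerprint = fp
      ),
      class = "trained_class_model"
    )
  }
  if (length(models) == 0L) {
    stop("no class had enough labeled sequences to train")
  }
  structure(
    list(
      registry = registry,
      models = models,
      fingerprint = fp,
      threshold = config$threshold,
      config = unclass(config),
      skipped = skipped
    ),
    class = "model_bundle"
  )
}

#' @export
print.model_bundle <- function(x, ...) {
  cat("niffindr model bundle: ", length(x$models), " trained class(es) of ",
      length(x$registry), " registry labels\n", sep = "")
  for (m in x$models) {
    cat(sprintf("  %-8s %s  F1=%.4f acc=%.4f\n", m$class_name,
                toupper(m$model$architecture), m$report$f1,
                m$report$accuracy))
  }
  if (nrow(x$skipped) > 0L) {
    cat("  skipped:", paste(x$skipped$class, collapse = ", "), "\n")
  }
  invisible(x)
}
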