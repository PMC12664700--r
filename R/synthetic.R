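#' Specify a synthetic protein family
#'
#' A synthetic family emulates a motif-conserved protein class: all
#' members descend from one random ancestor carrying implanted consensus
#' motifs, and diverge by independent per-site substitutions applied at a
#' low rate inside the motifs (the conserved signal) and a higher rate
#' outside them. Substitutions replace a residue uniformly by one of the
#' other 19 canonical letters and never introduce non-canonical codes.
#'
#' When `motifs` is `NULL`, `n_motifs` consensus strings of
#' `motif_length` random residues are generated deterministically from the
#' seed and anchored at evenly spaced positions that fit the minimum
#' sequence length.
#'
#' @param name Class label.
#' @param n Number of member sequences (default 150).
#' @param length_mean,length_jitter Ancestor length is drawn uniformly
#'   from `length_mean +/- length_jitter` (defaults 300 +/- 30).
#' @param motifs Optional data frame with columns `consensus` and
#'   `anchor` (1-based start position).
#' @param n_motifs,motif_length Used to auto-generate motifs (defaults 3
#'   and 24).
#' @param motif_sub_rate Per-site substitution probability inside motifs
#'   (default 0.02); must not exceed `background_sub_rate`.
#' @param background_sub_rate Per-site substitution probability outside
#'   motifs (default 0.30).
#' @param seed Integer seed; `NA` to let [generate_benchmark()] derive one.
#' @return A list of class `family_spec`.
#' @export
family_spec <- function(name, n = 150L, length_mean = 300L,
                        length_jitter = 30L, motifs = NULL,
                        n_motifs = 3L, motif_length = 24L,
                        motif_sub_rate = 0.02, background_sub_rate = 0.30,
                        seed = NA_integer_) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            n >= 1, length_mean >= 1, length_jitter >= 0,
            length_jitter < length_mean)
  if (motif_sub_rate < 0 || motif_sub_rate > 1 ||
      background_sub_rate < 0 || background_sub_rate > 1) {
    stop("substitution rates must lie in [0, 1]")
  }
  if (motif_sub_rate > background_sub_rate) {
    stop("motif_sub_rate must not exceed background_sub_rate ",
         "(motifs are the conserved signal)")
  }
  min_len <- as.integer(length_mean - length_jitter)
  if (is.null(motifs)) {
    if (is.na(seed)) {
      motifs <- NULL  # deferred until a seed is known
    } else {
      motifs <- auto_motifs(as.integer(n_motifs), as.integer(motif_length),
                            min_len, seed)
    }
  } else {
    motifs <- as.data.frame(motifs, stringsAsFactors = FALSE)
    stopifnot(all(c("consensus", "anchor") %in% names(motifs)))
    motifs$anchor <- as.integer(motifs$anchor)
    if (any(motifs$anchor < 1L) ||
        any(motifs$anchor + nchar(motifs$consensus) - 1L > min_len)) {
      stop("motif(s) do not fit within the minimum sequence length")
    }
  }
  structure(
    list(
      name = name, n = as.integer(n),
      length_mean = as.integer(length_mean),
      length_jitter = as.integer(length_jitter),
      motifs = motifs,
      n_motifs = as.integer(n_motifs), motif_length = as.integer(motif_length),
      motif_sub_rate = motif_sub_rate,
      background_sub_rate = background_sub_rate,
      seed = as.integer(seed)
    ),
    class = "family_spec"
  )
}

# Deterministic motif consensi at evenly spaced anchors. Drawn on a
# derived seed so the ancestor (drawn on the spec seed itself) does not
# share the motif RNG stream.
auto_motifs <- function(n_motifs, motif_length, min_len, seed) {
  segment <- min_len %/% n_motifs
  if (segment < motif_length) {
    stop("motifs do not fit: ", n_motifs, " x ", motif_length,
         " residues in a minimum length of ", min_len)
  }
  aa <- amino_alphabet()$letters
  consensus <- with_rng(derive_seed(seed, 500009L), {
    vapply(seq_len(n_motifs), function(i) {
      paste(sample(aa, motif_length, replace = TRUE), collapse = "")
    }, character(1))
  })
  anchor <- (seq_len(n_motifs) - 1L) * segment +
    (segment - motif_length) %/% 2L + 1L
  data.frame(consensus = consensus, anchor = anchor,
             stringsAsFactors = FALSE)
}

#' Generate one synthetic protein family
#'
#' Realizes a [family_spec()]: draws the ancestor (uniform residues,
#' motif consensi implanted at their anchors), then emits `n` members by
#' independent per-site substitution at the spec rates. Byte-identical
#' regeneration is guaranteed for a fixed spec (including seed).
#'
#' @param spec A `family_spec` with a non-`NA` seed.
#' @return List with `records` (data frame `id`, `desc`, `seq`), `truth`
#'   (named label vector) and `spec` (with materialized motifs).
#' @export
generate_family <- function(spec) {
  stopifnot(inherits(spec, "family_spec"))
  if (is.na(spec$seed)) stop("family spec needs a seed to be realized")
  if (is.null(spec$motifs)) {
    spec$motifs <- auto_motifs(spec$n_motifs, spec$motif_length,
                               spec$length_mean - spec$length_jitter,
                               spec$seed)
  }
  aa <- amino_alphabet()$letters
  out <- with_rng(spec$seed, {
    L <- if (spec$length_jitter > 0L) {
      sample(seq.int(spec$length_mean - spec$length_jitter,
                     spec$length_mean + spec$length_jitter), 1L)
    } else {
      spec$length_mean
    }
    ancestor <- sample(aa, L, replace = TRUE)
    motif_site <- logical(L)
    for (j in seq_len(nrow(spec$motifs))) {
      cons <- strsplit(spec$motifs$consensus[j], "", fixed = TRUE)[[1L]]
      pos <- spec$motifs$anchor[j] + seq_along(cons) - 1L
      ancestor[pos] <- cons
      motif_site[pos] <- TRUE
    }
    rate <- ifelse(motif_site, spec$motif_sub_rate, spec$background_sub_rate)
    anc_code <- match(ancestor, aa) - 1L
    seqs <- vapply(seq_len(spec$n), function(i) {
      mut <- stats::runif(L) < rate
      codes <- anc_code
      n_mut <- sum(mut)
      if (n_mut > 0L) {
        # uniform over the other 19 letters: add a nonzero offset mod 20
        codes[mut] <- (codes[mut] + sample.int(19L, n_mut, replace = TRUE)) %% 20L
      }
      paste(aa[codes + 1L], collapse = "")
    }, character(1))
    list(ancestor = paste(ancestor, collapse = ""), seqs = seqs)
  })
  ids <- sprintf("%s_%03d", spec$name, seq_len(spec$n))
  records <- data.frame(
    id = ids,
    desc = paste0(ids, " synthetic ", spec$name, " family member"),
    seq = out$seqs,
    stringsAsFactors = FALSE
  )
  list(records = records,
       truth = stats::setNames(rep(spec$name, spec$n), ids),
       spec = spec)
}

#' Generate unrelated background sequences
#'
#' I.i.d. uniform sequences over the 20 canonical residues, emulating the
#' non-Nif pool. Deterministic given the seed.
#'
#' @param n Number of sequences.
#' @param length_mean,length_jitter Per-sequence length is uniform on
#'   `length_mean +/- length_jitter` (defaults 300 +/- 30).
#' @param seed Integer seed.
#' @return Data frame with `id`, `desc`, `seq`.
#' @export
generate_background <- function(n, length_mean = 300L, length_jitter = 30L,
                                seed = 1L) {
  stopifnot(n >= 1, length_jitter >= 0, length_jitter < length_mean)
  aa <- amino_alphabet()$letters
  lens_range <- seq.int(length_mean - length_jitter,
                        length_mean + length_jitter)
  seqs <- with_rng(seed, {
    vapply(seq_len(n), function(i) {
      L <- if (length_jitter > 0L) sample(lens_range, 1L) else as.integer(length_mean)
      paste(sample(aa, L, replace = TRUE), collapse = "")
    }, character(1))
  })
  ids <- sprintf("bg_%04d", seq_len(n))
  data.frame(
    id = ids,
    desc = paste0(ids, " synthetic background sequence"),
    seq = seqs,
    stringsAsFactors = FALSE
  )
}

#' Generate a labeled synthetic benchmark
#'
#' Unions the realized families with `round(background_ratio x total
#' positives)` background sequences labeled `"non-Nif"` — the default
#' ratio 2 mirrors the pipeline's 1:2 positive:negative balance — and
#' records a generation manifest from which [regenerate_benchmark()]
#' reproduces the records byte-identically.
#'
#' @param family_specs List of [family_spec()]s (>= 2, unique names).
#'   Specs without a seed get one derived from `seed`.
#' @param background_ratio Background sequences per positive (default 2).
#' @param seed Master seed.
#' @return An object of class `benchmark_set`: list with `records`,
#'   `truth` (named label vector) and `manifest`.
#' @export
generate_benchmark <- function(family_specs, background_ratio = 2,
                               seed = 1L) {
  stopifnot(is.list(family_specs), length(family_specs) >= 2L,
            background_ratio >= 0)
  if (!all(vapply(family_specs, inherits, logical(1), "family_spec"))) {
    stop("family_specs must be a list of family_spec objects")
  }
  nm <- vapply(family_specs, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("duplicate family names: ",
                              paste(unique(nm[duplicated(nm)]), collapse = ", "))
  for (i in seq_along(family_specs)) {
    if (is.na(family_specs[[i]]$seed)) {
      family_specs[[i]]$seed <- derive_seed(seed, i)
    }
  }
  manifest <- list(
    format = "niffindr-benchmark-1",
    seed = as.integer(seed),
    background_ratio = background_ratio,
    background_length_mean = 300L,
    background_length_jitter = 30L,
    background_seed = derive_seed(seed, 999983L),
    families = lapply(family_specs, function(s) {
      if (is.null(s$motifs)) {
        s$motifs <- auto_motifs(s$n_motifs, s$motif_length,
                                s$length_mean - s$length_jitter, s$seed)
      }
      list(
        name = s$name, n = s$n,
        length_mean = s$length_mean, length_jitter = s$length_jitter,
        motif_consensus = as.list(s$motifs$consensus),
        motif_anchor = as.list(s$motifs$anchor),
        motif_sub_rate = s$motif_sub_rate,
        background_sub_rate = s$background_sub_rate,
        seed = s$seed
      )
    })
  )
  realize_benchmark(manifest)
}

realize_benchmark <- function(manifest) {
  fams <- lapply(manifest$families, function(f) {
    generate_family(family_spec(
      name = f$name, n = f$n,
      length_mean = f$length_mean, length_jitter = f$length_jitter,
      motifs = data.frame(consensus = unlist(f$motif_consensus),
                          anchor = unlist(f$motif_anchor),
                          stringsAsFactors = FALSE),
      motif_sub_rate = f$motif_sub_rate,
      background_sub_rate = f$background_sub_rate,
      seed = f$seed
    ))
  })
  records <- do.call(rbind, lapply(fams, `[[`, "records"))
  truth <- do.call(c, lapply(fams, `[[`, "truth"))
  n_bg <- round(manifest$background_ratio * nrow(records))
  if (n_bg > 0L) {
    bg <- generate_background(n_bg, manifest$background_length_mean,
                              manifest$background_length_jitter,
                              seed = manifest$background_seed)
    records <- rbind(records, bg)
    truth <- c(truth, stats::setNames(rep("non-Nif", n_bg), bg$id))
  }
  rownames(records) <- NULL
  structure(
    list(records = records, truth = truth, manifest = manifest),
    class = "benchmark_set"
  )
}

#' Regenerate a benchmark from its manifest
#'
#' @param manifest A manifest list as stored in a `benchmark_set` or read
#'   back from `manifest.yaml`.
#' @return A `benchmark_set` byte-identical to the original.
#' @export
regenerate_benchmark <- function(manifest) {
  if (!identical(manifest$format, "niffindr-benchmark-1")) {
    stop("unsupported benchmark manifest format")
  }
  realize_benchmark(manifest)
}

#' Write a benchmark set to disk
#'
#' Emits `benchmark.fasta`, `truth.tsv` and `manifest.yaml` under `dir`.
#'
#' @param benchmark A `benchmark_set`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_benchmark <- function(benchmark, dir) {
  stopifnot(inherits(benchmark, "benchmark_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(benchmark$records, file.path(dir, "benchmark.fasta"))
  write_truth(benchmark$truth, file.path(dir, "truth.tsv"))
  yaml::write_yaml(benchmark$manifest, file.path(dir, "manifest.yaml"),
                   precision = 17L)
  invisible(dir)
}

#' @export
print.benchmark_set <- function(x, ...) {
  n_pos <- sum(x$truth != "non-Nif")
  cat("Synthetic benchmark: ", nrow(x$records), " records (",
      n_pos, " family members in ", length(x$manifest$families),
      " families + ", sum(x$truth == "non-Nif"), " background)\n", sep = "")
  invisible(x)
}
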