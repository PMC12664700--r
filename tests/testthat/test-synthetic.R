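test_that("zero substitution rates yield identical copies of the ancestor", {
  spec <- family_spec("NifH", n = 5, length_mean = 100, length_jitter = 0,
                      motif_sub_rate = 0, background_sub_rate = 0, seed = 3)
  fam <- generate_family(spec)
  expect_identical(length(unique(fam$records$seq)), 1L)
  expect_identical(nchar(fam$records$seq[1]), 100L)
  expect_identical(unname(fam$truth), rep("NifH", 5))
})

test_that("motif sites stay near-consensus at the configured rate", {
  spec <- family_spec("NifD", n = 100, length_mean = 300, length_jitter = 0,
                      motif_sub_rate = 0.02, background_sub_rate = 0.30,
                      seed = 5)
  fam <- generate_family(spec)
  motifs <- fam$spec$motifs
  site_identity <- function(seqs, consensus, anchor) {
    cons <- strsplit(consensus, "")[[1]]
    hits <- vapply(seqs, function(s) {
      obs <- strsplit(substr(s, anchor, anchor + length(cons) - 1), "")[[1]]
      mean(obs == cons)
    }, numeric(1))
    mean(hits)
  }
  idents <- mapply(site_identity, consensus = motifs$consensus,
                   anchor = motifs$anchor,
                   MoreArgs = list(seqs = fam$records$seq))
  # binomial expectation: identity ~ 1 - 0.02
  expect_true(all(abs(idents - 0.98) < 0.01))
  # background diverges much faster
  bg_ident <- mean(vapply(fam$records$seq, function(s) {
    a <- strsplit(s, "")[[1]]
    b <- strsplit(fam$records$seq[1], "")[[1]]
    mean(a == b)
  }, numeric(1)))
  expect_lt(bg_ident, 0.9)
})

test_that("family generation is deterministic and validates its spec", {
  spec <- family_spec("NifK", n = 10, seed = 9)
  f1 <- generate_family(spec)
  f2 <- generate_family(spec)
  expect_identical(f1$records, f2$records)
  expect_error(family_spec("x", motif_sub_rate = 0.5,
                           background_sub_rate = 0.1),
               "must not exceed")
  expect_error(family_spec("x", motifs = data.frame(consensus = strrep("A", 500),
                                                    anchor = 1)),
               "do not fit")
})

test_that("background sequences are uniform over the alphabet", {
  bg <- generate_background(300, length_mean = 300, length_jitter = 30,
                            seed = 11)
  lens <- nchar(bg$seq)
  expect_true(all(lens >= 270 & lens <= 330))
  freq <- table(strsplit(paste(bg$seq, collapse = ""), "")[[1]])
  expect_setequal(names(freq), AA20)
  expect_true(all(abs(freq / sum(freq) - 0.05) < 0.01))
  # seed sensitivity
  bg2 <- generate_background(300, seed = 12)
  expect_false(identical(bg$seq, bg2$seq))
})

test_that("benchmark assembles families, background and a complete truth table", {
  bench <- small_benchmark(n_families = 3, n_per = 20, seed = 7)
  n_pos <- 3L * 20L
  expect_identical(nrow(bench$records), n_pos + 2L * n_pos)
  expect_setequal(names(bench$truth), bench$records$id)
  expect_identical(sum(bench$truth == "non-Nif"), 2L * n_pos)
  expect_setequal(unique(unname(bench$truth)),
                  c(nif_registry()[1:3], "non-Nif"))
  expect_error(
    generate_benchmark(list(family_spec("A", seed = 1),
                            family_spec("A", seed = 2))),
    "duplicate family names"
  )
})

test_that("the manifest regenerates the benchmark byte-identically", {
  bench <- small_benchmark(n_families = 2, n_per = 8, seed = 13)
  again <- regenerate_benchmark(bench$manifest)
  expect_identical(bench$records, again$records)
  expect_identical(bench$truth, again$truth)
  # and survives a YAML round trip on disk
  dir <- withr::local_tempdir()
  write_benchmark(bench, dir)
  manifest <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  once_more <- regenerate_benchmark(manifest)
  expect_identical(bench$records, once_more$records)
  # written records parse back with the same residues
  back <- read_fasta(file.path(dir, "benchmark.fasta"))
  expect_identical(back$seq, bench$records$seq)
  expect_identical(read_truth(file.path(dir, "truth.tsv")), bench$truth)
})

test_that("harder generator settings reduce downstream separability signal", {
  # same composition, no conserved motifs: families become indistinguishable
  easy <- family_spec("NifH", n = 15, length_mean = 120, length_jitter = 0,
                      motif_sub_rate = 0.02, background_sub_rate = 0.30,
                      n_motifs = 2, motif_length = 16, seed = 21)
  hard <- family_spec("NifH", n = 15, length_mean = 120, length_jitter = 0,
                      motif_sub_rate = 0.5, background_sub_rate = 0.5,
                      n_motifs = 2, motif_length = 16, seed = 21)
  mean_pairwise_identity <- function(fam) {
    seqs <- strsplit(fam$records$seq, "")
    pairs <- utils::combn(length(seqs), 2)
    mean(apply(pairs, 2, function(p) mean(seqs[[p[1]]] == seqs[[p[2]]])))
  }
  expect_gt(mean_pairwise_identity(generate_family(easy)),
            mean_pairwise_identity(generate_family(hard)))
})
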