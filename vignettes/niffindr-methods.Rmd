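---
title: "Methods: spaced-word projections and per-class neural networks for Nif protein prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spaced-word projections and per-class neural networks for Nif protein prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Biological nitrogen fixation is carried out by the Mo-nitrogenase system,
encoded by up to 24 *nif* genes: the structural subunits NifH, NifD and
NifK plus a larger set of assembly, processing and regulatory proteins
(NifB, NifE, NifN, NifU, NifS, ...). Most computational predictors cover
only the core subunits; annotating the full complement across bacterial
and archaeal proteomes requires a classifier per class that works without
alignments, at proteome scale, and degrades gracefully on unrelated
sequences. `niffindr` implements such a pipeline: an alignment-free
fixed-length encoding of each protein, one binary neural network per Nif
class, and a thresholded argmax to assign at most one class per sequence,
with everything below threshold reported as `non-Nif`.

## The SWeeP encoding

A spaced-word mask is a binary pattern slid along the sequence; `1`
positions are read and `0` positions skipped. The default mask `"11011"`
(span $m = 5$, weight $k = 4$) turns each window into a 4-letter word, so
a sequence of length $L$ yields up to $L - m + 1$ words out of a
vocabulary of $20^k = 160{,}000$. The sequence is first represented as
the sparse occurrence vector $h \in \{0,1\}^{20^k}$ (one entry per
distinct observed word; a count mode that accumulates multiplicities is
available as an option). The fixed-length encoding is the projection

$$ v = h^\top W, \qquad W \in \mathbb{R}^{20^k \times 1369}, $$

where $W$ has standard-normal entries drawn from a pinned, seeded
generator and subsequently orthonormalized columns. Orthonormal columns
make the projection an approximate isometry on the sparse word vectors,
so cosine structure in word space survives into the 1369 coordinates (the
package's acceptance experiment measures Pearson $r \ge 0.95$ between
pairwise cosine similarities before and after projection on
family-structured vectors).

Numerical choices worth knowing:

* **Orthonormalization** is Cholesky-based: $W \leftarrow W R^{-1}$ with
  $R = \operatorname{chol}(W^\top W)$, iterated (at most three passes)
  until $\max |W^\top W - I| < 10^{-9}$. For a tall random matrix with
  $d_{hi} \gg d_{low}$ the Gram matrix is well conditioned and one pass
  lands near machine precision; this costs roughly half the flops of a
  dense QR and avoids two extra full-size copies of $W$.
* **Determinism**: the matrix is a pure function of
  `(d_hi, d_low, seed)` under a pinned RNG kind; regeneration is
  bitwise-identical. Because every model is only meaningful against the
  projection it was trained with, the tuple (mask, mode, dimensions,
  projection seed) travels with every vector matrix and bundle as a
  *fingerprint*, and a mismatch at prediction time is a hard error.
* **Non-canonical residues** (B, J, O, U, X, Z, `*`, gaps): any window
  that reads one is skipped. This avoids inventing substitution
  semantics; a sequence whose every window is skipped (or that is shorter
  than the mask span) becomes a zero vector with a warning rather than an
  error, so whole-proteome scans never abort on one degenerate record.
* **Case**: sequences are upper-cased before encoding.
* The default projection width 1369 is stored as a flat
  $160{,}000 \times 1369$ matrix; nothing in the pipeline depends on its
  factorization as $37 \times 37$.
* The default high-dimensional mode is binary occurrence; counts add
  length information but make long sequences dominate norms, which the
  classifiers would then have to undo.

## Per-class classifiers

Each Nif class gets an independent binary classifier (one-vs-rest), and
two architectures are trained per class:

* **MLP 5:3:1** — two tanh hidden layers of 5 and 3 units and a logistic
  output on the 1369-long input. Training minimizes binary cross-entropy
  by full-batch Adam (default 300 epochs, step 0.01), with per-feature
  standardization folded into the first affine layer afterwards, so the
  stored model is exactly the documented
  logistic–affine–tanh–affine–tanh–affine composition on raw vectors.
  A small L2 weight decay (default $10^{-3}$, biases exempt) keeps the
  network's response far from the training manifold close to its output
  bias; without it the far-field score of a tiny unregularized network is
  arbitrary, which shows up as spurious confident scores on unrelated
  sequences.
* **RBF, 51 basis functions** — Gaussian units
  $\phi_j(x) = \exp(-\lVert x - c_j\rVert^2 / 2\sigma_j^2)$ with centers
  from seeded k-means over the pooled training vectors, widths equal to
  the nearest-other-center distance (floored at $10^{-6}$), and a
  ridge-regularized logistic output layer on the activations. If fewer
  distinct training vectors than basis functions are available the basis
  count is reduced to fit, with a warning.

Hidden activations, the optimizer, epochs, learning rate, the k-means
center rule and the width heuristic are not dictated by the architecture
sizes themselves; the defaults above were fixed once for determinism and
standard practice, live in `run_config()`, and every stochastic step is
seed-derived, so a configuration plus seeds fully determines the bundle.

**Selection.** Both models are evaluated on the held-out partition and
the candidate with the higher F1 wins; equal F1 falls back to the higher
accuracy, and any remaining tie to a fixed architecture order (MLP before
RBF). The decision threshold on the logistic score is 0.5 throughout.
Ratios with zero denominators (empty prediction sets and the like) are
reported as 0 and flagged `undefined` rather than NaN, so selection and
reporting stay total.

## Dataset assembly

For each class with at least `min_positives = 10` labeled sequences:

* **Negatives** are sampled at the 1:2 positive:negative ratio, drawn
  half from the non-Nif background pool and half from *other* Nif
  classes. The inter-class half is what teaches a classifier the boundary
  between its class and the other Nif families — without it, every Nif
  protein looks positive to every Nif model. The proportion is
  configurable (`background_fraction`); shortfalls in one pool are backfilled
  from the other, and a pool smaller than the request is used whole with
  a warning.
* **Split**: positives and negatives are split 70/30 independently
  (stratified), floor on the training side, at least one vector per
  partition.
* A greedy redundancy filter (`reduce_redundancy()`) is available for
  curating training sets: incremental clustering on 4-mer Jaccard
  similarity at a 0.5 threshold, keeping the longest member per cluster.
  It is a deliberately simple, deterministic filter, not a
  reimplementation of any published clustering tool, and is not applied
  implicitly anywhere.

Classes with too few sequences are skipped and listed in the bundle
manifest with a reason. Bifunctional fusion proteins (NifEN, NifNB) are
ordinary optional registry entries: a fusion protein competes as its own
class instead of double-labeling.

## Prediction and outputs

Query sequences are vectorized under the bundle's fingerprint, scored by
every class model, and assigned by thresholded argmax: no score at or
above 0.5 means `non-Nif`; exact ties go to the earlier registry label.
Raising the threshold can only shrink the assigned set. Outputs are a
labeled FASTA containing only the assigned sequences (header suffixed
with `[NifFinder=<class> score=<4 decimals>]`), a TSV with one row per
input including all per-class scores, and a YAML sidecar with the
threshold and fingerprint. Bundles round-trip through a text-only on-disk
format (YAML metadata plus 17-significant-digit TSV weight arrays), which
reproduces scores exactly.

## The synthetic benchmark generator

Real Nif training corpora are genome-scale external resources; the
package instead ships a generator whose output exercises every pipeline
stage. A family is a random uniform ancestor with consensus motifs
implanted at fixed anchors; members diverge by independent per-site
substitutions at a low rate inside motifs (default 0.02) and a high rate
outside (default 0.30), substitutions drawing uniformly from the other 19
canonical letters. Background sequences are i.i.d. uniform. Family sizes,
lengths (default 300 ± 30), rates and seeds are recorded in a manifest
from which the records regenerate byte-identically. The default
conditions — 6 families of 150 sequences plus a 1:2 background — mirror
the sampling balance the classifiers are trained at; under them every
class model reaches held-out F1 of essentially 1.0, and the acceptance
experiments assert the $\ge 0.9$ recovery gate at exactly these
conditions.

What the generator does *not* emulate: indels and alignment shifts,
phylogenetic correlation between members, realistic residue composition,
homologous-but-distinct families sharing motifs, and fragmentary
proteins. Passing the synthetic recovery experiments therefore
demonstrates that the machinery (encoding, training, selection,
thresholding, I/O) is correct and that conserved motifs against a noisy
background are recoverable — it does not certify the accuracy figures one
should expect on real proteomes, where inter-family similarity is far
higher. The generator's difficulty is monotone: raising the motif
substitution rate toward the background rate removes the conserved
signal, and with identical rates on distinct ancestors the families
collapse into the background distribution.

The binary-uniform background also means background vectors are nearly
orthogonal to everything, so the hardest real-world failure mode
(homologs of accessory proteins just below the family boundary) is
underrepresented; the inter-class negative sampling is the main defense
the pipeline trains for that case.

## Problem sizes and reproducibility

The shipped experiments use 100 vectors for the projection-geometry
check, 1000 window-conservation cases, 200 sequences for the oracle
equivalence sweep, and the 6-family benchmark (2700 records) for
class recovery — sizes at which the full suite, including one build of
the default projection matrix (about a minute, after which it is
memoized and disk-cached), completes in a few minutes on one core.
`scripts/acceptance.R --seed N --out f.json` reruns the study end to end:
it regenerates the benchmark (with uneven family sizes, 150 down to 40,
reflecting the class imbalance the method is meant to tolerate and
keeping the class-count correlation well-defined), trains at the default
configuration, and reports validation and held-out metrics as JSON. Every
random step in the package — projection, sampling, splitting, weight
initialization, k-means — goes through one seeded-RNG helper with a
pinned generator kind, so identical inputs and seeds give bitwise
identical vectors, bundles and outputs.

## Known limitations

* The projection seed (default 1369) defines a *particular* SWeeP space;
  published weight sets from other implementations are not importable
  because their projection constructions are not public.
* The class-count correlation is a Pearson correlation of per-class
  totals; it is undefined on constant count vectors and is reported as
  `NA` with a warning in that case.
* Training at the stated fixed hyperparameters replaces any broader
  cross-validated search; with the architectures this small, the benefit
  of a grid would be marginal on separable data and unknowable without
  real corpora.
* `reduce_redundancy()` compares each record to cluster founders only,
  so chains of gradually diverging sequences can split into several
  clusters where a full-linkage method would merge them.
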