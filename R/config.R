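#' Default Nif class registry
#'
#' The ordered set of Nif protein classes the pipeline can train and
#' predict: the 20 canonical Mo-nitrogenase structural, assembly and
#' regulatory proteins plus NifP, NifO, NifI1I2 and NifXa (24 labels).
#' The bifunctional fusion proteins NifEN and NifNB can be appended as
#' ordinary additional classes; a fusion protein then competes as its own
#' class rather than double-labeling. Registry order is the documented
#' tie-break for equal prediction scores.
#'
#' @param include_bifunctional Append `NifEN` and `NifNB`.
#' @return Character vector of class labels.
#' @examples
#' length(nif_registry())  # 24
#' @export
nif_registry <- function(include_bifunctional = FALSE) {
  labels <- c(
    "NifH", "NifD", "NifK", "NifE", "NifN", "NifB", "NifQ", "NifU",
    "NifS", "NifV", "NifW", "NifZ", "NifM", "NifF", "NifL", "NifA",
    "NifX", "NifT", "NifY", "NifJ", "NifP", "NifO", "NifI1I2", "NifXa"
  )
  if (isTRUE(include_bifunctional)) labels <- c(labels, "NifEN", "NifNB")
  labels
}

#' Read a class registry file
#'
#' One label per line; blank lines and `#` comments are ignored.
#'
#' @param path Path to a text file.
#' @return Character vector of labels.
#' @export
read_registry <- function(path) {
  if (!file.exists(path)) stop("registry file not found: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("registry file contains no labels")
  if (anyDuplicated(lines)) stop("registry labels must be unique")
  if ("non-Nif" %in% lines) stop("'non-Nif' is reserved and cannot be a registry label")
  lines
}

#' Pipeline run configuration
#'
#' Collects every tunable parameter of the vectorize/train/predict pipeline
#' with validated defaults. Defaults follow the method's standard
#' configuration: mask `"11011"`, 1369-coordinate projection, 1:2
#' positive:negative sampling, stratified 70/30 split, decision threshold
#' 0.5, MLP hidden layers 5:3 and 51 RBF basis functions.
#'
#' @param ... Named overrides of the defaults listed below. Unknown names
#'   and out-of-range values are rejected.
#' @return A list of class `run_config` with elements:
#' \describe{
#'   \item{mask}{spaced-word mask pattern (default `"11011"`)}
#'   \item{hdv_mode}{`"occurrence"` or `"count"` (default occurrence)}
#'   \item{d_low}{projected dimension (default 1369)}
#'   \item{projection_seed}{seed of the shared projection (default 1369)}
#'   \item{training_seed}{base seed for sampling/init (default 101)}
#'   \item{negative_ratio}{negatives per positive (default 2)}
#'   \item{background_fraction}{share of negatives drawn from the non-Nif
#'     background pool, the rest from other Nif classes (default 0.5)}
#'   \item{train_fraction}{training share of the stratified split (default 0.7)}
#'   \item{threshold}{decision threshold on classifier scores (default 0.5)}
#'   \item{min_positives}{minimum positives to train a class (default 10)}
#'   \item{mlp_hidden}{MLP hidden layer sizes (default `c(5, 3)`)}
#'   \item{mlp_epochs}{full-batch training epochs (default 300)}
#'   \item{mlp_learning_rate}{Adam step size (default 0.01)}
#'   \item{mlp_weight_decay}{L2 penalty on MLP weights (default 1e-3)}
#'   \item{rbf_n_basis}{RBF basis functions (default 51)}
#'   \item{rbf_lambda}{ridge penalty of the RBF output layer (default 0.01)}
#'   \item{redundancy_threshold}{Jaccard threshold of the redundancy filter
#'     (default 0.5)}
#'   \item{redundancy_word_size}{k-mer size of the redundancy filter
#'     (default 4)}
#' }
#' @export
run_config <- function(...) {
  defaults <- list(
    mask = "11011",
    hdv_mode = "occurrence",
    d_low = 1369L,
    projection_seed = 1369L,
    training_seed = 101L,
    negative_ratio = 2,
    background_fraction = 0.5,
    train_fraction = 0.7,
    threshold = 0.5,
    min_positives = 10L,
    mlp_hidden = c(5L, 3L),
    mlp_epochs = 300L,
    mlp_learning_rate = 0.01,
    mlp_weight_decay = 1e-3,
    rbf_n_basis = 51L,
    rbf_lambda = 0.01,
    redundancy_threshold = 0.5,
    redundancy_word_size = 4L
  )
  overrides <- list(...)
  if (length(overrides) > 0L) {
    if (is.null(names(overrides)) || any(!nzchar(names(overrides)))) {
      stop("config overrides must be named")
    }
    unknown <- setdiff(names(overrides), names(defaults))
    if (length(unknown) > 0L) {
      stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    }
    defaults[names(overrides)] <- overrides
  }
  cfg <- defaults
  as_mask(cfg$mask)  # validates
  cfg$hdv_mode <- match.arg(cfg$hdv_mode, c("occurrence", "count"))
  check_range <- function(x, name, lo, hi, lo_open = FALSE, hi_open = FALSE) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
        (if (lo_open) x <= lo else x < lo) ||
        (if (hi_open) x >= hi else x > hi)) {
      stop("config value out of range for ", name)
    }
  }
  check_range(cfg$d_low, "d_low", 1, Inf)
  check_range(cfg$projection_seed, "projection_seed", -2^31 + 1, 2^31 - 1)
  check_range(cfg$training_seed, "training_seed", -2^31 + 1, 2^31 - 1)
  check_range(cfg$negative_ratio, "negative_ratio", 0, Inf, lo_open = TRUE)
  check_range(cfg$background_fraction, "background_fraction", 0, 1)
  check_range(cfg$train_fraction, "train_fraction", 0, 1,
              lo_open = TRUE, hi_open = TRUE)
  check_range(cfg$threshold, "threshold", 0, 1)
  check_range(cfg$min_positives, "min_positives", 1, Inf)
  check_range(cfg$mlp_epochs, "mlp_epochs", 1, Inf)
  check_range(cfg$mlp_learning_rate, "mlp_learning_rate", 0, Inf, lo_open = TRUE)
  check_range(cfg$mlp_weight_decay, "mlp_weight_decay", 0, Inf)
  check_range(cfg$rbf_n_basis, "rbf_n_basis", 1, Inf)
  check_range(cfg$rbf_lambda, "rbf_lambda", 0, Inf)
  check_range(cfg$redundancy_threshold, "redundancy_threshold", 0, 1)
  check_range(cfg$redundancy_word_size, "redundancy_word_size", 1, Inf)
  if (!is.numeric(cfg$mlp_hidden) || length(cfg$mlp_hidden) < 1L ||
      any(cfg$mlp_hidden < 1)) {
    stop("config value out of range for mlp_hidden")
  }
  cfg$d_low <- as.integer(cfg$d_low)
  cfg$min_positives <- as.integer(cfg$min_positives)
  cfg$mlp_hidden <- as.integer(cfg$mlp_hidden)
  cfg$mlp_epochs <- as.integer(cfg$mlp_epochs)
  cfg$rbf_n_basis <- as.integer(cfg$rbf_n_basis)
  cfg$redundancy_word_size <- as.integer(cfg$redundancy_word_size)
  structure(cfg, class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' Missing keys take their documented defaults; unknown keys are rejected.
#'
#' @param path Path to a YAML key/value file, or `NULL` for pure defaults.
#' @return A [run_config()].
#' @export
load_config <- function(path = NULL) {
  if (is.null(path)) return(run_config())
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) return(run_config())
  if (!is.list(vals)) stop("config file must be a YAML mapping")
  do.call(run_config, vals)
}

#' @export
print.run_config <- function(x, ...) {
  cat("niffindr run configuration:\n")
  for (k in names(x)) {
    cat("  ", format(k, width = 22), paste(x[[k]], collapse = " "), "\n", sep = "")
  }
  invisible(x)
}

config_fingerprint <- function(config) {
  sweep_fingerprint(config$mask, config$hdv_mode, config$d_low,
                    config$projection_seed)
}
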