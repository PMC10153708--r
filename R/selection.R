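#' Configuration for AUC-frequency stability selection
#'
#' Features are retained when their univariate discriminative AUC exceeds
#' `auc_threshold` (strictly) in at least `frequency_threshold` of the
#' `n_folds * n_rounds` resampled evaluations. The per-extractor frequency
#' defaults used in the analysis are 0.4 (AlexNet), 0.6 (ResNet152V2) and
#' 1.0 (InceptionV3); they are configuration, not code.
#'
#' @param auc_threshold AUC cutoff in (0.5, 1); exceedance is strict (`>`).
#' @param n_folds Folds per round (>= 2).
#' @param n_rounds Independent rounds (>= 1).
#' @param frequency_threshold Minimum exceedance fraction in (0, 1];
#'   comparison is inclusive (`>=`).
#' @param fold_seed Integer seed; round r uses `fold_seed + r - 1`.
#' @param auc_scope `"heldout"` (default) evaluates each feature's AUC on
#'   the removed fold itself — the reading under which graded exceedance
#'   frequencies arise and per-extractor frequency thresholds are
#'   meaningful; `"retained"` evaluates on the retained
#'   (n_folds-1)/n_folds portion, whose frequencies are nearly
#'   all-or-nothing because consecutive evaluations share 90% of rows.
#' @param symmetrize If `TRUE`, use `max(auc, 1 - auc)` so anti-predictive
#'   features also count; default `FALSE` (literal one-sided exceedance).
#' @return A `selection_config` list.
#' @export
selection_config <- function(auc_threshold = 0.7, n_folds = 10L,
                             n_rounds = 5L, frequency_threshold = 0.4,
                             fold_seed = 1L,
                             auc_scope = c("heldout", "retained"),
                             symmetrize = FALSE) {
  stopifnot(auc_threshold > 0.5, auc_threshold < 1,
            n_folds >= 2L, n_rounds >= 1L,
            frequency_threshold > 0, frequency_threshold <= 1)
  structure(list(auc_threshold = auc_threshold, n_folds = as.integer(n_folds),
                 n_rounds = as.integer(n_rounds),
                 frequency_threshold = frequency_threshold,
                 fold_seed = as.integer(fold_seed),
                 auc_scope = match.arg(auc_scope),
                 symmetrize = isTRUE(symmetrize)),
            class = "selection_config")
}

#' Indices of features with nonzero variance
#'
#' Exact test: a feature survives iff its values are not all identical on
#' the given rows.
#'
#' @param x Numeric matrix (patients x features).
#' @return Integer vector of surviving column indices (possibly empty).
#' @export
variance_filter <- function(x) {
  stopifnot(is.matrix(x), nrow(x) >= 1)
  keep <- apply(x, 2L, function(col) min(col) != max(col))
  unname(which(keep))
}

#' Univariate rank AUC
#'
#' The probability that a random positive case scores above a random
#' negative case, ties counted half — the Mann-Whitney statistic divided by
#' n1*n0.
#'
#' @param x Numeric feature/score vector.
#' @param y Binary 0/1 labels (1 = positive).
#' @return AUC in [0, 1].
#' @export
univariate_auc <- function(x, y) {
  y <- as.integer(y)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("univariate_auc requires both classes present")
  r <- rank(x)                       # midranks handle ties at 0.5 weight
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Columnwise rank AUC for a matrix; same statistic as univariate_auc.
colwise_auc <- function(x, y) {
  y <- as.integer(y)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  r <- apply(x, 2L, rank)
  (colSums(r[y == 1L, , drop = FALSE]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Stratified fold assignment: within each class, fold labels are dealt in
# random order so fold sizes differ by at most one per class.
make_stratified_folds <- function(y, n_folds, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  folds <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    folds[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  folds
}

#' AUC-exceedance frequency of each feature over repeated cross-validation
#'
#' For each of `n_rounds` independent stratified partitions of the training
#' rows into `n_folds` sets, each fold is removed in turn and every
#' feature's univariate AUC is computed on the remaining portion (or on the
#' removed fold, per `auc_scope`). The returned frequency is the fraction of
#' the `n_rounds * n_folds` evaluations in which the AUC strictly exceeded
#' `auc_threshold`. Evaluations whose evaluation rows are single-class are
#' skipped with a warning and the denominator reduced.
#'
#' @param x Numeric matrix of training rows x features.
#' @param y Binary 0/1 training labels.
#' @param config A [selection_config()].
#' @return Numeric vector of frequencies in [0, 1], one per column of `x`.
#' @export
stability_frequencies <- function(x, y, config) {
  stopifnot(is.matrix(x), nrow(x) == length(y))
  y <- as.integer(y)
  if (length(unique(y)) < 2L)
    stop("training labels must contain both classes")
  exceed <- numeric(ncol(x))
  n_eval <- 0L
  for (round in seq_len(config$n_rounds)) {
    folds <- make_stratified_folds(y, config$n_folds,
                                   config$fold_seed + round - 1L)
    for (k in seq_len(config$n_folds)) {
      rows <- if (config$auc_scope == "retained") folds != k else folds == k
      yk <- y[rows]
      if (length(unique(yk)) < 2L) {
        warning("skipping single-class evaluation (round ", round,
                ", fold ", k, ")")
        next
      }
      a <- colwise_auc(x[rows, , drop = FALSE], yk)
      if (config$symmetrize) a <- pmax(a, 1 - a)
      exceed <- exceed + (a > config$auc_threshold)
      n_eval <- n_eval + 1L
    }
  }
  if (n_eval == 0L) stop("no valid evaluations: every subsample single-class")
  stats::setNames(exceed / n_eval, colnames(x))
}

#' Select features by exceedance frequency
#'
#' @param frequencies Vector from [stability_frequencies()].
#' @param frequency_threshold Inclusive minimum frequency.
#' @return Integer indices (original column order) with
#'   `frequency >= frequency_threshold`.
#' @export
select_features <- function(frequencies, frequency_threshold) {
  which(frequencies >= frequency_threshold)
}

#' Run the full selection procedure on training rows
#'
#' Zero-variance filter, then AUC-exceedance frequencies on the surviving
#' features, then the frequency threshold.
#'
#' @inheritParams stability_frequencies
#' @return A `selection_result` list: `retained_after_variance` (indices
#'   into the original columns), `frequencies` (named, over retained
#'   features), `selected` (original column indices), `config`.
#' @export
run_selection <- function(x, y, config) {
  retained <- variance_filter(x)
  if (length(retained) == 0L)
    return(structure(list(retained_after_variance = integer(0),
                          frequencies = numeric(0), selected = integer(0),
                          config = config), class = "selection_result"))
  freq <- stability_frequencies(x[, retained, drop = FALSE], y, config)
  sel <- retained[select_features(freq, config$frequency_threshold)]
  structure(list(retained_after_variance = retained, frequencies = freq,
                 selected = sel, config = config),
            class = "selection_result")
}

#' Fit z-score normalization on training rows and apply it
#'
#' Per-feature `(x - mean) / sd` with mean and sample SD estimated on the
#' training rows only, applied to both matrices.
#'
#' @param train Numeric training matrix (columns must be non-constant).
#' @param other Optional matrix with the same columns (e.g. test rows).
#' @return List with `train`, `other` (or `NULL`), `mean`, `sd`.
#' @export
zscore_fit_apply <- function(train, other = NULL) {
  stopifnot(is.matrix(train))
  mu <- colMeans(train)
  sdv <- apply(train, 2L, stats::sd)
  if (any(sdv == 0))
    stop("zero-SD training column(s): ",
         paste(which(sdv == 0), collapse = ", "),
         " (variance filter should have removed them)")
  list(train = sweep(sweep(train, 2L, mu), 2L, sdv, "/"),
       other = if (!is.null(other))
         sweep(sweep(other, 2L, mu), 2L, sdv, "/"),
       mean = mu, sd = sdv)
}
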