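#' Stratified hold-out split
#'
#' Samples each class proportionally so that the test set has exactly
#' `floor(test_fraction * n)` patients, allocating per-class test counts by
#' largest remainder. With 144 patients (40 positive) at 20% this yields
#' the 116/28 train/test partition. Deterministic given `seed`.
#'
#' @param labels Binary 0/1 vector for the whole cohort.
#' @param test_fraction Fraction held out (default 0.2).
#' @param seed Integer seed.
#' @return A `split_spec` list: `train_idx`, `test_idx` (sorted indices),
#'   `test_fraction`, `seed`.
#' @export
stratified_holdout_split <- function(labels, test_fraction = 0.2, seed = 1L) {
  y <- as.integer(labels)
  n <- length(y)
  n_test <- floor(test_fraction * n)
  stopifnot(n_test >= 2, length(unique(y)) == 2L)
  classes <- sort(unique(y))
  exact <- vapply(classes, function(cl) sum(y == cl) * test_fraction,
                  numeric(1))
  base <- floor(exact)
  rem <- exact - base
  short <- n_test - sum(base)
  if (short > 0)  # largest remainder; ties broken toward the first class
    base[order(rem, decreasing = TRUE)[seq_len(short)]] <-
      base[order(rem, decreasing = TRUE)[seq_len(short)]] + 1
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  test_idx <- integer(0)
  for (k in seq_along(classes)) {
    idx <- which(y == classes[k])
    if (base[k] >= length(idx) || base[k] < 1)
      stop("class ", classes[k], " too small to appear on both sides")
    test_idx <- c(test_idx, sample(idx, base[k]))
  }
  test_idx <- sort(test_idx)
  structure(list(train_idx = setdiff(seq_len(n), test_idx),
                 test_idx = test_idx, test_fraction = test_fraction,
                 seed = as.integer(seed)),
            class = "split_spec")
}

#' Train a linear support vector machine
#'
#' Maximum-margin linear classifier (libsvm C-classification) returning a
#' model whose real-valued decision score is oriented so that larger means
#' more likely recurrence.
#'
#' @param x Numeric feature matrix (no missing values).
#' @param y Binary 0/1 labels, both classes present.
#' @param cost Regularization constant C (default 1).
#' @return A `linear_svm` wrapper; score new rows with [svm_scores()].
#' @export
train_linear_svm <- function(x, y, cost = 1) {
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("single-class input: cannot train SVM")
  fit <- e1071::svm(x = x, y = factor(y, levels = c(0L, 1L)),
                    kernel = "linear", cost = cost, scale = FALSE)
  structure(list(fit = fit), class = "linear_svm")
}

#' Decision scores of a fitted linear SVM
#'
#' @param model A `linear_svm`.
#' @param x Feature matrix.
#' @return Numeric vector; higher score = predicted recurrence.
#' @export
svm_scores <- function(model, x) {
  dv <- attr(stats::predict(model$fit, x, decision.values = TRUE),
             "decision.values")
  s <- as.numeric(dv[, 1])
  # libsvm orients the score toward the first label it saw; flip to "1 high"
  if (colnames(dv)[1] == "0/1") s <- -s
  s
}

#' Repeated stratified cross-validated decision scores
#'
#' For each round, the training rows are partitioned into stratified folds;
#' each patient is scored by the SVM trained on the other folds, giving one
#' complete out-of-fold score vector per round.
#'
#' @param x Training feature matrix.
#' @param y Binary training labels.
#' @param n_folds,n_rounds Cross-validation scheme (default 10 x 5).
#' @param seed Integer seed; round r uses `seed + r - 1`.
#' @param cost SVM regularization constant.
#' @param max_retries Fold re-draws allowed when a fold complement is
#'   single-class (only possible at tiny n).
#' @return Numeric matrix `length(y) x n_rounds` of out-of-fold scores.
#' @export
crossval_scores <- function(x, y, n_folds = 10L, n_rounds = 5L, seed = 1L,
                            cost = 1, max_retries = 10L) {
  y <- as.integer(y)
  out <- matrix(NA_real_, length(y), n_rounds)
  for (r in seq_len(n_rounds)) {
    rs <- seed + r - 1L
    for (try in 0:max_retries) {
      folds <- make_stratified_folds(y, n_folds, rs + 1000L * try)
      ok <- all(vapply(seq_len(n_folds), function(k)
        length(unique(y[folds != k])) == 2L, logical(1)))
      if (ok) break
      if (try == max_retries) stop("degenerate folds after ", max_retries,
                                   " re-draws")
    }
    for (k in seq_len(n_folds)) {
      tr <- folds != k
      model <- train_linear_svm(x[tr, , drop = FALSE], y[tr], cost)
      out[folds == k, r] <- svm_scores(model, x[folds == k, , drop = FALSE])
    }
  }
  out
}

#' Youden-index optimal threshold
#'
#' Maximizes J = sensitivity + specificity - 1 over the midpoints between
#' adjacent sorted unique scores (prediction rule: score > threshold is
#' positive); ties resolve to the lowest such threshold. With fewer than
#' two distinct scores the single score itself is the only candidate.
#'
#' @param scores Numeric decision scores.
#' @param labels Binary 0/1 labels.
#' @return Numeric threshold.
#' @export
youden_threshold <- function(scores, labels) {
  y <- as.integer(labels)
  stopifnot(length(unique(y)) == 2L)
  u <- sort(unique(scores))
  cand <- if (length(u) >= 2L) (u[-length(u)] + u[-1]) / 2 else u
  j <- vapply(cand, function(th) {
    pred <- scores > th
    sum(pred & y == 1L) / sum(y == 1L) + sum(!pred & y == 0L) / sum(y == 0L) - 1
  }, numeric(1))
  cand[which.max(j)]   # first maximum = lowest threshold on ties
}

#' Threshold-based classification metrics plus AUC
#'
#' AUC uses the rank (Mann-Whitney) formula shared with
#' [univariate_auc()]; accuracy, sensitivity and specificity count the
#' confusion table at the rule `score > threshold` = predicted recurrence.
#'
#' @param scores Numeric decision scores.
#' @param labels Binary 0/1 labels.
#' @param threshold Decision threshold (e.g. from [youden_threshold()]).
#' @return Named list `auc`, `acc`, `sens`, `spe`, `threshold`.
#' @export
compute_metrics <- function(scores, labels, threshold) {
  y <- as.integer(labels)
  pred <- scores > threshold
  tp <- sum(pred & y == 1L); fn <- sum(!pred & y == 1L)
  tn <- sum(!pred & y == 0L); fp <- sum(pred & y == 0L)
  list(auc = univariate_auc(scores, y),
       acc = (tp + tn) / length(y),
       sens = tp / (tp + fn),
       spe = tn / (tn + fp),
       threshold = threshold)
}

#' Model/evaluation configuration
#'
#' @param cost SVM regularization constant C.
#' @param n_folds,n_rounds Cross-validation scheme for the hold-out
#'   training metrics.
#' @param cv_seed Seed for the CV fold draws.
#' @param test_threshold `"test"` recomputes the Youden threshold on the
#'   hold-out test scores (default); `"train"` carries the threshold fitted
#'   on the pooled training CV scores.
#' @param impute_scope Passed to [prepare_clinical()].
#' @param impute_seed Seed for the imputation forests.
#' @return A `model_config` list.
#' @export
model_config <- function(cost = 1, n_folds = 10L, n_rounds = 5L,
                         cv_seed = 100L,
                         test_threshold = c("test", "train"),
                         impute_scope = c("train_only", "all"),
                         impute_seed = 7L) {
  structure(list(cost = cost, n_folds = as.integer(n_folds),
                 n_rounds = as.integer(n_rounds),
                 cv_seed = as.integer(cv_seed),
                 test_threshold = match.arg(test_threshold),
                 impute_scope = match.arg(impute_scope),
                 impute_seed = as.integer(impute_seed)),
            class = "model_config")
}

#' Evaluate one (dilation, extractor) configuration
#'
#' The full learning procedure on one feature table: stability selection on
#' the hold-out training rows only; z-score normalization of the selected
#' features (training statistics); clinical encoding and imputation
#' (training-fitted by default); feature fusion; repeated stratified
#' cross-validation on the hold-out training set, reporting the mean over
#' rounds of the metrics computed on pooled out-of-fold scores with a
#' per-round Youden threshold; and a final refit on the full hold-out
#' training set scored on the hold-out test set with its own Youden
#' threshold. No test-row information reaches selection, normalization,
#' imputation fitting or SVM fitting.
#'
#' @param table A [build_feature_table()] result for the whole cohort at
#'   one dilation.
#' @param clinical Clinical data.frame per [clinical_schema()], or `NULL`
#'   for a radiomics-only model.
#' @param split A [stratified_holdout_split()].
#' @param sel_cfg A [selection_config()].
#' @param mod_cfg A [model_config()].
#' @param clinical_prepared Optional precomputed [prepare_clinical()]
#'   output (lets callers share one imputation across dilations).
#' @return An `eval_report` list: `dilation_px`, `extractor`,
#'   `n_selected_features`, `selection`, `train_cv` and `test` metric
#'   lists, `clinical_only` flag.
#' @export
evaluate_configuration <- function(table, clinical, split, sel_cfg,
                                   mod_cfg = model_config(),
                                   clinical_prepared = NULL) {
  stopifnot(inherits(table, "feature_table"), inherits(split, "split_spec"))
  y <- table$labels
  tr <- split$train_idx; te <- split$test_idx
  sel <- run_selection(table$values[tr, , drop = FALSE], y[tr], sel_cfg)
  clinical_only <- length(sel$selected) == 0L
  rad <- NULL
  if (!clinical_only) {
    z <- zscore_fit_apply(table$values[tr, sel$selected, drop = FALSE],
                          table$values[te, sel$selected, drop = FALSE])
    rad <- list(train = z$train, test = z$other)
  }
  cli <- NULL
  if (!is.null(clinical) || !is.null(clinical_prepared)) {
    prep <- clinical_prepared %||%
      prepare_clinical(clinical, tr, te, seed = mod_cfg$impute_seed,
                       scope = mod_cfg$impute_scope)
    keep <- variance_filter(prep$train)
    zc <- zscore_fit_apply(prep$train[, keep, drop = FALSE],
                           prep$test[, keep, drop = FALSE])
    cli <- list(train = zc$train, test = zc$other)
  }
  if (is.null(rad) && is.null(cli))
    stop("no radiomic features selected and no clinical data supplied")
  x_tr <- cbind(rad$train, cli$train)
  x_te <- cbind(rad$test, cli$test)

  cv <- crossval_scores(x_tr, y[tr], mod_cfg$n_folds, mod_cfg$n_rounds,
                        seed = mod_cfg$cv_seed, cost = mod_cfg$cost)
  per_round <- lapply(seq_len(ncol(cv)), function(r) {
    th <- youden_threshold(cv[, r], y[tr])
    compute_metrics(cv[, r], y[tr], th)
  })
  train_cv <- lapply(stats::setNames(nm = c("auc", "acc", "sens", "spe",
                                            "threshold")),
                     function(m) mean(vapply(per_round, `[[`, numeric(1), m)))

  final <- train_linear_svm(x_tr, y[tr], mod_cfg$cost)
  s_te <- svm_scores(final, x_te)
  th_te <- if (mod_cfg$test_threshold == "train")
    youden_threshold(as.vector(cv), rep(y[tr], ncol(cv)))
  else youden_threshold(s_te, y[te])
  test <- compute_metrics(s_te, y[te], th_te)

  structure(list(dilation_px = table$dilation_px,
                 extractor = table$extractor,
                 n_selected_features = length(sel$selected),
                 selection = sel, train_cv = train_cv, test = test,
                 clinical_only = clinical_only,
                 config = list(selection = unclass(sel_cfg),
                               model = unclass(mod_cfg))),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  f <- function(m) sprintf("AUC %.2f Acc %.2f Sens %.2f Spe %.2f",
                           m$auc, m$acc, m$sens, m$spe)
  cat(sprintf("<eval_report> dilation %d, %s, %d selected features%s\n",
              x$dilation_px, x$extractor, x$n_selected_features,
              if (x$clinical_only) " (clinical-only)" else ""))
  cat("  hold-out training (CV): ", f(x$train_cv), "\n")
  cat("  hold-out test:          ", f(x$test), "\n")
  invisible(x)
}
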