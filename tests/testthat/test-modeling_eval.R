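test_that("the 80/20 stratified split reproduces the cohort arithmetic", {
  y <- rep(c(0, 1), c(104, 40))   # 144 patients, 40 recurrences
  sp <- stratified_holdout_split(y, 0.2, seed = 1)
  expect_length(sp$train_idx, 116)
  expect_length(sp$test_idx, 28)
  expect_equal(sum(y[sp$test_idx]), 8)   # proportional positives
  expect_length(intersect(sp$train_idx, sp$test_idx), 0)
  expect_setequal(c(sp$train_idx, sp$test_idx), seq_along(y))
  # determinism
  sp2 <- stratified_holdout_split(y, 0.2, seed = 1)
  expect_identical(sp, sp2)
  expect_false(identical(sp$test_idx,
                         stratified_holdout_split(y, 0.2, seed = 2)$test_idx))
})

test_that("small balanced cohorts split one of each class into the test set", {
  y <- rep(c(0, 1), each = 5)
  sp <- stratified_holdout_split(y, 0.2, seed = 3)
  expect_length(sp$test_idx, 2)
  expect_equal(sum(y[sp$test_idx]), 1)
  expect_error(stratified_holdout_split(rep(c(0, 1), c(19, 1)), 0.2, 4),
               "too small")
})

test_that("the linear SVM separates separable data with oriented scores", {
  set.seed(1)
  x <- cbind(c(rnorm(20, -2), rnorm(20, 2)), rnorm(40))
  y <- rep(c(0, 1), each = 20)
  for (ord in list(seq_len(40), c(21:40, 1:20))) {  # both label orders
    m <- train_linear_svm(x[ord, ], y[ord])
    s <- svm_scores(m, x[ord, ])
    expect_true(all(s[y[ord] == 1] > 0))
    expect_true(all(s[y[ord] == 0] < 0))
  }
  expect_error(train_linear_svm(x, rep(1, 40)), "single-class")
})

test_that("duplicated feature columns barely move the decision scores", {
  # duplicating a column rescales the linear kernel, which perturbs the
  # soft-margin solution slightly; the decision ordering must stay put
  set.seed(6)
  x <- matrix(rnorm(60), 30, 2)
  y <- as.integer(x[, 1] + 0.5 * x[, 2] + rnorm(30, 0, 0.5) > 0)
  m1 <- train_linear_svm(zscore_fit_apply(x)$train, y)
  xdup <- cbind(x, x)
  m2 <- train_linear_svm(zscore_fit_apply(xdup)$train, y)
  s1 <- svm_scores(m1, zscore_fit_apply(x)$train)
  s2 <- svm_scores(m2, zscore_fit_apply(xdup)$train)
  expect_gt(cor(s1, s2, method = "spearman"), 0.99)
  expect_equal(univariate_auc(s1, y), univariate_auc(s2, y),
               tolerance = 0.02)
})

test_that("label-permuted data cross-validates near chance", {
  set.seed(21)
  x <- matrix(rnorm(60 * 5), 60, 5)
  y <- sample(rep(c(0, 1), each = 30))
  cv <- crossval_scores(x, y, n_folds = 5, n_rounds = 2, seed = 21)
  auc <- univariate_auc(as.vector(cv), rep(y, ncol(cv)))
  expect_gt(auc, 0.3)
  expect_lt(auc, 0.7)
})

test_that("cross-validation scores every patient once per round", {
  set.seed(2)
  x <- matrix(rnorm(40 * 3), 40, 3)
  y <- rep(c(0, 1), each = 20)
  x[, 1] <- x[, 1] + y
  cv <- crossval_scores(x, y, n_folds = 4, n_rounds = 3, seed = 5)
  expect_equal(dim(cv), c(40, 3))
  expect_false(anyNA(cv))
  expect_identical(cv, crossval_scores(x, y, 4, 3, seed = 5))
})

test_that("Youden threshold maximizes J over score midpoints", {
  th <- youden_threshold(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_equal(th, 0.5)
  # all-equal scores: the single candidate yields J = 0
  expect_equal(youden_threshold(rep(0.3, 6), c(0, 0, 0, 1, 1, 1)), 0.3)
})

test_that("Youden threshold equals an exhaustive scan over all candidates", {
  exhaustive <- function(s, y) {
    u <- sort(unique(s))
    cand <- if (length(u) >= 2) (u[-length(u)] + u[-1]) / 2 else u
    js <- sapply(cand, function(th) {
      sens <- sum(s > th & y == 1) / sum(y == 1)
      spe <- sum(s <= th & y == 0) / sum(y == 0)
      sens + spe - 1
    })
    cand[which.max(js)]
  }
  for (seed in 1:10) {
    set.seed(seed + 60)
    s <- round(rnorm(20), 2)   # rounding forces ties
    y <- sample(rep(c(0, 1), 10))
    expect_equal(youden_threshold(s, y), exhaustive(s, y))
  }
})

test_that("metrics recover the confusion-table ratios at a threshold", {
  perfect <- compute_metrics(c(1, 2, 3, 9, 10), c(0, 0, 0, 1, 1), 5)
  expect_equal(unlist(perfect[c("auc", "acc", "sens", "spe")]),
               c(auc = 1, acc = 1, sens = 1, spe = 1))
  inv <- compute_metrics(c(1, 1.5, 4, 5), c(1, 1, 0, 0), 3)
  expect_equal(inv$auc, 0.0)
  # TP=4 FN=1 TN=18 FP=5 -> sens 0.80, spe 18/23
  scores <- c(rep(1, 4), 0, rep(0, 18), rep(1, 5))
  labels <- c(rep(1, 5), rep(0, 23))
  m <- compute_metrics(scores, labels, 0.5)
  expect_equal(m$sens, 0.80)
  expect_equal(m$spe, 18 / 23, tolerance = 1e-12)
  expect_equal(m$acc, 22 / 28, tolerance = 1e-12)
})

test_that("metric AUC equals the pairwise oracle exhaustively at small n", {
  set.seed(77)
  for (rep in 1:30) {
    n <- sample(4:12, 1)
    y <- c(0, 1, sample(0:1, n - 2, TRUE))
    s <- sample(round(rnorm(n), 1), n)
    expect_equal(compute_metrics(s, y, median(s))$auc, pairwise_auc(s, y))
  }
})

test_that("evaluate_configuration fuses features and reports both sets", {
  co <- small_cohort(n = 40, seed = 12)
  spec <- extractor_spec("mock_bank")
  tab <- build_feature_table(lapply(co$scans, extract_roi, 10), spec,
                             co$labels)
  split <- stratified_holdout_split(co$labels, 0.2, 7)
  rep <- evaluate_configuration(
    tab, co$clinical, split,
    selection_config(n_folds = 4, n_rounds = 2, frequency_threshold = 0.5,
                     fold_seed = 3),
    model_config(n_folds = 4, n_rounds = 2))
  for (m in list(rep$train_cv, rep$test)) {
    expect_true(all(unlist(m[c("auc", "acc", "sens", "spe")]) >= 0))
    expect_true(all(unlist(m[c("auc", "acc", "sens", "spe")]) <= 1))
  }
  expect_equal(rep$dilation_px, 10L)
  expect_equal(rep$extractor, "mock_bank")
  expect_equal(rep$n_selected_features, length(rep$selection$selected))
})

test_that("a test-only perfect feature cannot reach training-side selection", {
  co <- small_cohort(n = 40, seed = 15)
  spec <- extractor_spec("mock_bank")
  tab <- build_feature_table(lapply(co$scans, extract_roi, 10), spec,
                             co$labels)
  split <- stratified_holdout_split(co$labels, 0.2, 7)
  cfg <- selection_config(n_folds = 4, n_rounds = 2,
                          frequency_threshold = 0.5, fold_seed = 3)
  mcfg <- model_config(n_folds = 4, n_rounds = 2)
  base <- evaluate_configuration(tab, co$clinical, split, cfg, mcfg)
  # plant a leak: on test rows only, feature 1 becomes the label itself
  poisoned <- tab
  poisoned$values[split$test_idx, 1] <-
    co$labels[split$test_idx] * 1e6
  leak <- evaluate_configuration(poisoned, co$clinical, split, cfg, mcfg)
  expect_identical(leak$selection$frequencies, base$selection$frequencies)
  expect_identical(leak$selection$selected, base$selection$selected)
  expect_identical(leak$train_cv, base$train_cv)
})
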