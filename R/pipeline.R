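#' Pipeline run configuration
#'
#' One document holding every analysis constant with the study's values as
#' defaults: crop dilations 0/10/20 (the sweep extends to 60), the AUC
#' cutoff 0.7 over 10 folds x 5 rounds, the per-extractor frequency
#' thresholds, the 80/20 stratified split, and the linear-SVM settings.
#'
#' @param dilations Integer vector of crop dilations in pixels.
#' @param extractors Named list: extractor name -> its frequency threshold.
#' @param extractor_seed Seed for the mock filter bank.
#' @param auc_threshold,n_folds,n_rounds,fold_seed Selection scheme; see
#'   [selection_config()].
#' @param test_fraction,split_seed Hold-out split; see
#'   [stratified_holdout_split()].
#' @param model A [model_config()].
#' @return A `run_config` list.
#' @export
run_config <- function(dilations = c(0L, 10L, 20L),
                       extractors = list(mock_bank = 0.8),
                       extractor_seed = 1234L,
                       auc_threshold = 0.7, n_folds = 10L, n_rounds = 5L,
                       fold_seed = 11L, test_fraction = 0.2,
                       split_seed = 42L, model = model_config()) {
  stopifnot(all(dilations >= 0), length(extractors) >= 1)
  structure(list(dilations = as.integer(dilations), extractors = extractors,
                 extractor_seed = as.integer(extractor_seed),
                 auc_threshold = auc_threshold, n_folds = as.integer(n_folds),
                 n_rounds = as.integer(n_rounds),
                 fold_seed = as.integer(fold_seed),
                 test_fraction = test_fraction,
                 split_seed = as.integer(split_seed), model = model),
            class = "run_config")
}

# Feature table for every cohort scan at one dilation.
cohort_feature_table <- function(cohort, dilation, spec) {
  crops <- lapply(cohort$scans, extract_roi, dilation_px = dilation)
  build_feature_table(crops, spec, cohort$labels)
}

#' Run the full pipeline over a dilation x extractor grid
#'
#' For every (dilation, extractor) pair: extract max-area-slice crops,
#' build the feature table, and run the full selection + fusion + SVM
#' evaluation against one shared stratified hold-out split and one shared
#' training-fitted clinical imputation. Returns the report in the layout
#' of the analysis result tables (one row per pair, hold-out training CV
#' and hold-out test metrics side by side) plus a manifest sufficient to
#' re-run bit-identically with the deterministic extractor.
#'
#' @param cohort A cohort list ([generate_cohort()] / [read_cohort()]).
#' @param config A [run_config()].
#' @param out_dir Optional directory; when given, writes `report.csv` and
#'   `manifest.json` there.
#' @param use_clinical Include the clinical covariates (default `TRUE`).
#' @return A list `report` (data.frame), `reports` (full `eval_report`
#'   objects), `split`, `manifest`.
#' @export
run_pipeline <- function(cohort, config = run_config(), out_dir = NULL,
                         use_clinical = TRUE) {
  split <- stratified_holdout_split(cohort$labels, config$test_fraction,
                                    config$split_seed)
  clin_prep <- NULL
  if (use_clinical)
    clin_prep <- prepare_clinical(cohort$clinical, split$train_idx,
                                  split$test_idx,
                                  seed = config$model$impute_seed,
                                  scope = config$model$impute_scope)
  reports <- list()
  for (ex_name in names(config$extractors)) {
    spec <- extractor_spec(ex_name, seed = config$extractor_seed)
    sel_cfg <- selection_config(
      auc_threshold = config$auc_threshold, n_folds = config$n_folds,
      n_rounds = config$n_rounds,
      frequency_threshold = config$extractors[[ex_name]],
      fold_seed = config$fold_seed)
    for (d in config$dilations) {
      tab <- cohort_feature_table(cohort, d, spec)
      rep <- evaluate_configuration(tab, if (use_clinical) cohort$clinical,
                                    split, sel_cfg, config$model,
                                    clinical_prepared = clin_prep)
      reports[[sprintf("%s_d%d", ex_name, d)]] <- rep
    }
  }
  report <- do.call(rbind, lapply(reports, report_row))
  rownames(report) <- NULL
  manifest <- list(
    n_patients = length(cohort$labels),
    n_recurrence = sum(cohort$labels),
    dilations = config$dilations, extractors = config$extractors,
    extractor_seed = config$extractor_seed,
    split = list(seed = config$split_seed,
                 test_fraction = config$test_fraction,
                 n_train = length(split$train_idx),
                 n_test = length(split$test_idx)),
    selection = list(auc_threshold = config$auc_threshold,
                     n_folds = config$n_folds, n_rounds = config$n_rounds,
                     fold_seed = config$fold_seed),
    model = unclass(config$model),
    package_version = as.character(utils::packageVersion("perirad")))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(report, file.path(out_dir, "report.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(report = report, reports = reports, split = split,
       manifest = manifest)
}

report_row <- function(r) {
  data.frame(dilation_px = r$dilation_px, extractor = r$extractor,
             n_selected_features = r$n_selected_features,
             train_auc = r$train_cv$auc, train_acc = r$train_cv$acc,
             train_sens = r$train_cv$sens, train_spe = r$train_cv$spe,
             test_auc = r$test$auc, test_acc = r$test$acc,
             test_sens = r$test$sens, test_spe = r$test$spe,
             clinical_only = r$clinical_only, stringsAsFactors = FALSE)
}

#' AUC versus crop dilation for one extractor
#'
#' Evaluates a fixed extractor over a list of dilations (default the
#' 0-to-60 sweep) and reports one row per dilation — the shape of the
#' dilation-sweep experiment, which peaks where the crop covers the
#' informative peritumoral annulus and degrades once the crop takes in
#' remote confounding structure.
#'
#' @param cohort A cohort list.
#' @param config A [run_config()]; its first extractor is used unless
#'   `extractor` is given.
#' @param dilations Dilations to sweep (default `seq(0, 60, 10)`).
#' @param extractor Extractor name.
#' @param use_clinical Include clinical covariates.
#' @return Data.frame with one row per dilation (train/test metrics).
#' @export
sweep_dilations <- function(cohort, config = run_config(),
                            dilations = seq(0L, 60L, 10L),
                            extractor = names(config$extractors)[1],
                            use_clinical = TRUE) {
  config$dilations <- as.integer(dilations)
  config$extractors <- config$extractors[extractor]
  run_pipeline(cohort, config, use_clinical = use_clinical)$report
}

#' Per-pooling-layer evaluation at a fixed dilation
#'
#' Compares pooling depths of one extractor at one crop dilation (the
#' layer-comparison experiment shape): early pooling grids preserve the
#' local texture detail that carries the peritumoral signal; deep coarse
#' grids average it away.
#'
#' @param cohort A cohort list.
#' @param config A [run_config()].
#' @param layer_tags Layer tags to compare (mock extractor:
#'   `"pool1"`, `"pool2"`, `"pool5"`).
#' @param dilation Fixed crop dilation (default 20).
#' @param extractor Extractor name supporting the tags.
#' @param use_clinical Include clinical covariates.
#' @return Data.frame with one row per layer tag.
#' @export
sweep_layers <- function(cohort, config = run_config(),
                         layer_tags = c("pool1", "pool2", "pool5"),
                         dilation = 20L,
                         extractor = names(config$extractors)[1],
                         use_clinical = TRUE) {
  split <- stratified_holdout_split(cohort$labels, config$test_fraction,
                                    config$split_seed)
  clin_prep <- if (use_clinical)
    prepare_clinical(cohort$clinical, split$train_idx, split$test_idx,
                     seed = config$model$impute_seed,
                     scope = config$model$impute_scope)
  sel_cfg <- selection_config(
    auc_threshold = config$auc_threshold, n_folds = config$n_folds,
    n_rounds = config$n_rounds,
    frequency_threshold = config$extractors[[extractor]],
    fold_seed = config$fold_seed)
  rows <- lapply(layer_tags, function(tag) {
    spec <- extractor_spec(extractor, layer_tag = tag,
                           seed = config$extractor_seed)
    tab <- cohort_feature_table(cohort, dilation, spec)
    rep <- evaluate_configuration(tab, if (use_clinical) cohort$clinical,
                                  split, sel_cfg, config$model,
                                  clinical_prepared = clin_prep)
    cbind(layer_tag = tag, report_row(rep), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
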