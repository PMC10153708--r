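#' Clinical data dictionary
#'
#' The clinical table mirrors the variables recorded at NSCLC diagnosis:
#' age (years), weight (lbs), gender, smoking pack-years, histology,
#' pathological T and N stage, histopathological grade, lymph-vascular
#' invasion and pleural invasion. Missing values (`NA`, empty string, or
#' `"not collected"` for lymph-vascular invasion) are allowed in weight,
#' pack-years and lymph-vascular invasion.
#'
#' @return A data.frame describing each column: name, type and allowed
#'   values.
#' @export
clinical_schema <- function() {
  data.frame(
    column = c("age_years", "weight_lbs", "gender", "pack_years",
               "histology", "pT", "pN", "grade",
               "lymph_vascular_invasion", "pleural_invasion"),
    type = c("continuous", "continuous", "binary", "continuous",
             "categorical", "ordinal", "ordinal", "ordinal",
             "binary", "binary"),
    values = c("positive real", "positive real (NA allowed)",
               "female|male", "nonnegative real (NA allowed)",
               "adenocarcinoma|squamous|NOS", "T1|T2|T3|T4", "N0|N1|N2",
               "G1|G2|G3", "absent|present|not collected|NA", "no|yes"),
    stringsAsFactors = FALSE)
}

clin_levels <- list(
  gender = c("female", "male"),
  histology = c("adenocarcinoma", "squamous", "NOS"),
  pT = c("T1", "T2", "T3", "T4"),
  pN = c("N0", "N1", "N2"),
  grade = c("G1", "G2", "G3"),
  lymph_vascular_invasion = c("absent", "present"),
  pleural_invasion = c("no", "yes"))

#' Encode a clinical table numerically
#'
#' Continuous variables pass through; binaries map to 0/1 (second level =
#' 1); ordinals take their rank (T1..T4 -> 1..4, N0..N2 -> 0..2,
#' G1..G3 -> 1..3); histology expands to a 3-column one-hot group. A
#' `"not collected"` lymph-vascular invasion entry is treated as missing.
#'
#' @param records Data.frame following [clinical_schema()].
#' @return An `encoded_clinical` list: `values` (numeric matrix, `NA` where
#'   missing), `missing_mask` (logical matrix), `column_kinds`,
#'   `onehot_group` (column name -> group id, `NA` for ungrouped columns).
#' @export
encode_clinical <- function(records) {
  need <- clinical_schema()$column
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("clinical table lacks column(s): ",
                         paste(miss, collapse = ", "))
  n <- nrow(records)
  norm_cat <- function(col, field) {
    v <- trimws(as.character(records[[field]]))
    v[v == "" | tolower(v) == "not collected"] <- NA
    bad <- !is.na(v) & !v %in% clin_levels[[field]]
    if (any(bad))
      stop("unknown category in '", field, "' at record(s) ",
           paste(which(bad), collapse = ", "), ": ",
           paste(unique(v[bad]), collapse = ", "))
    v
  }
  ord_rank <- function(field, ranks) {
    v <- norm_cat(NULL, field)
    ranks[match(v, clin_levels[[field]])]
  }
  gender <- norm_cat(NULL, "gender")
  hist <- norm_cat(NULL, "histology")
  lvi <- norm_cat(NULL, "lymph_vascular_invasion")
  pleu <- norm_cat(NULL, "pleural_invasion")
  values <- cbind(
    age_years = as.numeric(records$age_years),
    weight_lbs = as.numeric(records$weight_lbs),
    gender_male = as.numeric(gender == "male"),
    pack_years = as.numeric(records$pack_years),
    hist_adenocarcinoma = as.numeric(hist == "adenocarcinoma"),
    hist_squamous = as.numeric(hist == "squamous"),
    hist_NOS = as.numeric(hist == "NOS"),
    pT = ord_rank("pT", 1:4),
    pN = ord_rank("pN", 0:2),
    grade = ord_rank("grade", 1:3),
    lvi_present = as.numeric(lvi == "present"),
    pleural_yes = as.numeric(pleu == "yes"))
  rownames(values) <- rownames(records)
  kinds <- c(age_years = "continuous", weight_lbs = "continuous",
             gender_male = "binary", pack_years = "continuous",
             hist_adenocarcinoma = "onehot", hist_squamous = "onehot",
             hist_NOS = "onehot", pT = "ordinal", pN = "ordinal",
             grade = "ordinal", lvi_present = "binary",
             pleural_yes = "binary")
  groups <- stats::setNames(rep(NA_character_, ncol(values)),
                            colnames(values))
  groups[c("hist_adenocarcinoma", "hist_squamous", "hist_NOS")] <- "histology"
  structure(list(values = values, missing_mask = is.na(values),
                 column_kinds = kinds, onehot_group = groups),
            class = "encoded_clinical")
}

#' Construct an encoded clinical matrix directly
#'
#' Lower-level companion to [encode_clinical()] for callers that already
#' hold a numeric matrix (e.g. simulation studies of the imputer): wraps a
#' matrix with `NA`s as missing into the `encoded_clinical` container.
#'
#' @param values Numeric matrix; `NA` marks missing entries.
#' @param column_kinds Character vector per column: `"continuous"`,
#'   `"ordinal"`, `"binary"` or `"onehot"` (default all continuous).
#' @param onehot_group Character vector mapping one-hot columns to their
#'   group id, `NA` elsewhere (default none).
#' @return An `encoded_clinical` object.
#' @export
encoded_clinical <- function(values,
                             column_kinds = rep("continuous", ncol(values)),
                             onehot_group = rep(NA_character_,
                                                ncol(values))) {
  stopifnot(is.matrix(values), length(column_kinds) == ncol(values))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("v%02d", seq_len(ncol(values)))
  structure(list(values = values, missing_mask = is.na(values),
                 column_kinds = stats::setNames(column_kinds,
                                                colnames(values)),
                 onehot_group = stats::setNames(onehot_group,
                                                colnames(values))),
            class = "encoded_clinical")
}

# Typed working frame for the forests: one-hot groups collapse to a factor,
# binaries become factors, continuous/ordinal stay numeric.
encoded_to_frame <- function(enc) {
  vals <- enc$values
  kinds <- enc$column_kinds
  groups <- enc$onehot_group
  cols <- list(); miss <- list()
  for (g in unique(stats::na.omit(groups))) {
    members <- names(groups)[!is.na(groups) & groups == g]
    sub <- vals[, members, drop = FALSE]
    lev <- sub("^[a-z]+_", "", members)
    idx <- apply(sub, 1L, function(r) if (anyNA(r)) NA_integer_
                 else which.max(r))
    cols[[g]] <- factor(lev[idx], levels = lev)
    miss[[g]] <- is.na(idx)
  }
  for (cn in names(kinds)[is.na(groups)]) {
    v <- vals[, cn]
    cols[[cn]] <- if (kinds[[cn]] == "binary")
      factor(v, levels = c(0, 1)) else v
    miss[[cn]] <- is.na(v)
  }
  list(frame = as.data.frame(cols, stringsAsFactors = FALSE),
       missing = as.data.frame(miss))
}

# Expand the typed frame back to the encoded numeric layout.
frame_to_values <- function(frame, enc) {
  out <- enc$values
  groups <- enc$onehot_group
  for (g in unique(stats::na.omit(groups))) {
    members <- names(groups)[!is.na(groups) & groups == g]
    lev <- sub("^[a-z]+_", "", members)
    for (j in seq_along(members))
      out[, members[j]] <- as.numeric(frame[[g]] == lev[j])
  }
  for (cn in names(groups)[is.na(groups)]) {
    v <- frame[[cn]]
    out[, cn] <- if (is.factor(v)) as.numeric(as.character(v)) else v
  }
  out
}

init_fill <- function(frame, missing, stats_list = NULL) {
  st <- stats_list %||% lapply(frame, function(col) {
    if (is.factor(col)) {
      tab <- table(col)
      names(tab)[which.max(tab)]       # mode; ties -> first level
    } else mean(col, na.rm = TRUE)
  })
  for (cn in names(frame)) {
    idx <- which(missing[[cn]])
    if (!length(idx)) next
    frame[[cn]][idx] <- if (is.factor(frame[[cn]]))
      factor(st[[cn]], levels = levels(frame[[cn]])) else st[[cn]]
  }
  list(frame = frame, stats = st)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Iterative random-forest (MissForest-style) imputation
#'
#' Implements the Stekhoven-Buhlmann scheme on the encoded clinical matrix:
#' missing entries are initialized with the column mean (continuous /
#' ordinal) or mode (binary / one-hot group); columns are visited in order
#' of ascending missingness; for each incomplete column a random forest is
#' fitted on the rows observed for that column, using all other columns as
#' predictors, and its predictions replace the missing entries. Iteration
#' stops the first time the change criterion (normalized squared difference
#' for numeric columns, disagreement proportion for categorical) increases,
#' returning the previous iterate, or at `max_iter`. One-hot groups are
#' imputed as a single categorical variable and re-expanded, so imputed
#' rows stay valid one-hot rows.
#'
#' @param encoded An [encode_clinical()] result; every column must have at
#'   least one observed value.
#' @param rf_config List: `ntree` (default 100) and `mtry` (default
#'   `floor(sqrt(p))`).
#' @param seed Integer seed; output is deterministic in (input, seed).
#' @param max_iter Hard iteration cap (default 10).
#' @return A `missforest_fit` list: `values` (completed numeric matrix),
#'   `n_iter`, `log` (per-iteration criteria), plus the fitted forests and
#'   initialization statistics needed by [missforest_apply()].
#' @export
missforest_impute <- function(encoded, rf_config = list(), seed = 1L,
                              max_iter = 10L) {
  stopifnot(inherits(encoded, "encoded_clinical"))
  if (any(colSums(!encoded$missing_mask) == 0))
    stop("fully missing column(s): ",
         paste(colnames(encoded$values)[colSums(!encoded$missing_mask) == 0],
               collapse = ", "))
  ntree <- rf_config$ntree %||% 100L
  wf <- encoded_to_frame(encoded)
  frame <- wf$frame; missing <- wf$missing
  mtry <- rf_config$mtry %||% max(1L, floor(sqrt(ncol(frame) - 1L)))
  ini <- init_fill(frame, missing)
  cur <- ini$frame
  n_miss <- vapply(missing, sum, integer(1))
  visit <- names(sort(n_miss[n_miss > 0]))
  if (!length(visit))
    return(structure(list(values = frame_to_values(cur, encoded),
                          n_iter = 0L, log = NULL, models = list(),
                          visit = visit, init_stats = ini$stats,
                          encoded_template = encoded),
                     class = "missforest_fit"))

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)

  crit <- function(new, prev) {
    num <- 0; den <- 0; dis <- 0; ncat <- 0
    for (cn in visit) {
      idx <- which(missing[[cn]])
      if (is.factor(new[[cn]])) {
        dis <- dis + sum(new[[cn]][idx] != prev[[cn]][idx])
        ncat <- ncat + length(idx)
      } else {
        num <- num + sum((new[[cn]][idx] - prev[[cn]][idx])^2)
        den <- den + sum(new[[cn]][idx]^2)
      }
    }
    c(numeric_delta = if (den > 0) num / den else 0,
      categorical_delta = if (ncat > 0) dis / ncat else 0)
  }

  best <- cur; best_models <- NULL
  prev_crit <- c(numeric_delta = Inf, categorical_delta = Inf)
  log <- NULL
  iter <- 0L
  repeat {
    iter <- iter + 1L
    prev <- cur
    models <- list()
    for (cn in visit) {
      obs <- !missing[[cn]]
      # ordinals are imputed by regression on purpose; silence the
      # few-unique-values advisory randomForest emits for them
      fit <- withCallingHandlers(
        randomForest::randomForest(
          x = cur[obs, setdiff(names(cur), cn), drop = FALSE],
          y = cur[[cn]][obs], ntree = ntree, mtry = mtry),
        warning = function(w) {
          if (grepl("five or fewer unique values", conditionMessage(w)))
            invokeRestart("muffleWarning")
        })
      models[[cn]] <- fit
      pred <- stats::predict(fit,
        cur[missing[[cn]], setdiff(names(cur), cn), drop = FALSE])
      cur[[cn]][missing[[cn]]] <- pred
    }
    cc <- crit(cur, prev)
    log <- rbind(log, cc)
    worse <- (cc["numeric_delta"] > prev_crit["numeric_delta"]) ||
      (cc["categorical_delta"] > prev_crit["categorical_delta"])
    if (worse && iter > 1L) break      # keep previous iterate
    best <- cur; best_models <- models
    prev_crit <- cc
    if (iter >= max_iter) break
  }
  rownames(log) <- paste0("iter", seq_len(nrow(log)))
  structure(list(values = frame_to_values(best, encoded),
                 n_iter = iter, log = log, models = best_models,
                 visit = visit, init_stats = ini$stats,
                 encoded_template = encoded),
            class = "missforest_fit")
}

#' Apply a fitted imputation to new rows (predict-only)
#'
#' Missing entries in the new rows are initialized with the training
#' means/modes and then filled by one pass of the training-fitted forests in
#' the training visit order. No statistic or forest is refitted, so no
#' information flows from the new rows back into the imputation model.
#'
#' @param fit A `missforest_fit`.
#' @param encoded_new [encode_clinical()] output for the new rows.
#' @return Completed numeric matrix in the encoded layout.
#' @export
missforest_apply <- function(fit, encoded_new) {
  stopifnot(inherits(fit, "missforest_fit"),
            inherits(encoded_new, "encoded_clinical"))
  wf <- encoded_to_frame(encoded_new)
  cur <- init_fill(wf$frame, wf$missing, fit$init_stats)$frame
  for (cn in fit$visit) {
    idx <- which(wf$missing[[cn]])
    if (!length(idx) || is.null(fit$models[[cn]])) next
    cur[[cn]][idx] <- stats::predict(
      fit$models[[cn]], cur[idx, setdiff(names(cur), cn), drop = FALSE])
  }
  frame_to_values(cur, encoded_new)
}

#' Encode and impute clinical data for a train/test split
#'
#' With `scope = "train_only"` (default) the imputation model is fitted on
#' the training rows and applied to the test rows predict-only, so no test
#' information reaches the model. `scope = "all"` fits on the full table
#' before splitting (the literal pre-split reading).
#'
#' @param records Clinical data.frame per [clinical_schema()].
#' @param train_idx,test_idx Disjoint row indices.
#' @param seed Integer seed for the forests.
#' @param scope `"train_only"` or `"all"`.
#' @param rf_config Passed to [missforest_impute()].
#' @return List of completed numeric matrices `train` and `test`.
#' @export
prepare_clinical <- function(records, train_idx, test_idx, seed = 1L,
                             scope = c("train_only", "all"),
                             rf_config = list()) {
  scope <- match.arg(scope)
  if (scope == "all") {
    enc <- encode_clinical(records)
    fit <- missforest_impute(enc, rf_config, seed)
    list(train = fit$values[train_idx, , drop = FALSE],
         test = fit$values[test_idx, , drop = FALSE])
  } else {
    enc_tr <- encode_clinical(records[train_idx, , drop = FALSE])
    enc_te <- encode_clinical(records[test_idx, , drop = FALSE])
    fit <- missforest_impute(enc_tr, rf_config, seed)
    list(train = fit$values, test = missforest_apply(fit, enc_te))
  }
}
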