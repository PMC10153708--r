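#' Declared feature extractors
#'
#' The pipeline extracts texture features from an early pooling layer of a
#' convolutional network applied to each tumor crop. Three ImageNet
#' pretrained architectures are declared (AlexNet pool2, ResNet152V2 second
#' max-pool, InceptionV3 second max-pool) together with `mock_bank`, a
#' fully deterministic seeded convolution filter bank with average pooling
#' that exercises the identical pipeline without any deep-learning backend.
#'
#' Early pooling layers capture local detail — edges, dots, texture energy —
#' which is what distinguishes the peritumoral annulus from smooth tumor
#' core and clean lung background.
#'
#' `layer_tag` selects among pooling depths where the extractor supports
#' them; for `mock_bank` the tags pool1/pool2/pool5 map to pooling grids of
#' 16/8/4 cells per side over the same 16-filter bank (coarser grids emulate
#' deeper pooling).
#'
#' @param name One of `"alexnet_pool2"`, `"resnet152v2_maxpool"`,
#'   `"inceptionv3_maxpool"`, `"mock_bank"`.
#' @param layer_tag Optional pooling-layer tag overriding the extractor's
#'   default (`mock_bank` only: `"pool1"`, `"pool2"`, `"pool5"`).
#' @param seed Integer seed for the `mock_bank` filter weights.
#' @param normalization Intensity normalization before resizing:
#'   `"fixed_scale"` (default) divides by `intensity_max` and clips to
#'   [0, 1] — the fixed-window convention standard for calibrated CT
#'   intensities, which keeps a crop's features independent of its own
#'   extreme values; `"minmax"` rescales each crop by its own min-max
#'   range, for uncalibrated sources.
#' @param intensity_max Full-scale intensity for `"fixed_scale"`.
#' @return An `extractor_spec` list with fields `name`, `input_size_px`,
#'   `layer_tag`, `declared_output_dims`, `backend`, `seed`,
#'   `normalization`.
#' @export
extractor_spec <- function(name, layer_tag = NULL, seed = 1234L,
                           normalization = c("fixed_scale", "minmax"),
                           intensity_max = 255) {
  registry <- list(
    alexnet_pool2 = list(input_size_px = 227L, layer_tag = "pool2",
                         declared_output_dims = c(13L, 13L, 256L),
                         backend = "cnn"),
    resnet152v2_maxpool = list(input_size_px = 224L, layer_tag = "maxpool",
                               declared_output_dims = c(28L, 28L, 256L),
                               backend = "cnn"),
    inceptionv3_maxpool = list(input_size_px = 299L, layer_tag = "maxpool",
                               declared_output_dims = c(35L, 35L, 192L),
                               backend = "cnn"),
    mock_bank = list(input_size_px = 64L, layer_tag = "pool2",
                     declared_output_dims = c(8L, 8L, 16L),
                     backend = "mock"))
  if (!name %in% names(registry))
    stop("unknown extractor '", name, "'; registered: ",
         paste(names(registry), collapse = ", "))
  spec <- registry[[name]]
  if (!is.null(layer_tag)) {
    if (spec$backend != "mock")
      stop("layer_tag override is only supported for mock_bank")
    grid <- c(pool1 = 16L, pool2 = 8L, pool5 = 4L)[[layer_tag]]
    if (is.null(grid)) stop("unknown layer_tag '", layer_tag, "'")
    spec$layer_tag <- layer_tag
    spec$declared_output_dims <- c(grid, grid, 16L)
  }
  spec$name <- name
  spec$seed <- as.integer(seed)
  spec$channel_rule <- "replicate-grayscale-to-3"
  spec$normalization <- match.arg(normalization)
  spec$intensity_max <- intensity_max
  class(spec) <- "extractor_spec"
  spec
}

#' @export
print.extractor_spec <- function(x, ...) {
  cat(sprintf("<extractor_spec> %s (%s): input %dpx, output %s = %d features\n",
              x$name, x$layer_tag, x$input_size_px,
              paste(x$declared_output_dims, collapse = "x"),
              expected_feature_length(x)))
  invisible(x)
}

#' Flattened length implied by an extractor's declared output dimensions
#'
#' @param spec An [extractor_spec()].
#' @return Integer: the product of the declared (h, w, channels).
#' @export
expected_feature_length <- function(spec) {
  as.integer(prod(spec$declared_output_dims))
}

#' Preprocess a crop for feature extraction
#'
#' Linearly rescales the crop's intensities to [0, 1] — by the fixed
#' intensity window under the default `"fixed_scale"` normalization, or by
#' the crop's own min-max range under `"minmax"` (a constant crop then
#' maps to all zeros) — then resizes to the extractor's square input size
#' with bilinear interpolation (pixel-center sampling, edges clamped) and
#' replicates the grayscale channel to 3 channels.
#'
#' @param crop An `roi_crop`.
#' @param spec An [extractor_spec()].
#' @return Numeric array `input_size_px x input_size_px x 3` with values in
#'   [0, 1].
#' @export
preprocess_crop <- function(crop, spec) {
  px <- crop$pixels
  stopifnot(is.matrix(px), length(px) > 0)
  scaled <- if (identical(spec$normalization, "minmax")) {
    rng <- range(px)
    if (diff(rng) > 0) (px - rng[1]) / diff(rng) else px * 0
  } else pmin(pmax(px / spec$intensity_max, 0), 1)
  n <- spec$input_size_px
  resized <- if (all(dim(scaled) == c(n, n))) scaled else
    EBImage::imageData(EBImage::resize(EBImage::Image(scaled), w = n, h = n,
                                       filter = "bilinear"))
  # bilinear can overshoot float epsilon outside [0,1] at clamped edges
  resized <- pmin(pmax(resized, 0), 1)
  array(resized, dim = c(n, n, 3L))
}

# Deterministic zero-mean 5x5 filter bank; local RNG, global seed untouched.
mock_filter_bank <- function(seed, n_filters = 16L, ksize = 5L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  lapply(seq_len(n_filters), function(i) {
    f <- matrix(stats::rnorm(ksize * ksize), ksize, ksize)
    f <- f - mean(f)          # zero-mean: responds to texture, not brightness
    f / sqrt(sum(f^2))
  })
}

# 'same' 2D convolution by shifted accumulation (zero padding).
conv2_same <- function(img, kernel) {
  k <- dim(kernel)[1]; h <- (k - 1L) %/% 2L
  n <- nrow(img); m <- ncol(img)
  pad <- matrix(0, n + 2L * h, m + 2L * h)
  pad[(h + 1L):(h + n), (h + 1L):(h + m)] <- img
  out <- matrix(0, n, m)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    w <- kernel[i, j]
    if (w != 0)
      out <- out + w * pad[i:(i + n - 1L), j:(j + m - 1L)]
  }
  out
}

#' Extract a flattened pooling-layer feature vector
#'
#' For `mock_bank`, the grayscale input is convolved with a seeded bank of
#' 16 zero-mean filters, rectified (ReLU), and average-pooled on a fixed
#' `g x g` grid; the result is flattened row-fastest, then column, then
#' channel, giving stable feature names. For the three CNN specs no
#' inference backend ships with this package, so the call fails with an
#' instructive error; their declared geometry remains available through
#' [expected_feature_length()].
#'
#' @param image Preprocessed array from [preprocess_crop()] (or a matrix,
#'   taken as grayscale) matching the spec's input size.
#' @param spec An [extractor_spec()].
#' @return Named numeric vector of length `expected_feature_length(spec)`.
#' @export
extract_features <- function(image, spec) {
  if (spec$backend != "mock")
    stop("no deep-learning inference backend is available for '", spec$name,
         "'; use extractor_spec(\"mock_bank\") for a deterministic extractor")
  gray <- if (is.matrix(image)) image else
    (image[, , 1] + image[, , 2] + image[, , 3]) / 3
  n <- spec$input_size_px
  if (!all(dim(gray) == c(n, n)))
    stop("image size ", paste(dim(gray), collapse = "x"),
         " does not match spec input ", n)
  g <- spec$declared_output_dims[1]
  cell <- n %/% g
  filters <- mock_filter_bank(spec$seed)
  # block-mean pooling as a matrix product: P acts on rows, t(P) on columns
  P <- matrix(0, g, n)
  P[cbind(rep(seq_len(g), each = cell), seq_len(n))] <- 1 / cell
  pooled <- vapply(filters, function(f) {
    act <- pmax(conv2_same(gray, f), 0)
    P %*% act %*% t(P)
  }, matrix(0, g, g))
  out <- as.vector(pooled)  # h fastest, then w, then filter channel
  names(out) <- feature_names(spec)
  out
}

# Stable flattened feature names: index = h + (w-1)*H + (c-1)*H*W.
feature_names <- function(spec) {
  d <- spec$declared_output_dims
  sprintf("%s_%s_f%05d", spec$name, spec$layer_tag, seq_len(prod(d)))
}

#' Extract features for one crop
#'
#' Convenience wrapper: [preprocess_crop()] then [extract_features()].
#' @inheritParams preprocess_crop
#' @return Named numeric feature vector.
#' @export
extract_crop_features <- function(crop, spec) {
  extract_features(preprocess_crop(crop, spec), spec)
}

#' Assemble a cohort feature table
#'
#' One row per patient in cohort order, columns named by the extractor's
#' stable flattened-feature names, with the binary recurrence labels
#' attached. All crops must share one dilation.
#'
#' @param crops List of `roi_crop`, one per patient.
#' @param spec An [extractor_spec()].
#' @param labels 0/1 vector, one per crop (1 = recurrence), optionally named
#'   by patient id.
#' @return A `feature_table`: list with `patient_ids`, `values` (matrix),
#'   `labels`, `dilation_px`, `extractor`.
#' @export
build_feature_table <- function(crops, spec, labels) {
  ids <- unname(vapply(crops, function(cr) cr$patient_id, character(1)))
  if (anyDuplicated(ids))
    stop("duplicate patient_ids in crops: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (length(labels) != length(crops))
    stop("missing crop or label; crops for: ", paste(ids, collapse = ", "))
  dil <- unique(vapply(crops, function(cr) cr$dilation_px, integer(1)))
  if (length(dil) != 1L) stop("crops mix dilations: ",
                              paste(dil, collapse = ", "))
  values <- t(vapply(crops, function(cr) extract_crop_features(cr, spec),
                     numeric(expected_feature_length(spec))))
  rownames(values) <- ids
  structure(list(patient_ids = ids, values = values,
                 labels = as.integer(labels), dilation_px = dil,
                 extractor = spec$name),
            class = "feature_table")
}

#' Write a feature table to CSV with a JSON spec sidecar
#'
#' @param table A `feature_table`.
#' @param path CSV path (first column `patient_id`, then features, then
#'   `label`); sidecar written as `<path>.json`.
#' @param spec The [extractor_spec()] that produced the table.
#' @return Invisibly, `path`.
#' @export
write_feature_table <- function(table, path, spec = NULL) {
  df <- data.frame(patient_id = table$patient_ids, table$values,
                   label = table$labels, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(spec))
    jsonlite::write_json(unclass(spec), paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(path)
}
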