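make_crop <- function(pixels, id = "C1", d = 0L) {
  structure(list(patient_id = id, dilation_px = d, slice_index = 1L,
                 bbox = bbox(1, nrow(pixels), 1, ncol(pixels)),
                 pixels = pixels, clamped = FALSE),
            class = "roi_crop")
}

test_that("declared output geometry gives the flattened feature lengths", {
  expect_equal(expected_feature_length(extractor_spec("alexnet_pool2")),
               13 * 13 * 256)
  expect_equal(expected_feature_length(extractor_spec("inceptionv3_maxpool")),
               35 * 35 * 192)
  expect_equal(expected_feature_length(extractor_spec("resnet152v2_maxpool")),
               28 * 28 * 256)
  expect_equal(expected_feature_length(extractor_spec("mock_bank")),
               8 * 8 * 16)
  expect_error(extractor_spec("vgg16"), "unknown extractor")
})

test_that("preprocessing normalizes, resizes and replicates channels", {
  spec <- extractor_spec("mock_bank")
  # constant crop under min-max normalization degenerates to all zeros
  mm <- extractor_spec("mock_bank", normalization = "minmax")
  out <- preprocess_crop(make_crop(matrix(50, 50, 50)), mm)
  expect_equal(dim(out), c(64, 64, 3))
  expect_true(all(out == 0))
  # under the fixed window it maps to the constant 50/255
  outf <- preprocess_crop(make_crop(matrix(50, 50, 50)), spec)
  expect_true(all(abs(outf - 50 / 255) < 1e-12))
  # input already at spec size: resize is the identity up to rescale
  px <- matrix(runif(64 * 64, 0, 255), 64, 64)
  idt <- preprocess_crop(make_crop(px), spec)
  expect_equal(idt[, , 1], px / 255)
  expect_equal(idt[, , 2], idt[, , 1])
  expect_equal(idt[, , 3], idt[, , 1])
  # outputs always within [0, 1]
  big <- preprocess_crop(make_crop(matrix(rnorm(900, 128, 200), 30, 30)), spec)
  expect_true(all(big >= 0 & big <= 1))
})

test_that("bilinear resize matches closed-form pixel-center interpolation", {
  # independent oracle: sample output pixel centers back into source
  # coordinates, clamp to the edge pixel centers, interpolate by hand
  bilinear_ref <- function(src, n_out) {
    n_in <- nrow(src)
    out <- matrix(0, n_out, n_out)
    coord <- function(i) {
      x <- (i - 0.5) * n_in / n_out + 0.5  # physical -> source index space
      min(max(x, 1), n_in)
    }
    for (i in seq_len(n_out)) for (j in seq_len(n_out)) {
      x <- coord(i); y <- coord(j)
      x0 <- floor(x); x1 <- min(x0 + 1, n_in); wx <- x - x0
      y0 <- floor(y); y1 <- min(y0 + 1, n_in); wy <- y - y0
      out[i, j] <- (1 - wx) * (1 - wy) * src[x0, y0] +
        wx * (1 - wy) * src[x1, y0] +
        (1 - wx) * wy * src[x0, y1] + wx * wy * src[x1, y1]
    }
    out
  }
  src <- matrix(c(0, 1, 1, 0), 2, 2)
  got <- EBImage::imageData(EBImage::resize(EBImage::Image(src), w = 4,
                                            h = 4, filter = "bilinear"))
  expect_equal(got, bilinear_ref(src, 4), tolerance = 1e-12)
  src2 <- matrix(runif(25), 5, 5)
  got2 <- EBImage::imageData(EBImage::resize(EBImage::Image(src2), w = 8,
                                             h = 8, filter = "bilinear"))
  expect_equal(got2, bilinear_ref(src2, 8), tolerance = 1e-12)
})

test_that("mock bank features are deterministic and match declared length", {
  spec <- extractor_spec("mock_bank")
  img <- preprocess_crop(make_crop(matrix(runif(400, 0, 255), 20, 20)), spec)
  f1 <- extract_features(img, spec)
  f2 <- extract_features(img, spec)
  expect_identical(f1, f2)
  expect_length(f1, expected_feature_length(spec))
  # a different filter seed changes the features
  f3 <- extract_features(img, extractor_spec("mock_bank", seed = 99))
  expect_false(identical(unname(f1), unname(f3)))
  # every mock layer tag honors its declared geometry
  for (tag in c("pool1", "pool2", "pool5")) {
    sp <- extractor_spec("mock_bank", layer_tag = tag)
    expect_length(extract_features(img, sp), expected_feature_length(sp))
  }
})

test_that("mock extraction does not disturb the global RNG stream", {
  spec <- extractor_spec("mock_bank")
  img <- preprocess_crop(make_crop(matrix(runif(400, 0, 255), 20, 20)), spec)
  set.seed(7); before <- rnorm(3)
  set.seed(7); invisible(extract_features(img, spec)); after <- rnorm(3)
  expect_identical(before, after)
})

test_that("CNN adapters without a backend fail pointing at mock_bank", {
  spec <- extractor_spec("alexnet_pool2")
  img <- array(0.5, c(227, 227, 3))
  expect_error(extract_features(img, spec), "mock_bank")
  expect_error(extract_features(array(0.5, c(10, 10, 3)),
                                extractor_spec("mock_bank")),
               "does not match")
})

test_that("feature tables preserve cohort order and reject bad input", {
  co <- small_cohort(n = 5, seed = 2)
  spec <- extractor_spec("mock_bank")
  crops <- lapply(co$scans, extract_roi, dilation_px = 0)
  tab <- build_feature_table(crops, spec, co$labels)
  expect_equal(tab$patient_ids, names(co$scans))
  expect_equal(dim(tab$values), c(5, 1024))
  expect_false(anyNA(tab$values))
  expect_error(build_feature_table(crops[c(1, 1)], spec, co$labels[1:2]),
               "duplicate")
  expect_error(build_feature_table(crops, spec, co$labels[1:3]), "label")
  mixed <- c(crops[1:4], list(extract_roi(co$scans[[5]], 10)))
  expect_error(build_feature_table(mixed, spec, co$labels), "dilations")
})

test_that("feature tables serialize to CSV with a spec sidecar", {
  co <- small_cohort(n = 3, seed = 8)
  spec <- extractor_spec("mock_bank")
  tab <- build_feature_table(lapply(co$scans, extract_roi, 0), spec,
                             co$labels)
  path <- tempfile(fileext = ".csv")
  write_feature_table(tab, path, spec)
  back <- utils::read.csv(path, check.names = FALSE)
  expect_equal(back$patient_id, tab$patient_ids)
  expect_equal(as.matrix(back[, colnames(tab$values)]), tab$values,
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(jsonlite::read_json(paste0(path, ".json"))$name, "mock_bank")
})
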