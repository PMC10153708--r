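# Shared fixture builders; everything is generated in code.

# A scan with a filled rectangle of foreground per slice; `boxes` is a list
# of c(rmin, rmax, cmin, cmax) per slice (NULL = empty slice).
rect_scan <- function(boxes, px = 32L, id = "T01", fg = 255) {
  n <- length(boxes)
  img <- array(seq_len(px * px * n) %% 97, dim = c(px, px, n))
  msk <- array(0, dim = c(px, px, n))
  for (s in seq_len(n)) {
    b <- boxes[[s]]
    if (!is.null(b)) msk[b[1]:b[2], b[3]:b[4], s] <- fg
  }
  segmented_scan(id, img, msk)
}

# Random blob mask on a single slice, plus the scan around it.
random_blob_scan <- function(seed, px = 40L, n_fg = 30L, id = "B01") {
  set.seed(seed)
  msk <- matrix(0, px, px)
  pts <- cbind(sample(5:(px - 5), n_fg, TRUE), sample(5:(px - 5), n_fg, TRUE))
  msk[pts] <- 255
  img <- matrix(rnorm(px * px, 100, 10), px, px)
  list(scan = segmented_scan(id, array(img, c(px, px, 1)),
                             array(msk, c(px, px, 1))),
       points = pts)
}

# Brute-force pairwise-count AUC: the independent oracle for the rank AUC.
pairwise_auc <- function(x, y) {
  pos <- x[y == 1]; neg <- x[y == 0]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# A tiny clinical table covering every category, with controlled missing.
tiny_clinical <- function() {
  data.frame(
    age_years = c(70, 55, 64, 80, 47, 69),
    weight_lbs = c(150, NA, 200, 170, 130, 182),
    gender = c("female", "male", "male", "male", "female", "male"),
    pack_years = c(20, 40, NA, 10, 0, 60),
    histology = c("adenocarcinoma", "squamous", "NOS", "adenocarcinoma",
                  "squamous", "adenocarcinoma"),
    pT = c("T1", "T2", "T3", "T4", "T1", "T2"),
    pN = c("N0", "N1", "N2", "N0", "N0", "N1"),
    grade = c("G1", "G2", "G3", "G2", "G1", "G3"),
    lymph_vascular_invasion = c("absent", "present", "not collected",
                                "absent", "absent", "present"),
    pleural_invasion = c("no", "yes", "no", "no", "yes", "no"),
    stringsAsFactors = FALSE)
}

# Fast small cohort for pipeline-level tests.
small_cohort <- function(n = 40L, seed = 1L, ...) {
  generate_cohort(synthetic_config(
    n_patients = n, n_slices = 1L, image_px = 64L,
    tumor_radius_px = c(6, 9), rim_width_px = 12L, periphery_px = 4L, seed = seed, ...))
}

# Feature table from plain matrices, bypassing image extraction.
matrix_feature_table <- function(values, labels, dilation = 0L,
                                 extractor = "synthetic") {
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("f%03d", seq_len(ncol(values)))
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("P%03d", seq_len(nrow(values)))
  structure(list(patient_ids = rownames(values), values = values,
                 labels = as.integer(labels), dilation_px = dilation,
                 extractor = extractor),
            class = "feature_table")
}
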