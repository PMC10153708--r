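#!/usr/bin/env Rscript
# Build the per-dilation radiomic feature tables. For every patient the
# max-area tumor slice is cropped at dilations 0/10/20, preprocessed
# (fixed intensity window, bilinear resize, 3-channel replication) and
# passed through the deterministic mock_bank pooling-layer extractor
# (16 seeded filters, 8x8 average-pool grid -> 1024 features).
#
# Writes results/features_d{0,10,20}.csv with a JSON extractor sidecar.

library(perirad)

cohort <- read_cohort("results/cohort")
spec <- extractor_spec("mock_bank")
cat(sprintf("Extractor: %s (%s), %d features per crop\n",
            spec$name, spec$layer_tag, expected_feature_length(spec)))

for (d in c(0L, 10L, 20L)) {
  crops <- lapply(cohort$scans, extract_roi, dilation_px = d)
  n_clamped <- sum(vapply(crops, function(cr) cr$clamped, logical(1)))
  tab <- build_feature_table(crops, spec, cohort$labels)
  path <- sprintf("results/features_d%d.csv", d)
  write_feature_table(tab, path, spec)
  sizes <- t(vapply(crops, function(cr) dim(cr$pixels), numeric(2)))
  cat(sprintf(
    "dilation %2d: median crop %dx%d px, %d clamped at border -> %s\n",
    d, median(sizes[, 1]), median(sizes[, 2]), n_clamped, path))
}
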