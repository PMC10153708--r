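#' Read a cohort directory of per-slice image stacks
#'
#' A cohort directory holds one PNG (or TIFF) file per slice for the CT
#' stack and the mask stack, a `manifest.json` pairing them per patient in
#' slice order, and `clinical.csv` / `labels.csv` tables. Image files store
#' intensities in [0, 1]; they are rescaled to the 0-255 range on read. Mask
#' pixels above 0.5 are treated as foreground.
#'
#' @param dir Cohort directory containing `manifest.json`.
#' @return A list with `scans` (list of [segmented_scan()]), `clinical`
#'   (data.frame), and `labels` (named 0/1 integer vector), plus `truth`
#'   when a ground-truth table is present.
#' @seealso [write_cohort()]
#' @export
read_cohort <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  read_img <- function(path) {
    p <- file.path(dir, path)
    if (grepl("\\.tiff?$", p, ignore.case = TRUE)) {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("reading TIFF slices requires the 'tiff' package")
      tiff::readTIFF(p)
    } else png::readPNG(p)
  }
  scans <- lapply(man$patients, function(p) {
    imgs <- lapply(p$image_slices, read_img)
    msks <- lapply(p$mask_slices, read_img)
    image <- array(unlist(imgs), dim = c(dim(imgs[[1]]), length(imgs))) * 255
    mask <- array(unlist(msks) > 0.5, dim = dim(image)) * 255
    spacing <- if (!is.null(p$pixel_spacing_mm)) unlist(p$pixel_spacing_mm)
    segmented_scan(p$patient_id, image, mask, spacing)
  })
  names(scans) <- vapply(scans, function(s) s$patient_id, character(1))
  clinical <- utils::read.csv(file.path(dir, "clinical.csv"),
                              stringsAsFactors = FALSE)
  lab <- utils::read.csv(file.path(dir, "labels.csv"), stringsAsFactors = FALSE)
  labels <- stats::setNames(as.integer(lab$recurrence), lab$patient_id)
  out <- list(scans = scans, clinical = clinical, labels = labels)
  tp <- file.path(dir, "truth.csv")
  if (file.exists(tp)) out$truth <- utils::read.csv(tp, stringsAsFactors = FALSE)
  out
}

#' Write a cohort to a directory of per-slice PNG stacks
#'
#' Inverse of [read_cohort()]: one PNG per slice per patient for image and
#' mask, `manifest.json`, `clinical.csv`, `labels.csv` and, if present, the
#' generator's `truth.csv`. Intensities are clipped to [0, 255] and stored
#' as [0, 1] PNG values.
#'
#' @param cohort A list as returned by [generate_cohort()] or [read_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  patients <- lapply(cohort$scans, function(s) {
    n <- dim(s$image)[3]
    ipaths <- sprintf("%s_img_%02d.png", s$patient_id, seq_len(n))
    mpaths <- sprintf("%s_msk_%02d.png", s$patient_id, seq_len(n))
    for (k in seq_len(n)) {
      img <- pmin(pmax(s$image[, , k], 0), 255) / 255
      png::writePNG(img, file.path(dir, ipaths[k]))
      png::writePNG(s$mask[, , k] * 1, file.path(dir, mpaths[k]))
    }
    list(patient_id = s$patient_id, image_slices = as.list(ipaths),
         mask_slices = as.list(mpaths),
         pixel_spacing_mm = s$pixel_spacing_mm)
  })
  jsonlite::write_json(list(patients = unname(patients)),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  utils::write.csv(cohort$clinical, file.path(dir, "clinical.csv"),
                   row.names = FALSE)
  utils::write.csv(
    data.frame(patient_id = names(cohort$labels),
               recurrence = as.integer(cohort$labels)),
    file.path(dir, "labels.csv"), row.names = FALSE)
  if (!is.null(cohort$truth))
    utils::write.csv(cohort$truth, file.path(dir, "truth.csv"),
                     row.names = FALSE)
  invisible(dir)
}
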