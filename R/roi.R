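#' Construct a segmented CT scan
#'
#' Bundles a patient's CT intensity stack with its aligned binary tumor
#' segmentation. Both stacks are stored as 3D arrays indexed
#' `[row, col, slice]`; the mask is strictly two-valued with foreground 255
#' (the convention used by rasterized tumor segmentations) or, equivalently,
#' any single nonzero value.
#'
#' @param patient_id Character scalar identifying the patient.
#' @param image Numeric 3D array (rows x cols x slices) of CT intensities,
#'   in arbitrary units.
#' @param mask Array of the same dimensions with exactly two values,
#'   background 0 and a single positive foreground value (normally 255).
#' @param pixel_spacing_mm Optional length-2 positive numeric (row, col
#'   spacing in mm); carried as metadata only.
#' @return An object of class `segmented_scan`.
#' @export
segmented_scan <- function(patient_id, image, mask, pixel_spacing_mm = NULL) {
  stopifnot(is.character(patient_id), length(patient_id) == 1L)
  if (is.matrix(image)) image <- array(image, dim = c(dim(image), 1L))
  if (is.matrix(mask)) mask <- array(mask, dim = c(dim(mask), 1L))
  if (!is.array(image) || length(dim(image)) != 3L)
    stop("`image` must be a 3D array (rows x cols x slices)")
  if (!identical(dim(image), dim(mask)))
    stop("image and mask dimensions differ for patient ", patient_id)
  vals <- sort(unique(as.vector(mask)))
  if (length(vals) > 2L || (length(vals) == 2L && vals[1] != 0))
    stop("mask must be two-valued {0, fg} for patient ", patient_id)
  if (!any(mask > 0))
    stop("empty mask: no foreground pixel in any slice for patient ", patient_id)
  if (!is.null(pixel_spacing_mm))
    stopifnot(length(pixel_spacing_mm) == 2L, all(pixel_spacing_mm > 0))
  structure(
    list(patient_id = patient_id, image = image, mask = mask != 0,
         pixel_spacing_mm = pixel_spacing_mm),
    class = "segmented_scan")
}

#' @export
print.segmented_scan <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("<segmented_scan> patient %s: %d x %d x %d slices, %d foreground px\n",
              x$patient_id, d[1], d[2], d[3], sum(x$mask)))
  invisible(x)
}

#' Find the slice with the largest tumor area
#'
#' Returns the 1-based index of the slice whose segmentation mask contains
#' the greatest number of foreground pixels; ties are broken by the lowest
#' slice index.
#'
#' @param scan A `segmented_scan`.
#' @return Integer slice index.
#' @export
find_max_area_slice <- function(scan) {
  stopifnot(inherits(scan, "segmented_scan"))
  counts <- apply(scan$mask, 3L, sum)
  if (all(counts == 0))
    stop("empty mask: no foreground pixel in any slice for patient ",
         scan$patient_id)
  which.max(counts)  # which.max takes the first maximum: lowest index on ties
}

#' Tight bounding box around a mask slice
#'
#' The smallest axis-aligned box containing every foreground pixel of a 2D
#' binary mask, as 1-based inclusive pixel bounds.
#'
#' @param mask_slice 2D logical/numeric matrix; nonzero means foreground.
#' @return A `bbox` list with `row_min`, `row_max`, `col_min`, `col_max`.
#' @export
tumor_bounding_box <- function(mask_slice) {
  stopifnot(is.matrix(mask_slice))
  fg <- which(mask_slice != 0, arr.ind = TRUE)
  if (nrow(fg) == 0L) stop("empty mask slice: no foreground pixel")
  bbox(min(fg[, 1]), max(fg[, 1]), min(fg[, 2]), max(fg[, 2]))
}

#' @rdname tumor_bounding_box
#' @param row_min,row_max,col_min,col_max 1-based inclusive bounds.
#' @export
bbox <- function(row_min, row_max, col_min, col_max) {
  stopifnot(row_min <= row_max, col_min <= col_max, row_min >= 1, col_min >= 1)
  structure(list(row_min = as.integer(row_min), row_max = as.integer(row_max),
                 col_min = as.integer(col_min), col_max = as.integer(col_max)),
            class = "bbox")
}

#' Dilate a bounding box and clamp it to the image
#'
#' Expands each side of the box by `dilation_px` pixels, then clamps the
#' result to the image extent. The returned box carries a `clamped`
#' attribute that is `TRUE` iff any side hit the border.
#'
#' @param box A `bbox`.
#' @param dilation_px Nonnegative integer dilation in pixels.
#' @param image_shape Length-2 integer (rows, cols).
#' @return A `bbox` with attribute `clamped`.
#' @export
dilate_and_clamp <- function(box, dilation_px, image_shape) {
  stopifnot(inherits(box, "bbox"), dilation_px >= 0, length(image_shape) >= 2)
  d <- as.integer(dilation_px)
  raw <- c(box$row_min - d, box$row_max + d, box$col_min - d, box$col_max + d)
  cl <- c(max(raw[1], 1L), min(raw[2], image_shape[1]),
          max(raw[3], 1L), min(raw[4], image_shape[2]))
  out <- bbox(cl[1], cl[2], cl[3], cl[4])
  attr(out, "clamped") <- !all(raw == cl)
  out
}

#' Crop a dilated tumor ROI from a CT slice
#'
#' Copies raw intensities (never the mask) from the selected slice inside an
#' already dilated-and-clamped bounding box, keeping provenance.
#'
#' @param scan A `segmented_scan`.
#' @param slice_index 1-based slice index.
#' @param box A `bbox`, already dilated and clamped.
#' @param dilation_px The dilation that produced `box` (provenance).
#' @return An object of class `roi_crop` with fields `patient_id`,
#'   `dilation_px`, `slice_index`, `bbox`, `pixels`, `clamped`.
#' @export
crop_roi <- function(scan, slice_index, box, dilation_px) {
  stopifnot(inherits(scan, "segmented_scan"), inherits(box, "bbox"))
  d <- dim(scan$image)
  if (slice_index < 1L || slice_index > d[3])
    stop("slice index ", slice_index, " out of range for patient ",
         scan$patient_id)
  if (box$row_max > d[1] || box$col_max > d[2])
    stop("bounding box exceeds image extent")
  structure(
    list(patient_id = scan$patient_id,
         dilation_px = as.integer(dilation_px),
         slice_index = as.integer(slice_index),
         bbox = box,
         pixels = scan$image[, , slice_index][box$row_min:box$row_max,
                                              box$col_min:box$col_max,
                                              drop = FALSE],
         clamped = isTRUE(attr(box, "clamped"))),
    class = "roi_crop")
}

#' Extract the max-area-slice ROI at a given dilation
#'
#' Convenience wrapper chaining [find_max_area_slice()],
#' [tumor_bounding_box()], [dilate_and_clamp()] and [crop_roi()].
#'
#' @inheritParams find_max_area_slice
#' @param dilation_px Nonnegative integer dilation in pixels.
#' @return An `roi_crop`.
#' @export
extract_roi <- function(scan, dilation_px = 0L) {
  s <- find_max_area_slice(scan)
  box <- tumor_bounding_box(scan$mask[, , s])
  box <- dilate_and_clamp(box, dilation_px, dim(scan$image)[1:2])
  crop_roi(scan, s, box, dilation_px)
}

#' Write an ROI crop as PNG with a JSON provenance sidecar
#'
#' Intensities are min-max rescaled to [0, 1] for the 8/16-bit PNG encoding;
#' the sidecar records the original intensity range, bounding box, slice and
#' dilation so the crop is traceable to its source scan.
#'
#' @param crop An `roi_crop`.
#' @param path Output PNG path; the sidecar is written next to it as
#'   `<path>.json`.
#' @return Invisibly, the sidecar path.
#' @export
write_crop_png <- function(crop, path) {
  stopifnot(inherits(crop, "roi_crop"))
  px <- crop$pixels
  rng <- range(px)
  scaled <- if (diff(rng) > 0) (px - rng[1]) / diff(rng) else px * 0
  png::writePNG(scaled, path)
  prov <- list(patient_id = crop$patient_id, dilation_px = crop$dilation_px,
               slice_index = crop$slice_index,
               bbox = unclass(crop$bbox), clamped = crop$clamped,
               intensity_min = rng[1], intensity_max = rng[2])
  side <- paste0(path, ".json")
  jsonlite::write_json(prov, side, auto_unbox = TRUE, digits = NA)
  invisible(side)
}
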