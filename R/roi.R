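# ROI preprocessing: three representative slices, 1 cm in-plane margin,
# HU windowing. Slices run along the third (acquisition z) array axis.

#' Select the three representative tumor slices
#'
#' Returns the first slice with any mask voxel, the slice with the maximum
#' cross-sectional mask area (ties broken to the lowest index), and the last
#' slice with any mask voxel.
#'
#' @param mask 3-D binary array (slices along the third axis).
#' @return integer vector `(first, max_area, last)`, non-decreasing.
#' @export
select_three_slices <- function(mask) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  areas <- apply(mask != 0, 3L, sum)
  nz <- which(areas > 0L)
  if (length(nz) == 0L) stop_mdafm("mask has no nonzero voxels")
  c(first = min(nz), max_area = which.max(areas), last = max(nz))
}

#' Crop one slice to the mask bounding box plus a physical margin
#'
#' The in-plane bounding box of the mask on `slice_index` is expanded by
#' `ceiling(margin_mm / spacing)` voxels per side (per axis) and clamped to
#' the image border; no padding is added beyond the border.
#'
#' @param intensities 3-D intensity array (HU).
#' @param mask 3-D binary array, same shape.
#' @param slice_index slice to crop.
#' @param spacing_mm voxel size, length 3; in-plane spacings are the first
#'   two entries.
#' @param margin_mm margin in millimetres (default 10 = 1 cm).
#' @return 2-D intensity crop.
#' @export
crop_with_margin <- function(intensities, mask, slice_index,
                             spacing_mm = c(1, 1, 1), margin_mm = 10) {
  stopifnot(all(dim(intensities) == dim(mask)), margin_mm >= 0,
            all(spacing_mm > 0))
  d <- dim(mask)
  if (slice_index < 1L || slice_index > d[3])
    stop_mdafm("slice_index %d outside volume (1..%d)", slice_index, d[3])
  m2 <- mask[, , slice_index] != 0
  if (!any(m2)) stop_mdafm("mask empty on slice %d", slice_index)
  rows <- range(which(apply(m2, 1L, any)))
  cols <- range(which(apply(m2, 2L, any)))
  ex <- ceiling(margin_mm / spacing_mm[1:2])
  r0 <- max(1L, rows[1] - ex[1]); r1 <- min(d[1], rows[2] + ex[1])
  c0 <- max(1L, cols[1] - ex[2]); c1 <- min(d[2], cols[2] + ex[2])
  intensities[r0:r1, c0:c1, slice_index]
}

#' Window and normalize a HU crop to [0, 1]
#'
#' Clips to `[window[1], window[2]]` and min-max scales by the window bounds
#' themselves (not the crop's own extremes), so the mapping is fixed across
#' patients.
#'
#' @param crop 2-D numeric array.
#' @param window length-2 `(low, high)` HU window; default `c(-100, 300)`,
#'   a standard abdominal soft-tissue range.
#' @return 2-D array in `[0, 1]`.
#' @export
window_and_normalize <- function(crop, window = c(-100, 300)) {
  if (!(is.numeric(window) && length(window) == 2L && window[1] < window[2]))
    stop_mdafm("window must be (low, high) with low < high")
  pmin(pmax((crop - window[1]) / (window[2] - window[1]), 0), 1)
}

#' Extract the three normalized ROI crops for one phase
#'
#' @param intensities,mask 3-D arrays of equal shape.
#' @param spacing_mm voxel size (length 3).
#' @param window HU window, see [window_and_normalize()].
#' @param margin_mm margin, see [crop_with_margin()].
#' @return `roi_slices` list: `crops` (list of three `[0,1]` matrices),
#'   `slice_indices`, `window`.
#' @export
extract_roi_slices <- function(intensities, mask, spacing_mm = c(1, 1, 1),
                               window = c(-100, 300), margin_mm = 10) {
  idx <- select_three_slices(mask)
  crops <- lapply(idx, function(s)
    window_and_normalize(
      crop_with_margin(intensities, mask, s, spacing_mm, margin_mm), window))
  structure(list(crops = unname(crops), slice_indices = unname(idx),
                 window = window),
            class = "roi_slices")
}

#' Bilinear resize of a 2-D array
#'
#' Align-corners convention: source coordinates are linearly mapped so the
#' first and last rows/columns correspond exactly.
#'
#' @param x 2-D numeric array.
#' @param out_shape target `(rows, cols)`.
#' @return resized array.
#' @export
resize_bilinear <- function(x, out_shape = c(224L, 224L)) {
  stopifnot(length(dim(x)) == 2L, all(out_shape >= 1))
  src <- dim(x); out <- as.integer(out_shape)
  map <- function(n_out, n_src) {
    if (n_out == 1L || n_src == 1L) rep(1, n_out)
    else (seq_len(n_out) - 1) * (n_src - 1) / (n_out - 1) + 1
  }
  ri <- map(out[1], src[1]); ci <- map(out[2], src[2])
  r0 <- pmin(floor(ri), src[1] - (src[1] > 1)); r1 <- pmin(r0 + 1, src[1])
  c0 <- pmin(floor(ci), src[2] - (src[2] > 1)); c1 <- pmin(c0 + 1, src[2])
  fr <- ri - r0; fc <- ci - c0
  a <- x[r0, c0, drop = FALSE]; b <- x[r0, c1, drop = FALSE]
  cc <- x[r1, c0, drop = FALSE]; dd <- x[r1, c1, drop = FALSE]
  top <- a * (1 - fc)[col(a)] + b * fc[col(b)]
  bot <- cc * (1 - fc)[col(cc)] + dd * fc[col(dd)]
  top * (1 - fr)[row(top)] + bot * fr[row(bot)]
}
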