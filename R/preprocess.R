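#' Clamp a raw CT slice to a Hounsfield window
#'
#' Soft-tissue windowing for abdominal CT: values below `lo` are set to `lo`,
#' values above `hi` to `hi`. The default `[-100, 200]` window retains liver
#' parenchyma and excludes air and dense bone.
#'
#' @param slice A [ct_slice] with `intensity_state = "raw_hu"`.
#' @param lo,hi Window bounds in HU, `lo < hi`.
#' @return The windowed slice, `intensity_state = "windowed"`; the window is
#'   recorded on the slice for downstream equalisation.
#' @export
window_hounsfield <- function(slice, lo = -100, hi = 200) {
  stopifnot(inherits(slice, "ct_slice"))
  if (lo >= hi) stop("`lo` must be < `hi`", call. = FALSE)
  if (slice$intensity_state != "raw_hu")
    stop("window_hounsfield expects a raw_hu slice", call. = FALSE)
  px <- pmin(pmax(slice$pixels, lo), hi)
  ct_slice(px, slice$patient_id, slice$slice_index, "windowed",
           window = c(lo, hi))
}

#' Global histogram equalisation over the windowed range
#'
#' Intensities are quantised into `n_bins` equal bins over the recorded
#' window and remapped through the normalised cumulative histogram. The
#' mapping is monotone non-decreasing, so the rank order of pixels is always
#' preserved; a constant slice maps to a constant slice.
#'
#' @param slice A windowed [ct_slice].
#' @param n_bins Number of histogram bins (default 256).
#' @return The equalised slice on a `[0, 1]` scale,
#'   `intensity_state = "equalized"`.
#' @export
equalize_histogram <- function(slice, n_bins = 256L) {
  stopifnot(inherits(slice, "ct_slice"))
  if (slice$intensity_state != "windowed")
    stop("equalize_histogram expects a windowed slice", call. = FALSE)
  w <- slice$window %||% range(slice$pixels)
  px <- slice$pixels
  if (w[2] <= w[1]) w[2] <- w[1] + 1
  bin <- pmin(pmax(floor((px - w[1]) / (w[2] - w[1]) * n_bins) + 1L, 1L), n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  cdf <- cumsum(counts) / length(px)
  out <- matrix(cdf[bin], nrow(px), ncol(px))
  if (max(px) == min(px)) out[] <- cdf[bin[1]]   # degenerate single-bin image
  ct_slice(out, slice$patient_id, slice$slice_index, "equalized",
           window = slice$window)
}

#' Resize a slice or mask to the network input size
#'
#' Images are resampled bilinearly; masks use nearest-neighbour so the output
#' stays in `{0, 1}`. An input already at the target size is returned
#' unchanged.
#'
#' @param x A [ct_slice] or [binary_mask].
#' @param side Target side length in pixels (square output; default 256).
#' @return Same class as the input, resized to `side x side`.
#' @export
resize_to_network <- function(x, side = 256L) {
  if (side < 16L) stop("`side` must be >= 16", call. = FALSE)
  m <- as_pixel_matrix(x)
  if (nrow(m) == side && ncol(m) == side) return(x)
  if (inherits(x, "binary_mask")) {
    out <- resample_nearest(m, side, side)
    binary_mask((out != 0) * 1, x$label_kind)
  } else if (inherits(x, "ct_slice")) {
    out <- EBImage::resize(EBImage::Image(m), w = side, h = side,
                           filter = "bilinear")
    ct_slice(matrix(EBImage::imageData(out), side, side),
             x$patient_id, x$slice_index, x$intensity_state, x$window)
  } else {
    stop("expected a ct_slice or binary_mask", call. = FALSE)
  }
}

# nearest-neighbour resample (exact {0,1} closure for masks)
resample_nearest <- function(m, h, w) {
  ri <- pmin(pmax(round((seq_len(h) - 0.5) * nrow(m) / h + 0.5), 1L), nrow(m))
  ci <- pmin(pmax(round((seq_len(w) - 0.5) * ncol(m) / w + 0.5), 1L), ncol(m))
  m[ri, ci, drop = FALSE]
}

#' Affinely rescale an equalised slice to the unit interval
#'
#' Maps `[min, max]` to `[0, 1]`; a constant slice maps to all zeros (stated
#' degenerate rule).
#'
#' @param slice An equalised [ct_slice].
#' @return The normalised slice, `intensity_state = "normalized"`.
#' @export
normalize_unit <- function(slice) {
  stopifnot(inherits(slice, "ct_slice"))
  if (slice$intensity_state != "equalized")
    stop("normalize_unit expects an equalized slice", call. = FALSE)
  px <- slice$pixels
  rng <- range(px)
  out <- if (rng[2] > rng[1]) (px - rng[1]) / (rng[2] - rng[1])
         else matrix(0, nrow(px), ncol(px))
  ct_slice(out, slice$patient_id, slice$slice_index, "normalized")
}

#' Full preprocessing pipeline for one raw slice
#'
#' Fixed order: window -> equalise -> resize -> normalise. Maps any raw HU
#' slice into `[0, 1]` at the network input size.
#'
#' @param slice A raw [ct_slice].
#' @param lo,hi Hounsfield window.
#' @param side Network input side length.
#' @return A normalised `side x side` [ct_slice].
#' @export
preprocess_slice <- function(slice, lo = -100, hi = 200, side = 256L) {
  s <- window_hounsfield(slice, lo, hi)
  s <- equalize_histogram(s)
  s <- resize_to_network(s, side)
  normalize_unit(s)
}

#' Patient-level train/validation/test split
#'
#' Assigns whole patients, never individual slices, so no subject leaks
#' across sets: `test_fraction` of all patients go to test, then
#' `val_fraction` of the remainder to validation and the rest to training.
#'
#' @param patient_ids Character vector of distinct patient identifiers.
#' @param test_fraction Fraction of patients held out for testing
#'   (default 0.10).
#' @param val_fraction Fraction of the *remaining* patients used for
#'   validation (default 0.30).
#' @param seed Integer seed; the same seed always yields the same partition.
#' @return List with character vectors `train`, `val`, `test` (disjoint,
#'   exhaustive).
#' @export
split_patients <- function(patient_ids, test_fraction = 0.10,
                           val_fraction = 0.30, seed = 1L) {
  patient_ids <- unique(as.character(patient_ids))
  n <- length(patient_ids)
  if (test_fraction <= 0 || test_fraction >= 1 ||
      val_fraction <= 0 || val_fraction >= 1)
    stop("fractions must lie in (0, 1)", call. = FALSE)
  n_test <- max(1L, round(test_fraction * n))
  n_val <- max(1L, round(val_fraction * (n - n_test)))
  if (n - n_test - n_val < 1L)
    stop(sprintf("too few patients (%d) to populate train, val and test", n),
         call. = FALSE)
  with_stream(as.integer(seed), {
    shuffled <- sample(patient_ids)
    list(test = sort(shuffled[seq_len(n_test)]),
         val = sort(shuffled[n_test + seq_len(n_val)]),
         train = sort(shuffled[(n_test + n_val + 1L):n]))
  })
}
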