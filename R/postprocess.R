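#' Construct a probability map
#'
#' The pre-threshold network output: a 2-D grid of values in `[0, 1]` with
#' provenance.
#'
#' @param pixels Numeric matrix in `[0, 1]`.
#' @param patient_id,slice_index Provenance.
#' @return A `probability_map` object.
#' @export
probability_map <- function(pixels, patient_id = "anon", slice_index = 0L) {
  if (!is.matrix(pixels) || min(pixels) < 0 || max(pixels) > 1)
    stop("probability_map: values must lie in [0, 1]", call. = FALSE)
  structure(list(pixels = pixels, patient_id = as.character(patient_id),
                 slice_index = as.integer(slice_index)),
            class = "probability_map")
}

#' @export
print.probability_map <- function(x, ...) {
  cat(sprintf("<probability_map %s #%d  %dx%d  mean=%.3f>\n", x$patient_id,
              x$slice_index, nrow(x$pixels), ncol(x$pixels), mean(x$pixels)))
  invisible(x)
}

#' Threshold a probability map into a binary mask
#'
#' A pixel strictly greater than the threshold becomes foreground (1); a
#' pixel less than or equal to it becomes background (0) -- ties go to
#' background. Idempotent when reapplied to its own output viewed as
#' probabilities.
#'
#' @param map A `probability_map` or matrix in `[0, 1]`.
#' @param threshold Decision threshold in (0, 1), default 0.5.
#' @param label_kind Label for the resulting mask.
#' @return A [binary_mask].
#' @export
binarize <- function(map, threshold = 0.5, label_kind = "liver") {
  if (threshold <= 0 || threshold >= 1)
    stop("`threshold` must lie in (0, 1)", call. = FALSE)
  p <- if (inherits(map, "probability_map")) map$pixels else map
  if (!is.matrix(p)) stop("binarize: expected a matrix or probability_map",
                          call. = FALSE)
  if (min(p) < 0 || max(p) > 1)
    stop("binarize: values outside [0, 1]", call. = FALSE)
  binary_mask((p > threshold) * 1, label_kind)
}

#' Clip a predicted tumour mask to the predicted liver
#'
#' Optional constraint when both segmentation heads are run: a tumour voxel
#' outside the predicted liver is set to background.
#'
#' @param tumor_mask,liver_mask [binary_mask] objects of equal shape.
#' @return The clipped tumour [binary_mask].
#' @export
clip_tumor_to_liver <- function(tumor_mask, liver_mask) {
  t <- as_pixel_matrix(tumor_mask); l <- as_pixel_matrix(liver_mask)
  if (!all(dim(t) == dim(l))) stop("mask shapes differ", call. = FALSE)
  binary_mask(t * l, "tumor")
}

#' Stack per-slice masks into a 3-D binary volume
#'
#' @param masks Ordered list of [binary_mask] objects sharing dimensions.
#' @param patient_id Optional patient identity check: if the masks carry
#'   `patient_id` attributes they must all match.
#' @return 3-D array of shape `(n_slices, height, width)` with attribute
#'   `patient_id`; exportable with [write_nifti()].
#' @export
stack_volume <- function(masks, patient_id = NULL) {
  if (!length(masks)) stop("stack_volume: no masks", call. = FALSE)
  mats <- lapply(masks, as_pixel_matrix)
  d <- dim(mats[[1]])
  if (!all(vapply(mats, function(m) all(dim(m) == d), logical(1))))
    stop("assembly error: masks have differing shapes", call. = FALSE)
  pids <- unlist(lapply(masks, function(m) attr(m, "patient_id")))
  if (!is.null(patient_id)) pids <- c(pids, patient_id)
  if (length(unique(pids)) > 1L)
    stop("assembly error: masks from different patients", call. = FALSE)
  vol <- array(0, c(length(mats), d[1], d[2]))
  for (k in seq_along(mats)) vol[k, , ] <- mats[[k]]
  attr(vol, "patient_id") <- if (length(pids)) pids[1] else "anon"
  vol
}

#' Slice a stacked volume back into masks
#'
#' Inverse of [stack_volume()]: returns the original masks bit-exactly.
#'
#' @param volume 3-D array `(n, h, w)` over `{0, 1}`.
#' @param label_kind Label for the masks.
#' @return List of [binary_mask] objects.
#' @export
unstack_volume <- function(volume, label_kind = "liver") {
  stopifnot(length(dim(volume)) == 3L)
  lapply(seq_len(dim(volume)[1]), function(k)
    binary_mask(matrix(volume[k, , ], dim(volume)[2], dim(volume)[3]),
                label_kind))
}
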