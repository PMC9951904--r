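#' Construct a CT slice
#'
#' A `ct_slice` is one axial 2-D grid of scalar intensities together with its
#' provenance (patient, slice index) and an `intensity_state` marker that the
#' preprocessing pipeline advances through
#' `raw_hu -> windowed -> equalized -> normalized`.
#'
#' @param pixels Numeric matrix (rows = image rows, origin top-left).
#' @param patient_id Character scalar identifying the patient.
#' @param slice_index Zero-based integer position along the axial axis.
#' @param intensity_state One of `"raw_hu"`, `"windowed"`, `"equalized"`,
#'   `"normalized"`.
#' @param window Optional numeric length-2 vector recording the Hounsfield
#'   window `[lo, hi]` applied to the slice (set by [window_hounsfield()]).
#' @return An object of class `ct_slice`.
#' @export
ct_slice <- function(pixels, patient_id = "anon", slice_index = 0L,
                     intensity_state = "raw_hu", window = NULL) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  if (!all(is.finite(pixels)))
    stop("ct_slice pixels must all be finite", call. = FALSE)
  intensity_state <- match.arg(intensity_state,
                               c("raw_hu", "windowed", "equalized", "normalized"))
  if (intensity_state == "normalized" &&
      (min(pixels) < 0 || max(pixels) > 1))
    stop("normalized ct_slice must have pixels in [0, 1]", call. = FALSE)
  structure(list(pixels = pixels,
                 patient_id = as.character(patient_id),
                 slice_index = as.integer(slice_index),
                 intensity_state = intensity_state,
                 window = window),
            class = "ct_slice")
}

#' Construct a binary mask
#'
#' Ground-truth or predicted segmentation over `{0, 1}`: liver (or tumour)
#' pixels are 1, background 0.
#'
#' @param pixels Matrix containing only 0 and 1.
#' @param label_kind `"liver"` or `"tumor"`.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(pixels, label_kind = c("liver", "tumor")) {
  label_kind <- match.arg(label_kind)
  if (!is.matrix(pixels))
    stop("`pixels` must be a matrix", call. = FALSE)
  storage.mode(pixels) <- "double"
  if (!all(pixels %in% c(0, 1)))
    stop("binary_mask pixels must contain only 0 and 1", call. = FALSE)
  structure(list(pixels = pixels, label_kind = label_kind),
            class = "binary_mask")
}

#' Construct a CT volume
#'
#' An ordered stack of [ct_slice] objects from one patient; all slices must
#' share dimensions and have strictly increasing `slice_index`.
#'
#' @param slices List of `ct_slice` objects.
#' @param patient_id Character scalar; defaults to the first slice's patient.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(slices, patient_id = NULL) {
  if (!length(slices)) stop("a ct_volume needs at least one slice", call. = FALSE)
  if (!all(vapply(slices, inherits, logical(1), "ct_slice")))
    stop("all elements of `slices` must be ct_slice objects", call. = FALSE)
  dims <- vapply(slices, function(s) dim(s$pixels), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all slices in a volume must share dimensions", call. = FALSE)
  idx <- vapply(slices, `[[`, integer(1), "slice_index")
  if (any(diff(idx) <= 0))
    stop("slice_index must be strictly increasing within a volume", call. = FALSE)
  pid <- vapply(slices, `[[`, character(1), "patient_id")
  if (length(unique(pid)) > 1L)
    stop("a ct_volume must contain slices from a single patient", call. = FALSE)
  structure(list(slices = slices,
                 patient_id = as.character(patient_id %||% pid[1])),
            class = "ct_volume")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ct_slice <- function(x, ...) {
  cat(sprintf("<ct_slice %s #%d  %dx%d  state=%s>\n",
              x$patient_id, x$slice_index,
              nrow(x$pixels), ncol(x$pixels), x$intensity_state))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask %s  %dx%d  positive=%d>\n", x$label_kind,
              nrow(x$pixels), ncol(x$pixels), sum(x$pixels)))
  invisible(x)
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$slices[[1]]$pixels)
  cat(sprintf("<ct_volume %s  %d slices of %dx%d>\n",
              x$patient_id, length(x$slices), d[1], d[2]))
  invisible(x)
}

# internal: pull a plain matrix out of ct_slice / binary_mask / matrix
as_pixel_matrix <- function(x) {
  if (inherits(x, "ct_slice") || inherits(x, "binary_mask")) x$pixels
  else if (is.matrix(x)) x
  else stop("expected a ct_slice, binary_mask or matrix", call. = FALSE)
}
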