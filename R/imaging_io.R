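#' @title Slice and mask input/output
#' @description Readers and writers for the on-disk formats the tool touches:
#'   DICOM series (read), NIfTI volumes (read/write), per-slice image/mask
#'   pairs as JPG/PNG. Coordinate convention throughout the package:
#'   row-major matrices, origin top-left, 0-based slice indices; masks on disk
#'   may store any nonzero value for foreground and are binarised to `{0,1}`
#'   on read.
#' @name imaging_io
NULL

#' Write a binary mask as single-channel PNG
#'
#' Foreground is stored as 255 (the common annotation-tool convention);
#' [read_mask_png()] binarises any nonzero value back to 1, so write/read
#' round-trips are exact.
#'
#' @param mask A [binary_mask] or 0/1 matrix.
#' @param path Output file.
#' @export
write_mask_png <- function(mask, path) {
  m <- as_pixel_matrix(mask)
  png::writePNG(m, target = path)   # 0/1 doubles -> 8-bit 0/255
  invisible(path)
}

#' Read a single-channel PNG mask, binarising nonzero values to 1
#'
#' @param path PNG file.
#' @param label_kind Passed to [binary_mask()].
#' @return A [binary_mask].
#' @export
read_mask_png <- function(path, label_kind = "liver") {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  binary_mask((m != 0) * 1, label_kind)
}

# Write a slice image scaled to 8-bit with a fixed affine map from HU.
# 3 identical channels, per the export convention for abdominal slice sets.
write_slice_image <- function(slice, path, format = c("png", "jpg"),
                              hu_range = c(-160, 240)) {
  format <- match.arg(format)
  m <- as_pixel_matrix(slice)
  m <- pmin(pmax(m, hu_range[1]), hu_range[2])
  m <- (m - hu_range[1]) / (hu_range[2] - hu_range[1])
  arr <- array(rep(m, 3L), c(dim(m), 3L))
  if (format == "png") png::writePNG(arr, target = path)
  else jpeg::writeJPEG(arr, target = path, quality = 0.95)
  invisible(path)
}

#' Read a paired slice image and mask
#'
#' Three-channel images are collapsed to one channel (channels are identical
#' by convention; otherwise they are averaged). The mask is strictly
#' binarised: any nonzero pixel becomes 1.
#'
#' @param image_path JPG or PNG image (1 or 3 channels).
#' @param mask_path Single-channel PNG mask.
#' @param patient_id,slice_index Provenance attached to the returned slice.
#' @return List with `slice` ([ct_slice], intensity state `raw_hu` on the
#'   stored 8-bit scale) and `mask` ([binary_mask]).
#' @export
read_slice_pair <- function(image_path, mask_path,
                            patient_id = "anon", slice_index = 0L) {
  ext <- tolower(tools::file_ext(image_path))
  img <- if (ext %in% c("jpg", "jpeg")) jpeg::readJPEG(image_path)
         else png::readPNG(image_path)
  if (length(dim(img)) == 3L) {
    ch <- dim(img)[3]
    same <- all(vapply(seq_len(ch)[-1], function(k)
      isTRUE(all.equal(img[, , k], img[, , 1])), logical(1)))
    img <- if (same) img[, , 1] else apply(img, c(1, 2), mean)
  }
  mask <- read_mask_png(mask_path)
  if (!all(dim(img) == dim(mask$pixels)))
    stop(sprintf("pairing error: image is %dx%d but mask is %dx%d",
                 nrow(img), ncol(img), nrow(mask$pixels), ncol(mask$pixels)),
         call. = FALSE)
  list(slice = ct_slice(img, patient_id, slice_index, "raw_hu"),
       mask = mask)
}

# --- NIfTI -----------------------------------------------------------------

#' Read a 3-D NIfTI volume as a stack of axial CT slices
#'
#' @param path NIfTI file (.nii / .nii.gz).
#' @param patient_id Provenance token for the returned slices.
#' @return A [ct_volume] with one slice per axial plane, indices `0..N-1`.
#' @export
read_nifti <- function(path, patient_id = "anon") {
  vol <- RNifti::readNifti(path)
  d <- dim(vol)
  if (length(d) != 3L)
    stop(sprintf("format error: expected a 3-D volume, got %d dimensions",
                 length(d)), call. = FALSE)
  if (any(!is.finite(vol)))
    stop("format error: volume contains non-finite voxels", call. = FALSE)
  slices <- lapply(seq_len(d[3]), function(k)
    ct_slice(matrix(vol[, , k], d[1], d[2]), patient_id, k - 1L, "raw_hu"))
  ct_volume(slices, patient_id)
}

#' Write a 3-D array or stacked mask volume as NIfTI
#'
#' @param x 3-D numeric array `(n_slices, height, width)` as produced by
#'   [stack_volume()], or a [ct_volume].
#' @param path Output file.
#' @export
write_nifti <- function(x, path) {
  if (inherits(x, "ct_volume")) {
    d <- dim(x$slices[[1]]$pixels)
    arr <- array(0, c(d[1], d[2], length(x$slices)))
    for (k in seq_along(x$slices)) arr[, , k] <- x$slices[[k]]$pixels
  } else {
    stopifnot(length(dim(x)) == 3L)
    arr <- aperm(x, c(2, 3, 1))   # (n,h,w) -> (h,w,n)
  }
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  invisible(path)
}

# --- minimal DICOM ---------------------------------------------------------
# No DICOM reader ships with the installed R stack, so a minimal parser for
# uncompressed Explicit-VR little-endian single-frame files is implemented
# here, covering the tags a CT series needs (geometry, rescale, pixel data).

dicom_tag <- function(group, element) sprintf("%04X%04X", group, element)

DCM_TAGS <- list(
  patient_id   = dicom_tag(0x0010, 0x0020),
  instance     = dicom_tag(0x0020, 0x0013),
  slice_loc    = dicom_tag(0x0020, 0x1041),
  rows         = dicom_tag(0x0028, 0x0010),
  cols         = dicom_tag(0x0028, 0x0011),
  bits_alloc   = dicom_tag(0x0028, 0x0100),
  pixel_rep    = dicom_tag(0x0028, 0x0103),
  intercept    = dicom_tag(0x0028, 0x1052),
  slope        = dicom_tag(0x0028, 0x1053),
  pixel_data   = dicom_tag(0x7FE0, 0x0010))

read_dicom_elements <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 132L || rawToChar(raw[129:132]) != "DICM")
    stop(sprintf("format error: '%s' is not a DICOM file (missing DICM magic)",
                 path), call. = FALSE)
  pos <- 133L
  n <- length(raw)
  elements <- list()
  u16 <- function(at) as.integer(raw[at]) + 256L * as.integer(raw[at + 1L])
  u32 <- function(at) sum(as.double(raw[at + 0:3]) * 256^(0:3))
  while (pos + 7L <= n) {
    group <- u16(pos); element <- u16(pos + 2L)
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
      len <- u32(pos + 8L); data_at <- pos + 12L
    } else {
      len <- u16(pos + 6L); data_at <- pos + 8L
    }
    if (data_at + len - 1L > n)
      stop(sprintf("format error: truncated DICOM element in '%s'", path),
           call. = FALSE)
    bytes <- if (len > 0) raw[data_at:(data_at + len - 1L)] else raw(0)
    elements[[dicom_tag(group, element)]] <- list(vr = vr, bytes = bytes)
    pos <- data_at + len
  }
  elements
}

dcm_string <- function(el) if (is.null(el)) NULL else trimws(rawToChar(el$bytes))
dcm_number <- function(el) if (is.null(el)) NULL else as.numeric(dcm_string(el))
dcm_u16    <- function(el) if (is.null(el)) NULL else
  as.integer(el$bytes[1]) + 256L * as.integer(el$bytes[2])

read_dicom_file <- function(path) {
  el <- read_dicom_elements(path)
  need <- function(tag, what) {
    if (is.null(el[[tag]]))
      stop(sprintf("format error: '%s' is missing %s", path, what), call. = FALSE)
    el[[tag]]
  }
  rows <- dcm_u16(need(DCM_TAGS$rows, "Rows (0028,0010)"))
  cols <- dcm_u16(need(DCM_TAGS$cols, "Columns (0028,0011)"))
  slope <- dcm_number(el[[DCM_TAGS$slope]])
  intercept <- dcm_number(el[[DCM_TAGS$intercept]])
  if (is.null(slope) || is.null(intercept))
    stop(sprintf("format error: '%s' is missing rescale slope/intercept tags",
                 path), call. = FALSE)
  bits <- dcm_u16(el[[DCM_TAGS$bits_alloc]]) %||% 16L
  if (bits != 16L)
    stop(sprintf("format error: '%s' has unsupported BitsAllocated=%d",
                 path, bits), call. = FALSE)
  signed <- identical(dcm_u16(el[[DCM_TAGS$pixel_rep]]), 1L)
  px <- need(DCM_TAGS$pixel_data, "PixelData (7FE0,0010)")$bytes
  vals <- readBin(px, "integer", n = rows * cols, size = 2L,
                  signed = signed, endian = "little")
  if (!signed) vals <- vals %% 65536
  list(patient_id = dcm_string(el[[DCM_TAGS$patient_id]]) %||% "anon",
       instance = dcm_number(el[[DCM_TAGS$instance]]) %||% NA_real_,
       slice_loc = dcm_number(el[[DCM_TAGS$slice_loc]]) %||% NA_real_,
       hu = matrix(vals * slope + intercept, rows, cols, byrow = TRUE))
}

#' Read one patient's DICOM series as a CT volume in Hounsfield units
#'
#' Parses uncompressed Explicit-VR little-endian files, rescales stored
#' values to HU with each file's slope/intercept, and orders slices by
#' slice location (ties broken by instance number).
#'
#' @param directory Directory containing the `.dcm` files of one series.
#' @return A [ct_volume] with `intensity_state = "raw_hu"`.
#' @export
read_dicom_series <- function(directory) {
  files <- sort(list.files(directory, pattern = "\\.dcm$", full.names = TRUE,
                           ignore.case = TRUE))
  if (!length(files))
    stop(sprintf("format error: no DICOM files found in '%s'", directory),
         call. = FALSE)
  parsed <- lapply(files, read_dicom_file)
  pids <- unique(vapply(parsed, `[[`, character(1), "patient_id"))
  if (length(pids) > 1L)
    stop(sprintf("format error: directory mixes patients: %s",
                 paste(pids, collapse = ", ")), call. = FALSE)
  loc <- vapply(parsed, `[[`, numeric(1), "slice_loc")
  inst <- vapply(parsed, `[[`, numeric(1), "instance")
  ord <- order(loc, inst, na.last = TRUE)
  slices <- lapply(seq_along(ord), function(i)
    ct_slice(parsed[[ord[i]]]$hu, pids, i - 1L, "raw_hu"))
  ct_volume(slices, pids)
}

#' Write a synthetic single-frame DICOM file (test fixture writer)
#'
#' Emits a minimal uncompressed Explicit-VR little-endian file carrying only
#' the tags [read_dicom_series()] consumes. This is a synthetic fixture
#' generator for tests and examples, not a general DICOM writer.
#'
#' @param hu Matrix of Hounsfield values.
#' @param path Output file.
#' @param patient_id Patient identifier tag value.
#' @param instance Instance number.
#' @param slice_loc Slice location (mm).
#' @param slope,intercept Rescale applied when reading back
#'   (`stored = (hu - intercept) / slope`).
#' @export
write_dicom_slice <- function(hu, path, patient_id = "anon",
                              instance = 1L, slice_loc = 0,
                              slope = 1, intercept = -1024) {
  stored <- round((hu - intercept) / slope)
  if (any(stored < 0) || any(stored > 65535))
    stop("stored values out of unsigned 16-bit range for given slope/intercept",
         call. = FALSE)
  w16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con); writeBin(charToRaw("DICM"), con)
  put_str <- function(group, element, vr, s) {
    b <- charToRaw(s)
    if (length(b) %% 2 == 1) b <- c(b, charToRaw(" "))
    w16(group); w16(element); writeBin(charToRaw(vr), con); w16(length(b))
    writeBin(b, con)
  }
  put_u16 <- function(group, element, v) {
    w16(group); w16(element); writeBin(charToRaw("US"), con); w16(2L); w16(v)
  }
  put_str(0x0010, 0x0020, "LO", as.character(patient_id))
  put_str(0x0020, 0x0013, "IS", as.character(instance))
  put_str(0x0020, 0x1041, "DS", as.character(slice_loc))
  put_u16(0x0028, 0x0010, nrow(hu))
  put_u16(0x0028, 0x0011, ncol(hu))
  put_u16(0x0028, 0x0100, 16L)
  put_u16(0x0028, 0x0103, 0L)    # unsigned
  put_str(0x0028, 0x1052, "DS", as.character(intercept))
  put_str(0x0028, 0x1053, "DS", as.character(slope))
  px <- as.integer(t(stored))    # row-major on disk
  w16(0x7FE0); w16(0x0010); writeBin(charToRaw("OW"), con); w16(0L)
  writeBin(as.integer(length(px) * 2L), con, size = 4L, endian = "little")
  # values may exceed signed 16-bit max; write as two bytes each
  writeBin(as.raw(rbind(px %% 256L, px %/% 256L)), con)
  invisible(path)
}
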