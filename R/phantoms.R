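#' Configuration for the synthetic abdominal phantom generator
#'
#' The phantom generator emulates the statistical structure of liver-bearing
#' abdominal CT slices so the whole pipeline can be exercised without patient
#' data: one bright, convex-ish liver region per slice against darker
#' background clutter, optional hypodense tumour blobs inside the liver,
#' additive Gaussian noise, and per-patient stacks whose liver cross-section
#' grows towards mid-volume and shrinks at the ends.
#'
#' Default intensities place the liver (60 +/- 10 HU) and tumours (offset
#' -30 HU) inside the standard abdominal soft-tissue window `[-100, 200]`,
#' with background clutter in the -100..0 HU range.
#'
#' @param height,width Slice dimensions in pixels (>= 16).
#' @param liver_axes_range Length-2 vector: interval for the liver ellipse
#'   semi-axes, in pixels.
#' @param liver_hu_mean,liver_hu_sd Liver parenchyma intensity, HU.
#' @param background_hu_mean,background_hu_sd Background soft-tissue
#'   intensity, HU.
#' @param tumor_probability Probability that a slice carries tumours.
#' @param tumor_count_range Integer interval for the number of tumours on a
#'   tumour-bearing slice.
#' @param tumor_radius_range Interval for tumour radii, pixels.
#' @param tumor_hu_offset Added to liver HU inside tumours (negative =
#'   hypodense).
#' @param clutter_count Number of background clutter ellipses.
#' @param noise_sd Additive Gaussian noise, HU.
#' @param boundary_wobble Maximum relative radial perturbation of the liver
#'   boundary (keeps the region connected and its area analytically
#'   boundable; see [phantom_area_bounds()]).
#' @param seed Integer seed keying the counter-based random stream.
#' @return A `phantom_config` list, validated.
#' @seealso [generate_slice()], [generate_volume()], [generate_dataset()]
#' @export
phantom_config <- function(height = 256L, width = 256L,
                           liver_axes_range = pmax(2, c(round(height * 0.12), round(height * 0.30))),
                           liver_hu_mean = 60, liver_hu_sd = 10,
                           background_hu_mean = -50, background_hu_sd = 25,
                           tumor_probability = 0.5,
                           tumor_count_range = c(1L, 3L),
                           tumor_radius_range = pmax(1, c(round(height * 0.02), round(height * 0.06))),
                           tumor_hu_offset = -30,
                           clutter_count = 6L,
                           noise_sd = 5,
                           boundary_wobble = 0.12,
                           seed = 1L) {
  cfg <- list(height = as.integer(height), width = as.integer(width),
              liver_axes_range = as.numeric(liver_axes_range),
              liver_hu_mean = liver_hu_mean, liver_hu_sd = liver_hu_sd,
              background_hu_mean = background_hu_mean,
              background_hu_sd = background_hu_sd,
              tumor_probability = tumor_probability,
              tumor_count_range = as.integer(tumor_count_range),
              tumor_radius_range = as.numeric(tumor_radius_range),
              tumor_hu_offset = tumor_hu_offset,
              clutter_count = as.integer(clutter_count),
              noise_sd = noise_sd,
              boundary_wobble = boundary_wobble,
              seed = as.integer(seed))
  class(cfg) <- "phantom_config"
  validate_phantom_config(cfg)
  cfg
}

validate_phantom_config <- function(cfg) {
  chk_range <- function(r, name) {
    if (length(r) != 2L || any(!is.finite(r)) || r[1] > r[2] || r[1] <= 0)
      stop(sprintf("phantom_config: invalid `%s` (need nonempty range with low <= high)",
                   name), call. = FALSE)
  }
  if (cfg$height < 16L || cfg$width < 16L)
    stop("phantom_config: `height` and `width` must be >= 16", call. = FALSE)
  chk_range(cfg$liver_axes_range, "liver_axes_range")
  chk_range(cfg$tumor_count_range, "tumor_count_range")
  chk_range(cfg$tumor_radius_range, "tumor_radius_range")
  if (cfg$tumor_probability < 0 || cfg$tumor_probability > 1)
    stop("phantom_config: `tumor_probability` must lie in [0, 1]", call. = FALSE)
  if (cfg$noise_sd < 0)
    stop("phantom_config: `noise_sd` must be >= 0", call. = FALSE)
  if (cfg$boundary_wobble < 0 || cfg$boundary_wobble >= 0.5)
    stop("phantom_config: `boundary_wobble` must lie in [0, 0.5)", call. = FALSE)
  invisible(cfg)
}

# --- counter-based deterministic stream ------------------------------------
# Any slice is reproducible in isolation: the RNG substream is keyed by
# (seed, patient_id, slice_index, role) through an integer mix, so generation
# order never matters.
hash_string <- function(s) {
  v <- utf8ToInt(s)
  h <- 5381
  for (x in v) h <- (h * 33 + x) %% 2147483647
  as.integer(h)
}

mix_seed <- function(seed, pid, idx, role = 0L) {
  h <- (as.double(seed) * 2654435761) %% 2147483647
  h <- (h + as.double(hash_string(as.character(pid))) * 40503) %% 2147483647
  h <- (h + (as.double(idx) + 1) * 97911) %% 2147483647
  h <- (h + as.double(role) * 15485863) %% 2147483647
  as.integer(h)
}

with_stream <- function(stream_seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(stream_seed)
  force(expr)
}

# uniform integer draw that is safe when lo == hi (sample() would treat a
# scalar as 1:n)
sample_int_range <- function(lo, hi) {
  if (lo >= hi) return(as.integer(lo))
  sample(seq.int(lo, hi), 1L)
}

# Boundary radius multiplier: 1 + bounded low-frequency perturbation.
wobble_fun <- function(amplitudes, phases) {
  ks <- seq_along(amplitudes) + 1L
  function(theta) {
    out <- rep(1, length(theta))
    for (i in seq_along(ks))
      out <- out + amplitudes[i] * cos(ks[i] * theta + phases[i])
    out
  }
}

# Rasterise a wobbled ellipse into a 0/1 matrix.
rasterize_blob <- function(h, w, cx, cy, a, b, angle, radial) {
  x <- matrix(rep(seq_len(w), each = h), h, w) - cx
  y <- matrix(rep(seq_len(h), times = w), h, w) - cy
  xr <- cos(angle) * x + sin(angle) * y
  yr <- -sin(angle) * x + cos(angle) * y
  theta <- atan2(yr, xr)
  # ellipse boundary radius at angle theta, scaled by the radial perturbation
  re <- a * b / sqrt((b * cos(theta))^2 + (a * sin(theta))^2)
  inside <- (xr^2 + yr^2) <= (re * radial(theta))^2
  mask <- matrix(0, h, w)
  mask[inside] <- 1
  mask
}

generate_slice_impl <- function(config, patient_id, slice_index, axes_scale = 1) {
  h <- config$height; w <- config$width
  s <- with_stream(mix_seed(config$seed, patient_id, slice_index, 1L), {
    axr <- config$liver_axes_range * axes_scale
    a <- runif(1, axr[1], axr[2])
    b <- runif(1, axr[1], axr[2])
    angle <- runif(1, 0, pi)
    cx <- w / 2 + runif(1, -w / 10, w / 10)
    cy <- h / 2 + runif(1, -h / 10, h / 10)
    n_harm <- 4L
    amp <- runif(n_harm, 0, 1)
    amp <- amp / sum(amp) * runif(1, 0, config$boundary_wobble)
    ph <- runif(n_harm, 0, 2 * pi)
    liver <- rasterize_blob(h, w, cx, cy, a, b, angle, wobble_fun(amp, ph))

    # tumours: hypodense disks fully clipped to the liver
    tumor <- matrix(0, h, w)
    if (runif(1) < config$tumor_probability && sum(liver) > 0) {
      n_t <- sample_int_range(config$tumor_count_range[1], config$tumor_count_range[2])
      inside_idx <- which(liver == 1)
      for (i in seq_len(n_t)) {
        ctr <- arrayInd(inside_idx[sample.int(length(inside_idx), 1L)], c(h, w))
        r <- runif(1, config$tumor_radius_range[1], config$tumor_radius_range[2])
        tumor <- pmax(tumor,
                      rasterize_blob(h, w, ctr[2], ctr[1], r, r, 0, function(t) rep(1, length(t))))
      }
      tumor <- tumor * liver
    }

    # image: background field + clutter + liver + tumours + noise
    img <- matrix(rnorm(h * w, config$background_hu_mean, config$background_hu_sd), h, w)
    for (i in seq_len(config$clutter_count)) {
      ca <- runif(1, h / 30, h / 8); cb <- runif(1, h / 30, h / 8)
      ccx <- runif(1, 1, w); ccy <- runif(1, 1, h)
      cang <- runif(1, 0, pi)
      blob <- rasterize_blob(h, w, ccx, ccy, ca, cb, cang, function(t) rep(1, length(t)))
      blob <- blob * (1 - liver)   # clutter never overwrites the liver
      img[blob == 1] <- img[blob == 1] + runif(1, -50, 50)
    }
    liver_tex <- rnorm(h * w, config$liver_hu_mean, config$liver_hu_sd)
    img[liver == 1] <- liver_tex[liver == 1]
    img[tumor == 1] <- img[tumor == 1] + config$tumor_hu_offset
    if (config$noise_sd > 0) img <- img + rnorm(h * w, 0, config$noise_sd)
    list(img = img, liver = liver, tumor = tumor)
  })
  list(image = ct_slice(s$img, patient_id, slice_index, "raw_hu"),
       liver_mask = binary_mask(s$liver, "liver"),
       tumor_mask = binary_mask(s$tumor, "tumor"),
       patient_id = as.character(patient_id),
       slice_index = as.integer(slice_index))
}

#' Generate one synthetic abdominal CT slice with ground-truth masks
#'
#' Deterministic function of `(config$seed, patient_id, slice_index)`: the
#' generator uses a counter-based substream, so any slice is reproducible in
#' isolation and generation order never matters.
#'
#' @param config A [phantom_config()].
#' @param patient_id Character token entering the random stream.
#' @param slice_index Zero-based slice counter (>= 0).
#' @return A `phantom_slice` list with elements `image` ([ct_slice], HU),
#'   `liver_mask`, `tumor_mask` ([binary_mask]; tumour is always a pixelwise
#'   subset of liver), `patient_id`, `slice_index`.
#' @examples
#' ph <- generate_slice(phantom_config(height = 64, width = 64), "p1", 0)
#' sum(ph$liver_mask$pixels)
#' @export
generate_slice <- function(config, patient_id, slice_index) {
  validate_phantom_config(config)
  if (slice_index < 0) stop("`slice_index` must be >= 0", call. = FALSE)
  out <- generate_slice_impl(config, patient_id, slice_index)
  class(out) <- "phantom_slice"
  out
}

# Smooth axial profile: liver cross-section small at the volume ends,
# largest mid-volume. Deterministic given n.
axial_profile <- function(n) {
  if (n == 1L) return(1)
  t <- (seq_len(n) - 0.5) / n
  0.55 + 0.45 * sin(pi * t)^0.75
}

#' Generate a synthetic patient volume
#'
#' Stacks `n_slices` phantom slices for one patient. The liver semi-axes are
#' modulated by a smooth axial profile so the cross-sectional area is small at
#' the volume ends and largest mid-volume, emulating anatomical variation
#' along a real liver stack.
#'
#' @inheritParams generate_slice
#' @param n_slices Number of slices (>= 1).
#' @return List with `volume` (a [ct_volume]), `liver_masks`, `tumor_masks`
#'   (lists of [binary_mask], slice order).
#' @export
generate_volume <- function(config, patient_id, n_slices) {
  validate_phantom_config(config)
  if (n_slices < 1) stop("`n_slices` must be >= 1", call. = FALSE)
  prof <- axial_profile(n_slices)
  out <- lapply(seq_len(n_slices), function(i)
    generate_slice_impl(config, patient_id, i - 1L, axes_scale = prof[i]))
  list(volume = ct_volume(lapply(out, `[[`, "image"), patient_id),
       liver_masks = lapply(out, `[[`, "liver_mask"),
       tumor_masks = lapply(out, `[[`, "tumor_mask"))
}

#' Write a labelled synthetic dataset to disk
#'
#' Lays out one directory per patient with `images/`, `masks_liver/` and
#' `masks_tumor/` subdirectories and writes a flat JSON manifest. Masks are
#' single-channel PNG with liver pixels stored as 255 and background 0 (the
#' readers binarise any nonzero value to 1). Images are written as 3-channel
#' files, either lossless PNG (default) or JPG.
#'
#' @inheritParams generate_slice
#' @param out_dir Destination directory (created if missing).
#' @param n_patients Number of patients (>= 1).
#' @param slices_per_patient Integer interval; each patient's slice count is
#'   drawn uniformly from it (deterministically under `config$seed`).
#' @param image_format `"png"` (lossless, default) or `"jpg"`.
#' @return The manifest, invisibly: a list with one entry per patient giving
#'   file paths. Also written to `<out_dir>/manifest.json`.
#' @export
generate_dataset <- function(config, out_dir, n_patients,
                             slices_per_patient = c(10L, 10L),
                             image_format = c("png", "jpg")) {
  validate_phantom_config(config)
  image_format <- match.arg(image_format)
  if (n_patients < 1) stop("`n_patients` must be >= 1", call. = FALSE)
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir))
    stop(sprintf("cannot create output directory '%s'", out_dir), call. = FALSE)
  manifest <- list()
  for (p in seq_len(n_patients)) {
    pid <- sprintf("patient%03d", p)
    n_sl <- with_stream(mix_seed(config$seed, pid, 0L, 99L),
                        sample_int_range(slices_per_patient[1],
                                         slices_per_patient[2]))
    vol <- generate_volume(config, pid, n_sl)
    pdir <- file.path(out_dir, pid)
    for (sub in c("images", "masks_liver", "masks_tumor"))
      dir.create(file.path(pdir, sub), showWarnings = FALSE, recursive = TRUE)
    entries <- vector("list", n_sl)
    for (i in seq_len(n_sl)) {
      idx <- i - 1L
      img_path <- file.path(pdir, "images",
                            sprintf("%04d.%s", idx, image_format))
      write_slice_image(vol$volume$slices[[i]], img_path, format = image_format)
      lm_path <- file.path(pdir, "masks_liver", sprintf("%04d.png", idx))
      tm_path <- file.path(pdir, "masks_tumor", sprintf("%04d.png", idx))
      write_mask_png(vol$liver_masks[[i]], lm_path)
      write_mask_png(vol$tumor_masks[[i]], tm_path)
      entries[[i]] <- list(slice_index = idx, image = img_path,
                           mask_liver = lm_path, mask_tumor = tm_path)
    }
    manifest[[pid]] <- entries
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Analytic bounds on the liver-pixel area of generated slices
#'
#' The liver region is an ellipse with semi-axes drawn from
#' `liver_axes_range`, perturbed radially by at most `boundary_wobble`; its
#' area therefore lies between `pi * a_min^2 * (1 - w)^2` and
#' `pi * a_max^2 * (1 + w)^2` (up to rasterisation error, for which a margin
#' argument is provided).
#'
#' @param config A [phantom_config()].
#' @param raster_margin Additive pixel tolerance for rasterisation of the
#'   boundary (default: 4 * perimeter upper bound estimate is overkill; a
#'   flat fraction of the lower bound is used).
#' @return Named numeric vector `c(lower =, upper =)` in pixels.
#' @export
phantom_area_bounds <- function(config, raster_margin = 0.05) {
  a <- config$liver_axes_range
  wob <- config$boundary_wobble
  lower <- pi * a[1]^2 * (1 - wob)^2 * (1 - raster_margin)
  upper <- pi * a[2]^2 * (1 + wob)^2 * (1 + raster_margin)
  c(lower = lower, upper = upper)
}
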