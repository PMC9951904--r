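#' Six-transform paired augmentation policy
#'
#' The augmentation set applied to training pairs: centre crop, clockwise
#' rotation, counter-clockwise rotation, grid distortion, vertical flip, and
#' random brightness/contrast. Each transform produces exactly one extra
#' view, so a dataset of `n` pairs grows to `7n` including the originals.
#' Geometric transforms are applied with identical parameters to image and
#' mask (bilinear for images, nearest-neighbour for masks, background fill
#' 0); photometric transforms never touch the mask.
#'
#' @param crop_fraction Centre-crop side fraction before resizing back
#'   (default 0.875).
#' @param rotate_degrees Magnitude of the clockwise / counter-clockwise
#'   rotations (default 15).
#' @param grid_cells Grid distortion cells per side (default 5).
#' @param grid_magnitude Maximum relative cell-step distortion (default 0.3).
#' @param brightness_delta,contrast_delta Maximum photometric deltas
#'   (default 0.2 each).
#' @param seed Integer seed; augmentation is deterministic under it.
#' @return An `augmentation_policy` object.
#' @export
augmentation_policy <- function(crop_fraction = 0.875, rotate_degrees = 15,
                                grid_cells = 5L, grid_magnitude = 0.3,
                                brightness_delta = 0.2, contrast_delta = 0.2,
                                seed = 1L) {
  stopifnot(crop_fraction > 0, crop_fraction <= 1, rotate_degrees > 0,
            grid_cells >= 2, grid_magnitude >= 0, grid_magnitude < 1)
  structure(list(transforms = c("center_crop", "rotate_cw", "rotate_ccw",
                                "grid_distortion", "vertical_flip",
                                "random_brightness_contrast"),
                 crop_fraction = crop_fraction,
                 rotate_degrees = rotate_degrees,
                 grid_cells = as.integer(grid_cells),
                 grid_magnitude = grid_magnitude,
                 brightness_delta = brightness_delta,
                 contrast_delta = contrast_delta,
                 seed = as.integer(seed)),
            class = "augmentation_policy")
}

# --- warping primitives ----------------------------------------------------
# Sample matrix m at real-valued (row, col) source coordinates.
sample_bilinear <- function(m, sr, sc, fill = 0) {
  h <- nrow(m); w <- ncol(m)
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  get <- function(r, c) {
    ok <- r >= 1 & r <= h & c >= 1 & c <= w
    out <- rep(fill, length(r))
    out[ok] <- m[cbind(r[ok], c[ok])]
    out
  }
  v00 <- get(r0, c0); v01 <- get(r0, c0 + 1)
  v10 <- get(r0 + 1, c0); v11 <- get(r0 + 1, c0 + 1)
  v <- v00 * (1 - fr) * (1 - fc) + v01 * (1 - fr) * fc +
       v10 * fr * (1 - fc) + v11 * fr * fc
  matrix(v, h, w)
}

sample_nearest <- function(m, sr, sc, fill = 0) {
  h <- nrow(m); w <- ncol(m)
  r <- round(sr); c <- round(sc)
  ok <- r >= 1 & r <= h & c >= 1 & c <= w
  out <- rep(fill, length(r))
  out[ok] <- m[cbind(r[ok], c[ok])]
  matrix(out, h, w)
}

warp_pair <- function(img, msk, sr, sc) {
  list(img = sample_bilinear(img, sr, sc),
       msk = (sample_nearest(msk, sr, sc) != 0) * 1)
}

grid_coords <- function(h, w) {
  list(r = rep(seq_len(h), times = w), c = rep(seq_len(w), each = h))
}

rotate_pair <- function(img, msk, degrees) {
  h <- nrow(img); w <- ncol(img)
  th <- degrees * pi / 180
  g <- grid_coords(h, w)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  # inverse map: rotate output coords by -theta around the centre
  dr <- g$r - cy; dc <- g$c - cx
  sr <- cy + cos(th) * dr - sin(th) * dc
  sc <- cx + sin(th) * dr + cos(th) * dc
  warp_pair(img, msk, sr, sc)
}

center_crop_pair <- function(img, msk, fraction) {
  h <- nrow(img); w <- ncol(img)
  g <- grid_coords(h, w)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  sr <- cy + (g$r - cy) * fraction
  sc <- cx + (g$c - cx) * fraction
  warp_pair(img, msk, sr, sc)
}

# Piecewise-linear grid distortion: node steps of a regular grid are
# rescaled by random factors in [1-m, 1+m], then coordinates are remapped
# monotonically (normalised so the image still spans its full extent).
grid_distort_pair <- function(img, msk, cells, magnitude) {
  h <- nrow(img); w <- ncol(img)
  distort_axis <- function(n, cells) {
    steps <- runif(cells, 1 - magnitude, 1 + magnitude)
    nodes0 <- seq(0, 1, length.out = cells + 1)
    nodes1 <- c(0, cumsum(steps))
    nodes1 <- nodes1 / nodes1[length(nodes1)]
    x <- (seq_len(n) - 1) / (n - 1)
    # inverse map: where in the source does each output coordinate sample
    stats::approx(nodes1, nodes0, xout = x, rule = 2)$y * (n - 1) + 1
  }
  sr <- distort_axis(h, cells)
  sc <- distort_axis(w, cells)
  g <- grid_coords(h, w)
  warp_pair(img, msk, sr[g$r], sc[g$c])
}

#' Create the six augmented views of a slice/mask pair
#'
#' @param slice A [ct_slice] (any intensity state).
#' @param mask The paired [binary_mask].
#' @param policy An [augmentation_policy()].
#' @param pair_index Integer folded into the random stream so different
#'   pairs receive different random draws while the whole augmentation stays
#'   deterministic under `policy$seed`.
#' @return A list of six `list(slice =, mask =)` pairs, one per transform,
#'   in the policy's transform order.
#' @export
augment_pair <- function(slice, mask, policy = augmentation_policy(),
                         pair_index = 0L) {
  stopifnot(inherits(policy, "augmentation_policy"))
  img <- as_pixel_matrix(slice); msk <- as_pixel_matrix(mask)
  if (!all(dim(img) == dim(msk)))
    stop("slice and mask dimensions differ", call. = FALSE)
  mk <- function(im, mk_, tag) {
    if (inherits(slice, "ct_slice") && slice$intensity_state == "normalized")
      im <- pmin(pmax(im, 0), 1)   # photometric shifts must stay in [0,1]
    s <- if (inherits(slice, "ct_slice"))
      ct_slice(im, slice$patient_id, slice$slice_index, slice$intensity_state,
               slice$window)
    else im
    m <- if (inherits(mask, "binary_mask")) binary_mask(mk_, mask$label_kind) else mk_
    list(slice = s, mask = m, transform = tag)
  }
  with_stream(mix_seed(policy$seed, "augment", pair_index, 7L), {
    out <- vector("list", 6L)
    p1 <- center_crop_pair(img, msk, policy$crop_fraction)
    out[[1]] <- mk(p1$img, p1$msk, "center_crop")
    p2 <- rotate_pair(img, msk, +policy$rotate_degrees)
    out[[2]] <- mk(p2$img, p2$msk, "rotate_cw")
    p3 <- rotate_pair(img, msk, -policy$rotate_degrees)
    out[[3]] <- mk(p3$img, p3$msk, "rotate_ccw")
    p4 <- grid_distort_pair(img, msk, policy$grid_cells, policy$grid_magnitude)
    out[[4]] <- mk(p4$img, p4$msk, "grid_distortion")
    out[[5]] <- mk(img[nrow(img):1, , drop = FALSE],
                   msk[nrow(msk):1, , drop = FALSE], "vertical_flip")
    b <- runif(1, -policy$brightness_delta, policy$brightness_delta)
    cadj <- runif(1, -policy$contrast_delta, policy$contrast_delta)
    photometric <- (img - mean(img)) * (1 + cadj) + mean(img) + b * diff(range(img))
    out[[6]] <- mk(photometric, msk, "random_brightness_contrast")
    out
  })
}

#' Augment a whole training set of pairs
#'
#' @param pairs List of `list(slice =, mask =)` pairs.
#' @param policy An [augmentation_policy()].
#' @return A list of `7 * length(pairs)` pairs: each original followed by its
#'   six views.
#' @export
augment_dataset <- function(pairs, policy = augmentation_policy()) {
  out <- vector("list", 0L)
  for (i in seq_along(pairs)) {
    p <- pairs[[i]]
    out <- c(out, list(list(slice = p$slice, mask = p$mask, transform = "original")),
             augment_pair(p$slice, p$mask, policy, pair_index = i - 1L))
  }
  out
}
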