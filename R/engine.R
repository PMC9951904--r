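#' @useDynLib aimunet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

BN_EPS <- 1e-3
BN_MOMENTUM <- 0.9

#' Initialise network weights
#'
#' He-normal initialisation for all convolution kernels (sd =
#' `sqrt(2 / fan_in)`), zero biases; batch-norm scale 1, shift 0, running
#' mean 0, running variance 1.
#'
#' @param net An `aim_unet` built by [build_aim_unet()].
#' @param seed Integer seed; identical seeds give identical weights.
#' @return A weight set: list indexed by graph node id.
#' @export
init_weights <- function(net, seed = 1L) {
  stopifnot(inherits(net, "aim_unet"))
  with_stream(as.integer(seed), {
    weights <- vector("list", length(net$graph$nodes))
    for (nd in net$graph$nodes) {
      if (nd$kind %in% c("conv", "output") ||
          (nd$kind == "upsample" && identical(nd$op, "tconv"))) {
        kh <- nd$kernel[1]; kw <- nd$kernel[2]
        fan_in <- kh * kw * nd$cin
        weights[[nd$id]] <- list(
          W = array(rnorm(kh * kw * nd$cin * nd$cout, 0, sqrt(2 / fan_in)),
                    c(kh, kw, nd$cin, nd$cout)),
          b = numeric(nd$cout))
      } else if (nd$kind == "batch_norm") {
        c_ <- nd$channels
        weights[[nd$id]] <- list(gamma = rep(1, c_), beta = numeric(c_),
                                 rmean = numeric(c_), rvar = rep(1, c_))
      }
    }
    weights
  })
}

# --- forward / backward ----------------------------------------------------
# Activations are 4-D arrays (h, w, c, n); per-sample compiled kernels are
# applied in a loop over the batch; batch norm uses joint batch statistics.

apply_act <- function(x, act) {
  switch(act,
         linear = x,
         relu = relu_fw(x),
         sigmoid = 1 / (1 + exp(-x)))
}

forward_graph <- function(net, weights, xbatch, training = FALSE) {
  nodes <- net$graph$nodes
  acts <- vector("list", length(nodes))
  caches <- vector("list", length(nodes))
  for (nd in nodes) {
    id <- nd$id
    val <- switch(nd$kind,
      input = xbatch,
      conv = ,
      output = {
        xin <- acts[[nd$inputs]]
        w <- weights[[id]]
        pre <- conv2d_fw_b(xin, w$W, w$b)
        out <- apply_act(pre, nd$activation)
        caches[[id]] <- list(out = out)
        out
      },
      batch_norm = {
        xin <- acts[[nd$inputs]]
        w <- weights[[id]]
        if (training) {
          mo <- bn_moments(xin, nd$channels)
          mu <- mo$mean
          va <- pmax(mo$m2 - mo$mean^2, 0)
          weights[[id]]$rmean <- BN_MOMENTUM * w$rmean + (1 - BN_MOMENTUM) * mu
          weights[[id]]$rvar <- BN_MOMENTUM * w$rvar + (1 - BN_MOMENTUM) * va
        } else {
          mu <- w$rmean; va <- w$rvar
        }
        pre <- bn_apply(xin, mu, va, w$gamma, w$beta, BN_EPS)
        out <- apply_act(pre, nd$activation)
        caches[[id]] <- list(mu = mu, va = va, training = training, out = out)
        out
      },
      max_pool = {
        xin <- acts[[nd$inputs]]
        r <- maxpool_fw_b(xin, nd$kernel, nd$stride)
        caches[[id]] <- list(argmax = r$argmax, xdim = dim(xin))
        r$y
      },
      upsample = {
        xin <- acts[[nd$inputs]]
        if (identical(nd$op, "tconv")) {
          w <- weights[[id]]
          tconv2d_fw_b(xin, w$W, w$b)
        } else {
          d <- dim(xin)
          idx_r <- rep(seq_len(d[1]), each = 2)
          idx_c <- rep(seq_len(d[2]), each = 2)
          caches[[id]] <- list(d = d)
          xin[idx_r, idx_c, , , drop = FALSE]
        }
      },
      concat = {
        parts <- lapply(nd$inputs, function(i) acts[[i]])
        d1 <- dim(parts[[1]])
        chans <- vapply(parts, function(p) dim(p)[3], numeric(1))
        out <- array(0, c(d1[1], d1[2], sum(chans), d1[4]))
        off <- 0L
        for (p in parts) {
          out[, , off + seq_len(dim(p)[3]), ] <- p
          off <- off + dim(p)[3]
        }
        caches[[id]] <- list(chans = chans)
        out
      },
      dropout = {
        xin <- acts[[nd$inputs]]
        if (training && nd$rate > 0) {
          keep <- array(stats::runif(length(xin)) >= nd$rate, dim(xin))
          caches[[id]] <- list(keep = keep)
          xin * keep / (1 - nd$rate)
        } else {
          caches[[id]] <- list(keep = NULL)
          xin
        }
      },
      stop("unknown node kind: ", nd$kind))
    acts[[id]] <- val
  }
  list(output = acts[[length(nodes)]], acts = acts, caches = caches,
       weights = weights)
}

backward_graph <- function(net, weights, fw, gout) {
  nodes <- net$graph$nodes
  n_nodes <- length(nodes)
  grads_out <- vector("list", n_nodes)
  pgrads <- vector("list", n_nodes)
  grads_out[[n_nodes]] <- gout
  for (id in rev(seq_len(n_nodes))) {
    nd <- nodes[[id]]
    g <- grads_out[[id]]
    if (is.null(g)) next
    cache <- fw$caches[[id]]
    push <- function(to, val) {
      grads_out[[to]] <<- if (is.null(grads_out[[to]])) val
                          else grads_out[[to]] + val
    }
    switch(nd$kind,
      input = {},
      conv = ,
      output = {
        if (nd$activation == "relu") g <- g * (cache$out > 0)
        if (nd$activation == "sigmoid") g <- g * cache$out * (1 - cache$out)
        w <- weights[[id]]
        r <- conv2d_bw_b(fw$acts[[nd$inputs]], w$W, g)
        pgrads[[id]] <- list(W = r$gw, b = r$gb)
        push(nd$inputs, r$gx)
      },
      batch_norm = {
        if (nd$activation == "relu") g <- g * (cache$out > 0)
        w <- weights[[id]]
        r <- bn_backward(fw$acts[[nd$inputs]], g, cache$mu, cache$va,
                         w$gamma, BN_EPS, cache$training)
        pgrads[[id]] <- list(gamma = r$ggamma, beta = r$gbeta)
        push(nd$inputs, r$gx)
      },
      max_pool = {
        push(nd$inputs, maxpool_bw_b(cache$argmax, g,
                                     as.integer(cache$xdim)))
      },
      upsample = {
        if (identical(nd$op, "tconv")) {
          w <- weights[[id]]
          r <- tconv2d_bw_b(fw$acts[[nd$inputs]], w$W, g)
          pgrads[[id]] <- list(W = r$gw, b = r$gb)
          push(nd$inputs, r$gx)
        } else {
          d <- cache$d
          # sum the 2x2 output cells feeding each input cell
          gx <- g[seq(1, 2 * d[1], 2), seq(1, 2 * d[2], 2), , , drop = FALSE] +
                g[seq(2, 2 * d[1], 2), seq(1, 2 * d[2], 2), , , drop = FALSE] +
                g[seq(1, 2 * d[1], 2), seq(2, 2 * d[2], 2), , , drop = FALSE] +
                g[seq(2, 2 * d[1], 2), seq(2, 2 * d[2], 2), , , drop = FALSE]
          push(nd$inputs, gx)
        }
      },
      concat = {
        off <- 0L
        for (i in seq_along(nd$inputs)) {
          ci <- cache$chans[i]
          push(nd$inputs[i], g[, , off + seq_len(ci), , drop = FALSE])
          off <- off + ci
        }
      },
      dropout = {
        if (!is.null(cache$keep)) g <- g * cache$keep / (1 - nd$rate)
        push(nd$inputs, g)
      })
    grads_out[[id]] <- NULL   # free
  }
  pgrads
}

#' Forward pass on a batch of normalised slices
#'
#' @param net An `aim_unet`.
#' @param weights Weight set from [init_weights()] or [train()].
#' @param xbatch 4-D array `(h, w, channels, n)`, or a single matrix /
#'   normalised [ct_slice].
#' @param training Logical; training mode uses batch statistics in batch
#'   norm and applies dropout.
#' @return List with `output` (probability maps, 4-D) and internal state for
#'   the backward pass.
#' @keywords internal
net_forward <- function(net, weights, xbatch, training = FALSE) {
  forward_graph(net, weights, xbatch, training)
}

#' Predict the segmentation probability map for one slice
#'
#' Runs the network in inference mode; output values lie strictly inside
#' (0, 1) (sigmoid head).
#'
#' @param net An `aim_unet`.
#' @param weights Weight set.
#' @param slice A normalised [ct_slice], or a matrix in `[0, 1]`.
#' @return A `probability_map` object: `pixels` in (0,1) plus provenance.
#' @export
predict_slice <- function(net, weights, slice) {
  m <- as_pixel_matrix(slice)
  if (inherits(slice, "ct_slice") && slice$intensity_state != "normalized")
    stop("predict_slice expects a normalized slice", call. = FALSE)
  cfg <- net$config
  if (nrow(m) != cfg$input_height || ncol(m) != cfg$input_width)
    stop(sprintf("inference error: slice is %dx%d but the network expects %dx%d",
                 nrow(m), ncol(m), cfg$input_height, cfg$input_width),
         call. = FALSE)
  x <- array(m, c(nrow(m), ncol(m), 1L, 1L))
  fw <- forward_graph(net, weights, x, training = FALSE)
  probability_map(matrix(fw$output[, , 1, 1], nrow(m), ncol(m)),
                  patient_id = if (inherits(slice, "ct_slice")) slice$patient_id else "anon",
                  slice_index = if (inherits(slice, "ct_slice")) slice$slice_index else 0L)
}

#' Predict probability maps for a list of slices
#'
#' @inheritParams predict_slice
#' @param slices List of normalised slices/matrices; input order is
#'   preserved in the output.
#' @return List of `probability_map` objects.
#' @export
predict_batch <- function(net, weights, slices) {
  lapply(slices, function(s) predict_slice(net, weights, s))
}
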