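#' Binary cross-entropy between a probability map and a binary mask
#'
#' Mean over pixels of `-[g log(p) + (1 - g) log(1 - p)]`, with predictions
#' clipped to `[1e-7, 1 - 1e-7]` before the logarithm.
#'
#' @param pred Probability map (matrix / array / `probability_map`), values
#'   in `[0, 1]`.
#' @param truth Binary mask (matrix / [binary_mask]) of the same shape.
#' @param eps Clipping constant (default `1e-7`).
#' @return Non-negative scalar loss.
#' @export
bce_loss <- function(pred, truth, eps = 1e-7) {
  p <- if (inherits(pred, "probability_map")) pred$pixels else pred
  g <- as_pixel_matrix_or_array(truth)
  if (!all(dim(p) == dim(g)))
    stop("bce_loss: shapes of `pred` and `truth` differ", call. = FALSE)
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(g * log(p) + (1 - g) * log(1 - p))
}

as_pixel_matrix_or_array <- function(x) {
  if (inherits(x, "binary_mask") || inherits(x, "ct_slice")) x$pixels else x
}

#' Training configuration
#'
#' Defaults follow the reference training protocol: Adam with learning rate
#' `1e-3`, batch size 3, 100 epochs, a 0.20 within-training validation
#' division, binary cross-entropy loss, optional early stopping on the
#' validation loss with patience 5 (off by default).
#'
#' @param batch_size Mini-batch size (default 3).
#' @param epochs Training epochs (default 100).
#' @param learning_rate Adam step size (default `1e-3`).
#' @param val_fraction Fraction of the training pairs held out for per-epoch
#'   validation metrics (default 0.20). Set to 0 to validate on the training
#'   set itself (tiny overfit experiments).
#' @param early_stopping Logical: stop when the validation loss has not
#'   improved for `patience` epochs.
#' @param patience Early-stopping patience (default 5).
#' @param seed Integer seed controlling shuffling, weight initialisation and
#'   dropout.
#' @return A `train_config` object.
#' @export
train_config <- function(batch_size = 3L, epochs = 100L,
                         learning_rate = 1e-3, val_fraction = 0.20,
                         early_stopping = FALSE, patience = 5L, seed = 1L) {
  if (batch_size < 1L) stop("`batch_size` must be >= 1", call. = FALSE)
  if (learning_rate <= 0) stop("`learning_rate` must be > 0", call. = FALSE)
  if (val_fraction < 0 || val_fraction >= 1)
    stop("`val_fraction` must lie in [0, 1)", call. = FALSE)
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 optimizer = "adam", loss = "bce",
                 val_fraction = val_fraction,
                 early_stopping = isTRUE(early_stopping),
                 patience = as.integer(patience),
                 seed = as.integer(seed)),
            class = "train_config")
}

# Adam state and update over an arbitrary nested list of parameter arrays.
adam_init <- function(weights) {
  list(m = rapply(weights, function(x) x * 0, how = "replace"),
       v = rapply(weights, function(x) x * 0, how = "replace"),
       t = 0L)
}

adam_step <- function(weights, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (id in seq_along(grads)) {
    gr <- grads[[id]]
    if (is.null(gr)) next
    for (nm in names(gr)) {
      g <- gr[[nm]]
      state$m[[id]][[nm]] <- beta1 * state$m[[id]][[nm]] + (1 - beta1) * g
      state$v[[id]][[nm]] <- beta2 * state$v[[id]][[nm]] + (1 - beta2) * g^2
      mhat <- state$m[[id]][[nm]] / bc1
      vhat <- state$v[[id]][[nm]] / bc2
      weights[[id]][[nm]] <- weights[[id]][[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(weights = weights, state = state)
}

# dataset: list of list(x = matrix in [0,1], y = 0/1 matrix)
as_training_pairs <- function(dataset) {
  lapply(dataset, function(p) {
    x <- as_pixel_matrix_or_array(p$x %||% p$slice)
    y <- as_pixel_matrix_or_array(p$y %||% p$mask)
    if (inherits(p$slice %||% p$x, "ct_slice")) {
      st <- (p$slice %||% p$x)$intensity_state
      if (st != "normalized")
        stop("train: all slices must be normalized before training",
             call. = FALSE)
    }
    if (min(x) < 0 || max(x) > 1)
      stop("train: inputs must lie in [0, 1] (normalize first)", call. = FALSE)
    list(x = x, y = y)
  })
}

batch_metrics <- function(probs, truths, threshold = 0.5) {
  # probs/truths: lists of matrices
  dice <- iou <- rec <- prec <- numeric(length(probs))
  for (i in seq_along(probs)) {
    pm <- (probs[[i]] > threshold) * 1
    cc <- confusion(pm, truths[[i]])
    dice[i] <- dice_from_counts(cc)
    iou[i] <- jaccard_from_counts(cc)
    rec[i] <- recall(cc)
    prec[i] <- precision(cc)
  }
  c(dice = mean(dice), iou = mean(iou), recall = mean(rec),
    precision = mean(prec))
}

#' Train the network
#'
#' Runs the mini-batch protocol: shuffled batches, Adam updates on the
#' binary cross-entropy, per-epoch loss and thresholded Dice/IoU/recall/
#' precision on the held-out validation fraction, optional early stopping
#' on validation loss, and retention of the best-validation-loss weights.
#' With a fixed seed the run is reproducible on one machine.
#'
#' @param net An `aim_unet` from [build_aim_unet()].
#' @param dataset List of `list(x = , y = )` pairs (normalised slice and
#'   0/1 mask, matrices or package objects), all at the network input size.
#' @param config A [train_config()].
#' @param weights Optional starting weights (default: fresh
#'   [init_weights()] under `config$seed`).
#' @param max_steps Optional cap on the total number of optimisation steps
#'   (for bounded experiments); `Inf` = no cap.
#' @param target_dice Optional early exit: stop once the epoch's evaluated
#'   Dice reaches this value.
#' @param verbose Print one line per epoch.
#' @return List with `weights` (best by validation loss; final weights if no
#'   validation set), `history` (data frame: epoch, loss, val_loss, dice,
#'   iou, recall, precision) and `steps` (optimisation steps executed).
#' @export
train <- function(net, dataset, config = train_config(), weights = NULL,
                  max_steps = Inf, target_dice = NULL, verbose = FALSE) {
  stopifnot(inherits(net, "aim_unet"), inherits(config, "train_config"))
  if (!length(dataset)) stop("train: empty dataset", call. = FALSE)
  pairs <- as_training_pairs(dataset)
  hdim <- c(net$config$input_height, net$config$input_width)
  for (p in pairs)
    if (!all(dim(p$x) == hdim))
      stop("train: all slices must match the network input size", call. = FALSE)
  if (is.null(weights)) weights <- init_weights(net, config$seed)
  history <- data.frame()
  if (config$epochs == 0L)
    return(list(weights = weights, history = history, steps = 0L))

  with_stream(mix_seed(config$seed, "train", 0L, 3L), {
    n <- length(pairs)
    n_val <- floor(config$val_fraction * n)
    idx <- sample(n)
    val_idx <- if (n_val > 0) idx[seq_len(n_val)] else integer(0)
    tr_idx <- if (n_val > 0) idx[-seq_len(n_val)] else idx
    if (!length(tr_idx)) stop("train: no training pairs left after the validation split",
                              call. = FALSE)
    state <- adam_init(weights)
    best <- list(loss = Inf, weights = weights)
    wait <- 0L
    steps <- 0L
    eval_set <- function(w, which_idx) {
      probs <- list(); truths <- list(); losses <- numeric(0)
      for (i in which_idx) {
        x <- array(pairs[[i]]$x, c(hdim, 1L, 1L))
        fw <- forward_graph(net, w, x, training = FALSE)
        pm <- matrix(fw$output[, , 1, 1], hdim[1], hdim[2])
        probs <- c(probs, list(pm)); truths <- c(truths, list(pairs[[i]]$y))
        losses <- c(losses, bce_loss(pm, pairs[[i]]$y))
      }
      c(loss = mean(losses), batch_metrics(probs, truths))
    }
    for (epoch in seq_len(config$epochs)) {
      ord <- sample(tr_idx)
      ep_losses <- numeric(0)
      for (b0 in seq(1, length(ord), config$batch_size)) {
        if (steps >= max_steps) break
        bidx <- ord[b0:min(b0 + config$batch_size - 1L, length(ord))]
        nb <- length(bidx)
        x <- array(0, c(hdim, 1L, nb))
        y <- array(0, c(hdim, 1L, nb))
        for (s in seq_len(nb)) {
          x[, , 1, s] <- pairs[[bidx[s]]]$x
          y[, , 1, s] <- pairs[[bidx[s]]]$y
        }
        fw <- forward_graph(net, weights, x, training = TRUE)
        weights <- fw$weights           # running BN statistics advanced
        p <- pmin(pmax(fw$output, 1e-7), 1 - 1e-7)
        loss <- -mean(y * log(p) + (1 - y) * log(1 - p))
        gout <- (p - y) / (p * (1 - p)) / length(y)   # d(BCE)/d(prob)
        grads <- backward_graph(net, weights, fw, gout)
        upd <- adam_step(weights, grads, state, config$learning_rate)
        weights <- upd$weights; state <- upd$state
        steps <- steps + 1L
        ep_losses <- c(ep_losses, loss)
      }
      ev_idx <- if (length(val_idx)) val_idx else tr_idx
      ev <- eval_set(weights, ev_idx)
      history <- rbind(history, data.frame(
        epoch = epoch, loss = mean(ep_losses), val_loss = ev[["loss"]],
        dice = ev[["dice"]], iou = ev[["iou"]], recall = ev[["recall"]],
        precision = ev[["precision"]]))
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  val %.4f  dice %.4f",
                        epoch, mean(ep_losses), ev[["loss"]], ev[["dice"]]))
      if (ev[["loss"]] < best$loss - 1e-9) {
        best <- list(loss = ev[["loss"]], weights = weights)
        wait <- 0L
      } else wait <- wait + 1L
      if (config$early_stopping && wait >= config$patience) break
      if (!is.null(target_dice) && ev[["dice"]] >= target_dice) break
      if (steps >= max_steps) break
    }
    list(weights = if (length(val_idx)) best$weights else weights,
         history = history, steps = steps)
  })
}
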