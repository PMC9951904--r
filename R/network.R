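#' Specification of one inception module part (IMP)
#'
#' Each skip connection carries an IMP: two repetitions of a four-branch
#' block (1x1; 1x1 then 5x5; 1x1 then 3x3 then 3x3; 3x3 max-pool stride 1
#' then 1x1) whose outputs are concatenated, followed by two closing 3x3
#' convolutions. Batch normalisation and ReLU follow every convolution.
#' All spatial dimensions are preserved (stride 1, same padding).
#'
#' @param branch_filters Output channels of each of the four branches (one
#'   repetition).
#' @param reduce_filters Channels of the 1x1 reduction convolutions and of
#'   the middle 3x3 convolution in the double-3x3 branch.
#' @param tail_filters Length-2 integer vector: channels of the two closing
#'   3x3 convolutions.
#' @param pool_kernel Kernel of the shape-preserving max-pool branch
#'   (stride 1, default 3).
#' @return An `imp_spec` object.
#' @export
imp_spec <- function(branch_filters, reduce_filters, tail_filters,
                     pool_kernel = 3L) {
  spec <- list(branch_filters = as.integer(branch_filters),
               reduce_filters = as.integer(reduce_filters),
               tail_filters = as.integer(tail_filters),
               pool_kernel = as.integer(pool_kernel))
  if (spec$branch_filters < 1L || spec$reduce_filters < 1L ||
      any(spec$tail_filters < 1L))
    stop("imp_spec: all filter counts must be >= 1", call. = FALSE)
  if (length(spec$tail_filters) != 2L)
    stop("imp_spec: `tail_filters` must have length 2", call. = FALSE)
  structure(spec, class = "imp_spec")
}

#' Default per-level IMP specifications
#'
#' The shipped widths for the full-size network (base 64 filters, depth 4)
#' are calibrated so that the complete per-layer parameter accounting
#' reproduces the published totals of the architecture (41,695,169
#' parameters, 23,040 of them non-trainable, 188 graph nodes); see the
#' methods vignette for the calibration. For reduced configurations the
#' widths are scaled proportionally to `base_filters` (floor 1) and the tail
#' widths follow the encoder width at each level.
#'
#' @param depth Number of skip levels.
#' @param base_filters First-stage encoder filters.
#' @param growth Per-stage filter multiplier.
#' @return List of [imp_spec] objects, one per level.
#' @export
default_imp_specs <- function(depth = 4L, base_filters = 64L, growth = 2L) {
  calib_b <- c(256L, 160L, 16L, 8L)
  calib_r <- c(8L, 8L, 208L, 128L)
  scale <- base_filters / 64
  lapply(seq_len(depth), function(k) {
    i <- min(k, 4L)
    ck <- as.integer(base_filters * growth^(k - 1))
    imp_spec(branch_filters = max(1L, round(calib_b[i] * scale)),
             reduce_filters = max(1L, round(calib_r[i] * scale)),
             tail_filters = c(ck, ck))
  })
}

#' Network configuration
#'
#' Defaults build the full-size network: 256x256x1 input, four encoder /
#' decoder stages with 64/128/256/512 filters, a 1024-filter bottleneck, an
#' IMP on each of the four skip connections, 2x2 transposed-convolution
#' upsampling, and a 1x1 sigmoid head. Batch normalisation is placed on the
#' IMP convolutions plus the contracting path (encoder and bottleneck); the
#' placement is configurable because it changes the non-trainable parameter
#' total.
#'
#' @param input_height,input_width Input size in pixels; must be divisible
#'   by `2^depth`.
#' @param input_channels Input channels (1 for CT).
#' @param depth Number of encoder/decoder stages (default 4).
#' @param base_filters First-stage filters (default 64).
#' @param growth Per-stage filter multiplier (default 2).
#' @param imp_specs List of [imp_spec], one per skip level;
#'   `NULL` = [default_imp_specs()].
#' @param upsample_mode `"transposed_conv"` (2x2, stride 2) or
#'   `"upsample_then_conv"` (nearest upsampling followed by a 2x2
#'   convolution; same parameter count, one extra graph node per stage).
#' @param bn_placement Where batch normalisation lives:
#'   `"contracting"` (IMPs + encoder + bottleneck; default), `"imp_only"`,
#'   or `"everywhere"` (also decoder convolutions).
#' @param dropout_rate Rate of the two dropout nodes (end of the last
#'   encoder stage and of the bottleneck); 0 disables dropping while the
#'   nodes remain in the graph.
#' @param output_channels Output channels (1: binary liver/tumour map).
#' @return A `network_config` object.
#' @export
network_config <- function(input_height = 256L, input_width = 256L,
                           input_channels = 1L, depth = 4L,
                           base_filters = 64L, growth = 2L,
                           imp_specs = NULL,
                           upsample_mode = c("transposed_conv",
                                             "upsample_then_conv"),
                           bn_placement = c("contracting", "imp_only",
                                            "everywhere"),
                           dropout_rate = 0,
                           output_channels = 1L) {
  upsample_mode <- match.arg(upsample_mode)
  bn_placement <- match.arg(bn_placement)
  if (is.null(imp_specs))
    imp_specs <- default_imp_specs(depth, base_filters, growth)
  cfg <- list(input_height = as.integer(input_height),
              input_width = as.integer(input_width),
              input_channels = as.integer(input_channels),
              depth = as.integer(depth),
              base_filters = as.integer(base_filters),
              growth = as.integer(growth),
              imp_specs = imp_specs,
              upsample_mode = upsample_mode,
              bn_placement = bn_placement,
              dropout_rate = dropout_rate,
              output_channels = as.integer(output_channels))
  class(cfg) <- "network_config"
  validate_network_config(cfg)
  cfg
}

validate_network_config <- function(cfg) {
  if (cfg$base_filters < 1L) stop("`base_filters` must be >= 1", call. = FALSE)
  if (cfg$depth < 1L) stop("`depth` must be >= 1", call. = FALSE)
  div <- 2^cfg$depth
  if (cfg$input_height %% div != 0L || cfg$input_width %% div != 0L)
    stop(sprintf("input dimensions must be divisible by 2^depth = %d", div),
         call. = FALSE)
  if (length(cfg$imp_specs) != cfg$depth)
    stop("`imp_specs` must contain one spec per skip level", call. = FALSE)
  if (!all(vapply(cfg$imp_specs, inherits, logical(1), "imp_spec")))
    stop("`imp_specs` entries must be imp_spec objects", call. = FALSE)
  if (cfg$dropout_rate < 0 || cfg$dropout_rate >= 1)
    stop("`dropout_rate` must lie in [0, 1)", call. = FALSE)
  invisible(cfg)
}

# --- graph builder ---------------------------------------------------------
# Nodes carry everything both views need: the layer table (kind, shapes,
# parameter counts) and the runtime executor (op metadata, input edges).

new_graph <- function() {
  env <- new.env(parent = emptyenv())
  env$nodes <- list()
  env
}

add_node <- function(g, kind, name, inputs, out_shape,
                     n_train = 0, n_nontrain = 0, ...) {
  id <- length(g$nodes) + 1L
  in_shape <- if (length(inputs)) g$nodes[[inputs[1]]]$out_shape else NULL
  g$nodes[[id]] <- c(list(id = id, kind = kind, name = name,
                          inputs = as.integer(inputs),
                          in_shape = in_shape, out_shape = out_shape,
                          n_train = n_train, n_nontrain = n_nontrain),
                     list(...))
  id
}

# conv (+ optional BN node) + activation attribute on the last value node
add_conv <- function(g, name, input, kh, kw, cout, bn, act = "relu") {
  sh <- g$nodes[[input]]$out_shape
  cin <- sh[3]
  id <- add_node(g, "conv", name, input, c(sh[1], sh[2], cout),
                 n_train = kh * kw * cin * cout + cout,
                 kernel = c(kh, kw), cin = cin, cout = cout,
                 activation = if (bn) "linear" else act)
  if (bn)
    id <- add_node(g, "batch_norm", paste0(name, "_bn"), id,
                   c(sh[1], sh[2], cout),
                   n_train = 2 * cout, n_nontrain = 2 * cout,
                   channels = cout, activation = act)
  id
}

add_imp_nodes <- function(g, input, level, spec) {
  prefix <- sprintf("imp%d", level)
  b <- spec$branch_filters; r <- spec$reduce_filters
  x <- input
  for (rep in 1:2) {
    p <- sprintf("%s_r%d", prefix, rep)
    b1 <- add_conv(g, paste0(p, "_b1_1x1"), x, 1, 1, b, bn = TRUE)
    b2 <- add_conv(g, paste0(p, "_b2_1x1"), x, 1, 1, r, bn = TRUE)
    b2 <- add_conv(g, paste0(p, "_b2_5x5"), b2, 5, 5, b, bn = TRUE)
    b3 <- add_conv(g, paste0(p, "_b3_1x1"), x, 1, 1, r, bn = TRUE)
    b3 <- add_conv(g, paste0(p, "_b3_3x3a"), b3, 3, 3, r, bn = TRUE)
    b3 <- add_conv(g, paste0(p, "_b3_3x3b"), b3, 3, 3, b, bn = TRUE)
    sh <- g$nodes[[x]]$out_shape
    pl <- add_node(g, "max_pool", paste0(p, "_pool"), x, sh,
                   kernel = spec$pool_kernel, stride = 1L)
    b4 <- add_conv(g, paste0(p, "_b4_1x1"), pl, 1, 1, b, bn = TRUE)
    x <- add_node(g, "concat", paste0(p, "_concat"), c(b1, b2, b3, b4),
                  c(sh[1], sh[2], 4L * b))
  }
  x <- add_conv(g, paste0(prefix, "_tail1"), x, 3, 3, spec$tail_filters[1],
                bn = TRUE)
  add_conv(g, paste0(prefix, "_tail2"), x, 3, 3, spec$tail_filters[2],
           bn = TRUE)
}

aim_unet_graph <- function(cfg) {
  g <- new_graph()
  bn_enc <- cfg$bn_placement %in% c("contracting", "everywhere")
  bn_dec <- cfg$bn_placement == "everywhere"
  x <- add_node(g, "input", "input", integer(0),
                c(cfg$input_height, cfg$input_width, cfg$input_channels))
  skips <- integer(cfg$depth)
  filters <- cfg$base_filters * cfg$growth^(seq_len(cfg$depth) - 1L)
  for (k in seq_len(cfg$depth)) {
    x <- add_conv(g, sprintf("enc%d_conv1", k), x, 3, 3, filters[k], bn_enc)
    x <- add_conv(g, sprintf("enc%d_conv2", k), x, 3, 3, filters[k], bn_enc)
    skips[k] <- x
    if (k == cfg$depth)
      x <- add_node(g, "dropout", sprintf("enc%d_dropout", k), x,
                    g$nodes[[x]]$out_shape, rate = cfg$dropout_rate)
    sh <- g$nodes[[x]]$out_shape
    x <- add_node(g, "max_pool", sprintf("enc%d_pool", k), x,
                  c(sh[1] %/% 2L, sh[2] %/% 2L, sh[3]),
                  kernel = 2L, stride = 2L)
  }
  base_f <- cfg$base_filters * cfg$growth^cfg$depth
  x <- add_conv(g, "base_conv1", x, 3, 3, base_f, bn_enc)
  x <- add_conv(g, "base_conv2", x, 3, 3, base_f, bn_enc)
  x <- add_node(g, "dropout", "base_dropout", x, g$nodes[[x]]$out_shape,
                rate = cfg$dropout_rate)
  imps <- vapply(seq_len(cfg$depth), function(k)
    add_imp_nodes(g, skips[k], k, cfg$imp_specs[[k]]), integer(1))
  for (k in rev(seq_len(cfg$depth))) {
    sh <- g$nodes[[x]]$out_shape
    cout <- filters[k]
    if (cfg$upsample_mode == "transposed_conv") {
      x <- add_node(g, "upsample", sprintf("dec%d_up", k), x,
                    c(sh[1] * 2L, sh[2] * 2L, cout),
                    n_train = 2 * 2 * sh[3] * cout + cout,
                    op = "tconv", kernel = c(2L, 2L), cin = sh[3], cout = cout)
    } else {
      x <- add_node(g, "upsample", sprintf("dec%d_up", k), x,
                    c(sh[1] * 2L, sh[2] * 2L, sh[3]), op = "nearest")
      x <- add_conv(g, sprintf("dec%d_upconv", k), x, 2, 2, cout, bn = FALSE)
    }
    esh <- g$nodes[[skips[k]]]$out_shape
    ish <- g$nodes[[imps[k]]]$out_shape
    x <- add_node(g, "concat", sprintf("dec%d_concat", k),
                  c(skips[k], imps[k], x),
                  c(esh[1], esh[2], esh[3] + ish[3] + cout))
    x <- add_conv(g, sprintf("dec%d_conv1", k), x, 3, 3, cout, bn_dec)
    x <- add_conv(g, sprintf("dec%d_conv2", k), x, 3, 3, cout, bn_dec)
  }
  sh <- g$nodes[[x]]$out_shape
  add_node(g, "output", "head_1x1_sigmoid", x,
           c(sh[1], sh[2], cfg$output_channels),
           n_train = sh[3] * cfg$output_channels + cfg$output_channels,
           kernel = c(1L, 1L), cin = sh[3], cout = cfg$output_channels,
           activation = "sigmoid")
  g
}

graph_layer_table <- function(g) {
  fmt <- function(s) if (is.null(s)) "" else paste(s, collapse = "x")
  data.frame(
    name = vapply(g$nodes, `[[`, character(1), "name"),
    kind = vapply(g$nodes, `[[`, character(1), "kind"),
    input_shape = vapply(g$nodes, function(n) fmt(n$in_shape), character(1)),
    output_shape = vapply(g$nodes, function(n) fmt(n$out_shape), character(1)),
    n_trainable = vapply(g$nodes, function(n) as.numeric(n$n_train), numeric(1)),
    n_non_trainable = vapply(g$nodes, function(n) as.numeric(n$n_nontrain),
                             numeric(1)),
    stringsAsFactors = FALSE)
}

graph_edges <- function(g) {
  do.call(rbind, lapply(g$nodes, function(n)
    if (length(n$inputs))
      data.frame(from = n$inputs, to = n$id) else NULL))
}

#' Build the full network description
#'
#' Constructs the complete computation graph -- encoder, bottleneck, one IMP
#' per skip connection, decoder, sigmoid head -- and records every node as a
#' layer with its shapes and trainable / non-trainable parameter counts.
#' Layer counting convention: every graph node of kind input, convolution,
#' batch normalisation, max-pool, upsampling, concatenation, dropout or
#' output counts as one layer; ReLU/sigmoid activations are attributes of
#' the node that produces the activation, not separate nodes.
#'
#' @param config A [network_config()].
#' @return An `aim_unet` object with elements `config`, `layers` (the layer
#'   table), `edges`, `totals` (`n_layers`, `total`, `trainable`,
#'   `non_trainable`) and the internal node graph used by the runtime.
#' @examples
#' net <- build_aim_unet(network_config(input_height = 64, input_width = 64,
#'                                      base_filters = 8))
#' net$totals
#' @export
build_aim_unet <- function(config = network_config()) {
  validate_network_config(config)
  g <- aim_unet_graph(config)
  layers <- graph_layer_table(g)
  totals <- list(n_layers = nrow(layers),
                 total = sum(layers$n_trainable) + sum(layers$n_non_trainable),
                 trainable = sum(layers$n_trainable),
                 non_trainable = sum(layers$n_non_trainable))
  structure(list(config = config, graph = g, layers = layers,
                 edges = graph_edges(g), totals = totals),
            class = "aim_unet")
}

#' Build one standalone IMP subgraph description
#'
#' Useful for structural audits: the returned layer table contains exactly
#' 16 convolutions (7 per repetition x 2, plus the two closing 3x3
#' convolutions), 2 concatenations and 2 stride-1 pools, all
#' shape-preserving.
#'
#' @param level Skip level index (names the layers).
#' @param in_channels Channels of the incoming encoder feature map.
#' @param spec An [imp_spec()].
#' @param input_size Spatial size used for the shape records.
#' @return A list with `layers` (layer table) and `totals`, as in
#'   [build_aim_unet()].
#' @export
build_imp <- function(level, in_channels, spec, input_size = c(64L, 64L)) {
  if (in_channels < 1L) stop("`in_channels` must be >= 1", call. = FALSE)
  stopifnot(inherits(spec, "imp_spec"))
  g <- new_graph()
  x <- add_node(g, "input", "input", integer(0),
                c(input_size[1], input_size[2], as.integer(in_channels)))
  add_imp_nodes(g, x, level, spec)
  layers <- graph_layer_table(g)
  list(layers = layers,
       totals = list(n_layers = nrow(layers),
                     total = sum(layers$n_trainable) + sum(layers$n_non_trainable),
                     trainable = sum(layers$n_trainable),
                     non_trainable = sum(layers$n_non_trainable)))
}

#' Parameter totals of a built network
#'
#' @param net An `aim_unet` object.
#' @return Named numeric vector `c(total, trainable, non_trainable)`;
#'   `total = trainable + non_trainable` always.
#' @export
count_parameters <- function(net) {
  stopifnot(inherits(net, "aim_unet"))
  c(total = net$totals$total, trainable = net$totals$trainable,
    non_trainable = net$totals$non_trainable)
}

#' @export
print.aim_unet <- function(x, ...) {
  cat(sprintf("<aim_unet  input %dx%dx%d  depth %d  base %d>\n",
              x$config$input_height, x$config$input_width,
              x$config$input_channels, x$config$depth, x$config$base_filters))
  cat(sprintf("  layers: %d   parameters: %s (%s trainable, %s non-trainable)\n",
              x$totals$n_layers,
              format(x$totals$total, big.mark = ","),
              format(x$totals$trainable, big.mark = ","),
              format(x$totals$non_trainable, big.mark = ",")))
  invisible(x)
}

#' Layer table of a built network as a data frame
#'
#' @param x An `aim_unet` object.
#' @param ... Unused.
#' @return The layer table (one row per graph node).
#' @export
as.data.frame.aim_unet <- function(x, ...) x$layers
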