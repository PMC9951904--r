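# shared fixtures: tiny configs and an independent closed-form parameter
# oracle used to audit the graph builder's accounting

tiny_phantom_config <- function(side = 32L, ...) {
  phantom_config(height = side, width = side, seed = 11L, ...)
}

tiny_network_config <- function(side = 16L, base = 2L, depth = 2L, ...) {
  network_config(input_height = side, input_width = side,
                 base_filters = base, depth = depth,
                 imp_specs = lapply(seq_len(depth), function(k)
                   imp_spec(base, base, rep(base * 2L^(k - 1L), 2L))),
                 ...)
}

# spreadsheet-style per-layer oracle: sums kh*kw*cin*cout + cout per conv
# and 2C trainable + 2C non-trainable per batch-normalised conv, following
# the architecture layout but sharing no code with the builder.
oracle_param_totals <- function(cfg) {
  f <- cfg$base_filters * cfg$growth^(0:(cfg$depth - 1))
  conv_p <- function(k, cin, cout) k * k * cin * cout + cout
  tr <- 0; nt <- 0
  bn_enc <- cfg$bn_placement %in% c("contracting", "everywhere")
  bn_dec <- cfg$bn_placement == "everywhere"
  add_bn <- function(ch) { tr <<- tr + 2 * ch; nt <<- nt + 2 * ch }
  cin <- cfg$input_channels
  for (k in seq_len(cfg$depth)) {
    tr <- tr + conv_p(3, cin, f[k]) + conv_p(3, f[k], f[k])
    if (bn_enc) { add_bn(f[k]); add_bn(f[k]) }
    cin <- f[k]
  }
  fb <- cfg$base_filters * cfg$growth^cfg$depth
  tr <- tr + conv_p(3, cin, fb) + conv_p(3, fb, fb)
  if (bn_enc) { add_bn(fb); add_bn(fb) }
  for (k in seq_len(cfg$depth)) {
    sp <- cfg$imp_specs[[k]]
    C <- f[k]; b <- sp$branch_filters; r <- sp$reduce_filters
    for (rep in 1:2) {
      W <- if (rep == 1) C else 4 * b
      tr <- tr + conv_p(1, W, b) + conv_p(1, W, r) + conv_p(5, r, b) +
            conv_p(1, W, r) + conv_p(3, r, r) + conv_p(3, r, b) +
            conv_p(1, W, b)
      for (ch in c(b, r, b, r, r, b, b)) add_bn(ch)
    }
    tr <- tr + conv_p(3, 4 * b, sp$tail_filters[1]) +
          conv_p(3, sp$tail_filters[1], sp$tail_filters[2])
    add_bn(sp$tail_filters[1]); add_bn(sp$tail_filters[2])
  }
  up_in <- fb
  for (k in rev(seq_len(cfg$depth))) {
    C <- f[k]
    tr <- tr + if (cfg$upsample_mode == "transposed_conv")
      2 * 2 * up_in * C + C else conv_p(2, up_in, C)
    dec_in <- C + cfg$imp_specs[[k]]$tail_filters[2] + C
    tr <- tr + conv_p(3, dec_in, C) + conv_p(3, C, C)
    if (bn_dec) { add_bn(C); add_bn(C) }
    up_in <- C
  }
  tr <- tr + f[1] * cfg$output_channels + cfg$output_channels
  c(total = tr + nt, trainable = tr, non_trainable = nt)
}

random_binary_mask <- function(h = 8L, w = 8L, p = 0.4) {
  matrix(rbinom(h * w, 1, p), h, w)
}
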