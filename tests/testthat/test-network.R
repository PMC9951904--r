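test_that("each IMP contains 16 convolutions, 2 concats, 2 stride-1 pools", {
  spec <- imp_spec(8, 4, c(16, 16))
  sub <- build_imp(1, 8, spec, input_size = c(32L, 32L))
  kinds <- table(sub$layers$kind)
  expect_equal(unname(kinds["conv"]), 16)
  expect_equal(unname(kinds["concat"]), 2)
  expect_equal(unname(kinds["max_pool"]), 2)
  expect_equal(unname(kinds["batch_norm"]), 16)
  # spatial dims preserved end-to-end
  out_shapes <- sub$layers$output_shape[sub$layers$kind != "input"]
  expect_true(all(grepl("^32x32x", out_shapes)))
})

test_that("skip level 1 of the full net concatenates to the published width", {
  net <- build_aim_unet(network_config())
  tail2 <- net$layers[net$layers$name == "imp1_tail2_bn", ]
  expect_equal(tail2$output_shape, "256x256x64")
  cc <- net$layers[net$layers$name == "dec1_concat", ]
  # encoder 64 + IMP 64 = 128 published skip filters, + 64 upsampled
  expect_equal(cc$output_shape, "256x256x192")
})

test_that("shape conservation holds for arbitrary valid input sizes", {
  for (side in c(16L, 48L)) {
    cfg <- tiny_network_config(side = side)
    net <- build_aim_unet(cfg)
    out <- net$layers[nrow(net$layers), ]
    expect_equal(out$output_shape, sprintf("%dx%dx1", side, side))
  }
})

test_that("parameter totals are invariant to spatial input size", {
  a <- build_aim_unet(network_config(input_height = 256, input_width = 256))
  b <- build_aim_unet(network_config(input_height = 64, input_width = 64))
  expect_identical(count_parameters(a), count_parameters(b))
})

test_that("accounting identity holds and matches the closed-form oracle", {
  set.seed(31)
  for (trial in 1:6) {
    depth <- sample(2:3, 1)
    base <- sample(c(2L, 4L, 8L), 1)
    specs <- lapply(seq_len(depth), function(k)
      imp_spec(sample(2:8, 1), sample(2:8, 1),
               rep(base * 2L^(k - 1L), 2L)))
    cfg <- network_config(input_height = 32, input_width = 32,
                          base_filters = base, depth = depth,
                          imp_specs = specs,
                          upsample_mode = sample(c("transposed_conv",
                                                   "upsample_then_conv"), 1),
                          bn_placement = sample(c("contracting", "imp_only",
                                                  "everywhere"), 1))
    net <- build_aim_unet(cfg)
    got <- count_parameters(net)
    expect_equal(got[["total"]], got[["trainable"]] + got[["non_trainable"]])
    want <- oracle_param_totals(cfg)
    expect_equal(got[["total"]], want[["total"]])
    expect_equal(got[["trainable"]], want[["trainable"]])
    expect_equal(got[["non_trainable"]], want[["non_trainable"]])
  }
})

test_that("non-trainable total equals twice the batch-normalised channels", {
  net <- build_aim_unet(network_config())
  bn_rows <- net$layers[net$layers$kind == "batch_norm", ]
  chans <- as.integer(sub(".*x", "", bn_rows$output_shape))
  expect_equal(net$totals$non_trainable, 2 * sum(chans))
})

test_that("invalid configurations are rejected", {
  expect_error(network_config(input_height = 100), "divisible")
  expect_error(network_config(imp_specs = list(imp_spec(1, 1, c(1, 1)))),
               "one spec per skip level")
  expect_error(imp_spec(0, 1, c(1, 1)), ">= 1")
})

test_that("single conv / batch-norm parameter counts follow the closed forms", {
  sub <- build_imp(1, 1, imp_spec(8, 8, c(8, 8)), input_size = c(16L, 16L))
  conv1 <- sub$layers[sub$layers$name == "imp1_r1_b1_1x1", ]
  expect_equal(conv1$n_trainable, 1 * 1 * 1 * 8 + 8)
  bn1 <- sub$layers[sub$layers$name == "imp1_r1_b1_1x1_bn", ]
  expect_equal(bn1$n_trainable, 16)
  expect_equal(bn1$n_non_trainable, 16)
  t1 <- sub$layers[sub$layers$name == "imp1_tail1", ]
  expect_equal(t1$n_trainable, 3 * 3 * 32 * 8 + 8)
})
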