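# runtime audit: compiled kernels against naive per-sample references, and
# analytic gradients against finite differences on a tiny graph

test_that("batched convolution matches the per-sample kernels exactly", {
  set.seed(5)
  h <- 6L; w <- 7L; cin <- 3L; cout <- 4L; n <- 3L
  x <- array(rnorm(h * w * cin * n), c(h, w, cin, n))
  for (k in c(1L, 3L, 5L)) {
    W <- array(rnorm(k * k * cin * cout), c(k, k, cin, cout))
    b <- rnorm(cout)
    yb <- aimunet:::conv2d_fw_b(x, W, b)
    gy <- array(rnorm(h * w * cout * n), c(h, w, cout, n))
    rb <- aimunet:::conv2d_bw_b(x, W, gy)
    gWs <- array(0, dim(W)); gbs <- numeric(cout)
    for (s in seq_len(n)) {
      xs <- array(x[, , , s], c(h, w, cin))
      expect_equal(yb[, , , s],
                   aimunet:::conv2d_fw(xs, W, b), tolerance = 1e-12)
      r1 <- aimunet:::conv2d_bw(xs, W, array(gy[, , , s], c(h, w, cout)))
      expect_equal(rb$gx[, , , s], r1$gx, tolerance = 1e-12)
      gWs <- gWs + r1$gw; gbs <- gbs + r1$gb
    }
    expect_equal(rb$gw, gWs, tolerance = 1e-10)
    expect_equal(rb$gb, gbs, tolerance = 1e-10)
  }
})

test_that("convolution agrees with a naive direct-loop oracle", {
  set.seed(6)
  h <- 5L; w <- 5L; cin <- 2L; cout <- 2L; k <- 3L
  x <- array(rnorm(h * w * cin), c(h, w, cin))
  W <- array(rnorm(k * k * cin * cout), c(k, k, cin, cout))
  b <- rnorm(cout)
  y <- aimunet:::conv2d_fw(x, W, b)
  naive <- array(0, c(h, w, cout))
  for (co in 1:cout) for (i in 1:h) for (j in 1:w) {
    acc <- b[co]
    for (ci in 1:cin) for (di in 1:k) for (dj in 1:k) {
      si <- i + di - 2L; sj <- j + dj - 2L
      if (si >= 1 && si <= h && sj >= 1 && sj <= w)
        acc <- acc + x[si, sj, ci] * W[di, dj, ci, co]
    }
    naive[i, j, co] <- acc
  }
  expect_equal(y, naive, tolerance = 1e-12)
})

test_that("transposed convolution doubles dims and inverts pooling strides", {
  set.seed(7)
  x <- array(rnorm(4 * 4 * 2 * 2), c(4, 4, 2, 2))
  W <- array(rnorm(2 * 2 * 2 * 3), c(2, 2, 2, 3))
  y <- aimunet:::tconv2d_fw_b(x, W, numeric(3))
  expect_equal(dim(y), c(8L, 8L, 3L, 2L))
  # each 2x2 output cell of sample 1, channel 1 comes from one input pixel
  expect_equal(y[1, 1, 1, 1], sum(x[1, 1, , 1] * W[1, 1, , 1]))
  expect_equal(y[2, 2, 1, 1], sum(x[1, 1, , 1] * W[2, 2, , 1]))
})

test_that("max pooling halves dims (stride 2) or preserves them (stride 1)", {
  x <- array(seq_len(4 * 4), c(4, 4, 1, 1))
  p2 <- aimunet:::maxpool_fw_b(x, 2L, 2L)
  expect_equal(dim(p2$y), c(2L, 2L, 1L, 1L))
  expect_equal(p2$y[1, 1, 1, 1], max(x[1:2, 1:2, 1, 1]))
  p3 <- aimunet:::maxpool_fw_b(x, 3L, 1L)
  expect_equal(dim(p3$y), c(4L, 4L, 1L, 1L))
  expect_equal(p3$y[2, 2, 1, 1], max(x[1:3, 1:3, 1, 1]))
  # backward routes gradient to the argmax only
  gy <- array(1, dim(p2$y))
  gx <- aimunet:::maxpool_bw_b(p2$argmax, gy, dim(x))
  expect_equal(sum(gx), 4)
  expect_equal(gx[2, 2, 1, 1], 1)   # max of the first 2x2 block
})

test_that("analytic gradients match finite differences on a tiny graph", {
  cfg <- tiny_network_config(side = 16L, base = 2L, depth = 2L)
  net <- build_aim_unet(cfg)
  w <- init_weights(net, 42)
  set.seed(8)
  x <- array(runif(16 * 16 * 2), c(16, 16, 1, 2))
  y <- array(rbinom(16 * 16 * 2, 1, 0.4), c(16, 16, 1, 2))
  loss_at <- function(wts) {
    p <- aimunet:::forward_graph(net, wts, x, training = TRUE)$output
    p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
    -mean(y * log(p) + (1 - y) * log(1 - p))
  }
  fw <- aimunet:::forward_graph(net, w, x, training = TRUE)
  p <- pmin(pmax(fw$output, 1e-7), 1 - 1e-7)
  gout <- (p - y) / (p * (1 - p)) / length(y)
  gr <- aimunet:::backward_graph(net, fw$weights, fw, gout)
  ids <- which(!vapply(gr, is.null, logical(1)))
  picks <- ids[round(seq(2, length(ids), length.out = 5))]
  eps <- 1e-5
  for (id in picks) {
    nm <- names(gr[[id]])[1]
    w2 <- w; w2[[id]][[nm]][1] <- w2[[id]][[nm]][1] + eps
    w3 <- w; w3[[id]][[nm]][1] <- w3[[id]][[nm]][1] - eps
    num <- (loss_at(w2) - loss_at(w3)) / (2 * eps)
    ana <- gr[[id]][[nm]][1]
    expect_equal(ana, num, tolerance = 5e-3)
  }
})

test_that("prediction emits sigmoid-bounded maps of the input geometry", {
  cfg <- tiny_network_config(side = 16L)
  net <- build_aim_unet(cfg)
  w <- init_weights(net, 3)
  m <- matrix(runif(256), 16, 16)
  pm <- predict_slice(net, w, m)
  expect_s3_class(pm, "probability_map")
  expect_equal(dim(pm$pixels), c(16L, 16L))
  expect_true(all(pm$pixels > 0 & pm$pixels < 1))
  expect_error(predict_slice(net, w, matrix(0.5, 8, 8)), "inference error")
  # batching preserves order
  slices <- list(matrix(runif(256), 16, 16), matrix(runif(256), 16, 16))
  maps <- predict_batch(net, w, slices)
  expect_identical(maps[[1]]$pixels, predict_slice(net, w, slices[[1]])$pixels)
})
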