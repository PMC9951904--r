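test_that("confusion counts match hand-enumerated pixels", {
  pred <- matrix(c(1, 0, 1, 0), 2, 2)   # [[1,1],[0,0]] row-wise
  truth <- matrix(c(1, 1, 0, 0), 2, 2)  # [[1,0],[1,0]] row-wise
  cc <- confusion(pred, truth)
  expect_equal(cc$TP, 1); expect_equal(cc$FP, 1)
  expect_equal(cc$FN, 1); expect_equal(cc$TN, 1)
  expect_equal(as.numeric(accuracy(cc)), 0.5)
  expect_equal(as.numeric(recall(cc)), 0.5)
  expect_equal(as.numeric(precision(cc)), 0.5)
  expect_equal(dice(pred, truth), 0.5)
  expect_equal(jaccard(pred, truth), 1 / 3)

  m <- random_binary_mask()
  cc2 <- confusion(m, m)
  expect_equal(cc2$FP + cc2$FN, 0)
  cc3 <- confusion(1 - m, m)
  expect_equal(cc3$TP + cc3$TN, 0)
  expect_error(confusion(matrix(0.5, 2, 2), matrix(0, 2, 2)), "binary")
  expect_error(confusion(matrix(0, 2, 2), matrix(0, 3, 3)), "shapes")
})

test_that("degenerate cases are flagged, not NaN", {
  empty <- matrix(0, 4, 4)
  cc <- confusion(empty, empty)
  expect_equal(as.numeric(accuracy(cc)), 1)
  r <- recall(cc)
  expect_equal(as.numeric(r), 0)
  expect_true(isTRUE(attr(r, "degenerate")))
  d <- dice(empty, empty)
  expect_equal(as.numeric(d), 1)
  expect_true(isTRUE(attr(d, "degenerate")))
})

test_that("confusion agrees with a naive per-pixel loop on random masks", {
  set.seed(12)
  for (i in 1:25) {
    p <- random_binary_mask(16, 16); g <- random_binary_mask(16, 16)
    cc <- confusion(p, g)
    tp <- fp <- tn <- fn <- 0
    for (r in 1:16) for (c_ in 1:16) {
      if (p[r, c_] == 1 && g[r, c_] == 1) tp <- tp + 1
      else if (p[r, c_] == 1) fp <- fp + 1
      else if (g[r, c_] == 1) fn <- fn + 1
      else tn <- tn + 1
    }
    expect_equal(unlist(cc[c("TP", "FP", "TN", "FN")]),
                 c(TP = tp, FP = fp, TN = tn, FN = fn))
  }
})

test_that("metric algebra: DL = 1 - DSC, DSC = 2J/(1+J), symmetry, bounds", {
  set.seed(13)
  for (i in 1:200) {
    p <- random_binary_mask(8, 8, runif(1, 0.1, 0.9))
    g <- random_binary_mask(8, 8, runif(1, 0.1, 0.9))
    d <- dice(p, g); j <- jaccard(p, g)
    expect_equal(dice_loss(p, g), 1 - d, tolerance = 1e-12)
    expect_equal(d, 2 * j / (1 + j), tolerance = 1e-12)
    expect_equal(d, dice(g, p))
    expect_equal(j, jaccard(g, p))
    cc <- confusion(p, g)
    vals <- c(as.numeric(accuracy(cc)), as.numeric(recall(cc)),
              as.numeric(precision(cc)), d, j)
    expect_true(all(vals >= 0 & vals <= 1))
  }
})

test_that("aggregation reports mean and population sd in percent format", {
  reps <- rbind(metric_report(matrix(1, 2, 2), matrix(1, 2, 2)),
                metric_report(matrix(0, 2, 2), matrix(1, 2, 2)))
  agg <- aggregate_metrics(reps)
  d <- agg[agg$metric == "dice", ]
  expect_equal(d$mean, 0.5)
  expect_equal(d$sd, 0.5)             # two-point population sd
  expect_equal(d$formatted, "50.00 ± 50.00")
  single <- aggregate_metrics(metric_report(matrix(1, 2, 2), matrix(1, 2, 2)))
  expect_true(all(single$sd == 0))
  # permutation invariance
  agg2 <- aggregate_metrics(reps[2:1, ])
  expect_equal(agg$mean, agg2$mean)
  expect_error(aggregate_metrics(reps[0, ]), "empty")
})

test_that("bce matches direct formula evaluation", {
  truth <- matrix(1, 3, 3)
  expect_equal(bce_loss(matrix(0.5, 3, 3), truth), log(2), tolerance = 1e-12)
  expect_lt(bce_loss(truth, truth), 1e-6)
  p <- matrix(runif(9), 3, 3); g <- random_binary_mask(3, 3)
  expect_equal(bce_loss(p, g), bce_loss(1 - p, 1 - g), tolerance = 1e-12)
  expect_error(bce_loss(matrix(0.5, 2, 2), matrix(1, 3, 3)), "shapes")
})
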