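raw_slice <- function(px) ct_slice(px, "p", 0L, "raw_hu")

test_that("Hounsfield windowing clamps exactly to [lo, hi]", {
  s <- raw_slice(matrix(c(-300, 500, 150, -100, 200, 0), 2, 3))
  w <- window_hounsfield(s)
  expect_equal(as.vector(w$pixels), c(-100, 200, 150, -100, 200, 0))
  expect_equal(w$intensity_state, "windowed")
  expect_error(window_hounsfield(s, 10, 10), "lo")
  expect_error(window_hounsfield(w), "raw_hu")
})

test_that("histogram equalisation follows the CDF and preserves rank order", {
  # two-level image: 25% at level a < 75% at level b
  px <- matrix(c(rep(-50, 16), rep(100, 48)), 8, 8)
  eq <- equalize_histogram(window_hounsfield(raw_slice(px)))
  lvl <- sort(unique(as.vector(eq$pixels)))
  expect_equal(lvl, c(0.25, 1))          # normalised cumulative histogram

  cst <- equalize_histogram(window_hounsfield(raw_slice(matrix(42, 5, 5))))
  expect_equal(length(unique(as.vector(cst$pixels))), 1L)

  set.seed(9)
  px <- matrix(runif(400, -100, 200), 20, 20)
  eq <- equalize_histogram(window_hounsfield(raw_slice(px)))
  expect_true(all(diff(eq$pixels[order(px)]) >= 0))   # monotone mapping
})

test_that("resizing halves a 512-grid to 256 and keeps masks binary", {
  skip_if_not_installed("EBImage")
  s <- raw_slice(matrix(runif(512 * 512), 512, 512))
  r <- resize_to_network(s, 256)
  expect_equal(dim(r$pixels), c(256L, 256L))

  same <- resize_to_network(s, 512)
  expect_identical(same$pixels, s$pixels)

  checker <- binary_mask((outer(1:512, 1:512, "+") %% 2), "liver")
  small <- resize_to_network(checker, 256)
  expect_true(all(small$pixels %in% c(0, 1)))
  expect_error(resize_to_network(s, 8), "side")
})

test_that("unit normalisation maps extremes to 0 and 1", {
  s <- ct_slice(matrix(c(0.2, 0.5, 0.9, 0.4), 2, 2), "p", 0L, "equalized")
  n <- normalize_unit(s)
  expect_equal(min(n$pixels), 0)
  expect_equal(max(n$pixels), 1)
  # linear ramp stays a linear ramp
  ramp <- ct_slice(matrix(seq(0.1, 0.9, length.out = 16), 4, 4), "p", 0L,
                   "equalized")
  nr <- normalize_unit(ramp)
  expect_equal(nr$pixels, (ramp$pixels - 0.1) / 0.8, tolerance = 1e-12)
  cst <- normalize_unit(ct_slice(matrix(0.7, 3, 3), "p", 0L, "equalized"))
  expect_true(all(cst$pixels == 0))
})

test_that("the composed pipeline lands any raw slice in [0,1] at 256x256", {
  ph <- generate_slice(tiny_phantom_config(48), "p", 0)
  out <- preprocess_slice(ph$image, side = 32)
  expect_equal(dim(out$pixels), c(32L, 32L))
  expect_gte(min(out$pixels), 0)
  expect_lte(max(out$pixels), 1)
  expect_equal(out$intensity_state, "normalized")
})

test_that("patient splits are whole-patient, exhaustive and deterministic", {
  ids <- sprintf("pt%02d", 1:50)
  sp <- split_patients(ids, seed = 4)
  expect_length(sp$test, 5)               # 10% of 50
  expect_setequal(c(sp$train, sp$val, sp$test), ids)
  expect_length(intersect(sp$train, sp$val), 0)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_length(intersect(sp$val, sp$test), 0)
  expect_identical(sp, split_patients(ids, seed = 4))
  expect_false(identical(sp, split_patients(ids, seed = 5)))
  expect_error(split_patients(c("a", "b")), "too few")
})
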