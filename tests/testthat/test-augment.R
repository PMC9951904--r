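aug_fixture <- function(side = 32L) {
  ph <- generate_slice(tiny_phantom_config(side), "p", 0)
  list(slice = preprocess_slice(ph$image, side = side), mask = ph$liver_mask)
}

test_that("augmentation yields exactly six views, 7n with originals", {
  fx <- aug_fixture()
  views <- augment_pair(fx$slice, fx$mask)
  expect_length(views, 6)
  expect_setequal(vapply(views, `[[`, character(1), "transform"),
                  c("center_crop", "rotate_cw", "rotate_ccw",
                    "grid_distortion", "vertical_flip",
                    "random_brightness_contrast"))
  pairs <- replicate(4, fx, simplify = FALSE)
  expect_length(augment_dataset(pairs), 7 * 4)
})

test_that("geometric views keep masks binary; photometric views keep them identical", {
  fx <- aug_fixture()
  views <- augment_pair(fx$slice, fx$mask)
  for (v in views)
    expect_true(all(v$mask$pixels %in% c(0, 1)))
  bc <- views[[6]]
  expect_identical(bc$mask$pixels, fx$mask$pixels)
})

test_that("vertical flip is an involution", {
  fx <- aug_fixture()
  flip1 <- augment_pair(fx$slice, fx$mask)[[5]]
  flip2 <- augment_pair(flip1$slice, flip1$mask)[[5]]
  expect_identical(flip2$slice$pixels, fx$slice$pixels)
  expect_identical(flip2$mask$pixels, fx$mask$pixels)
})

test_that("augmentation is deterministic under the policy seed", {
  fx <- aug_fixture()
  p <- augmentation_policy(seed = 21)
  a <- augment_pair(fx$slice, fx$mask, p, pair_index = 2)
  b <- augment_pair(fx$slice, fx$mask, p, pair_index = 2)
  for (k in 1:6) expect_identical(a[[k]]$slice$pixels, b[[k]]$slice$pixels)
  c_ <- augment_pair(fx$slice, fx$mask, augmentation_policy(seed = 22),
                     pair_index = 2)
  expect_false(identical(a[[4]]$slice$pixels, c_[[4]]$slice$pixels))
})

test_that("rotations move mass in opposite directions but preserve dims", {
  fx <- aug_fixture()
  views <- augment_pair(fx$slice, fx$mask)
  cw <- views[[2]]$mask$pixels; ccw <- views[[3]]$mask$pixels
  expect_equal(dim(cw), dim(fx$mask$pixels))
  expect_false(identical(cw, ccw))
})
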