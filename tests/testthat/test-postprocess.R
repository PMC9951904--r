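test_that("thresholding follows the strict >0.5 rule with ties to background", {
  pm <- probability_map(matrix(c(0.7, 0.3, 0.5, 0.500001), 2, 2))
  m <- binarize(pm)
  expect_equal(as.vector(m$pixels), c(1, 0, 0, 1))
  expect_error(binarize(pm, 0), "threshold")
  expect_error(binarize(matrix(1.2, 2, 2)), "outside")
  # idempotence: a binarised mask re-thresholded is unchanged
  again <- binarize(m$pixels)
  expect_identical(again$pixels, m$pixels)
})

test_that("volume stacking preserves order, voxels and inverts exactly", {
  masks <- lapply(1:5, function(k) binary_mask(random_binary_mask(12, 10)))
  vol <- stack_volume(masks)
  expect_equal(dim(vol), c(5L, 12L, 10L))
  expect_equal(sum(vol), sum(vapply(masks, function(m) sum(m$pixels),
                                    numeric(1))))
  back <- unstack_volume(vol)
  for (k in 1:5) expect_identical(back[[k]]$pixels, masks[[k]]$pixels)
})

test_that("stacking rejects mixed patients and mismatched shapes", {
  a <- binary_mask(random_binary_mask(4, 4)); attr(a, "patient_id") <- "p1"
  b <- binary_mask(random_binary_mask(4, 4)); attr(b, "patient_id") <- "p2"
  expect_error(stack_volume(list(a, b)), "assembly error")
  c_ <- binary_mask(random_binary_mask(6, 4))
  expect_error(stack_volume(list(a, c_)), "assembly error")
})

test_that("stacked volumes export to NIfTI and read back", {
  td <- withr::local_tempdir()
  masks <- lapply(1:3, function(k) binary_mask(random_binary_mask(8, 8)))
  vol <- stack_volume(masks)
  write_nifti(vol, file.path(td, "v.nii.gz"))
  rt <- read_nifti(file.path(td, "v.nii.gz"))
  expect_length(rt$slices, 3)
  expect_equal(rt$slices[[2]]$pixels, masks[[2]]$pixels, tolerance = 1e-7)
})

test_that("tumour predictions can be clipped to the predicted liver", {
  liver <- binary_mask(matrix(c(1, 1, 0, 0), 2, 2), "liver")
  tumor <- binary_mask(matrix(c(1, 0, 1, 0), 2, 2), "tumor")
  clipped <- clip_tumor_to_liver(tumor, liver)
  expect_equal(as.vector(clipped$pixels), c(1, 0, 0, 0))
})
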