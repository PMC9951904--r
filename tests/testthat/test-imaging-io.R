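test_that("DICOM series round-trip in position order with HU rescale", {
  td <- withr::local_tempdir()
  hu <- lapply(1:3, function(k) matrix(k * 10 + seq(0, 55, length.out = 56),
                                       7, 8))
  # write out of order; slice_loc defines the stacking order
  write_dicom_slice(hu[[2]], file.path(td, "b.dcm"), "pat1", 2, 10)
  write_dicom_slice(hu[[1]], file.path(td, "a.dcm"), "pat1", 1, 5)
  write_dicom_slice(hu[[3]], file.path(td, "c.dcm"), "pat1", 3, 15)
  vol <- read_dicom_series(td)
  expect_length(vol$slices, 3)
  expect_equal(vol$patient_id, "pat1")
  for (k in 1:3)
    expect_equal(vol$slices[[k]]$pixels, hu[[k]], tolerance = 1e-12)
  expect_equal(vol$slices[[1]]$intensity_state, "raw_hu")
})

test_that("DICOM rescale applies slope and intercept", {
  td <- withr::local_tempdir()
  hu <- matrix(60, 4, 4)    # stored = 60 - (-1024) = 1084 with slope 1
  write_dicom_slice(hu, file.path(td, "s.dcm"), slope = 1, intercept = -1024)
  vol <- read_dicom_series(td)
  expect_equal(vol$slices[[1]]$pixels[1, 1], 60)
})

test_that("DICOM reader rejects degenerate input", {
  td <- withr::local_tempdir()
  expect_error(read_dicom_series(td), "format error")
  write_dicom_slice(matrix(0, 4, 4), file.path(td, "p1.dcm"), "pat1")
  write_dicom_slice(matrix(0, 4, 4), file.path(td, "p2.dcm"), "pat2")
  expect_error(read_dicom_series(td), "mixes patients")
})

test_that("NIfTI volumes split into axial slices and round-trip", {
  td <- withr::local_tempdir()
  arr <- array(rnorm(8 * 8 * 5), c(8, 8, 5))
  RNifti::writeNifti(RNifti::asNifti(arr), file.path(td, "v.nii.gz"))
  vol <- read_nifti(file.path(td, "v.nii.gz"), "p")
  expect_length(vol$slices, 5)
  expect_equal(dim(vol$slices[[1]]$pixels), c(8L, 8L))
  for (k in 1:5)
    expect_equal(vol$slices[[k]]$pixels, matrix(arr[, , k], 8, 8),
                 tolerance = 1e-6)

  write_nifti(vol, file.path(td, "w.nii.gz"))
  vol2 <- read_nifti(file.path(td, "w.nii.gz"), "p")
  for (k in 1:5)
    expect_equal(vol2$slices[[k]]$pixels, vol$slices[[k]]$pixels)

  arr[2, 3, 1] <- NaN
  RNifti::writeNifti(RNifti::asNifti(arr), file.path(td, "bad.nii.gz"))
  expect_error(read_nifti(file.path(td, "bad.nii.gz")), "finite")
  RNifti::writeNifti(RNifti::asNifti(array(0, c(4, 4, 2, 2))),
                     file.path(td, "fourd.nii.gz"))
  expect_error(read_nifti(file.path(td, "fourd.nii.gz")), "3-D")
})

test_that("slice/mask pairs binarise masks and collapse equal channels", {
  td <- withr::local_tempdir()
  img <- matrix(seq(0, 1, length.out = 64), 8, 8)
  arr <- array(rep(img, 3), c(8, 8, 3))
  png::writePNG(arr, file.path(td, "img.png"))
  mask <- matrix(c(0, 255)[1 + (img > 0.5)], 8, 8) / 255
  png::writePNG(mask, file.path(td, "mask.png"))
  pair <- read_slice_pair(file.path(td, "img.png"), file.path(td, "mask.png"))
  expect_true(all(pair$mask$pixels %in% c(0, 1)))
  expect_equal(pair$mask$pixels, (img > 0.5) * 1)
  expect_equal(pair$slice$pixels, img, tolerance = 1 / 255)

  png::writePNG(matrix(0, 4, 4), file.path(td, "small.png"))
  expect_error(read_slice_pair(file.path(td, "img.png"),
                               file.path(td, "small.png")), "pairing error")
})

test_that("mask PNG write/read round-trips exactly", {
  td <- withr::local_tempdir()
  m <- binary_mask(random_binary_mask(16, 16), "liver")
  write_mask_png(m, file.path(td, "m.png"))
  expect_identical(read_mask_png(file.path(td, "m.png"))$pixels, m$pixels)
})
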