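test_that("slice generation is deterministic and respects tumour settings", {
  cfg <- tiny_phantom_config()
  a <- generate_slice(cfg, "p1", 3)
  b <- generate_slice(cfg, "p1", 3)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$liver_mask$pixels, b$liver_mask$pixels)
  expect_identical(a$tumor_mask$pixels, b$tumor_mask$pixels)

  other <- generate_slice(cfg, "p2", 3)
  expect_false(identical(a$liver_mask$pixels, other$liver_mask$pixels))

  no_tumor <- tiny_phantom_config(tumor_probability = 0)
  for (i in 0:5)
    expect_equal(sum(generate_slice(no_tumor, "p1", i)$tumor_mask$pixels), 0)
})

test_that("configuration errors name the violated field", {
  expect_error(phantom_config(height = 8), "height")
  expect_error(phantom_config(tumor_probability = 1.5), "tumor_probability")
  expect_error(phantom_config(noise_sd = -1), "noise_sd")
  expect_error(phantom_config(liver_axes_range = c(50, 10)), "liver_axes_range")
  cfg <- tiny_phantom_config()
  expect_error(generate_slice(cfg, "p", -1), "slice_index")
})

test_that("mask purity and tumour containment hold over 1000 slices", {
  cfg <- tiny_phantom_config(tumor_probability = 1)
  ok_binary <- ok_contained <- TRUE
  for (i in 0:999) {
    ph <- generate_slice(cfg, sprintf("p%d", i %% 7), i)
    ok_binary <- ok_binary &&
      all(ph$liver_mask$pixels %in% c(0, 1)) &&
      all(ph$tumor_mask$pixels %in% c(0, 1))
    ok_contained <- ok_contained &&
      sum(ph$tumor_mask$pixels * (1 - ph$liver_mask$pixels)) == 0
  }
  expect_true(ok_binary)
  expect_true(ok_contained)
})

test_that("liver areas stay within the analytic ellipse bounds", {
  cfg <- phantom_config(height = 96, width = 96, seed = 5)
  bounds <- phantom_area_bounds(cfg, raster_margin = 0.15)
  areas <- vapply(0:99, function(i)
    sum(generate_slice(cfg, sprintf("pt%d", i %/% 10), i)$liver_mask$pixels),
    numeric(1))
  expect_true(all(areas >= bounds["lower"]))
  expect_true(all(areas <= bounds["upper"]))
})

test_that("mean liver-pixel fraction over 500 slices sits inside analytic bounds", {
  cfg <- phantom_config(height = 48, width = 48, seed = 19)
  bounds <- phantom_area_bounds(cfg, raster_margin = 0.15) / (48 * 48)
  fracs <- vapply(0:499, function(i)
    mean(generate_slice(cfg, sprintf("pf%d", i %/% 25), i)$liver_mask$pixels),
    numeric(1))
  expect_gte(mean(fracs), bounds["lower"])
  expect_lte(mean(fracs), bounds["upper"])
})

test_that("volumes profile the liver area along the axial axis", {
  cfg <- tiny_phantom_config()
  v1 <- generate_volume(cfg, "pA", 1)
  expect_length(v1$volume$slices, 1)

  v <- generate_volume(cfg, "pA", 73)
  areas <- vapply(v$liver_masks, function(m) sum(m$pixels), numeric(1))
  expect_gte(areas[37], areas[1])
  expect_gte(areas[37], areas[73])
  idx <- vapply(v$volume$slices, `[[`, integer(1), "slice_index")
  expect_true(all(diff(idx) > 0))
  expect_error(generate_volume(cfg, "pA", 0), "n_slices")
})

test_that("datasets land on disk in the documented layout and round-trip", {
  cfg <- tiny_phantom_config()
  td <- withr::local_tempdir()
  man <- generate_dataset(cfg, td, n_patients = 3,
                          slices_per_patient = c(4L, 4L))
  expect_length(man, 3)
  imgs <- list.files(td, pattern = "\\.png$", recursive = TRUE)
  expect_equal(sum(grepl("images/", imgs)), 12)
  expect_equal(sum(grepl("masks_liver/", imgs)), 12)
  expect_true(file.exists(file.path(td, "manifest.json")))

  entry <- man[[1]][[1]]
  vol <- generate_volume(cfg, names(man)[1],
                         length(man[[1]]))
  reread <- read_mask_png(entry$mask_liver)
  expect_identical(reread$pixels, vol$liver_masks[[1]]$pixels)
})

test_that("tumour prevalence across slices matches the configured probability", {
  cfg <- tiny_phantom_config(tumor_probability = 0.5)
  n <- 200
  hits <- sum(vapply(seq_len(n) - 1L, function(i)
    sum(generate_slice(cfg, sprintf("q%d", i %/% 8), i)$tumor_mask$pixels) > 0,
    logical(1)))
  ci <- qbinom(c(0.005, 0.995), n, 0.5)
  expect_gte(hits, ci[1])
  expect_lte(hits, ci[2])
})
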