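# Synthetic volume where every voxel equals its slice number: makes slice
# identity trivially checkable.
slice_coded_volume <- function(n_slices = 91, height = 109, width = 91) {
  v <- array(0, c(n_slices, height, width))
  for (s in seq_len(n_slices)) v[s, , ] <- s
  datscan_volume(v, source = "synthetic-slice-coded")
}

test_that("slice extraction returns the indexed plane with the right shape", {
  vol <- slice_coded_volume()
  s41 <- extract_slice(vol)  # default index 41
  expect_equal(dim(s41$pixels), c(109, 91))
  expect_true(all(s41$pixels == 41))
  expect_equal(s41$slice_index, 41L)

  expect_true(all(extract_slice(vol, 1)$pixels == 1))
  expect_error(extract_slice(vol, 0), class = "frlf_data_error")
  expect_error(extract_slice(vol, 92), class = "frlf_data_error")
})

test_that("black-border crop finds the tight bounding box and is idempotent", {
  px <- matrix(0, 10, 10)
  px[4:7, 3:6] <- 1
  img <- slice_image(px)
  cropped <- crop_black_border(img)
  expect_equal(dim(cropped$pixels), c(4, 4))
  expect_equal(unname(cropped$crop_box), c(3L, 2L, 7L, 6L))

  # no black border: identity crop
  full <- slice_image(matrix(1, 5, 5))
  expect_equal(dim(crop_black_border(full)$pixels), c(5, 5))

  # all-black image collapses to its 1x1 centre pixel
  black <- crop_black_border(slice_image(matrix(0, 9, 9)))
  expect_equal(dim(black$pixels), c(1, 1))
  expect_equal(unname(black$crop_box), c(4L, 4L, 5L, 5L))

  # idempotence
  twice <- crop_black_border(cropped)
  expect_equal(twice$pixels, cropped$pixels)
})

test_that("resize and scale yields the requested square in [0, 1]", {
  img <- slice_image(matrix(runif(109 * 91, 0, 40), 109, 91))
  out <- resize_and_scale(img)
  expect_equal(dim(out$pixels), c(224, 224))
  expect_gte(min(out$pixels), 0)
  expect_lte(max(out$pixels), 1)
  expect_equal(range(out$pixels), c(0, 1))

  # identity resize of an image already at the target size and full range
  base <- matrix(seq(0, 1, length.out = 224 * 224), 224, 224)
  same <- resize_and_scale(slice_image(base))
  expect_equal(same$pixels, base, tolerance = 1e-12)

  # constant image maps to zeros by convention
  flat <- resize_and_scale(slice_image(matrix(7, 30, 30)), side = 8)
  expect_true(all(flat$pixels == 0))

  expect_error(resize_and_scale(img, side = 0), class = "frlf_usage_error")
})

test_that("pipeline composition always lands on a 224x224 [0,1] image", {
  set.seed(5)
  for (rep in 1:3) {
    v <- array(runif(20 * 30 * 25, 0, 100), c(20, 30, 25))
    out <- preprocess_volume(datscan_volume(v), index = sample(20, 1))
    expect_equal(dim(out$pixels), c(224, 224))
    expect_true(all(out$pixels >= 0 & out$pixels <= 1))
  }
})

test_that("brightness augmentation scales, clips, and validates the factor", {
  ones <- slice_image(matrix(1, 4, 4))
  expect_equal(brightness_augment(ones, factor = 1.0)$pixels, ones$pixels)
  expect_true(all(brightness_augment(ones, factor = 0.1)$pixels == 0.1))
  bright <- brightness_augment(slice_image(matrix(0.8, 4, 4)), factor = 1.5)
  expect_true(all(bright$pixels == 1))
  expect_error(brightness_augment(ones, factor = 2),
               class = "frlf_usage_error")
  # seeded sampled factor is reproducible
  a <- brightness_augment(ones, seed = 9)
  b <- brightness_augment(ones, seed = 9)
  expect_equal(a$pixels, b$pixels)
})

test_that("slice images round-trip through PNG (8-bit) and TIFF (16-bit)", {
  img <- resize_and_scale(slice_image(matrix(runif(400), 20, 20)), side = 20)
  png_path <- withr::local_tempfile(fileext = ".png")
  tif_path <- withr::local_tempfile(fileext = ".tif")
  write_slice(img, png_path)
  write_slice(img, tif_path)
  expect_lt(max(abs(read_slice(png_path)$pixels - img$pixels)), 1 / 255)
  expect_lt(max(abs(read_slice(tif_path)$pixels - img$pixels)), 1 / 65535)
})

test_that("train/test split partitions with the expected test size", {
  ids <- sprintf("img%03d", 1:645)
  labels <- c(rep("PD", 432), rep("nonPD", 213))
  sp <- split_dataset(ids, labels, test_fraction = 0.2, seed = 3)
  expect_equal(nrow(sp$test), 129)
  expect_equal(nrow(sp$train), 516)
  expect_setequal(c(sp$train$sample_id, sp$test$sample_id), ids)
  expect_length(intersect(sp$train$sample_id, sp$test$sample_id), 0)

  # seeded determinism
  sp2 <- split_dataset(ids, labels, test_fraction = 0.2, seed = 3)
  expect_identical(sp$test$sample_id, sp2$test$sample_id)

  # small cases
  sp3 <- split_dataset(1:10, rep("x", 10), 0.2, seed = 1)
  expect_equal(nrow(sp3$test), 2)
  sp4 <- split_dataset(1:4, rep(c("a", "b"), 2), 0.5, seed = 1)
  expect_equal(nrow(sp4$test), 2)

  # stratified mode respects per-class proportions
  sp5 <- split_dataset(ids, labels, 0.2, seed = 1, stratified = TRUE)
  expect_equal(sum(sp5$test$label == "PD"), round(0.2 * 432))
  expect_equal(sum(sp5$test$label == "nonPD"), round(0.2 * 213))

  expect_error(split_dataset(1, "a", 0.2), class = "frlf_data_error")
  expect_error(split_dataset(1:5, rep("a", 5), 1.2),
               class = "frlf_usage_error")
})
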