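test_that("image I/O round-trips PNG, BMP and rejects bad input", {
  set.seed(4)
  img <- matrix(sample(0:255, 60 * 80, replace = TRUE), 60, 80)
  f_png <- tempfile(fileext = ".png")
  write_image(img, f_png)
  expect_identical(load_image(f_png), img)

  f_bmp <- tempfile(fileext = ".bmp")
  write_image(img, f_bmp)
  expect_identical(load_image(f_bmp), img)

  rgb <- array(sample(0:255, 40 * 50 * 3, replace = TRUE), c(40, 50, 3))
  f_rgb <- tempfile(fileext = ".bmp")
  write_image(rgb, f_rgb)
  back <- load_image(f_rgb)
  expect_equal(dim(back), c(40, 50, 3))
  expect_identical(as.integer(back), as.integer(rgb))

  expect_error(load_image(tempfile(fileext = ".jpg")), class = "bq_input_error")
  f_txt <- tempfile(fileext = ".jpg")
  writeLines("this is not an image", f_txt)
  expect_error(load_image(f_txt), class = "bq_format_error")
  f_tif <- tempfile(fileext = ".tif")
  writeLines("x", f_tif)
  expect_error(load_image(f_tif), class = "bq_format_error")
})

test_that("16-bit PNG input is rejected with a clear error", {
  # minimal PNG signature + IHDR claiming bit depth 16
  f <- tempfile(fileext = ".png")
  sig <- as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a))
  ihdr <- c(as.raw(c(0, 0, 0, 13)), charToRaw("IHDR"),
            as.raw(c(0, 0, 0, 8, 0, 0, 0, 8, 16, 0, 0, 0, 0)))
  writeBin(c(sig, ihdr), f)
  expect_error(load_image(f), class = "bq_format_error")
})

test_that("greyscale conversion uses BT.601 luma weights with round-half-up", {
  const <- array(100, c(4, 4, 3))
  expect_true(all(to_greyscale(const) == 100))
  red <- array(0, c(2, 2, 3)); red[, , 1] <- 255
  expect_true(all(to_greyscale(red) == 76))       # round(0.299 * 255)
  grey <- matrix(7, 5, 5)
  expect_identical(to_greyscale(grey), grey)
})

test_that("geometry adjustment crops 64 top rows from 1280x1024 and resizes", {
  img <- matrix(50, 1024, 1280)
  img[1:64, ] <- 250                      # marker: the region that must go
  out <- adjust_geometry(img)
  expect_equal(dim(out), c(480, 640))
  expect_true(all(out < 100))             # the bright top band was cut
  expect_equal(1024 / 1280, 0.8)
  expect_equal((1024 - 64) / 1280, 0.75)
})

test_that("geometry adjustment handles canonical, 0.75-ratio and wide inputs", {
  canon <- matrix(sample(0:255, 480 * 640, replace = TRUE), 480, 640)
  expect_identical(adjust_geometry(canon), canon)

  r75 <- matrix(sample(0:255, 600 * 800, replace = TRUE), 600, 800)
  expect_equal(dim(adjust_geometry(r75)), c(480, 640))

  wide <- matrix(10, 480, 700)
  wide[, 1:30] <- 200; wide[, 671:700] <- 200   # side bands to be cut
  outw <- adjust_geometry(wide)
  expect_equal(dim(outw), c(480, 640))
  expect_true(all(outw < 100))

  expect_error(adjust_geometry(matrix(0, 4, 100)), class = "bq_input_error")
})

test_that("geometry adjustment is idempotent", {
  set.seed(11)
  img <- matrix(sample(0:255, 1024 * 1280, replace = TRUE), 1024, 1280)
  once <- adjust_geometry(img)
  expect_identical(adjust_geometry(once), once)
})

test_that("contrast stretch saturates 1% per tail and is monotone", {
  const <- matrix(128, 480, 640)
  expect_warning(out <- stretch_intensity(const), "constant")
  expect_identical(out, const)

  set.seed(21)
  img <- matrix(sample(100:150, 480 * 640, replace = TRUE), 480, 640)
  out <- stretch_intensity(img)
  # hand oracle: type-1 empirical quantiles and the affine map; with tied
  # 8-bit values the saturated mass is at most 1% plus one tied value
  x <- as.numeric(img)
  lo <- sort(x)[ceiling(0.01 * length(x))]
  hi <- sort(x)[ceiling(0.99 * length(x))]
  expect_lte(mean(x < lo), 0.01)
  expect_lte(mean(x > hi), 0.01)
  expect_true(all(out[img <= lo] == 0))
  expect_true(all(out[img >= hi] == 255))
  expected <- round(pmin(pmax((img - lo) * 255 / (hi - lo), 0), 255))
  expect_equal(out, expected)
  # monotonicity of the pixel ordering
  ord <- order(as.numeric(img))
  expect_true(all(diff(as.numeric(out)[ord]) >= 0))
})

test_that("standardization is deterministic and always yields 640x480 8-bit", {
  ph <- generate_phantom(phantom_spec(seed = 3))
  f <- tempfile(fileext = ".png")
  write_image(ph$image, f)
  a <- standardize_image(f)
  b <- standardize_image(f)
  expect_identical(a, b)
  expect_equal(dim(a), c(480, 640))
  expect_true(all(a >= 0 & a <= 255))
})
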