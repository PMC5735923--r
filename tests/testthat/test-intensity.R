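mk_region <- function(vals) {
  img <- matrix(vals, 1)
  list(img = img, mask = matrix(TRUE, 1, length(vals)))
}

test_that("first-order statistics match their definitions", {
  r <- mk_region(c(10, 20, 30))
  expect_equal(mean_grey(r$img, r$mask), 20)
  expect_equal(std_dev(r$img, r$mask), 10)       # Eq. with n-1 denominator
  c77 <- mk_region(rep(77, 9))
  expect_equal(mean_grey(c77$img, c77$mask), 77)
  expect_equal(std_dev(c77$img, c77$mask), 0)
  expect_true(is.na(std_dev(matrix(5), matrix(TRUE))))
  expect_error(mean_grey(matrix(5), matrix(FALSE)), class = "bq_region_error")
})

test_that("mode value breaks ties toward the smallest intensity", {
  expect_equal(mode_value(matrix(c(5, 5, 9), 1), matrix(TRUE, 1, 3)), 5)
  expect_equal(mode_value(matrix(c(3, 3, 7, 7), 1), matrix(TRUE, 1, 4)), 3)
  expect_equal(mode_value(matrix(200, 2, 2), matrix(TRUE, 2, 2)), 200)
})

test_that("intensity-band fractions use inclusive bounds", {
  r <- mk_region(c(10, 10, 10, 10, rep(100, 12)))
  expect_equal(fraction_dark(r$img, r$mask, 16), 0.25)
  expect_equal(fraction_dark(mk_region(rep(100, 5))$img,
                             matrix(TRUE, 1, 5), 5), 0)
  expect_equal(fraction_dark(matrix(25), matrix(TRUE), 1), 1)  # boundary
  expect_equal(fraction_bright(matrix(230), matrix(TRUE), 1), 1)
  expect_equal(fraction_bright(matrix(229), matrix(TRUE), 1), 0)
  expect_equal(fraction_bright(matrix(255, 2, 2), matrix(TRUE, 2, 2), 4), 1)

  const <- mk_region(rep(40, 8))
  expect_equal(fraction_near_mean(const$img, const$mask, 8), 1)
  expect_equal(fraction_near_mean(matrix(c(0, 255), 1), matrix(TRUE, 1, 2), 2), 0)
})

test_that("statistics agree with streaming oracles on random masked regions", {
  set.seed(61)
  for (i in 1:100) {
    n <- sample(2:60, 1)
    vals <- sample(0:255, n, replace = TRUE)
    img <- matrix(vals, 1); mask <- matrix(TRUE, 1, n)
    expect_equal(mean_grey(img, mask), sum(vals) / n, tolerance = 1e-9)
    expect_equal(std_dev(img, mask),
                 sqrt(sum((vals - mean(vals))^2) / (n - 1)), tolerance = 1e-9)
    tab <- table(vals)
    expect_equal(mode_value(img, mask),
                 min(as.integer(names(tab)[tab == max(tab)])))
    m <- mean(vals)
    expect_equal(fraction_near_mean(img, mask, n),
                 sum(vals >= m - 10 & vals <= m + 10) / n, tolerance = 1e-9)
    expect_lte(fraction_dark(img, mask, n) + fraction_bright(img, mask, n), 1)
  }
})

test_that("shifting intensities shifts mean and mode, not the deviation", {
  set.seed(67)
  vals <- sample(30:180, 40, replace = TRUE)
  img <- matrix(vals, 1); mask <- matrix(TRUE, 1, 40)
  shifted <- img + 50
  expect_equal(mean_grey(shifted, mask), mean_grey(img, mask) + 50)
  expect_equal(mode_value(shifted, mask), mode_value(img, mask) + 50)
  expect_equal(std_dev(shifted, mask), std_dev(img, mask))
})

test_that("Otsu bright fraction splits a bimodal region and bounds hold", {
  vals <- c(rep(50, 200), rep(200, 200))
  img <- matrix(vals, 20); mask <- matrix(TRUE, 20, 20)
  got <- sum_er(img, mask, 400)
  # oracle: exhaustive search over all 256 thresholds
  best <- -1; thr_best <- 0
  for (t in 0:255) {
    w0 <- mean(vals <= t); w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    m0 <- mean(vals[vals <= t]); m1 <- mean(vals[vals > t])
    bc <- w0 * w1 * (m0 - m1)^2
    if (bc > best) { best <- bc; thr_best <- t }
  }
  expect_equal(got, sum(vals > thr_best) / 400, tolerance = 0.01)
  expect_equal(got, 0.5, tolerance = 0.01)

  const <- sum_er(matrix(80, 5, 5), matrix(TRUE, 5, 5), 25)
  expect_equal(as.numeric(const), 0)
  expect_true(isTRUE(attr(const, "degenerate_otsu")))

  set.seed(71)
  img2 <- matrix(sample(0:255, 100, replace = TRUE), 10)
  f <- sum_er(img2, matrix(TRUE, 10, 10), 100)
  expect_gte(f, 0); expect_lte(f, 1)
})

test_that("the intensity feature block is named and ordered canonically", {
  ph <- generate_phantom(uniform_phantom(150, seed = 72))
  m <- phantom_masks(ph)
  iv <- intensity_features(m)
  expect_named(iv, c("Radius ER", "Sum ER", "Mean grey ER",
                     "Deviation RR", "Mean grey RR", "Mode value RR",
                     "Dark RR", "Mean Count RR", "Bright RR",
                     "Deviation TE", "Mean grey TE", "Mode value TE",
                     "Dark TE", "Mean Count TE", "Bright TE"))
  expect_equal(iv[["Radius ER"]], 155)
  fr <- iv[c("Sum ER", "Dark RR", "Mean Count RR", "Bright RR",
             "Dark TE", "Mean Count TE", "Bright TE")]
  expect_true(all(fr >= 0 & fr <= 1))
})
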