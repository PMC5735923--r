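test_that("quantization bins masked pixels into 8 grey levels", {
  img <- matrix(50, 4, 4); mask <- matrix(TRUE, 4, 4)
  q <- quantize8(img, mask)
  expect_true(all(q == 0))

  vals <- round(seq(0, 255, length.out = 8))    # 0, 36, 73, ..., 255
  img2 <- matrix(vals, 1)
  q2 <- quantize8(img2, matrix(TRUE, 1, 8))
  expect_identical(as.integer(q2), 0:7)

  one <- quantize8(matrix(9, 1, 1), matrix(TRUE, 1, 1))
  expect_identical(as.integer(one), 0L)
  expect_error(quantize8(img, matrix(FALSE, 4, 4)), class = "bq_region_error")
  # background stays NA
  m3 <- matrix(c(TRUE, FALSE), 4, 4)
  expect_true(all(is.na(quantize8(img, m3)[!m3])))
})

test_that("co-occurrence counts follow pair enumeration at the default offset", {
  q <- matrix(c(0L, 0L, 0L, 0L), 2, 2)
  g <- compute_glcm(q)
  expect_equal(g$p[1, 1], 1)
  expect_equal(g$n_pairs, 2)          # two horizontal pairs in a 2x2

  # row 0,7,0,7: pairs (0,7), (7,0), (0,7)
  g2 <- compute_glcm(matrix(c(0L, 7L, 0L, 7L), 1))
  expect_equal(g2$n_pairs, 3)
  expect_equal(g2$p[1, 8], 2 / 3)
  expect_equal(g2$p[8, 1], 1 / 3)
  expect_equal(sum(g2$p), 1)

  # degenerate: no pairs
  g3 <- compute_glcm(matrix(NA_integer_, 3, 3))
  expect_equal(g3$n_pairs, 0)
  expect_equal(glcm_contrast(g3), 0)
  expect_true(is.na(glcm_energy(g3)))
})

test_that("texture statistics reproduce their analytic identities", {
  const <- compute_glcm(matrix(0L, 10, 10))
  expect_equal(glcm_contrast(const), 0)
  expect_equal(glcm_energy(const), 1)
  expect_equal(glcm_homogeneity(const), 1)     # diagonal GLCM
  expect_true(is.nan(glcm_correlation(const))) # zero marginal variance

  # all mass on p(0,7) and p(7,0), half each
  p <- matrix(0, 8, 8); p[1, 8] <- 0.5; p[8, 1] <- 0.5
  g <- glcm_from_p(p)
  expect_equal(glcm_contrast(g), 49)
  expect_equal(glcm_correlation(g), -1)
  expect_equal(glcm_energy(g), 0.5)
  expect_equal(glcm_homogeneity(g), 0.125)

  # neighbour pairs exactly on j = i + 1 -> correlation +1
  ramp <- matrix(rep(0:7, each = 6), 6, 8, byrow = FALSE)
  g_up <- compute_glcm(matrix(as.integer(ramp), 6, 8))
  expect_equal(glcm_correlation(g_up), 1)

  # uniform over all 64 cells
  expect_equal(glcm_energy(glcm_from_p(matrix(1 / 64, 8, 8))), 1 / 64)
})

test_that("every statistic matches the brute-force double-loop oracle", {
  set.seed(31)
  for (i in 1:20) {
    img <- matrix(sample(0:255, 15 * 15, replace = TRUE), 15, 15)
    mask <- matrix(runif(225) > 0.2, 15, 15)
    if (sum(mask) < 4) next
    q <- quantize8(img, mask)
    g <- compute_glcm(q)
    if (g$n_pairs == 0) next
    o <- oracle_glcm_stats(g$p)
    expect_equal(glcm_contrast(g), o$contrast, tolerance = 1e-12)
    expect_equal(glcm_energy(g), o$energy, tolerance = 1e-12)
    expect_equal(glcm_homogeneity(g), o$homogeneity, tolerance = 1e-12)
    if (!is.nan(o$correlation))
      expect_equal(glcm_correlation(g), o$correlation, tolerance = 1e-12)
    expect_equal(sum(g$p), 1, tolerance = 1e-12)
    expect_gte(glcm_contrast(g), 0)
    expect_gt(glcm_energy(g), 0); expect_lte(glcm_energy(g), 1)
    expect_gt(glcm_homogeneity(g), 0); expect_lte(glcm_homogeneity(g), 1)
    if (!is.nan(g2 <- glcm_correlation(g)))
      expect_true(g2 >= -1 - 1e-12 && g2 <= 1 + 1e-12)
  }
})

test_that("grey-level flip leaves contrast, energy and homogeneity unchanged", {
  set.seed(37)
  for (i in 1:10) {
    q <- matrix(sample(0:7, 100, replace = TRUE), 10, 10)
    g <- compute_glcm(q)
    gf <- compute_glcm(7L - q)
    expect_equal(glcm_contrast(g), glcm_contrast(gf), tolerance = 1e-12)
    expect_equal(glcm_energy(g), glcm_energy(gf), tolerance = 1e-12)
    expect_equal(glcm_homogeneity(g), glcm_homogeneity(gf), tolerance = 1e-12)
  }
})

test_that("texture features cover RR and TE with identical-texture symmetry", {
  # same periodic texture painted everywhere: variables 1-4 equal 5-8
  ph <- generate_phantom(uniform_phantom(seed = 41, noise_sd = 0,
                                         blur_sigma = 0))
  img <- ph$image
  img[] <- (row(img) + col(img)) %% 8 * 30    # shared texture
  m <- phantom_masks(ph)
  m$crop <- img[m$offset["y"]:(m$offset["y"] + nrow(m$crop) - 1),
                m$offset["x"]:(m$offset["x"] + ncol(m$crop) - 1)]
  tf <- texture_features(m)
  expect_named(tf, c("Contrast RR", "Correlation RR", "Energy RR",
                     "Homogeneity RR", "Contrast TE", "Correlation TE",
                     "Energy TE", "Homogeneity TE"))
  expect_equal(tf[["Contrast RR"]], tf[["Contrast TE"]], tolerance = 0.05)
  expect_equal(tf[["Energy RR"]], tf[["Energy TE"]], tolerance = 0.02)

  # constant RR interior: energy 1, contrast 0
  flat <- m
  flat$crop <- matrix(120, nrow(m$crop), ncol(m$crop))
  tf2 <- texture_features(flat)
  expect_equal(tf2[["Energy RR"]], 1)
  expect_equal(tf2[["Contrast RR"]], 0)
})
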