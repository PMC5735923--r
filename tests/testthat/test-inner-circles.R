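test_that("planted inclusions are counted exactly on uniform embryos", {
  inc <- ring_inclusions(150, n_dark_small = 3)
  ph <- generate_phantom(uniform_phantom(150, inc, seed = 51))
  m <- phantom_masks(ph)
  cs <- detect_inner_circles(m$crop, m$er_mask, "dark", c(4L, 8L), 0.935)
  expect_equal(nrow(cs$circles), 3)

  none <- generate_phantom(uniform_phantom(150, NULL, seed = 52))
  m0 <- phantom_masks(none)
  cs0 <- detect_inner_circles(m0$crop, m0$er_mask, "dark", c(4L, 8L), 0.935)
  expect_equal(nrow(cs0$circles), 0)

  inc2 <- ring_inclusions(180, n_light_large = 2)
  ph2 <- generate_phantom(uniform_phantom(180, inc2, seed = 53))
  m2 <- phantom_masks(ph2)
  cs2 <- detect_inner_circles(m2$crop, m2$er_mask, "light", c(9L, 15L), 0.94)
  expect_equal(nrow(cs2$circles), 2)
})

test_that("detected circle geometry matches the planted ground truth", {
  inc <- ring_inclusions(150, n_dark_small = 2, n_dark_large = 1)
  ph <- generate_phantom(uniform_phantom(150, inc, seed = 54))
  m <- phantom_masks(ph)
  cs <- detect_inner_circles(m$crop, m$er_mask, "dark", c(4L, 8L), 0.935)
  expect_equal(nrow(cs$circles), 2)
  # centres within 2 px of the planted small inclusions (crop frame)
  planted <- inc[inc$radius == 6, ]
  px <- planted$x - m$offset["x"] + 1
  py <- planted$y - m$offset["y"] + 1
  for (i in seq_len(nrow(cs$circles))) {
    dmin <- min(sqrt((px - cs$circles$center_x[i])^2 +
                     (py - cs$circles$center_y[i])^2))
    expect_lte(dmin, 2)
  }
  expect_true(all(cs$circles$radius >= 4 & cs$circles$radius <= 8))
})

test_that("circle mean intensity agrees with a brute-force raster oracle", {
  inc <- data.frame(x = c(280, 370, 250), y = c(180, 300, 280), radius = 6,
                    intensity = 20, polarity = "dark")
  ph <- generate_phantom(uniform_phantom(150, inc, seed = 55, noise_sd = 0,
                                         blur_sigma = 0))
  m <- phantom_masks(ph)
  cs <- detect_inner_circles(m$crop, m$er_mask, "dark", c(4L, 8L), 0.935)
  expect_equal(nrow(cs$circles), 3)
  got <- circle_mean_intensity(cs, m$crop, m$er_mask)
  # oracle: rasterize the disc union at the mean radius and average
  rmean <- mean(cs$circles$radius)
  un <- matrix(FALSE, nrow(m$crop), ncol(m$crop))
  for (i in seq_len(nrow(cs$circles))) {
    dy2 <- (seq_len(nrow(un)) - cs$circles$center_y[i])^2
    dx2 <- (seq_len(ncol(un)) - cs$circles$center_x[i])^2
    un <- un | outer(dy2, dx2, "+") <= rmean^2
  }
  un <- un & m$er_mask
  expect_lte(abs(got - mean(m$crop[un])), 1)
  # well-separated constant discs: mean close to the planted intensity
  expect_lte(abs(got - 20), 2)
})

test_that("empty circle sets yield the zero mean-intensity convention", {
  cs <- structure(list(circles = data.frame(center_x = numeric(),
                                            center_y = numeric(),
                                            radius = numeric(),
                                            metric = numeric()),
                       polarity = "dark", radius_range = c(4, 8),
                       sensitivity = 0.935), class = "circle_set")
  expect_equal(circle_mean_intensity(cs, matrix(100, 10, 10),
                                     matrix(TRUE, 10, 10)), 0)
})

test_that("circle features report the four detector combinations in order", {
  inc <- ring_inclusions(150, n_dark_small = 2, n_light_large = 1)
  ph <- generate_phantom(uniform_phantom(150, inc, seed = 56))
  m <- phantom_masks(ph)
  cf <- circle_features(m)
  expect_named(cf, c("DC1", "Mean DC1", "LC1", "Mean LC1",
                     "DC2", "Mean DC2", "LC2", "Mean LC2"))
  expect_equal(unname(cf[c("DC1", "LC1", "DC2", "LC2")]), c(2, 0, 0, 1))
  expect_equal(unname(cf[c("Mean LC1", "Mean DC2")]), c(0, 0))
  expect_true(all(cf[c("Mean DC1", "Mean LC2")] >= 0 &
                    cf[c("Mean DC1", "Mean LC2")] <= 255))
  counts <- cf[c("DC1", "LC1", "DC2", "LC2")]
  expect_true(all(counts == round(counts) & counts >= 0))
})
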