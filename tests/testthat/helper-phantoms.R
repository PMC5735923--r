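# Shared fixtures: phantoms are rendered in code at test time.

# a fabricated embryo circle (bypasses detection for module-level tests)
fixed_circle <- function(cx = 320, cy = 240, r = 150) {
  structure(list(center_x = cx, center_y = cy, radius = r, metric = 1,
                 stage = if (r < 150) 1L else 2L),
            class = "embryo_circle")
}

# uniform-interior embryo phantom (no texture, no ICM) with inclusions
uniform_phantom <- function(r = 150, inclusions = NULL, seed = 1,
                            noise_sd = 2, blur_sigma = 0.8) {
  phantom_spec(width = 640, height = 480, embryo_radius = r,
               inclusions = inclusions, seed = seed, noise_sd = noise_sd,
               blur_sigma = blur_sigma, icm = list(present = FALSE),
               te_texture = c(140, 0, 3), mottle = c(0, 2))
}

# masks of a phantom using its true circle (segmentation bypassed)
phantom_masks <- function(ph) {
  tc <- ph$truth$circle
  make_masks(fixed_circle(tc["center_x"], tc["center_y"], tc["radius"]),
             ph$image)
}

# inclusions at well-separated angular positions, 0.45 r from the centre
ring_inclusions <- function(r, n_dark_small = 0, n_light_small = 0,
                            n_dark_large = 0, n_light_large = 0) {
  n <- n_dark_small + n_light_small + n_dark_large + n_light_large
  if (n == 0) return(NULL)
  angs <- seq(0, 2 * pi, length.out = n + 1)[seq_len(n)] + 0.3
  rads <- c(rep(6, n_dark_small), rep(6, n_light_small),
            rep(12, n_dark_large), rep(12, n_light_large))
  pols <- c(rep("dark", n_dark_small), rep("light", n_light_small),
            rep("dark", n_dark_large), rep("light", n_light_large))
  data.frame(x = 320 + 0.45 * r * cos(angs), y = 240 + 0.45 * r * sin(angs),
             radius = rads, intensity = ifelse(pols == "dark", 60, 235),
             polarity = pols)
}

# brute-force GLCM statistics from explicit double loops over the 8x8 grid
# (independent oracle for the vectorized implementation)
oracle_glcm_stats <- function(p) {
  lev <- 0:(nrow(p) - 1)
  contrast <- 0; energy <- 0; homog <- 0
  for (i in seq_along(lev)) for (j in seq_along(lev)) {
    contrast <- contrast + abs(lev[i] - lev[j])^2 * p[i, j]
    energy <- energy + p[i, j]^2
    homog <- homog + p[i, j] / (1 + abs(lev[i] - lev[j]))
  }
  mu_i <- 0; mu_j <- 0
  for (i in seq_along(lev)) for (j in seq_along(lev)) {
    mu_i <- mu_i + lev[i] * p[i, j]
    mu_j <- mu_j + lev[j] * p[i, j]
  }
  v_i <- 0; v_j <- 0; cov <- 0
  for (i in seq_along(lev)) for (j in seq_along(lev)) {
    v_i <- v_i + (lev[i] - mu_i)^2 * p[i, j]
    v_j <- v_j + (lev[j] - mu_j)^2 * p[i, j]
    cov <- cov + (lev[i] - mu_i) * (lev[j] - mu_j) * p[i, j]
  }
  corr <- if (v_i * v_j > 0) cov / sqrt(v_i * v_j) else NaN
  list(contrast = contrast, correlation = corr, energy = energy,
       homogeneity = homog)
}

# glcm object from an explicit probability matrix
glcm_from_p <- function(p, n_pairs = 100) {
  structure(list(p = p, counts = p * n_pairs, n_pairs = n_pairs,
                 d = 1, theta = 0, levels = nrow(p)),
            class = "glcm")
}
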