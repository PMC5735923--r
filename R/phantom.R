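# Synthetic blastocyst phantoms with ground truth. The renderer emulates the
# structure of a brightfield blastocyst micrograph: bright background, a
# roughly circular embryo with a zona-pellucida ring, a textured
# trophectoderm annulus, fine mottle in the blastocoel, a homogeneous dark
# elliptical inner cell mass, optional small dark/light circular inclusions,
# Gaussian optical blur and additive sensor noise.

#' Specify a synthetic blastocyst phantom
#'
#' All geometry is given in standardized-frame units (the 640x480 frame the
#' pipeline operates in); when `width` is 1280 the phantom is rendered at
#' 1280x1024 so that standardization exercises the 64-row crop and the 2x
#' downscale. The inner cell mass is rendered homogeneous and sharp-edged
#' (the focal plane passes through it) while the blastocoel and
#' trophectoderm carry fine texture - the property that makes the ICM the
#' largest watershed basin.
#'
#' @param width,height rendered image size in px; 1280x1024 (default) or
#'   640x480.
#' @param embryo_center c(x, y) of the embryo in standardized coordinates.
#' @param embryo_radius embryo radius in standardized px, in 100..245.
#' @param background_intensity bright-field background level (0..255).
#' @param interior_intensity blastocoel base level.
#' @param dome_amplitude radial brightening of the blastocoel towards the
#'   embryo centre (intensity units).
#' @param mottle fine blastocoel texture as c(sd, scale): intensity sd and
#'   correlation length in px.
#' @param te_width trophectoderm annulus width in standardized px.
#' @param te_texture c(mean, sd, scale): TE mean intensity, texture sd and
#'   blob correlation length in px.
#' @param zona list(offset, width, intensity): bright zona ring rendered
#'   `offset` px inside the embryo rim.
#' @param icm list(present, offset = c(x, y) relative to the embryo centre,
#'   a, b semi-axes (a >= b), angle in degrees, intensity, rim_intensity of
#'   the bright refractile fringe at the ICM boundary). `NULL` uses
#'   radius-scaled defaults; `list(present = FALSE)` omits the ICM.
#' @param inclusions data.frame with columns `x`, `y`, `radius` (4..15),
#'   `intensity`, `polarity` ("dark"/"light"), standardized coordinates.
#' @param blur_sigma Gaussian optical blur sigma in standardized px.
#' @param noise_sd additive Gaussian sensor noise sd (intensity units).
#' @param seed integer; fixes all randomness (texture and noise).
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(width = 1280, height = 1024,
                         embryo_center = c(320, 240),
                         embryo_radius = 150,
                         background_intensity = 220,
                         interior_intensity = 170,
                         dome_amplitude = 12,
                         mottle = c(sd = 6, scale = 2),
                         te_width = 40,
                         te_texture = c(mean = 140, sd = 15, scale = 3),
                         zona = list(offset = 4, width = 6, intensity = 165),
                         icm = NULL,
                         inclusions = NULL,
                         blur_sigma = 0.8,
                         noise_sd = 2,
                         seed = 1L) {
  if (!(width == 1280 && height == 1024) && !(width == 640 && height == 480))
    bq_stop("bq_spec_error", "phantom size must be 1280x1024 or 640x480")
  if (embryo_radius < 100 || embryo_radius > 245)
    bq_stop("bq_spec_error", "embryo_radius must be in [100, 245]")
  if (embryo_center[1] < 1 || embryo_center[1] > 640 ||
      embryo_center[2] < 1 || embryo_center[2] > 480)
    bq_stop("bq_spec_error", "embryo centre must lie inside the 640x480 frame")
  r <- embryo_radius
  if (is.null(icm)) {
    icm <- list(present = TRUE, offset = NULL, a = 0.30 * r, b = 0.19 * r,
                angle = 30, intensity = 80)
  }
  icm$present <- icm$present %||% TRUE
  if (icm$present) {
    icm$a <- icm$a %||% (0.30 * r)
    icm$b <- icm$b %||% (0.19 * r)
    if (is.null(icm$offset)) {
      # place the ICM inside the reduced disc, off-centre as in micrographs
      off <- min(0.28 * r, max(0, r - te_width - icm$a - 3))
      icm$offset <- c(-off * cos(pi / 5), off * sin(pi / 5))
    }
    icm$angle <- icm$angle %||% 30
    icm$intensity <- icm$intensity %||% 80
    icm$rim_intensity <- icm$rim_intensity %||% 195
    if (icm$a < icm$b) bq_stop("bq_spec_error", "icm semi-axes need a >= b")
  }
  if (is.null(inclusions)) {
    inclusions <- data.frame(x = numeric(), y = numeric(), radius = numeric(),
                             intensity = numeric(), polarity = character())
  }
  if (nrow(inclusions) > 0) {
    if (any(inclusions$radius < 4 | inclusions$radius > 15))
      bq_stop("bq_spec_error", "inclusion radii must be in [4, 15]")
    d <- sqrt((inclusions$x - embryo_center[1])^2 +
              (inclusions$y - embryo_center[2])^2)
    if (any(d + inclusions$radius > r))
      bq_stop("bq_spec_error", "inclusions must lie inside the embryo")
  }
  structure(list(width = width, height = height,
                 embryo_center = embryo_center, embryo_radius = embryo_radius,
                 background_intensity = background_intensity,
                 interior_intensity = interior_intensity,
                 dome_amplitude = dome_amplitude, mottle = mottle,
                 te_width = te_width, te_texture = te_texture, zona = zona,
                 icm = icm, inclusions = inclusions, blur_sigma = blur_sigma,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

# correlated Gaussian field with unit sd (blurred white noise, renormalized)
blob_field <- function(h, w, scale) {
  z <- matrix(rnorm(h * w), h, w)
  if (scale > 0) {
    z <- t(EBImage::imageData(EBImage::gblur(EBImage::Image(t(z)),
                                             sigma = scale)))
  }
  z / sd(z)
}

#' Render a synthetic blastocyst phantom
#'
#' Renders the phantom described by a [phantom_spec()] and returns the 8-bit
#' image together with its ground truth in standardized-frame coordinates.
#' Rendering is fully deterministic for a fixed spec (seeded texture and
#' noise).
#'
#' @param spec a `phantom_spec`.
#' @return list with `image` (integer matrix, `height` x `width`), `truth`
#'   (list: `circle` = c(center_x, center_y, radius); `icm` = list(area,
#'   eccentricity, a, b, center); `inclusions` data.frame with a `size_class`
#'   column: 1 for radii 4-8, 2 for 9-15), and the `spec`.
#' @export
#' @examples
#' ph <- generate_phantom(phantom_spec(seed = 42))
#' dim(ph$image)
#' ph$truth$circle
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  s <- spec$width / 640                      # render scale
  h <- spec$height; w <- spec$width
  cx <- spec$embryo_center[1] * s
  cy <- if (s == 2) spec$embryo_center[2] * s + 64 else spec$embryo_center[2]
  R <- spec$embryo_radius * s
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  d <- sqrt((xx - cx)^2 + (yy - cy)^2)
  with_seed(spec$seed, {
    img <- matrix(spec$background_intensity, h, w)
    emb <- d <= R
    img[emb] <- spec$interior_intensity +
      spec$dome_amplitude * (1 - (d[emb] / R)^2)
    blasto <- d <= R - spec$te_width * s
    img[blasto] <- img[blasto] +
      spec$mottle[1] * blob_field(h, w, spec$mottle[2] * s)[blasto]
    te <- emb & !blasto
    img[te] <- spec$te_texture[1] +
      spec$te_texture[2] * blob_field(h, w, spec$te_texture[3] * s)[te]
    zr_out <- R - spec$zona$offset * s
    zona <- d <= zr_out & d > zr_out - spec$zona$width * s
    img[zona] <- spec$zona$intensity
    if (nrow(spec$inclusions) > 0) {
      for (i in seq_len(nrow(spec$inclusions))) {
        inc <- spec$inclusions[i, ]
        icx <- inc$x * s
        icy <- if (s == 2) inc$y * s + 64 else inc$y
        disc <- (xx - icx)^2 + (yy - icy)^2 <= (inc$radius * s)^2
        img[disc] <- inc$intensity
      }
    }
    if (spec$blur_sigma > 0) {
      img <- t(EBImage::imageData(EBImage::gblur(EBImage::Image(t(img / 255)),
                                                 sigma = spec$blur_sigma * s))) * 255
    }
    # the ICM is composited after the optical blur with a crisp edge: the
    # capture protocol places the focal plane through the widest section of
    # the ICM, so its boundary is the sharpest structure in the frame
    icm_truth <- NULL
    if (spec$icm$present) {
      ix <- cx + spec$icm$offset[1] * s
      iy <- cy + spec$icm$offset[2] * s
      th <- spec$icm$angle * pi / 180
      u <- (xx - ix) * cos(th) + (yy - iy) * sin(th)
      v <- -(xx - ix) * sin(th) + (yy - iy) * cos(th)
      ed <- sqrt((u / (spec$icm$a * s))^2 + (v / (spec$icm$b * s))^2)
      ell <- ed <= 1
      # refractile fringe: brightfield images of a dense cell mass show a
      # bright diffraction line hugging its boundary
      rim <- ed > 1 & ed <= 1 + 2 / min(spec$icm$a, spec$icm$b)
      soft_of <- function(m, sig) t(EBImage::imageData(EBImage::gblur(
        EBImage::Image(t(matrix(as.numeric(m), h, w))), sigma = sig)))
      rim_soft <- soft_of(rim, 1.0 * s)
      img <- img * (1 - rim_soft) +
        pmax(img, spec$icm$rim_intensity) * rim_soft
      soft <- soft_of(ell, 0.8 * s)
      img <- img * (1 - soft) + spec$icm$intensity * soft
      icm_truth <- list(
        area = pi * spec$icm$a * spec$icm$b,
        eccentricity = sqrt(1 - (spec$icm$b / spec$icm$a)^2),
        a = spec$icm$a, b = spec$icm$b,
        center = c(x = spec$embryo_center[1] + spec$icm$offset[1],
                   y = spec$embryo_center[2] + spec$icm$offset[2]))
    }
    if (spec$noise_sd > 0) img <- img + rnorm(h * w, sd = spec$noise_sd)
    img <- round(pmin(pmax(img, 0), 255))
    inc <- spec$inclusions
    if (nrow(inc) > 0) inc$size_class <- ifelse(inc$radius <= 8, 1L, 2L)
    list(image = img,
         truth = list(circle = c(center_x = spec$embryo_center[1],
                                 center_y = spec$embryo_center[2],
                                 radius = spec$embryo_radius),
                      icm = icm_truth, inclusions = inc),
         spec = spec)
  })
}

#' Generate a phantom dataset on disk
#'
#' Renders `n` phantoms with parameters drawn from stated ranges under one
#' master seed, writes them as JPG (quality 95) plus a ground-truth CSV.
#' Identical `(n, seed)` reproduce identical files.
#'
#' @param n number of phantoms (>= 1).
#' @param seed master seed.
#' @param dir output directory (created if missing).
#' @param radius_range range the embryo radius is drawn from (standardized px).
#' @param size phantom render size: "hires" (1280x1024) or "std" (640x480).
#' @param max_inclusions maximum number of inclusions drawn per size class
#'   and polarity (counts drawn uniformly from 0..max).
#' @param noise_sd sensor noise passed to every [phantom_spec()].
#' @return invisibly, a list with `images` (file paths) and `truth`
#'   (data.frame, also written to `truth.csv` in `dir`).
#' @export
generate_dataset <- function(n, seed, dir, radius_range = c(110, 245),
                             size = c("hires", "std"), max_inclusions = 2,
                             noise_sd = 2) {
  if (n < 1) bq_stop("bq_input_error", "n must be >= 1")
  size <- match.arg(size)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wh <- if (size == "hires") c(1280, 1024) else c(640, 480)
  rows <- list(); paths <- character(n)
  specs <- with_seed(seed, {
    lapply(seq_len(n), function(i) {
      r <- runif(1, radius_range[1], radius_range[2])
      inc <- random_inclusions(r, max_inclusions)
      phantom_spec(width = wh[1], height = wh[2], embryo_radius = r,
                   inclusions = inc, noise_sd = noise_sd,
                   seed = sample.int(.Machine$integer.max - 1, 1))
    })
  })
  for (i in seq_len(n)) {
    ph <- generate_phantom(specs[[i]])
    paths[i] <- file.path(dir, sprintf("phantom_%03d.jpg", i))
    write_image(ph$image, paths[i], quality = 95)
    tr <- ph$truth
    rows[[i]] <- data.frame(
      id = sprintf("phantom_%03d", i),
      center_x = tr$circle["center_x"], center_y = tr$circle["center_y"],
      radius = tr$circle["radius"],
      icm_area = if (is.null(tr$icm)) NA else tr$icm$area,
      icm_eccentricity = if (is.null(tr$icm)) NA else tr$icm$eccentricity,
      n_dark_small = sum(tr$inclusions$polarity == "dark" &
                           tr$inclusions$size_class == 1),
      n_light_small = sum(tr$inclusions$polarity == "light" &
                            tr$inclusions$size_class == 1),
      n_dark_large = sum(tr$inclusions$polarity == "dark" &
                           tr$inclusions$size_class == 2),
      n_light_large = sum(tr$inclusions$polarity == "light" &
                            tr$inclusions$size_class == 2),
      row.names = NULL)
  }
  truth <- do.call(rbind, rows)
  write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(list(images = paths, truth = truth))
}

# draw well-separated inclusions in the blastocoel, away from the ICM zone;
# uses the current RNG stream
random_inclusions <- function(radius, max_per_class) {
  classes <- expand.grid(polarity = c("dark", "light"), class = 1:2,
                         stringsAsFactors = FALSE)
  out <- list()
  placed <- data.frame(x = numeric(), y = numeric(), radius = numeric())
  for (i in seq_len(nrow(classes))) {
    k <- sample.int(max_per_class + 1, 1) - 1
    rng <- if (classes$class[i] == 1) c(4, 8) else c(9, 15)
    for (j in seq_len(k)) {
      for (try in 1:50) {
        rr <- runif(1, rng[1], rng[2])
        ang <- runif(1, 0, 2 * pi)
        # blastocoel half away from the default ICM (which sits at angle ~144deg)
        dd <- runif(1, 0, radius - 40 - rr - 4)
        x <- 320 + dd * cos(ang); y <- 240 + dd * sin(ang)
        icm_off <- 0.28 * radius
        icm_c <- c(320 - icm_off * cos(pi / 5), 240 + icm_off * sin(pi / 5))
        clear_icm <- sqrt(sum((c(x, y) - icm_c)^2)) > 0.32 * radius + rr + 6
        clear_others <- nrow(placed) == 0 ||
          all(sqrt((placed$x - x)^2 + (placed$y - y)^2) >
                placed$radius + rr + 4)
        if (clear_icm && clear_others) {
          placed <- rbind(placed, data.frame(x = x, y = y, radius = rr))
          out[[length(out) + 1]] <- data.frame(
            x = x, y = y, radius = rr,
            intensity = if (classes$polarity[i] == "dark") 60 else 235,
            polarity = classes$polarity[i])
          break
        }
      }
    }
  }
  if (length(out) == 0) {
    data.frame(x = numeric(), y = numeric(), radius = numeric(),
               intensity = numeric(), polarity = character())
  } else do.call(rbind, out)
}
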