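# Small dark/light circle detection inside the isolated embryo
# (variables 9-16): gradient-direction Hough voting with polarity.

#' Detect small dark or light circles in the embryo
#'
#' Accumulator-based circle detection with intensity polarity. Every pixel
#' with gradient magnitude above `config$cht_edge_threshold` casts one vote
#' per candidate radius at the putative circle centre: against the gradient
#' direction for dark circles (interior darker than surroundings), along it
#' for light circles. Each radius slice of the accumulator is smoothed and
#' normalized by the circle perimeter so a complete, well-contrasted circle
#' scores an O(1) metric. Peaks are accepted while their metric exceeds
#' `3 * (1 - sensitivity)` (the sensitivity-to-threshold mapping is
#' implementation-defined) with greedy non-maximum suppression; circles whose
#' centres fall outside the region mask are discarded.
#'
#' @param img greyscale matrix (typically the ER crop).
#' @param mask logical matrix; detected centres must fall inside it.
#' @param polarity `"dark"` or `"light"`.
#' @param radius_range integer `c(min, max)` circle radii in px.
#' @param sensitivity detection sensitivity in (0,1); higher accepts weaker
#'   accumulator peaks.
#' @param config a [pipeline_config()].
#' @return object of class `circle_set`: list with `circles` (data.frame of
#'   `center_x`, `center_y`, `radius`, `metric`), `polarity`,
#'   `radius_range`, `sensitivity`. Empty detection is a valid result.
#' @export
detect_inner_circles <- function(img, mask, polarity = c("dark", "light"),
                                 radius_range, sensitivity,
                                 config = pipeline_config()) {
  polarity <- match.arg(polarity)
  stopifnot(identical(dim(img), dim(mask)))
  h <- nrow(img); w <- ncol(img)
  g <- sobel_gradient(img)
  sel <- which(g$mag >= config$cht_edge_threshold & mask)
  # guard radii beyond the requested range: a circle slightly outside the
  # range is claimed by its own radius slice (and suppressed) instead of
  # being mis-detected at the range boundary
  radii <- seq.int(max(2, radius_range[1] - 3), radius_range[2] + 4)
  in_range <- radii >= radius_range[1] & radii <= radius_range[2]
  acc <- lapply(radii, function(r) matrix(0, h, w))
  if (length(sel) > 0) {
    py <- (sel - 1) %% h + 1
    px <- (sel - 1) %/% h + 1
    ux <- g$gx[sel] / g$mag[sel]
    uy <- g$gy[sel] / g$mag[sel]
    wt <- g$mag[sel]                          # gradient-magnitude weighting
    sgn <- if (polarity == "dark") -1 else 1  # gradient points dark -> bright
    for (k in seq_along(radii)) {
      r <- radii[k]
      vx <- round(px + sgn * r * ux)
      vy <- round(py + sgn * r * uy)
      ok <- vx >= 1 & vx <= w & vy >= 1 & vy <= h
      if (!any(ok)) next
      idx <- (vx[ok] - 1) * h + vy[ok]
      slice <- numeric(h * w)
      agg <- rowsum(wt[ok], idx)
      slice[as.integer(rownames(agg))] <- agg
      acc[[k]] <- matrix(slice, h, w)
    }
    # smooth each slice (votes scatter by ~1 px) and normalize so a complete
    # circle with a moderately contrasted edge (gradient ~12 units/px)
    # scores ~1; weak peaks are pruned by verify_circle afterwards
    g_ref <- 12
    for (k in seq_along(radii)) {
      acc[[k]] <- smooth_sigma1(acc[[k]]) *
        (2.5 / (2 * pi * radii[k] * g_ref))
    }
  }
  thr <- 3 * (1 - sensitivity)
  found <- list()
  # per-slice running maxima: suppression only lowers values, so a slice
  # needs rescanning only when its cached argmax was suppressed
  peak_val <- vapply(acc, max, 0)
  peak_idx <- vapply(acc, which.max, 0L)
  repeat {
    k <- which.max(peak_val)
    if (peak_val[k] < thr || length(found) >= 200) break
    i <- peak_idx[k]
    cy <- (i - 1) %% h + 1
    cx <- (i - 1) %/% h + 1
    r <- radii[k]
    if (mask[cy, cx] && in_range[k] &&
        verify_circle(img, mask, g, cx, cy, r, polarity))
      found[[length(found) + 1]] <- c(cx, cy, r, peak_val[k])
    # suppress the neighbourhood in every radius slice
    ys <- max(1, cy - r - 2):min(h, cy + r + 2)
    xs <- max(1, cx - r - 2):min(w, cx + r + 2)
    supp <- outer((ys - cy)^2, (xs - cx)^2, "+") <= (r + 2)^2
    for (kk in seq_along(radii)) {
      sl <- acc[[kk]][ys, xs, drop = FALSE]
      sl[supp] <- 0
      acc[[kk]][ys, xs] <- sl
      py <- (peak_idx[kk] - 1) %% h + 1
      px <- (peak_idx[kk] - 1) %/% h + 1
      if (py >= ys[1] && py <= ys[length(ys)] &&
          px >= xs[1] && px <= xs[length(xs)]) {
        peak_idx[kk] <- which.max(acc[[kk]])
        peak_val[kk] <- acc[[kk]][peak_idx[kk]]
      }
    }
  }
  circles <- if (length(found) == 0) {
    data.frame(center_x = numeric(), center_y = numeric(),
               radius = numeric(), metric = numeric())
  } else {
    m <- do.call(rbind, found)
    data.frame(center_x = m[, 1], center_y = m[, 2],
               radius = m[, 3], metric = m[, 4])
  }
  structure(list(circles = circles, polarity = polarity,
                 radius_range = radius_range, sensitivity = sensitivity),
            class = "circle_set")
}

# separable 7-tap Gaussian (sigma 1) smoothing with replicated borders
smooth_sigma1 <- function(m) {
  k <- dnorm(-3:3); k <- k / sum(k)
  out <- 0
  for (j in -3:3) out <- out + k[j + 4] * shift_rep(m, 0, j)
  res <- 0
  for (j in -3:3) res <- res + k[j + 4] * shift_rep(out, j, 0)
  res
}

# Candidate verification: an accepted circle must (a) be darker/brighter
# than its surrounding ring by at least `min_contrast` in the stated
# polarity, and (b) be supported by polarity-consistent radial edge pixels
# over most of its circumference (rejects arc-like responses from larger
# structures such as the inner-cell-mass boundary).
verify_circle <- function(img, mask, g, cx, cy, r, polarity,
                          min_contrast = 22, min_sectors = 8, n_sectors = 12) {
  h <- nrow(img); w <- ncol(img)
  ys <- max(1, cy - r - 4):min(h, cy + r + 4)
  xs <- max(1, cx - r - 4):min(w, cx + r + 4)
  dy <- ys - cy; dx <- xs - cx
  d2 <- outer(dy^2, dx^2, "+")
  sub <- img[ys, xs, drop = FALSE]
  okm <- mask[ys, xs, drop = FALSE]
  inside <- d2 <= (r - 1)^2 & okm
  ring <- d2 > (r + 1)^2 & d2 <= (r + 4)^2 & okm
  if (sum(inside) < 3 || sum(ring) < 3) return(FALSE)
  sgn_pol <- if (polarity == "light") -1 else 1
  diff <- sgn_pol * (mean(sub[ring]) - mean(sub[inside]))
  if (diff < min_contrast) return(FALSE)
  # the surround must contrast in (almost) every direction: a dark/bright
  # stripe through the candidate stays flat along its own axis
  ri <- which(ring)
  ry <- dy[(ri - 1) %% length(dy) + 1]
  rx <- dx[(ri - 1) %/% length(dy) + 1]
  quad <- floor((atan2(ry, rx) + pi) / (pi / 2)) %% 4
  qd <- vapply(0:3, function(qq) {
    if (!any(quad == qq)) return(NA_real_)
    sgn_pol * (mean(sub[ring][quad == qq]) - mean(sub[inside]))
  }, 0)
  if (sum(!is.na(qd)) < 3 || !all(qd >= min_contrast / 2, na.rm = TRUE))
    return(FALSE)
  # a true disc interior is homogeneous; a candidate straddling a foreign
  # edge has interior variance comparable to its apparent contrast
  if (sd(sub[inside]) > 0.6 * diff) return(FALSE)
  # angular coverage of radial, polarity-consistent edge support
  band <- abs(sqrt(d2) - r) <= 2 & okm
  if (!any(band)) return(FALSE)
  bi <- which(band)
  by <- dy[(bi - 1) %% length(dy) + 1]
  bx <- dx[(bi - 1) %/% length(dy) + 1]
  rad <- sqrt(bx^2 + by^2); rad[rad == 0] <- 1
  gx <- g$gx[ys, xs, drop = FALSE][bi]
  gy <- g$gy[ys, xs, drop = FALSE][bi]
  gm <- sqrt(gx^2 + gy^2)
  sgn <- if (polarity == "dark") 1 else -1   # dark: gradient points outward
  radial <- sgn * (gx * bx + gy * by) / (rad * pmax(gm, 1e-9))
  # support must be strong relative to the disc's own contrast, so that a
  # partial arc of a larger structure plus noise cannot fill the sectors
  support <- gm >= max(5, 0.3 * diff) & radial > 0.5
  if (!any(support)) return(FALSE)
  # edge support must sit at the claimed radius, not at a nearby one
  if (abs(mean(rad[support]) - r) > 1.25) return(FALSE)
  ang <- atan2(by[support], bx[support])
  sect <- unique(pmin(floor((ang + pi) / (2 * pi) * n_sectors), n_sectors - 1))
  length(sect) >= min_sectors
}

#' @export
print.circle_set <- function(x, ...) {
  cat(sprintf("%d %s circle(s), radii %d-%d px, sensitivity %.3f\n",
              nrow(x$circles), x$polarity, x$radius_range[1],
              x$radius_range[2], x$sensitivity))
  invisible(x)
}

#' Mean intensity over detected circles
#'
#' Builds a binary mask of discs placed at every detected centre with the
#' mean radius of all detected circles, and returns the mean grey intensity
#' of the image over the union of those discs (restricted to the region
#' mask). An empty circle set yields 0 by convention.
#'
#' @param cs a `circle_set`.
#' @param img,mask the image and region mask the circles were detected in.
#' @return mean intensity in 0..255 (0 for an empty set).
#' @export
circle_mean_intensity <- function(cs, img, mask) {
  if (nrow(cs$circles) == 0) return(0)
  rm_ <- mean(cs$circles$radius)
  h <- nrow(img); w <- ncol(img)
  disc <- matrix(FALSE, h, w)
  for (i in seq_len(nrow(cs$circles))) {
    cx <- cs$circles$center_x[i]; cy <- cs$circles$center_y[i]
    ys <- max(1, floor(cy - rm_)):min(h, ceiling(cy + rm_))
    xs <- max(1, floor(cx - rm_)):min(w, ceiling(cx + rm_))
    d2 <- outer((ys - cy)^2, (xs - cx)^2, "+")
    disc[ys, xs] <- disc[ys, xs] | d2 <= rm_^2
  }
  disc <- disc & mask
  if (!any(disc)) return(0)
  mean(img[disc])
}

#' Inclusion-circle features (variables 9-16)
#'
#' The four (polarity, radius range) detector combinations on the ER image:
#' dark and light circles of radii 4-8 px (DC1/LC1, sensitivity 0.935) and
#' 9-15 px (DC2/LC2, sensitivity 0.94), each reported as a count and the
#' mean intensity over the detected discs.
#'
#' @param masks a `region_masks` object.
#' @param config a [pipeline_config()].
#' @return named numeric vector of length 8 in canonical order.
#' @export
circle_features <- function(masks, config = pipeline_config()) {
  run <- function(pol, range_i) {
    cs <- detect_inner_circles(masks$crop, masks$er_mask, polarity = pol,
                               radius_range = config$inner_ranges[[range_i]],
                               sensitivity = config$inner_sensitivities[range_i],
                               config = config)
    c(nrow(cs$circles),
      circle_mean_intensity(cs, masks$crop, masks$er_mask))
  }
  dc1 <- run("dark", 1); lc1 <- run("light", 1)
  dc2 <- run("dark", 2); lc2 <- run("light", 2)
  c("DC1" = dc1[1], "Mean DC1" = dc1[2], "LC1" = lc1[1], "Mean LC1" = lc1[2],
    "DC2" = dc2[1], "Mean DC2" = dc2[2], "LC2" = lc2[1], "Mean LC2" = lc2[2])
}
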