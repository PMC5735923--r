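# Watershed segmentation of the isolated embryo and the inner-cell-mass
# descriptors (variables 32-36).

#' Watershed segmentation of the embryo
#'
#' Watershed transform of the greyscale intensity surface restricted to the
#' region mask: dark pixels are low, catchment basins form around regional
#' minima. The background is raised to a plateau above the 8-bit range so it
#' seeds no interior basin, and basin labels outside the mask are dropped.
#' No marker control is applied; an optional Gaussian pre-smoothing
#' (`config$watershed_smooth_sigma`, off by default) is available because an
#' unsuppressed watershed over-segments noisy images.
#'
#' @param img greyscale matrix (the ER crop).
#' @param mask logical region mask.
#' @param config a [pipeline_config()] (supplies `watershed_tolerance` and
#'   `watershed_smooth_sigma`).
#' @return object of class `label_map`: list with `labels` (integer matrix;
#'   0 = outside mask, k >= 1 = basin k) and `n_regions`.
#' @export
watershed_segment <- function(img, mask, config = pipeline_config()) {
  stopifnot(identical(dim(img), dim(mask)))
  if (!any(mask)) bq_stop("bq_region_error", "empty mask")
  surf <- img
  if (config$watershed_smooth_sigma > 0) {
    sm <- EBImage::gblur(as_ebi(img), sigma = config$watershed_smooth_sigma)
    surf <- from_ebi(sm)
  }
  surf[!mask] <- 256            # background plateau above the 8-bit range
  inv <- (256 - surf) / 256     # basins around minima = peaks of inverted
  ws <- EBImage::watershed(EBImage::Image(t(inv)),
                           tolerance = config$watershed_tolerance / 256,
                           ext = 1)
  labels <- t(EBImage::imageData(ws))
  labels[!mask] <- 0L
  keep <- sort(unique(labels[labels > 0]))
  if (length(keep) == 0) {      # constant surface: the mask is one basin
    labels[mask] <- 1L
    keep <- 1L
  }
  labels <- matrix(match(labels, keep, nomatch = 0L), nrow(labels))
  structure(list(labels = labels, n_regions = length(keep)),
            class = "label_map")
}

#' Number of watershed regions (variable 32)
#'
#' @param lm a `label_map` from [watershed_segment()].
#' @return integer count of basins intersecting the mask.
#' @export
wsn <- function(lm) lm$n_regions

# pixel-set shape helpers -------------------------------------------------

# area of the convex hull of a pixel set = number of pixel centres inside
# (or on) the convex polygon spanned by the pixel centres
convex_hull_area <- function(ys, xs) {
  if (length(ys) <= 2) return(length(ys))
  pts <- unique(cbind(xs, ys))
  hull <- grDevices::chull(pts)            # clockwise vertex order
  hx <- pts[hull, 1]; hy <- pts[hull, 2]
  if (length(hull) <= 2) return(nrow(pts))
  n <- length(hx)
  signed2 <- sum(hx * hy[c(2:n, 1)] - hx[c(2:n, 1)] * hy)
  if (signed2 < 0) { hx <- rev(hx); hy <- rev(hy) }  # force counter-clockwise
  gx <- seq(min(xs), max(xs)); gy <- seq(min(ys), max(ys))
  cand <- cbind(rep(gx, each = length(gy)), rep(gy, length(gx)))
  inside <- rep(TRUE, nrow(cand))
  for (k in seq_len(n)) {                   # half-plane test per hull edge
    k2 <- if (k == n) 1 else k + 1
    ex <- hx[k2] - hx[k]; ey <- hy[k2] - hy[k]
    cr <- ex * (cand[, 2] - hy[k]) - ey * (cand[, 1] - hx[k])
    inside <- inside & cr >= -1e-9
  }
  sum(inside)
}

# eccentricity of the ellipse with the same second central moments as the
# pixel set: focal distance over major axis length, 0 = circle, 1 = line
moment_eccentricity <- function(ys, xs) {
  n <- length(ys)
  if (n <= 1) return(0)
  mx <- mean(xs); my <- mean(ys)
  mu20 <- mean((xs - mx)^2); mu02 <- mean((ys - my)^2)
  mu11 <- mean((xs - mx) * (ys - my))
  common <- sqrt((mu20 - mu02)^2 + 4 * mu11^2)
  l1 <- (mu20 + mu02 + common) / 2          # major-axis variance
  l2 <- (mu20 + mu02 - common) / 2
  if (l1 <= 0) return(0)
  sqrt(pmax(0, 1 - l2 / l1))
}

#' Inner-cell-mass descriptors (variables 33-36)
#'
#' Selects the watershed basin with the largest pixel count (ties broken
#' toward the smallest label) as the ICM mask, and returns its area, the
#' area of its convex hull (the smallest convex polygon containing it), the
#' eccentricity of the ellipse with the same second moments (0 = circle,
#' 1 = line segment), and its mean grey intensity.
#'
#' @param lm a `label_map`.
#' @param img the greyscale image the labels refer to.
#' @return list with `area`, `convex_area`, `eccentricity`,
#'   `mean_intensity` and the selected `label` and logical `mask`.
#' @export
icm_props <- function(lm, img) {
  stopifnot(lm$n_regions >= 1)
  areas <- tabulate(lm$labels[lm$labels > 0], nbins = lm$n_regions)
  lab <- which.max(areas)                   # first max = smallest label
  sel <- lm$labels == lab
  idx <- which(sel)
  ys <- (idx - 1) %% nrow(sel) + 1
  xs <- (idx - 1) %/% nrow(sel) + 1
  list(area = length(idx),
       convex_area = convex_hull_area(ys, xs),
       eccentricity = moment_eccentricity(ys, xs),
       mean_intensity = mean(img[sel]),
       label = lab, mask = sel)
}

#' Watershed features (variables 32-36)
#'
#' @param masks a `region_masks` object.
#' @param config a [pipeline_config()]; `watershed_region` selects whether
#'   the transform runs on the whole isolated embryo (ER, default) or on RR.
#' @return named numeric vector: WSN, Area ICM, Convex ICM, Eccen ICM,
#'   Mean ICM.
#' @export
watershed_features <- function(masks, config = pipeline_config()) {
  mask <- if (config$watershed_region == "er") masks$er_mask else masks$rr_mask
  lm <- watershed_segment(masks$crop, mask, config)
  pr <- icm_props(lm, masks$crop)
  c("WSN" = wsn(lm), "Area ICM" = pr$area, "Convex ICM" = pr$convex_area,
    "Eccen ICM" = pr$eccentricity, "Mean ICM" = pr$mean_intensity)
}
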