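# First-order intensity statistics and the Otsu-based Sum ER
# (variables 17-31).

region_pixels <- function(img, mask) {
  if (!any(mask)) bq_stop("bq_region_error", "empty region")
  as.numeric(img[mask])
}

#' Otsu bright fraction of the ER region (variable 18)
#'
#' Computes the Otsu threshold over the masked ER pixels, counts the pixels
#' above it, and divides by the total embryo area (the ER pixel count). A
#' constant region has no Otsu threshold and yields 0 with a
#' `degenerate_otsu` attribute.
#'
#' @param img greyscale matrix (ER crop).
#' @param mask logical ER mask.
#' @param total_area total embryo area in px (defaults to `sum(mask)`).
#' @return fraction in 0..1.
#' @export
sum_er <- function(img, mask, total_area = sum(mask)) {
  x <- region_pixels(img, mask)
  if (min(x) == max(x)) {
    out <- 0
    attr(out, "degenerate_otsu") <- TRUE
    return(out)
  }
  thr <- EBImage::otsu(EBImage::Image(matrix(x / 255, 1)),
                       range = c(0, 1), levels = 256) * 255
  sum(x > thr) / total_area
}

#' First-order region statistics
#'
#' `mean_grey` is the arithmetic mean of the masked intensities;
#' `std_dev` the sample standard deviation (n - 1 denominator; NA for fewer
#' than two pixels); `mode_value` the most frequent intensity with ties
#' broken toward the smallest value.
#'
#' @param img greyscale matrix.
#' @param mask logical region mask.
#' @return a single numeric value.
#' @export
mean_grey <- function(img, mask) mean(region_pixels(img, mask))

#' @rdname mean_grey
#' @export
std_dev <- function(img, mask) {
  x <- region_pixels(img, mask)
  if (length(x) < 2) return(NA_real_)
  sd(x)
}

#' @rdname mean_grey
#' @export
mode_value <- function(img, mask) {
  x <- region_pixels(img, mask)
  counts <- tabulate(as.integer(x) + 1L, nbins = 256)
  which.max(counts) - 1  # which.max takes the first (= smallest) on ties
}

#' Intensity-band pixel fractions
#'
#' Counts of masked pixels in an intensity band, divided by the total embryo
#' area: `fraction_dark` counts intensities `<= 25`, `fraction_bright`
#' intensities `>= 230` (each bound inclusive, i.e. the darkest/lightest 10%
#' of the 8-bit range), and `fraction_near_mean` intensities within
#' `+/- band` of the region's own mean intensity (bounds inclusive).
#'
#' @param img greyscale matrix.
#' @param mask logical region mask.
#' @param total_area total embryo area in px (the ER pixel count).
#' @param threshold intensity cutoff.
#' @param band half-width of the near-mean band.
#' @return fraction (>= 0; 0..1 when `total_area` covers the region).
#' @export
fraction_dark <- function(img, mask, total_area, threshold = 25) {
  sum(img[mask] <= threshold) / total_area
}

#' @rdname fraction_dark
#' @export
fraction_bright <- function(img, mask, total_area, threshold = 230) {
  sum(img[mask] >= threshold) / total_area
}

#' @rdname fraction_dark
#' @export
fraction_near_mean <- function(img, mask, total_area, band = 10) {
  x <- region_pixels(img, mask)
  m <- mean(x)
  sum(x >= m - band & x <= m + band) / total_area
}

#' Intensity features (variables 17-31)
#'
#' Radius ER (half of the ER crop width), the Otsu-based Sum ER, the mean
#' grey intensity of ER, and for each of RR and TE: standard deviation,
#' mean, mode, dark fraction, near-mean fraction and bright fraction (all
#' fractions relative to the total embryo area).
#'
#' @param masks a `region_masks` object.
#' @param config a [pipeline_config()].
#' @return named numeric vector of length 15 in canonical order.
#' @export
intensity_features <- function(masks, config = pipeline_config()) {
  img <- masks$crop; ta <- masks$total_area
  block <- function(mask, tag) {
    v <- c(std_dev(img, mask), mean_grey(img, mask), mode_value(img, mask),
           fraction_dark(img, mask, ta, config$dark_threshold),
           fraction_near_mean(img, mask, ta, config$near_mean_band),
           fraction_bright(img, mask, ta, config$bright_threshold))
    names(v) <- paste(c("Deviation", "Mean grey", "Mode value", "Dark",
                        "Mean Count", "Bright"), tag)
    v
  }
  c("Radius ER" = masks$radius_er,
    "Sum ER" = as.numeric(sum_er(img, masks$er_mask, ta)),
    "Mean grey ER" = mean_grey(img, masks$er_mask),
    block(masks$rr_mask, "RR"),
    block(masks$te_mask, "TE"))
}
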