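# Grey-level co-occurrence texture: 8-level quantization, GLCM at a fixed
# offset, and the four Haralick-type statistics used as variables 1-8.

#' Quantize a masked region to 8 grey levels
#'
#' Masked pixels are binned into `levels` equal-width bins spanning the
#' minimum..maximum of the masked pixels (the conventional grey-limits
#' behaviour); a constant region collapses to level 0. Background pixels are
#' excluded via the mask and keep the value NA in the output grid.
#'
#' @param img greyscale matrix (0..255).
#' @param mask logical matrix of the same size; TRUE = region pixel.
#' @param levels number of output levels (default 8).
#' @param limits optional fixed `c(min, max)` binning range overriding the
#'   masked-pixel range.
#' @return integer matrix with values 0..levels-1 inside the mask, NA outside.
#' @export
quantize8 <- function(img, mask, levels = 8, limits = NULL) {
  stopifnot(identical(dim(img), dim(mask)))
  if (!any(mask)) bq_stop("bq_region_error", "empty mask")
  v <- img[mask]
  lo <- if (is.null(limits)) min(v) else limits[1]
  hi <- if (is.null(limits)) max(v) else limits[2]
  q <- matrix(NA_integer_, nrow(img), ncol(img))
  if (hi <= lo) {
    q[mask] <- 0L
  } else {
    q[mask] <- pmin(as.integer(floor((img[mask] - lo) / (hi - lo) * levels)),
                    levels - 1L)
  }
  q
}

glcm_offset <- function(d, theta) {
  switch(as.character(theta),
         "0"   = c(0L, as.integer(d)),      # (row, col) offset
         "45"  = c(-as.integer(d), as.integer(d)),
         "90"  = c(-as.integer(d), 0L),
         "135" = c(-as.integer(d), -as.integer(d)),
         bq_stop("bq_config_error", "theta must be one of 0, 45, 90, 135"))
}

#' Compute a grey-level co-occurrence matrix
#'
#' Joint distribution of quantized intensities of pixel pairs (p, p + offset)
#' where both pixels lie inside the mask. Probabilities are counts normalized
#' by the total pair count; the matrix is not symmetrized.
#'
#' @param q quantized grid from [quantize8()] (NA outside the mask).
#' @param d offset distance in px (default 1).
#' @param theta offset angle in degrees: 0 (to the right), 45, 90 or 135.
#' @param levels number of grey levels (default 8).
#' @return object of class `glcm`: list with `p` (levels x levels probability
#'   matrix), `counts`, `n_pairs`, `d`, `theta`. `n_pairs = 0` marks a
#'   degenerate matrix.
#' @export
#' @examples
#' q <- matrix(c(0L, 7L, 0L, 7L), 1)
#' g <- compute_glcm(q)
#' g$p[1, 8]  # P(0 -> 7)
compute_glcm <- function(q, d = 1, theta = 0, levels = 8) {
  off <- glcm_offset(d, theta)
  h <- nrow(q); w <- ncol(q)
  counts <- matrix(0, levels, levels)
  r1 <- max(1, 1 - off[1]):min(h, h - off[1])
  c1 <- max(1, 1 - off[2]):min(w, w - off[2])
  if (length(r1) > 0 && length(c1) > 0) {
    a <- q[r1, c1, drop = FALSE]
    b <- q[r1 + off[1], c1 + off[2], drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    if (any(ok)) {
      tab <- table(factor(a[ok], levels = 0:(levels - 1)),
                   factor(b[ok], levels = 0:(levels - 1)))
      counts <- matrix(as.numeric(tab), levels, levels)
    }
  }
  n <- sum(counts)
  structure(list(p = if (n > 0) counts / n else counts,
                 counts = counts, n_pairs = n, d = d, theta = theta,
                 levels = levels),
            class = "glcm")
}

glcm_marginals <- function(g) {
  lev <- seq_len(g$levels) - 1
  pi_ <- rowSums(g$p); pj <- colSums(g$p)
  mu_i <- sum(lev * pi_); mu_j <- sum(lev * pj)
  list(mu_i = mu_i, mu_j = mu_j,
       sigma_i = sqrt(sum((lev - mu_i)^2 * pi_)),
       sigma_j = sqrt(sum((lev - mu_j)^2 * pj)))
}

#' GLCM texture statistics
#'
#' The four co-occurrence statistics of the pipeline. With `p(i,j)` the GLCM
#' probabilities over levels `i, j = 0..7`:
#' * contrast: `sum |i-j|^2 p(i,j)` (0 for a constant region);
#' * correlation: `sum (i-mu_i)(j-mu_j) p(i,j) / (sigma_i sigma_j)`
#'   (+1/-1 for perfectly linearly related neighbour pairs; NaN when a
#'   marginal variance is zero, e.g. a constant region);
#' * energy: `sum p(i,j)^2` (1 for a constant region);
#' * homogeneity: `sum p(i,j) / (1 + |i-j|)` (1 for a diagonal GLCM).
#'
#' A degenerate GLCM (no pixel pairs) yields contrast 0 and NA for the other
#' statistics.
#'
#' @param g a `glcm` object from [compute_glcm()].
#' @return a single numeric value.
#' @export
glcm_contrast <- function(g) {
  if (g$n_pairs == 0) return(0)
  lev <- seq_len(g$levels) - 1
  sum(outer(lev, lev, function(i, j) abs(i - j)^2) * g$p)
}

#' @rdname glcm_contrast
#' @export
glcm_correlation <- function(g) {
  if (g$n_pairs == 0) return(NA_real_)
  m <- glcm_marginals(g)
  if (m$sigma_i * m$sigma_j == 0) return(NaN)
  lev <- seq_len(g$levels) - 1
  sum(outer(lev - m$mu_i, lev - m$mu_j) * g$p) / (m$sigma_i * m$sigma_j)
}

#' @rdname glcm_contrast
#' @export
glcm_energy <- function(g) {
  if (g$n_pairs == 0) return(NA_real_)
  sum(g$p^2)
}

#' @rdname glcm_contrast
#' @export
glcm_homogeneity <- function(g) {
  if (g$n_pairs == 0) return(NA_real_)
  lev <- seq_len(g$levels) - 1
  sum(g$p / (1 + outer(lev, lev, function(i, j) abs(i - j))))
}

# all four statistics of one masked region
glcm_stats_region <- function(img, mask, config) {
  q <- quantize8(img, mask, levels = config$glcm_levels)
  g <- compute_glcm(q, d = config$glcm_d, theta = config$glcm_theta,
                    levels = config$glcm_levels)
  c(contrast = glcm_contrast(g), correlation = glcm_correlation(g),
    energy = glcm_energy(g), homogeneity = glcm_homogeneity(g))
}

#' Texture features of the RR and TE regions (variables 1-8)
#'
#' Contrast, correlation, energy and homogeneity of the GLCM computed on the
#' reduced region RR (variables 1-4) and on the trophectoderm annulus TE
#' (variables 5-8).
#'
#' @param masks a `region_masks` object from [make_masks()].
#' @param config a [pipeline_config()].
#' @return named numeric vector of length 8.
#' @export
texture_features <- function(masks, config = pipeline_config()) {
  rr <- glcm_stats_region(masks$crop, masks$rr_mask, config)
  te <- glcm_stats_region(masks$crop, masks$te_mask, config)
  c("Contrast RR" = unname(rr["contrast"]),
    "Correlation RR" = unname(rr["correlation"]),
    "Energy RR" = unname(rr["energy"]),
    "Homogeneity RR" = unname(rr["homogeneity"]),
    "Contrast TE" = unname(te["contrast"]),
    "Correlation TE" = unname(te["correlation"]),
    "Energy TE" = unname(te["energy"]),
    "Homogeneity TE" = unname(te["homogeneity"]))
}
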