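# Embryo localization: Sobel gradient -> binary edge image -> two-stage
# circular Hough transform -> ER/RR/TE region masks.

# shift with replicated borders; dy/dx are the source offsets, so the result
# at (y, x) holds m[y + dy, x + dx]
shift_rep <- function(m, dy, dx) {
  h <- nrow(m); w <- ncol(m)
  ri <- pmin(pmax(seq_len(h) + dy, 1), h)
  ci <- pmin(pmax(seq_len(w) + dx, 1), w)
  m[ri, ci, drop = FALSE]
}

# Sobel derivative estimates (intensity units per px): gx increases to the
# right (+x), gy increases downward (+y, growing row index)
sobel_gradient <- function(img) {
  m <- matrix(as.numeric(img), nrow(img))
  gx <- (shift_rep(m, -1, 1) + 2 * shift_rep(m, 0, 1) + shift_rep(m, 1, 1) -
         shift_rep(m, -1, -1) - 2 * shift_rep(m, 0, -1) - shift_rep(m, 1, -1)) / 8
  gy <- (shift_rep(m, 1, -1) + 2 * shift_rep(m, 1, 0) + shift_rep(m, 1, 1) -
         shift_rep(m, -1, -1) - 2 * shift_rep(m, -1, 0) - shift_rep(m, -1, 1)) / 8
  list(gx = gx, gy = gy, mag = sqrt(gx^2 + gy^2))
}

#' Gradient magnitude image
#'
#' Per-pixel gradient magnitude from 3x3 Sobel first-derivative kernels,
#' linearly rescaled to 0..255. Edges of the roughly circular embryo respond
#' in all orientations, which is what the subsequent circle detection needs.
#'
#' @param img greyscale matrix (0..255), typically a standardized image.
#' @return integer matrix of the same size, 0..255.
#' @export
gradient_magnitude <- function(img) {
  mag <- sobel_gradient(img)$mag
  m <- max(mag)
  if (m == 0) return(matrix(0L, nrow(img), ncol(img)))
  round(mag * (255 / m))
}

#' Binarize a gradient image
#'
#' @param grad 8-bit image (matrix, 0..255).
#' @param threshold intensity threshold; pixels `>= threshold` are TRUE.
#' @return logical matrix.
#' @export
binarize <- function(grad, threshold = 128) {
  grad >= threshold
}

# Annulus-kernel Hough accumulator, evaluated by FFT convolution: for each
# candidate radius, the accumulator is the count of edge pixels on a 1-px
# annulus around each centre, normalized by the annulus size so a complete
# edge ring scores ~1 regardless of radius.
cht_ring_search <- function(binary, radii) {
  h <- nrow(binary); w <- ncol(binary)
  B <- matrix(as.numeric(binary), h, w)
  FB <- fft(B)
  dy <- c(0:(h %/% 2), -((h - h %/% 2 - 1):1))
  dx <- c(0:(w %/% 2), -((w - w %/% 2 - 1):1))
  D <- sqrt(outer(dy^2, dx^2, "+"))
  best <- list(metric = -Inf)
  for (r in radii) {
    K <- matrix(0, h, w)
    K[abs(D - r) <= 1] <- 1
    A <- Re(fft(FB * Conj(fft(K)), inverse = TRUE)) / (length(B) * sum(K))
    i <- which.max(A)
    if (A[i] > best$metric) {
      best <- list(center_y = (i - 1) %% h + 1,
                   center_x = (i - 1) %/% h + 1,
                   radius = r, metric = A[i])
    }
  }
  best
}

#' Detect the embryo circle
#'
#' Two-stage circular Hough transform on the binary edge image: the first
#' stage searches radii 100-150 px (early blastocysts), the second 150-250 px
#' (expanded blastocysts). From each stage the best-scoring circle is kept;
#' the circle with the higher accumulator metric wins, with ties broken
#' toward the larger radius.
#'
#' @param binary logical edge matrix (typically
#'   `binarize(gradient_magnitude(std))`).
#' @param config a [pipeline_config()]; supplies the stage radius ranges and
#'   the minimum acceptable accumulator metric.
#' @return an object of class `embryo_circle`: list with `center_x`,
#'   `center_y`, `radius`, `metric`, `stage`, and both per-stage candidates
#'   under `$candidates`.
#' @export
#' @examples
#' ph <- generate_phantom(phantom_spec(seed = 5, embryo_radius = 150))
#' std <- standardize_image(ph$image)
#' circ <- detect_embryo_circle(binarize(gradient_magnitude(std)))
#' circ$radius
detect_embryo_circle <- function(binary, config = pipeline_config()) {
  stopifnot(is.logical(binary) || all(binary %in% c(0, 1)))
  s1 <- cht_ring_search(binary, config$stage1_radii)
  # the wide second stage is searched at step 2, then refined around the
  # best radius; the annulus kernel is 2 px thick, so no radius is missed
  r2 <- config$stage2_radii
  coarse <- cht_ring_search(binary, r2[seq(1, length(r2), by = 2)])
  fine <- intersect(coarse$radius + (-1:1), r2)
  s2 <- cht_ring_search(binary, fine)
  if (max(s1$metric, s2$metric) < config$min_circle_metric)
    bq_stop("bq_detection_error", sprintf(
      "no embryo circle found (stage metrics %.3f / %.3f below %.3f)",
      s1$metric, s2$metric, config$min_circle_metric),
      stage1 = s1, stage2 = s2)
  # best metric wins; exact tie -> larger radius
  pick <- if (s2$metric >= s1$metric) list(c = s2, stage = 2L)
          else list(c = s1, stage = 1L)
  out <- pick$c
  out$radius <- min(max(out$radius, min(config$stage1_radii)),
                    max(config$stage2_radii))
  out$stage <- pick$stage
  out$candidates <- list(stage1 = s1, stage2 = s2)
  class(out) <- "embryo_circle"
  out
}

#' @export
print.embryo_circle <- function(x, ...) {
  cat(sprintf("embryo circle: centre (%.1f, %.1f), radius %.1f px, metric %.3f (stage %d)\n",
              x$center_x, x$center_y, x$radius, x$metric, x$stage))
  invisible(x)
}

#' Build ER / RR / TE region masks
#'
#' From the detected embryo circle, builds the expanded disc ER (radius
#' r + 5 px, so the zona pellucida is included), the reduced disc RR (radius
#' r - 40 px, trophectoderm discarded) and their set difference TE (the
#' trophectoderm annulus). The standardized image is cropped to the ER
#' bounding square; pixels outside a region (or outside the image border)
#' are excluded through explicit logical masks rather than sentinel values.
#'
#' @param circle an `embryo_circle`.
#' @param img the standardized image the circle was detected in.
#' @param config a [pipeline_config()] (supplies `er_delta`, `rr_delta`).
#' @return object of class `region_masks`: list with `crop` (the ER bounding
#'   square sub-image), logical masks `er_mask`, `rr_mask`, `te_mask` of the
#'   same size, `total_area` (pixels in ER), `radius_er`, the source
#'   `circle` and the crop `offset` (top-left pixel in image coordinates).
#' @export
make_masks <- function(circle, img, config = pipeline_config()) {
  r <- unname(circle$radius)
  r_er <- r + config$er_delta
  r_rr <- r + config$rr_delta
  if (r_rr < 1)
    bq_stop("bq_region_error", sprintf("degenerate RR region (radius %.1f)", r_rr))
  rp <- round(r_er)
  cx <- round(unname(circle$center_x)); cy <- round(unname(circle$center_y))
  side <- 2L * as.integer(rp)
  y0 <- cy - rp + 1L; x0 <- cx - rp + 1L       # crop top-left in image frame
  rows <- y0:(y0 + side - 1L); cols <- x0:(x0 + side - 1L)
  vr <- rows >= 1 & rows <= nrow(img)
  vc <- cols >= 1 & cols <= ncol(img)
  crop <- matrix(0L, side, side)
  crop[vr, vc] <- img[rows[vr], cols[vc]]
  inside <- outer(vr, vc, "&")                  # pixels backed by the image
  yy <- matrix(rows, side, side)
  xx <- matrix(cols, side, side, byrow = TRUE)
  d2 <- (xx - unname(circle$center_x))^2 + (yy - unname(circle$center_y))^2
  er <- d2 <= r_er^2 & inside
  rr <- d2 <= r_rr^2 & inside
  te <- er & !rr
  structure(list(crop = crop, er_mask = er, rr_mask = rr, te_mask = te,
                 total_area = sum(er), radius_er = rp,
                 circle = circle, offset = c(y = y0, x = x0)),
            class = "region_masks")
}

#' @export
print.region_masks <- function(x, ...) {
  cat(sprintf("region masks: ER %d px (radius %d), RR %d px, TE %d px, crop %dx%d\n",
              sum(x$er_mask), x$radius_er, sum(x$rr_mask), sum(x$te_mask),
              nrow(x$crop), ncol(x$crop)))
  invisible(x)
}
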