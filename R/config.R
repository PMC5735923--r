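#' Pipeline configuration
#'
#' Builds the configuration list consumed by every pipeline stage. The
#' defaults are the published parameters of the method: binary threshold 128,
#' two-stage embryo search over radii 100-150 and 150-250 px, ER expansion
#' +5 px, RR reduction -40 px, inclusion-circle searches over radii 4-8
#' (sensitivity 0.935) and 9-15 (sensitivity 0.94), GLCM with 8 grey levels
#' at offset d = 1, theta = 0, dark threshold <= 25, bright threshold >= 230,
#' near-mean band +/- 10, and 1% histogram saturation at each tail.
#'
#' @param binary_threshold intensity threshold for the gradient binarization
#'   (pixels >= threshold are edge pixels).
#' @param stage1_radii,stage2_radii integer vectors of candidate embryo radii
#'   (px) for the two Hough search stages.
#' @param er_delta,rr_delta radius offsets (px) defining the expanded (ER)
#'   and reduced (RR) discs relative to the detected embryo radius.
#' @param inner_ranges list of two integer vectors: small and large
#'   inclusion-circle radius ranges (px).
#' @param inner_sensitivities detection sensitivities in (0,1) for the two
#'   inclusion-circle searches; higher accepts weaker accumulator peaks.
#' @param glcm_d,glcm_theta GLCM offset distance (px) and angle (degrees;
#'   one of 0, 45, 90, 135).
#' @param glcm_levels number of grey levels for GLCM quantization.
#' @param dark_threshold,bright_threshold inclusive intensity cutoffs for the
#'   dark and bright pixel fractions.
#' @param near_mean_band half-width (intensity units) of the near-mean band.
#' @param stretch_tails length-2 numeric, fraction of pixels saturated at the
#'   lower and upper tail by the contrast stretch.
#' @param min_circle_metric minimum normalized accumulator peak for the
#'   embryo detection to be accepted.
#' @param cht_edge_threshold minimum gradient magnitude (intensity units per
#'   px) for a pixel to vote in the inclusion-circle accumulator.
#' @param watershed_tolerance basin-merging depth (intensity units) passed to
#'   the watershed; small values approximate an unsuppressed transform.
#' @param watershed_smooth_sigma Gaussian pre-smoothing sigma (px) applied
#'   before the watershed; 0 disables smoothing (default).
#' @param watershed_region region the watershed runs on: "er" or "rr".
#' @param seed integer seed used by stochastic helpers (phantom generation).
#'
#' @return a named list of class `bq_config`.
#' @export
#' @examples
#' cfg <- pipeline_config()
#' cfg$binary_threshold
pipeline_config <- function(binary_threshold = 128,
                            stage1_radii = 100:150,
                            stage2_radii = 150:250,
                            er_delta = 5,
                            rr_delta = -40,
                            inner_ranges = list(c(4L, 8L), c(9L, 15L)),
                            inner_sensitivities = c(0.935, 0.94),
                            glcm_d = 1,
                            glcm_theta = 0,
                            glcm_levels = 8,
                            dark_threshold = 25,
                            bright_threshold = 230,
                            near_mean_band = 10,
                            stretch_tails = c(0.01, 0.01),
                            min_circle_metric = 0.25,
                            cht_edge_threshold = 5,
                            watershed_tolerance = 1,
                            watershed_smooth_sigma = 0,
                            watershed_region = c("er", "rr"),
                            seed = 1L) {
  cfg <- list(
    binary_threshold = binary_threshold,
    stage1_radii = as.integer(stage1_radii),
    stage2_radii = as.integer(stage2_radii),
    er_delta = er_delta,
    rr_delta = rr_delta,
    inner_ranges = inner_ranges,
    inner_sensitivities = inner_sensitivities,
    glcm_d = glcm_d,
    glcm_theta = glcm_theta,
    glcm_levels = glcm_levels,
    dark_threshold = dark_threshold,
    bright_threshold = bright_threshold,
    near_mean_band = near_mean_band,
    stretch_tails = stretch_tails,
    min_circle_metric = min_circle_metric,
    cht_edge_threshold = cht_edge_threshold,
    watershed_tolerance = watershed_tolerance,
    watershed_smooth_sigma = watershed_smooth_sigma,
    watershed_region = match.arg(watershed_region),
    seed = as.integer(seed)
  )
  validate_config(cfg)
  class(cfg) <- "bq_config"
  cfg
}

validate_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) bq_stop("bq_config_error", msg)
  chk(cfg$binary_threshold >= 0 && cfg$binary_threshold <= 255,
      "binary_threshold must be in [0, 255]")
  chk(all(cfg$stage1_radii >= 1) && all(cfg$stage2_radii >= 1),
      "search radii must be positive")
  chk(cfg$rr_delta < 0, "rr_delta must be negative")
  chk(length(cfg$inner_ranges) == 2 &&
        all(vapply(cfg$inner_ranges, length, 1L) == 2),
      "inner_ranges must be two (min, max) pairs")
  chk(all(cfg$inner_sensitivities > 0 & cfg$inner_sensitivities < 1),
      "sensitivities must be in (0, 1)")
  chk(cfg$glcm_theta %in% c(0, 45, 90, 135),
      "glcm_theta must be one of 0, 45, 90, 135")
  chk(cfg$glcm_levels >= 2, "glcm_levels must be >= 2")
  chk(all(cfg$stretch_tails >= 0) && sum(cfg$stretch_tails) < 1,
      "stretch_tails must be nonnegative and sum to < 1")
  invisible(cfg)
}

#' Read / write a pipeline configuration file
#'
#' Configurations are stored as flat YAML key-value files; every key is an
#' argument of [pipeline_config()], so a partial file overrides only the
#' listed parameters.
#'
#' @param path file path.
#' @param cfg a `bq_config` list.
#' @return `read_config` returns a `bq_config`; `write_config` returns
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) bq_stop("bq_input_error", paste("no such file:", path))
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "bq_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
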