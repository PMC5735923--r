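# Orchestration: the canonical 36-variable feature vector and its table
# layout (ID, variables 1-36, three embryologist grades, their mode).

#' Canonical names of the 36 quantitative variables
#'
#' @return character vector of length 36 in canonical column order.
#' @export
feature_names <- function() {
  c("Contrast RR", "Correlation RR", "Energy RR", "Homogeneity RR",
    "Contrast TE", "Correlation TE", "Energy TE", "Homogeneity TE",
    "DC1", "Mean DC1", "LC1", "Mean LC1",
    "DC2", "Mean DC2", "LC2", "Mean LC2",
    "Radius ER", "Sum ER", "Mean grey ER",
    "Deviation RR", "Mean grey RR", "Mode value RR",
    "Dark RR", "Mean Count RR", "Bright RR",
    "Deviation TE", "Mean grey TE", "Mode value TE",
    "Dark TE", "Mean Count TE", "Bright TE",
    "WSN", "Area ICM", "Convex ICM", "Eccen ICM", "Mean ICM")
}

#' Extract the full 36-variable feature vector from one image
#'
#' Runs the complete pipeline on a single micrograph: standardization,
#' gradient + binarization, two-stage embryo circle detection, ER/RR/TE
#' isolation, GLCM texture (variables 1-8), inclusion circles (9-16),
#' intensity statistics (17-31) and watershed ICM descriptors (32-36).
#' Deterministic for a fixed input and configuration. A segmentation failure
#' raises a structured error carrying the image id and stage diagnostics
#' rather than returning a partial row.
#'
#' @param x file path or canonical pixel array.
#' @param config a [pipeline_config()].
#' @param image_id identifier stored with the result (defaults to the file
#'   name, or "image" for in-memory input).
#' @return object of class `feature_vector`: list with `image_id`, `values`
#'   (named numeric of length 36), `quality_flags` (character vector naming
#'   degenerate statistics) and the detected `circle`.
#' @export
#' @examples
#' ph <- generate_phantom(phantom_spec(width = 640, height = 480, seed = 9))
#' fv <- extract_all(ph$image)
#' length(fv$values)
extract_all <- function(x, config = pipeline_config(),
                        image_id = NULL) {
  if (is.null(image_id))
    image_id <- if (is.character(x)) basename(x) else "image"
  std <- standardize_image(x, config)
  circ <- withCallingHandlers(
    tryCatch(
      detect_embryo_circle(binarize(gradient_magnitude(std),
                                    config$binary_threshold), config),
      bq_detection_error = function(e) {
        bq_stop("bq_extraction_error",
                paste0("segmentation failed for '", image_id, "': ",
                       conditionMessage(e)),
                image_id = image_id, stage = "detect_embryo_circle")
      }),
    warning = function(w) invokeRestart("muffleWarning"))
  masks <- make_masks(circ, std, config)
  vals <- c(texture_features(masks, config),
            circle_features(masks, config),
            intensity_features(masks, config),
            watershed_features(masks, config))
  vals <- vals[feature_names()]
  flags <- character()
  if (any(is.nan(vals[c("Correlation RR", "Correlation TE")])))
    flags <- c(flags, "correlation_undefined")
  if (any(is.na(vals) & !is.nan(vals)))
    flags <- c(flags, paste0("undefined:", names(vals)[is.na(vals) & !is.nan(vals)]))
  if (vals[["DC1"]] == 0 || vals[["LC1"]] == 0 ||
      vals[["DC2"]] == 0 || vals[["LC2"]] == 0)
    flags <- c(flags, "empty_circle_set_mean_zero")
  structure(list(image_id = image_id, values = vals,
                 quality_flags = flags, circle = circ),
            class = "feature_vector")
}

#' @export
print.feature_vector <- function(x, ...) {
  cat("36-variable feature vector for", x$image_id, "\n")
  print(round(x$values, 4))
  if (length(x$quality_flags))
    cat("flags:", paste(x$quality_flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.feature_vector <- function(x, ...) {
  df <- data.frame(ID = x$image_id, check.names = FALSE)
  df[feature_names()] <- as.list(unname(x$values))
  df
}

#' Write / read the feature table
#'
#' CSV layout mirroring the deposited table: an ID column, the 36 variables
#' in canonical order, then the three embryologist grades and their mode
#' when grade records are supplied. Undefined statistics (NaN/NA) are
#' written as empty cells; rows without grades keep empty grade cells.
#'
#' @param rows a list of `feature_vector` objects (or a single one).
#' @param path output CSV path.
#' @param grades optional data.frame with columns `ID`, `g1`, `g2`, `g3`
#'   (grades in 1..3); the mode column is computed with [modal_grade()].
#' @return `write_feature_table` returns `path` invisibly;
#'   `read_feature_table` returns a data.frame with the same layout.
#' @export
write_feature_table <- function(rows, path, grades = NULL) {
  if (inherits(rows, "feature_vector")) rows <- list(rows)
  if (length(rows) < 1) bq_stop("bq_input_error", "no rows to write")
  df <- do.call(rbind, lapply(rows, as.data.frame))
  df$g1 <- NA_integer_; df$g2 <- NA_integer_; df$g3 <- NA_integer_
  df$mode <- NA_integer_
  if (!is.null(grades)) {
    m <- match(df$ID, grades$ID)
    df$g1 <- grades$g1[m]; df$g2 <- grades$g2[m]; df$g3 <- grades$g3[m]
    ok <- !is.na(df$g1)
    df$mode[ok] <- modal_grade(df$g1[ok], df$g2[ok], df$g3[ok])
  }
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) bq_stop("bq_input_error", paste("no such file:", path))
  df <- read.csv(path, check.names = FALSE)
  missing_cols <- setdiff(feature_names(), names(df))
  if (length(missing_cols) > 0)
    bq_stop("bq_format_error",
            paste("feature table lacks columns:",
                  paste(missing_cols, collapse = ", ")))
  df
}
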