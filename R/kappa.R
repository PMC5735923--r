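# Embryologist-grade utilities: modal grade and inter-rater agreement.

#' Modal grade of three embryologist evaluations
#'
#' Majority grade of three IETS evaluations (1 excellent/good, 2 fair,
#' 3 poor). A three-way disagreement (1, 2, 3) has no majority and resolves
#' to the median, grade 2; since grades are ordinal the middle order
#' statistic implements both rules at once. Vectorized.
#'
#' @param g1,g2,g3 integer grades in 1..3.
#' @return integer vector of modal grades.
#' @export
#' @examples
#' modal_grade(1, 1, 2)   # 1
#' modal_grade(1, 2, 3)   # 2 (tie -> median)
modal_grade <- function(g1, g2, g3) {
  g <- cbind(g1, g2, g3)
  if (any(is.na(g)) || !all(g %in% 1:3))
    bq_stop("bq_input_error", "grades must be integers in 1..3")
  apply(g, 1, function(r) sort(r)[2])
}

#' Fleiss' kappa for multi-rater categorical agreement
#'
#' Chance-corrected agreement for a fixed number of raters assigning one of
#' `k` categories to each item: `kappa = (Pbar - Pe) / (1 - Pe)` with the
#' usual per-item pairwise agreement `Pbar` and category-proportion
#' expectation `Pe`. When every rating falls in one category `Pe = 1` and
#' kappa is undefined (NaN).
#'
#' @param grades matrix or data.frame, items x raters, category labels.
#' @param categories vector of possible categories (default: observed ones).
#' @return kappa in -1..1, or NaN when agreement is undefined.
#' @export
#' @examples
#' g <- cbind(c(1, 2, 3, 1), c(1, 2, 3, 1), c(1, 2, 3, 2))
#' fleiss_kappa(g)
fleiss_kappa <- function(grades, categories = NULL) {
  g <- as.matrix(grades)
  if (nrow(g) < 2) bq_stop("bq_input_error", "need at least 2 items")
  if (any(is.na(g))) bq_stop("bq_input_error", "grades must not be missing")
  if (is.null(categories)) categories <- sort(unique(as.vector(g)))
  n_r <- ncol(g)
  counts <- do.call(rbind, lapply(seq_len(nrow(g)), function(i)
    as.numeric(table(factor(g[i, ], levels = categories)))))
  p_j <- colSums(counts) / (nrow(g) * n_r)
  P_i <- (rowSums(counts^2) - n_r) / (n_r * (n_r - 1))
  P_bar <- mean(P_i)
  P_e <- sum(p_j^2)
  if (1 - P_e == 0) return(NaN)
  (P_bar - P_e) / (1 - P_e)
}

# Cohen's kappa for two raters (used by Light's kappa)
cohen_kappa <- function(a, b, categories) {
  ta <- factor(a, levels = categories); tb <- factor(b, levels = categories)
  tab <- table(ta, tb) / length(a)
  po <- sum(diag(tab))
  pe <- sum(rowSums(tab) * colSums(tab))
  if (1 - pe == 0) return(NaN)
  (po - pe) / (1 - pe)
}

#' Light's kappa (mean pairwise Cohen's kappa)
#'
#' Alternative multi-rater agreement statistic: the mean of Cohen's kappa
#' over all rater pairs. Reported alongside [fleiss_kappa()] because the
#' named variant behind a published kappa is not always stated.
#'
#' @inheritParams fleiss_kappa
#' @return mean pairwise kappa, or NaN when undefined.
#' @export
light_kappa <- function(grades, categories = NULL) {
  g <- as.matrix(grades)
  if (is.null(categories)) categories <- sort(unique(as.vector(g)))
  pairs <- utils::combn(ncol(g), 2)
  ks <- apply(pairs, 2, function(p) cohen_kappa(g[, p[1]], g[, p[2]],
                                                categories))
  mean(ks)
}

#' Grade-table summary: modal counts and inter-rater kappa
#'
#' Reads (or accepts) a table with three grade columns, recomputes the modal
#' grade per item, and reports per-grade modal counts plus both kappa
#' variants.
#'
#' @param x data.frame with columns `g1`, `g2`, `g3` (grades 1..3), or a
#'   path to a CSV with those columns.
#' @return list with `n`, `mode_counts` (named counts over grades 1..3),
#'   `fleiss_kappa`, `light_kappa`.
#' @export
grade_statistics <- function(x) {
  df <- if (is.character(x)) {
    if (!file.exists(x)) bq_stop("bq_input_error", paste("no such file:", x))
    read.csv(x, check.names = FALSE)
  } else x
  need <- c("g1", "g2", "g3")
  if (!all(need %in% names(df)))
    bq_stop("bq_format_error", "table must have columns g1, g2, g3")
  g <- as.matrix(df[, need])
  if (any(is.na(g)) || !all(g %in% 1:3))
    bq_stop("bq_format_error", "grades must be integers in 1..3")
  modes <- modal_grade(g[, 1], g[, 2], g[, 3])
  list(n = nrow(g),
       mode_counts = table(factor(modes, levels = 1:3)),
       fleiss_kappa = fleiss_kappa(g, categories = 1:3),
       light_kappa = light_kappa(g, categories = 1:3))
}
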