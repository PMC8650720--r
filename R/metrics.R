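#' Dice overlap coefficient between two binary masks
#'
#' `2|A n B| / (|A| + |B|)`; two empty masks have Dice 1 by convention.
#'
#' @param a,b `binary_mask` objects or 0/1 arrays of identical shape.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b) {
  av <- mask_values(a) != 0
  bv <- mask_values(b) != 0
  if (!identical(dim(av), dim(bv)))
    stop("dice_coefficient: mask shapes differ (",
         paste(dim(av), collapse = "x"), " vs ",
         paste(dim(bv), collapse = "x"), ")")
  sa <- sum(av); sb <- sum(bv)
  if (sa + sb == 0) return(1.0)
  2 * sum(av & bv) / (sa + sb)
}

#' Signed Euclidean distance map of a binary mask
#'
#' Distance is measured in mm between voxel centers, honoring anisotropic
#' spacing: outside the mask the value is the (positive) distance to the
#' nearest foreground voxel center; inside it is minus the distance to the
#' nearest background voxel center.
#'
#' @param mask `binary_mask` or 0/1 array.
#' @param spacing Voxel spacing in mm; taken from the mask when omitted.
#' @return 3D numeric array (mm) with a `spacing` attribute; negative inside.
#' @export
signed_distance <- function(mask, spacing = NULL) {
  m <- mask_values(mask) != 0
  spacing <- as.numeric(spacing %||% grid_spacing(mask))
  if (!any(m)) stop("signed_distance: mask has no foreground voxel")
  if (all(m)) stop("signed_distance: mask has no background voxel")
  dims <- dim(m)
  d_out <- sqrt(cpp_edt_sq(as.numeric(m), dims, spacing))
  d_in <- sqrt(cpp_edt_sq(as.numeric(!m), dims, spacing))
  d <- ifelse(m, -d_in, d_out)
  d <- array(d, dims)
  attr(d, "spacing") <- spacing
  d
}

#' Intraclass correlation ICC(2,1)
#'
#' Two-way random effects, absolute agreement, single rater, from the ANOVA
#' decomposition: `(MSR - MSE) / (MSR + (k-1) MSE + k/n (MSC - MSE))`.
#' Degenerate inputs (constant matrix, zero denominator) return `NA`, which
#' downstream robustness screens treat as a failure.
#'
#' @param ratings Numeric matrix, subjects in rows, raters in columns.
#' @return ICC(2,1) value, or `NA_real_` if undefined.
#' @export
icc_2_1 <- function(ratings) {
  x <- as.matrix(ratings)
  n <- nrow(x); k <- ncol(x)
  if (n < 3 || k < 2) stop("icc_2_1 needs >= 3 subjects and >= 2 raters")
  if (!all(is.finite(x))) stop("icc_2_1: ratings must be finite")
  gm <- mean(x)
  rm_ <- rowMeans(x); cm <- colMeans(x)
  ssr <- k * sum((rm_ - gm)^2)
  ssc <- n * sum((cm - gm)^2)
  sst <- sum((x - gm)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k / n * (msc - mse)
  if (!is.finite(denom) || abs(denom) < 1e-30) return(NA_real_)
  (msr - mse) / denom
}

#' Assemble a prediction table
#'
#' One row per (subject, label source): true class, predicted class, and the
#' continuous classifier score for the disease class.
#'
#' @param subject_id,label_source,true_class,predicted_class,score Vectors of
#'   equal length; `score` in `[0, 1]`.
#' @param ... Further columns (e.g. permutation / fold ids), recycled by
#'   `data.frame()`.
#' @return A `data.frame` of class `prediction_table`.
#' @export
prediction_table <- function(subject_id, label_source, true_class,
                             predicted_class, score, ...) {
  df <- data.frame(subject_id = as.character(subject_id),
                   label_source = as.character(label_source),
                   true_class = as.character(true_class),
                   predicted_class = as.character(predicted_class),
                   score = as.numeric(score), ...,
                   stringsAsFactors = FALSE)
  if (any(df$score < 0 | df$score > 1)) stop("scores must lie in [0, 1]")
  class(df) <- c("prediction_table", class(df))
  df
}

#' Classification consistency index (CCI)
#'
#' Fraction of subjects receiving the same predicted diagnosis under two
#' label sources; equals one minus the normalized Hamming distance between
#' the two prediction vectors.
#'
#' @param preds_a,preds_b Data frames with `subject_id` and `predicted_class`
#'   covering the identical subject set.
#' @return CCI in `[0, 1]`.
#' @export
cci <- function(preds_a, preds_b) {
  ia <- as.character(preds_a$subject_id)
  ib <- as.character(preds_b$subject_id)
  if (!setequal(ia, ib) || anyDuplicated(ia) || anyDuplicated(ib)) {
    miss <- c(setdiff(ia, ib), setdiff(ib, ia))
    stop("cci: subject sets differ or contain duplicates",
         if (length(miss)) paste0(" (mismatch: ",
                                  paste(utils::head(miss, 5), collapse = ", "),
                                  ")"))
  }
  pb <- preds_b$predicted_class[match(ia, ib)]
  mean(preds_a$predicted_class == pb)
}

# Mann-Whitney / rank formulation of the AUC with half credit for ties.
auc_rank <- function(score, is_positive) {
  n1 <- sum(is_positive); n0 <- sum(!is_positive)
  if (n1 == 0 || n0 == 0)
    stop("AUC undefined: both classes must be present")
  r <- rank(score)
  (sum(r[is_positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification metric panel for one test split
#'
#' Accuracy, AUC (rank formulation, ties counted one half), balanced
#' accuracy, sensitivity (PD recall), and specificity (HC recall).
#'
#' @param table A `prediction_table` slice for one label source and split.
#' @param threshold Score threshold for the class call (used only if
#'   `predicted_class` is absent).
#' @param positive Name of the disease class.
#' @return Named numeric vector `accuracy, auc, bac, sensitivity, specificity`.
#' @export
classification_panel <- function(table, threshold = 0.5, positive = "PD") {
  truth <- table$true_class == positive
  if (!any(truth) || all(truth))
    stop("classification_panel: both true classes must be present")
  pred <- if (!is.null(table$predicted_class))
    table$predicted_class == positive else table$score >= threshold
  sens <- mean(pred[truth])
  spec <- mean(!pred[!truth])
  c(accuracy = mean(pred == truth),
    auc = auc_rank(table$score, truth),
    bac = (sens + spec) / 2,
    sensitivity = sens,
    specificity = spec)
}

#' Paired comparison of per-split metrics with multiple-comparison correction
#'
#' Matched-samples t-test on the per-split differences; the p-value is
#' corrected for `n_comparisons` tests (Bonferroni by default: multiplied and
#' capped at 1).
#'
#' @param metric_a,metric_b Equal-length numeric vectors paired by split.
#' @param n_comparisons Number of simultaneous comparisons.
#' @param method `"bonferroni"` or `"none"`.
#' @return List with `t_statistic`, `p_uncorrected`, `p_corrected`,
#'   `mean_difference`.
#' @export
paired_comparison <- function(metric_a, metric_b, n_comparisons = 1,
                              method = c("bonferroni", "none")) {
  method <- match.arg(method)
  stopifnot(length(metric_a) == length(metric_b), length(metric_a) >= 3)
  d <- metric_a - metric_b
  if (stats::sd(d) == 0) {
    if (mean(d) == 0)
      return(list(t_statistic = 0, p_uncorrected = 1, p_corrected = 1,
                  mean_difference = 0))
    return(list(t_statistic = sign(mean(d)) * Inf, p_uncorrected = 0,
                p_corrected = 0, mean_difference = mean(d)))
  }
  tt <- stats::t.test(metric_a, metric_b, paired = TRUE)
  p <- tt$p.value
  pc <- if (method == "bonferroni") min(1, p * n_comparisons) else p
  list(t_statistic = unname(tt$statistic), p_uncorrected = p,
       p_corrected = pc, mean_difference = mean(d))
}

# Aggregate per-split panels (rows) into mean +/- sd per metric.
panel_summary <- function(panels) {
  m <- as.matrix(panels)
  data.frame(metric = colnames(m), mean = colMeans(m),
             sd = apply(m, 2, stats::sd), row.names = NULL)
}
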