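# The 13 unique 3D direction offsets for co-occurrence statistics (one per
# antipodal pair of the 26-neighborhood).
glcm_offsets <- function() {
  list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
       c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
       c(0, 1, 1), c(0, 1, -1),
       c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))
}

# Gray-level co-occurrence statistics averaged over the 13 unique 3D
# directions at 1-voxel offset, after fixed-bin discretization of the
# in-mask intensities. Symmetric, normalized matrices.
glcm_features <- function(vol, m, n_bins = 16) {
  x <- vol[m]
  rng <- range(x)
  if (diff(rng) <= 0) {
    # single gray level: co-occurrence is a point mass
    return(c(glcm_contrast = 0, glcm_dissimilarity = 0, glcm_homogeneity = 1,
             glcm_energy = 1, glcm_correlation = 0, glcm_entropy = 0))
  }
  bins <- array(NA_integer_, dim(m))
  bins[m] <- pmin(n_bins, 1L + as.integer(floor((vol[m] - rng[1]) /
                                                  diff(rng) * n_bins)))
  d <- dim(m)
  stats_per_dir <- vapply(glcm_offsets(), function(off) {
    xi <- seq_len(d[1] - abs(off[1])) + max(0, -off[1])
    yi <- seq_len(d[2] - abs(off[2])) + max(0, -off[2])
    zi <- seq_len(d[3] - abs(off[3])) + max(0, -off[3])
    a <- bins[xi, yi, zi, drop = FALSE]
    b <- bins[xi + off[1], yi + off[2], zi + off[3], drop = FALSE]
    keep <- !is.na(a) & !is.na(b)
    if (!any(keep)) return(c(0, 0, 1, 1, 0, 0))
    tab <- table(factor(a[keep], levels = 1:n_bins),
                 factor(b[keep], levels = 1:n_bins))
    P <- (tab + t(tab))
    P <- P / sum(P)
    i <- row(P); j <- col(P)
    mu <- sum(i * P)
    sg2 <- sum((i - mu)^2 * P)
    corr <- if (sg2 > 0) sum((i - mu) * (j - mu) * P) / sg2 else 0
    pe <- P[P > 0]
    c(sum((i - j)^2 * P),               # contrast
      sum(abs(i - j) * P),              # dissimilarity
      sum(P / (1 + (i - j)^2)),         # homogeneity (inverse difference)
      sum(P^2),                         # energy / angular second moment
      corr,
      -sum(pe * log2(pe)))              # entropy
  }, numeric(6))
  out <- rowMeans(stats_per_dir)
  names(out) <- c("glcm_contrast", "glcm_dissimilarity", "glcm_homogeneity",
                  "glcm_energy", "glcm_correlation", "glcm_entropy")
  out
}

shape_features <- function(m, spacing) {
  idx <- which(m, arr.ind = TRUE)
  n <- nrow(idx)
  pts <- sweep(idx - 1, 2, spacing, `*`)
  rim <- interior_rim(m)
  if (n >= 2) {
    ev <- sort(eigen(stats::cov(pts), symmetric = TRUE,
                     only.values = TRUE)$values, decreasing = TRUE)
    ev <- pmax(ev, 0)
    elong <- if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 0
    flat <- if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 0
    # max 3D diameter over foreground voxel centers
    dmax <- sqrt(max(as.matrix(stats::dist(pts))^2))
  } else {
    elong <- flat <- dmax <- 0
  }
  c(shape_n_voxels = n,
    shape_volume_mm3 = n * prod(spacing),
    shape_surface_voxels = sum(rim),
    shape_elongation = elong,
    shape_flatness = flat,
    shape_max_diameter_mm = dmax)
}

first_order_features <- function(x, n_bins = 16) {
  n <- length(x)
  q <- unname(quantile(x, c(0.10, 0.25, 0.75, 0.90), type = 7))
  mid <- x[x >= q[1] & x <= q[4]]
  rmad <- mean(abs(mid - mean(mid)))
  rng <- range(x)
  if (diff(rng) > 0) {
    b <- pmin(n_bins, 1L + floor((x - rng[1]) / diff(rng) * n_bins))
    p <- tabulate(b, n_bins) / n
    p <- p[p > 0]
    entropy <- -sum(p * log2(p))
    uniformity <- sum(p^2)
  } else {
    entropy <- 0
    uniformity <- 1
  }
  s <- stats::sd(x)
  skew <- if (s > 0) mean((x - mean(x))^3) / s^3 else 0
  kurt <- if (s > 0) mean((x - mean(x))^4) / s^4 else 0
  c(fo_mean = mean(x), fo_sd = s, fo_median = median(x),
    fo_p10 = q[1], fo_p25 = q[2], fo_p75 = q[3], fo_p90 = q[4],
    fo_iqr = q[3] - q[2], fo_min = rng[1], fo_max = rng[2],
    fo_range = diff(rng), fo_energy = sum(x^2), fo_entropy = entropy,
    fo_uniformity = uniformity, fo_skewness = skew, fo_kurtosis = kurt,
    fo_rmad = rmad)
}

#' Extract the radiomics feature vector of a masked region
#'
#' Deterministic, documented 29-feature subset spanning first-order
#' intensity statistics, shape descriptors, and gray-level co-occurrence
#' texture (16 fixed bins over the in-mask range, 1-voxel offsets averaged
#' over the 13 unique 3D directions). Designed as a compact stand-in for a
#' full radiomics configuration; the extractor is pluggable wherever a
#' feature table is consumed.
#'
#' @param volume `volume_grid` (or 3D array).
#' @param mask `binary_mask` (or 0/1 array), non-empty.
#' @param n_bins Discretization bins for entropy/texture (default 16).
#' @return Named numeric feature vector.
#' @export
extract_features <- function(volume, mask, n_bins = 16) {
  vol <- if (inherits(volume, "volume_grid")) volume$values else volume
  m <- mask_values(mask) != 0
  if (!identical(dim(vol), dim(m)))
    stop("extract_features: volume and mask shapes differ")
  if (!any(m)) stop("extract_features: empty mask")
  spacing <- grid_spacing(mask, grid_spacing(volume))
  c(first_order_features(vol[m], n_bins),
    shape_features(m, spacing),
    glcm_features(vol, m, n_bins))
}

#' Build the subjects-by-features matrix for one label source
#'
#' @param cohort An `sn_cohort`.
#' @param masks Named list of masks (one per subject id).
#' @param n_bins Passed to [extract_features()].
#' @return Numeric matrix, rownames = subject ids.
#' @export
feature_table <- function(cohort, masks, n_bins = 16) {
  ids <- cohort_ids(cohort)
  rows <- lapply(ids, function(id)
    extract_features(cohort$subjects[[id]]$volume, masks[[id]], n_bins))
  out <- do.call(rbind, rows)
  rownames(out) <- ids
  out
}

#' ICC(2,1) robustness screen across label sources
#'
#' A feature is preserved only if its ICC(2,1) between the reference source
#' and *every* perturbed source exceeds 0.8 (strict inequality). Degenerate
#' features (constant ratings) fail the screen.
#'
#' @param features_by_source Named list of subject-by-feature matrices with
#'   identical dimnames; the first element is the reference source.
#' @param threshold ICC threshold (default 0.8, kept iff strictly above).
#' @return List with `kept_names`, `icc_values` (features x pairings matrix),
#'   and `min_icc` per feature.
#' @export
icc_screen <- function(features_by_source, threshold = 0.8) {
  stopifnot(is.list(features_by_source), length(features_by_source) >= 2)
  ref <- features_by_source[[1]]
  others <- features_by_source[-1]
  if (nrow(ref) < 3) stop("icc_screen needs at least 3 subjects")
  feats <- colnames(ref)
  for (o in others)
    if (!identical(dimnames(o), dimnames(ref)))
      stop("icc_screen: all sources must share subjects and feature names")
  icc_values <- sapply(seq_along(others), function(j) {
    vapply(feats, function(f) {
      v <- tryCatch(icc_2_1(cbind(ref[, f], others[[j]][, f])),
                    error = function(e) NA_real_)
      v
    }, numeric(1))
  })
  icc_values <- matrix(icc_values, nrow = length(feats),
                       dimnames = list(feats, names(others) %||%
                                         paste0("source", seq_along(others))))
  min_icc <- apply(icc_values, 1, function(v) {
    if (any(is.na(v))) NA_real_ else min(v)
  })
  kept <- feats[!is.na(min_icc) & min_icc > threshold]
  list(kept_names = kept, icc_values = icc_values, min_icc = min_icc)
}

standardize_fit <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[!is.finite(scl) | scl <= 0] <- 1
  list(center = ctr, scale = scl)
}

fit_ridge_logistic <- function(Xs, y01, lambda) {
  nm <- colnames(Xs)
  if (ncol(Xs) == 1) {
    # glmnet requires >= 2 columns; a constant zero column is inert under
    # the penalty and its coefficient stays 0
    Xs <- cbind(Xs, `.zero.` = 0)
  }
  fit <- withCallingHandlers(
    glmnet::glmnet(Xs, y01, family = "binomial", alpha = 0,
                   lambda = lambda, standardize = FALSE),
    # routine at desk-scale split sizes; the ridge penalty bounds the fit
    warning = function(w) {
      if (grepl("fewer than 8\\s+observations", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  cf <- as.numeric(glmnet::coef.glmnet(fit))
  list(intercept = cf[1],
       weights = stats::setNames(cf[seq_along(nm) + 1], nm))
}

#' Train a logistic classifier with recursive feature elimination
#'
#' Features are standardized internally; an L2-regularized logistic model is
#' refit repeatedly, each iteration dropping the feature with the smallest
#' absolute standardized weight (ties broken by eliminating the
#' lexicographically first name, for determinism), until `n_final` survive.
#'
#' @param X Subject-by-feature numeric matrix (column names required).
#' @param y Class labels (`"PD"`/`"HC"` or any two-level vector).
#' @param n_final Number of features to keep (default 10).
#' @param lambda Ridge penalty used at every iteration (default 0.1).
#' @param positive Disease class label (default `"PD"`).
#' @return An `sn_lr` model: selected features, weights, intercept, and the
#'   per-feature standardization.
#' @export
rfe_train <- function(X, y, n_final = 10, lambda = 0.1, positive = "PD") {
  X <- as.matrix(X)
  if (is.null(colnames(X))) stop("rfe_train: X needs column names")
  y01 <- as.integer(y == positive)
  if (sum(y01) < 2 || sum(1 - y01) < 2)
    stop("rfe_train needs at least 2 subjects per class")
  if (n_final >= ncol(X)) {
    if (n_final > ncol(X))
      warning("n_final >= number of features; keeping all features")
    n_final <- ncol(X)
  }
  std <- standardize_fit(X)
  Xs <- sweep(sweep(X, 2, std$center), 2, std$scale, `/`)
  active <- sort(colnames(X))
  eliminated <- character(0)
  while (length(active) > n_final) {
    fit <- fit_ridge_logistic(Xs[, active, drop = FALSE], y01, lambda)
    aw <- abs(fit$weights)
    drop_name <- names(sort(aw))[1]  # stable sort: lexicographic tie-break
    eliminated <- c(eliminated, drop_name)
    active <- setdiff(active, drop_name)
  }
  fit <- fit_ridge_logistic(Xs[, active, drop = FALSE], y01, lambda)
  structure(list(features = active, weights = fit$weights,
                 intercept = fit$intercept,
                 center = std$center[active], scale = std$scale[active],
                 lambda = lambda, positive = positive,
                 eliminated = eliminated),
            class = "sn_lr")
}

#' @export
print.sn_lr <- function(x, ...) {
  cat("<sn_lr> ridge-logistic classifier,", length(x$features),
      "features (lambda =", x$lambda, ")\n")
  print(round(x$weights, 4))
  invisible(x)
}

#' @export
coef.sn_lr <- function(object, ...) {
  c(`(Intercept)` = object$intercept, object$weights)
}

#' Predict disease-class probabilities from an `sn_lr` model
#'
#' @param model An `sn_lr` model.
#' @param X Feature matrix containing all selected feature columns.
#' @return Numeric scores in `[0, 1]` (probability of the positive class).
#' @export
predict_scores <- function(model, X) {
  X <- as.matrix(X)
  missing_cols <- setdiff(model$features, colnames(X))
  if (length(missing_cols))
    stop("predict_scores: missing feature column(s): ",
         paste(missing_cols, collapse = ", "))
  Xs <- sweep(sweep(X[, model$features, drop = FALSE], 2, model$center),
              2, model$scale, `/`)
  as.numeric(plogis(model$intercept + Xs %*% model$weights))
}

#' @export
predict.sn_lr <- function(object, newdata, ...) {
  predict_scores(object, newdata)
}
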