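#' Configuration of the 3D feature extractor
#'
#' A stack of stride-1 convolution blocks (convolution, channel
#' normalization, ReLU). The first block is fixed to 6 channels with a
#' 5x5x5 kernel; with all strides 1 the feature-map grid stays aligned
#' voxel-for-voxel with the input ROI grid, which is what makes mask-derived
#' pooling gates geometrically meaningful.
#'
#' @param input_roi_shape ROI grid shape fed to the extractor.
#' @param conv_specs List of `c(channels, kernel)` per block; the first must
#'   be `c(6, 5)`.
#' @param norm Use per-sample channel normalization (default `TRUE`).
#' @param activation Nonlinearity (only `"relu"` implemented).
#' @return An `extractor_config`.
#' @export
extractor_config <- function(input_roi_shape = c(16, 16, 12),
                             conv_specs = list(c(6, 5), c(12, 3), c(16, 3)),
                             norm = FALSE, activation = "relu") {
  stopifnot(length(input_roi_shape) == 3)
  if (!identical(as.integer(conv_specs[[1]]), c(6L, 5L)))
    stop("the first extractor block is fixed to 6 channels, kernel 5x5x5, ",
         "stride 1")
  if (activation != "relu") stop("only the relu activation is implemented")
  for (cs in conv_specs)
    if (cs[2] %% 2 != 1) stop("kernels must be odd for same-padding")
  structure(list(input_roi_shape = as.integer(input_roi_shape),
                 conv_specs = conv_specs, norm = isTRUE(norm),
                 activation = activation),
            class = "extractor_config")
}

extractor_out_channels <- function(cfg) {
  tail(cfg$conv_specs, 1)[[1]][1]
}

init_extractor <- function(cfg, seed = 1) {
  with_seed(seed, {
    cin <- 1
    layers <- lapply(cfg$conv_specs, function(cs) {
      p <- conv_params(cin, cs[1], cs[2], norm = cfg$norm)
      cin <<- cs[1]
      p
    })
    layers
  })
}

extractor_fwd <- function(x, layers) {
  caches <- vector("list", length(layers))
  h <- x
  for (i in seq_along(layers)) {
    caches[[i]] <- block_fwd(h, layers[[i]])
    h <- caches[[i]]$out
  }
  list(out = h, caches = caches)
}

extractor_bwd <- function(caches, layers, gout) {
  grads <- vector("list", length(layers))
  g <- gout
  for (i in rev(seq_along(layers))) {
    bb <- block_bwd(caches[[i]], layers[[i]], g)
    grads[[i]] <- bb$grads
    g <- bb$gin
  }
  list(gin = g, grads = grads)
}

# Bounding box (1-based, inclusive) of a mask dilated by `margin` voxels and
# clipped to the grid.
crop_box <- function(mask, margin) {
  m <- mask_values(mask) != 0
  if (!any(m)) stop("crop_roi: empty mask")
  idx <- which(m, arr.ind = TRUE)
  d <- dim(m)
  lo <- pmax(apply(idx, 2, min) - margin, 1)
  hi <- pmin(apply(idx, 2, max) + margin, d)
  list(lo = as.integer(lo), hi = as.integer(hi))
}

# Trilinear resampling of a box of a 3D array onto a target grid shape.
resample_box <- function(vol, box, out_shape) {
  d <- dim(vol)
  coords_axis <- function(axis) {
    n <- out_shape[axis]
    lo0 <- box$lo[axis] - 1
    hi0 <- box$hi[axis] - 1
    if (n == 1) rep((lo0 + hi0) / 2, 1)
    else lo0 + (0:(n - 1)) * (hi0 - lo0) / (n - 1)
  }
  g <- expand.grid(x = coords_axis(1), y = coords_axis(2), z = coords_axis(3))
  s <- cpp_trilinear(as.numeric(vol), as.integer(d), as.matrix(g), fill = 0)
  array(s, out_shape)
}

#' Crop and resample the region of interest around an SN mask
#'
#' Takes the bounding box of the mask dilated by `margin` voxels (clipped to
#' the grid) and trilinearly resamples both the volume and the mask onto the
#' extractor ROI grid. The crop geometry is recorded so the operation is
#' reproducible and invertible.
#'
#' @param volume `volume_grid`.
#' @param mask `binary_mask` (non-empty) defining the box; also resampled.
#' @param out_shape Target ROI grid shape.
#' @param margin Dilation margin in voxels (default 4).
#' @param box Optional precomputed box (`list(lo, hi)`), e.g. a shared
#'   population box; when given, `mask` may still be resampled for gating.
#' @return List with `volume` (array), `mask` (0/1 array), `box`,
#'   `roi_spacing` (effective mm per ROI voxel).
#' @export
crop_roi <- function(volume, mask, out_shape = c(16, 16, 12), margin = 4,
                     box = NULL) {
  if (is.null(box)) box <- crop_box(mask, margin)
  v <- resample_box(volume$values, box, out_shape)
  m <- resample_box(mask_values(mask), box, out_shape)
  m <- array(as.numeric(m >= 0.5), out_shape)
  roi_spacing <- (box$hi - box$lo + 1) / out_shape *
    grid_spacing(volume)
  list(volume = v, mask = m, box = box, roi_spacing = roi_spacing)
}

#' Gated pooling of feature maps
#'
#' Pools each channel of a feature-map stack under a spatial gate. Two
#' normalizations are provided: `"weighted"` divides by the gate mass
#' (`sum(gate * f) / sum(gate)`, the in-mask average for a binary gate) and
#' `"global"` divides by the ROI size (`mean(gate * f)`, the form used by
#' the probability-gated joint model). An all-ones gate reduces both to
#' plain global average pooling.
#'
#' @param feature_maps Array `(X, Y, Z, C)`.
#' @param gate Array `(X, Y, Z)` with values in `[0, 1]`.
#' @param normalization `"weighted"` or `"global"`.
#' @return Numeric vector, one pooled value per channel.
#' @export
gated_pool <- function(feature_maps, gate,
                       normalization = c("weighted", "global")) {
  normalization <- match.arg(normalization)
  d <- dim(feature_maps)
  if (!identical(as.integer(dim(gate)), as.integer(d[1:3])))
    stop("gated_pool: gate grid must match the feature-map grid")
  if (any(gate < 0 | gate > 1)) stop("gated_pool: gate values must be in [0,1]")
  n <- prod(d[1:3])
  fm <- matrix(feature_maps, n, d[4])
  gv <- as.numeric(gate)
  if (normalization == "weighted") {
    gs <- sum(gv)
    if (gs <= 0) stop("gated_pool: gate sum is zero in weighted mode")
    as.numeric(crossprod(fm, gv)) / gs
  } else {
    as.numeric(crossprod(fm, gv)) / n
  }
}

# Gradient of gated pooling w.r.t. the feature maps (gate held fixed).
gated_pool_bwd <- function(dims, gate, normalization, gvec) {
  n <- prod(dims[1:3])
  gv <- as.numeric(gate)
  denom <- if (normalization == "weighted") sum(gv) else n
  array(outer(gv / denom, gvec), dims)
}

init_pdnet <- function(cfg, head_hidden = 12, seed = 1) {
  ext <- init_extractor(cfg, seed = seed)
  head <- with_seed(seed + 1, head_params(extractor_out_channels(cfg),
                                          head_hidden))
  list(ext = ext, head = head)
}

# Forward pass for either conditioning mode. `x` is the (already normalized
# and, for masked mode, already zero-masked) ROI tensor; `gate` is used only
# in gated mode. Returns score = P(PD).
pdnet_fwd <- function(x, gate, mode, params, normalization = "weighted") {
  ex <- extractor_fwd(x, params$ext)
  d <- dim(ex$out)
  vec <- if (mode == "masked") {
    colMeans(matrix(ex$out, prod(d[1:3]), d[4]))
  } else {
    gated_pool(ex$out, gate, normalization)
  }
  hd <- head_fwd(vec, params$head)
  list(score = hd$probs[2], probs = hd$probs, vec = vec, ex = ex, hd = hd,
       dims = d, gate = gate, mode = mode, normalization = normalization)
}

pdnet_bwd <- function(fw, params, glogits) {
  hb <- head_bwd(fw$hd, params$head, glogits)
  gmaps <- if (fw$mode == "masked") {
    n <- prod(fw$dims[1:3])
    array(rep(hb$gv / n, each = n), fw$dims)
  } else {
    gated_pool_bwd(fw$dims, fw$gate, fw$normalization, hb$gv)
  }
  eb <- extractor_bwd(fw$ex$caches, params$ext, gmaps)
  list(grads = list(ext = eb$grads, head = hb$grads))
}

#' Masked-input forward pass (zero outside the SN label)
#'
#' The classical conditioning: the ROI volume is multiplied by the binary
#' label before entering the extractor, so the label edge becomes a sharp
#' intensity edge in the input — the mechanism behind label-induced
#' instability. Pooling is plain global averaging.
#'
#' @param roi_volume,roi_mask ROI-grid arrays from [crop_roi()].
#' @param params PDNet parameters (from training or [init_pdnet]).
#' @return Disease-class score in `[0, 1]`.
#' @export
masked_forward <- function(roi_volume, roi_mask, params) {
  x <- array(scale_intensity(roi_volume) * roi_mask, c(dim(roi_volume), 1))
  pdnet_fwd(x, NULL, "masked", params)$score
}

#' Gated-pooling forward pass (label enters only at pooling)
#'
#' The un-zeroed ROI volume is encoded by the extractor; the label acts only
#' as a pooling gate over the feature maps. Perturbations of the label
#' strictly outside its support cannot change the extractor activations —
#' only the pooled weighting.
#'
#' @param roi_volume ROI-grid array (not masked).
#' @param gate Gate field on the ROI grid (binary mask or `[0, 1]` weights).
#' @param params PDNet parameters.
#' @param normalization Pooling normalization, see [gated_pool()].
#' @return Disease-class score in `[0, 1]`.
#' @export
gated_forward <- function(roi_volume, gate, params,
                          normalization = "weighted") {
  x <- array(scale_intensity(roi_volume), c(dim(roi_volume), 1))
  pdnet_fwd(x, gate, "gated", params, normalization)$score
}

#' Training configuration for the PDNet classifiers
#'
#' @param extractor An [extractor_config()].
#' @param epochs Training epochs (default 10).
#' @param lr Adam learning rate.
#' @param head_hidden Hidden width of the classifier head.
#' @param margin ROI crop margin, voxels.
#' @param normalization Gated-pooling normalization for binary gates.
#' @param box Optional fixed population crop box (`list(lo, hi)`); default
#'   `NULL` crops each subject's own label bounding box.
#' @param seed Seed for initialization and batch shuffling.
#' @return A `pdnet_train_cfg` list.
#' @export
pdnet_train_cfg <- function(extractor = extractor_config(), epochs = 15,
                            lr = 5e-3, head_hidden = 12, margin = 4,
                            normalization = "weighted", box = NULL,
                            seed = 1) {
  structure(list(extractor = extractor, epochs = epochs, lr = lr,
                 head_hidden = head_hidden, margin = margin,
                 normalization = normalization, box = box,
                 seed = as.integer(seed)),
            class = "pdnet_train_cfg")
}

# Precompute normalized ROI inputs for one label source.
# mode "masked": x = scale_intensity(roi_vol) * roi_mask; mode "gated": x =
# scale_intensity(roi_vol), gate = roi_mask. A fixed population box in
# cfg$box overrides the per-subject bounding box.
prepare_inputs <- function(cohort, masks, cfg, mode, ids = cohort_ids(cohort)) {
  shape <- cfg$extractor$input_roi_shape
  out <- lapply(ids, function(id) {
    s <- cohort$subjects[[id]]
    roi <- crop_roi(s$volume, masks[[id]], out_shape = shape,
                    margin = cfg$margin, box = cfg$box)
    if (mode == "masked") {
      list(x = array(scale_intensity(roi$volume) * roi$mask, c(shape, 1)), gate = NULL)
    } else {
      list(x = array(scale_intensity(roi$volume), c(shape, 1)), gate = roi$mask)
    }
  })
  names(out) <- ids
  out
}

#' Train a PDNet classifier (masked-input or gated-pooling mode)
#'
#' Cross-entropy objective, Adam updates on single-volume batches,
#' fixed-seed initialization and shuffling; after every epoch the model is
#' scored on the validation split and the best-validation weights are kept.
#'
#' @param cohort An `sn_cohort`.
#' @param masks Named per-subject list of label masks (the training label
#'   source).
#' @param mode `"masked"` or `"gated"`.
#' @param split List with character vectors `train` and `val` of subject ids.
#' @param cfg A [pdnet_train_cfg()].
#' @return A `pdnet_model`: best parameters, config, mode, training log.
#' @export
train_classifier <- function(cohort, masks, mode = c("masked", "gated"),
                             split, cfg = pdnet_train_cfg()) {
  mode <- match.arg(mode)
  dx <- cohort_diagnoses(cohort)
  if (length(unique(dx[split$train])) < 2)
    stop("train_classifier: both classes must be present in the training split")
  inputs <- prepare_inputs(cohort, masks, cfg, mode,
                           ids = c(split$train, split$val))
  y <- ifelse(dx == "PD", 2L, 1L)  # class index into the softmax pair
  params <- init_pdnet(cfg$extractor, cfg$head_hidden, seed = cfg$seed)
  state <- adam_init(params)
  best <- list(params = params, val_acc = -Inf, epoch = 0)
  log <- data.frame()
  with_seed(cfg$seed + 101, {
    for (ep in seq_len(cfg$epochs)) {
      order_ids <- sample(split$train)
      loss_sum <- 0
      for (id in order_ids) {
        fw <- pdnet_fwd(inputs[[id]]$x, inputs[[id]]$gate, mode, params,
                        cfg$normalization)
        if (!all(is.finite(fw$probs)))
          stop("train_classifier: divergence (non-finite probabilities) at ",
               "epoch ", ep)
        yi <- y[id]
        loss_sum <- loss_sum - log(max(fw$probs[yi], 1e-12))
        glog <- fw$probs
        glog[yi] <- glog[yi] - 1
        bw <- pdnet_bwd(fw, params, glog)
        st <- adam_step(params, bw$grads, state, lr = cfg$lr)
        params <- st$params
        state <- st$state
      }
      val_scores <- vapply(split$val, function(id)
        pdnet_fwd(inputs[[id]]$x, inputs[[id]]$gate, mode, params,
                  cfg$normalization)$score, numeric(1))
      val_acc <- mean((val_scores >= 0.5) == (dx[split$val] == "PD"))
      log <- rbind(log, data.frame(epoch = ep,
                                   train_loss = loss_sum / length(order_ids),
                                   val_acc = val_acc))
      if (val_acc >= best$val_acc) {
        best <- list(params = params, val_acc = val_acc, epoch = ep)
      }
    }
  })
  structure(list(params = best$params, cfg = cfg, mode = mode, log = log,
                 best_epoch = best$epoch, val_acc = best$val_acc),
            class = "pdnet_model")
}

#' @export
print.pdnet_model <- function(x, ...) {
  cat("<pdnet_model>", x$mode, "mode,", nrow(x$log), "epochs trained,",
      "best val acc", round(x$val_acc, 3), "at epoch", x$best_epoch, "\n")
  invisible(x)
}

#' Predict disease scores for prepared or raw inputs
#'
#' @param object A `pdnet_model`.
#' @param cohort An `sn_cohort`.
#' @param masks Per-subject label masks of the label source used at test
#'   time.
#' @param ids Subjects to score (default: all).
#' @param inputs Optional precomputed [prepare_inputs()] list (caching hook
#'   for the experiment harness).
#' @param ... Unused.
#' @return `data.frame` with `subject_id`, `true_class`, `score`,
#'   `predicted_class`.
#' @export
predict.pdnet_model <- function(object, cohort, masks = NULL,
                                ids = cohort_ids(cohort), inputs = NULL, ...) {
  if (is.null(inputs))
    inputs <- prepare_inputs(cohort, masks, object$cfg, object$mode, ids = ids)
  dx <- cohort_diagnoses(cohort)
  score <- vapply(ids, function(id)
    pdnet_fwd(inputs[[id]]$x, inputs[[id]]$gate, object$mode, object$params,
              object$cfg$normalization)$score, numeric(1))
  data.frame(subject_id = ids, true_class = unname(dx[ids]),
             score = unname(score),
             predicted_class = ifelse(score >= 0.5, "PD", "HC"),
             stringsAsFactors = FALSE)
}
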