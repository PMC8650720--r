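#' Parameters of the piecewise-linear probability gate
#'
#' The gate maps a segmentation probability p to a pooling weight:
#' 0 for `p <= t_lo`, `slope * p + intercept` on `(t_lo, t_hi]`, and 1 for
#' `p > t_hi`. The printed constants (0.4, 0.6, 5, -2) make the gate
#' continuous with `delta(t_lo) = 0` and `delta(t_hi) = 1`; the constructor
#' enforces exactly that continuity.
#'
#' @param t_lo,t_hi Break points.
#' @param slope,intercept Linear middle branch.
#' @return A `gate_params` list.
#' @export
gate_params <- function(t_lo = 0.4, t_hi = 0.6, slope = 5, intercept = -2) {
  if (abs(slope * t_lo + intercept) > 1e-9 ||
      abs(slope * t_hi + intercept - 1) > 1e-9)
    stop("gate_params: discontinuous gate; require slope*t_lo+intercept = 0 ",
         "and slope*t_hi+intercept = 1")
  structure(list(t_lo = t_lo, t_hi = t_hi, slope = slope,
                 intercept = intercept), class = "gate_params")
}

#' Piecewise-linear gate delta(p) on a probability map
#'
#' @param p Numeric array/vector of probabilities in `[0, 1]`.
#' @param params A [gate_params()] object.
#' @return Gate weights with the same shape as `p`, in `[0, 1]`.
#' @export
delta_gate <- function(p, params = gate_params()) {
  if (any(p < -1e-9 | p > 1 + 1e-9, na.rm = TRUE))
    stop("delta_gate: probabilities must lie in [0, 1]")
  out <- ifelse(p > params$t_hi, 1,
                ifelse(p > params$t_lo, params$slope * p + params$intercept,
                       0))
  if (is.array(p)) array(out, dim(p)) else out
}

# Derivative of the gate (piecewise constant; defined a.e.).
delta_gate_prime <- function(p, params = gate_params()) {
  out <- ifelse(p > params$t_lo & p <= params$t_hi, params$slope, 0)
  if (is.array(p)) array(out, dim(p)) else out
}

#' Configuration of the coarse-to-fine segmentation network
#'
#' A pooling-free trunk (no spatial downsampling anywhere — the no-pooling
#' invariant is enforced) built from a densely connected block: each
#' convolution receives the channel concatenation of the input and all
#' previous layer outputs. Two parallel trunk instances feed (1) an initial
#' segmentation softmax head and (2) a signed-distance regression head;
#' their outputs are concatenated along channels and fused by a further
#' convolution followed by softmax, giving the fine segmentation.
#'
#' @param depth Dense-block depth per trunk.
#' @param growth Channels added per dense layer.
#' @param kernel Trunk kernel size (odd).
#' @param fusion_kernel Fusion convolution kernel (odd).
#' @param strides Per-layer strides; must all be 1 (no downsampling).
#' @param norm Per-sample channel normalization in trunk blocks.
#' @param dist_clip Distance-target clip, mm; targets are scaled to [-1, 1].
#' @param loss_weights Named weights `seg`, `dist`, `cls`.
#' @param roi_shape ROI grid the network operates on.
#' @param margin Crop margin in voxels for the population ROI box.
#' @return An `sn2_config`.
#' @export
sn2_config <- function(depth = 3, growth = 6, kernel = 3, fusion_kernel = 3,
                       strides = NULL, norm = TRUE, dist_clip = 10,
                       loss_weights = c(seg = 1, dist = 0.5, cls = 1),
                       roi_shape = c(16, 16, 12), margin = 4) {
  strides <- strides %||% rep(1L, depth)
  structure(list(depth = as.integer(depth), growth = as.integer(growth),
                 kernel = as.integer(kernel),
                 fusion_kernel = as.integer(fusion_kernel),
                 strides = as.integer(strides), norm = isTRUE(norm),
                 dist_clip = dist_clip, loss_weights = loss_weights,
                 roi_shape = as.integer(roi_shape), margin = margin),
            class = "sn2_config")
}

#' Build (initialize) an SN2 segmentation model
#'
#' @param cfg An [sn2_config()]; configs containing any spatial
#'   downsampling (stride > 1) are rejected.
#' @param seed Initialization seed.
#' @return List of parameter tensors (`trunkA`, `headA`, `trunkB`, `headB`,
#'   `fusion`) with a `n_params` attribute.
#' @export
build_sn2 <- function(cfg, seed = 1) {
  if (any(cfg$strides != 1L))
    stop("build_sn2: the trunk must be pooling-free ",
         "(all strides 1, no downsampling)")
  if (cfg$kernel %% 2 != 1 || cfg$fusion_kernel %% 2 != 1)
    stop("build_sn2: kernels must be odd")
  make_trunk <- function(seed_off) with_seed(seed + seed_off, {
    lapply(seq_len(cfg$depth), function(i)
      conv_params(1 + (i - 1) * cfg$growth, cfg$growth, cfg$kernel,
                  norm = cfg$norm))
  })
  ctop <- 1 + cfg$depth * cfg$growth
  params <- list(
    trunkA = make_trunk(0),
    headA = with_seed(seed + 11, conv_params(ctop, 2, 1, norm = FALSE)),
    trunkB = make_trunk(23),
    headB = with_seed(seed + 37, conv_params(ctop, 1, 1, norm = FALSE)),
    fusion = with_seed(seed + 41, conv_params(3, 2, cfg$fusion_kernel,
                                              norm = FALSE)))
  n_par <- sum(unlist(lapply(params, function(p)
    sum(vapply(rapply(p, length, how = "unlist"), sum, 0)))))
  attr(params, "n_params") <- n_par
  params
}

concat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  array(c(a, b), c(da[1:3], da[4] + db[4]))
}

# Dense block forward: layer i consumes the concatenation of the input and
# all previous layer outputs.
dense_trunk_fwd <- function(x, layers) {
  feats <- x
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    caches[[i]] <- block_fwd(feats, layers[[i]])
    feats <- concat_ch(feats, caches[[i]]$out)
  }
  list(out = feats, caches = caches)
}

dense_trunk_bwd <- function(caches, layers, gfeats) {
  d <- dim(gfeats)
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    cin <- dim(caches[[i]]$x)[4]
    gout_i <- gfeats[, , , (cin + 1):d[4], drop = FALSE]
    bb <- block_bwd(caches[[i]], layers[[i]], gout_i)
    gfeats <- gfeats[, , , seq_len(cin), drop = FALSE] + bb$gin
    d <- dim(gfeats)
    grads[[i]] <- bb$grads
  }
  list(gin = gfeats, grads = grads)
}

# Voxelwise softmax over the 2-channel class dimension.
softmax2_vox <- function(l) {
  m <- pmax(l[, , , 1], l[, , , 2])
  e1 <- exp(l[, , , 1] - m)
  e2 <- exp(l[, , , 2] - m)
  s <- e1 + e2
  array(c(e1 / s, e2 / s), dim(l))
}

softmax2_vox_bwd <- function(p, gp) {
  dot <- gp[, , , 1] * p[, , , 1] + gp[, , , 2] * p[, , , 2]
  array(c(p[, , , 1] * (gp[, , , 1] - dot),
          p[, , , 2] * (gp[, , , 2] - dot)), dim(p))
}

# Full SN2 forward. x: (X,Y,Z,1) normalized ROI tensor.
sn2_fwd <- function(x, params) {
  A <- dense_trunk_fwd(x, params$trunkA)
  pa_logits <- conv_fwd(A$out, params$headA)
  pA <- softmax2_vox(pa_logits)
  B <- dense_trunk_fwd(x, params$trunkB)
  dist <- conv_fwd(B$out, params$headB)
  fus_in <- concat_ch(pA, dist)
  f_logits <- conv_fwd(fus_in, params$fusion)
  fine <- softmax2_vox(f_logits)
  list(fine = fine, init_prob = pA, dist = dist[, , , 1],
       A = A, B = B, fus_in = fus_in, x = x)
}

# Backward through SN2 given gradients on the fine probability channels and
# on the distance map. Returns a grads tree mirroring the parameter tree.
sn2_bwd <- function(fw, params, g_fine, g_dist) {
  g_flogits <- softmax2_vox_bwd(fw$fine, g_fine)
  fb <- conv_bwd(fw$fus_in, params$fusion, g_flogits)
  g_pA <- fb$gin[, , , 1:2, drop = FALSE]
  g_d <- fb$gin[, , , 3] + g_dist
  g_pa_logits <- softmax2_vox_bwd(fw$init_prob, g_pA)
  hA <- conv_bwd(fw$A$out, params$headA, g_pa_logits)
  tA <- dense_trunk_bwd(fw$A$caches, params$trunkA, hA$gin)
  hB <- conv_bwd(fw$B$out, params$headB,
                 array(g_d, c(dim(g_d), 1)))
  tB <- dense_trunk_bwd(fw$B$caches, params$trunkB, hB$gin)
  list(grads = list(trunkA = tA$grads,
                    headA = list(W = hA$gW, b = hA$gb),
                    trunkB = tB$grads,
                    headB = list(W = hB$gW, b = hB$gb),
                    fusion = list(W = fb$gW, b = fb$gb)),
       gin = tA$gin + tB$gin)
}

# Segmentation loss gradients: voxelwise cross-entropy + soft Dice on the
# fine foreground probability, L1 on the scaled distance head. Returns the
# loss value and gradients on (fine probs, dist).
seg_loss_grads <- function(fine, dist, target_mask, target_dist, w_seg,
                           w_dist, eps = 1e-6) {
  p <- fine[, , , 2]
  t <- target_mask
  n <- length(t)
  pc <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  ce <- -mean(t * log(pc) + (1 - t) * log(1 - pc))
  gp2_ce <- -(t / pc - (1 - t) / (1 - pc)) / n
  S <- sum(p) + sum(t) + eps
  inter2 <- 2 * sum(p * t) + eps
  dice_soft <- inter2 / S
  gp2_dice <- -(2 * t * S - inter2) / S^2
  l1 <- mean(abs(dist - target_dist))
  gdist <- w_dist * sign(dist - target_dist) / n
  g_fine <- array(0, dim(fine))
  g_fine[, , , 2] <- w_seg * (gp2_ce + gp2_dice)
  list(loss = w_seg * (ce + (1 - dice_soft)) + w_dist * l1,
       g_fine = g_fine, g_dist = gdist)
}

# Shared population ROI box over a set of masks (union of per-subject boxes).
population_box <- function(masks, margin, grid_dim) {
  los <- his <- NULL
  for (m in masks) {
    b <- crop_box(m, margin)
    los <- rbind(los, b$lo)
    his <- rbind(his, b$hi)
  }
  list(lo = as.integer(pmax(apply(los, 2, min), 1)),
       hi = as.integer(pmin(apply(his, 2, max), grid_dim)))
}

# Prepare SN2 training tensors on the shared box: normalized volume, ROI
# mask, scaled clipped signed-distance target.
prepare_sn2_inputs <- function(cohort, masks, cfg, box, ids) {
  shape <- cfg$roi_shape
  out <- lapply(ids, function(id) {
    s <- cohort$subjects[[id]]
    roi <- crop_roi(s$volume, masks[[id]], out_shape = shape,
                    margin = cfg$margin, box = box)
    td <- if (any(roi$mask != 0) && any(roi$mask == 0)) {
      sd_map <- signed_distance(roi$mask, spacing = roi$roi_spacing)
      pmin(pmax(sd_map / cfg$dist_clip, -1), 1)
    } else {
      array(1, shape)  # no foreground in ROI: everything is "far outside"
    }
    list(x = array(scale_intensity(roi$volume), c(shape, 1)), mask = roi$mask,
         dist = td)
  })
  names(out) <- ids
  out
}

#' Train the SN2 segmentation network
#'
#' Loss: `w_seg * (soft Dice + voxel cross-entropy)` on the fine
#' segmentation plus `w_dist * L1` on the signed-distance head (targets from
#' [signed_distance()], clipped to `dist_clip` mm and scaled to `[-1, 1]`).
#' The network operates on a shared population ROI box computed from the
#' training reference masks, so segmenting a new volume needs no mask.
#'
#' @param cohort An `sn_cohort`.
#' @param masks Per-subject reference masks (training labels).
#' @param split List with `train` and `val` id vectors.
#' @param cfg An [sn2_config()].
#' @param epochs,lr Optimization settings.
#' @param seed Seed for initialization and shuffling.
#' @return An `sn2_model` with best-validation parameters, the population
#'   box, and a per-epoch log of loss and validation Dice.
#' @export
train_sn2 <- function(cohort, masks, split, cfg = sn2_config(), epochs = 10,
                      lr = 2e-3, seed = 1) {
  grid_dim <- dim(cohort$subjects[[1]]$volume$values)
  box <- population_box(masks[split$train], cfg$margin, grid_dim)
  ids <- c(split$train, split$val)
  inputs <- prepare_sn2_inputs(cohort, masks, cfg, box, ids)
  params <- build_sn2(cfg, seed = seed)
  state <- adam_init(params)
  w <- cfg$loss_weights
  best <- list(params = params, val_dice = -Inf, epoch = 0)
  log <- data.frame()
  with_seed(seed + 211, {
    for (ep in seq_len(epochs)) {
      loss_sum <- 0
      for (id in sample(split$train)) {
        inp <- inputs[[id]]
        fw <- sn2_fwd(inp$x, params)
        if (!all(is.finite(fw$fine)))
          stop("train_sn2: divergence (non-finite probabilities) at epoch ",
               ep)
        lg <- seg_loss_grads(fw$fine, fw$dist, inp$mask, inp$dist,
                             w[["seg"]], w[["dist"]])
        loss_sum <- loss_sum + lg$loss
        bw <- sn2_bwd(fw, params, lg$g_fine, lg$g_dist)
        st <- adam_step(params, bw$grads, state, lr = lr)
        params <- st$params
        state <- st$state
      }
      val_dice <- mean(vapply(split$val, function(id) {
        fw <- sn2_fwd(inputs[[id]]$x, params)
        dice_coefficient(fw$fine[, , , 2] >= 0.5 + 0, inputs[[id]]$mask)
      }, numeric(1)))
      log <- rbind(log, data.frame(epoch = ep,
                                   train_loss = loss_sum /
                                     length(split$train),
                                   val_dice = val_dice))
      if (val_dice >= best$val_dice)
        best <- list(params = params, val_dice = val_dice, epoch = ep)
    }
  })
  structure(list(params = best$params, cfg = cfg, box = box, log = log,
                 val_dice = best$val_dice, best_epoch = best$epoch),
            class = "sn2_model")
}

#' @export
print.sn2_model <- function(x, ...) {
  cat("<sn2_model> dense depth", x$cfg$depth, "growth", x$cfg$growth,
      "| best val Dice", round(x$val_dice, 3), "at epoch", x$best_epoch, "\n")
  invisible(x)
}

#' Segment a volume with a trained SN2 model
#'
#' Mask-free inference: the stored population ROI box is cropped, the fine
#' probability map is computed and resampled back onto the full grid.
#'
#' @param model An `sn2_model`.
#' @param volume A `volume_grid`.
#' @return List with `prob` (full-grid probability array) and `mask`
#'   (`binary_mask`, probability thresholded at 0.5).
#' @export
sn2_segment <- function(model, volume) {
  cfg <- model$cfg
  box <- model$box
  shape <- cfg$roi_shape
  v <- resample_box(volume$values, box, shape)
  x <- array(scale_intensity(v), c(shape, 1))
  fw <- sn2_fwd(x, model$params)
  p_roi <- fw$fine[, , , 2]
  d <- dim(volume$values)
  prob <- array(0, d)
  xi <- box$lo[1]:box$hi[1]
  yi <- box$lo[2]:box$hi[2]
  zi <- box$lo[3]:box$hi[3]
  step <- (box$hi - box$lo) / pmax(shape - 1, 1)
  g <- expand.grid(x = (xi - box$lo[1]) / step[1],
                   y = (yi - box$lo[2]) / step[2],
                   z = (zi - box$lo[3]) / step[3])
  s <- cpp_trilinear(as.numeric(p_roi), as.integer(shape), as.matrix(g),
                     fill = 0)
  prob[xi, yi, zi] <- array(s, c(length(xi), length(yi), length(zi)))
  list(prob = prob,
       mask = binary_mask(array(as.numeric(prob >= 0.5), d),
                          volume$spacing))
}

#' Forward pass of the joint end-to-end diagnosis model
#'
#' The SN2 fine probability map is turned into pooling weights by the
#' piecewise-linear gate and fused with the extractor feature maps as the
#' global mean of `delta(p) * feature_map`; the classifier head maps the
#' pooled vector to a diagnosis score. No external mask is consumed.
#'
#' @param x Normalized ROI tensor `(X, Y, Z, 1)`.
#' @param params Joint parameter tree (`sn2`, `ext`, `head`).
#' @param gate A [gate_params()] object.
#' @return List with `score`, `probs`, fine probability map `p`, gate field
#'   `g`, `degenerate` flag (gate identically zero), and caches.
#' @keywords internal
joint_fwd <- function(x, params, gate = gate_params()) {
  sf <- sn2_fwd(x, params$sn2)
  p <- sf$fine[, , , 2]
  g <- delta_gate(p, gate)
  ex <- extractor_fwd(x, params$ext)
  d <- dim(ex$out)
  n <- prod(d[1:3])
  fm <- matrix(ex$out, n, d[4])
  vec <- as.numeric(crossprod(fm, as.numeric(g))) / n
  degenerate <- all(g == 0)
  hd <- head_fwd(vec, params$head)
  list(score = hd$probs[2], probs = hd$probs, p = p, g = g,
       degenerate = degenerate, sf = sf, ex = ex, hd = hd, fm = fm,
       dims = d, gate = gate)
}

# Backward of the classification path of the joint model; returns gradient
# contributions for ext, head, and the fine-probability map (through the
# gate), to be combined with the segmentation-loss gradients.
joint_cls_bwd <- function(fw, params, glogits) {
  hb <- head_bwd(fw$hd, params$head, glogits)
  n <- prod(fw$dims[1:3])
  gmaps <- array(outer(as.numeric(fw$g) / n, hb$gv), fw$dims)
  eb <- extractor_bwd(fw$ex$caches, params$ext, gmaps)
  gp_vec <- as.numeric(fw$fm %*% hb$gv) / n
  gp <- array(gp_vec, fw$dims[1:3]) * delta_gate_prime(fw$p, fw$gate)
  list(ext = eb$grads, head = hb$grads, g_p = gp)
}

#' Train the unified segmentation + classification model end-to-end
#'
#' Combined loss `w_seg * seg + w_dist * dist + w_cls * cross-entropy`;
#' gradients flow through the piecewise-linear gate (differentiable almost
#' everywhere). Reference labels supervise the segmentation branch during
#' training only — inference is mask-free. Training warm-starts the SN2
#' branch with a few segmentation-only epochs for stability.
#'
#' @param cohort An `sn_cohort`.
#' @param masks Per-subject reference masks (training supervision).
#' @param split List with `train` and `val` ids.
#' @param cfg An [sn2_config()] (loss weights taken from here).
#' @param extractor An [extractor_config()] sharing the ROI shape.
#' @param epochs Joint training epochs.
#' @param warmup_epochs Segmentation-only warm-start epochs (0 = end-to-end
#'   from scratch; ignored when `init` is given).
#' @param lr Adam learning rate.
#' @param head_hidden Classifier head width.
#' @param seed Seed.
#' @param gate A [gate_params()] object.
#' @param init Optional warm start: list with `sn2` (a trained `sn2_model`)
#'   and `classifier` (a trained gated `pdnet_model`). The classifier head
#'   is rescaled from gate-mass (weighted) to ROI-size (global-mean) pooling
#'   normalization before end-to-end fine-tuning.
#' @return A `joint_model`.
#' @export
train_joint <- function(cohort, masks, split, cfg = sn2_config(),
                        extractor = extractor_config(), epochs = 10,
                        warmup_epochs = 3, lr = 2e-3, head_hidden = 12,
                        seed = 1, gate = gate_params(), init = NULL) {
  stopifnot(identical(as.integer(cfg$roi_shape),
                      as.integer(extractor$input_roi_shape)))
  grid_dim <- dim(cohort$subjects[[1]]$volume$values)
  box <- population_box(masks[split$train], cfg$margin, grid_dim)
  ids <- c(split$train, split$val)
  inputs <- prepare_sn2_inputs(cohort, masks, cfg, box, ids)
  dx <- cohort_diagnoses(cohort)
  y <- ifelse(dx == "PD", 2L, 1L)
  if (is.null(init)) {
    params <- list(sn2 = build_sn2(cfg, seed = seed),
                   ext = init_extractor(extractor, seed = seed + 7),
                   head = with_seed(seed + 13,
                                    head_params(extractor_out_channels(extractor),
                                                head_hidden)))
  } else {
    params <- list(sn2 = init$sn2$params,
                   ext = init$classifier$params$ext,
                   head = init$classifier$params$head)
    # the warm-started head was trained under gate-mass normalization;
    # global-mean pooling shrinks the vector by the mean gate mass, so the
    # first dense layer is rescaled to compensate
    mass <- mean(vapply(split$train, function(id) {
      fw <- sn2_fwd(inputs[[id]]$x, params$sn2)
      mean(delta_gate(fw$fine[, , , 2], gate))
    }, numeric(1)))
    params$head$fc1$W <- params$head$fc1$W / max(mass, 1e-3)
    warmup_epochs <- 0
  }
  state <- adam_init(params)
  w <- cfg$loss_weights
  best <- list(params = params, val_acc = -Inf, epoch = 0)
  if (!is.null(init)) {
    # warm-started models start from a working classifier; keep it unless
    # fine-tuning improves validation accuracy
    acc0 <- mean(vapply(split$val, function(id)
      (joint_fwd(inputs[[id]]$x, params, gate)$score >= 0.5) ==
        (dx[id] == "PD"), logical(1)))
    best <- list(params = params, val_acc = acc0, epoch = 0)
  }
  log <- data.frame()
  with_seed(seed + 307, {
    for (ep in seq_len(warmup_epochs + epochs)) {
      warm <- ep <= warmup_epochs
      sums <- c(seg = 0, cls = 0)
      for (id in sample(split$train)) {
        inp <- inputs[[id]]
        fw <- joint_fwd(inp$x, params, gate)
        if (!all(is.finite(fw$probs)))
          stop("train_joint: divergence (non-finite probabilities) at epoch ",
               ep)
        lg <- seg_loss_grads(fw$sf$fine, fw$sf$dist, inp$mask, inp$dist,
                             w[["seg"]], w[["dist"]])
        sums["seg"] <- sums["seg"] + lg$loss
        g_fine <- lg$g_fine
        grads <- list(sn2 = NULL, ext = tree_zero(params$ext),
                      head = tree_zero(params$head))
        if (!warm && w[["cls"]] > 0) {
          yi <- y[id]
          sums["cls"] <- sums["cls"] - log(max(fw$probs[yi], 1e-12))
          glog <- fw$probs
          glog[yi] <- glog[yi] - 1
          glog <- glog * w[["cls"]]
          cb <- joint_cls_bwd(fw, params, glog)
          grads$ext <- cb$ext
          grads$head <- cb$head
          g_fine[, , , 2] <- g_fine[, , , 2] + cb$g_p
        }
        sb <- sn2_bwd(fw$sf, params$sn2, g_fine, lg$g_dist)
        grads$sn2 <- sb$grads
        st <- adam_step(params, grads, state, lr = lr)
        params <- st$params
        state <- st$state
      }
      val <- vapply(split$val, function(id) {
        fv <- joint_fwd(inputs[[id]]$x, params, gate)
        c(acc = as.numeric((fv$score >= 0.5) == (dx[id] == "PD")),
          dice = dice_coefficient(fv$p >= 0.5 + 0, inputs[[id]]$mask))
      }, numeric(2))
      val_acc <- mean(val["acc", ])
      log <- rbind(log, data.frame(epoch = ep, warmup = warm,
                                   seg_loss = sums["seg"] /
                                     length(split$train),
                                   cls_loss = sums["cls"] /
                                     length(split$train),
                                   val_acc = val_acc,
                                   val_dice = mean(val["dice", ])))
      if (!warm && val_acc >= best$val_acc)
        best <- list(params = params, val_acc = val_acc, epoch = ep)
    }
  })
  structure(list(params = best$params, cfg = cfg, extractor = extractor,
                 box = box, gate = gate, log = log, val_acc = best$val_acc,
                 best_epoch = best$epoch),
            class = "joint_model")
}

#' @export
print.joint_model <- function(x, ...) {
  cat("<joint_model> end-to-end segmentation + diagnosis | best val acc",
      round(x$val_acc, 3), "at epoch", x$best_epoch, "\n")
  invisible(x)
}

#' Mask-free prediction with the joint model
#'
#' @param object A `joint_model`.
#' @param cohort An `sn_cohort`.
#' @param ids Subjects to score.
#' @param ... Unused.
#' @return `data.frame` with `subject_id`, `true_class`, `score`,
#'   `predicted_class`, and a `degenerate_gate` flag per subject.
#' @export
predict.joint_model <- function(object, cohort, ids = cohort_ids(cohort),
                                ...) {
  shape <- object$cfg$roi_shape
  dx <- cohort_diagnoses(cohort)
  rows <- lapply(ids, function(id) {
    v <- resample_box(cohort$subjects[[id]]$volume$values, object$box, shape)
    x <- array(scale_intensity(v), c(shape, 1))
    fw <- joint_fwd(x, object$params, object$gate)
    data.frame(subject_id = id, true_class = unname(dx[id]),
               score = fw$score,
               predicted_class = if (fw$score >= 0.5) "PD" else "HC",
               degenerate_gate = fw$degenerate, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
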