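test_that("the probability gate matches its printed constants", {
  expect_equal(delta_gate(0), 0)
  expect_equal(delta_gate(0.4), 0)
  expect_equal(delta_gate(0.5), 0.5)    # 5 * 0.5 - 2
  expect_equal(delta_gate(0.6), 1)
  expect_equal(delta_gate(0.7), 1)
  expect_equal(delta_gate(1), 1)
  expect_error(gate_params(t_lo = 0.3), "continuous")
  expect_error(delta_gate(1.5), "\\[0, 1\\]")
})

test_that("the gate is continuous, monotone, and onto [0,1] on a fine grid", {
  p <- seq(0, 1, length.out = 10000)
  g <- delta_gate(p)
  expect_true(all(diff(g) >= 0))
  expect_true(all(g >= 0 & g <= 1))
  expect_lt(max(abs(diff(g))), 1e-3)  # no jumps at the breakpoints
  expect_equal(range(g), c(0, 1))
})

test_that("SN2 rejects pooling and keeps grid shape with softmax outputs", {
  expect_error(build_sn2(sn2_config(strides = c(1, 2, 1))), "pooling-free")
  cfg <- sn2_config(roi_shape = c(10, 10, 8))
  params <- build_sn2(cfg, seed = 1)
  zero <- array(0, c(10, 10, 8, 1))
  fw <- nigrastab:::sn2_fwd(zero, params)
  expect_true(all(is.finite(fw$fine)))
  expect_equal(dim(fw$fine)[1:3], c(10L, 10L, 8L))  # no downsampling
  expect_equal(fw$fine[, , , 1] + fw$fine[, , , 2],
               array(1, c(10, 10, 8)), tolerance = 1e-12)
  expect_equal(fw$init_prob[, , , 1] + fw$init_prob[, , , 2],
               array(1, c(10, 10, 8)), tolerance = 1e-12)
})

test_that("dense blocks consume the concatenation of all previous outputs", {
  cfg <- sn2_config(depth = 3, growth = 6, roi_shape = c(10, 10, 8))
  params <- build_sn2(cfg, seed = 1)
  x <- array(rnorm(10 * 10 * 8), c(10, 10, 8, 1))
  tr <- nigrastab:::dense_trunk_fwd(x, params$trunkA)
  for (i in 1:3) {
    expect_equal(dim(tr$caches[[i]]$x)[4], 1L + (i - 1L) * 6L)
    expect_equal(dim(tr$caches[[i]]$out)[4], 6L)
  }
  expect_equal(dim(tr$out)[4], 1L + 3L * 6L)
})

test_that("SN2 loss gradients match finite differences", {
  withr::with_seed(7, {
    cfg <- sn2_config(depth = 2, growth = 3, roi_shape = c(8, 8, 6))
    params <- build_sn2(cfg, seed = 2)
    x <- array(rnorm(8 * 8 * 6), c(8, 8, 6, 1))
    tmask <- array(0, c(8, 8, 6)); tmask[3:5, 3:5, 2:4] <- 1
    tdist <- pmin(pmax(signed_distance(tmask, c(1, 1, 1)) / 10, -1), 1)
    loss_of <- function(params) {
      fw <- nigrastab:::sn2_fwd(x, params)
      nigrastab:::seg_loss_grads(fw$fine, fw$dist, tmask, tdist, 1, 0.5)$loss
    }
    fw <- nigrastab:::sn2_fwd(x, params)
    lg <- nigrastab:::seg_loss_grads(fw$fine, fw$dist, tmask, tdist, 1, 0.5)
    bw <- nigrastab:::sn2_bwd(fw, params, lg$g_fine, lg$g_dist)
    eps <- 1e-6
    for (probe in list(c("fusion", 5), c("headB", 2))) {
      pp <- params; pm <- params
      pp[[probe[1]]]$W[as.integer(probe[2])] <-
        pp[[probe[1]]]$W[as.integer(probe[2])] + eps
      pm[[probe[1]]]$W[as.integer(probe[2])] <-
        pm[[probe[1]]]$W[as.integer(probe[2])] - eps
      fd <- (loss_of(pp) - loss_of(pm)) / (2 * eps)
      expect_equal(bw$grads[[probe[1]]]$W[as.integer(probe[2])], fd,
                   tolerance = 1e-4)
    }
    pp <- params; pm <- params
    pp$trunkA[[1]]$W[3] <- pp$trunkA[[1]]$W[3] + eps
    pm$trunkA[[1]]$W[3] <- pm$trunkA[[1]]$W[3] - eps
    fd <- (loss_of(pp) - loss_of(pm)) / (2 * eps)
    expect_equal(bw$grads$trunkA[[1]]$W[3], fd, tolerance = 1e-4)
  })
})

test_that("an untrained SN2 segments phantoms near chance", {
  coh <- small_cohort(2)
  masks <- cohort_masks(coh)
  cfg <- sn2_config()
  params <- build_sn2(cfg, seed = 9)
  box <- nigrastab:::population_box(masks, cfg$margin,
                                    dim(coh$subjects[[1]]$volume$values))
  inp <- nigrastab:::prepare_sn2_inputs(coh, masks, cfg, box,
                                        nigrastab:::cohort_ids(coh))
  d <- vapply(inp, function(i) {
    fw <- nigrastab:::sn2_fwd(i$x, params)
    dice_coefficient(fw$fine[, , , 2] >= 0.5 + 0, i$mask)
  }, numeric(1))
  expect_lt(mean(d), 0.3)
})

test_that("binary probabilities reduce joint pooling to binary gating", {
  withr::with_seed(8, {
    fm <- array(rnorm(6 * 6 * 4 * 3), c(6, 6, 4, 3))
    mask <- array(0, c(6, 6, 4)); mask[2:4, 2:4, 2:3] <- 1
    # delta(1) = 1, delta(0) = 0: the gate equals the mask itself
    expect_identical(delta_gate(mask), mask)
    expect_equal(gated_pool(fm, delta_gate(mask), "global"),
                 gated_pool(fm, mask, "global"))
    # probabilities uniformly 0.2 gate to zero everywhere (degenerate path)
    expect_true(all(delta_gate(array(0.2, c(6, 6, 4))) == 0))
  })
})

test_that("joint inference consumes only the volume, never a mask", {
  coh <- fixture("crisp8", function()
    generate_cohort(4, 4, crisp_params(), seed = 19))
  masks <- cohort_masks(coh)
  ids <- nigrastab:::cohort_ids(coh)
  split <- list(train = ids[c(1:3, 5:7)], val = ids[c(4, 8)])
  jm <- fixture("joint_tiny", function()
    train_joint(coh, masks, split, epochs = 2, warmup_epochs = 2,
                lr = 2e-3, seed = 1))
  p1 <- predict(jm, coh)
  mangled <- coh
  for (id in ids)
    mangled$subjects[[id]]$mask <- binary_mask(
      array(0, dim(coh$subjects[[id]]$mask$values)))
  p2 <- predict(jm, mangled)
  expect_identical(p1, p2)
  expect_true(all(p1$score >= 0 & p1$score <= 1))
})

test_that("the class head receives no gradient when its loss weight is 0", {
  coh <- fixture("crisp8", function()
    generate_cohort(4, 4, crisp_params(), seed = 19))
  masks <- cohort_masks(coh)
  ids <- nigrastab:::cohort_ids(coh)
  split <- list(train = ids[c(1:3, 5:7)], val = ids[c(4, 8)])
  cfg0 <- sn2_config(loss_weights = c(seg = 1, dist = 0.5, cls = 0))
  jm <- train_joint(coh, masks, split, cfg = cfg0, epochs = 2,
                    warmup_epochs = 0, lr = 2e-3, seed = 3)
  init_head <- nigrastab:::with_seed(3 + 13, nigrastab:::head_params(16, 12))
  expect_identical(jm$params$head, init_head)
})
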