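roi_fixture <- function() {
  fixture("roi_inputs", function() {
    s <- small_cohort(2)$subjects[[1]]
    crop_roi(s$volume, s$mask, out_shape = c(16, 16, 12), margin = 4)
  })
}

test_that("ROI cropping geometry follows the mask bounding box", {
  s <- small_cohort(2)$subjects[[1]]
  d <- dim(s$volume$values)
  # mask filling the whole grid, margin 0: box is the full grid
  full <- binary_mask(array(1, d), s$volume$spacing)
  roi <- crop_roi(s$volume, full, out_shape = c(16, 16, 12), margin = 0)
  expect_equal(roi$box$lo, c(1L, 1L, 1L))
  expect_equal(roi$box$hi, as.integer(d))
  # single-voxel mask, margin 4: a 9x9x9 box before clipping
  single <- array(0, d); single[20, 20, 16] <- 1
  b <- nigrastab:::crop_box(binary_mask(single, s$volume$spacing), 4)
  expect_equal(b$hi - b$lo + 1L, c(9L, 9L, 9L))
  # label sources sharing a bounding box give identical ROI volumes
  m2 <- s$mask$values
  interior <- nigrastab:::interior_rim(m2 == 1)
  m2[which(interior)[1]] <- 0  # erode one boundary voxel: box unchanged
  roi_a <- crop_roi(s$volume, s$mask, out_shape = c(16, 16, 12), margin = 4)
  roi_b <- crop_roi(s$volume, binary_mask(m2, s$volume$spacing),
                    out_shape = c(16, 16, 12), margin = 4)
  expect_identical(roi_a$box, roi_b$box)
  expect_identical(roi_a$volume, roi_b$volume)
  expect_error(crop_roi(s$volume, binary_mask(array(0, d))), "empty")
})

test_that("gated pooling reduces to GAP and to in-mask means", {
  withr::with_seed(4, {
    fm <- array(rnorm(4 * 4 * 2 * 3), c(4, 4, 2, 3))
    ones <- array(1, c(4, 4, 2))
    gap <- colMeans(matrix(fm, 32, 3))
    expect_equal(gated_pool(fm, ones, "weighted"), gap, tolerance = 1e-12)
    expect_equal(gated_pool(fm, ones, "global"), gap, tolerance = 1e-12)
    gate <- array(0, c(4, 4, 2)); gate[1:2, 1:2, 1] <- 1
    # brute-force in-mask mean per channel
    manual <- vapply(1:3, function(c1) mean(fm[1:2, 1:2, 1, c1]), numeric(1))
    expect_equal(gated_pool(fm, gate, "weighted"), manual, tolerance = 1e-12)
    expect_equal(gated_pool(fm, gate, "global"),
                 manual * sum(gate) / 32, tolerance = 1e-12)
    # perturbations strictly outside the gate support cannot change pooling
    fm2 <- fm
    fm2[3:4, , , ] <- fm2[3:4, , , ] + 100
    expect_equal(gated_pool(fm2, gate, "weighted"),
                 gated_pool(fm, gate, "weighted"))
    expect_equal(gated_pool(fm2, gate, "global"),
                 gated_pool(fm, gate, "global"))
    expect_error(gated_pool(fm, gate * 0, "weighted"), "zero")
    expect_error(gated_pool(fm, array(1, c(3, 3, 3))), "grid")
  })
})

test_that("gated and masked forward agree for a full-support gate", {
  roi <- roi_fixture()
  params <- nigrastab:::init_pdnet(extractor_config(), seed = 5)
  ones <- array(1, dim(roi$volume))
  expect_equal(gated_forward(roi$volume, ones, params),
               masked_forward(roi$volume, ones, params), tolerance = 1e-12)
  # deterministic inference
  expect_identical(masked_forward(roi$volume, roi$mask, params),
                   masked_forward(roi$volume, roi$mask, params))
})

test_that("only pooling, not extractor activations, sees the gate", {
  roi <- roi_fixture()
  params <- nigrastab:::init_pdnet(extractor_config(), seed = 5)
  x <- array(nigrastab:::scale_intensity(roi$volume), c(dim(roi$volume), 1))
  ex1 <- nigrastab:::extractor_fwd(x, params$ext)
  gate2 <- roi$mask
  gate2[1, 1, 1] <- 1 - gate2[1, 1, 1]
  fw1 <- nigrastab:::pdnet_fwd(x, roi$mask, "gated", params)
  fw2 <- nigrastab:::pdnet_fwd(x, gate2, "gated", params)
  expect_identical(fw1$ex$out, ex1$out)
  expect_identical(fw2$ex$out, ex1$out)  # activations blind to the gate
  expect_false(identical(fw1$score, fw2$score))  # pooling is not
  # masked mode: the same label change alters the input itself
  xm1 <- x * array(roi$mask, c(dim(roi$mask), 1))
  xm2 <- x * array(gate2, c(dim(gate2), 1))
  expect_false(identical(xm1, xm2))
})

test_that("training separates a high-contrast phantom cohort", {
  coh <- fixture("crisp16", function()
    generate_cohort(8, 8, crisp_params(), seed = 31))
  masks <- cohort_masks(coh)
  ids <- nigrastab:::cohort_ids(coh)
  split <- list(train = ids[c(1:6, 9:14)], val = ids[c(7:8, 15:16)])
  cfg <- pdnet_train_cfg(epochs = 20, seed = 1)
  m <- train_classifier(coh, masks, "masked", split, cfg)
  train_pred <- predict(m, coh, masks, ids = split$train)
  expect_gt(mean(train_pred$predicted_class == train_pred$true_class), 0.9)
  # deterministic retraining
  m2 <- train_classifier(coh, masks, "masked", split, cfg)
  expect_identical(m$params, m2$params)
})

test_that("a zero-contrast cohort yields chance-level AUC", {
  null_params <- phantom_params(hc_mean = 100, pd_mean = 100.0001,
                                hc_sd = 12, pd_sd = 12, texture_sd = 8)
  coh <- fixture("null_cohort", function()
    generate_cohort(38, 38, null_params, seed = 13))
  masks <- cohort_masks(coh)
  ids <- nigrastab:::cohort_ids(coh)
  pd <- ids[1:38]; hc <- ids[39:76]
  split <- list(train = c(pd[1:6], hc[1:6]), val = c(pd[7:8], hc[7:8]))
  test_ids <- c(pd[9:38], hc[9:38])
  m <- train_classifier(coh, masks, "masked", split,
                        pdnet_train_cfg(epochs = 8, seed = 2))
  pr <- predict(m, coh, masks, ids = test_ids)
  auc <- unname(classification_panel(pr)["auc"])
  expect_gt(auc, 0.35)
  expect_lt(auc, 0.65)
})
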