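test_that("Dice matches hand-counted overlaps and its conventions", {
  a <- array(c(1, 1, 1, 1, 0, 0, 0, 0, 0), c(3, 3, 1))
  b <- array(c(0, 0, 1, 1, 1, 1, 0, 0, 0), c(3, 3, 1))
  expect_equal(dice_coefficient(a, b), 0.5)  # |A|=4, |B|=4, overlap 2
  expect_equal(dice_coefficient(a, a), 1)
  disj <- array(c(0, 0, 0, 0, 0, 1, 1, 1, 1), c(3, 3, 1))
  expect_equal(dice_coefficient(a, disj), 0)
  empty <- array(0, c(3, 3, 1))
  expect_equal(dice_coefficient(empty, empty), 1)
  expect_error(dice_coefficient(a, array(0, c(2, 2, 1))), "shape")
})

test_that("Dice is symmetric, bounded, and translation invariant", {
  withr::with_seed(1, {
    for (i in 1:5) {
      a <- array(runif(8 * 8 * 4) > 0.6, c(8, 8, 4))
      b <- array(runif(8 * 8 * 4) > 0.6, c(8, 8, 4))
      d <- dice_coefficient(a, b)
      expect_equal(d, dice_coefficient(b, a))
      expect_gte(d, 0)
      expect_lte(d, 1)
      # simultaneous translation of both masks (content away from edges)
      a2 <- array(FALSE, c(8, 8, 4)); a2[2:8, , ] <- a[1:7, , ]
      b2 <- array(FALSE, c(8, 8, 4)); b2[2:8, , ] <- b[1:7, , ]
      a[8, , ] <- b[8, , ] <- FALSE
      expect_equal(dice_coefficient(a2, b2), dice_coefficient(a, b))
    }
  })
})

test_that("signed distance follows the center-to-center convention", {
  m <- array(FALSE, c(9, 9, 9)); m[5, 5, 5] <- TRUE
  d <- signed_distance(m, c(1, 1, 1))
  expect_equal(d[6, 5, 5], 1)           # face-adjacent outside: +1 mm
  expect_equal(d[5, 5, 5], -1)          # the lone voxel: bg center 1 mm away
  expect_true(all(sign(d[m]) < 0) && all(sign(d[!m]) > 0))
})

test_that("signed distance magnitude matches brute-force search", {
  m <- array(FALSE, c(10, 10, 8)); m[3:8, 3:8, 3:6] <- TRUE
  sp <- c(0.86, 0.86, 1.0)
  d <- signed_distance(m, sp)
  idx_bg <- which(!m, arr.ind = TRUE)
  idx_fg <- which(m, arr.ind = TRUE)
  bf <- function(pt, pool) {
    min(sqrt(colSums((t(pool) - pt)^2)))
  }
  pts_fg <- sweep(idx_fg - 1, 2, sp, `*`)
  pts_bg <- sweep(idx_bg - 1, 2, sp, `*`)
  withr::with_seed(3, probe <- sample(nrow(idx_fg), 10))
  for (i in probe) {
    expect_equal(-d[idx_fg[i, 1], idx_fg[i, 2], idx_fg[i, 3]],
                 bf(pts_fg[i, ], pts_bg), tolerance = 1e-12)
  }
  # negating the mask swaps the sign pattern
  d2 <- signed_distance(!m, sp)
  expect_true(all(sign(d2[m]) > 0) && all(sign(d2[!m]) < 0))
  expect_error(signed_distance(array(TRUE, c(8, 8, 8))), "background")
})

# Independent ICC(2,1) oracle via aov-based two-way ANOVA mean squares.
icc_oracle <- function(x) {
  n <- nrow(x); k <- ncol(x)
  df <- data.frame(y = as.vector(x),
                   subj = factor(rep(seq_len(n), k)),
                   rater = factor(rep(seq_len(k), each = n)))
  ms <- anova(stats::aov(y ~ subj + rater, data = df))$`Mean Sq`
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
}

test_that("ICC(2,1) agrees with an aov-based ANOVA oracle to 1e-10", {
  withr::with_seed(10, {
    for (i in 1:8) {
      x <- matrix(rnorm(40), 20, 2)
      expect_equal(icc_2_1(x), icc_oracle(x), tolerance = 1e-10)
    }
  })
})

test_that("ICC(2,1) behaves at agreement, offset, noise, and degeneracy", {
  withr::with_seed(2, x <- rnorm(20, 0, 2))
  expect_equal(icc_2_1(cbind(x, x)), 1)
  # absolute agreement penalizes a constant offset
  small <- seq(0, 1, length.out = 6)
  expect_lt(icc_2_1(cbind(small, small + 10)), 0.2)
  withr::with_seed(3, noise <- matrix(rnorm(100), 50, 2))
  expect_lt(abs(icc_2_1(noise)), 0.3)
  expect_true(is.na(icc_2_1(matrix(1, 10, 2))))
  expect_error(icc_2_1(matrix(1, 2, 2)), "3 subjects")
})

test_that("CCI counts agreements and validates subject sets", {
  n <- 1000
  a <- data.frame(subject_id = sprintf("S%04d", 1:n),
                  predicted_class = "PD")
  b <- a
  b$predicted_class[1:74] <- "HC"   # 926 of 1,000 agree
  expect_equal(cci(a, b), 0.926)
  expect_equal(cci(a, a), 1)
  d10 <- data.frame(subject_id = sprintf("S%02d", 1:10),
                    predicted_class = rep("PD", 10))
  d10b <- d10; d10b$predicted_class <- "HC"
  expect_equal(cci(d10, d10b), 0)
  expect_error(cci(a, a[-1, ]), "differ")
})

test_that("CCI is symmetric with unit diagonal on random tables", {
  for (s in 1:5) {
    a <- random_predictions(30, s)
    b <- random_predictions(30, s + 100)
    expect_equal(cci(a, b), cci(b, a))
    expect_equal(cci(a, a), 1)
  }
})

test_that("the metric panel matches closed-form and brute-force AUC", {
  tab <- data.frame(true_class = c("PD", "PD", "PD", "HC", "HC"),
                    score = c(0.9, 0.6, 0.4, 0.5, 0.3),
                    predicted_class = c("PD", "PD", "HC", "PD", "HC"))
  pan <- classification_panel(tab)
  # 6 PD/HC pairs: 0.9>0.5, 0.9>0.3, 0.6>0.5, 0.6>0.3, 0.4<0.5, 0.4>0.3
  expect_equal(unname(pan["auc"]), 5 / 6)
  tied <- data.frame(true_class = c("PD", "PD", "HC", "HC"),
                     score = c(0.9, 0.5, 0.5, 0.3),
                     predicted_class = c("PD", "PD", "PD", "HC"))
  # 4 pairs: 3 wins + 1 tie at half credit
  expect_equal(unname(classification_panel(tied)["auc"]), 3.5 / 4)
  expect_equal(unname(pan["sensitivity"]), 2 / 3)
  expect_equal(unname(pan["specificity"]), 1 / 2)
  expect_equal(unname(pan["bac"]), (2 / 3 + 1 / 2) / 2)
  sep <- data.frame(true_class = rep(c("PD", "HC"), each = 4),
                    score = c(0.9, 0.8, 0.85, 0.7, 0.2, 0.1, 0.3, 0.15),
                    predicted_class = rep(c("PD", "HC"), each = 4))
  expect_equal(unname(classification_panel(sep)["auc"]), 1)
  expect_equal(unname(classification_panel(sep)["accuracy"]), 1)
  anti <- sep; anti$score <- rev(anti$score)
  expect_equal(unname(classification_panel(anti)["auc"]), 0)
  expect_error(classification_panel(tab[tab$true_class == "PD", ]), "classes")
})

test_that("rank AUC equals brute-force pair enumeration with half ties", {
  brute_auc <- function(score, pos) {
    s1 <- score[pos]; s0 <- score[!pos]
    cmp <- outer(s1, s0, function(a, b) (a > b) + 0.5 * (a == b))
    mean(cmp)
  }
  withr::with_seed(8, {
    for (i in 1:10) {
      n <- sample(6:50, 1)
      sc <- round(runif(n), 2)          # rounding forces ties
      pos <- sample(c(TRUE, FALSE), n, replace = TRUE)
      if (!any(pos) || all(pos)) next
      expect_equal(nigrastab:::auc_rank(sc, pos), brute_auc(sc, pos))
    }
  })
})

test_that("paired comparisons are corrected and handle ties", {
  a <- c(0.8, 0.81, 0.79, 0.8, 0.82, 0.8, 0.78, 0.8, 0.81, 0.8)
  expect_equal(paired_comparison(a, a)$p_corrected, 1)
  withr::with_seed(4, b <- a - 0.05 + rnorm(10, 0, 1e-3))
  pc <- paired_comparison(a, b, n_comparisons = 3)
  expect_lt(pc$p_corrected, 0.05)
  expect_gte(pc$p_corrected, pc$p_uncorrected)
  # closed-form check of the t statistic on the same differences
  d <- a - b
  expect_equal(pc$t_statistic, mean(d) / (sd(d) / sqrt(length(d))),
               tolerance = 1e-12)
})
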