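test_that("dice handles identity, disjoint, partial overlap and empty masks", {
  a <- square_mask()
  expect_equal(dice(a, a), 1)
  b <- matrix(0, 16, 16); b[1:3, 1:3] <- 1          # disjoint from a
  expect_equal(dice(a, b), 0)
  # |P| = 4, |R| = 4, overlap 2 -> 0.5
  p <- matrix(0, 4, 4); p[1, 1:4] <- 1
  r <- matrix(0, 4, 4); r[1, 3:4] <- 1; r[2, 1:2] <- 1
  expect_equal(dice(p, r), 0.5)
  z <- matrix(0, 16, 16)
  expect_equal(dice(z, z), 1)   # both empty: nothing missed
  expect_equal(dice(a, z), 0)   # one empty
  expect_error(dice(a, matrix(0, 8, 8)), class = "ennseg_shape_error")
  expect_error(dice(a * 2, a), class = "ennseg_value_error")
})

test_that("dice is symmetric and agrees with the cardinality oracle", {
  withr::with_seed(71, {
    for (i in 1:25) {
      a <- matrix(rbinom(100, 1, runif(1, 0.1, 0.6)), 10, 10)
      b <- matrix(rbinom(100, 1, runif(1, 0.1, 0.6)), 10, 10)
      expect_equal(dice(a, b), dice(b, a))
      expect_equal(dice(a, b), oracle_dice(a, b))
    }
  })
})

test_that("binary entropy has the closed-form boundary and midpoint values", {
  expect_equal(binary_entropy(0.5), 1)
  expect_equal(binary_entropy(0), 0)
  expect_equal(binary_entropy(1), 0)
  expect_equal(binary_entropy(0.25), -0.25 * log2(0.25) - 0.75 * log2(0.75))
  expect_error(binary_entropy(1.2), class = "ennseg_value_error")
  p <- seq(0, 1, by = 0.01)
  h <- binary_entropy(p)
  expect_true(all(h >= 0 & h <= 1))
  expect_equal(h, rev(h))  # symmetry about 0.5
})

test_that("foreground entropy averages H over predicted foreground only", {
  prob <- matrix(0, 4, 4)
  prob[1, 1] <- 1; prob[1, 2] <- 0.5
  e <- foreground_entropy(prob)
  expect_equal(as.numeric(e), 0.5)  # mean of H(1)=0 and H(0.5)=1
  expect_false(attr(e, "empty_foreground"))
  # certain prediction -> zero entropy
  expect_equal(as.numeric(foreground_entropy((square_mask()) * 1)), 0)
  # empty predicted foreground -> 1 with flag
  e0 <- foreground_entropy(matrix(0.1, 4, 4))
  expect_equal(as.numeric(e0), 1)
  expect_true(attr(e0, "empty_foreground"))
})

test_that("foreground entropy of a fused binary map is 0 when foreground exists", {
  withr::with_seed(5, {
    for (i in 1:10) {
      m <- matrix(rbinom(64, 1, 0.4), 8, 8)
      if (sum(m) == 0) m[3, 3] <- 1
      pr <- fuse(list(m * 1, m * 1))
      expect_equal(as.numeric(foreground_entropy(pr)), 0)
    }
  })
})

test_that("roc matches the pairwise-concordance oracle on known cases", {
  # 3 of 4 pairs concordant -> AUC 0.75
  r <- roc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1), polarity = "high")
  expect_equal(r$auc, 0.75)
  # perfectly separating scores
  rp <- roc(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1), polarity = "high")
  expect_equal(rp$auc, 1)
  # low polarity: low score predicts positive
  rl <- roc(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0), polarity = "low")
  expect_equal(rl$auc, 1)
  expect_error(roc(1:4, c(1, 1, 1, 1)), class = "ennseg_value_error")
})

test_that("roc AUC is ~0.5 for random labels at large n", {
  withr::with_seed(99, {
    s <- runif(1000)
    l <- rbinom(1000, 1, 0.5)
    expect_lt(abs(roc(s, l, "high")$auc - 0.5), 0.05)
  })
})

test_that("roc AUC agrees with pROC on random instances", {
  skip_if_not_installed("pROC")
  withr::with_seed(123, {
    for (i in 1:10) {
      n <- sample(20:80, 1)
      s <- round(runif(n), 2)  # force ties
      l <- rbinom(n, 1, 0.5)
      if (length(unique(l)) < 2) next
      ours <- roc(s, l, "high")$auc
      ref <- as.numeric(suppressMessages(
        pROC::auc(pROC::roc(l, s, direction = "<", quiet = TRUE))))
      expect_equal(ours, ref, tolerance = 1e-12)
    }
  })
})

test_that("youden cutoff maximises J and matches exhaustive search", {
  withr::with_seed(17, {
    for (polarity in c("high", "low")) {
      for (i in 1:20) {
        n <- 20
        s <- round(runif(n), 1)
        l <- rbinom(n, 1, 0.5)
        if (length(unique(l)) < 2) next
        r <- roc(s, l, polarity)
        cut <- youden_cutoff(r)
        o <- oracle_youden(s, l, polarity)
        expect_equal(as.numeric(cut), o$threshold)
        expect_equal(attr(cut, "j"), o$j)
        # definitional: J at cutoff >= J at every empirical cutoff
        expect_true(all(attr(cut, "j") >=
                          r$points$sensitivity + r$points$specificity - 1 - 1e-12))
      }
    }
  })
})

test_that("confusion stats follow the standard definitions", {
  expect_equal(confusion_stats(c(1, 0, 1), c(1, 0, 1)),
               list(sensitivity = 1, specificity = 1, accuracy = 1))
  expect_equal(confusion_stats(c(0, 1, 0), c(1, 0, 1)),
               list(sensitivity = 0, specificity = 0, accuracy = 0))
  # TP=3 FN=1 TN=4 FP=2
  pred <- c(rep(1, 3), rep(0, 1), rep(0, 4), rep(1, 2))
  tru <- c(rep(1, 4), rep(0, 6))
  cs <- confusion_stats(pred, tru)
  expect_equal(cs$sensitivity, 0.75)
  expect_equal(cs$specificity, 4 / 6)
  expect_equal(cs$accuracy, 0.7)
  expect_error(confusion_stats(c(1, 0), c(1, 0, 1)),
               class = "ennseg_shape_error")
})

test_that("patient dice pools voxels across slices", {
  a <- square_mask(8, 3, 6)          # 16 voxels
  disjoint <- matrix(0, 8, 8)
  disjoint[1:2, 1:8] <- 1            # 16 voxels, disjoint from a
  expect_equal(sum(a * disjoint), 0)
  # one slice: equals slice dice
  expect_equal(patient_dice(list(a), list(a)), dice(a, a))
  expect_equal(patient_dice(list(a, a), list(a, a)), 1)
  # slices with dice 1 and 0 at equal |P| = |R| areas pool to 0.5
  expect_equal(patient_dice(list(a, disjoint), list(a, a)), 0.5)
})

test_that("pooled patient dice differs from mean slice dice for unequal areas", {
  big_ref <- square_mask(16, 1, 12)   # 144 voxels
  small_ref <- square_mask(16, 8, 9)  # 4 voxels
  big_pred <- big_ref                 # dice 1 on the big slice
  small_pred <- matrix(0, 16, 16); small_pred[14:15, 14:15] <- 1  # dice 0
  pooled <- patient_dice(list(big_pred, small_pred), list(big_ref, small_ref))
  per_slice_mean <- mean(c(dice(big_pred, big_ref), dice(small_pred, small_ref)))
  expect_equal(pooled, 2 * 144 / (148 + 148))
  expect_gt(pooled, per_slice_mean)  # big accurate slice dominates the pool
})

test_that("median_iqr uses linear-interpolation quantiles", {
  x <- c(1, 2, 3, 4, 10)
  s <- median_iqr(x)
  expect_equal(s$median, 3)
  expect_equal(s$iqr_low, unname(quantile(x, 0.25)))
  expect_equal(s$iqr_high, unname(quantile(x, 0.75)))
})
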