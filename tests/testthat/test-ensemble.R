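toy_pairs <- function(n_slices, size = 16, seed = 50) {
  withr::with_seed(seed, {
    lapply(seq_len(n_slices), function(i) {
      m <- disc_mask(size, sample(5:(size - 5), 1), sample(5:(size - 5), 1), 3)
      px <- 1000 + 600 * m + matrix(rnorm(size^2, 0, 50), size, size)
      list(slice = px, mask = m)
    })
  })
}

test_that("soft dice loss matches the closed form and its bounds", {
  t <- square_mask(8, 3, 6)
  # perfect binary prediction, smooth -> 0: loss 0
  expect_equal(soft_dice_loss(t * 1, t, smooth = 1e-12), 0, tolerance = 1e-9)
  # complement prediction: loss 1
  expect_equal(soft_dice_loss(1 - t, t, smooth = 1e-12), 1, tolerance = 1e-9)
  # pred constant 0.5, target half foreground on a 2x2 grid -> 1/3
  pred <- matrix(0.5, 2, 2)
  targ <- matrix(c(1, 1, 0, 0), 2, 2)
  expect_equal(soft_dice_loss(pred, targ, smooth = 1e-12), 1 / 3,
               tolerance = 1e-9)
  # bounds on random inputs
  withr::with_seed(31, {
    for (i in 1:20) {
      p <- matrix(runif(64), 8, 8)
      tt <- matrix(rbinom(64, 1, 0.4), 8, 8)
      l <- soft_dice_loss(p, tt)
      expect_gte(l, 0); expect_lte(l, 1)
    }
  })
  expect_error(soft_dice_loss(matrix(2, 2, 2), matrix(1, 2, 2)),
               class = "ennseg_value_error")
})

test_that("soft dice loss equals 1 - hard dice on binary predictions", {
  withr::with_seed(77, {
    for (i in 1:25) {
      p <- matrix(rbinom(100, 1, runif(1, 0.1, 0.6)), 10, 10)
      r <- matrix(rbinom(100, 1, runif(1, 0.1, 0.6)), 10, 10)
      if (sum(p) + sum(r) == 0) next
      expect_equal(1 - soft_dice_loss(p * 1, r, smooth = 1e-12), dice(p, r),
                   tolerance = 1e-9)
    }
  })
})

test_that("fuse is the elementwise member mean with round-half-up mask", {
  m1 <- matrix(0.9, 2, 2); m2 <- matrix(0.9, 2, 2)
  m3 <- matrix(0.2, 2, 2); m4 <- matrix(0.2, 2, 2)
  pr <- fuse(list(m1, m2, m3, m4))
  expect_equal(pr$fused_prob, matrix(0.55, 2, 2))
  expect_equal(pr$binary_mask, matrix(1, 2, 2))
  # exact tie 0.5 -> foreground
  tie <- fuse(list(matrix(0.6, 1, 1), matrix(0.4, 1, 1)))
  expect_equal(tie$fused_prob[1, 1], 0.5)
  expect_equal(tie$binary_mask[1, 1], 1)
  # identical maps: mean identity
  one <- matrix(runif(16), 4, 4)
  expect_equal(fuse(list(one, one, one))$fused_prob, one)
  expect_error(fuse(list(matrix(0.5, 2, 2), matrix(0.5, 3, 3))),
               class = "ennseg_shape_error")
  expect_error(fuse(list(matrix(2, 2, 2))), class = "ennseg_value_error")
  expect_error(fuse(list()), class = "ennseg_value_error")
})

test_that("fusion equals a brute-force loop mean and is order-invariant", {
  withr::with_seed(12, {
    maps <- lapply(1:5, function(i) matrix(runif(36), 6, 6))
    pr <- fuse(maps)
    manual <- matrix(0, 6, 6)
    for (m in maps) manual <- manual + m
    manual <- manual / 5
    expect_equal(pr$fused_prob, manual)
    perm <- fuse(maps[c(3, 5, 1, 4, 2)])
    expect_equal(perm$fused_prob, pr$fused_prob)
    expect_equal(perm$binary_mask, pr$binary_mask)
    # mask consistency at every voxel
    expect_true(all((pr$binary_mask == 1) == (pr$fused_prob >= 0.5)))
  })
})

test_that("augmentations keep pairs aligned and masks binary", {
  px <- matrix(seq_len(64), 8, 8) * 1.0
  m <- square_mask(8, 2, 4)
  # identity config
  id <- apply_augmentation(px, m)
  expect_identical(id$pixels, px)
  expect_identical(id$mask, m)
  # horizontal flip is an involution
  f1 <- apply_augmentation(px, m, hflip = TRUE)
  f2 <- apply_augmentation(f1$pixels, f1$mask, hflip = TRUE)
  expect_identical(f2$pixels, px)
  expect_identical(f2$mask, m)
  # 90 degree rotation moves an off-center blob to the rotated position
  blob <- matrix(0, 15, 15); blob[3:5, 7:9] <- 1   # centroid (4, 8)
  rot <- apply_augmentation(blob, blob, angle = 90)
  cen <- function(mm) colMeans(which(mm == 1, arr.ind = TRUE))
  # rotating the sampling grid by +90 deg maps source (4,8) to (8, 12)
  expect_equal(unname(cen(rot$mask)), c(8, 12), tolerance = 0.2)
  expect_true(all(rot$mask %in% c(0, 1)))
  # intensity jitter leaves the mask untouched
  j <- apply_augmentation(px, m, intensity = 1.1)
  expect_equal(j$pixels, px * 1.1)
  expect_identical(j$mask, m)
})

test_that("network gradients agree with finite differences", {
  ns <- asNamespace("ennseg")
  withr::with_seed(2, {
    H <- 8; W <- 8; B <- 2; C <- 3
    wts <- ns$tiny_unet_init(C)
    x <- array(rnorm(H * W * B), c(H, W, 1, B))
    t <- array(rbinom(H * W * B, 1, 0.3), c(H, W, B))
    loss_of <- function(w) {
      fw <- ns$tiny_unet_forward(w, x, keep_cache = TRUE)
      ns$batch_soft_dice(ns$sigmoid(fw$logits), t, 1)$loss
    }
    fw <- ns$tiny_unet_forward(wts, x, keep_cache = TRUE)
    ls <- ns$batch_soft_dice(ns$sigmoid(fw$logits), t, 1)
    gr <- ns$tiny_unet_backward(wts, fw$cache, ls$dlogits)
    eps <- 1e-6
    for (nm in names(wts)) {
      idx <- sample(length(wts[[nm]]), min(5, length(wts[[nm]])))
      for (i in idx) {
        wp <- wts; wp[[nm]][i] <- wp[[nm]][i] + eps
        wm <- wts; wm[[nm]][i] <- wm[[nm]][i] - eps
        num <- (loss_of(wp) - loss_of(wm)) / (2 * eps)
        expect_equal(gr[[nm]][i], num, tolerance = 1e-4)
      }
    }
  })
})

test_that("training is deterministic and members are independently seeded", {
  pairs <- toy_pairs(10)
  cfg <- ensemble_config(n_members = 2L, epochs = 2L, batch_size = 4L,
                         channels = 2L, base_seed = 7L)
  m0a <- train_member(pairs, pairs[1:3], cfg, 0L)
  m0b <- train_member(pairs, pairs[1:3], cfg, 0L)
  expect_identical(m0a$log, m0b$log)
  expect_identical(m0a$weights, m0b$weights)
  m1 <- train_member(pairs, pairs[1:3], cfg, 1L)
  expect_false(identical(m0a$weights$W1, m1$weights$W1))
  expect_false(m0a$seed == m1$seed)
  # loss decreases over epochs on this separable toy problem
  expect_lt(tail(m0a$log$train_loss, 1), m0a$log$train_loss[1])
  expect_error(train_member(list(), pairs, cfg, 0L),
               class = "ennseg_value_error")
  expect_error(train_member(pairs, pairs, cfg, 5L),
               class = "ennseg_value_error")
})

test_that("prediction fuses members and handles degenerate ensembles", {
  pairs <- toy_pairs(8, seed = 51)
  cfg <- ensemble_config(n_members = 1L, epochs = 2L, batch_size = 4L,
                         channels = 2L, base_seed = 19L)
  ens1 <- train_ensemble(pairs, NULL, cfg)
  pr1 <- predict_slice(ens1, pairs[[1]]$slice)
  # M = 1: fused equals the single member output
  expect_equal(pr1$fused_prob, pr1$member_probs[[1]])
  # ensemble of M copies of one member predicts exactly like that member
  ens3 <- ens1
  ens3$members <- rep(ens1$members, 3)
  pr3 <- predict_slice(ens3, pairs[[1]]$slice)
  expect_equal(pr3$fused_prob, pr1$fused_prob)
  expect_equal(pr3$binary_mask, pr1$binary_mask)
  # odd-sized input is incompatible with the downsampling backbone
  expect_error(predict_slice(ens1, matrix(0, 15, 15)),
               class = "ennseg_shape_error")
})

test_that("unknown backbones are rejected", {
  expect_error(ensemble_config(backbone = "deeplabv3_resnet50"),
               class = "ennseg_value_error")
  expect_error(ensemble_config(backbone = "nope"),
               class = "ennseg_value_error")
})

test_that("checkpoints round-trip through save_ensemble / load_ensemble", {
  td <- withr::local_tempdir()
  pairs <- toy_pairs(6, seed = 52)
  cfg <- ensemble_config(n_members = 2L, epochs = 2L, batch_size = 4L,
                         channels = 2L, base_seed = 23L)
  ens <- train_ensemble(pairs, pairs[1:2], cfg)
  save_ensemble(ens, file.path(td, "ckpt"))
  expect_true(file.exists(file.path(td, "ckpt", "manifest.json")))
  expect_true(file.exists(file.path(td, "ckpt", "member_00.rds")))
  expect_true(file.exists(file.path(td, "ckpt", "member_01_log.csv")))
  back <- load_ensemble(file.path(td, "ckpt"))
  expect_equal(back$members[[1]]$weights, ens$members[[1]]$weights)
  expect_equal(back$config_hash, ens$config_hash)
  pr_a <- predict_slice(ens, pairs[[1]]$slice)
  pr_b <- predict_slice(back, pairs[[1]]$slice)
  expect_identical(pr_a$fused_prob, pr_b$fused_prob)
})

test_that("a trained ensemble segments a conspicuous phantom slice well", {
  fx <- tiny_trained_fixture()
  preds <- predict_slices(fx$ensemble, lapply(fx$holdout_pairs, `[[`, "slice"))
  ev <- evaluate_predictions(preds, lapply(fx$holdout_pairs, `[[`, "mask"))
  # the most conspicuous slice should be segmented nearly perfectly, and
  # the ensemble must be clearly better than chance overall
  expect_gt(max(ev$dice), 0.8)
  expect_gt(median(ev$dice), 0.3)
  # validation-selected weights recorded per member
  for (m in fx$ensemble$members) {
    expect_true(m$best_epoch %in% seq_len(fx$config$epochs))
    expect_true(all(is.finite(m$log$train_loss)))
  }
})
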