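# Ensemble training and fusion: M independently seeded members trained with
# SGD + momentum on a soft-Dice loss, fused at inference by averaging the
# member sigmoid outputs and rounding at 0.5.

#' Ensemble training configuration
#'
#' Defaults follow the training protocol the method was designed with:
#' 20 epochs, batches of 64 slices, learning rate 0.1, SGD with momentum
#' 0.9, ten members. Member diversity comes from (1) random weight
#' initialisation, (2) random shuffling of the training slices each epoch,
#' and (3) random augmentations applied at each iteration; each member's
#' RNG stream is derived deterministically from `(base_seed, member_index)`.
#'
#' @param n_members number of ensemble members M.
#' @param epochs training epochs per member.
#' @param batch_size slices per SGD step.
#' @param learning_rate SGD learning rate.
#' @param momentum SGD momentum.
#' @param backbone backbone architecture name; `"tiny_unet"` is the compact
#'   encoder-decoder shipped with the package.
#' @param channels backbone width (feature channels).
#' @param augmentations character subset of `c("hflip", "vflip", "rotate",
#'   "intensity")`; empty vector disables augmentation.
#' @param rotate_range maximal absolute rotation angle in degrees.
#' @param intensity_range multiplicative intensity jitter range, applied to
#'   the standardised slice.
#' @param smooth additive smoothing constant of the soft-Dice loss.
#' @param base_seed integer seed from which all member seeds are derived.
#' @return an object of class `ensemble_config`.
#' @export
ensemble_config <- function(n_members = 10L, epochs = 20L, batch_size = 64L,
                            learning_rate = 0.1, momentum = 0.9,
                            backbone = "tiny_unet", channels = 4L,
                            augmentations = c("hflip", "vflip", "rotate",
                                              "intensity"),
                            rotate_range = 15, intensity_range = c(0.9, 1.1),
                            smooth = 1, base_seed = 1L) {
  stopifnot(n_members >= 1, epochs >= 1, batch_size >= 1,
            learning_rate > 0, momentum >= 0, momentum < 1,
            channels >= 1, rotate_range >= 0,
            length(intensity_range) == 2,
            intensity_range[1] <= intensity_range[2], smooth >= 0)
  if (!all(augmentations %in% c("hflip", "vflip", "rotate", "intensity"))) {
    stop_ennseg("unknown augmentation name",
                class = "ennseg_value_error")
  }
  backbone_registry(backbone)  # validates the name
  structure(list(n_members = as.integer(n_members), epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, momentum = momentum,
                 backbone = backbone, channels = as.integer(channels),
                 augmentations = augmentations, rotate_range = rotate_range,
                 intensity_range = as.numeric(intensity_range),
                 smooth = smooth, base_seed = as.integer(base_seed)),
            class = "ensemble_config")
}

#' Soft-Dice loss
#'
#' Differentiable Dice-based loss on sigmoid probabilities:
#' `loss = 1 - (2 sum(p t) + smooth) / (sum(p^2) + sum(t^2) + smooth)`.
#' The squared-denominator form coincides with the cardinality form on
#' binary inputs, so with `smooth -> 0` the loss equals `1 - dice(p, t)`
#' for binary `p`.
#'
#' @param pred_prob predicted probabilities in \[0,1\], aligned with
#'   `target`.
#' @param target binary target mask (`mask_slice` or array).
#' @param smooth additive smoothing constant (default 1).
#' @return loss value in \[0, 1\].
#' @export
soft_dice_loss <- function(pred_prob, target, smooth = 1) {
  target <- as_mask_array(target)
  check_prob(pred_prob, "pred_prob")
  check_binary(target, "target")
  check_same_shape(pred_prob, target, "prediction and target")
  1 - (2 * sum(pred_prob * target) + smooth) /
    (sum(pred_prob^2) + sum(target^2) + smooth)
}

# Loss and dlogit gradient for a batch: mean per-slice soft Dice.
# p, t: (H, W, B); returns list(loss, dlogits).
batch_soft_dice <- function(p, t, smooth) {
  B <- dim(p)[3]
  loss <- 0
  dp <- array(0, dim(p))
  for (b in seq_len(B)) {
    pb <- p[, , b]; tb <- t[, , b]
    I <- sum(pb * tb); S <- sum(pb^2); Tt <- sum(tb^2)
    den <- S + Tt + smooth
    loss <- loss + 1 - (2 * I + smooth) / den
    dp[, , b] <- -(2 * tb * den - (2 * I + smooth) * 2 * pb) / den^2
  }
  list(loss = loss / B, dlogits = dp * p * (1 - p) / B)
}

#' Fuse member probability maps into an ensemble prediction
#'
#' Elementwise arithmetic mean of the member sigmoid outputs, rounded at
#' 0.5 into the binary mask. The tie `fused == 0.5` maps to foreground
#' (round half up).
#'
#' @param member_probs list of M probability maps of identical shape, values
#'   in \[0,1\].
#' @param slice_index,patient_id,phase optional slice identity carried into
#'   the prediction object.
#' @return an object of class `ensemble_prediction`: list with
#'   `member_probs`, `fused_prob`, `binary_mask` and the slice identity.
#' @export
fuse <- function(member_probs, slice_index = NA_integer_,
                 patient_id = NA_character_, phase = NA_character_) {
  if (!is.list(member_probs) || length(member_probs) < 1) {
    stop_ennseg("member_probs must be a nonempty list of probability maps",
                class = "ennseg_value_error")
  }
  for (m in member_probs) {
    check_prob(m, "member probability map")
    check_same_shape(m, member_probs[[1]], "member probability maps")
  }
  fused <- Reduce(`+`, member_probs) / length(member_probs)
  mask <- (fused >= 0.5) * 1
  structure(list(member_probs = member_probs, fused_prob = fused,
                 binary_mask = mask, slice_index = slice_index,
                 patient_id = patient_id, phase = phase),
            class = "ensemble_prediction")
}

#' @export
print.ensemble_prediction <- function(x, ...) {
  cat(sprintf("ensemble_prediction: %d member(s), %s voxels foreground, patient %s slice %s\n",
              length(x$member_probs), format(sum(x$binary_mask)),
              x$patient_id, format(x$slice_index)))
  invisible(x)
}

# Bilinear (image) / nearest (mask) rotation about the image centre,
# zero fill outside.
rotate_pair <- function(pixels, mask, angle_deg) {
  if (angle_deg == 0) return(list(pixels = pixels, mask = mask))
  n <- nrow(pixels); m <- ncol(pixels)
  a <- angle_deg * pi / 180
  cy <- (n + 1) / 2; cx <- (m + 1) / 2
  iy <- matrix(seq_len(n), n, m) - cy
  ix <- matrix(seq_len(m), n, m, byrow = TRUE) - cx
  sy <- cos(a) * iy - sin(a) * ix + cy
  sx <- sin(a) * iy + cos(a) * ix + cx
  y0 <- floor(sy); x0 <- floor(sx)
  fy <- sy - y0; fx <- sx - x0
  at <- function(img, yy, xx) {
    ok <- yy >= 1 & yy <= n & xx >= 1 & xx <= m
    v <- numeric(length(yy))
    v[ok] <- img[cbind(yy[ok], xx[ok])]
    v
  }
  y0v <- as.vector(y0); x0v <- as.vector(x0)
  fyv <- as.vector(fy); fxv <- as.vector(fx)
  img_out <- (1 - fyv) * (1 - fxv) * at(pixels, y0v, x0v) +
    fyv * (1 - fxv) * at(pixels, y0v + 1, x0v) +
    (1 - fyv) * fxv * at(pixels, y0v, x0v + 1) +
    fyv * fxv * at(pixels, y0v + 1, x0v + 1)
  yr <- round(sy); xr <- round(sx)
  mask_out <- at(mask, as.vector(yr), as.vector(xr))
  list(pixels = matrix(img_out, n, m), mask = matrix(round(mask_out), n, m))
}

#' Apply a fixed augmentation to an image/mask pair
#'
#' Geometric transforms (flips, rotation) are applied identically to image
#' and mask so the pair stays aligned; the multiplicative intensity factor
#' is applied to the image only. The mask stays binary (nearest-neighbour
#' resampling).
#'
#' @param pixels image matrix.
#' @param mask aligned binary mask matrix.
#' @param hflip,vflip logical: flip columns / rows.
#' @param angle rotation angle in degrees (bilinear for the image, nearest
#'   for the mask, zero fill).
#' @param intensity multiplicative intensity factor.
#' @return list with `pixels` and `mask`.
#' @export
apply_augmentation <- function(pixels, mask, hflip = FALSE, vflip = FALSE,
                               angle = 0, intensity = 1) {
  check_same_shape(pixels, mask, "image and mask")
  if (hflip) {
    pixels <- pixels[, rev(seq_len(ncol(pixels))), drop = FALSE]
    mask <- mask[, rev(seq_len(ncol(mask))), drop = FALSE]
  }
  if (vflip) {
    pixels <- pixels[rev(seq_len(nrow(pixels))), , drop = FALSE]
    mask <- mask[rev(seq_len(nrow(mask))), , drop = FALSE]
  }
  if (angle != 0) {
    r <- rotate_pair(pixels, mask, angle)
    pixels <- r$pixels; mask <- r$mask
  }
  list(pixels = pixels * intensity, mask = mask)
}

#' Randomly augment an image/mask pair
#'
#' Draws one augmentation from the configured suite using the current RNG
#' stream: horizontal/vertical flips with probability 0.5 each, rotation
#' uniform in `[-rotate_range, rotate_range]` degrees, and multiplicative
#' intensity jitter uniform in `intensity_range` (image only).
#'
#' @param pixels image matrix (standardised slice).
#' @param mask aligned binary mask.
#' @param config an [ensemble_config()]; `config$augmentations` selects the
#'   active transforms.
#' @return list with `pixels` and `mask`.
#' @export
augment <- function(pixels, mask, config) {
  aug <- config$augmentations
  apply_augmentation(
    pixels, mask,
    hflip = "hflip" %in% aug && stats::runif(1) < 0.5,
    vflip = "vflip" %in% aug && stats::runif(1) < 0.5,
    angle = if ("rotate" %in% aug)
      stats::runif(1, -config$rotate_range, config$rotate_range) else 0,
    intensity = if ("intensity" %in% aug)
      stats::runif(1, config$intensity_range[1], config$intensity_range[2])
    else 1)
}

# Normalise assorted slice/mask pair representations into plain matrices.
pair_matrices <- function(pair) {
  px <- if (inherits(pair$slice, "ct_slice")) pair$slice$pixels else pair$slice
  mk <- as_mask_array(pair$mask)
  list(pixels = px, mask = mk)
}

# Stack a list of (pixels, mask) into batch arrays (H, W, 1, B) / (H, W, B).
stack_batch <- function(pixels_list, mask_list) {
  H <- nrow(pixels_list[[1]]); W <- ncol(pixels_list[[1]])
  B <- length(pixels_list)
  # (H, W, B) and (H, W, 1, B) share the same column-major layout
  x <- array(unlist(pixels_list, use.names = FALSE), c(H, W, 1, B))
  t <- array(unlist(mask_list, use.names = FALSE), c(H, W, B))
  list(x = x, t = t)
}

#' Train one ensemble member
#'
#' Trains a single backbone with SGD (configured learning rate and
#' momentum) on the soft-Dice loss. The member's RNG seed is a
#' deterministic function of `(config$base_seed, member_index)`, so
#' training is reproducible and distinct members see distinct
#' initialisations, shuffle orders and augmentation draws. After each epoch
#' the validation soft-Dice loss is computed; the returned weights are
#' those of the epoch with the best validation loss.
#'
#' @param train_pairs list of `list(slice =, mask =)` pairs (as produced by
#'   [tumor_slices()]); slices are standardised internally (per-slice zero
#'   mean, unit variance).
#' @param val_pairs validation pairs (same structure); may be `NULL`, in
#'   which case the final epoch's weights are kept.
#' @param config an [ensemble_config()].
#' @param member_index 0-based member index in `[0, n_members)`.
#' @return an object of class `ennseg_member`: list with `weights`,
#'   `member_index`, `seed`, `best_epoch`, `log` (data.frame of per-epoch
#'   `train_loss`, `val_loss`), `config`.
#' @export
train_member <- function(train_pairs, val_pairs, config, member_index = 0L) {
  stopifnot(inherits(config, "ensemble_config"))
  if (length(train_pairs) == 0) {
    stop_ennseg("empty training set", class = "ennseg_value_error")
  }
  if (member_index < 0 || member_index >= config$n_members) {
    stop_ennseg("member_index must lie in [0, n_members)",
                class = "ennseg_value_error")
  }
  bk <- backbone_registry(config$backbone)
  tr <- lapply(train_pairs, pair_matrices)
  tr_px <- lapply(tr, function(p) standardize_slice(p$pixels))
  tr_mk <- lapply(tr, `[[`, "mask")
  va <- lapply(val_pairs %||% list(), pair_matrices)
  va_px <- lapply(va, function(p) standardize_slice(p$pixels))
  va_mk <- lapply(va, `[[`, "mask")
  seed <- derive_seed(config$base_seed, member_index)
  n_tr <- length(tr_px)
  local_seed(seed, {
    weights <- bk$init(config$channels)
    velocity <- lapply(weights, function(w) w * 0)
    best_val <- Inf
    best_weights <- weights
    best_epoch <- NA_integer_
    log <- data.frame(epoch = integer(), train_loss = numeric(),
                      val_loss = numeric())
    for (epoch in seq_len(config$epochs)) {
      perm <- sample.int(n_tr)
      ep_loss <- 0; n_batches <- 0
      for (start in seq(1, n_tr, by = config$batch_size)) {
        idx <- perm[start:min(start + config$batch_size - 1, n_tr)]
        pairs <- lapply(idx, function(k) {
          if (length(config$augmentations) > 0) {
            augment(tr_px[[k]], tr_mk[[k]], config)
          } else {
            list(pixels = tr_px[[k]], mask = tr_mk[[k]])
          }
        })
        bt <- stack_batch(lapply(pairs, `[[`, "pixels"),
                          lapply(pairs, `[[`, "mask"))
        fw <- bk$forward(weights, bt$x, keep_cache = TRUE)
        p <- sigmoid(fw$logits)
        ls <- batch_soft_dice(p, bt$t, config$smooth)
        if (!is.finite(ls$loss)) {
          stop_ennseg("training diverged (non-finite loss) at epoch ", epoch,
                      ", member ", member_index,
                      class = "ennseg_divergence_error")
        }
        grads <- bk$backward(weights, fw$cache, ls$dlogits)
        for (nm in names(weights)) {
          velocity[[nm]] <- config$momentum * velocity[[nm]] -
            config$learning_rate * grads[[nm]]
          weights[[nm]] <- weights[[nm]] + velocity[[nm]]
        }
        ep_loss <- ep_loss + ls$loss
        n_batches <- n_batches + 1
      }
      val_loss <- if (length(va_px) > 0) {
        member_loss(bk, weights, va_px, va_mk, config)
      } else {
        NA_real_
      }
      log <- rbind(log, data.frame(epoch = epoch,
                                   train_loss = ep_loss / n_batches,
                                   val_loss = val_loss))
      if (!is.na(val_loss) && val_loss < best_val) {
        best_val <- val_loss
        best_weights <- weights
        best_epoch <- epoch
      }
    }
    if (is.na(best_epoch)) {
      best_weights <- weights
      best_epoch <- config$epochs
    }
    structure(list(weights = best_weights, member_index = as.integer(member_index),
                   seed = seed, best_epoch = best_epoch, log = log,
                   config = config),
              class = "ennseg_member")
  })
}

# Mean soft-Dice loss of fixed weights over a slice set, in batches.
member_loss <- function(bk, weights, px, mk, config) {
  total <- 0; nb <- 0
  for (start in seq(1, length(px), by = config$batch_size)) {
    idx <- start:min(start + config$batch_size - 1, length(px))
    bt <- stack_batch(px[idx], mk[idx])
    fw <- bk$forward(weights, bt$x, keep_cache = FALSE)
    p <- sigmoid(fw$logits)
    total <- total + batch_soft_dice(p, bt$t, config$smooth)$loss * length(idx)
    nb <- nb + length(idx)
  }
  total / nb
}

#' Train a full ensemble
#'
#' Trains `config$n_members` members independently (see [train_member()])
#' and bundles them with the configuration and normalisation rule.
#'
#' @inheritParams train_member
#' @param verbose print per-member progress.
#' @return an object of class `ennseg_ensemble`: list with `members`,
#'   `config`, `normalization`, `config_hash`.
#' @export
train_ensemble <- function(train_pairs, val_pairs, config, verbose = FALSE) {
  members <- lapply(seq_len(config$n_members) - 1L, function(mi) {
    if (verbose) message("training member ", mi + 1, "/", config$n_members)
    train_member(train_pairs, val_pairs, config, mi)
  })
  structure(list(members = members, config = config,
                 normalization = "per-slice z-score",
                 config_hash = hash_of(unclass(config))),
            class = "ennseg_ensemble")
}

#' @export
print.ennseg_ensemble <- function(x, ...) {
  cat(sprintf("ennseg_ensemble: %d member(s), backbone %s (%d channels), base seed %d\n",
              length(x$members), x$config$backbone, x$config$channels,
              x$config$base_seed))
  invisible(x)
}

#' Predict a batch of slices with a trained ensemble
#'
#' Runs every member on the identically standardised inputs, applies the
#' sigmoid, and fuses the member probabilities ([fuse()]).
#'
#' @param ensemble an [train_ensemble()] result.
#' @param slices list of [ct_slice()] objects or image matrices.
#' @return list of [fuse()] `ensemble_prediction` objects, one per slice.
#' @export
predict_slices <- function(ensemble, slices) {
  stopifnot(inherits(ensemble, "ennseg_ensemble"))
  bk <- backbone_registry(ensemble$config$backbone)
  px <- lapply(slices, function(s) {
    standardize_slice(if (inherits(s, "ct_slice")) s$pixels else s)
  })
  H <- nrow(px[[1]]); W <- ncol(px[[1]])
  member_probs <- vector("list", length(ensemble$members))
  bs <- ensemble$config$batch_size
  for (m in seq_along(ensemble$members)) {
    probs <- vector("list", length(px))
    for (start in seq(1, length(px), by = bs)) {
      idx <- start:min(start + bs - 1, length(px))
      bt <- stack_batch(px[idx], px[idx])  # mask unused at inference
      fw <- bk$forward(ensemble$members[[m]]$weights, bt$x)
      p <- sigmoid(fw$logits)
      for (k in seq_along(idx)) probs[[idx[k]]] <- p[, , k]
    }
    member_probs[[m]] <- probs
  }
  lapply(seq_along(slices), function(k) {
    s <- slices[[k]]
    fuse(lapply(member_probs, `[[`, k),
         slice_index = if (inherits(s, "ct_slice")) s$slice_index else NA_integer_,
         patient_id = if (inherits(s, "ct_slice")) s$patient_id else NA_character_,
         phase = if (inherits(s, "ct_slice")) s$phase else NA_character_)
  })
}

#' @rdname predict_slices
#' @param slice a single [ct_slice()] or image matrix.
#' @export
predict_slice <- function(ensemble, slice) {
  predict_slices(ensemble, list(slice))[[1]]
}

#' Save or load a trained ensemble
#'
#' One file per member plus a JSON manifest recording M, member seeds,
#' configuration (and its hash) and the input normalisation rule; training
#' logs as CSV.
#'
#' @param ensemble an `ennseg_ensemble`.
#' @param dir checkpoint directory.
#' @return `save_ensemble` returns `dir` invisibly; `load_ensemble` returns
#'   the ensemble.
#' @export
save_ensemble <- function(ensemble, dir) {
  stopifnot(inherits(ensemble, "ennseg_ensemble"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(n_members = length(ensemble$members),
                   member_seeds = vapply(ensemble$members, `[[`, integer(1), "seed"),
                   best_epochs = vapply(ensemble$members, `[[`, integer(1), "best_epoch"),
                   config = unclass(ensemble$config),
                   config_hash = ensemble$config_hash,
                   normalization = ensemble$normalization)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (m in seq_along(ensemble$members)) {
    saveRDS(ensemble$members[[m]],
            file.path(dir, sprintf("member_%02d.rds", m - 1)))
    utils::write.csv(ensemble$members[[m]]$log,
                     file.path(dir, sprintf("member_%02d_log.csv", m - 1)),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname save_ensemble
#' @export
load_ensemble <- function(dir) {
  mf_path <- file.path(dir, "manifest.json")
  if (!file.exists(mf_path)) {
    stop_ennseg("no manifest.json in ", dir, "; run the train step first",
                class = "ennseg_io_error")
  }
  mf <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  cfg <- do.call(ensemble_config, mf$config[names(formals(ensemble_config))])
  members <- lapply(seq_len(mf$n_members), function(m) {
    readRDS(file.path(dir, sprintf("member_%02d.rds", m - 1)))
  })
  structure(list(members = members, config = cfg,
                 normalization = mf$normalization,
                 config_hash = mf$config_hash),
            class = "ennseg_ensemble")
}
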