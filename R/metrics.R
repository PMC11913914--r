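# Evaluation primitives: Dice overlap, binary entropy, foreground entropy,
# success dichotomisation, empirical ROC/AUC, Youden cutoff, confusion
# statistics, and per-slice / per-patient evaluation tables.

#' Dice similarity coefficient between two binary masks
#'
#' Computes `D = 2|P ∩ R| / (|P| + |R|)` between a predicted and a reference
#' mask of identical shape (2D slices or 3D stacks). Conventions for the
#' degenerate cases: if both masks are empty the score is 1 (nothing to
#' segment, nothing segmented); if exactly one is empty the score is 0.
#'
#' @param pred,ref binary arrays (values in \{0,1\}) of identical shape.
#'   `mask_slice` objects are accepted and unwrapped.
#' @return a number in \[0, 1\]; 1 means perfect agreement.
#' @examples
#' a <- matrix(0, 4, 4); a[1:2, 1:2] <- 1
#' b <- matrix(0, 4, 4); b[1:2, 1:2] <- 1
#' dice(a, b) # 1
#' @export
dice <- function(pred, ref) {
  pred <- as_mask_array(pred)
  ref <- as_mask_array(ref)
  check_same_shape(pred, ref, "masks")
  check_binary(pred, "pred")
  check_binary(ref, "ref")
  sp <- sum(pred)
  sr <- sum(ref)
  if (sp + sr == 0) return(1)
  2 * sum(pred * ref) / (sp + sr)
}

as_mask_array <- function(x) {
  if (inherits(x, "mask_slice")) x$mask else x
}

#' Binary Shannon entropy in bits
#'
#' `H(p) = -p log2(p) - (1-p) log2(1-p)` with the usual convention
#' `0 log 0 = 0`, so `H(0) = H(1) = 0` and `H(0.5) = 1`. Vectorised.
#'
#' @param p probabilities in \[0, 1\].
#' @return entropies in \[0, 1\] bits, same shape as `p`.
#' @export
binary_entropy <- function(p) {
  check_prob(p, "p")
  h <- ifelse(p <= 0 | p >= 1, 0,
              -p * log2(p) - (1 - p) * log2(1 - p))
  dim(h) <- dim(p)
  h
}

#' Average foreground entropy of an ensemble prediction
#'
#' The confidence score: the mean per-voxel binary entropy (in bits) of the
#' fused probability map, taken over the voxels of the *predicted* foreground
#' (the binary mask obtained by rounding). Low values mean the ensemble
#' members agreed confidently inside their own segmentation; high values mean
#' disagreement and hence likely inadequate segmentation. No reference mask
#' is involved.
#'
#' If the predicted foreground is empty the score is defined as 1 (maximal
#' uncertainty) and the result carries `attr(, "empty_foreground") = TRUE`,
#' so empty predictions sort together with low-confidence ones.
#'
#' @param x an [ensemble_prediction()] object, or a probability map
#'   (matrix in \[0,1\]).
#' @param mask optional binary foreground mask; defaults to `x >= 0.5`
#'   when `x` is a plain probability map.
#' @param source for ensemble predictions, which probability to use:
#'   `"fused"` (default) uses the fused pre-rounding probability;
#'   `"votes"` uses the fraction of members voting foreground (each member
#'   map rounded at 0.5 first), a documented alternative construction.
#' @return a number in \[0, 1\] (bits), with attribute `empty_foreground`.
#' @export
foreground_entropy <- function(x, mask = NULL, source = c("fused", "votes")) {
  source <- match.arg(source)
  if (inherits(x, "ensemble_prediction")) {
    mask <- x$binary_mask
    prob <- if (source == "fused") {
      x$fused_prob
    } else {
      Reduce(`+`, lapply(x$member_probs, function(p) (p >= 0.5) * 1)) /
        length(x$member_probs)
    }
  } else {
    prob <- x
    check_prob(prob, "x")
    if (is.null(mask)) mask <- (prob >= 0.5) * 1
  }
  check_same_shape(prob, mask, "probability map and mask")
  fg <- mask > 0
  if (!any(fg)) {
    return(structure(1, empty_foreground = TRUE))
  }
  structure(mean(binary_entropy(prob[fg])), empty_foreground = FALSE)
}

#' Empirical ROC curve and AUC
#'
#' Builds the empirical receiver-operating-characteristic of a score against
#' binary labels over all distinct score cutoffs. `polarity` states which
#' direction of the score predicts the positive class: `"high"` classifies
#' positive when `score >= cutoff`; `"low"` (the foreground-entropy case,
#' where low entropy predicts success) classifies positive when
#' `score < cutoff`. AUC is computed as the Mann-Whitney concordance
#' probability with ties counted 1/2, which equals the trapezoidal area
#' under the empirical curve.
#'
#' @param scores numeric scores.
#' @param labels binary labels (1 = positive class), same length.
#' @param polarity `"high"` or `"low"`: which end of the score scale
#'   indicates the positive class.
#' @return an object of class `roc_result`: a list with `points`
#'   (data.frame of `threshold`, `sensitivity`, `specificity`), `auc`,
#'   `polarity`, `n_pos`, `n_neg`.
#' @export
roc <- function(scores, labels, polarity = c("high", "low")) {
  polarity <- match.arg(polarity)
  if (length(scores) != length(labels)) {
    stop_ennseg("scores and labels must have equal length",
                class = "ennseg_shape_error")
  }
  check_binary(labels, "labels")
  if (anyNA(scores) || any(!is.finite(scores))) {
    stop_ennseg("scores must be finite", class = "ennseg_value_error")
  }
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop_ennseg("labels contain a single class; ROC needs at least one ",
                "positive and one negative", class = "ennseg_value_error")
  }
  thr <- sort(unique(scores))
  if (polarity == "high") {
    # positive call: score >= threshold; +Inf gives the all-negative corner
    thr <- c(thr, Inf)
    sens <- vapply(thr, function(t) sum(scores >= t & labels == 1) / n_pos,
                   numeric(1))
    spec <- vapply(thr, function(t) sum(scores < t & labels == 0) / n_neg,
                   numeric(1))
    oriented <- scores
  } else {
    # positive call: score < threshold (strict); +Inf gives the all-positive
    # corner, the minimum score the all-negative one
    thr <- c(thr, Inf)
    sens <- vapply(thr, function(t) sum(scores < t & labels == 1) / n_pos,
                   numeric(1))
    spec <- vapply(thr, function(t) sum(scores >= t & labels == 0) / n_neg,
                   numeric(1))
    oriented <- -scores
  }
  r <- rank(oriented)
  auc <- (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  structure(list(points = data.frame(threshold = thr, sensitivity = sens,
                                     specificity = spec),
                 auc = auc, polarity = polarity,
                 n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("Empirical ROC: AUC = %.4f (%d positive / %d negative, %s-score-positive)\n",
              x$auc, x$n_pos, x$n_neg, x$polarity))
  invisible(x)
}

#' Youden-index optimal cutoff of an ROC curve
#'
#' Selects the empirical cutoff maximising `J = sensitivity + specificity - 1`.
#' Ties are broken toward the cutoff with the higher sensitivity, then toward
#' the lower threshold value.
#'
#' @param x a `roc_result` from [roc()].
#' @return the cutoff value, with attributes `j`, `sensitivity`,
#'   `specificity` at the cutoff.
#' @export
youden_cutoff <- function(x) {
  stopifnot(inherits(x, "roc_result"))
  p <- x$points
  j <- p$sensitivity + p$specificity - 1
  ord <- order(-j, -p$sensitivity, p$threshold)
  best <- ord[1]
  structure(p$threshold[best],
            j = j[best],
            sensitivity = p$sensitivity[best],
            specificity = p$specificity[best])
}

#' Sensitivity, specificity and accuracy of binary predictions
#'
#' @param predicted,truth binary vectors of equal length; `truth` must
#'   contain both classes.
#' @return list with `sensitivity`, `specificity`, `accuracy`.
#' @export
confusion_stats <- function(predicted, truth) {
  if (length(predicted) != length(truth)) {
    stop_ennseg("predicted and truth must have equal length",
                class = "ennseg_shape_error")
  }
  check_binary(predicted, "predicted")
  check_binary(truth, "truth")
  tp <- sum(predicted == 1 & truth == 1)
  tn <- sum(predicted == 0 & truth == 0)
  fp <- sum(predicted == 1 & truth == 0)
  fn <- sum(predicted == 0 & truth == 1)
  list(sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       accuracy = (tp + tn) / length(truth))
}

#' Pooled-voxel Dice over all slices of one patient
#'
#' Volumetric aggregation: predicted and reference slices are pooled into
#' voxel stacks and a single Dice score is computed on the stacks,
#' `2 sum|P ∩ R| / (sum|P| + sum|R|)`. This weights slices by their tumor
#' area and generally differs from the mean of per-slice Dice scores when
#' slice areas differ.
#'
#' @param pred_slices,ref_slices lists of aligned binary masks (matrices or
#'   `mask_slice` objects) for one patient, in matching order.
#' @return pooled Dice score in \[0, 1\].
#' @export
patient_dice <- function(pred_slices, ref_slices) {
  if (length(pred_slices) != length(ref_slices) || length(pred_slices) == 0) {
    stop_ennseg("need equal, nonzero numbers of predicted and reference slices",
                class = "ennseg_shape_error")
  }
  inter <- 0; sp <- 0; sr <- 0
  for (k in seq_along(pred_slices)) {
    p <- as_mask_array(pred_slices[[k]])
    r <- as_mask_array(ref_slices[[k]])
    check_same_shape(p, r, "masks")
    check_binary(p, "pred")
    check_binary(r, "ref")
    inter <- inter + sum(p * r)
    sp <- sp + sum(p)
    sr <- sr + sum(r)
  }
  if (sp + sr == 0) return(1)
  2 * inter / (sp + sr)
}

#' Per-slice evaluation table
#'
#' Scores a list of ensemble predictions against reference masks, producing
#' one row per slice with the Dice score, the average foreground entropy of
#' the fused probability, and the binary success label (`dice > threshold`,
#' strictly greater).
#'
#' @param predictions list of [ensemble_prediction()] objects.
#' @param references list of aligned reference masks (`mask_slice` or binary
#'   matrices), in matching order.
#' @param dice_success_threshold success dichotomisation threshold
#'   (default 0.8).
#' @param entropy_source passed to [foreground_entropy()].
#' @return data.frame with columns `patient_id`, `slice_index`, `phase`,
#'   `dice`, `fg_entropy`, `success`.
#' @export
evaluate_predictions <- function(predictions, references,
                                 dice_success_threshold = 0.8,
                                 entropy_source = "fused") {
  if (length(predictions) != length(references)) {
    stop_ennseg("predictions and references must have equal length",
                class = "ennseg_shape_error")
  }
  rows <- lapply(seq_along(predictions), function(k) {
    pr <- predictions[[k]]
    stopifnot(inherits(pr, "ensemble_prediction"))
    d <- dice(pr$binary_mask, references[[k]])
    e <- foreground_entropy(pr, source = entropy_source)
    data.frame(patient_id = pr$patient_id %||% NA_character_,
               slice_index = pr$slice_index %||% NA_integer_,
               phase = pr$phase %||% NA_character_,
               dice = d,
               fg_entropy = as.numeric(e),
               success = as.integer(d > dice_success_threshold),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-patient evaluation table
#'
#' Aggregates slice-level predictions to one row per (patient, phase):
#' pooled-voxel Dice over the patient's slices ([patient_dice()]) and the
#' mean slice-level foreground entropy.
#'
#' @inheritParams evaluate_predictions
#' @return data.frame with columns `patient_id`, `phase`, `dice`,
#'   `fg_entropy`, `n_slices`, `success`.
#' @export
evaluate_patients <- function(predictions, references,
                              dice_success_threshold = 0.8,
                              entropy_source = "fused") {
  slices <- evaluate_predictions(predictions, references,
                                 dice_success_threshold, entropy_source)
  key <- paste(slices$patient_id, slices$phase, sep = "\r")
  rows <- lapply(split(seq_len(nrow(slices)), key), function(idx) {
    d <- patient_dice(lapply(predictions[idx], `[[`, "binary_mask"),
                      references[idx])
    data.frame(patient_id = slices$patient_id[idx[1]],
               phase = slices$phase[idx[1]],
               dice = d,
               fg_entropy = mean(slices$fg_entropy[idx]),
               n_slices = length(idx),
               success = as.integer(d > dice_success_threshold),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Median and interquartile range summary
#'
#' Summary statistic used in evaluation reports: median and 25th/75th
#' percentiles (linear interpolation, `stats::quantile` type 7).
#'
#' @param x numeric vector.
#' @return list with `median`, `iqr_low`, `iqr_high`, `n`.
#' @export
median_iqr <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  list(median = q[2], iqr_low = q[1], iqr_high = q[3], n = length(x))
}
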