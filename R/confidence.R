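# Entropy -> success confidence classifier: calibrated once on a hold-out
# evaluation set (ROC + Youden cutoff), then applied to new predictions
# without any reference mask.

#' Calibrate the entropy-based confidence classifier
#'
#' Builds the ROC of average foreground entropy against segmentation
#' success (`dice > dice_success_threshold`, low entropy predicting
#' success) and selects the operating cutoff by the Youden index. The
#' cutoff is always derived from the supplied evaluations — it is a
#' property of a particular model and dataset, never a constant.
#'
#' @param evaluations data.frame with columns `dice` and `fg_entropy`
#'   (from [evaluate_predictions()] or [evaluate_patients()]).
#' @param dice_success_threshold Dice level strictly above which a
#'   segmentation counts as successful (default 0.8).
#' @param granularity `"slice"` or `"patient"`, recorded in provenance.
#' @param dataset_id free-text provenance tag.
#' @return an object of class `ennseg_calibration`: list with
#'   `entropy_cutoff`, `dice_success_threshold`, `roc` (a
#'   [roc()] result), `granularity`, `provenance`.
#' @export
calibrate <- function(evaluations, dice_success_threshold = 0.8,
                      granularity = c("slice", "patient"),
                      dataset_id = NA_character_) {
  granularity <- match.arg(granularity)
  stopifnot(is.data.frame(evaluations),
            all(c("dice", "fg_entropy") %in% names(evaluations)))
  success <- as.integer(evaluations$dice > dice_success_threshold)
  if (length(unique(success)) < 2) {
    stop_ennseg("calibration needs both successful (dice > ",
                dice_success_threshold, ") and inadequate evaluations; ",
                "got ", sum(success), " successes out of ", length(success),
                ". Provide a more diverse evaluation set.",
                class = "ennseg_value_error")
  }
  r <- roc(evaluations$fg_entropy, success, polarity = "low")
  cutoff <- youden_cutoff(r)
  structure(list(entropy_cutoff = as.numeric(cutoff),
                 dice_success_threshold = dice_success_threshold,
                 roc = r,
                 granularity = granularity,
                 provenance = list(dataset_id = dataset_id,
                                   n_success = r$n_pos,
                                   n_inadequate = r$n_neg)),
            class = "ennseg_calibration")
}

#' @export
print.ennseg_calibration <- function(x, ...) {
  cat(sprintf(paste0("ennseg_calibration (%s level): entropy cutoff %.4f, ",
                     "AUC %.3f (%d success / %d inadequate)\n"),
              x$granularity, x$entropy_cutoff, x$roc$auc,
              x$provenance$n_success, x$provenance$n_inadequate))
  invisible(x)
}

#' Assess the confidence of a prediction
#'
#' Computes the average foreground entropy of a prediction and compares it
#' to the calibrated cutoff. Success is predicted when entropy is strictly
#' below the cutoff; the tie `entropy == cutoff` is classified inadequate,
#' so borderline cases are flagged for review. No reference mask is read.
#'
#' @param pred an [ensemble_prediction][fuse()], or a bare foreground
#'   entropy value in \[0,1\].
#' @param cal an [calibrate()] result.
#' @return an object of class `confidence_report`: list with `fg_entropy`,
#'   `predicted_success` (logical), `entropy_cutoff`, `granularity`.
#' @export
assess <- function(pred, cal) {
  if (!inherits(cal, "ennseg_calibration")) {
    stop_ennseg("cal must be an ennseg_calibration (run calibrate() first)",
                class = "ennseg_value_error")
  }
  e <- if (inherits(pred, "ensemble_prediction")) {
    as.numeric(foreground_entropy(pred))
  } else {
    check_prob(pred, "entropy")
    as.numeric(pred)
  }
  structure(list(fg_entropy = e,
                 predicted_success = e < cal$entropy_cutoff,
                 entropy_cutoff = cal$entropy_cutoff,
                 granularity = cal$granularity),
            class = "confidence_report")
}

#' @export
print.confidence_report <- function(x, ...) {
  cat(sprintf("confidence_report: FG entropy %.4f %s cutoff %.4f -> %s\n",
              x$fg_entropy, if (x$predicted_success) "<" else ">=",
              x$entropy_cutoff,
              if (x$predicted_success) "predicted success"
              else "predicted inadequate (review)"))
  invisible(x)
}

#' Evaluate a fixed calibration on fresh data
#'
#' Applies the calibrated cutoff to evaluations that carry true Dice
#' scores (the external-test pattern: fixed cutoff, new data) and reports
#' accuracy, sensitivity and specificity of the success prediction.
#'
#' @param cal an [calibrate()] result (fixed before seeing these data).
#' @param evaluations data.frame with `dice` and `fg_entropy` columns.
#' @return list with `accuracy`, `sensitivity`, `specificity`, `n`.
#' @export
evaluate_calibration <- function(cal, evaluations) {
  stopifnot(inherits(cal, "ennseg_calibration"),
            is.data.frame(evaluations),
            all(c("dice", "fg_entropy") %in% names(evaluations)))
  truth <- as.integer(evaluations$dice > cal$dice_success_threshold)
  predicted <- as.integer(evaluations$fg_entropy < cal$entropy_cutoff)
  cs <- confusion_stats(predicted, truth)
  c(cs[c("accuracy", "sensitivity", "specificity")],
    list(n = nrow(evaluations)))
}

#' Save or load a calibration as JSON
#'
#' Persists the cutoff, the ROC points and provenance.
#'
#' @param cal an `ennseg_calibration`.
#' @param path JSON file path.
#' @return `write_calibration` returns `path` invisibly; `read_calibration`
#'   returns the calibration.
#' @export
write_calibration <- function(cal, path) {
  stopifnot(inherits(cal, "ennseg_calibration"))
  pts <- cal$roc$points
  pts$threshold[!is.finite(pts$threshold)] <- NA  # Inf has no JSON literal
  out <- list(entropy_cutoff = cal$entropy_cutoff,
              dice_success_threshold = cal$dice_success_threshold,
              granularity = cal$granularity,
              auc = cal$roc$auc,
              polarity = cal$roc$polarity,
              n_pos = cal$roc$n_pos, n_neg = cal$roc$n_neg,
              roc_points = pts,
              provenance = cal$provenance)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  r <- structure(list(points = as.data.frame(x$roc_points),
                      auc = x$auc, polarity = x$polarity,
                      n_pos = x$n_pos, n_neg = x$n_neg),
                 class = "roc_result")
  # JSON null -> Inf round-trip for the open upper threshold
  r$points$threshold[is.na(r$points$threshold)] <- Inf
  structure(list(entropy_cutoff = x$entropy_cutoff,
                 dice_success_threshold = x$dice_success_threshold,
                 roc = r, granularity = x$granularity,
                 provenance = as.list(x$provenance)),
            class = "ennseg_calibration")
}
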