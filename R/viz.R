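# Overlay rendering: red-to-green voxelwise probability shading,
# iso-probability contour lines, and the purple reference contour, drawn
# over the windowed grayscale CT slice. Rendering is pure: identical inputs
# give byte-identical PNG output (no timestamps, no external state).

#' Overlay rendering style
#'
#' @param alpha blending weight of the probability shading over the
#'   grayscale base, in \[0,1\].
#' @param floor probability below which no shading is drawn. The colormap
#'   nominally colors every voxel (red = 0% tumor probability), but literal
#'   red over the whole background would obliterate the CT; set `floor = 0`
#'   for the literal rendering.
#' @param contour_thresholds strictly increasing probability levels at
#'   which contour lines are drawn; each line uses its level's colormap
#'   color.
#' @param reference_color RGB triple in \[0,1\] for the reference-standard
#'   contour (default purple).
#' @param window optional CT display window `c(width, level)` for the
#'   grayscale base; `NULL` uses min-max scaling (the phantom default).
#' @return an object of class `overlay_style`.
#' @export
overlay_style <- function(alpha = 0.4, floor = 0.05,
                          contour_thresholds = c(0.1, 0.25, 0.5, 0.75, 0.9),
                          reference_color = c(0.6, 0, 0.6),
                          window = NULL) {
  stopifnot(alpha >= 0, alpha <= 1, floor >= 0, floor < 1,
            length(contour_thresholds) >= 1,
            all(diff(contour_thresholds) > 0),
            all(contour_thresholds > 0 & contour_thresholds < 1),
            length(reference_color) == 3)
  if (floor >= min(contour_thresholds)) {
    stop_ennseg("shading floor must lie below the lowest contour threshold",
                class = "ennseg_value_error")
  }
  structure(list(alpha = alpha, floor = floor,
                 contour_thresholds = contour_thresholds,
                 reference_color = as.numeric(reference_color),
                 window = window),
            class = "overlay_style")
}

#' Probability colormap: red through yellow to green
#'
#' Linear hue sweep with red at probability 0 and green at probability 1
#' (through yellow at 0.5), keeping mid probabilities visually distinct.
#' The green channel is non-decreasing and the red channel non-increasing
#' in p.
#'
#' @param p probabilities in \[0,1\].
#' @return matrix with columns `r`, `g`, `b` in \[0,1\].
#' @export
prob_colormap <- function(p) {
  check_prob(p, "p")
  r <- pmin(1, 2 * (1 - p))
  g <- pmin(1, 2 * p)
  cbind(r = r, g = g, b = rep(0, length(p)))
}

windowed_gray <- function(pixels, window = NULL) {
  if (is.null(window)) {
    lo <- min(pixels); hi <- max(pixels)
    if (hi <= lo) hi <- lo + 1
  } else {
    lo <- window[2] - window[1] / 2
    hi <- window[2] + window[1] / 2
  }
  pmin(pmax((pixels - lo) / (hi - lo), 0), 1)
}

new_panel <- function(img, legend) {
  structure(list(image = img, legend = legend), class = "rendered_panel")
}

#' @export
print.rendered_panel <- function(x, ...) {
  cat(sprintf("rendered_panel: %dx%d RGB\n", dim(x$image)[1], dim(x$image)[2]))
  invisible(x)
}

base_panel <- function(slice, style) {
  px <- if (inherits(slice, "ct_slice")) slice$pixels else slice
  g <- windowed_gray(px, style$window)
  img <- array(0, c(nrow(g), ncol(g), 3))
  img[, , 1] <- g; img[, , 2] <- g; img[, , 3] <- g
  new_panel(img, list(kind = "plain", window = style$window))
}

#' Voxelwise probability shading over a CT slice
#'
#' Alpha-blends the red-to-green colormap color of each voxel's fused
#' tumor probability onto the windowed grayscale CT. Voxels with
#' probability below `style$floor` are left untouched.
#'
#' @param slice a [ct_slice()] or image matrix.
#' @param prob probability map aligned with the slice.
#' @param style an [overlay_style()].
#' @return a `rendered_panel` (RGB array in \[0,1\] plus legend metadata).
#' @export
probability_overlay <- function(slice, prob, style = overlay_style()) {
  panel <- base_panel(slice, style)
  check_prob(prob, "prob")
  check_same_shape(panel$image[, , 1], prob, "slice and probability map")
  sel <- prob >= style$floor
  if (any(sel)) {
    cols <- prob_colormap(prob[sel])
    for (ch in 1:3) {
      plane <- panel$image[, , ch]
      plane[sel] <- (1 - style$alpha) * plane[sel] + style$alpha * cols[, ch]
      panel$image[, , ch] <- plane
    }
  }
  panel$legend <- list(kind = "probability", alpha = style$alpha,
                       floor = style$floor)
  panel
}

# 1-pixel-wide boundary of {prob >= level}: set pixels with at least one
# 4-neighbour outside the set.
level_boundary <- function(prob, level) {
  inside <- prob >= level
  n <- nrow(inside); m <- ncol(inside)
  shift_out <- function(dy, dx) {
    out <- matrix(FALSE, n, m)
    ys <- seq_len(n) + dy; xs <- seq_len(m) + dx
    ok_y <- ys >= 1 & ys <= n; ok_x <- xs >= 1 & xs <= m
    out[ok_y, ok_x] <- !inside[ys[ok_y], xs[ok_x]]
    out
  }
  inside & (shift_out(1, 0) | shift_out(-1, 0) |
              shift_out(0, 1) | shift_out(0, -1))
}

paint <- function(img, sel, color) {
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[sel] <- color[ch]
    img[, , ch] <- plane
  }
  img
}

#' Iso-probability contour lines
#'
#' Draws the level set boundary of the probability map at each configured
#' threshold, each in its level's colormap color, one pixel wide. Levels
#' with an empty level set draw nothing.
#'
#' @param panel a `rendered_panel` (e.g. from [probability_overlay()]).
#' @param prob probability map aligned with the panel.
#' @param style an [overlay_style()].
#' @return the panel with contours drawn.
#' @export
contour_overlay <- function(panel, prob, style = overlay_style()) {
  stopifnot(inherits(panel, "rendered_panel"))
  check_prob(prob, "prob")
  check_same_shape(panel$image[, , 1], prob, "panel and probability map")
  for (th in style$contour_thresholds) {
    sel <- level_boundary(prob, th)
    if (any(sel)) {
      panel$image <- paint(panel$image, sel, prob_colormap(th)[1, ])
    }
  }
  panel$legend <- c(panel$legend,
                    list(contour_thresholds = style$contour_thresholds))
  panel
}

#' Reference-standard contour
#'
#' Draws the boundary of the reference mask in purple over the panel. An
#' empty reference leaves the panel unchanged.
#'
#' @param panel a `rendered_panel`.
#' @param ref reference mask (`mask_slice` or binary matrix).
#' @param style an [overlay_style()].
#' @return the panel with the reference contour drawn.
#' @export
reference_overlay <- function(panel, ref, style = overlay_style()) {
  stopifnot(inherits(panel, "rendered_panel"))
  m <- as_mask_array(ref)
  check_binary(m, "ref")
  check_same_shape(panel$image[, , 1], m, "panel and reference mask")
  sel <- level_boundary(m, 0.5)
  if (any(sel)) {
    panel$image <- paint(panel$image, sel, style$reference_color)
  }
  panel$legend <- c(panel$legend, list(reference = TRUE))
  panel
}

#' Render the full panel set for one case
#'
#' Produces the plain CT panel, the probability-shaded panel and the
#' contour panel (the latter two with the reference contour when a
#' reference mask is given), plus a JSON-able sidecar with the Dice score
#' (if a reference is given), the average foreground entropy, and the
#' predicted success flag (if a calibration is given). When `out_dir` is
#' set, panels are written as PNG and the sidecar as JSON; outputs are
#' byte-stable across reruns.
#'
#' @param slice a [ct_slice()] or image matrix.
#' @param pred an [ensemble_prediction][fuse()] for the slice.
#' @param ref optional reference mask.
#' @param cal optional [calibrate()] result.
#' @param style an [overlay_style()].
#' @param out_dir optional output directory.
#' @param basename file stem for outputs (default from slice identity).
#' @return list with `panels` (named `rendered_panel`s) and `sidecar`;
#'   invisibly when writing to disk.
#' @export
render_case <- function(slice, pred, ref = NULL, cal = NULL,
                        style = overlay_style(), out_dir = NULL,
                        basename = NULL) {
  stopifnot(inherits(pred, "ensemble_prediction"))
  panels <- list(
    plain = base_panel(slice, style),
    probability = probability_overlay(slice, pred$fused_prob, style),
    contour = contour_overlay(base_panel(slice, style), pred$fused_prob, style))
  sidecar <- list(fg_entropy = as.numeric(foreground_entropy(pred)))
  if (!is.null(ref)) {
    panels$probability <- reference_overlay(panels$probability, ref, style)
    panels$contour <- reference_overlay(panels$contour, ref, style)
    sidecar$dice <- dice(pred$binary_mask, ref)
  }
  if (!is.null(cal)) {
    rep <- assess(pred, cal)
    sidecar$predicted_success <- rep$predicted_success
    sidecar$entropy_cutoff <- rep$entropy_cutoff
  }
  sidecar$slice_index <- pred$slice_index
  sidecar$patient_id <- pred$patient_id
  out <- list(panels = panels, sidecar = sidecar)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (is.null(basename)) {
      basename <- sprintf("%s_slice%03d",
                          if (is.na(sidecar$patient_id)) "case" else sidecar$patient_id,
                          if (is.na(sidecar$slice_index)) 0L else sidecar$slice_index)
    }
    for (nm in names(panels)) {
      png::writePNG(panels[[nm]]$image,
                    file.path(out_dir, paste0(basename, "_", nm, ".png")))
    }
    jsonlite::write_json(sidecar,
                         file.path(out_dir, paste0(basename, ".json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
    return(invisible(out))
  }
  out
}
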