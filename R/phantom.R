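# Synthetic phantom cohorts: pseudo-CT axial slices with tumor-like
# foreground blobs over a textured background with organ-like distractors,
# two contrast-phase intensity variants per patient, plus graded-quality
# mask degradations and soft predictions that serve as oracles for the
# metrics and confidence machinery without any training.

#' Phantom generation parameters
#'
#' Defaults target desk-scale testing at a 64-pixel axial plane; all pixel
#' ranges are absolute pixels at that size. Intensities are drawn in a
#' 12-bit subrange of the 16-bit scale to mimic stored CT values.
#'
#' @param image_size axial plane size in pixels (square).
#' @param n_patients number of simulated patients.
#' @param slices_per_patient_range inclusive integer range for the number of
#'   axial slices per patient.
#' @param tumor_radius_range inclusive range for the maximal in-plane tumor
#'   radius, in pixels. Must stay below `image_size / 2`.
#' @param tumor_contrast nominal additive intensity offset of tumor over
#'   background. Each patient draws an enhancement factor uniform in
#'   [0.5, 1.3] of this value, so cohorts span conspicuous to
#'   poorly-enhancing tumors.
#' @param background_texture_scale correlation length (pixels) of the smooth
#'   background texture.
#' @param noise_sd standard deviation of additive voxel noise.
#' @param phases 1 or 2 contrast-phase variants per patient. Phase 2 shares
#'   geometry and mask with phase 1 but applies a monotone intensity remap
#'   and an independent noise draw.
#' @param seed integer seed; generation is fully deterministic given it.
#' @return an object of class `phantom_params`.
#' @export
phantom_params <- function(image_size = 64L, n_patients = 10L,
                           slices_per_patient_range = c(5L, 20L),
                           tumor_radius_range = c(4, 10),
                           tumor_contrast = 900,
                           background_texture_scale = 8,
                           noise_sd = 60,
                           phases = 2L,
                           seed = 1L) {
  if (max(tumor_radius_range) >= image_size / 2) {
    stop_ennseg("tumor radius must stay below image_size/2",
                class = "ennseg_value_error")
  }
  stopifnot(image_size >= 16, n_patients >= 1,
            length(slices_per_patient_range) == 2,
            slices_per_patient_range[1] >= 3,
            slices_per_patient_range[1] <= slices_per_patient_range[2],
            length(tumor_radius_range) == 2,
            tumor_radius_range[1] > 0,
            tumor_radius_range[1] <= tumor_radius_range[2],
            tumor_contrast > 0, background_texture_scale > 0, noise_sd >= 0,
            phases %in% c(1L, 2L))
  structure(list(image_size = as.integer(image_size),
                 n_patients = as.integer(n_patients),
                 slices_per_patient_range = as.integer(slices_per_patient_range),
                 tumor_radius_range = as.numeric(tumor_radius_range),
                 tumor_contrast = as.numeric(tumor_contrast),
                 background_texture_scale = as.numeric(background_texture_scale),
                 noise_sd = as.numeric(noise_sd),
                 phases = as.integer(phases),
                 seed = as.integer(seed)),
            class = "phantom_params")
}

# Separable Gaussian blur with in-range kernel renormalisation at the
# borders (no wrap-around, no edge darkening); exact and deterministic.
gauss_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  blur_mat <- function(n) {
    r <- ceiling(3 * sigma)
    K <- outer(seq_len(n), seq_len(n),
               function(i, j) ifelse(abs(i - j) <= r,
                                     exp(-((i - j)^2) / (2 * sigma^2)), 0))
    K / rowSums(K)
  }
  Kr <- blur_mat(nrow(x))
  Kc <- blur_mat(ncol(x))
  Kr %*% x %*% t(Kc)
}

# Smooth background texture: blurred white noise rescaled to unit sd.
smooth_texture <- function(n, scale) {
  t <- gauss_blur(matrix(stats::rnorm(n * n), n, n), scale / 2)
  s <- stats::sd(as.vector(t))
  if (s < 1e-12) matrix(0, n, n) else (t - mean(t)) / s
}

# Rasterise a perturbed-ellipse blob: boundary radius r * (1 + sum of low
# harmonics), guaranteed nonempty for r >= 1.
blob_mask <- function(n, cy, cx, r, harm_amp, harm_phase, aspect = 1) {
  iy <- matrix(seq_len(n), n, n)
  ix <- matrix(seq_len(n), n, n, byrow = TRUE)
  dy <- (iy - cy) * aspect
  dx <- ix - cx
  theta <- atan2(dy, dx)
  rad <- r * (1 + Reduce(`+`, lapply(seq_along(harm_amp), function(h) {
    harm_amp[h] * cos((h + 1) * theta + harm_phase[h])
  })))
  m <- (sqrt(dy^2 + dx^2) <= pmax(rad, 1)) * 1
  m
}

ellipse_mask <- function(n, cy, cx, ay, ax, angle = 0) {
  iy <- matrix(seq_len(n), n, n)
  ix <- matrix(seq_len(n), n, n, byrow = TRUE)
  dy <- iy - cy; dx <- ix - cx
  ca <- cos(angle); sa <- sin(angle)
  u <- ca * dx + sa * dy
  v <- -sa * dx + ca * dy
  ((u / ax)^2 + (v / ay)^2 <= 1) * 1
}

BASE_LEVEL <- 1200
TEXTURE_SD <- 150
ORGAN_CONTRAST <- 350
INTENSITY_MAX <- 4095

#' Generate a synthetic phantom cohort
#'
#' For each patient, draws a shared geometry (slice count, tumor blob shape
#' and position, 1-3 ellipsoidal organ-like distractors) and renders one
#' volume per contrast phase. The tumor spans a contiguous run of slices
#' with its in-plane area waxing and waning along z (elliptic profile); its
#' intensity is `tumor_contrast` above the local background. Phase 2 applies
#' a monotone intensity remap of the same structure with an independent
#' noise draw, so patient-grouped splitting is exercised exactly where it
#' matters. Generation is deterministic given `params$seed`.
#'
#' @param params a [phantom_params()] object.
#' @return an object of class `phantom_cohort`: list with `params` and
#'   `cases`; each case holds `volume` (a [ct_volume()]), `mask` (3D binary
#'   array) and `meta` (`case_id`, `patient_id`, `phase`, 0-based
#'   `tumor_slices`, per-slice `tumor_area`).
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "phantom_params"))
  n <- params$image_size
  local_seed(params$seed, {
    cases <- list()
    case_no <- 0L
    for (p in seq_len(params$n_patients)) {
      pid <- sprintf("P%04d", p)
      nz <- sample(seq(params$slices_per_patient_range[1],
                       params$slices_per_patient_range[2]), 1)
      r_max <- stats::runif(1, params$tumor_radius_range[1],
                            params$tumor_radius_range[2])
      # per-patient enhancement factor: tumor conspicuity varies between
      # patients (poorly enhancing tumors approach organ/texture contrast),
      # so realistic cohorts contain both easy and hard cases
      contrast_p <- params$tumor_contrast * stats::runif(1, 0.5, 1.3)
      margin <- r_max * 1.5 + 2
      cy <- stats::runif(1, margin, n - margin)
      cx <- stats::runif(1, margin, n - margin)
      harm_amp <- stats::rnorm(3, 0, 0.07)
      harm_phase <- stats::runif(3, 0, 2 * pi)
      aspect <- stats::runif(1, 0.8, 1.25)
      # contiguous tumor run with waxing/waning radius
      n_t <- sample(3:nz, 1)
      z0 <- sample(seq_len(nz - n_t + 1), 1)
      zc <- z0 + (n_t - 1) / 2
      radii <- vapply(z0:(z0 + n_t - 1), function(k) {
        u <- (k - zc) / ((n_t + 1) / 2)
        max(1.2, r_max * sqrt(max(0, 1 - u^2)))
      }, numeric(1))
      # organ-like distractors, kept clear of the tumor
      n_org <- sample(1:3, 1)
      organs <- list()
      for (o in seq_len(n_org)) {
        for (try in 1:25) {
          ay <- stats::runif(1, 5, 11) * n / 64
          ax <- stats::runif(1, 5, 11) * n / 64
          ocy <- stats::runif(1, ay + 2, n - ay - 2)
          ocx <- stats::runif(1, ax + 2, n - ax - 2)
          if (sqrt((ocy - cy)^2 + (ocx - cx)^2) > r_max * 1.3 + max(ay, ax) + 2)
            break
        }
        organs[[o]] <- list(cy = ocy, cx = ocx, ay = ay, ax = ax,
                            angle = stats::runif(1, 0, pi))
      }
      organ_img <- Reduce(`+`, lapply(organs, function(g) {
        ellipse_mask(n, g$cy, g$cx, g$ay, g$ax, g$angle)
      }))
      organ_img <- pmin(organ_img, 1)
      # shared structure (noise-free) and mask, slice by slice
      mask <- array(0, c(n, n, nz))
      structure_img <- array(0, c(n, n, nz))
      for (k in seq_len(nz)) {
        tex <- smooth_texture(n, params$background_texture_scale) * TEXTURE_SD
        s <- BASE_LEVEL + tex + ORGAN_CONTRAST * organ_img
        if (k >= z0 && k < z0 + n_t) {
          m <- blob_mask(n, cy, cx, radii[k - z0 + 1], harm_amp, harm_phase,
                         aspect)
          # tumor blob must not merge into an organ: carve organ contrast out
          s <- s + contrast_p * m - ORGAN_CONTRAST * organ_img * m
          mask[, , k] <- m
        }
        structure_img[, , k] <- s
      }
      tumor_idx <- which(apply(mask, 3, sum) > 0)
      meta_base <- list(patient_id = pid,
                        tumor_slices = as.integer(tumor_idx - 1L),
                        tumor_area = apply(mask, 3, sum)[tumor_idx])
      phase_names <- c("corticomedullary", "nephrogenic")
      for (ph in seq_len(params$phases)) {
        case_no <- case_no + 1L
        noise <- array(stats::rnorm(n * n * nz, 0, params$noise_sd), c(n, n, nz))
        vox <- if (ph == 1) {
          structure_img + noise
        } else {
          0.85 * structure_img + 180 + noise  # monotone phase remap
        }
        vox <- round(pmin(pmax(vox, 0), INTENSITY_MAX))
        dim(vox) <- c(n, n, nz)
        vol <- ct_volume(vox, spacing = c(3, 1, 1), patient_id = pid,
                         phase = phase_names[ph])
        meta <- c(list(case_id = sprintf("case_%05d", case_no),
                       phase = phase_names[ph]), meta_base)
        cases[[case_no]] <- list(volume = vol, mask = mask, meta = meta)
      }
    }
    structure(list(params = params, cases = cases), class = "phantom_cohort")
  })
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat(sprintf("phantom_cohort: %d cases (%d patients x %d phase(s)), %dx%d plane, seed %d\n",
              length(x$cases), x$params$n_patients, x$params$phases,
              x$params$image_size, x$params$image_size, x$params$seed))
  invisible(x)
}

#' Write a phantom cohort to disk in KiTS layout
#'
#' Each case becomes `case_XXXXX/{imaging,segmentation}.nii.gz` under `dir`,
#' plus a `manifest.json` recording parameters and per-case metadata.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "phantom_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(params = unclass(cohort$params),
                   cases = lapply(cohort$cases, function(cs) {
                     c(cs$meta, list(n_slices = dim(cs$volume$voxels)[3]))
                   }))
  for (cs in cohort$cases) {
    write_case(cs$volume, cs$mask, file.path(dir, cs$meta$case_id))
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a phantom cohort written by [write_cohort()]
#'
#' @param dir cohort directory containing `manifest.json`.
#' @return a `phantom_cohort` reconstructed from disk.
#' @export
read_cohort <- function(dir) {
  mf_path <- file.path(dir, "manifest.json")
  if (!file.exists(mf_path)) {
    stop_ennseg("no manifest.json in ", dir, "; run the simulate step first",
                class = "ennseg_io_error")
  }
  mf <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  params <- do.call(phantom_params, mf$params[names(formals(phantom_params))])
  cases <- lapply(seq_len(nrow(mf$cases)), function(i) {
    row <- mf$cases[i, ]
    cd <- file.path(dir, row$case_id)
    loaded <- suppressWarnings(load_case(cd, phase = row$phase))
    loaded$volume$patient_id <- row$patient_id
    list(volume = loaded$volume, mask = loaded$mask,
         meta = list(case_id = row$case_id, patient_id = row$patient_id,
                     phase = row$phase,
                     tumor_slices = as.integer(unlist(row$tumor_slices)),
                     tumor_area = as.numeric(unlist(row$tumor_area))))
  })
  structure(list(params = params, cases = cases), class = "phantom_cohort")
}

morph_steps <- function(mask, steps, op) {
  if (steps <= 0) return(mask)
  brush <- EBImage::makeBrush(3, "box")
  m <- mask
  for (i in seq_len(steps)) m <- op(m, brush)
  (m > 0) * 1
}

shift_mask <- function(mask, dy, dx) {
  n <- nrow(mask); m <- ncol(mask)
  out <- matrix(0, n, m)
  src_y <- seq_len(n) - dy
  src_x <- seq_len(m) - dx
  ok_y <- src_y >= 1 & src_y <= n
  ok_x <- src_x >= 1 & src_x <= m
  out[ok_y, ok_x] <- mask[src_y[ok_y], src_x[ok_x]]
  out
}

#' Controlled degradation of a reference mask
#'
#' Produces predicted masks with a tunable, monotone quality loss, used as
#' an oracle for the success/inadequate dichotomy. `severity = 0` returns
#' the input unchanged for every mode; increasing severity monotonically
#' lowers the expected Dice against the reference. Mode `"wrong_region"`
#' places a blob disjoint from the reference (Dice 0 by construction), the
#' archetypal confident-but-wrong failure (e.g., segmenting the wrong
#' organ).
#'
#' @param ref reference mask (`mask_slice` or binary matrix); must be
#'   nonempty for modes other than `"wrong_region"`.
#' @param severity degradation strength in \[0, 1\].
#' @param mode one of `"erode"`, `"dilate"`, `"shift"`, `"drop"`,
#'   `"wrong_region"`.
#' @param seed integer seed for the random components (shift direction,
#'   drop direction).
#' @return degraded mask of the same type as `ref` (`mask_slice` output has
#'   `origin = "predicted"`).
#' @export
degrade_mask <- function(ref, severity, mode = c("erode", "dilate", "shift",
                                                 "drop", "wrong_region"),
                         seed = 1L) {
  mode <- match.arg(mode)
  m <- as_mask_array(ref)
  check_binary(m, "ref")
  if (severity < 0 || severity > 1) {
    stop_ennseg("severity must be in [0,1]", class = "ennseg_value_error")
  }
  if (mode != "wrong_region" && sum(m) == 0) {
    stop_ennseg("reference mask is empty", class = "ennseg_value_error")
  }
  out <- if (severity == 0) m else local_seed(seed, {
    switch(mode,
      erode = morph_steps(m, ceiling(severity * 6), EBImage::erode),
      dilate = morph_steps(m, ceiling(severity * 6), EBImage::dilate),
      shift = {
        d <- severity * 0.25 * nrow(m)
        ang <- stats::runif(1, 0, 2 * pi)
        shift_mask(m, round(d * sin(ang)), round(d * cos(ang)))
      },
      drop = {
        ang <- stats::runif(1, 0, 2 * pi)
        idx <- which(m > 0, arr.ind = TRUE)
        proj <- idx[, 1] * sin(ang) + idx[, 2] * cos(ang)
        cut <- stats::quantile(proj, 1 - severity, type = 7)
        keep <- proj <= cut
        out <- matrix(0, nrow(m), ncol(m))
        out[idx[keep, , drop = FALSE]] <- 1
        out
      },
      wrong_region = {
        r <- max(1.5, sqrt(max(sum(m), 4) / pi) * (0.5 + 0.8 * severity))
        target <- wrong_region_center(m, r)
        blob <- ellipse_mask(nrow(m), target[1], target[2], r, r)
        blob[m > 0] <- 0  # enforce disjointness
        if (sum(blob) == 0) blob[round(target[1]), round(target[2])] <- 1
        blob
      })
  })
  if (inherits(ref, "mask_slice")) {
    mask_slice(out, ref$slice_index, ref$patient_id, origin = "predicted")
  } else {
    out
  }
}

# Pick the in-bounds center farthest from the reference foreground.
wrong_region_center <- function(m, r) {
  n <- nrow(m)
  if (sum(m) == 0) return(c(n / 4, n / 4))
  idx <- which(m > 0, arr.ind = TRUE)
  cy <- mean(idx[, 1]); cx <- mean(idx[, 2])
  lim <- function(v) min(max(v, r + 2), n - r - 2)
  corners <- rbind(c(lim(2), lim(2)), c(lim(2), lim(n - 1)),
                   c(lim(n - 1), lim(2)), c(lim(n - 1), lim(n - 1)))
  d <- (corners[, 1] - cy)^2 + (corners[, 2] - cx)^2
  corners[which.max(d), ]
}

#' Simulate an ensemble-style soft prediction of controllable quality
#'
#' Produces a probability map that mimics a fused ensemble output with a
#' tunable quality level, without any training. `quality = 1, blur = 0`
#' returns the reference exactly (probabilities in \{0,1\}, foreground
#' entropy 0). As quality decreases, the mask is geometrically corrupted
#' (shift plus erosion or dilation), its boundary blurred, and all
#' probabilities compressed toward 0.5, which raises the foreground entropy
#' and lowers the Dice of the thresholded map.
#'
#' @param ref reference mask (`mask_slice` or binary matrix), nonempty.
#' @param quality in \[0, 1\]; 1 is a perfect, maximally confident
#'   prediction.
#' @param blur baseline boundary blur (Gaussian sigma, pixels) applied even
#'   at full quality.
#' @param seed integer seed for the geometric corruption.
#' @return probability matrix in \[0, 1\], same shape as `ref`.
#' @export
simulate_soft_prediction <- function(ref, quality, blur = 0, seed = 1L) {
  m <- as_mask_array(ref)
  check_binary(m, "ref")
  if (quality < 0 || quality > 1) {
    stop_ennseg("quality must be in [0,1]", class = "ennseg_value_error")
  }
  if (sum(m) == 0) {
    stop_ennseg("reference mask is empty", class = "ennseg_value_error")
  }
  g <- 1 - quality
  if (g == 0 && blur <= 0) return(m * 1)
  local_seed(seed, {
    geo <- m
    if (g > 0) {
      ang <- stats::runif(1, 0, 2 * pi)
      d <- g * 4
      geo <- shift_mask(geo, round(d * sin(ang)), round(d * cos(ang)))
      steps <- round(g * 2)
      op <- if (stats::runif(1) < 0.5) EBImage::erode else EBImage::dilate
      geo <- morph_steps(geo, steps, op)
    }
    sigma <- blur + 1.2 * g
    p <- if (sigma > 0) gauss_blur(geo, sigma) else geo * 1
    p <- pmin(pmax(p, 0), 1)
    p <- quality * p + g * 0.5
    dim(p) <- dim(m)
    p
  })
}
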