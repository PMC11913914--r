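small_params <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(image_size = 48L, n_patients = 4L,
         slices_per_patient_range = c(4L, 8L),
         tumor_radius_range = c(3, 8), phases = 2L, seed = seed),
    list(...))
  do.call(phantom_params, args)
}

test_that("cohort generation is deterministic and respects counts", {
  a <- generate_cohort(small_params(seed = 7L))
  b <- generate_cohort(small_params(seed = 7L))
  expect_identical(a, b)
  d <- generate_cohort(small_params(seed = 8L))
  expect_false(identical(a, d))
  # n_patients x phases cases, distinct patient ids
  p20 <- phantom_params(image_size = 32L, n_patients = 20L,
                        slices_per_patient_range = c(3L, 5L),
                        tumor_radius_range = c(3, 6), phases = 2L, seed = 3L)
  coh <- generate_cohort(p20)
  expect_length(coh$cases, 40)
  expect_length(unique(vapply(coh$cases, function(cs) cs$meta$patient_id,
                              character(1))), 20)
})

test_that("every phantom case has a binary nonempty tumor with correct bookkeeping", {
  coh <- generate_cohort(small_params(seed = 21L))
  for (cs in coh$cases) {
    expect_true(all(cs$mask %in% c(0, 1)))
    expect_gt(sum(cs$mask), 0)
    per_slice <- apply(cs$mask, 3, sum)
    idx <- which(per_slice > 0)
    # contiguous run of tumor slices, 0-based in metadata
    expect_equal(idx, seq(min(idx), max(idx)))
    expect_equal(cs$meta$tumor_slices, as.integer(idx - 1L))
    expect_equal(cs$meta$tumor_area, per_slice[idx])
    # intensities inside a 12-bit subrange of the 16-bit scale
    expect_true(all(cs$volume$voxels >= 0 & cs$volume$voxels <= 4095))
  }
})

test_that("phases share geometry and mask but differ in intensity", {
  coh <- generate_cohort(small_params(seed = 5L))
  by_pat <- split(coh$cases,
                  vapply(coh$cases, function(cs) cs$meta$patient_id,
                         character(1)))
  for (cases in by_pat) {
    expect_length(cases, 2)
    expect_identical(cases[[1]]$mask, cases[[2]]$mask)
    expect_equal(dim(cases[[1]]$volume$voxels), dim(cases[[2]]$volume$voxels))
    expect_false(identical(cases[[1]]$volume$voxels, cases[[2]]$volume$voxels))
    expect_setequal(vapply(cases, function(cs) cs$meta$phase, character(1)),
                    c("corticomedullary", "nephrogenic"))
  }
})

test_that("tumor_slices count matches the generator's recorded count", {
  for (seed in c(2L, 13L, 44L)) {
    coh <- generate_cohort(small_params(seed = seed))
    for (cs in coh$cases) {
      pairs <- tumor_slices(cs$volume, cs$mask)
      expect_length(pairs, length(cs$meta$tumor_slices))
      expect_equal(vapply(pairs, function(p) p$slice$slice_index, integer(1)),
                   cs$meta$tumor_slices)
    }
  }
})

test_that("noise-free high-contrast tumors are recoverable by Otsu thresholding", {
  params <- phantom_params(image_size = 64L, n_patients = 3L,
                           slices_per_patient_range = c(4L, 6L),
                           tumor_radius_range = c(6, 10),
                           tumor_contrast = 2500, noise_sd = 0,
                           phases = 1L, seed = 9L)
  coh <- generate_cohort(params)
  for (cs in coh$cases) {
    k <- cs$meta$tumor_slices[ceiling(length(cs$meta$tumor_slices) / 2)] + 1L
    sl <- cs$volume$voxels[, , k]
    ref <- cs$mask[, , k]
    g <- (sl - min(sl)) / (max(sl) - min(sl))
    th <- EBImage::otsu(g, range = c(0, 1))
    expect_gt(dice((g > th) * 1, ref), 0.95)
  }
})

test_that("tumor radius must stay below half the image", {
  expect_error(phantom_params(image_size = 32L, tumor_radius_range = c(4, 16)),
               class = "ennseg_value_error")
})

test_that("write_cohort / read_cohort round-trips cases and manifest", {
  td <- withr::local_tempdir()
  coh <- generate_cohort(small_params(seed = 31L))
  write_cohort(coh, file.path(td, "cohort"))
  expect_true(file.exists(file.path(td, "cohort", "manifest.json")))
  back <- read_cohort(file.path(td, "cohort"))
  expect_length(back$cases, length(coh$cases))
  for (i in seq_along(coh$cases)) {
    expect_equal(as.vector(back$cases[[i]]$volume$voxels),
                 as.vector(coh$cases[[i]]$volume$voxels))
    expect_equal(as.vector(back$cases[[i]]$mask),
                 as.vector(coh$cases[[i]]$mask))
    expect_equal(back$cases[[i]]$meta$tumor_slices,
                 coh$cases[[i]]$meta$tumor_slices)
    expect_equal(back$cases[[i]]$meta$patient_id,
                 coh$cases[[i]]$meta$patient_id)
  }
})

test_that("degrade_mask: identity at severity 0, wrong_region disjoint", {
  m <- disc_mask(32, 16, 16, 6)
  for (mode in c("erode", "dilate", "shift", "drop", "wrong_region")) {
    expect_identical(degrade_mask(m, 0, mode, seed = 2), m)
  }
  for (seed in 1:5) {
    w <- degrade_mask(m, 0.5, "wrong_region", seed = seed)
    expect_equal(dice(w, m), 0)
    expect_gt(sum(w), 0)
  }
  # mask_slice wrapper keeps identity fields, flips origin
  ms <- mask_slice(m, 4L, "P1", "reference")
  out <- degrade_mask(ms, 0.3, "erode", seed = 1)
  expect_s3_class(out, "mask_slice")
  expect_equal(out$origin, "predicted")
  expect_equal(out$slice_index, 4L)
  expect_error(degrade_mask(matrix(0, 8, 8), 0.5, "erode"),
               class = "ennseg_value_error")
  expect_error(degrade_mask(m, 2, "erode"), class = "ennseg_value_error")
})

test_that("expected dice decreases monotonically with degradation severity", {
  m <- disc_mask(32, 15, 17, 7)
  severities <- c(0, 0.2, 0.4, 0.6, 0.8)
  for (mode in c("erode", "dilate", "shift", "drop")) {
    med <- sapply(severities, function(s) {
      median(sapply(1:50, function(seed) {
        dice(degrade_mask(m, s, mode, seed = seed), m)
      }))
    })
    expect_true(all(diff(med) <= 1e-12),
                info = paste("mode", mode, ":", paste(round(med, 3), collapse = " ")))
    expect_equal(med[1], 1)
  }
})

test_that("simulate_soft_prediction: exact at full quality, entropy 1 at p=0.5", {
  m <- disc_mask(32, 16, 16, 6)
  p <- simulate_soft_prediction(m, quality = 1, blur = 0, seed = 1)
  expect_identical(p, m * 1)
  expect_equal(as.numeric(foreground_entropy(p)), 0)
  # constant 0.5 inside predicted foreground has entropy 1 by definition
  half <- matrix(0.5, 8, 8)
  expect_equal(as.numeric(foreground_entropy(half, mask = matrix(1, 8, 8))), 1)
  expect_error(simulate_soft_prediction(m, 1.5), class = "ennseg_value_error")
  expect_error(simulate_soft_prediction(matrix(0, 4, 4), 1),
               class = "ennseg_value_error")
})

test_that("quality grid drives entropy up and dice down monotonically", {
  m <- disc_mask(48, 22, 26, 9)
  qualities <- c(1.0, 0.7, 0.4, 0.1)
  stats <- sapply(qualities, function(q) {
    e <- d <- numeric(50)
    for (seed in 1:50) {
      p <- simulate_soft_prediction(m, q, blur = 0, seed = seed)
      e[seed] <- as.numeric(foreground_entropy(p))
      d[seed] <- dice((p >= 0.5) * 1, m)
    }
    c(entropy = mean(e), dice = mean(d))
  })
  expect_true(all(diff(stats["entropy", ]) > 0))
  expect_true(all(diff(stats["dice", ]) < 0))
})
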