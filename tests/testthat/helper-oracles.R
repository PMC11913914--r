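# Shared fixtures and independent brute-force oracles used across the suite.

# Square mask centred in an n x n plane.
square_mask <- function(n = 16, lo = 5, hi = 12) {
  m <- matrix(0, n, n)
  m[lo:hi, lo:hi] <- 1
  m
}

# Disc mask, radius r at (cy, cx).
disc_mask <- function(n, cy, cx, r) {
  iy <- matrix(seq_len(n), n, n)
  ix <- matrix(seq_len(n), n, n, byrow = TRUE)
  ((iy - cy)^2 + (ix - cx)^2 <= r^2) * 1
}

# Brute-force Dice from set cardinalities (independent of dice()).
oracle_dice <- function(a, b) {
  ia <- which(a == 1)
  ib <- which(b == 1)
  if (length(ia) + length(ib) == 0) return(1)
  2 * length(intersect(ia, ib)) / (length(ia) + length(ib))
}

# Brute-force AUC as pairwise Mann-Whitney concordance, ties counted 1/2.
# polarity "high": higher score indicates the positive class.
oracle_auc <- function(scores, labels, polarity = "high") {
  s <- if (polarity == "high") scores else -scores
  pos <- s[labels == 1]
  neg <- s[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Exhaustive Youden-optimal cutoff search over all empirical cutoffs,
# applying the package's documented classification rules and tie-breaks
# independently of roc()/youden_cutoff().
oracle_youden <- function(scores, labels, polarity = "high") {
  thr <- c(sort(unique(scores)), Inf)
  best <- NULL
  for (t in thr) {
    pred <- if (polarity == "high") as.integer(scores >= t)
            else as.integer(scores < t)
    sens <- sum(pred == 1 & labels == 1) / sum(labels == 1)
    spec <- sum(pred == 0 & labels == 0) / sum(labels == 0)
    j <- sens + spec - 1
    if (is.null(best) || j > best$j + 1e-12 ||
        (abs(j - best$j) <= 1e-12 && sens > best$sens + 1e-12)) {
      best <- list(threshold = t, j = j, sens = sens, spec = spec)
    }
  }
  best
}

# Small trained ensemble + holdout pairs, cached per test run so several
# tests can share one (slow) training.
tiny_trained_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    params <- phantom_params(image_size = 32L, n_patients = 12L,
                             slices_per_patient_range = c(4L, 8L),
                             tumor_radius_range = c(3, 7),
                             tumor_contrast = 1100,
                             phases = 2L, seed = 301L)
    cohort <- generate_cohort(params)
    pats <- unique(vapply(cohort$cases, function(cs) cs$meta$patient_id,
                          character(1)))
    sp <- patient_split(pats, c(0.6, 0.2, 0.2), seed = 302L)
    pairs_of <- function(ids) {
      ps <- list()
      for (cs in cohort$cases) {
        if (cs$meta$patient_id %in% ids)
          ps <- c(ps, tumor_slices(cs$volume, cs$mask))
      }
      ps
    }
    cfg <- ensemble_config(n_members = 2L, epochs = 14L, batch_size = 16L,
                           channels = 4L, base_seed = 303L)
    ens <- train_ensemble(pairs_of(sp$train), pairs_of(sp$validation), cfg)
    cache <<- list(cohort = cohort, split = sp, config = cfg, ensemble = ens,
                   holdout_pairs = pairs_of(sp$holdout))
    cache
  }
})

# Quality-graded fake evaluations: phantom tumor masks turned into soft
# predictions of random quality, scored for dice and foreground entropy.
# Serves as the training-free oracle for confidence calibration.
quality_graded_evals <- function(n, seed) {
  withr::with_seed(seed, {
    coh <- generate_cohort(phantom_params(
      image_size = 48L, n_patients = 6L,
      slices_per_patient_range = c(4L, 8L),
      tumor_radius_range = c(4, 9), phases = 1L,
      seed = sample.int(1e6, 1)))
    masks <- list()
    for (cs in coh$cases) {
      for (k in cs$meta$tumor_slices + 1L) {
        masks[[length(masks) + 1]] <- cs$mask[, , k]
      }
    }
    rows <- lapply(seq_len(n), function(i) {
      m <- masks[[sample.int(length(masks), 1)]]
      q <- stats::runif(1, 0.05, 1)
      p <- simulate_soft_prediction(m, q, blur = 0,
                                    seed = sample.int(1e6, 1))
      d <- dice((p >= 0.5) * 1, m)
      data.frame(quality = q, dice = d,
                 fg_entropy = as.numeric(foreground_entropy(p)))
    })
    do.call(rbind, rows)
  })
}
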