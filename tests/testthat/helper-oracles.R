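# Independent oracles used across the suite. Each is a deliberately naive
# implementation kept separate from the package's code path.

# Exhaustive between-class-variance scan over all 255 candidate
# thresholds; smallest threshold wins ties.
otsu_brute <- function(counts) {
  p <- counts / sum(counts)
  v <- 0:255
  best_t <- -1L
  best <- -Inf
  for (t in 0:254) {
    w0 <- sum(p[1:(t + 1)])
    w1 <- 1 - w0
    if (w0 <= 0 || w1 <= 0) next
    mu0 <- sum(p[1:(t + 1)] * v[1:(t + 1)]) / w0
    mu1 <- sum(p[(t + 2):256] * v[(t + 2):256]) / w1
    s <- w0 * w1 * (mu0 - mu1)^2
    if (s > best + 1e-12) {
      best <- s
      best_t <- t
    }
  }
  best_t
}

# Slow per-pixel positivity: a cell is positive iff at least one of its
# pixels is stain-positive.
positivity_brute <- function(label_image, dab_mask) {
  labs <- sort(setdiff(unique(as.vector(label_image)), 0L))
  vapply(labs, function(L) any(dab_mask[label_image == L]), logical(1))
}

# AUC as the normalized Mann-Whitney U statistic (tie-aware via midranks).
auc_mann_whitney <- function(scores, labels) {
  labels <- as.logical(labels)
  r <- rank(scores)
  n1 <- sum(labels)
  n0 <- sum(!labels)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Step-interpolated average precision by explicit sweep over every
# distinct score.
ap_brute <- function(scores, labels) {
  labels <- as.logical(labels)
  ths <- sort(unique(scores), decreasing = TRUE)
  prev_rec <- 0
  ap <- 0
  for (t in ths) {
    pred <- scores >= t
    tp <- sum(pred & labels)
    rec <- tp / sum(labels)
    prec <- tp / sum(pred)
    ap <- ap + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  ap
}

# Hand-coded reading of the guideline table, one clause per branch.
csco_brute <- function(complete, weak, any_staining, moderate = 0) {
  if (!any_staining) return("0")
  if (complete > 0.10) return("3+")
  if (complete > 0) return("2+")
  if (moderate > 0.10) return("2+")
  if (weak > 0.10) return("1+")
  "0"
}

# Match detected instances to ground-truth cells by nearest center.
match_to_truth <- function(cells, truth_cells) {
  vapply(seq_len(nrow(cells)), function(i) {
    which.min((truth_cells$row - cells$row[i])^2 +
                (truth_cells$col - cells$col[i])^2)
  }, integer(1))
}

# Full measurement chain for one patch image: DAB mask, intensity,
# deconvolution, segmentation, rings, features.
measure_patch <- function(img, completeness_cutoff = 0.9) {
  dm <- extract_dab_mask(img)
  maps <- deconvolve(img)
  seg <- measure_rings(segment_cells(maps$h), dm)
  list(
    dab_mask = dm,
    seg = seg,
    features = patch_features(seg$cells, staining_intensity(img, dm),
                              completeness_cutoff)
  )
}
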