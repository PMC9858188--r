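# Tumor-tile detection: dataset utilities, lossless patch augmentation,
# a pluggable patch-classifier contract with three backends, slide-level
# probability maps, and their binarization.

#' Split indices into train and validation sets
#'
#' Disjoint, exhaustive partition of `1:n_items`; the train set holds
#' `round(n_items * ratio)` shuffled indices.
#'
#' @param n_items number of items (>= 2).
#' @param ratio train fraction, in (0, 1).
#' @param rng_seed integer seed; the same seed reproduces the partition.
#' @returns List with integer vectors `train` and `validation`.
#' @examples
#' lengths(split_dataset(16000, 0.9, rng_seed = 1))  # 14400 / 1600
#' @export
split_dataset <- function(n_items, ratio = 0.9, rng_seed = 1L) {
  stopifnot(n_items >= 2, ratio > 0, ratio < 1)
  n_train <- round_half_up(n_items * ratio)
  withr::with_seed(as.integer(rng_seed), {
    perm <- sample.int(n_items)
  })
  list(
    train = sort(perm[seq_len(n_train)]),
    validation = sort(perm[-seq_len(n_train)])
  )
}

AUGMENT_OPS <- c("identity", "rot90", "rot180", "rot270", "hflip", "vflip")

#' Lossless patch augmentation
#'
#' Exact 90-degree-multiple rotations and axis flips (pixel permutations
#' only; no interpolation, so labels are preserved exactly).
#'
#' @param patch H x W x 3 array or [rgb_image].
#' @param op one of `"identity"`, `"rot90"`, `"rot180"`, `"rot270"`,
#'   `"hflip"`, `"vflip"`. Rotations are counter-clockwise by 90-degree
#'   steps.
#' @returns Augmented array with the input's type.
#' @export
augment_patch <- function(patch, op = AUGMENT_OPS) {
  op <- match.arg(op)
  p <- img_pixels(patch)
  d <- dim(p)
  if (op %in% c("rot90", "rot270") && d[1] != d[2]) {
    stop("90/270-degree rotation requires a square patch", call. = FALSE)
  }
  rot90_mat <- function(m) t(m)[ncol(m):1, , drop = FALSE]
  apply_ch <- function(f) {
    out <- vapply(1:3, function(ch) f(p[, , ch]), f(p[, , 1]))
    out
  }
  q <- switch(op,
    identity = p,
    rot90 = apply_ch(rot90_mat),
    rot180 = p[d[1]:1, d[2]:1, , drop = FALSE],
    rot270 = apply_ch(function(m) rot90_mat(rot90_mat(rot90_mat(m)))),
    hflip = p[, d[2]:1, , drop = FALSE],
    vflip = p[d[1]:1, , , drop = FALSE]
  )
  if (inherits(patch, "rgb_image")) rgb_image(q, patch$level) else q
}

#' Color-statistic features of a patch
#'
#' The feature vector behind the statistical classifier backends: HSV
#' means and spread, the stained (non-background) pixel fraction, the
#' DAB-range pixel fraction and the blue (hematoxylin-range) fraction.
#'
#' @param patch RGB patch.
#' @returns Named numeric vector.
#' @export
patch_color_features <- function(patch) {
  ch <- rgb_to_hsv_channels(patch)
  stained <- ch$s >= 0.05 & ch$v <= 0.98
  dab <- ch$h >= 8 & ch$h <= 40 & ch$s >= 0.08 & ch$v >= 0.1 & ch$v <= 0.98
  blue <- ch$h >= 180 & ch$h <= 300 & ch$s >= 0.05
  c(
    mean_s = mean(ch$s),
    mean_v = mean(ch$v),
    sd_v = stats::sd(as.vector(ch$v)),
    stained_frac = mean(stained),
    dab_frac = mean(dab),
    blue_frac = mean(blue)
  )
}

#' Training configuration for the patch classifier
#'
#' Mirrors the usual patch-classifier training recipe (SGD, learning rate
#' 0.01, momentum 0.9, cross-entropy, 50 epochs, batch 64, 9:1 split,
#' lossless 90-degree/flip augmentation). With the built-in `nnet`
#' backend, `epochs` bounds the optimizer iterations; `optimizer`,
#' `learning_rate`, `momentum` and `batch_size` are recorded metadata for
#' external backends.
#'
#' @param optimizer,learning_rate,momentum,loss,epochs,batch_size
#'   training hyperparameters.
#' @param split_ratio train:validation fraction in (0, 1).
#' @param augmentations subset of the supported lossless ops.
#' @param hidden_units hidden-layer size of the `nnet` backend.
#' @param seed integer seed driving every random choice in training.
#' @returns List of class `train_config`.
#' @export
train_config <- function(optimizer = "sgd", learning_rate = 0.01,
                         momentum = 0.9, loss = "cross-entropy",
                         epochs = 50L, batch_size = 64L, split_ratio = 0.9,
                         augmentations = c("rot90", "rot180", "rot270",
                                           "hflip", "vflip"),
                         hidden_units = 4L, seed = 42L) {
  stopifnot(split_ratio > 0, split_ratio < 1, epochs >= 1)
  stopifnot(all(augmentations %in% AUGMENT_OPS))
  structure(
    list(optimizer = optimizer, learning_rate = learning_rate,
         momentum = momentum, loss = loss, epochs = as.integer(epochs),
         batch_size = as.integer(batch_size), split_ratio = split_ratio,
         augmentations = augmentations, hidden_units = as.integer(hidden_units),
         seed = as.integer(seed)),
    class = "train_config"
  )
}

#' Deterministic color-heuristic tumor classifier
#'
#' A fixed logistic over the stained-pixel fraction and DAB fraction:
#' dense stained tiles score high, sparse unstained tiles low. Needs no
#' training, which makes it the dependency-free default backend.
#'
#' @param intercept,w_stained,w_dab logistic coefficients.
#' @returns `her2_classifier` object with backend `"heuristic"`.
#' @export
heuristic_classifier <- function(intercept = -1.2, w_stained = 8,
                                 w_dab = 2) {
  structure(
    list(backend = "heuristic",
         coef = c(intercept = intercept, w_stained = w_stained,
                  w_dab = w_dab)),
    class = c("her2_heuristic", "her2_classifier")
  )
}

#' Wrap a prediction function as a classifier backend
#'
#' @param fn function taking a list of patches and returning tumor
#'   probabilities in \[0, 1\].
#' @param name backend name recorded in metadata.
#' @returns `her2_classifier` object.
#' @export
function_classifier <- function(fn, name = "function") {
  stopifnot(is.function(fn))
  structure(list(backend = name, fn = fn),
            class = c("her2_function", "her2_classifier"))
}

#' Train the statistical patch-classifier backend
#'
#' Computes [patch_color_features()] for every labeled patch, splits them
#' train:validation with [split_dataset()], and fits a single-hidden-layer
#' neural network (`nnet`) on standardized features. The returned
#' classifier records its validation accuracy and training log.
#'
#' @param patches list of RGB patches (or a data frame with a `patch`
#'   list-column and logical `tumor` column, as from [make_patch_set()]).
#' @param labels logical tumor labels (ignored when `patches` is a data
#'   frame carrying them).
#' @param config [train_config()].
#' @returns `her2_classifier` object with backend `"nnet"`, holding the
#'   fitted model, feature scaling, `validation_accuracy` and `config`.
#' @export
train_classifier <- function(patches, labels = NULL,
                             config = train_config()) {
  if (is.data.frame(patches)) {
    labels <- patches$tumor
    patches <- patches$patch
  }
  if (length(patches) == 0L) stop("empty patch list", call. = FALSE)
  labels <- as.logical(labels)
  stopifnot(length(labels) == length(patches))
  if (length(unique(labels)) < 2L) {
    stop("training data must contain both classes", call. = FALSE)
  }
  feats <- t(vapply(patches, patch_color_features, numeric(6)))
  split <- split_dataset(length(patches), config$split_ratio, config$seed)
  mu <- colMeans(feats[split$train, , drop = FALSE])
  sdv <- apply(feats[split$train, , drop = FALSE], 2, stats::sd)
  sdv[sdv == 0] <- 1
  zs <- function(m) sweep(sweep(m, 2, mu), 2, sdv, "/")
  xtr <- zs(feats[split$train, , drop = FALSE])
  ytr <- labels[split$train]
  withr::with_seed(config$seed, {
    fit <- nnet::nnet(xtr, ytr * 1, size = config$hidden_units,
                      maxit = config$epochs, decay = 1e-4,
                      entropy = TRUE, trace = FALSE)
  })
  xva <- zs(feats[split$validation, , drop = FALSE])
  pva <- as.numeric(predict(fit, xva))
  val_acc <- mean((pva >= 0.5) == labels[split$validation])
  structure(
    list(backend = "nnet", fit = fit, center = mu, scale = sdv,
         validation_accuracy = val_acc, config = config,
         log = tibble::tibble(
           n_train = length(split$train),
           n_validation = length(split$validation),
           converged = fit$convergence == 0,
           final_value = fit$value,
           validation_accuracy = val_acc
         )),
    class = c("her2_nnet", "her2_classifier")
  )
}

#' @export
print.her2_classifier <- function(x, ...) {
  cat(sprintf("<her2_classifier> backend: %s\n", x$backend))
  if (!is.null(x$validation_accuracy)) {
    cat(sprintf("  validation accuracy: %.3f\n", x$validation_accuracy))
  }
  invisible(x)
}

#' @method tidy her2_classifier
#' @export
tidy.her2_classifier <- function(x, ...) {
  if (!is.null(x$log)) return(x$log)
  tibble::tibble(backend = x$backend)
}

#' @method glance her2_classifier
#' @export
glance.her2_classifier <- function(x, ...) {
  tibble::tibble(
    backend = x$backend,
    validation_accuracy = x$validation_accuracy %||% NA_real_
  )
}

#' Tumor probabilities for a batch of patches
#'
#' @param clf `her2_classifier` backend.
#' @param patches list of RGB patches.
#' @returns Numeric vector of probabilities in \[0, 1\].
#' @export
predict_tumor_prob <- function(clf, patches) {
  UseMethod("predict_tumor_prob")
}

#' @export
predict_tumor_prob.her2_heuristic <- function(clf, patches) {
  vapply(patches, function(p) {
    f <- patch_color_features(p)
    stats::plogis(clf$coef[["intercept"]] +
                    clf$coef[["w_stained"]] * f[["stained_frac"]] +
                    clf$coef[["w_dab"]] * f[["dab_frac"]])
  }, numeric(1))
}

#' @export
predict_tumor_prob.her2_nnet <- function(clf, patches) {
  feats <- t(vapply(patches, patch_color_features, numeric(6)))
  z <- sweep(sweep(feats, 2, clf$center), 2, clf$scale, "/")
  pmin(1, pmax(0, as.numeric(predict(clf$fit, z))))
}

#' @export
predict_tumor_prob.her2_function <- function(clf, patches) {
  p <- clf$fn(patches)
  if (any(p < 0 | p > 1)) {
    stop("classifier backend returned probabilities outside [0, 1]",
         call. = FALSE)
  }
  p
}

#' Slide-level tumor probability map
#'
#' Evaluates the classifier on every admissible tile of the grid. The
#' result is order- and batch-size-invariant because each tile is scored
#' independently.
#'
#' @param slide level-0 [rgb_image] (or a `synthetic_slide`).
#' @param grid [enumerate_tiles()] result.
#' @param clf `her2_classifier` backend.
#' @param batch_size tiles scored per batch.
#' @returns Object of class `prob_map`: the grid tibble with a `prob`
#'   column; attributes carry the tile lattice shape so [prob_matrix()]
#'   can lay probabilities out as a matrix with `NaN` for non-tissue
#'   tiles.
#' @export
probability_map <- function(slide, grid, clf, batch_size = 64L) {
  if (inherits(slide, "synthetic_slide")) slide <- slide$levels[[1]]
  ts <- attr(grid, "tile_size")
  n <- nrow(grid)
  probs <- numeric(n)
  for (start in seq(1L, max(n, 1L), by = batch_size)) {
    if (n == 0L) break
    idx <- start:min(n, start + batch_size - 1L)
    tiles <- lapply(idx, function(i) {
      extract_tile(slide, grid$row0[i], grid$col0[i], ts)
    })
    p <- tryCatch(
      predict_tumor_prob(clf, tiles),
      error = function(e) {
        stop("classifier failed on tiles at (row0, col0) = ",
             paste(sprintf("(%d, %d)", grid$row0[idx], grid$col0[idx]),
                   collapse = ", "), ": ", conditionMessage(e),
             call. = FALSE)
      }
    )
    probs[idx] <- p
  }
  out <- grid
  out$prob <- probs
  class(out) <- c("prob_map", class(grid))
  out
}

#' Lay a probability map out on the full tile lattice
#'
#' @param pm `prob_map` from [probability_map()].
#' @returns Matrix of tile probabilities; `NaN` marks non-tissue tiles.
#' @export
prob_matrix <- function(pm) {
  ts <- attr(pm, "tile_size")
  m <- matrix(NaN, attr(pm, "n_tile_rows"), attr(pm, "n_tile_cols"))
  if (nrow(pm)) {
    m[cbind(pm$row0 %/% ts + 1L, pm$col0 %/% ts + 1L)] <- pm$prob
  }
  m
}

#' Binarize a probability map into a tumor tile mask
#'
#' Tiles with probability `>= threshold` are tumor (boundary values assign
#' positive).
#'
#' @param pm `prob_map` from [probability_map()].
#' @param threshold probability cutoff in (0, 1); default 0.5.
#' @returns The map tibble with a logical `tumor` column.
#' @export
binarize_map <- function(pm, threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1)
  pm$tumor <- pm$prob >= threshold
  pm
}
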