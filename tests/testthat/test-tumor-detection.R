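# Dataset splitting, lossless augmentation, classifier backends, and
# probability maps.

test_that("split_dataset produces exact, disjoint, seeded partitions", {
  s <- split_dataset(16000, 0.9, rng_seed = 1)
  expect_length(s$train, 14400)
  expect_length(s$validation, 1600)
  expect_length(intersect(s$train, s$validation), 0)
  expect_setequal(c(s$train, s$validation), 1:16000)

  s2 <- split_dataset(10, 0.9, rng_seed = 5)
  expect_length(s2$train, 9)
  expect_length(s2$validation, 1)

  expect_identical(split_dataset(100, 0.8, rng_seed = 7),
                   split_dataset(100, 0.8, rng_seed = 7))
  expect_error(split_dataset(1, 0.9), ">= 2")
})

test_that("augmentation ops satisfy the dihedral-group identities", {
  sp <- make_patch(6, 0.5, 1, 0.8, rng_seed = 1, size = 128)
  p <- sp$image$pixels
  r4 <- augment_patch(augment_patch(augment_patch(augment_patch(p, "rot90"),
                                                  "rot90"), "rot90"), "rot90")
  expect_identical(r4, p)
  expect_identical(augment_patch(augment_patch(p, "hflip"), "hflip"), p)
  expect_identical(augment_patch(augment_patch(p, "vflip"), "vflip"), p)
  expect_identical(augment_patch(p, "rot180"),
                   augment_patch(augment_patch(p, "vflip"), "hflip"))
  expect_identical(augment_patch(augment_patch(p, "rot90"), "rot270"), p)
  # lossless: pixel multiset preserved
  expect_identical(sort(as.vector(augment_patch(p, "rot90"))),
                   sort(as.vector(p)))
  expect_error(augment_patch(p[1:32, , , drop = FALSE], "rot90"), "square")
})

test_that("classifier backends separate the synthetic fixture", {
  set_ <- make_patch_set(n_tumor = 120, n_normal = 120, rng_seed = 1,
                         size = 96)
  # deterministic heuristic, no training
  h <- heuristic_classifier()
  ph <- predict_tumor_prob(h, set_$patch)
  expect_true(all(ph >= 0 & ph <= 1))
  expect_gte(mean((ph >= 0.5) == set_$tumor), 0.9)

  # trainable backend reaches higher validation accuracy
  clf <- train_classifier(set_, config = train_config(seed = 42))
  expect_gte(clf$validation_accuracy, 0.95)
  expect_s3_class(glance(clf), "tbl_df")

  # inference determinism
  p1 <- predict_tumor_prob(clf, set_$patch[1:10])
  p2 <- predict_tumor_prob(clf, set_$patch[1:10])
  expect_identical(p1, p2)

  expect_error(train_classifier(list(), logical(0)), "empty")
  expect_error(
    train_classifier(set_$patch[1:10], rep(TRUE, 10)),
    "both classes"
  )
})

test_that("probability maps are order-invariant and NaN off tissue", {
  sl <- make_slide("3+", n_tiles = 2, rng_seed = 2, tile_px = 128,
                   cells_per_tile = 5)
  m <- tissue_mask(sl$levels[[1]])
  g <- enumerate_tiles(m, 128, min_tissue_fraction = 0.25)
  clf <- heuristic_classifier()
  pm1 <- probability_map(sl$levels[[1]], g, clf, batch_size = 1)
  pm64 <- probability_map(sl$levels[[1]], g, clf, batch_size = 64)
  expect_equal(pm1$prob, pm64$prob, tolerance = 1e-6)

  mat <- prob_matrix(pm1)
  expect_equal(dim(mat), c(attr(g, "n_tile_rows"), attr(g, "n_tile_cols")))
  off_tissue <- is.nan(mat)
  expect_equal(sum(!off_tissue), nrow(g))

  # oracle classifier reproduces ground truth exactly
  oracle <- function_classifier(function(tiles) {
    vapply(tiles, function(tl) {
      as.numeric(mean(tl) < 250)  # tissue tiles are darker than background
    }, numeric(1))
  })
  pmo <- probability_map(sl$levels[[1]], g, oracle)
  expect_true(all(pmo$prob %in% c(0, 1)))
})

test_that("binarize_map uses the >= convention and is monotone", {
  g <- structure(
    tibble::tibble(row0 = c(0L, 0L, 128L), col0 = c(0L, 128L, 0L),
                   tissue_fraction = 1),
    tile_size = 128L, n_tile_rows = 2L, n_tile_cols = 2L,
    class = c("tile_grid", class(tibble::tibble()))
  )
  pm <- g
  pm$prob <- c(0.49, 0.50, 0.51)
  class(pm) <- c("prob_map", class(g))
  expect_equal(binarize_map(pm, 0.5)$tumor, c(FALSE, TRUE, TRUE))
  # raising the threshold never adds a tumor tile
  t1 <- binarize_map(pm, 0.3)$tumor
  t2 <- binarize_map(pm, 0.7)$tumor
  expect_true(all(t1 | !t2))
  expect_error(binarize_map(pm, 0))
  expect_error(binarize_map(pm, 1.2))
})

test_that("empty grids yield empty maps", {
  empty <- binary_mask(matrix(FALSE, 32, 32))
  g <- enumerate_tiles(empty, 32)
  pm <- probability_map(rgb_image(array(255L, c(32, 32, 3))), g,
                        heuristic_classifier())
  expect_equal(nrow(pm), 0)
})
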