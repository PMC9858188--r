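# Synthetic generator: determinism, conservation, composition model,
# pyramid contract, and class separability of generated slides.

test_that("empty and small patches honor the construction contract", {
  sp <- make_patch(0, positive_fraction = 0.5, rng_seed = 1, size = 64)
  expect_equal(nrow(sp$truth$cells), 0)
  expect_true(all(sp$image$pixels == 255L))

  sp <- make_patch(50, positive_fraction = 0.2, rng_seed = 7, size = 256)
  expect_equal(sum(sp$truth$cells$is_positive), 10)
  # background stays near-white
  bg <- sp$truth$cell_label_image == 0L
  for (ch in 1:3) expect_gte(min(sp$image$pixels[, , ch][bg]), 245)
})

test_that("identical seed and arguments give bit-identical output", {
  a <- make_patch(30, 0.4, 0.7, 0.6, rng_seed = 11, size = 256)
  b <- make_patch(30, 0.4, 0.7, 0.6, rng_seed = 11, size = 256)
  expect_identical(a, b)
  expect_false(identical(
    a$image$pixels,
    make_patch(30, 0.4, 0.7, 0.6, rng_seed = 12, size = 256)$image$pixels
  ))
})

test_that("positive-cell conservation holds across fractions", {
  for (p in c(0, 0.13, 0.5, 0.77, 1)) {
    sp <- make_patch(23, positive_fraction = p, rng_seed = 3, size = 192)
    expect_equal(sum(sp$truth$cells$is_positive), round(23 * p + 1e-9))
  }
})

test_that("ground-truth invariants hold", {
  sp <- make_patch(25, 0.4, 1, 0.8, rng_seed = 5, size = 192)
  labs <- setdiff(unique(as.vector(sp$truth$cell_label_image)), 0L)
  expect_setequal(labs, sp$truth$cells$label)
  # every center lies inside the tissue mask
  idx <- cbind(round(sp$truth$cells$row) + 1, round(sp$truth$cells$col) + 1)
  expect_true(all(sp$truth$tissue_mask[idx]))
  expect_true(all(sp$truth$cells$membrane_radius >
                    pmax(sp$truth$cells$nucleus_a, sp$truth$cells$nucleus_b)))
})

test_that("overcrowded layouts are rejected with a clear error", {
  expect_error(make_patch(500, rng_seed = 1, size = 64, max_attempts = 50),
               "too crowded")
})

test_that("compose_from_od implements the Beer-Lambert forward model", {
  # zero OD -> full transmission
  img <- compose_from_od(matrix(0, 8, 8), matrix(0, 8, 8))
  expect_true(all(img$pixels == 255L))

  # single-pixel hand evaluation against the exponential
  sv <- stain_vectors()
  oh <- matrix(0, 4, 4)
  oh[2, 3] <- 1
  img <- compose_from_od(oh, matrix(0, 4, 4), sv)
  expected <- floor(255 * 10^(-sv$hematoxylin) + 0.5)
  expect_equal(as.integer(img$pixels[2, 3, ]), as.integer(expected))

  expect_error(compose_from_od(matrix(0, 4, 4), matrix(0, 5, 5)),
               "identical shapes")
  expect_error(compose_from_od(matrix(-1, 4, 4), matrix(0, 4, 4)),
               "non-negative")
})

test_that("stain vectors are unit norm and well conditioned", {
  sv <- stain_vectors()
  m <- stain_matrix(sv)
  expect_equal(unname(sqrt(rowSums(m^2))), rep(1, 3), tolerance = 1e-9)
  expect_lt(kappa(m, exact = TRUE), 1e6)
  expect_equal(deconvolution_matrix(sv) %*% m, diag(3),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(stain_vectors(c(1, 0, 0), c(1, 0, 0)), "collinear")
})

test_that("slide pyramid levels halve and the class-0 slide is unstained", {
  sl <- make_slide("0", n_tiles = 1, rng_seed = 1, tile_px = 256,
                   cells_per_tile = 15, n_levels = 3)
  d0 <- dim(sl$levels[[1]]$pixels)[1:2]
  for (k in 1:2) {
    expect_equal(dim(sl$levels[[k + 1]]$pixels)[1:2], ceiling(d0 / 2^k))
    expect_equal(sl$levels[[k + 1]]$downsample, 2L^k)
  }
  expect_true(all(sl$truth$cells$dab_od == 0))
  expect_equal(sl$truth$aggregate$staining_intensity, 0)
})

test_that("generated slide aggregates stay inside their class intervals", {
  tab <- threshold_table()
  interval <- function(index, cl) {
    r <- tab[tab$index == index & tab$class == cl, ]
    c(r$min, r$max)
  }
  n_seeds <- 40  # per class; truth-level check, rendering skipped
  for (cl in c("0", "1+", "2+", "3+")) {
    for (s in seq_len(n_seeds) - 1) {
      tr <- make_slide(cl, n_tiles = 2, rng_seed = s, cells_per_tile = 60,
                       truth_only = TRUE)$truth
      a <- tr$aggregate
      si <- interval("staining", cl)
      pi_ <- interval("positive_ratio", cl)
      ci <- interval("circumferential", cl)
      expect_gte(a$staining_intensity, si[1])
      expect_lte(a$staining_intensity, si[2])
      expect_gte(a$positive_cell_ratio, pi_[1])
      expect_lte(a$positive_cell_ratio, pi_[2])
      expect_gte(a$circumferential_ratio, ci[1])
      expect_lte(a$circumferential_ratio, ci[2])
    }
  }
})

test_that("synthetic artifacts round-trip through disk formats", {
  dir <- withr::local_tempdir()
  sp <- make_patch(8, 0.5, 1, 0.8, rng_seed = 2, size = 128)
  write_synthetic_patch(sp, file.path(dir, "p"))
  img <- read_patch_png(file.path(dir, "p", "image.png"))
  expect_identical(img$pixels, sp$image$pixels)
  lab <- read_label_tiff(file.path(dir, "p", "labels.tiff"))
  expect_identical(lab, sp$truth$cell_label_image)
  truth <- jsonlite::read_json(file.path(dir, "p", "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(nrow(truth$cells), 8)

  sl <- make_slide("1+", n_tiles = 1, rng_seed = 1, tile_px = 128,
                   cells_per_tile = 6, n_levels = 2)
  write_synthetic_slide(sl, file.path(dir, "s"))
  lv <- read_slide_tiff(file.path(dir, "s", "slide.tiff"))
  expect_length(lv, 2)
  expect_identical(lv[[1]]$pixels, sl$levels[[1]]$pixels)
  expect_identical(lv[[2]]$pixels, sl$levels[[2]]$pixels)
})
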