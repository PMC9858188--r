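# DAB extraction, staining intensity, deconvolution, watershed
# segmentation, and membrane-ring measurement.

test_that("extract_dab_mask sees brown and ignores blue and white", {
  # hematoxylin-only patch
  sp <- make_patch(15, positive_fraction = 0, rng_seed = 1, size = 128)
  expect_false(any(extract_dab_mask(sp$image)))
  # all-white patch
  expect_false(any(extract_dab_mask(array(255L, c(64, 64, 3)))))
  # known membrane pixels
  sp <- make_patch(30, 0.5, 1, 0.8, rng_seed = 2, size = 256)
  m <- extract_dab_mask(sp$image)
  truth <- sp$truth$dab_mask
  expect_gte(sum(m & truth) / sum(truth), 0.95)  # recall
  expect_gte(sum(m & truth) / sum(m), 0.95)      # precision
})

test_that("staining_intensity matches its closed form and bounds", {
  expect_equal(staining_intensity(array(255L, c(8, 8, 3)),
                                  matrix(FALSE, 8, 8)), 0)
  # pure black pixels -> 1
  black <- array(0L, c(8, 8, 3))
  expect_equal(staining_intensity(black, matrix(TRUE, 8, 8)), 1)
  # composed DAB at known OD: per-pixel hand evaluation
  sv <- stain_vectors()
  for (d in c(0.3, 0.6, 0.9)) {
    img <- compose_from_od(matrix(0, 16, 16), matrix(d, 16, 16), sv)
    got <- staining_intensity(img, matrix(TRUE, 16, 16))
    i_hand <- floor(255 * 10^(-d * sv$dab) + 0.5)
    expected <- 1 - (0.299 * i_hand[1] + 0.587 * i_hand[2] +
                       0.114 * i_hand[3]) / 255
    expect_equal(got, expected, tolerance = 1e-12)
  }
  # monotone: darkening masked pixels never decreases intensity
  sp <- make_patch(20, 1, 1, 0.5, rng_seed = 3, size = 192)
  m <- extract_dab_mask(sp$image)
  darker <- sp$image$pixels
  for (ch in 1:3) darker[, , ch][m] <- pmax(0L, darker[, , ch][m] - 40L)
  expect_gte(staining_intensity(darker, m), staining_intensity(sp$image, m))
})

test_that("deconvolution inverts composition within quantization error", {
  # white patch -> zero maps
  maps <- deconvolve(array(255L, c(8, 8, 3)))
  expect_true(all(maps$h == 0) && all(maps$dab == 0))

  sv <- stain_vectors()
  withr::with_seed(10, {
    for (i in 1:20) {
      oh <- matrix(runif(32 * 32, 0, 0.7), 32, 32)
      od <- matrix(runif(32 * 32, 0, 0.7), 32, 32)
      img <- compose_from_od(oh, od, sv)
      rec <- deconvolve(img, sv)
      expect_lt(max(abs(rec$h - oh)), 0.02)
      expect_lt(max(abs(rec$dab - od)), 0.02)
    }
  })
  # pure single stain leaves the other channel near zero
  img <- compose_from_od(matrix(0.8, 16, 16), matrix(0, 16, 16), sv)
  rec <- deconvolve(img, sv)
  expect_lt(max(rec$dab), 0.02)
})

test_that("segmentation recovers separated cells exactly", {
  sp <- make_patch(50, 0.3, 1, 0.8, rng_seed = 1, size = 256)
  seg <- segment_cells(deconvolve(sp$image)$h)
  expect_equal(nrow(seg$cells), 50)
  expect_equal(sum(seg$cells$count), 50)
  near <- match_to_truth(seg$cells, sp$truth$cells)
  expect_equal(sort(near), 1:50)  # one-to-one matching
  d <- sqrt((sp$truth$cells$row[near] - seg$cells$row)^2 +
              (sp$truth$cells$col[near] - seg$cells$col)^2)
  expect_lt(max(d), 3)
  # blank patch
  expect_equal(nrow(segment_cells(matrix(0, 64, 64))$cells), 0)
})

test_that("watershed splits the adherent pair and crowded mode stays close", {
  op <- make_overlapping_pair(rng_seed = 1)
  seg <- segment_cells(deconvolve(op$image)$h)
  expect_equal(nrow(seg$cells), 2)

  # crowded mode: counts within +/-10%
  for (s in 1:3) {
    sp <- make_patch(30, 0, rng_seed = s, size = 256, min_dist_factor = 1.2)
    seg <- segment_cells(deconvolve(sp$image)$h)
    expect_gte(sum(seg$cells$count), 27)
    expect_lte(sum(seg$cells$count), 33)
  }
})

test_that("mask-product positivity equals the per-pixel brute force", {
  for (s in 1:3) {
    sp <- make_patch(35, 0.4, 1, 0.7, rng_seed = s, size = 256)
    dm <- extract_dab_mask(sp$image)
    seg <- measure_rings(segment_cells(deconvolve(sp$image)$h), dm)
    brute <- positivity_brute(seg$cell_label_image, dm)
    expect_identical(seg$cells$dab_overlap[order(seg$cells$label)], brute)
  }
})

test_that("ring coverage tracks membrane completeness", {
  sp <- make_patch(30, 1, 1, 0.8, rng_seed = 4, size = 256)
  dm <- extract_dab_mask(sp$image)
  seg <- measure_rings(segment_cells(deconvolve(sp$image)$h), dm)
  expect_true(all(seg$cells$ring_dab_fraction >= 0.9))

  sp <- make_patch(30, 1, 0.5, 0.8, rng_seed = 4, size = 256)
  dm <- extract_dab_mask(sp$image)
  seg <- measure_rings(segment_cells(deconvolve(sp$image)$h), dm)
  expect_true(all(seg$cells$ring_dab_fraction >= 0.35))
  expect_true(all(seg$cells$ring_dab_fraction <= 0.65))

  # empty DAB mask -> zero coverage, no positivity
  seg0 <- measure_rings(segment_cells(deconvolve(sp$image)$h),
                        matrix(FALSE, 256, 256))
  expect_true(all(seg0$cells$ring_dab_fraction == 0))
  expect_false(any(seg0$cells$dab_overlap))
})
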