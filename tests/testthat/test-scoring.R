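# Feature computation, aggregation, interval classification, and the
# guideline rule engine.

make_cells <- function(n, n_pos, n_complete) {
  tibble::tibble(
    label = seq_len(n),
    count = 1,
    dab_overlap = seq_len(n) <= n_pos,
    ring_dab_fraction = ifelse(seq_len(n) <= n_complete, 0.95,
                               ifelse(seq_len(n) <= n_pos, 0.4, 0))
  )
}

test_that("patch_features counts ratios directly", {
  f <- patch_features(make_cells(10, 3, 2), intensity = 0.2)
  expect_equal(f$positive_cell_ratio, 0.3)
  expect_equal(f$circumferential_ratio, 2 / 3)
  expect_equal(f$n_cells, 10)
  expect_false(f$low_confidence)

  f0 <- patch_features(make_cells(0, 0, 0), intensity = 0.5)
  expect_equal(f0$positive_cell_ratio, 0)
  expect_equal(f0$circumferential_ratio, 0)
  expect_true(f0$low_confidence)
  expect_equal(f0$staining_intensity, 0.5)
})

test_that("patch feature recovery matches generator truth", {
  sp <- make_patch(40, 0.5, 1, 0.8, rng_seed = 6, size = 256)
  m <- measure_patch(sp$image)
  expect_equal(m$features$positive_cell_ratio, 0.5, tolerance = 0.05)
  expect_equal(m$features$circumferential_ratio, 1, tolerance = 0.05)
})

test_that("aggregate_slide weights ratios by cell count", {
  one <- patch_features(make_cells(10, 5, 5), 0.3)
  expect_equal(aggregate_slide(one)$positive_cell_ratio, 0.5)

  two <- dplyr::bind_rows(
    patch_features(make_cells(10, 2, 0), 0.1),
    patch_features(make_cells(10, 4, 0), 0.3)
  )
  a <- aggregate_slide(two)
  expect_equal(a$positive_cell_ratio, 0.3)  # equal counts -> plain mean
  expect_equal(a$staining_intensity, 0.2)

  wt <- dplyr::bind_rows(
    patch_features(make_cells(10, 1, 0), 0.1),
    patch_features(make_cells(30, 15, 0), 0.1)
  )
  expect_equal(aggregate_slide(wt)$positive_cell_ratio, 16 / 40)

  # zero-cell tiles are excluded from ratio means, kept in intensity
  mix <- dplyr::bind_rows(
    patch_features(make_cells(0, 0, 0), 0.4),
    patch_features(make_cells(10, 10, 0), 0.2)
  )
  a2 <- aggregate_slide(mix)
  expect_equal(a2$positive_cell_ratio, 1)
  expect_equal(a2$staining_intensity, 0.3)

  expect_error(aggregate_slide(NULL), "no tumor tiles")
})

test_that("the default threshold table yields valid midpoint boundaries", {
  tab <- threshold_table()
  expect_equal(nrow(tab), 12)
  b <- decision_boundaries(tab)
  staining <- b$boundary[b$index == "staining"]
  expect_equal(staining, c((0.008 + 0.006) / 2, (0.189 + 0.146) / 2,
                           (0.367 + 0.541) / 2))
  for (ix in unique(b$index)) {
    expect_false(is.unsorted(b$boundary[b$index == ix], strictly = TRUE))
  }
  # malformed tables are rejected
  bad <- tibble::tibble(class = c("0", "1+", "2+", "3+"),
                        min = c(0.5, 0.1, 0.2, 0.3),
                        max = c(0.6, 0.15, 0.25, 0.35))
  expect_error(threshold_table(staining = bad), "non-decreasing")
})

test_that("staining-only classification brackets the intervals", {
  sf <- function(x) tibble::tibble(staining_intensity = x,
                                   positive_cell_ratio = 0,
                                   circumferential_ratio = 0, n_tiles = 1)
  expect_equal(as.character(classify_staining_only(sf(0))$ihc_class), "0")
  expect_equal(as.character(classify_staining_only(sf(0.58))$ihc_class), "3+")
  expect_equal(as.character(classify_staining_only(sf(0.2))$ihc_class), "2+")
  # boundary assigns upward
  expect_equal(as.character(classify_staining_only(sf(0.454))$ihc_class), "3+")
})

test_that("integrated classification takes the median ordinal vote", {
  sf <- tibble::tibble(staining_intensity = 0.58,
                       positive_cell_ratio = 0.30,
                       circumferential_ratio = 0.80, n_tiles = 4)
  sc <- classify_integrated(sf)
  expect_equal(as.character(sc$ihc_class), "3+")
  expect_equal(sc$her2_status, "Positive")
  expect_false(sc$ish_reflex)

  # votes (1+, 2+, 2+) -> 2+ with reflex flag
  sf2 <- tibble::tibble(staining_intensity = 0.05,
                        positive_cell_ratio = 0.2,
                        circumferential_ratio = 0.5, n_tiles = 4)
  sc2 <- classify_integrated(sf2)
  expect_equal(as.character(sc2$ihc_class), "2+")
  expect_match(sc2$her2_status, "Equivocal")
  expect_true(sc2$ish_reflex)

  sf0 <- tibble::tibble(staining_intensity = 0, positive_cell_ratio = 0,
                        circumferential_ratio = 0, n_tiles = 1)
  sc0 <- classify_integrated(sf0)
  expect_equal(as.character(sc0$ihc_class), "0")
  expect_equal(sc0$her2_status, "Negative")

  expect_named(tidy(sc2), c("index", "value", "vote"))
  expect_equal(glance(sc2)$ihc_class, "2+")
})

test_that("integrated classification is monotone in each feature", {
  base <- tibble::tibble(staining_intensity = 0.2, positive_cell_ratio = 0.2,
                         circumferential_ratio = 0.5, n_tiles = 1)
  rank_of <- function(sf) match(as.character(classify_integrated(sf)$ihc_class),
                                c("0", "1+", "2+", "3+"))
  r0 <- rank_of(base)
  for (col in c("staining_intensity", "positive_cell_ratio",
                "circumferential_ratio")) {
    for (delta in c(0.1, 0.3, 0.5)) {
      up <- base
      up[[col]] <- min(1, up[[col]] + delta)
      expect_gte(rank_of(up), r0)
    }
  }
})

test_that("the rule engine reproduces the guideline truth table", {
  expect_equal(as.character(apply_csco_rules(0.11, 0, TRUE)), "3+")
  expect_equal(as.character(apply_csco_rules(0.10, 0, TRUE)), "2+")
  expect_equal(as.character(apply_csco_rules(0.09, 0, TRUE)), "2+")
  expect_equal(as.character(apply_csco_rules(0, 0.40, TRUE)), "1+")
  expect_equal(as.character(apply_csco_rules(0, 0.05, TRUE)), "0")
  expect_equal(as.character(apply_csco_rules(0, 0, FALSE)), "0")
  expect_equal(as.character(apply_csco_rules(0, 0, TRUE, percent_moderate = 0.2)),
               "2+")

  # exhaustive grid against the hand-coded independent reading
  grid <- expand.grid(complete = seq(0, 1, by = 0.01),
                      weak = seq(0, 1, by = 0.05))
  got <- as.character(apply_csco_rules(grid$complete, grid$weak, TRUE))
  want <- mapply(csco_brute, grid$complete, grid$weak,
                 MoreArgs = list(any_staining = TRUE))
  expect_identical(got, unname(want))
})
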