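# Synthetic IHC patch and slide generator with exact ground truth.
#
# Staining follows the Beer-Lambert forward model: each pixel carries
# per-stain optical densities (hematoxylin for nuclei and a faint tissue
# wash, DAB for membrane arcs) and is rendered as transmitted light
# I_c = round(255 * 10^(-sum_s OD_s * v_s[c])). Membrane arcs are annuli
# whose stained angular fraction ("completeness") is controlled per cell,
# which is what distinguishes complete circumferential staining (3+) from
# incomplete staining (1+/2+).

GEOM_DEFAULTS <- list(
  nucleus_axes_range = c(4, 5),   # semi-axes sampled uniformly, px
  membrane_radius = 9,            # px; ~4.5 um at 0.5 um/px
  membrane_width = 4,             # px; apparent DAB membrane thickness
  nucleus_od = 0.6,               # peak hematoxylin OD in nuclei
  wash_od = 0.25,                 # hematoxylin wash over tissue stroma
  min_dist_factor = 2.5           # min center separation / membrane radius
)

#' Compose an RGB image from per-stain optical-density maps
#'
#' Beer--Lambert forward model: per channel,
#' `I = round(255 * 10^-(od_h * v_h + od_dab * v_dab))`, quantized half-up
#' to 8 bits. This is the exact inverse of [deconvolve()] up to
#' quantization and serves as its round-trip oracle.
#'
#' @param od_h_map,od_dab_map equal-shaped non-negative matrices of stain
#'   optical densities.
#' @param vectors [stain_vectors()] basis.
#' @param od_residual_map optional third concentration map.
#' @returns [rgb_image] of the same shape.
#' @examples
#' img <- compose_from_od(matrix(0.5, 8, 8), matrix(0, 8, 8))
#' @export
compose_from_od <- function(od_h_map, od_dab_map, vectors = stain_vectors(),
                            od_residual_map = NULL) {
  if (!identical(dim(od_h_map), dim(od_dab_map))) {
    stop("optical-density maps must have identical shapes", call. = FALSE)
  }
  if (min(od_h_map) < 0 || min(od_dab_map) < 0) {
    stop("optical densities must be non-negative", call. = FALSE)
  }
  d <- dim(od_h_map)
  out <- array(0L, c(d, 3L))
  for (ch in 1:3) {
    od <- od_h_map * vectors$hematoxylin[ch] + od_dab_map * vectors$dab[ch]
    if (!is.null(od_residual_map)) {
      od <- od + od_residual_map * vectors$residual[ch]
    }
    out[, , ch] <- pmin(255, pmax(0, round_half_up(255 * 10^(-od))))
  }
  rgb_image(out)
}

# Staining intensity (1 - luma/255) of a pure-DAB pixel at OD `d`,
# without 8-bit quantization.
dab_intensity_closed_form <- function(d, vectors = stain_vectors()) {
  i <- 255 * 10^(-d * vectors$dab)
  1 - (0.299 * i[1] + 0.587 * i[2] + 0.114 * i[3]) / 255
}

#' DAB optical density producing a target staining intensity
#'
#' Inverts the monotone map from membrane DAB optical density to the
#' staining-intensity index (mean `1 - luma/255` over stained pixels)
#' under the Beer--Lambert composition model.
#'
#' @param target desired staining intensity in \[0, ~0.75\].
#' @param vectors [stain_vectors()] basis.
#' @returns Scalar optical density (0 when `target <= 0`).
#' @export
dab_od_for_intensity <- function(target, vectors = stain_vectors()) {
  if (target <= 0) return(0)
  upper <- 4
  if (target >= dab_intensity_closed_form(upper, vectors)) {
    stop("target staining intensity out of reachable range", call. = FALSE)
  }
  uniroot(
    function(d) dab_intensity_closed_form(d, vectors) - target,
    interval = c(1e-9, upper), tol = 1e-9
  )$root
}

# Rejection-sample `n` centers with minimum pairwise distance `min_dist`.
# `accept` tests candidate (row, col) admissibility (0-based coords).
place_centers <- function(n, size_r, size_c, margin, min_dist,
                          accept = NULL, max_attempts = 400L) {
  rows <- numeric(n)
  cols <- numeric(n)
  if (n == 0L) return(cbind(row = rows, col = cols))
  for (i in seq_len(n)) {
    placed <- FALSE
    for (a in seq_len(max_attempts)) {
      r <- runif(1, margin, size_r - 1 - margin)
      cc <- runif(1, margin, size_c - 1 - margin)
      if (!is.null(accept) && !accept(r, cc)) next
      if (i > 1L) {
        d2 <- (rows[seq_len(i - 1L)] - r)^2 + (cols[seq_len(i - 1L)] - cc)^2
        if (min(d2) < min_dist^2) next
      }
      rows[i] <- r
      cols[i] <- cc
      placed <- TRUE
      break
    }
    if (!placed) {
      stop("patch too crowded: could not place cell ", i, " of ", n,
           call. = FALSE)
    }
  }
  cbind(row = rows, col = cols)
}

# Render one cell onto OD maps and the label image (all modified by
# reference semantics: returns updated list). Coordinates are 0-based.
render_cell <- function(maps, cell, geom) {
  rr <- cell$row
  cc <- cell$col
  rad <- cell$membrane_radius + geom$membrane_width / 2
  ext <- ceiling(rad) + 1L
  d <- dim(maps$od_h)
  r_idx <- max(1L, floor(rr + 1 - ext)):min(d[1], ceiling(rr + 1 + ext))
  c_idx <- max(1L, floor(cc + 1 - ext)):min(d[2], ceiling(cc + 1 + ext))
  # 0-based pixel coordinates of the local window
  gr <- outer(r_idx - 1, rep(1, length(c_idx)))
  gc <- outer(rep(1, length(r_idx)), c_idx - 1)
  dr <- gr - rr
  dc <- gc - cc
  rho <- sqrt(dr^2 + dc^2)

  # nucleus ellipse (axis-aligned)
  in_nuc <- (dr / cell$nucleus_a)^2 + (dc / cell$nucleus_b)^2 <= 1
  maps$od_h[r_idx, c_idx][in_nuc] <- geom$nucleus_od

  # membrane annulus arc; the stained arc displaces the stroma wash so
  # membrane pixels carry pure DAB (a blue underlay would rotate faint
  # brown out of any hue gate)
  if (cell$dab_od > 0 && cell$membrane_completeness > 0) {
    w2 <- geom$membrane_width / 2
    in_ring <- rho >= cell$membrane_radius - w2 & rho < cell$membrane_radius + w2
    theta <- (atan2(dr, dc) - cell$arc_start) %% (2 * pi)
    in_arc <- theta <= cell$membrane_completeness * 2 * pi
    maps$od_dab[r_idx, c_idx][in_ring & in_arc] <- cell$dab_od
    maps$od_h[r_idx, c_idx][in_ring & in_arc] <- 0
  }

  # cell footprint label, nearest-center wins on overlap
  in_disk <- rho <= rad
  sub <- maps$labels[r_idx, c_idx]
  old <- sub[in_disk]
  take <- old == 0L
  clash <- which(!take)
  if (length(clash)) {
    oc <- maps$centers[old[clash], , drop = FALSE]
    d_old <- (gr[in_disk][clash] - oc[, 1])^2 + (gc[in_disk][clash] - oc[, 2])^2
    take[clash] <- rho[in_disk][clash]^2 < d_old
  }
  vals <- old
  vals[take] <- cell$label
  sub[in_disk] <- vals
  maps$labels[r_idx, c_idx] <- sub
  maps
}

make_cells_tibble <- function(centers, geom, n_pos, n_complete = n_pos,
                              completeness, dab_od, incomplete_value = 0.5) {
  n <- nrow(centers)
  if (n == 0L) {
    return(tibble::tibble(
      label = integer(), row = numeric(), col = numeric(),
      nucleus_a = numeric(), nucleus_b = numeric(),
      membrane_radius = numeric(), membrane_completeness = numeric(),
      dab_od = numeric(), arc_start = numeric(), is_positive = logical()
    ))
  }
  axes_a <- runif(n, GEOM_DEFAULTS$nucleus_axes_range[1],
                  GEOM_DEFAULTS$nucleus_axes_range[2])
  axes_b <- runif(n, GEOM_DEFAULTS$nucleus_axes_range[1],
                  GEOM_DEFAULTS$nucleus_axes_range[2])
  pos <- sort(sample.int(n, n_pos))
  comp <- if (n_pos > 0) pos[sort(sample.int(n_pos, n_complete))] else integer()
  completeness_vec <- rep(0, n)
  completeness_vec[pos] <- incomplete_value
  completeness_vec[comp] <- completeness
  dab_vec <- rep(0, n)
  dab_vec[pos] <- dab_od
  tibble::tibble(
    label = seq_len(n),
    row = centers[, 1],
    col = centers[, 2],
    nucleus_a = axes_a,
    nucleus_b = axes_b,
    membrane_radius = geom$membrane_radius,
    membrane_completeness = completeness_vec,
    dab_od = dab_vec,
    arc_start = runif(n, 0, 2 * pi),
    is_positive = dab_vec > 0 & completeness_vec > 0
  )
}

render_truth <- function(cells, size_r, size_c, geom, wash_mask = NULL) {
  maps <- list(
    od_h = matrix(0, size_r, size_c),
    od_dab = matrix(0, size_r, size_c),
    labels = matrix(0L, size_r, size_c),
    centers = as.matrix(cells[, c("row", "col")])
  )
  if (!is.null(wash_mask)) maps$od_h[wash_mask] <- geom$wash_od
  for (i in seq_len(nrow(cells))) {
    maps <- render_cell(maps, as.list(cells[i, ]), geom)
  }
  maps
}

#' Generate a synthetic IHC patch with exact ground truth
#'
#' Places `n_cells` non-overlapping cells (hematoxylin nucleus plus, for
#' positive cells, a DAB membrane arc) on a white background and renders
#' them through the Beer--Lambert model. Exactly
#' `round(n_cells * positive_fraction)` cells are DAB-positive.
#'
#' @param n_cells number of cells (>= 0).
#' @param positive_fraction fraction of cells carrying a DAB membrane arc.
#' @param completeness stained fraction of the membrane circumference of
#'   positive cells, in \[0, 1\].
#' @param dab_od peak DAB optical density of stained membrane pixels.
#' @param rng_seed integer seed; identical arguments and seed give
#'   bit-identical output.
#' @param size patch side in pixels (>= 64).
#' @param wash_od hematoxylin OD of a faint tissue wash over the whole
#'   patch; 0 (default) leaves the background pure white.
#' @param min_dist_factor minimum center separation as a multiple of the
#'   membrane radius (default 2; use 1.2 for the crowded mode).
#' @param vectors [stain_vectors()] used for rendering.
#' @param max_attempts rejection-sampling attempts per cell before the
#'   layout is rejected as too crowded.
#' @returns Object of class `synthetic_patch`: list with `image`
#'   ([rgb_image]) and `truth` (cells tibble, `cell_label_image`,
#'   `tissue_mask`, OD maps, `dab_mask`, `rng_seed`, `target_class`).
#' @examples
#' sp <- make_patch(10, positive_fraction = 0.5, completeness = 1,
#'                  dab_od = 0.8, rng_seed = 1, size = 128)
#' sum(sp$truth$cells$is_positive)
#' @export
make_patch <- function(n_cells, positive_fraction = 0, completeness = 1,
                       dab_od = 0.8, rng_seed = 1L, size = 256L,
                       wash_od = 0, min_dist_factor = GEOM_DEFAULTS$min_dist_factor,
                       vectors = stain_vectors(), max_attempts = 400L) {
  stopifnot(n_cells >= 0, size >= 64,
            positive_fraction >= 0, positive_fraction <= 1,
            completeness >= 0, completeness <= 1, dab_od >= 0)
  geom <- GEOM_DEFAULTS
  withr::with_seed(as.integer(rng_seed), {
    margin <- geom$membrane_radius + geom$membrane_width / 2 + 1
    centers <- place_centers(
      n_cells, size, size, margin,
      min_dist = min_dist_factor * geom$membrane_radius,
      max_attempts = max_attempts
    )
    n_pos <- round_half_up(n_cells * positive_fraction)
    cells <- make_cells_tibble(centers, geom, n_pos,
                               completeness = completeness, dab_od = dab_od)
    wash <- if (wash_od > 0) matrix(TRUE, size, size) else NULL
    geom$wash_od <- if (wash_od > 0) wash_od else geom$wash_od
    maps <- render_truth(cells, size, size, geom, wash_mask = wash)
    img <- compose_from_od(maps$od_h, maps$od_dab, vectors)
    tissue <- if (wash_od > 0) matrix(TRUE, size, size) else maps$labels > 0L
    structure(
      list(
        image = img,
        truth = list(
          cells = cells,
          cell_label_image = maps$labels,
          tissue_mask = binary_mask(tissue),
          od_h = maps$od_h,
          od_dab = maps$od_dab,
          dab_mask = maps$od_dab > 0,
          target_class = NA_character_,
          rng_seed = as.integer(rng_seed)
        )
      ),
      class = "synthetic_patch"
    )
  })
}

#' Two overlapping cells for watershed testing
#'
#' Places two enlarged adherent cells whose centers sit `1.2 *
#' membrane_radius` apart, so the thresholded nuclei fuse into one blob
#' that distance-transform watershed must split into two instances.
#'
#' @param rng_seed integer seed.
#' @param size patch side in pixels.
#' @param dab_od peak DAB optical density of the membranes.
#' @returns `synthetic_patch` object with two cells.
#' @export
make_overlapping_pair <- function(rng_seed = 1L, size = 96L, dab_od = 0.8) {
  geom <- GEOM_DEFAULTS
  withr::with_seed(as.integer(rng_seed), {
    sep <- 1.2 * geom$membrane_radius
    mid <- (size - 1) / 2
    ang <- runif(1, 0, 2 * pi)
    centers <- rbind(
      c(mid + sin(ang) * sep / 2, mid + cos(ang) * sep / 2),
      c(mid - sin(ang) * sep / 2, mid - cos(ang) * sep / 2)
    )
    colnames(centers) <- c("row", "col")
    cells <- tibble::tibble(
      label = 1:2,
      row = centers[, 1],
      col = centers[, 2],
      nucleus_a = 6, nucleus_b = 6,
      membrane_radius = geom$membrane_radius,
      membrane_completeness = 1,
      dab_od = dab_od,
      arc_start = runif(2, 0, 2 * pi),
      is_positive = dab_od > 0
    )
    maps <- render_truth(cells, size, size, geom)
    img <- compose_from_od(maps$od_h, maps$od_dab)
    structure(
      list(
        image = img,
        truth = list(
          cells = cells,
          cell_label_image = maps$labels,
          tissue_mask = binary_mask(maps$labels > 0L),
          od_h = maps$od_h,
          od_dab = maps$od_dab,
          dab_mask = maps$od_dab > 0,
          target_class = NA_character_,
          rng_seed = as.integer(rng_seed)
        )
      ),
      class = "synthetic_patch"
    )
  })
}

# Per-class sampling sub-intervals for the slide generator. Each range lies
# strictly inside the default threshold-table interval for the class and
# inside the midpoint decision cell, so generated slides are recoverable by
# the default interval classifier (the printed intervals for the positive
# and circumferential ratios overlap between adjacent classes, so sampling
# the full interval would make some slides inherently ambiguous).
class_target_ranges <- function(class_label, staining_ambiguous = FALSE) {
  r <- switch(class_label,
    "0"  = list(s = c(0, 0),          p = c(0, 0),        cr = c(0, 0)),
    "1+" = list(s = c(0.09, 0.15),    p = c(0.04, 0.11),  cr = c(0.05, 0.33)),
    "2+" = list(s = c(0.20, 0.35),    p = c(0.15, 0.23),  cr = c(0.47, 0.58)),
    "3+" = list(s = c(0.545, 0.605),  p = c(0.26, 0.33),  cr = c(0.62, 0.88)),
    stop("unknown class label: ", class_label, call. = FALSE)
  )
  if (staining_ambiguous && class_label %in% c("2+", "3+")) {
    # straddles the 2+/3+ staining decision boundary (0.454): the staining
    # index alone cannot separate the classes on this fixture, while the
    # two cell-ratio indexes remain class-typical.
    r$s <- c(0.40, 0.50)
  }
  r
}

#' Generate a synthetic multi-level IHC slide with ground truth
#'
#' Emits a level-0 raster plus 2x-downsampled pyramid levels. Tissue
#' occupies one irregular elliptical blob per tile on a white background;
#' per-tile cell parameters are sampled so the slide's aggregate staining
#' intensity, positive-cell ratio, and circumferential-membrane cell ratio
#' fall inside the default per-class threshold intervals for
#' `class_label`.
#'
#' @param class_label target IHC class: `"0"`, `"1+"`, `"2+"` or `"3+"`.
#' @param n_tiles number of scoring tiles carrying tissue (>= 1).
#' @param rng_seed integer seed.
#' @param tile_px scoring-tile side at level 0 (default 512).
#' @param cells_per_tile cells placed in each tissue blob.
#' @param tissue_fraction approximate tissue area fraction per tile.
#' @param n_levels number of pyramid levels (level k is `2^k`-downsampled).
#' @param staining_ambiguous draw 2+/3+ staining targets straddling the
#'   2+/3+ staining boundary, making the staining index uninformative while
#'   the cell-ratio indexes stay class-typical (used to contrast
#'   staining-only and integrated scoring).
#' @param truth_only skip rendering and return only the ground truth
#'   (fast; for generator-contract checks).
#' @param vectors [stain_vectors()] used for rendering.
#' @returns Object of class `synthetic_slide`: list with `levels` (list of
#'   [rgb_image], absent when `truth_only`) and `truth` (cells tibble with
#'   level-0 coordinates, `cell_label_image`, `tissue_mask`, `target_class`,
#'   `targets`, realized `aggregate`, `dab_od`, `rng_seed`).
#' @examples
#' sl <- make_slide("3+", n_tiles = 1, rng_seed = 1, tile_px = 256,
#'                  cells_per_tile = 20)
#' sl$truth$aggregate
#' @export
make_slide <- function(class_label = c("0", "1+", "2+", "3+"), n_tiles = 4L,
                       rng_seed = 1L, tile_px = 512L, cells_per_tile = 80L,
                       tissue_fraction = 0.55, n_levels = 3L,
                       staining_ambiguous = FALSE, truth_only = FALSE,
                       vectors = stain_vectors()) {
  class_label <- match.arg(class_label)
  stopifnot(n_tiles >= 1)
  geom <- GEOM_DEFAULTS
  withr::with_seed(as.integer(rng_seed), {
    rg <- class_target_ranges(class_label, staining_ambiguous)
    s_target <- runif(1, rg$s[1], rg$s[2])
    p_target <- runif(1, rg$p[1], rg$p[2])
    c_target <- runif(1, rg$cr[1], rg$cr[2])
    dab <- dab_od_for_intensity(s_target, vectors)

    tps <- ceiling(sqrt(n_tiles))
    side <- tps * tile_px
    tiles <- tibble::tibble(
      tile = seq_len(n_tiles),
      row0 = (( seq_len(n_tiles) - 1L) %/% tps) * tile_px,
      col0 = (( seq_len(n_tiles) - 1L) %% tps) * tile_px
    )

    blob_r <- tile_px * sqrt(tissue_fraction / pi)
    tissue <- matrix(FALSE, side, side)
    all_cells <- list()
    margin <- geom$membrane_radius + geom$membrane_width / 2 + 1
    # Integer cell counts realizing the sampled targets. Rounding at small
    # counts can push the realized ratios outside the class intervals
    # (e.g. 4/9 complete < 0.454), so counts are clamped back into the
    # interval-consistent integer range where one exists.
    tab <- threshold_table()
    iv <- function(index) {
      r <- tab[tab$index == index & tab$class == class_label, ]
      c(r$min, r$max)
    }
    eps <- 1e-9
    n_pos <- round_half_up(cells_per_tile * p_target)
    n_complete <- 0L
    if (class_label != "0") {
      pv <- iv("positive_ratio")
      cv <- iv("circumferential")
      n_pos <- min(max(n_pos, ceiling(pv[1] * cells_per_tile - eps), 1),
                   max(floor(pv[2] * cells_per_tile + eps), 1))
      # a feasible complete-cell count needs floor(c_max*n_pos) >=
      # max(1, ceiling(c_min*n_pos)); bump n_pos within its range if not
      feasible <- function(np) {
        floor(cv[2] * np + eps) >= max(1, ceiling(cv[1] * np - eps))
      }
      hi_pos <- max(floor(pv[2] * cells_per_tile + eps), 1)
      while (!feasible(n_pos) && n_pos < hi_pos) n_pos <- n_pos + 1L
      lo_c <- max(1, ceiling(cv[1] * n_pos - eps))
      hi_c <- max(lo_c, floor(cv[2] * n_pos + eps))
      n_complete <- min(max(round_half_up(n_pos * c_target), lo_c), hi_c)
    }
    label_offset <- 0L
    gr <- outer(0:(side - 1), rep(1, side))
    gc <- outer(rep(1, side), 0:(side - 1))
    for (t in seq_len(n_tiles)) {
      ctr_r <- tiles$row0[t] + tile_px / 2 + runif(1, -0.04, 0.04) * tile_px
      ctr_c <- tiles$col0[t] + tile_px / 2 + runif(1, -0.04, 0.04) * tile_px
      ax_a <- blob_r * runif(1, 0.92, 1.05)
      ax_b <- blob_r^2 / ax_a   # keep area ~ pi * blob_r^2
      blob <- ((gr - ctr_r) / ax_a)^2 + ((gc - ctr_c) / ax_b)^2 <= 1
      tissue <- tissue | blob
      inside <- function(r, cc) {
        ((r - ctr_r) / (ax_a - margin))^2 +
          ((cc - ctr_c) / (ax_b - margin))^2 <= 1
      }
      centers <- place_centers(
        cells_per_tile, side, side, margin,
        min_dist = geom$min_dist_factor * geom$membrane_radius,
        accept = inside
      )
      cells <- make_cells_tibble(centers, geom, n_pos,
                                 n_complete = n_complete,
                                 completeness = 1, dab_od = dab)
      cells$label <- cells$label + label_offset
      cells$tile <- t
      label_offset <- label_offset + nrow(cells)
      all_cells[[t]] <- cells
    }
    cells <- dplyr::bind_rows(all_cells)

    total_pos <- sum(cells$is_positive)
    aggregate <- tibble::tibble(
      staining_intensity = if (total_pos > 0) s_target else 0,
      positive_cell_ratio = total_pos / nrow(cells),
      circumferential_ratio = if (total_pos > 0) {
        sum(cells$membrane_completeness >= 0.9 & cells$is_positive) / total_pos
      } else 0
    )

    truth <- list(
      cells = cells,
      tissue_mask = binary_mask(tissue),
      target_class = class_label,
      targets = tibble::tibble(staining_intensity = s_target,
                               positive_cell_ratio = p_target,
                               circumferential_ratio = c_target),
      aggregate = aggregate,
      dab_od = dab,
      tile_px = as.integer(tile_px),
      tiles = tiles,
      rng_seed = as.integer(rng_seed)
    )

    if (truth_only) {
      return(structure(list(levels = NULL, truth = truth),
                       class = "synthetic_slide"))
    }

    maps <- render_truth(cells, side, side, geom, wash_mask = tissue)
    truth$cell_label_image <- maps$labels
    truth$od_h <- maps$od_h
    truth$od_dab <- maps$od_dab
    truth$dab_mask <- maps$od_dab > 0
    img <- compose_from_od(maps$od_h, maps$od_dab, vectors)
    levels <- build_pyramid(img$pixels, n_levels = n_levels)
    structure(list(levels = levels, truth = truth),
              class = "synthetic_slide")
  })
}

#' Synthetic tumor / non-tumor patch set for classifier fixtures
#'
#' Tumor tiles are DAB-bearing, cell-dense and washed with faint
#' hematoxylin; non-tumor tiles are sparse and unstained. The two classes
#' are separable by color statistics by construction.
#'
#' @param n_tumor,n_normal number of tiles per class.
#' @param rng_seed integer seed.
#' @param size tile side in pixels.
#' @returns Tibble with columns `id`, `tumor` (logical) and `patch`
#'   (list-column of [rgb_image]).
#' @export
make_patch_set <- function(n_tumor = 100L, n_normal = 100L, rng_seed = 1L,
                           size = 96L) {
  withr::with_seed(as.integer(rng_seed), {
    seeds <- sample.int(.Machine$integer.max - 1L, n_tumor + n_normal)
  })
  dens <- (size / 256)^2
  make_one <- function(i) {
    withr::with_seed(seeds[i], {
      tumor <- i <= n_tumor
      if (tumor) {
        n <- sample(round(50 * dens):round(90 * dens), 1)
        make_patch(n, positive_fraction = runif(1, 0.3, 0.6),
                   completeness = 1, dab_od = runif(1, 0.5, 0.9),
                   rng_seed = seeds[i] %% 100000L, size = size,
                   wash_od = GEOM_DEFAULTS$wash_od,
                   min_dist_factor = 1.6)$image
      } else {
        n <- sample(0:max(1, round(8 * dens)), 1)
        make_patch(n, positive_fraction = 0, dab_od = 0,
                   rng_seed = seeds[i] %% 100000L, size = size)$image
      }
    })
  }
  tibble::tibble(
    id = seq_len(n_tumor + n_normal),
    tumor = seq_len(n_tumor + n_normal) <= n_tumor,
    patch = lapply(seq_len(n_tumor + n_normal), make_one)
  )
}

#' Write a synthetic patch to disk
#'
#' Writes `image.png`, a 16-bit `labels.tiff` and `truth.json` (cell table
#' and metadata) into `dir`.
#'
#' @param sp `synthetic_patch` object.
#' @param dir output directory (created if missing).
#' @returns `dir`, invisibly.
#' @export
write_synthetic_patch <- function(sp, dir) {
  stopifnot(inherits(sp, "synthetic_patch"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_patch_png(sp$image, file.path(dir, "image.png"))
  write_label_tiff(sp$truth$cell_label_image, file.path(dir, "labels.tiff"))
  jsonlite::write_json(
    list(
      cells = sp$truth$cells,
      target_class = sp$truth$target_class,
      rng_seed = sp$truth$rng_seed
    ),
    file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' Write a synthetic slide to disk
#'
#' Writes `slide.tiff` (one page per pyramid level), a 16-bit
#' `labels.tiff`, `tissue_mask.png` and `truth.json` into `dir`.
#'
#' @param sl `synthetic_slide` object (rendered, not `truth_only`).
#' @param dir output directory (created if missing).
#' @returns `dir`, invisibly.
#' @export
write_synthetic_slide <- function(sl, dir) {
  stopifnot(inherits(sl, "synthetic_slide"), !is.null(sl$levels))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_slide_tiff(sl$levels, file.path(dir, "slide.tiff"))
  write_label_tiff(sl$truth$cell_label_image, file.path(dir, "labels.tiff"))
  png::writePNG(sl$truth$tissue_mask * 1, file.path(dir, "tissue_mask.png"))
  jsonlite::write_json(
    list(
      cells = sl$truth$cells,
      target_class = sl$truth$target_class,
      targets = sl$truth$targets,
      aggregate = sl$truth$aggregate,
      tile_px = sl$truth$tile_px,
      rng_seed = sl$truth$rng_seed
    ),
    file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
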