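# Stage-3 measurement core: DAB (brown) extraction and staining intensity
# in HSV space, optical-density color deconvolution, distance-transform
# watershed cell segmentation, and membrane-ring measurement.

#' Convert an 8-bit RGB image to optical densities
#'
#' `OD = -log10(max(I, 1) / 255)` per channel (flooring at 1 avoids
#' infinities at zero intensity). Base-e is available for interop with
#' tools that use natural-log densities.
#'
#' @param img [rgb_image] or bare array.
#' @param base `"log10"` (default) or `"ln"`.
#' @returns H x W x 3 numeric array of non-negative finite densities.
#' @export
rgb_to_od <- function(img, base = c("log10", "ln")) {
  base <- match.arg(base)
  p <- img_pixels(img)
  od <- -log10(pmax(p, 1) / 255)
  if (base == "ln") od <- od * log(10)
  od
}

#' Default HSV bounds for the DAB (brown) chromogen
#'
#' Hue in degrees, saturation and value in \[0, 1\]. The low saturation
#' floor keeps faint 1+ staining detectable while pure-white background
#' (saturation 0) stays excluded.
#'
#' @param hue,sat,val length-2 numeric bounds.
#' @returns Named list of bounds.
#' @export
brown_hsv_range <- function(hue = c(8, 40), sat = c(0.08, 1),
                            val = c(0.10, 0.98)) {
  list(hue = hue, sat = sat, val = val)
}

#' Extract the DAB (brown) stain mask of a patch
#'
#' Thresholds the HSV representation inside the configured brown range,
#' then applies a morphological open and close with a 3 x 3 element to
#' suppress speckle and seal pinholes.
#'
#' @param patch 8-bit RGB patch.
#' @param hsv_range bounds from [brown_hsv_range()].
#' @param morphology apply the open+close cleanup (default `TRUE`).
#' @returns Logical mask of DAB pixels.
#' @export
extract_dab_mask <- function(patch, hsv_range = brown_hsv_range(),
                             morphology = TRUE) {
  ch <- rgb_to_hsv_channels(patch)
  m <- ch$h >= hsv_range$hue[1] & ch$h <= hsv_range$hue[2] &
    ch$s >= hsv_range$sat[1] & ch$s <= hsv_range$sat[2] &
    ch$v >= hsv_range$val[1] & ch$v <= hsv_range$val[2]
  if (morphology && any(m)) {
    k <- EBImage::makeBrush(3, "box")
    m <- from_ebi(EBImage::closing(EBImage::opening(as_ebi(m), k), k)) > 0.5
  }
  binary_mask(m, level = img_level(patch))
}

#' Staining intensity of the extracted DAB area
#'
#' Mean over mask-true pixels of `1 - gray/255` where gray is the Rec. 601
#' luma of the pixel. 0 means unstained, 1 saturated black; an empty mask
#' yields 0 (the no-DAB case).
#'
#' @param patch 8-bit RGB patch.
#' @param dab_mask logical mask from [extract_dab_mask()].
#' @returns Scalar in \[0, 1\].
#' @export
staining_intensity <- function(patch, dab_mask) {
  if (!any(dab_mask)) return(0)
  g <- luma(patch)
  mean(1 - g[dab_mask] / 255)
}

#' Separate stains by optical-density color deconvolution
#'
#' Converts the patch to OD space and multiplies each OD pixel vector by
#' the inverse stain matrix; negative concentrations (noise outside the
#' stain simplex) are floored at 0.
#'
#' @param patch 8-bit RGB patch.
#' @param vectors [stain_vectors()] basis.
#' @returns Object of class `stain_maps`: list of matrices `h`, `dab`,
#'   `residual` with the patch's shape.
#' @export
deconvolve <- function(patch, vectors = stain_vectors()) {
  od <- rgb_to_od(patch)
  d <- dim(od)
  odm <- matrix(od, d[1] * d[2], 3)
  conc <- odm %*% deconvolution_matrix(vectors)
  conc[conc < 0] <- 0
  structure(
    list(
      h = matrix(conc[, 1], d[1], d[2]),
      dab = matrix(conc[, 2], d[1], d[2]),
      residual = matrix(conc[, 3], d[1], d[2])
    ),
    class = "stain_maps"
  )
}

#' Segmentation parameters
#'
#' @param min_area minimum component area in px^2.
#' @param max_area maximum component area in px^2.
#' @param ws_tolerance watershed tolerance (minimum depth separating two
#'   objects in the distance transform).
#' @param opening_size diameter of the disc used for the pre-watershed
#'   morphological opening.
#' @param cell_expand radius (px) by which nuclei are expanded into cell
#'   regions (Voronoi-constrained growth).
#' @param clump_factor components larger than `clump_factor` x the median
#'   single-cell area are counted as multiple cells
#'   (`round(area / median area)`).
#' @returns Named list of parameters.
#' @export
segment_params <- function(min_area = 30, max_area = 5000, ws_tolerance = 1,
                           opening_size = 3, cell_expand = 5,
                           clump_factor = 3, wash_separation = 0.15) {
  list(min_area = min_area, max_area = max_area, ws_tolerance = ws_tolerance,
       opening_size = opening_size, cell_expand = cell_expand,
       clump_factor = clump_factor, wash_separation = wash_separation)
}

#' Segment cells from a hematoxylin concentration map
#'
#' Pipeline: Otsu threshold of the map's histogram, morphological opening,
#' hole filling, Euclidean distance transform, watershed, area filtering,
#' and area-based counting of unsplit clumps. Nuclei are then expanded
#' into cell regions by Voronoi-constrained growth within the dilated
#' nucleus mask.
#'
#' @param h_map hematoxylin concentration matrix (from [deconvolve()]).
#' @param params [segment_params()].
#' @returns Object of class `cell_segmentation`: list with
#'   `cell_label_image` (expanded cell regions), `nucleus_label_image`,
#'   and `cells` -- a tibble with one row per segmented instance (`label`,
#'   0-based `row`/`col` centroid, nucleus `area`, `cell_area`, and
#'   `count`, the number of cells the instance stands for after area-based
#'   clump splitting). An empty map yields zero cells.
#' @export
segment_cells <- function(h_map, params = segment_params()) {
  empty <- function() {
    structure(
      list(
        cell_label_image = matrix(0L, nrow(h_map), ncol(h_map)),
        nucleus_label_image = matrix(0L, nrow(h_map), ncol(h_map)),
        cells = tibble::tibble(
          label = integer(), row = numeric(), col = numeric(),
          area = numeric(), cell_area = numeric(), count = numeric()
        )
      ),
      class = "cell_segmentation"
    )
  }
  mx <- max(h_map)
  if (mx <= 0) return(empty())
  b <- hist256(h_map / mx)
  if (sum(b > 0) < 2L) return(empty())
  # bin b collects values rounding to b/255, so the value-space cut sits
  # half a bin above the returned threshold
  t <- (otsu_threshold(b) + 0.5) / 255 * mx
  # hierarchical second pass: on tissue with a hematoxylin stroma wash the
  # full-histogram threshold separates background from tissue, not stroma
  # from nuclei; re-threshold the upper class and accept the refinement
  # only when its two modes are separated by a clear OD gap (a plain
  # unwashed patch fails the guard and keeps the first threshold)
  sub <- h_map[h_map > t]
  if (length(sub) > 100L) {
    b2 <- hist256(sub / mx)
    if (sum(b2 > 0) >= 2L) {
      t2 <- (otsu_threshold(b2) + 0.5) / 255 * mx
      lo <- sub[sub <= t2]
      hi <- sub[sub > t2]
      if (length(lo) && length(hi) &&
          mean(hi) - mean(lo) > params$wash_separation) {
        t <- t2
      }
    }
  }
  mask <- h_map > t
  if (!any(mask)) return(empty())

  k_open <- EBImage::makeBrush(params$opening_size, "disc")
  mask <- from_ebi(EBImage::opening(as_ebi(mask), k_open)) > 0.5
  mask <- from_ebi(EBImage::fillHull(as_ebi(mask))) > 0.5
  if (!any(mask)) return(empty())

  dist <- EBImage::distmap(as_ebi(mask))
  labs <- EBImage::watershed(dist, tolerance = params$ws_tolerance, ext = 1)
  lab <- matrix(as.integer(from_ebi(labs)), nrow(h_map), ncol(h_map))

  areas <- component_areas(lab)
  keep <- which(areas >= params$min_area & areas <= params$max_area)
  if (!length(keep)) return(empty())
  relab <- integer(length(areas))
  relab[keep] <- seq_along(keep)
  lab[lab > 0L] <- relab[lab[lab > 0L]]
  areas <- areas[keep]

  med <- median(areas)
  count <- rep(1, length(areas))
  clumps <- areas > params$clump_factor * med
  count[clumps] <- round_half_up(areas[clumps] / med)

  idx <- which(lab > 0L)
  rows <- (idx - 1L) %% nrow(lab)          # 0-based
  cols <- (idx - 1L) %/% nrow(lab)
  lv <- lab[idx]
  cr <- tapply(rows, lv, mean)
  cc <- tapply(cols, lv, mean)

  # expand nuclei into cell regions
  k_exp <- EBImage::makeBrush(2L * as.integer(params$cell_expand) + 1L, "disc")
  cellmask <- from_ebi(EBImage::dilate(as_ebi(lab > 0L), k_exp)) > 0.5
  cell_lab <- EBImage::propagate(
    matrix(0, nrow(lab), ncol(lab)), as_ebi(lab), mask = cellmask
  )
  cell_lab <- matrix(as.integer(from_ebi(cell_lab)), nrow(lab), ncol(lab))
  cell_areas <- component_areas(cell_lab)

  cells <- tibble::tibble(
    label = as.integer(names(cr)),
    row = as.numeric(cr),
    col = as.numeric(cc),
    area = as.numeric(areas),
    cell_area = as.numeric(cell_areas[as.integer(names(cr))]),
    count = as.numeric(count)
  )
  structure(
    list(cell_label_image = cell_lab, nucleus_label_image = lab,
         cells = cells),
    class = "cell_segmentation"
  )
}

#' @export
print.cell_segmentation <- function(x, ...) {
  cat(sprintf("<cell_segmentation> %d instances (%g cells after clump counting)\n",
              nrow(x$cells), sum(x$cells$count)))
  invisible(x)
}

#' Measure membrane rings against the DAB mask
#'
#' For every segmented cell, builds the membrane ring (a band of width
#' `ring_width` straddling the cell-region contour) and records
#' `ring_dab_fraction = |ring intersect DAB| / |ring|` plus the
#' mask-product positivity flag `dab_overlap` (a cell is DAB-positive iff
#' its region contains at least one DAB pixel).
#'
#' @param seg `cell_segmentation` from [segment_cells()].
#' @param dab_mask logical DAB mask of the same patch.
#' @param ring_width ring thickness in pixels (default 2).
#' @returns The segmentation with `cells` gaining `ring_dab_fraction`,
#'   `ring_area` and `dab_overlap` columns.
#' @export
measure_rings <- function(seg, dab_mask, ring_width = 2) {
  stopifnot(inherits(seg, "cell_segmentation"))
  lab <- seg$cell_label_image
  if (!identical(dim(lab), dim(dab_mask))) {
    stop("`dab_mask` shape does not match the segmentation", call. = FALSE)
  }
  cells <- seg$cells
  if (nrow(cells) == 0L) {
    cells$ring_dab_fraction <- numeric()
    cells$ring_area <- numeric()
    cells$dab_overlap <- logical()
    seg$cells <- cells
    return(seg)
  }
  pos_labels <- unique(lab[lab > 0L & dab_mask])
  half_in <- ceiling(ring_width / 2)
  half_out <- floor(ring_width / 2)

  frac <- numeric(nrow(cells))
  rarea <- numeric(nrow(cells))
  h <- nrow(lab); w <- ncol(lab)
  for (i in seq_len(nrow(cells))) {
    L <- cells$label[i]
    idx <- which(lab == L)
    rr <- range((idx - 1L) %% h) + 1L
    cr <- range((idx - 1L) %/% h) + 1L
    r_idx <- max(1L, rr[1] - half_out - 1L):min(h, rr[2] + half_out + 1L)
    c_idx <- max(1L, cr[1] - half_out - 1L):min(w, cr[2] + half_out + 1L)
    m <- lab[r_idx, c_idx] == L
    din <- from_ebi(EBImage::distmap(as_ebi(m)))
    dout <- from_ebi(EBImage::distmap(as_ebi(!m)))
    band <- (m & din <= half_in) | (!m & dout <= half_out)
    rarea[i] <- sum(band)
    frac[i] <- if (rarea[i] > 0) {
      sum(band & dab_mask[r_idx, c_idx]) / rarea[i]
    } else 0
  }
  cells$ring_dab_fraction <- frac
  cells$ring_area <- rarea
  cells$dab_overlap <- cells$label %in% pos_labels
  seg$cells <- cells
  seg
}
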