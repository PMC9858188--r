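# Tissue-versus-background masking and tile enumeration. Masking runs on a
# low-resolution pyramid level: the image is converted to HSV, the H and S
# channels are thresholded by Otsu's method, the per-channel masks are
# combined (AND by default), and small components and holes are cleaned up.

#' Otsu threshold of a 256-bin histogram
#'
#' Returns the threshold `t` maximizing the between-class variance of the
#' split `bins 0..t` versus `bins (t+1)..255`; ties break to the smallest
#' `t`.
#'
#' @param counts integer vector of 256 bin counts (bin `i` holds value
#'   `i - 1`).
#' @returns Integer threshold in \[0, 254\].
#' @examples
#' h <- integer(256); h[c(11, 201)] <- 100  # mass at values 10 and 200
#' otsu_threshold(h)  # 10 by the smallest-tie rule
#' @export
otsu_threshold <- function(counts) {
  if (length(counts) != 256L) {
    stop("`counts` must have exactly 256 bins", call. = FALSE)
  }
  if (sum(counts > 0) < 2L) {
    stop("degenerate histogram: fewer than two occupied bins", call. = FALSE)
  }
  p <- counts / sum(counts)
  v <- 0:255
  w0 <- cumsum(p)[1:255]
  mu_cum <- cumsum(p * v)
  mu_total <- mu_cum[256]
  w1 <- 1 - w0
  sigma_b <- (mu_total * w0 - mu_cum[1:255])^2 / (w0 * w1)
  sigma_b[!is.finite(sigma_b)] <- -Inf
  which.max(sigma_b) - 1L
}

# 256-bin histogram of values in [0, 1].
hist256 <- function(x) {
  tabulate(pmin(255L, pmax(0L, as.integer(round_half_up(x * 255)))) + 1L,
           nbins = 256L)
}

# 8-connectivity labeling: 4-connectivity bwlabel plus a diagonal merge
# pass (union-find over the label adjacency found on the two diagonal
# shifts).
label_components <- function(mask) {
  lab <- matrix(as.integer(from_ebi(EBImage::bwlabel(as_ebi(mask)))),
                nrow(mask), ncol(mask))
  n <- max(lab)
  if (n < 2L) return(lab)
  h <- nrow(lab)
  w <- ncol(lab)
  a1 <- lab[-h, -w]; b1 <- lab[-1, -1]   # down-right diagonal
  a2 <- lab[-h, -1]; b2 <- lab[-1, -w]   # down-left diagonal
  keep1 <- a1 > 0L & b1 > 0L & a1 != b1
  keep2 <- a2 > 0L & b2 > 0L & a2 != b2
  pairs <- unique(rbind(cbind(a1[keep1], b1[keep1]),
                        cbind(a2[keep2], b2[keep2])))
  if (nrow(pairs)) {
    parent <- seq_len(n)
    find <- function(x) {
      while (parent[x] != x) {
        parent[x] <<- parent[parent[x]]
        x <- parent[x]
      }
      x
    }
    for (k in seq_len(nrow(pairs))) {
      ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
    root <- vapply(seq_len(n), find, integer(1))
    relab <- match(root, sort(unique(root)))
    lab[lab > 0L] <- relab[lab[lab > 0L]]
  }
  lab
}

component_areas <- function(lab) {
  if (max(lab) == 0L) return(integer(0))
  tabulate(lab[lab > 0L], nbins = max(lab))
}

#' Tissue mask from HSV per-channel Otsu thresholds
#'
#' Converts the image to HSV, thresholds the H and S channels independently
#' with [otsu_threshold()], keeps the side of each threshold whose pixels
#' have the higher mean saturation (white background has near-zero
#' saturation regardless of hue), combines the two channel masks, then
#' removes small components and fills small holes (both below
#' `min_component_frac` of the mask/tissue area, 8-connectivity).
#'
#' @param img low-resolution [rgb_image] (or bare array).
#' @param combine `"and"` (default) or `"or"` combination of the H and S
#'   channel masks.
#' @param min_component_frac components (and holes) smaller than this
#'   fraction of the mask area are removed (filled).
#' @returns Logical mask ([binary_mask]) at the image's level. An
#'   all-background image yields an empty mask with a warning.
#' @export
tissue_mask <- function(img, combine = c("and", "or"),
                        min_component_frac = 0.001) {
  combine <- match.arg(combine)
  ch <- rgb_to_hsv_channels(img)
  channel_mask <- function(values) {
    b <- hist256(values)
    if (sum(b > 0) < 2L) return(NULL)
    t <- otsu_threshold(b)
    hi <- round_half_up(values * 255) > t
    s_hi <- mean(ch$s[hi])
    s_lo <- mean(ch$s[!hi])
    if (isTRUE(s_hi >= s_lo) || !any(!hi)) hi else !hi
  }
  m_h <- channel_mask(ch$h / 360)
  m_s <- channel_mask(ch$s)
  if (is.null(m_h) && is.null(m_s)) {
    warning("degenerate H and S histograms: all-background slide")
    return(binary_mask(matrix(FALSE, nrow(ch$s), ncol(ch$s)),
                       level = img_level(img)))
  }
  mask <- if (is.null(m_h)) m_s
    else if (is.null(m_s)) m_h
    else if (combine == "and") m_h & m_s
    else m_h | m_s

  if (any(mask)) {
    # drop small components
    lab <- label_components(mask)
    areas <- component_areas(lab)
    small <- which(areas < min_component_frac * sum(mask))
    if (length(small)) mask[lab %in% small] <- FALSE
    # fill small interior holes (brown membrane pixels fall on the
    # background side of the H-channel threshold and would otherwise
    # puncture the tissue interior)
    if (any(mask)) {
      hole_lab <- label_components(!mask)
      if (max(hole_lab) > 0L) {
        border_labs <- unique(c(hole_lab[1, ], hole_lab[nrow(mask), ],
                                hole_lab[, 1], hole_lab[, ncol(mask)]))
        hole_areas <- component_areas(hole_lab)
        fill <- setdiff(which(hole_areas < min_component_frac * sum(mask)),
                        border_labs)
        if (length(fill)) mask[hole_lab %in% fill] <- TRUE
      }
    }
  }
  binary_mask(mask, level = img_level(img))
}

#' Pick the masking level of a pyramid
#'
#' Returns the index (1-based position in `levels`) of the
#' highest-resolution level whose longest side does not exceed
#' `max_side`; falls back to the smallest level.
#'
#' @param levels list of [rgb_image] pyramid levels.
#' @param max_side maximum allowed longest side in pixels.
#' @returns Integer index into `levels`.
#' @export
masking_level <- function(levels, max_side = 2048L) {
  sides <- vapply(levels, function(l) max(dim(l$pixels)[1:2]), numeric(1))
  ok <- which(sides <= max_side)
  if (length(ok)) min(ok) else length(levels)
}

#' Enumerate tissue-bearing tiles on a mask
#'
#' Lays a non-overlapping grid of `tile_size` x `tile_size` level-0 tiles
#' (0-based, half-open, row-major) over the mask and keeps tiles whose
#' tissue fraction reaches `min_tissue_fraction`. Only full tiles are
#' enumerated.
#'
#' @param mask logical tissue mask (its `downsample` attribute relates it
#'   to level 0; default 1).
#' @param tile_size tile side in level-0 pixels; must be divisible by the
#'   mask's downsample factor.
#' @param min_tissue_fraction minimum fraction of tissue pixels per tile.
#' @returns Tibble of class `tile_grid` with columns `row0`, `col0`
#'   (level-0 pixel coordinates of the tile's top-left corner) and
#'   `tissue_fraction`; attributes `tile_size`, `n_tile_rows`,
#'   `n_tile_cols`.
#' @export
enumerate_tiles <- function(mask, tile_size, min_tissue_fraction = 0.25) {
  ds <- mask_downsample(mask)
  if (tile_size %% ds != 0L) {
    stop("`tile_size` must be divisible by the mask's downsample factor",
         call. = FALSE)
  }
  ts <- tile_size %/% ds
  n_r <- nrow(mask) %/% ts
  n_c <- ncol(mask) %/% ts
  if (n_r == 0L || n_c == 0L || !any(mask)) {
    out <- tibble::tibble(row0 = integer(), col0 = integer(),
                          tissue_fraction = numeric())
  } else {
    m <- mask[seq_len(n_r * ts), seq_len(n_c * ts), drop = FALSE] * 1
    block <- rowsum(m, rep(seq_len(n_r), each = ts))
    block <- t(rowsum(t(block), rep(seq_len(n_c), each = ts)))
    frac <- block / (ts * ts)
    keep <- which(t(frac) >= min_tissue_fraction)  # row-major order
    tile_row <- (keep - 1L) %/% n_c
    tile_col <- (keep - 1L) %% n_c
    out <- tibble::tibble(
      row0 = as.integer(tile_row * tile_size),
      col0 = as.integer(tile_col * tile_size),
      tissue_fraction = as.numeric(t(frac))[keep]
    )
  }
  structure(out,
            tile_size = as.integer(tile_size),
            n_tile_rows = as.integer(n_r),
            n_tile_cols = as.integer(n_c),
            class = c("tile_grid", class(out)))
}
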