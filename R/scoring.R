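# Stage-3 decision layer: the three evaluation indexes per tile, slide
# aggregation, interval classification against per-class thresholds, and
# the CSCO-style membrane-staining rule engine.

IHC_CLASSES <- c("0", "1+", "2+", "3+")

ihc_factor <- function(x) {
  factor(x, levels = IHC_CLASSES, ordered = TRUE)
}

her2_status_for <- function(ihc_class) {
  unname(c("0" = "Negative",
           "1+" = "Low expression",
           "2+" = "Equivocal (reflex ISH)",
           "3+" = "Positive")[as.character(ihc_class)])
}

#' Per-tile evaluation indexes
#'
#' Computes the three interpretable indexes from a measured tile:
#' * `staining_intensity` -- passed through from [staining_intensity()];
#' * `positive_cell_ratio` -- DAB-positive cells / total cells (mask-product
#'   positivity, weighted by clump counts);
#' * `circumferential_ratio` -- among positive cells, the fraction whose
#'   membrane ring is covered by DAB for at least `completeness_cutoff` of
#'   its length (complete circumferential staining).
#'
#' A tile with zero cells reports zero ratios and is flagged low
#' confidence.
#'
#' @param cells cell tibble from [measure_rings()].
#' @param intensity staining intensity of the tile in \[0, 1\].
#' @param completeness_cutoff ring coverage defining "complete" (default
#'   0.9).
#' @returns One-row tibble of class `patch_features` with the three
#'   indexes, `n_cells` and `low_confidence`.
#' @export
patch_features <- function(cells, intensity, completeness_cutoff = 0.9) {
  stopifnot(intensity >= 0, intensity <= 1)
  if (inherits(cells, "cell_segmentation")) cells <- cells$cells
  n <- if (nrow(cells)) sum(cells$count) else 0
  if (n == 0) {
    pos <- 0
    circ <- 0
  } else {
    if (is.null(cells$dab_overlap)) {
      stop("cells lack ring measurements; run measure_rings() first",
           call. = FALSE)
    }
    w_pos <- sum(cells$count[cells$dab_overlap])
    pos <- w_pos / n
    circ <- if (w_pos > 0) {
      sum(cells$count[cells$dab_overlap &
                        cells$ring_dab_fraction >= completeness_cutoff]) / w_pos
    } else 0
  }
  structure(
    tibble::tibble(
      staining_intensity = intensity,
      positive_cell_ratio = pos,
      circumferential_ratio = circ,
      n_cells = n,
      low_confidence = n == 0
    ),
    class = c("patch_features", "tbl_df", "tbl", "data.frame")
  )
}

#' Aggregate tile features to slide level
#'
#' Staining intensity is averaged over all tumor tiles; the two cell
#' ratios are cell-count-weighted means over tiles that contain cells
#' (tiles with more tumor cells carry more evidence).
#'
#' @param features tibble of per-tile features (rows from
#'   [patch_features()]).
#' @returns One-row tibble of class `slide_features` with the three
#'   aggregated indexes and `n_tiles`.
#' @export
aggregate_slide <- function(features) {
  if (is.null(features) || nrow(features) == 0L) {
    stop("no tumor tiles to aggregate", call. = FALSE)
  }
  with_cells <- features[features$n_cells > 0, , drop = FALSE]
  wmean <- function(x, w) if (sum(w) > 0) sum(x * w) / sum(w) else 0
  structure(
    tibble::tibble(
      staining_intensity = mean(features$staining_intensity),
      positive_cell_ratio = wmean(with_cells$positive_cell_ratio,
                                  with_cells$n_cells),
      circumferential_ratio = wmean(with_cells$circumferential_ratio,
                                    with_cells$n_cells),
      n_tiles = nrow(features)
    ),
    class = c("slide_features", "tbl_df", "tbl", "data.frame")
  )
}

#' Per-class threshold table for the three indexes
#'
#' Defaults are the per-class min/max statistics of the three indexes
#' measured on a single-center cohort; decision boundaries between
#' adjacent classes are midpoints of the interval gap and can be derived
#' with [decision_boundaries()]. Fully overridable for other centers.
#'
#' @param staining,positive_ratio,circumferential per-index data frames
#'   with columns `class`, `min`, `max` (one row per class, in class
#'   order). Defaults reproduce the package's built-in table.
#' @returns Tibble of class `threshold_table` with columns `index`,
#'   `class`, `min`, `max`.
#' @examples
#' threshold_table()
#' decision_boundaries(threshold_table())
#' @export
threshold_table <- function(staining = NULL, positive_ratio = NULL,
                            circumferential = NULL) {
  default <- function(mins, maxs) {
    tibble::tibble(class = IHC_CLASSES, min = mins, max = maxs)
  }
  blocks <- list(
    staining = staining %||%
      default(c(0.000, 0.006, 0.146, 0.541), c(0.008, 0.189, 0.367, 0.611)),
    positive_ratio = positive_ratio %||%
      default(c(0.000, 0.004, 0.130, 0.173), c(0.041, 0.125, 0.318, 0.338)),
    circumferential = circumferential %||%
      default(c(0.000, 0.011, 0.454, 0.461), c(0.000, 0.360, 0.741, 0.908))
  )
  tab <- dplyr::bind_rows(lapply(names(blocks), function(nm) {
    b <- tibble::as_tibble(blocks[[nm]])
    stopifnot(identical(b$class, IHC_CLASSES), all(b$max >= b$min))
    if (is.unsorted(b$min) || is.unsorted(b$max)) {
      stop("class intervals must be non-decreasing in class order",
           call. = FALSE)
    }
    dplyr::mutate(b, index = nm, .before = 1)
  }))
  bounds <- decision_boundaries_impl(tab)
  if (any(tapply(bounds$boundary, bounds$index, function(x) is.unsorted(x, strictly = TRUE)))) {
    stop("decision boundaries must be strictly increasing", call. = FALSE)
  }
  structure(tab, class = c("threshold_table", class(tibble::tibble())))
}

decision_boundaries_impl <- function(tab) {
  dplyr::bind_rows(lapply(split(tab, tab$index), function(b) {
    b <- b[match(IHC_CLASSES, b$class), ]
    tibble::tibble(
      index = b$index[1],
      transition = paste(IHC_CLASSES[-4], IHC_CLASSES[-1], sep = "->"),
      boundary = (b$max[-4] + b$min[-1]) / 2
    )
  }))
}

#' Decision boundaries derived from a threshold table
#'
#' Midpoints between the `max` of each class interval and the `min` of the
#' next, per index.
#'
#' @param table [threshold_table()].
#' @returns Tibble with columns `index`, `transition`, `boundary`.
#' @export
decision_boundaries <- function(table = threshold_table()) {
  stopifnot(inherits(table, "threshold_table"))
  decision_boundaries_impl(table)
}

# value -> class via boundaries; boundary values assign upward (>=).
classify_by_boundaries <- function(value, boundaries) {
  IHC_CLASSES[1L + vapply(value, function(v) sum(v >= boundaries), integer(1))]
}

new_slide_score <- function(ihc_class, votes, method, features) {
  structure(
    list(
      ihc_class = ihc_factor(ihc_class),
      her2_status = her2_status_for(ihc_class),
      ish_reflex = ihc_class == "2+",
      votes = votes,
      method = method,
      features = features
    ),
    class = "slide_score"
  )
}

#' @export
print.slide_score <- function(x, ...) {
  cat(sprintf("<slide_score> IHC %s -- %s [%s method]\n",
              as.character(x$ihc_class), x$her2_status, x$method))
  if (x$ish_reflex) cat("  flagged for reflex ISH testing\n")
  invisible(x)
}

#' Classify a slide from the staining index alone
#'
#' Brackets the aggregate staining intensity between the staining decision
#' boundaries; values on a boundary assign to the higher class.
#'
#' @param slide [aggregate_slide()] features (or a one-row data frame with
#'   a `staining_intensity` column).
#' @param table [threshold_table()].
#' @returns `slide_score` object (`method = "staining_only"`).
#' @export
classify_staining_only <- function(slide, table = threshold_table()) {
  b <- decision_boundaries(table)
  bs <- b$boundary[b$index == "staining"]
  cls <- classify_by_boundaries(slide$staining_intensity, bs)
  new_slide_score(cls, votes = c(staining = cls), "staining_only", slide)
}

#' Classify a slide by integrating the three indexes
#'
#' Each index votes a class through its own decision boundaries; the final
#' class is the median of the three ordinal votes (ties are impossible
#' with three voters). 2+ results carry an explicit reflex-ISH flag and
#' are never auto-resolved.
#'
#' @inheritParams classify_staining_only
#' @returns `slide_score` object (`method = "integrated"`).
#' @export
classify_integrated <- function(slide, table = threshold_table()) {
  b <- decision_boundaries(table)
  vote <- function(index, value) {
    classify_by_boundaries(value, b$boundary[b$index == index])
  }
  votes <- c(
    staining = vote("staining", slide$staining_intensity),
    positive_ratio = vote("positive_ratio", slide$positive_cell_ratio),
    circumferential = vote("circumferential", slide$circumferential_ratio)
  )
  med <- IHC_CLASSES[median(match(votes, IHC_CLASSES))]
  new_slide_score(med, votes, "integrated", slide)
}

#' CSCO-style IHC scoring rules for HER2 membrane staining
#'
#' Implements the guideline criteria on cell-population fractions:
#' * **3+** -- complete, intense circumferential membrane staining in
#'   *more than* 10% of invasive tumor cells (strict `>`);
#' * **2+** -- complete intense staining present but in at most 10% of
#'   cells, or weak-to-moderate membrane staining in more than 10%;
#' * **1+** -- faint/barely perceptible incomplete membrane staining in
#'   more than 10% of cells;
#' * **0** -- no staining, or faint incomplete staining in at most 10%.
#'
#' @param percent_complete_intense fraction of invasive tumor cells with
#'   complete, intense circumferential membrane staining, in \[0, 1\].
#' @param percent_weak_incomplete fraction with faint/barely perceptible
#'   incomplete membrane staining.
#' @param any_staining is any membrane staining present at all?
#' @param percent_moderate fraction with weak-to-moderate membrane
#'   staining (guideline 2+ clause (a)); defaults to 0.
#' @returns Ordered factor with the IHC class (`"0"`, `"1+"`, `"2+"`,
#'   `"3+"`), vectorized over the inputs.
#' @examples
#' apply_csco_rules(0.11, 0, TRUE)   # 3+
#' apply_csco_rules(0.10, 0, TRUE)   # 2+ (strict > at the 10% boundary)
#' apply_csco_rules(0, 0.40, TRUE)   # 1+
#' apply_csco_rules(0, 0, FALSE)     # 0
#' @export
apply_csco_rules <- function(percent_complete_intense,
                             percent_weak_incomplete,
                             any_staining,
                             percent_moderate = 0) {
  n <- max(length(percent_complete_intense), length(percent_weak_incomplete),
           length(any_staining), length(percent_moderate))
  pci <- rep_len(percent_complete_intense, n)
  pwi <- rep_len(percent_weak_incomplete, n)
  any_s <- rep_len(any_staining, n)
  pm <- rep_len(percent_moderate, n)
  stopifnot(all(pci >= 0 & pci <= 1), all(pwi >= 0 & pwi <= 1),
            all(pm >= 0 & pm <= 1))
  cls <- ifelse(!any_s, "0",
         ifelse(pci > 0.10, "3+",
         ifelse(pci > 0 | pm > 0.10, "2+",
         ifelse(pwi > 0.10, "1+", "0"))))
  ihc_factor(cls)
}

#' @method tidy slide_score
#' @export
tidy.slide_score <- function(x, ...) {
  tibble::tibble(
    index = c("staining", "positive_ratio", "circumferential"),
    value = c(x$features$staining_intensity,
              x$features$positive_cell_ratio,
              x$features$circumferential_ratio),
    vote = as.character(x$votes[c("staining", "positive_ratio",
                                  "circumferential")])
  )
}

#' @method glance slide_score
#' @export
glance.slide_score <- function(x, ...) {
  tibble::tibble(
    ihc_class = as.character(x$ihc_class),
    her2_status = x$her2_status,
    ish_reflex = x$ish_reflex,
    method = x$method,
    n_tiles = x$features$n_tiles %||% NA_integer_
  )
}
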