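# End-to-end slide scoring: configuration, the three-stage pipeline, and
# report/overlay artifacts.

#' Pipeline configuration
#'
#' All tunable parameters of the three stages with their defaults. The
#' configuration round-trips losslessly through YAML ([write_config()] /
#' [read_config()]); unknown keys are rejected on construction.
#'
#' @param ... named overrides of the defaults (nested lists are merged
#'   key-wise).
#' @returns List of class `her2_config`.
#' @examples
#' cfg <- her2_config(prob_threshold = 0.6)
#' cfg$prob_threshold
#' @export
her2_config <- function(...) {
  defaults <- list(
    tile_size_classify = 256L,
    tile_size_score = 512L,
    min_tissue_fraction = 0.25,
    mask_level_max_side = 2048L,
    mask_combine = "and",
    brown_hsv = brown_hsv_range(),
    stain_vectors = list(
      hematoxylin = c(0.650, 0.704, 0.286),
      dab = c(0.268, 0.570, 0.776)
    ),
    segmentation = segment_params(),
    ring_width = 2L,
    completeness_cutoff = 0.9,
    prob_threshold = 0.5,
    classifier = "heuristic",
    checkpoint = NULL,
    seed = 1L,
    version = "0.1.0"
  )
  overrides <- list(...)
  if (length(overrides) == 1L && is.null(names(overrides)) &&
      is.list(overrides[[1]])) {
    overrides <- overrides[[1]]
  }
  check_keys <- function(def, over, path = "") {
    unknown <- setdiff(names(over), names(def))
    if (length(unknown)) {
      stop("unknown config key(s): ",
           paste0(path, unknown, collapse = ", "), call. = FALSE)
    }
  }
  check_keys(defaults, overrides)
  for (nm in names(overrides)) {
    if (is.list(defaults[[nm]]) && is.list(overrides[[nm]]) &&
        !is.null(names(defaults[[nm]]))) {
      check_keys(defaults[[nm]], overrides[[nm]], paste0(nm, "$"))
      defaults[[nm]] <- modifyList(defaults[[nm]], overrides[[nm]])
    } else {
      # single-bracket list assignment keeps keys whose value is NULL
      defaults[nm] <- list(overrides[[nm]])
    }
  }
  structure(defaults, class = "her2_config")
}

config_stain_vectors <- function(config) {
  stain_vectors(config$stain_vectors$hematoxylin,
                config$stain_vectors$dab)
}

#' Write a configuration as YAML
#' @param config [her2_config()] object.
#' @param path output file.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "her2_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read a configuration from YAML
#'
#' Unknown keys in the file are rejected.
#'
#' @param path YAML file written by [write_config()] (or hand-authored).
#' @returns [her2_config()] object.
#' @export
read_config <- function(path) {
  her2_config(yaml::read_yaml(path))
}

#' Compute the three indexes of one scoring tile
#'
#' Measurement core for a single tile: DAB mask and staining intensity,
#' color deconvolution, cell segmentation, ring measurement, and the
#' per-tile feature row.
#'
#' @param tile RGB tile (array or [rgb_image]).
#' @param config [her2_config()].
#' @returns One-row [patch_features()] tibble.
#' @export
score_tile <- function(tile, config = her2_config()) {
  sv <- config_stain_vectors(config)
  dab <- extract_dab_mask(tile, config$brown_hsv)
  intensity <- staining_intensity(tile, dab)
  maps <- deconvolve(tile, sv)
  seg <- segment_cells(maps$h, config$segmentation)
  seg <- measure_rings(seg, dab, config$ring_width)
  patch_features(seg$cells, intensity, config$completeness_cutoff)
}

#' Score a slide end to end
#'
#' Runs the three stages on a slide: tissue masking on a low-resolution
#' level, tumor-tile detection with the configured classifier backend,
#' per-tile index measurement on tumor tiles, aggregation, and both the
#' staining-only and integrated classifications. Optionally writes a JSON
#' report, a per-tile feature CSV, a tumor-probability heatmap overlay and
#' stain/cell overlays for the highest-cellularity tiles.
#'
#' @param slide a `synthetic_slide`, a list of pyramid [rgb_image] levels,
#'   or a path to a multi-page TIFF.
#' @param config [her2_config()].
#' @param classifier optional `her2_classifier` overriding
#'   `config$classifier` (`"heuristic"` builds the built-in backend).
#' @param out_dir directory for report artifacts (created if needed);
#'   `NULL` writes nothing.
#' @param top_k number of tiles to render cell overlays for.
#' @returns Object of class `slide_report`: list with `ihc_class`,
#'   `her2_status`, `ish_reflex`, `score_integrated`, `score_staining`,
#'   `slide_features`, `tile_features`, `prob_map`, `grid` and `timings`.
#'   A slide with no admissible tissue tiles reports class
#'   `"indeterminate"`.
#' @export
run_slide <- function(slide, config = her2_config(), classifier = NULL,
                      out_dir = NULL, top_k = 2L) {
  t0 <- proc.time()[["elapsed"]]
  if (is.character(slide)) {
    if (!file.exists(slide)) stop("unreadable slide: ", slide, call. = FALSE)
    slide <- read_slide_tiff(slide)
  }
  levels <- if (inherits(slide, "synthetic_slide")) slide$levels else slide
  if (inherits(levels, "rgb_image")) levels <- list(levels)

  clf <- classifier %||% switch(config$classifier,
    heuristic = heuristic_classifier(),
    stop("unknown classifier backend: ", config$classifier, call. = FALSE)
  )

  lev <- masking_level(levels, config$mask_level_max_side)
  mask <- tissue_mask(levels[[lev]], combine = config$mask_combine)
  t_mask <- proc.time()[["elapsed"]]

  grid <- enumerate_tiles(mask, config$tile_size_score,
                          config$min_tissue_fraction)
  indeterminate <- function(reason) {
    structure(
      list(ihc_class = "indeterminate", her2_status = NA_character_,
           ish_reflex = FALSE, reason = reason, grid = grid,
           tissue_mask = mask),
      class = "slide_report"
    )
  }
  if (nrow(grid) == 0L) {
    rep <- indeterminate("no tissue found")
    if (!is.null(out_dir)) write_slide_report(rep, out_dir, levels, config)
    return(rep)
  }

  pm <- probability_map(levels[[1]], grid, clf)
  bm <- binarize_map(pm, config$prob_threshold)
  tumor <- bm[bm$tumor, , drop = FALSE]
  t_map <- proc.time()[["elapsed"]]
  if (nrow(tumor) == 0L) {
    rep <- indeterminate("no tumor tiles above the probability threshold")
    rep$prob_map <- pm
    if (!is.null(out_dir)) write_slide_report(rep, out_dir, levels, config)
    return(rep)
  }

  feats <- dplyr::bind_rows(lapply(seq_len(nrow(tumor)), function(i) {
    tile <- extract_tile(levels[[1]], tumor$row0[i], tumor$col0[i],
                         config$tile_size_score)
    f <- score_tile(tile, config)
    f$row0 <- tumor$row0[i]
    f$col0 <- tumor$col0[i]
    f
  }))
  slide_feats <- aggregate_slide(feats)
  table <- threshold_table()
  score_int <- classify_integrated(slide_feats, table)
  score_sta <- classify_staining_only(slide_feats, table)
  t_score <- proc.time()[["elapsed"]]

  rep <- structure(
    list(
      ihc_class = as.character(score_int$ihc_class),
      her2_status = score_int$her2_status,
      ish_reflex = score_int$ish_reflex,
      score_integrated = score_int,
      score_staining = score_sta,
      slide_features = slide_feats,
      tile_features = feats,
      prob_map = pm,
      grid = grid,
      tissue_mask = mask,
      timings = tibble::tibble(
        stage = c("tissue_mask", "probability_map", "scoring"),
        seconds = c(t_mask - t0, t_map - t_mask, t_score - t_map)
      ),
      counts = tibble::tibble(
        tiles_total = nrow(grid), tiles_tumor = nrow(tumor),
        cells_segmented = sum(feats$n_cells)
      )
    ),
    class = "slide_report"
  )
  if (!is.null(out_dir)) {
    write_slide_report(rep, out_dir, levels, config, top_k = top_k)
  }
  rep
}

#' @export
print.slide_report <- function(x, ...) {
  cat(sprintf("<slide_report> IHC class: %s\n", x$ihc_class))
  if (!is.na(x$her2_status %||% NA)) {
    cat(sprintf("  HER2 status: %s\n", x$her2_status))
  }
  invisible(x)
}

#' @method glance slide_report
#' @export
glance.slide_report <- function(x, ...) {
  tibble::tibble(
    ihc_class = x$ihc_class,
    her2_status = x$her2_status %||% NA_character_,
    ish_reflex = isTRUE(x$ish_reflex),
    staining_intensity = x$slide_features$staining_intensity %||% NA_real_,
    positive_cell_ratio = x$slide_features$positive_cell_ratio %||% NA_real_,
    circumferential_ratio = x$slide_features$circumferential_ratio %||% NA_real_
  )
}

# Probability heatmap overlay and per-tile cell overlays, plus the JSON
# report and the per-tile feature table.
write_slide_report <- function(rep, out_dir, levels, config, top_k = 2L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(
    ihc_class = rep$ihc_class,
    her2_status = rep$her2_status %||% NA,
    ish_reflex = isTRUE(rep$ish_reflex),
    slide_features = if (!is.null(rep$slide_features))
      as.list(rep$slide_features) else NULL,
    votes = if (!is.null(rep$score_integrated))
      as.list(rep$score_integrated$votes) else NULL,
    counts = if (!is.null(rep$counts)) as.list(rep$counts) else NULL,
    config_version = config$version,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(rep$tile_features)) {
    utils::write.csv(rep$tile_features,
                     file.path(out_dir, "tile_features.csv"),
                     row.names = FALSE)
  }
  if (!is.null(rep$prob_map) && nrow(rep$prob_map)) {
    write_heatmap_png(rep$prob_map, levels,
                      file.path(out_dir, "tumor_heatmap.png"))
  }
  if (!is.null(rep$tile_features) && nrow(rep$tile_features) && top_k > 0) {
    ord <- order(rep$tile_features$n_cells, decreasing = TRUE)
    for (i in head(ord, top_k)) {
      tile <- extract_tile(levels[[1]], rep$tile_features$row0[i],
                           rep$tile_features$col0[i],
                           config$tile_size_score)
      write_cell_overlay_png(
        tile, config,
        file.path(out_dir, sprintf("tile_overlay_r%d_c%d.png",
                                   rep$tile_features$row0[i],
                                   rep$tile_features$col0[i]))
      )
    }
  }
  invisible(out_dir)
}

# Blend tile probabilities (blue -> red ramp) over the masking-level
# thumbnail.
write_heatmap_png <- function(pm, levels, path) {
  thumb <- levels[[length(levels)]]
  p <- img_pixels(thumb) / 255
  ds <- thumb$downsample
  ts <- attr(pm, "tile_size") %/% ds
  for (i in seq_len(nrow(pm))) {
    r <- (pm$row0[i] %/% ds + 1L):min(nrow(p), pm$row0[i] %/% ds + ts)
    cc <- (pm$col0[i] %/% ds + 1L):min(ncol(p), pm$col0[i] %/% ds + ts)
    a <- 0.45
    prob <- pm$prob[i]
    p[r, cc, 1] <- (1 - a) * p[r, cc, 1] + a * prob
    p[r, cc, 2] <- (1 - a) * p[r, cc, 2] + a * 0.1
    p[r, cc, 3] <- (1 - a) * p[r, cc, 3] + a * (1 - prob)
  }
  png::writePNG(p, path)
  invisible(path)
}

# Cell contours: positive cells yellow, negative dark blue (DAB mask
# boundary in red).
write_cell_overlay_png <- function(tile, config, path) {
  sv <- config_stain_vectors(config)
  dab <- extract_dab_mask(tile, config$brown_hsv)
  maps <- deconvolve(tile, sv)
  seg <- segment_cells(maps$h, config$segmentation)
  seg <- measure_rings(seg, dab, config$ring_width)
  p <- img_pixels(tile) / 255
  lab <- seg$cell_label_image
  if (max(lab) > 0) {
    er <- from_ebi(EBImage::erode(as_ebi(lab > 0), EBImage::makeBrush(3, "box"))) > 0.5
    edge <- (lab > 0) & !er
    pos <- matrix(FALSE, nrow(lab), ncol(lab))
    if (any(seg$cells$dab_overlap)) {
      pos <- lab %in% seg$cells$label[seg$cells$dab_overlap] &
        matrix(TRUE, nrow(lab), ncol(lab))
      pos <- matrix(pos, nrow(lab), ncol(lab))
    }
    for (ch in 1:3) {
      col_pos <- c(1, 0.9, 0.1)[ch]
      col_neg <- c(0.1, 0.1, 0.55)[ch]
      m <- p[, , ch]
      m[edge & pos] <- col_pos
      m[edge & !pos] <- col_neg
      p[, , ch] <- m
    }
  }
  png::writePNG(p, path)
  invisible(path)
}

#' Evaluate slide-level predictions against truth
#'
#' Joins predictions and truth on `slide_id` and builds one confusion
#' matrix per prediction method column.
#'
#' @param predictions data frame (or CSV path) with `slide_id` and one or
#'   more method columns of predicted classes.
#' @param truth data frame (or CSV path) with `slide_id` and `class`.
#' @returns Named list of `her2_confusion` objects, one per method.
#' @export
run_eval <- function(predictions, truth) {
  read_any <- function(x) {
    if (is.character(x)) utils::read.csv(x, colClasses = "character") else x
  }
  predictions <- read_any(predictions)
  truth <- read_any(truth)
  if (nrow(predictions) == 0L || nrow(truth) == 0L) {
    stop("empty predictions or truth table", call. = FALSE)
  }
  if (!all(c("slide_id") %in% names(predictions)) ||
      !all(c("slide_id", "class") %in% names(truth))) {
    stop("predictions need `slide_id`; truth needs `slide_id` and `class`",
         call. = FALSE)
  }
  if (!setequal(predictions$slide_id, truth$slide_id)) {
    stop("slide IDs of predictions and truth do not match", call. = FALSE)
  }
  truth <- truth[match(predictions$slide_id, truth$slide_id), ]
  methods <- setdiff(names(predictions), "slide_id")
  stats::setNames(lapply(methods, function(m) {
    confusion_matrix(truth$class, predictions[[m]],
                     classes = IHC_CLASSES)
  }), methods)
}
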