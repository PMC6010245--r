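# Assembly of the 100-feature collagen vector: 28 features per region
# (CV, PT, PS) and 16 whole-tissue features.
#
# Percentages count pixels of retained strings (components >= min_pixels),
# so aggregated% + distributed% = collagen% exactly in every scope. String
# counts and means use majority-region string assignment; counts are
# normalized per mm^2 of scope area; means over an empty string set are 0.

REGION_CODES <- c(CV = 1L, PT = 2L, PS = 3L)

scope_features <- function(strings, px_all, px_agg, px_scope, area_mm2,
                           scope_px) {
  colpct <- if (scope_px > 0) 100 * px_all / scope_px else 0
  aggpct <- if (scope_px > 0) 100 * px_agg / scope_px else 0
  dispct <- colpct - aggpct
  aggratio <- if (px_all > 0) 100 * px_agg / px_all else 0

  count_block <- function(s) {
    n <- function(x) if (area_mm2 > 0) x / area_mm2 else 0
    c(n(nrow(s)),
      n(sum(s$length_class == "short")), n(sum(s$length_class == "long")),
      n(sum(s$thickness == "thick")), n(sum(s$thickness == "thin")))
  }
  mean_block <- function(s) {
    m <- function(x) if (length(x) > 0) mean(x) else 0
    c(m(s$area_um2), m(s$length_um), m(s$width_um))
  }
  s_a <- strings[strings$aggregation == "aggregated", ]
  s_d <- strings[strings$aggregation == "distributed", ]
  c(colpct, aggpct, dispct, aggratio,
    count_block(strings), count_block(s_a), count_block(s_d),
    mean_block(strings), mean_block(s_a), mean_block(s_d))
}

#' Compute the 100-feature collagen vector of a tile
#'
#' Aggregates classified collagen strings and the region map into the
#' canonical feature vector: for each of the CV, PT and PS regions, collagen
#' percentages (all / aggregated / distributed / aggregated share), string
#' counts per mm2 (total and short/long/thick/thin, for all, aggregated and
#' distributed strings) and per-string mean area/length/width; plus 16
#' analogous whole-tissue features. A region absent from the specimen
#' contributes zeros and is listed in the `"missing_regions"` attribute.
#'
#' @param strings Classified string tibble from [extract_strings()] +
#'   [classify_strings()], still carrying its `"labels"` attribute.
#' @param region_map Integer matrix (0 = background, 1 = CV, 2 = PT,
#'   3 = PS), e.g. from [assign_regions()].
#' @param tissue Optional logical tissue mask; defaults to
#'   `region_map > 0`.
#' @param pixel_size Micrometres per pixel.
#' @return One-row tibble with the 100 columns of [feature_names()];
#'   attribute `"missing_regions"` names regions with no pixels.
#' @export
compute_features <- function(strings, region_map, tissue = NULL,
                             pixel_size = 200 / 512) {
  labels <- attr(strings, "labels")
  if (is.null(labels)) {
    abort("`strings` must carry the label matrix from extract_strings().")
  }
  needed <- c("aggregation", "thickness", "length_class")
  if (nrow(strings) > 0 && !all(needed %in% names(strings))) {
    abort("Strings must be classified first; see classify_strings().")
  }
  if (is.null(tissue)) tissue <- region_map > 0
  px2mm2 <- pixel_size^2 / 1e6

  # pixel-level membership of retained strings, split by aggregation
  agg_ids <- strings$string_id[strings$aggregation == "aggregated"]
  in_string <- labels > 0
  in_agg <- matrix(labels %in% agg_ids, nrow(labels), ncol(labels))

  missing_regions <- character(0)
  vals <- numeric(0)
  for (rg in names(REGION_CODES)) {
    scope <- region_map == REGION_CODES[[rg]]
    scope_px <- sum(scope)
    if (scope_px == 0) missing_regions <- c(missing_regions, rg)
    s_rg <- strings[!is.na(strings$region) & strings$region == rg, ]
    vals <- c(vals, scope_features(
      s_rg,
      px_all = sum(in_string & scope),
      px_agg = sum(in_agg & scope),
      px_scope = scope_px,
      area_mm2 = scope_px * px2mm2,
      scope_px = scope_px
    ))
  }

  tissue_px <- sum(tissue)
  area_mm2 <- tissue_px * px2mm2
  g <- scope_features(strings,
                      px_all = sum(in_string & tissue),
                      px_agg = sum(in_agg & tissue),
                      px_scope = tissue_px,
                      area_mm2 = area_mm2, scope_px = tissue_px)
  # global block keeps 16 of the 28 scope features:
  # 4 percentages, 5 all-string counts, total A/D counts, 3 all-string means,
  # mean aggregated and distributed string areas
  g16 <- g[c(1:9, 10, 15, 20:22, 23, 26)]
  vals <- c(vals, g16)

  out <- as_tibble(as.list(setNames(vals, feature_names())))
  attr(out, "missing_regions") <- missing_regions
  out
}

#' Aggregate per-tile feature vectors to the subject level
#'
#' Area-weighted mean of per-tile feature vectors; with equal-area tiles
#' (the native acquisition geometry) this is the plain mean.
#'
#' @param tile_features List of one-row feature tibbles (or a tibble of
#'   stacked rows).
#' @param weights Optional nonnegative tile weights (e.g. tissue areas);
#'   default equal.
#' @return One-row tibble of the 100 features.
#' @export
subject_features <- function(tile_features, weights = NULL) {
  df <- if (is.data.frame(tile_features)) tile_features
        else dplyr::bind_rows(tile_features)
  if (nrow(df) == 0) abort("No tile features supplied.")
  if (is.null(weights)) weights <- rep(1, nrow(df))
  if (length(weights) != nrow(df) || any(weights < 0) || sum(weights) == 0) {
    abort("`weights` must be nonnegative with a positive sum, one per tile.")
  }
  w <- weights / sum(weights)
  as_tibble(as.list(colSums(as.matrix(df[feature_names()]) * w)))
}

#' Full per-tile morphometry pipeline
#'
#' Convenience wrapper: noise removal, collagen segmentation, hole
#' detection, structure building and classification, region assignment,
#' string extraction and classification, and the 100-feature vector.
#'
#' @param tile An [tile_image()].
#' @param hole_model,structure_model CART models (see [train_hole_cart()]
#'   and [train_structure_cart()]); `NULL` uses the trees bundled with the
#'   package.
#' @param config Pipeline tunables from [pipeline_config()].
#' @return List: `features` (one-row tibble), `strings`, `region_map`,
#'   `collagen` (the mask object), `holes`, `structures`, `tissue`.
#' @export
analyze_tile <- function(tile, hole_model = NULL, structure_model = NULL,
                         config = pipeline_config()) {
  if (is.null(hole_model)) hole_model <- bundled_hole_cart()
  if (is.null(structure_model)) structure_model <- bundled_structure_cart()
  clean <- remove_noise(tile)
  col <- detect_collagen(clean$shg, levels = config$otsu_levels)
  tis <- tissue_mask(clean$tpef, frac = config$tissue_frac)
  holes <- detect_holes(clean$tpef, tis, col$mask,
                        min_area = config$min_hole_area_um2,
                        pixel_size = tile$pixel_size,
                        density_radius_um = config$density_radius_um,
                        annulus_um = config$annulus_um)
  holes <- classify_holes(hole_model, holes)
  structures <- build_structures(holes, col$mask,
                                 link_distance_um = config$link_distance_um,
                                 pixel_size = tile$pixel_size)
  structures <- classify_structures(structure_model, structures)
  rmap <- assign_regions(structures, holes, tis,
                         halo_radius_um = config$halo_radius_um,
                         pixel_size = tile$pixel_size)
  strings <- extract_strings(col$mask, rmap, pixel_size = tile$pixel_size,
                             min_pixels = config$min_string_pixels)
  strings <- classify_strings(strings, ratio = config$thick_ratio,
                              cutoff_um = config$length_cutoff_um)
  feats <- compute_features(strings, rmap, tissue = tis,
                            pixel_size = tile$pixel_size)
  list(features = feats, strings = strings, region_map = rmap,
       collagen = col, holes = holes, structures = structures, tissue = tis)
}
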