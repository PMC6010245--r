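# End-to-end pipelines: simulate a cohort to disk, extract the feature
# table, and validate the staging model. Every tunable lives in a single
# serializable config so a run is reproducible from (config, seed).

#' Pipeline configuration
#'
#' Collects every tunable of the image-analysis and staging pipeline with
#' its default. All lengths are physical (micrometres) so the settings are
#' resolution-independent.
#'
#' @param otsu_levels Histogram bins for Otsu thresholding.
#' @param tissue_frac TPEF fraction delimiting tissue (see [tissue_mask()]).
#' @param min_hole_area_um2 Minimum detected hole area.
#' @param density_radius_um Radius of the hole-density neighbourhood.
#' @param annulus_um Surrounding-collagen annulus width.
#' @param link_distance_um Hole-linkage distance for structures.
#' @param halo_radius_um Region halo around structure holes.
#' @param min_string_pixels Minimum collagen component size.
#' @param thick_ratio Width/length ratio above which a string is thick.
#' @param length_cutoff_um Absolute short/long cutoff; `NULL` = per-subject
#'   median rule.
#' @param k_max Features selected for the B-index.
#' @param reselect_per_fold Re-run selection inside each LOOCV fold.
#' @param seed Master seed.
#' @return Named list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(otsu_levels = 256, tissue_frac = 0.2,
                            min_hole_area_um2 = 5, density_radius_um = 100,
                            annulus_um = 15, link_distance_um = 50,
                            halo_radius_um = 25, min_string_pixels = 4,
                            thick_ratio = 0.25, length_cutoff_um = NULL,
                            k_max = 14, reselect_per_fold = FALSE,
                            seed = 1L) {
  structure(
    list(otsu_levels = otsu_levels, tissue_frac = tissue_frac,
         min_hole_area_um2 = min_hole_area_um2,
         density_radius_um = density_radius_um, annulus_um = annulus_um,
         link_distance_um = link_distance_um, halo_radius_um = halo_radius_um,
         min_string_pixels = min_string_pixels, thick_ratio = thick_ratio,
         length_cutoff_um = length_cutoff_um, k_max = k_max,
         reselect_per_fold = reselect_per_fold, seed = as.integer(seed),
         version = tryCatch(as.character(utils::packageVersion("shgfib")),
                            error = function(e) "dev")),
    class = "pipeline_config"
  )
}

#' Read / write a pipeline configuration as YAML
#'
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @return `write_config()` returns `path` invisibly; `read_config()` the
#'   config.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  obj <- yaml::read_yaml(path)
  cfg <- pipeline_config()
  for (nm in intersect(names(obj), names(cfg))) cfg[[nm]] <- obj[[nm]]
  cfg
}

#' Simulate a cohort to disk
#'
#' Writes each tile as a two-page 16-bit TIFF (SHG, TPEF), each ground-truth
#' region map as an indexed PNG (pixel value = region code), and a cohort
#' manifest CSV (`subject_id`, `stage`, `tile` paths).
#'
#' @param out_dir Output directory (created if needed).
#' @param n Number of subjects.
#' @param tiles_per_subject Tiles per subject.
#' @param config A [pipeline_config()]; its seed drives the simulation.
#' @param ... Passed to [generate_cohort()] / [tile_spec()].
#' @return The manifest tibble (invisibly), with the cohort attached as
#'   attribute `"cohort"`.
#' @export
run_simulate <- function(out_dir, n = 83, tiles_per_subject = 2,
                         config = pipeline_config(), ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- generate_cohort(n, tiles_per_subject = tiles_per_subject,
                            seed = config$seed, ...)
  rows <- list()
  for (i in seq_len(nrow(cohort))) {
    sid <- cohort$subject_id[i]
    for (t in seq_along(cohort$tiles[[i]])) {
      tl <- cohort$tiles[[i]][[t]]
      tile_path <- file.path(out_dir, sprintf("%s_tile%02d.tif", sid, t))
      write_tile_tiff(tl$tile, tile_path)
      if (requireNamespace("png", quietly = TRUE)) {
        png::writePNG(tl$truth$region_map / 255,
                      file.path(out_dir, sprintf("%s_tile%02d_regions.png",
                                                 sid, t)))
      }
      rows[[length(rows) + 1L]] <- tibble(
        subject_id = sid, stage = cohort$stage[i], tile = basename(tile_path)
      )
    }
  }
  manifest <- dplyr::bind_rows(rows)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  jsonlite::write_json(list(n = n, tiles_per_subject = tiles_per_subject,
                            seed = config$seed),
                       file.path(out_dir, "manifest.json"), auto_unbox = TRUE)
  attr(manifest, "cohort") <- cohort
  invisible(manifest)
}

#' Extract the subject-by-feature table from a cohort
#'
#' Runs the full image pipeline (noise removal, Otsu segmentation, hole
#' detection and classification, structure classification, region
#' assignment, string morphometry) on every tile and aggregates per-tile
#' feature vectors to tissue-area-weighted subject means.
#'
#' @param cohort Cohort tibble from [generate_cohort()] (or the attribute
#'   attached by [run_simulate()]).
#' @param config A [pipeline_config()].
#' @param hole_model,structure_model CART models; `NULL` uses the bundled
#'   trees.
#' @param out_csv Optional path for the feature CSV.
#' @return Tibble: `subject_id`, `stage`, 100 feature columns.
#' @export
run_extract <- function(cohort, config = pipeline_config(),
                        hole_model = NULL, structure_model = NULL,
                        out_csv = NULL) {
  if (nrow(cohort) == 0) {
    cols <- c(list(subject_id = character(0), stage = integer(0)),
              setNames(rep(list(numeric(0)), 100), feature_names()))
    out <- as_tibble(cols)
    if (!is.null(out_csv)) write.csv(out, out_csv, row.names = FALSE)
    return(out)
  }
  if (is.null(hole_model)) hole_model <- bundled_hole_cart()
  if (is.null(structure_model)) structure_model <- bundled_structure_cart()
  rows <- lapply(seq_len(nrow(cohort)), function(i) {
    res <- lapply(cohort$tiles[[i]], function(tl) {
      analyze_tile(tl$tile, hole_model, structure_model, config)
    })
    feats <- subject_features(
      lapply(res, `[[`, "features"),
      weights = vapply(res, function(r) sum(r$tissue), numeric(1))
    )
    dplyr::bind_cols(tibble(subject_id = cohort$subject_id[i],
                            stage = cohort$stage[i]), feats)
  })
  out <- dplyr::bind_rows(rows)
  if (!is.null(out_csv)) write.csv(out, out_csv, row.names = FALSE)
  out
}

#' Select, fit and cross-validate the B-index on a feature table
#'
#' Sequential forward selection on the full table (or per fold when
#' configured), B-index fit, leave-one-out cross-validated scores, and the
#' per-grouping diagnostic report.
#'
#' @param features Tibble with `subject_id`, `stage` and feature columns
#'   (from [run_extract()] or [generate_feature_table()]), or a CSV path.
#' @param config A [pipeline_config()].
#' @return List: `selection` (the [sfs_select()] result), `model`
#'   (full-data [fit_b_index()]), `scores` (LOOCV tibble), `report`
#'   ([staging_report()] on the LOOCV scores), `spearman`.
#' @export
run_validate <- function(features, config = pipeline_config()) {
  if (is.character(features)) {
    features <- as_tibble(read.csv(features, check.names = FALSE))
  }
  if (length(unique(features$stage)) < 2) {
    abort("Need at least two distinct stages to validate.")
  }
  k <- min(config$k_max, nrow(features) - 2)
  sel <- sfs_select(features, k_max = k)
  model <- fit_b_index(features, features = sel$selected)
  scores <- loocv_b_index(features, features = sel$selected,
                          reselect = config$reselect_per_fold, k_max = k)
  report <- staging_report(scores)
  list(selection = sel, model = model, scores = scores, report = report,
       spearman = attr(report, "spearman"))
}
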