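# Shared seed-fixed synthetic image cohort, generated once per test session
# and reused by the region, staging and acceptance tests. 10 subjects (two
# per stage), one tile each, default noise and geometry.

.shgfib_test_cache <- new.env(parent = emptyenv())

cached_image_cohort <- function() {
  if (!is.null(.shgfib_test_cache$cohort)) return(.shgfib_test_cache$cohort)
  cohort <- generate_cohort(10, tiles_per_subject = 1, seed = 42,
                            stages = rep(0:4, each = 2))
  hole_model <- bundled_hole_cart()
  structure_model <- bundled_structure_cart()
  config <- pipeline_config()

  analyses <- vector("list", nrow(cohort))
  region_acc <- numeric(nrow(cohort))
  labeled_holes <- list()
  labeled_structures <- list()
  feats <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    tl <- cohort$tiles[[i]][[1]]
    res <- analyze_tile(tl$tile, hole_model, structure_model, config)
    analyses[[i]] <- res
    region_acc[i] <- region_accuracy(res$region_map, tl$truth$region_map,
                                     tl$truth$tissue)
    lh <- gt_label_holes(res$holes, tl$truth)
    labeled_holes[[i]] <- lh
    lh$hole_class <- lh$class
    st <- build_structures(lh, res$collagen$mask)
    sl <- gt_label_structures(st, lh, tl$truth)
    labeled_structures[[i]] <- sl[!is.na(sl$class), ]
    feats[[i]] <- dplyr::bind_cols(
      tibble::tibble(subject_id = cohort$subject_id[i],
                     stage = cohort$stage[i]),
      res$features
    )
  }
  out <- list(
    cohort = cohort,
    analyses = analyses,
    region_accuracy = region_acc,
    holes = dplyr::bind_rows(labeled_holes),
    structures = dplyr::bind_rows(lapply(labeled_structures, function(s) {
      s[c("n_holes", "total_hole_area_um2", "max_hole_area_um2",
          "collagen_area_um2", "class")]
    })),
    features = dplyr::bind_rows(feats)
  )
  .shgfib_test_cache$cohort <- out
  out
}
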