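# String extraction, classification rules and the 100-feature vector.

ps <- 200 / 512

test_that("string geometry follows the ribbon model on analytic fixtures", {
  # 10 x 2 px horizontal bar: centerline of 10 pixels = 9 steps
  m <- matrix(FALSE, 32, 32)
  m[10:11, 5:14] <- TRUE
  s <- extract_strings(m, pixel_size = ps)
  expect_equal(nrow(s), 1)
  expect_equal(s$length_um, 9 * ps)
  expect_equal(s$area_um2, 20 * ps^2)
  expect_equal(s$width_um, s$area_um2 / s$length_um)
  # single-pixel component: length floored at one pixel
  m1 <- matrix(FALSE, 8, 8); m1[4, 4] <- TRUE
  s1 <- extract_strings(m1, pixel_size = ps, min_pixels = 1)
  expect_equal(s1$length_um, ps)
  expect_equal(s1$width_um, s1$area_um2 / s1$length_um)
  # two disjoint bars are two strings
  m2 <- matrix(FALSE, 32, 32)
  m2[5:6, 4:13] <- TRUE
  m2[20:21, 4:13] <- TRUE
  expect_equal(nrow(extract_strings(m2, pixel_size = ps)), 2)
  # empty mask
  expect_equal(nrow(extract_strings(matrix(FALSE, 8, 8))), 0)
})

test_that("cross-linking classification keys on skeleton branch points", {
  bar <- matrix(FALSE, 20, 20); bar[10, 3:17] <- TRUE
  sb <- extract_strings(bar, pixel_size = ps)
  expect_identical(sb$aggregation, "distributed")
  expect_equal(sb$n_branch_points, 0L)
  # T-shaped component
  tm <- matrix(FALSE, 20, 20); tm[5, 3:15] <- TRUE; tm[5:15, 9] <- TRUE
  st <- extract_strings(tm, pixel_size = ps)
  expect_identical(st$aggregation, "aggregated")
  expect_gte(st$n_branch_points, 1)
  # X-shaped component
  xm <- matrix(FALSE, 21, 21)
  for (i in 1:21) { xm[i, i] <- TRUE; xm[i, 22 - i] <- TRUE }
  sx <- extract_strings(xm, pixel_size = ps)
  expect_identical(sx$aggregation, "aggregated")
})

test_that("thickness uses a strict width/length > 0.25 rule", {
  s <- tibble::tibble(width_um = c(1, 1, 1), length_um = c(2, 10, 4))
  out <- classify_thickness(s)
  expect_identical(out$thickness, c("thick", "thin", "thin"))  # 0.5, 0.1, 0.25
})

test_that("length classes follow the median rule with strict comparison", {
  s <- tibble::tibble(length_um = c(1, 2, 3, 4))
  expect_identical(classify_length(s)$length_class,
                   c("short", "short", "long", "long"))  # median 2.5
  # all equal: nothing exceeds the median
  eq <- tibble::tibble(length_um = rep(2, 5))
  expect_true(all(classify_length(eq)$length_class == "short"))
  # absolute cutoff 0: everything is long
  expect_true(all(classify_length(s, cutoff_um = 0)$length_class == "long"))
})

test_that("the feature vector has the canonical 28/28/28/16 layout", {
  nm <- feature_names()
  expect_length(nm, 100)
  expect_equal(anyDuplicated(nm), 0)
  expect_length(grep("CV", nm[1:28]), 28)
  expect_length(grep("PT", nm[29:56]), 28)
  expect_true(all(selected_feature_names() %in% nm))
  # computed vector matches the registry exactly
  co <- cached_image_cohort()
  f <- co$analyses[[3]]$features
  expect_identical(names(f), nm)
})

test_that("empty masks yield all-zero features", {
  m <- matrix(FALSE, 64, 64)
  rmap <- matrix(3L, 64, 64)
  strings <- classify_strings(extract_strings(m, rmap, pixel_size = ps))
  f <- compute_features(strings, rmap, pixel_size = ps)
  expect_true(all(as.numeric(f) == 0))
  expect_setequal(attr(f, "missing_regions"), c("CV", "PT"))
})

test_that("counts conserve and percentages add across classes", {
  co <- cached_image_cohort()
  for (res in co$analyses[c(2, 6, 10)]) {
    f <- res$features
    s <- res$strings
    # count conservation per classification, as raw string tallies
    expect_equal(sum(s$aggregation == "aggregated") +
                   sum(s$aggregation == "distributed"), nrow(s))
    expect_equal(sum(s$thickness == "thick") + sum(s$thickness == "thin"),
                 nrow(s))
    expect_equal(sum(s$length_class == "short") +
                   sum(s$length_class == "long"), nrow(s))
    # normalized count conservation inside the feature vector
    for (rg in c("CV", "PT", "PS")) {
      n_all <- f[[paste0("NoStr", rg)]]
      expect_equal(f[[paste0("NoStr", rg, "A")]] +
                     f[[paste0("NoStr", rg, "D")]], n_all, tolerance = 1e-9)
      expect_equal(f[[paste0("NoShortStr", rg)]] +
                     f[[paste0("NoLongStr", rg)]], n_all, tolerance = 1e-9)
      expect_equal(f[[paste0("NoThickStr", rg)]] +
                     f[[paste0("NoThinStr", rg)]], n_all, tolerance = 1e-9)
    }
    # percentage additivity in every scope
    expect_equal(f$AggCV + f$DisCV, f$CV, tolerance = 1e-9)
    expect_equal(f$AggPT + f$DisPT, f$PT, tolerance = 1e-9)
    expect_equal(f$AggPS + f$DisPS, f$PS, tolerance = 1e-9)
    expect_equal(f$Agg + f$Dis, f$Col, tolerance = 1e-9)
    pct <- as.numeric(f[c("CV", "PT", "PS", "Col", "Agg", "Dis",
                          "AggCV", "DisCV", "AggPT", "DisPT",
                          "AggPS", "DisPS")])
    expect_true(all(pct >= 0 & pct <= 100))
  }
})

test_that("feature extraction is invariant to translation and rotation", {
  m <- matrix(FALSE, 64, 64)
  m[10:11, 5:24] <- TRUE
  m[30:40, 40] <- TRUE; m[35, 35:45] <- TRUE
  m[50:52, 10:18] <- TRUE
  rmap <- matrix(3L, 64, 64)
  base <- compute_features(
    classify_strings(extract_strings(m, rmap, pixel_size = ps)),
    rmap, pixel_size = ps)
  shifted <- matrix(as.logical(shgfib:::shift_mat(m, 4, 6, fill = FALSE)),
                    64, 64)
  f_sh <- compute_features(
    classify_strings(extract_strings(shifted, rmap, pixel_size = ps)),
    rmap, pixel_size = ps)
  rotated <- t(m)[, 64:1]
  f_rot <- compute_features(
    classify_strings(extract_strings(rotated, rmap, pixel_size = ps)),
    rmap, pixel_size = ps)
  expect_equal(as.numeric(f_sh), as.numeric(base), tolerance = 1e-6)
  expect_equal(as.numeric(f_rot), as.numeric(base), tolerance = 1e-6)
})

test_that("mirror-doubling the tile preserves intensive features", {
  half <- matrix(FALSE, 64, 32)
  half[10:11, 5:20] <- TRUE
  half[40:42, 8:20] <- TRUE; half[41, 8:20] <- TRUE
  whole <- cbind(half, half[, 32:1])
  rmap_half <- matrix(3L, 64, 32)
  rmap_whole <- matrix(3L, 64, 64)
  f_half <- compute_features(
    classify_strings(extract_strings(half, rmap_half, pixel_size = ps)),
    rmap_half, pixel_size = ps)
  f_whole <- compute_features(
    classify_strings(extract_strings(whole, rmap_whole, pixel_size = ps)),
    rmap_whole, pixel_size = ps)
  # percentages and per-mm2 counts unchanged, string count doubled
  expect_equal(f_whole$PS, f_half$PS, tolerance = 1e-9)
  expect_equal(f_whole$Col, f_half$Col, tolerance = 1e-9)
  expect_equal(f_whole$NoStrPS, f_half$NoStrPS, tolerance = 1e-9)
  s_half <- extract_strings(half, rmap_half, pixel_size = ps)
  s_whole <- extract_strings(whole, rmap_whole, pixel_size = ps)
  expect_equal(nrow(s_whole), 2 * nrow(s_half))
})

test_that("subject aggregation is the area-weighted tile mean", {
  co <- cached_image_cohort()
  f1 <- co$analyses[[1]]$features
  f2 <- co$analyses[[2]]$features
  both <- subject_features(list(f1, f2), weights = c(1, 1))
  expect_equal(as.numeric(both),
               (as.numeric(f1) + as.numeric(f2)) / 2, tolerance = 1e-12)
  w <- subject_features(list(f1, f2), weights = c(3, 1))
  expect_equal(as.numeric(w),
               (3 * as.numeric(f1) + as.numeric(f2)) / 4, tolerance = 1e-12)
  expect_error(subject_features(list(f1), weights = c(-1)), "nonnegative")
})
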