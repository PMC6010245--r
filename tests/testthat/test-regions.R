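# Hole detection, CART classification, structure building and the region
# map.

ps <- 200 / 512

make_disc_tile <- function(radius_px = 10, center = c(32, 32), size = 64) {
  tpef <- matrix(20000, size, size)
  d2 <- (row(tpef) - center[1])^2 + (col(tpef) - center[2])^2
  tpef[d2 <= radius_px^2] <- 0
  tpef
}

test_that("a circular hole is measured consistently with disc geometry", {
  tpef <- make_disc_tile()
  tissue <- matrix(TRUE, 64, 64)
  collagen <- matrix(FALSE, 64, 64)
  holes <- detect_holes(tpef, tissue, collagen, pixel_size = ps)
  expect_equal(nrow(holes), 1)
  expect_gte(holes$solidity, 0.95)
  expect_equal(holes$area_um2, pi * 10^2 * ps^2, tolerance = 0.05)
  expect_equal(holes$width_um, 2 * 10 * ps, tolerance = 0.08)
  expect_lte(holes$width_um, holes$length_um)
  expect_equal(holes$density, 0L)
})

test_that("border-touching holes and empty inputs give empty results", {
  tpef <- make_disc_tile(radius_px = 8, center = c(4, 32))  # touches border
  holes <- detect_holes(tpef, matrix(TRUE, 64, 64), matrix(FALSE, 64, 64),
                        pixel_size = ps)
  expect_equal(nrow(holes), 0)
  # uniform bright tissue
  bright <- detect_holes(matrix(20000, 64, 64), matrix(TRUE, 64, 64),
                         matrix(FALSE, 64, 64), pixel_size = ps)
  expect_equal(nrow(bright), 0)
  # empty tissue mask
  none <- detect_holes(make_disc_tile(), matrix(FALSE, 64, 64),
                       matrix(FALSE, 64, 64), pixel_size = ps)
  expect_equal(nrow(none), 0)
})

test_that("hole CART separates perfectly separable classes", {
  set.seed(2)
  holes <- tibble::tibble(
    density = sample(0:5, 60, replace = TRUE),
    width_um = runif(60, 3, 10), length_um = runif(60, 3, 12),
    solidity = runif(60, 0.9, 1),
    surrounding_collagen_um2 = c(runif(30, 40, 120), rep(0, 30)),
    class = rep(c("vessel_or_duct", "other"), each = 30)
  )
  fit <- train_hole_cart(holes)
  expect_identical(predict_cart(fit, holes), holes$class)
  # single-class input: one-leaf tree with a warning
  expect_warning(one <- train_hole_cart(holes[holes$class == "other", ]),
                 "Single-class")
  expect_identical(unique(predict_cart(one, holes)), "other")
})

test_that("CART models survive a JSON round trip and ignore column order", {
  co <- cached_image_cohort()
  fit <- train_hole_cart(co$holes)
  path <- withr::local_tempfile(fileext = ".json")
  write_cart(fit, path)
  back <- read_cart(path)
  expect_identical(predict_cart(back, co$holes), predict_cart(fit, co$holes))
  shuffled <- co$holes[, rev(names(co$holes))]
  expect_identical(predict_cart(fit, shuffled), predict_cart(fit, co$holes))
})

test_that("label permutation drops hole CART accuracy to the class prior", {
  co <- cached_image_cohort()
  holes <- co$holes
  n <- nrow(holes)
  prior <- max(table(holes$class)) / n
  set.seed(7)
  accs <- replicate(100, {
    sh <- holes
    sh$class <- sample(sh$class)
    train_idx <- sample.int(n, floor(n / 2))
    fit <- suppressWarnings(train_hole_cart(sh[train_idx, ]))
    mean(predict_cart(fit, sh[-train_idx, ]) == sh$class[-train_idx])
  })
  expect_lt(mean(accs), prior + 0.1)
  # and genuine labels beat the prior clearly
  set.seed(8)
  train_idx <- sample.int(n, floor(n / 2))
  fit <- train_hole_cart(holes[train_idx, ])
  expect_gte(mean(predict_cart(fit, holes[-train_idx, ]) ==
                    holes$class[-train_idx]), 0.85)
})

test_that("structure CART reaches held-out accuracy >= 0.9 on cohort data", {
  co <- cached_image_cohort()
  st <- co$structures
  set.seed(3)
  idx <- sample.int(nrow(st), floor(nrow(st) / 2))
  fit <- train_structure_cart(st[idx, ])
  acc <- mean(predict_cart(fit, st[-idx, ]) == st$class[-idx])
  expect_gte(acc, 0.9)
  # permuted labels fall back to the prior
  prior <- max(table(st$class)) / nrow(st)
  set.seed(9)
  accs <- replicate(50, {
    sh <- st
    sh$class <- sample(sh$class)
    f <- suppressWarnings(train_structure_cart(sh[idx, ]))
    mean(predict_cart(f, sh[-idx, ]) == sh$class[-idx])
  })
  expect_lt(mean(accs), prior + 0.12)
  expect_error(classify_structures(NULL, st), "trained")
})

test_that("structure linkage equals the single-linkage oracle", {
  # chain A-B-C with A-B and B-C within range but A-C beyond it
  holes <- tibble::tibble(
    hole_id = 1:3, n_pixels = 50L, area_um2 = 10,
    row = c(100, 100, 100), col = c(100, 200, 300),
    surrounding_collagen_um2 = 5
  )
  st <- build_structures(holes, matrix(FALSE, 512, 512),
                         link_distance_um = 50, pixel_size = ps)
  expect_equal(nrow(st), 1)
  expect_equal(st$n_holes, 3)
  # two far-apart holes stay separate
  far <- holes[c(1, 3), ]
  expect_equal(nrow(build_structures(far, matrix(FALSE, 512, 512),
                                     link_distance_um = 50,
                                     pixel_size = ps)), 2)
  # random instances against the brute-force transitive closure
  set.seed(11)
  for (k in 1:25) {
    n <- sample(2:12, 1)
    hh <- tibble::tibble(hole_id = seq_len(n), n_pixels = 10L, area_um2 = 5,
                         row = runif(n, 1, 512), col = runif(n, 1, 512),
                         surrounding_collagen_um2 = 0)
    st <- build_structures(hh, matrix(FALSE, 512, 512),
                           link_distance_um = 60, pixel_size = ps)
    oracle <- single_linkage_brute(cbind(hh$row, hh$col) * ps, 60)
    expect_equal(nrow(st), length(unique(oracle)))
    expect_true(all(st$max_hole_area_um2 <= st$total_hole_area_um2))
  }
})

test_that("region maps partition the tissue exactly", {
  co <- cached_image_cohort()
  for (res in co$analyses[c(1, 5, 9)]) {
    rmap <- res$region_map
    expect_true(all(rmap[res$tissue] %in% 1:3))
    expect_true(all(rmap[!res$tissue] == 0))
    n_cv <- sum(rmap == 1); n_pt <- sum(rmap == 2); n_ps <- sum(rmap == 3)
    expect_equal(n_cv + n_pt + n_ps, sum(res$tissue))
  }
  # no structures: everything perisinusoidal
  tissue <- matrix(TRUE, 32, 32)
  empty_structs <- build_structures(
    tibble::tibble(hole_id = integer(0), n_pixels = integer(0),
                   area_um2 = numeric(0), row = numeric(0), col = numeric(0),
                   surrounding_collagen_um2 = numeric(0)),
    matrix(FALSE, 32, 32), pixel_size = ps)
  rmap <- assign_regions(empty_structs, tibble::tibble(), tissue,
                         pixel_size = ps)
  expect_true(all(rmap[tissue] == 3))
})

test_that("overlapping halos go to the nearer structure", {
  # two single-hole structures close enough for halo overlap, small grid
  size <- 48
  lab <- matrix(0L, size, size)
  lab[20:22, 8:10] <- 1L
  lab[20:22, 38:40] <- 2L
  holes <- tibble::tibble(hole_id = 1:2, n_pixels = 9L,
                          area_um2 = 9 * ps^2,
                          row = c(21, 21), col = c(9, 39),
                          surrounding_collagen_um2 = 0)
  attr(holes, "labels") <- lab
  structures <- tibble::tibble(
    structure_id = 1:2, n_holes = 1L, total_hole_area_um2 = 9 * ps^2,
    max_hole_area_um2 = 9 * ps^2, collagen_area_um2 = 0,
    row = c(21, 21), col = c(9, 39), hole_ids = list(1L, 2L),
    class = c("central_vein", "portal_tract")
  )
  tissue <- matrix(TRUE, size, size)
  halo_um <- 10
  rmap <- assign_regions(structures, holes, tissue, halo_radius_um = halo_um,
                         pixel_size = ps)
  # per-pixel oracle: explicit distance to each hole pixel set
  px1 <- which(lab == 1L); px2 <- which(lab == 2L)
  rc1 <- cbind((px1 - 1) %% size + 1, (px1 - 1) %/% size + 1)
  rc2 <- cbind((px2 - 1) %% size + 1, (px2 - 1) %/% size + 1)
  for (r in seq_len(size)) for (c in seq_len(size)) {
    d1 <- sqrt(min((rc1[, 1] - r)^2 + (rc1[, 2] - c)^2))
    d2 <- sqrt(min((rc2[, 1] - r)^2 + (rc2[, 2] - c)^2))
    expected <- if (min(d1, d2) > halo_um / ps) 3L else if (d1 <= d2) 1L else 2L
    expect_identical(rmap[r, c], expected)
  }
})

test_that("automatic region maps agree with ground truth on the cohort", {
  co <- cached_image_cohort()
  expect_gte(mean(co$region_accuracy), 0.85)
})
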