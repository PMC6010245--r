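# Regenerates the bundled decision trees in inst/extdata from a fixed-seed
# synthetic training cohort with pixel-level ground truth.
# Run from the package root:  Rscript tools/make_cart_fixtures.R

devtools::load_all(".", quiet = TRUE)
suppressMessages(library(dplyr))

train_tiles <- function(seeds) {
  lapply(seeds, function(s) {
    generate_tile(tile_spec(stage = (s - 1) %% 5, seed = 1000 + s))
  })
}

collect_labeled <- function(tiles) {
  holes_all <- list()
  structs_all <- list()
  for (tl in tiles) {
    clean <- remove_noise(tl$tile)
    tis <- tissue_mask(clean$tpef)
    col <- detect_collagen(clean$shg)
    holes <- detect_holes(clean$tpef, tis, col$mask)
    if (nrow(holes) == 0) next
    lh <- gt_label_holes(holes, tl$truth)
    holes_all[[length(holes_all) + 1L]] <-
      lh[, c(HOLE_CART_FEATURES, "class")]
    # structures built from ground-truth hole classes so the structure tree
    # is trained on clean groupings
    lh$hole_class <- lh$class
    st <- build_structures(lh, col$mask)
    if (nrow(st) == 0) next
    sl <- gt_label_structures(st, lh, tl$truth)
    sl <- sl[!is.na(sl$class), ]
    structs_all[[length(structs_all) + 1L]] <-
      sl[, c(STRUCTURE_CART_FEATURES, "class")]
  }
  list(holes = bind_rows(holes_all), structures = bind_rows(structs_all))
}

set.seed(1)
train <- collect_labeled(train_tiles(1:60))
cat("training holes:", nrow(train$holes), "\n")
print(table(train$holes$class))
cat("training structures:", nrow(train$structures), "\n")
print(table(train$structures$class))

hole_cart <- train_hole_cart(train$holes)
structure_cart <- train_structure_cart(train$structures)
print(hole_cart)
print(structure_cart)

cat("hole training accuracy:",
    mean(predict_cart(hole_cart, train$holes) == train$holes$class), "\n")
cat("structure training accuracy:",
    mean(predict_cart(structure_cart, train$structures) ==
           train$structures$class), "\n")

dir.create("inst/extdata", showWarnings = FALSE, recursive = TRUE)
write_cart(hole_cart, "inst/extdata/cart_hole.json")
write_cart(structure_cart, "inst/extdata/cart_structure.json")
cat("written inst/extdata/cart_hole.json, cart_structure.json\n")
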