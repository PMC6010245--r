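# Classification trees for hole and structure labeling. Training is
# delegated to rpart (Gini impurity, depth-limited); the fitted tree is
# immediately converted to a plain nested-list representation that predicts
# by threshold traversal and serializes losslessly to JSON.

#' @keywords internal
rpart_to_cart <- function(fit, features) {
  classes <- attr(fit, "ylevels")
  frame <- fit$frame
  node_ids <- as.integer(rownames(frame))
  is_leaf <- frame$var == "<leaf>"
  splits <- fit$splits
  split_row <- cumsum(!is_leaf)  # row of `splits` for each internal node

  build <- function(id) {
    i <- match(id, node_ids)
    if (is_leaf[i]) {
      return(list(leaf = TRUE, class = classes[frame$yval[i]],
                  n = frame$n[i]))
    }
    s <- splits[split_row[i], ]
    feature <- as.character(frame$var[i])
    threshold <- unname(s["index"])
    # ncat -1: left child takes x < threshold; +1: left takes x >= threshold
    left_op <- if (s["ncat"] < 0) "lt" else "ge"
    list(leaf = FALSE, feature = feature, threshold = threshold,
         left_op = left_op, n = frame$n[i],
         left = build(2L * id), right = build(2L * id + 1L))
  }
  structure(list(tree = build(1L), features = features, classes = classes),
            class = "cart_model")
}

single_leaf_cart <- function(class, features, n) {
  structure(list(tree = list(leaf = TRUE, class = class, n = n),
                 features = features, classes = class),
            class = "cart_model")
}

train_cart <- function(data, label_col, features, maxdepth = 4,
                       minbucket = 5) {
  labs <- as.character(data[[label_col]])
  if (length(unique(labs)) < 2) {
    warn("Single-class training data: returning a one-leaf tree.")
    return(single_leaf_cart(labs[1], features, nrow(data)))
  }
  df <- as.data.frame(data[features])
  df$.class <- factor(labs)
  fit <- rpart::rpart(
    .class ~ ., data = df, method = "class",
    parms = list(split = "gini"),
    control = rpart::rpart.control(
      maxdepth = maxdepth, minbucket = minbucket, minsplit = 2 * minbucket,
      cp = 0, xval = 0, maxcompete = 0, maxsurrogate = 0, usesurrogate = 0
    )
  )
  rpart_to_cart(fit, features)
}

#' Predict classes from a CART model
#'
#' Traverses the decision tree for each row of `data`. Prediction depends
#' only on the named feature columns, so it is invariant to column order.
#'
#' @param model A `"cart_model"` from [train_hole_cart()],
#'   [train_structure_cart()] or [read_cart()].
#' @param data Data frame containing the model's feature columns.
#' @return Character vector of predicted classes.
#' @export
predict_cart <- function(model, data) {
  stopifnot(inherits(model, "cart_model"))
  missing <- setdiff(model$features, names(data))
  if (length(missing) > 0) {
    abort(paste0("Missing feature column(s): ", paste(missing, collapse = ", ")))
  }
  one <- function(row) {
    node <- model$tree
    while (!node$leaf) {
      x <- row[[node$feature]]
      go_left <- if (node$left_op == "lt") x < node$threshold else x >= node$threshold
      node <- if (go_left) node$left else node$right
    }
    node$class
  }
  if (nrow(data) == 0) return(character(0))
  vapply(seq_len(nrow(data)), function(i) one(data[i, , drop = FALSE]),
         character(1))
}

#' Serialize / restore a CART model as a JSON tree
#'
#' @param model A `"cart_model"`.
#' @param path File path.
#' @return `write_cart()` returns `path` invisibly; `read_cart()` the model.
#' @export
write_cart <- function(model, path) {
  stopifnot(inherits(model, "cart_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cart
#' @export
read_cart <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  fix <- function(node) {
    node$leaf <- isTRUE(node$leaf)
    if (!node$leaf) {
      node$threshold <- as.numeric(node$threshold)
      node$left <- fix(node$left)
      node$right <- fix(node$right)
    }
    node
  }
  structure(list(tree = fix(obj$tree),
                 features = as.character(unlist(obj$features)),
                 classes = as.character(unlist(obj$classes))),
            class = "cart_model")
}

#' @export
print.cart_model <- function(x, ...) {
  rec <- function(node, indent) {
    pad <- strrep("  ", indent)
    if (node$leaf) {
      cat(pad, "-> ", node$class, " (n=", node$n, ")\n", sep = "")
    } else {
      op <- if (node$left_op == "lt") "<" else ">="
      cat(pad, node$feature, " ", op, " ", signif(node$threshold, 4), "\n",
          sep = "")
      rec(node$left, indent + 1)
      rec(node$right, indent + 1)
    }
  }
  cat("CART model (classes: ", paste(x$classes, collapse = ", "), ")\n",
      sep = "")
  rec(x$tree, 0)
  invisible(x)
}

HOLE_CART_FEATURES <- c("density", "width_um", "length_um", "solidity",
                        "surrounding_collagen_um2")
STRUCTURE_CART_FEATURES <- c("n_holes", "total_hole_area_um2",
                             "max_hole_area_um2", "collagen_area_um2")

#' Train the hole-classification CART
#'
#' Distinguishes holes caused by vessels and bile ducts from other holes
#' (steatosis, cracks) using the five hole features: neighbour density,
#' width, length, solidity and surrounding collagen area. Gini impurity,
#' depth at most 4, at least 5 holes per leaf.
#'
#' @param holes Tibble from [detect_holes()] with a `class` column taking
#'   values `"vessel_or_duct"` and `"other"`.
#' @param maxdepth,minbucket Tree size controls.
#' @return A `"cart_model"`.
#' @export
train_hole_cart <- function(holes, maxdepth = 4, minbucket = 5) {
  train_cart(holes, "class", HOLE_CART_FEATURES, maxdepth, minbucket)
}

#' Train the portal-tract / central-vein structure CART
#'
#' Separates portal-tract from central-vein structures using the number of
#' holes, total and maximal hole areas, and associated collagen area.
#'
#' @param structures Tibble from [build_structures()] with a `class` column
#'   taking values `"portal_tract"` and `"central_vein"`.
#' @inheritParams train_hole_cart
#' @return A `"cart_model"`.
#' @export
train_structure_cart <- function(structures, maxdepth = 4, minbucket = 5) {
  train_cart(structures, "class", STRUCTURE_CART_FEATURES, maxdepth, minbucket)
}

#' Classify holes / structures with a CART model
#'
#' @param model A `"cart_model"`.
#' @param holes,structures Feature tibbles.
#' @return The tibble with a `hole_class` / `class` column added.
#' @export
classify_holes <- function(model, holes) {
  out <- dplyr::mutate(holes, hole_class = predict_cart(model, holes))
  attr(out, "labels") <- attr(holes, "labels")
  out
}

#' @rdname classify_holes
#' @export
classify_structures <- function(model, structures) {
  if (is.null(model)) abort("`model` must be a trained cart_model.")
  dplyr::mutate(structures, class = predict_cart(model, structures))
}

#' Decision trees bundled with the package
#'
#' The hole and structure CARTs shipped in `inst/extdata`, trained on a
#' fixed-seed synthetic cohort with pixel-level ground truth (the clinical
#' trees behind the original instrument are not public). See
#' `vignette("shgfib-methods")`.
#'
#' @return A `"cart_model"`.
#' @export
bundled_hole_cart <- function() {
  read_cart(system.file("extdata", "cart_hole.json", package = "shgfib",
                        mustWork = TRUE))
}

#' @rdname bundled_hole_cart
#' @export
bundled_structure_cart <- function() {
  read_cart(system.file("extdata", "cart_structure.json", package = "shgfib",
                        mustWork = TRUE))
}
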