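# Collagen-string morphometry. A "string" is an 8-connected component of the
# collagen mask. Its skeleton is the Zhang-Suen thinned centerline; length is
# the geodesic length of the skeleton (orthogonal steps count 1 pixel,
# diagonal steps sqrt(2)); width is area / length (ribbon model); a string is
# aggregated (cross-linked) when its skeleton has at least one branch point.

# One Zhang-Suen subiteration, vectorized over the whole matrix.
zs_subiteration <- function(sk, second) {
  p <- lapply(seq_len(8), function(i) {
    shift_mat(sk, NEIGHBOR_OFFSETS_8[i, 1], NEIGHBOR_OFFSETS_8[i, 2])
  })
  # clockwise order from north: P2=N, P3=NE, P4=E, P5=SE, P6=S, P7=SW, P8=W, P9=NW
  # offsets rows: 1=NW,2=N,3=NE,4=W,5=E,6=SW,7=S,8=SE
  P2 <- p[[2]]; P3 <- p[[3]]; P4 <- p[[5]]; P5 <- p[[8]]
  P6 <- p[[7]]; P7 <- p[[6]]; P8 <- p[[4]]; P9 <- p[[1]]
  B <- P2 + P3 + P4 + P5 + P6 + P7 + P8 + P9
  ring <- list(P2, P3, P4, P5, P6, P7, P8, P9, P2)
  A <- matrix(0, nrow(sk), ncol(sk))
  for (i in seq_len(8)) A <- A + (ring[[i]] == 0 & ring[[i + 1]] == 1)
  cond <- sk == 1 & B >= 2 & B <= 6 & A == 1
  if (!second) {
    cond <- cond & (P2 * P4 * P6 == 0) & (P4 * P6 * P8 == 0)
  } else {
    cond <- cond & (P2 * P4 * P8 == 0) & (P2 * P6 * P8 == 0)
  }
  sk[cond] <- 0
  sk
}

#' Skeletonize a binary mask (Zhang-Suen thinning)
#'
#' Iteratively peels border pixels that do not break connectivity until the
#' mask is one pixel wide.
#'
#' @param mask Logical or 0/1 matrix.
#' @return Logical matrix of skeleton pixels.
#' @export
skeletonize <- function(mask) {
  sk <- matrix(as.numeric(mask != 0), nrow(mask), ncol(mask))
  repeat {
    before <- sk
    sk <- zs_subiteration(sk, second = FALSE)
    sk <- zs_subiteration(sk, second = TRUE)
    if (identical(sk, before)) break
  }
  sk == 1
}

# Geodesic length of a skeleton pixel set, in pixels: each orthogonal
# adjacency contributes 1, each diagonal adjacency sqrt(2). Thinning erodes
# roughly half the ribbon width (~1 px) from every fiber end, so one step is
# added per skeleton endpoint (pixel with <= 1 skeleton neighbour); this also
# gives an isolated skeleton pixel length 1 (floor convention).
skeleton_length_px <- function(sk) {
  if (!any(sk)) return(1)  # fully annihilated compact blob: point-like
  s <- matrix(as.numeric(sk), nrow(sk), ncol(sk))
  n_orth <- sum(s * shift_mat(s, 0, 1)) + sum(s * shift_mat(s, 1, 0))
  n_diag <- sum(s * shift_mat(s, 1, 1)) + sum(s * shift_mat(s, 1, -1))
  n_end <- sum(sk & neighbor_sum8(s) <= 1)
  max(n_orth + sqrt(2) * n_diag + n_end, 1)
}

# number of skeleton pixels with >= 3 skeleton neighbors (junctions)
skeleton_branch_points <- function(sk) {
  if (!any(sk)) return(0L)
  s <- matrix(as.numeric(sk), nrow(sk), ncol(sk))
  sum(sk & neighbor_sum8(s) >= 3)
}

#' Extract collagen strings from a mask
#'
#' Labels the 8-connected components of the collagen mask, skeletonizes each,
#' and measures per-string morphometry. Components smaller than `min_pixels`
#' are treated as noise and dropped. Each string is assigned the region
#' (CV/PT/PS) holding the majority of its pixels.
#'
#' @param mask Logical collagen matrix, or a `"collagen_mask"` from
#'   [detect_collagen()].
#' @param region_map Optional region map (integer matrix from
#'   [assign_regions()], or `NULL` for whole-tissue analysis).
#' @param pixel_size Micrometres per pixel.
#' @param min_pixels Minimum component size in pixels (default 4;
#'   sub-resolution objects have undefined skeletons).
#' @return Tibble with one row per string: `string_id`, `n_pixels`,
#'   `area_um2`, `length_um`, `width_um`, `n_branch_points`, `aggregation`,
#'   `region`, plus the label matrix as attribute `"labels"`.
#' @export
#' @examples
#' m <- matrix(FALSE, 32, 32); m[10:11, 5:24] <- TRUE
#' extract_strings(m)
extract_strings <- function(mask, region_map = NULL, pixel_size = 200 / 512,
                            min_pixels = 4) {
  if (inherits(mask, "collagen_mask")) mask <- mask$mask
  lab <- label_components8(mask)
  comps <- component_pixels(lab)
  comps <- Filter(function(px) length(px) >= min_pixels, comps)
  empty <- tibble(string_id = integer(0), n_pixels = integer(0),
                  area_um2 = numeric(0), length_um = numeric(0),
                  width_um = numeric(0), n_branch_points = integer(0),
                  aggregation = character(0), region = character(0))
  if (length(comps) == 0) {
    attr(empty, "labels") <- matrix(0L, nrow(mask), ncol(mask))
    return(empty)
  }
  nr <- nrow(mask)
  region_names <- c("CV", "PT", "PS")
  out_lab <- matrix(0L, nrow(mask), ncol(mask))
  rows <- vector("list", length(comps))
  for (i in seq_along(comps)) {
    px <- comps[[i]]
    out_lab[px] <- i
    rc <- cbind((px - 1L) %% nr + 1L, (px - 1L) %/% nr + 1L)
    # skeletonize within the component bounding box (padded by 1)
    r0 <- max(min(rc[, 1]) - 1L, 1L); r1 <- min(max(rc[, 1]) + 1L, nr)
    c0 <- max(min(rc[, 2]) - 1L, 1L); c1 <- min(max(rc[, 2]) + 1L, ncol(mask))
    sub <- matrix(FALSE, r1 - r0 + 1L, c1 - c0 + 1L)
    sub[cbind(rc[, 1] - r0 + 1L, rc[, 2] - c0 + 1L)] <- TRUE
    sk <- skeletonize(sub)
    len_um <- skeleton_length_px(sk) * pixel_size
    area_um2 <- length(px) * pixel_size^2
    nb <- skeleton_branch_points(sk)
    region <- if (is.null(region_map)) {
      NA_character_
    } else {
      r <- region_map[px]
      r <- r[r %in% 1:3]
      if (length(r) == 0) NA_character_ else {
        region_names[which.max(tabulate(r, nbins = 3))]
      }
    }
    rows[[i]] <- tibble(
      string_id = i, n_pixels = length(px), area_um2 = area_um2,
      length_um = len_um, width_um = area_um2 / len_um,
      n_branch_points = as.integer(nb),
      aggregation = if (nb >= 1) "aggregated" else "distributed",
      region = region
    )
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "labels") <- out_lab
  out
}

#' Classify strings as aggregated or distributed
#'
#' Aggregated (cross-linked) collagen is operationalized as a string whose
#' skeleton contains at least one branch point (a skeleton pixel with three
#' or more skeleton neighbours); distributed collagen has none.
#'
#' @param strings Tibble from [extract_strings()].
#' @return The tibble with its `aggregation` column (re)computed.
#' @export
classify_aggregation <- function(strings) {
  dplyr::mutate(strings,
                aggregation = ifelse(.data$n_branch_points >= 1,
                                     "aggregated", "distributed"))
}

#' Classify strings as thick or thin
#'
#' A string is thick when its width/length ratio is strictly greater than
#' `ratio` (default 0.25); a ratio of exactly 0.25 is thin.
#'
#' @param strings Tibble from [extract_strings()].
#' @param ratio Width/length cutoff.
#' @return The tibble with a `thickness` column.
#' @export
classify_thickness <- function(strings, ratio = 0.25) {
  dplyr::mutate(strings,
                thickness = ifelse(.data$width_um / .data$length_um > ratio,
                                   "thick", "thin"))
}

#' Classify strings as short or long
#'
#' By default a string is long when its length strictly exceeds the median
#' string length of the same subject (relative definition); with `cutoff_um`
#' given, an absolute cutoff in micrometres is used instead. When all
#' lengths are equal under the median rule, nothing exceeds the median and
#' every string is short.
#'
#' @param strings Tibble from [extract_strings()].
#' @param cutoff_um Optional absolute length cutoff in micrometres.
#' @return The tibble with a `length_class` column.
#' @export
classify_length <- function(strings, cutoff_um = NULL) {
  cut <- if (is.null(cutoff_um)) median(strings$length_um) else cutoff_um
  dplyr::mutate(strings,
                length_class = ifelse(.data$length_um > cut, "long", "short"))
}

#' Classify all string attributes
#'
#' Convenience wrapper applying [classify_aggregation()],
#' [classify_thickness()] and [classify_length()].
#'
#' @inheritParams classify_length
#' @inheritParams classify_thickness
#' @return Fully classified string tibble.
#' @export
classify_strings <- function(strings, ratio = 0.25, cutoff_um = NULL) {
  if (nrow(strings) == 0) {
    return(dplyr::mutate(strings, thickness = character(0),
                         length_class = character(0)))
  }
  strings |>
    classify_aggregation() |>
    classify_thickness(ratio = ratio) |>
    classify_length(cutoff_um = cutoff_um)
}
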