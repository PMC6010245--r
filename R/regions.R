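# Region segmentation: holes in the TPEF channel -> hole CART -> structures
# -> portal-tract / central-vein CART -> CV/PT/PS region map. Region codes:
# 0 = background, 1 = CV, 2 = PT, 3 = PS.

hole_moments_um <- function(rc, pixel_size) {
  # best-fit ellipse axes from second moments: full axis = 4 * sqrt(eigval)
  if (nrow(rc) < 2) {
    return(c(width = pixel_size, length = pixel_size))
  }
  cv <- stats::cov(rc) * (nrow(rc) - 1) / nrow(rc)
  # pixel extent adds 1/12 variance per axis
  cv <- cv + diag(1 / 12, 2)
  ev <- sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values)
  c(width = 4 * sqrt(max(ev[1], 0)) * pixel_size,
    length = 4 * sqrt(max(ev[2], 0)) * pixel_size)
}

hole_solidity <- function(rc) {
  if (nrow(rc) < 3) return(1)
  h <- grDevices::chull(rc)
  poly <- rc[h, , drop = FALSE]
  n <- nrow(poly)
  if (n < 3) return(1)
  x <- poly[, 1]; y <- poly[, 2]
  area <- abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  # hull pixel count = lattice points in the closed hull polygon, by Pick:
  # interior + boundary = A + B/2 + 1, with B from the edge gcds
  gcd2 <- function(a, b) {
    while (b != 0) { t <- a %% b; a <- b; b <- t }
    a
  }
  dx <- abs(x - c(x[-1], x[1])); dy <- abs(y - c(y[-1], y[1]))
  boundary <- sum(mapply(gcd2, dx, dy))
  hull_px <- area + boundary / 2 + 1
  min(nrow(rc) / hull_px, 1)
}

#' Detect holes in the TPEF channel
#'
#' Holes are connected dark components (vessel lumina, bile ducts, steatosis
#' vacuoles, cracks) lying fully inside the tissue. Components touching the
#' image border are discarded (their features would be truncated), as are
#' components below `min_area`. Each hole is measured: area, best-fit
#' ellipse width and length, solidity (area / convex-hull area), density
#' (number of neighbouring holes with centroids within
#' `density_radius_um`), and the collagen area within an annulus of
#' `annulus_um` around the hole.
#'
#' @param tpef Noise-removed TPEF intensity matrix.
#' @param tissue Logical tissue mask (see [tissue_mask()]).
#' @param collagen Logical collagen mask.
#' @param min_area Minimum hole area in square micrometres.
#' @param pixel_size Micrometres per pixel.
#' @param frac Fraction of the maximum TPEF intensity below which a pixel is
#'   dark.
#' @param density_radius_um Neighbourhood radius for the hole-density count.
#' @param annulus_um Width of the surrounding-collagen annulus.
#' @return Tibble with one row per hole (`hole_id`, `n_pixels`, `area_um2`,
#'   `width_um`, `length_um`, `solidity`, `density`,
#'   `surrounding_collagen_um2`, `row`, `col`) carrying the hole label
#'   matrix as attribute `"labels"`. An empty tissue mask yields an empty
#'   tibble.
#' @export
detect_holes <- function(tpef, tissue, collagen, min_area = 5,
                         pixel_size = 200 / 512, frac = 0.2,
                         density_radius_um = 100, annulus_um = 15) {
  nr <- nrow(tpef); nc <- ncol(tpef)
  empty <- tibble(hole_id = integer(0), n_pixels = integer(0),
                  area_um2 = numeric(0), width_um = numeric(0),
                  length_um = numeric(0), solidity = numeric(0),
                  density = integer(0), surrounding_collagen_um2 = numeric(0),
                  row = numeric(0), col = numeric(0))
  attr(empty, "labels") <- matrix(0L, nr, nc)
  if (!any(tissue)) return(empty)
  dark <- tissue & (tpef <= frac * max(tpef))
  if (!any(dark)) return(empty)
  lab <- label_components8(dark)
  comps <- component_pixels(lab)

  min_px <- ceiling(min_area / pixel_size^2)
  keep <- vapply(comps, function(px) {
    rc <- cbind((px - 1L) %% nr + 1L, (px - 1L) %/% nr + 1L)
    length(px) >= min_px &&
      !any(rc[, 1] %in% c(1L, nr) | rc[, 2] %in% c(1L, nc))
  }, logical(1))
  comps <- comps[keep]
  if (length(comps) == 0) return(empty)

  out_lab <- matrix(0L, nr, nc)
  ann_px <- annulus_um / pixel_size
  rows <- vector("list", length(comps))
  for (i in seq_along(comps)) {
    px <- comps[[i]]
    out_lab[px] <- i
    rc <- cbind((px - 1L) %% nr + 1L, (px - 1L) %/% nr + 1L)
    axes <- hole_moments_um(rc, pixel_size)
    # surrounding collagen within the annulus, computed in a padded
    # bounding box to keep the distance transform local
    pad <- ceiling(ann_px) + 1L
    r0 <- max(min(rc[, 1]) - pad, 1L); r1 <- min(max(rc[, 1]) + pad, nr)
    c0 <- max(min(rc[, 2]) - pad, 1L); c1 <- min(max(rc[, 2]) + pad, nc)
    sub <- matrix(FALSE, r1 - r0 + 1L, c1 - c0 + 1L)
    sub[cbind(rc[, 1] - r0 + 1L, rc[, 2] - c0 + 1L)] <- TRUE
    d <- distance_to(sub)
    ann <- d > 0 & d <= ann_px
    surr <- sum(ann & collagen[r0:r1, c0:c1, drop = FALSE])
    rows[[i]] <- tibble(
      hole_id = i, n_pixels = length(px),
      area_um2 = length(px) * pixel_size^2,
      width_um = unname(axes["width"]), length_um = unname(axes["length"]),
      solidity = hole_solidity(rc), density = 0L,
      surrounding_collagen_um2 = surr * pixel_size^2,
      row = mean(rc[, 1]), col = mean(rc[, 2])
    )
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) > 1) {
    d <- as.matrix(stats::dist(cbind(out$row, out$col))) * pixel_size
    out$density <- as.integer(rowSums(d <= density_radius_um) - 1L)
  }
  attr(out, "labels") <- out_lab
  out
}

#' Group holes into candidate vascular structures
#'
#' Single-linkage grouping of vessel/duct holes: two holes belong to the
#' same structure when their centroids are within `link_distance_um`
#' (transitively closed). With `link_by_collagen = TRUE` holes whose
#' surrounding-collagen annuli touch the same collagen component are also
#' linked; the default is off because bridging septa in advanced fibrosis
#' are contiguous collagen connecting distinct structures.
#'
#' @param holes Tibble from [detect_holes()], optionally filtered by the
#'   hole CART (only rows with `hole_class == "vessel_or_duct"` are grouped
#'   when the column is present).
#' @param collagen Logical collagen mask.
#' @param link_distance_um Centroid-distance linkage threshold.
#' @param pixel_size Micrometres per pixel.
#' @param link_by_collagen Also link holes bridged by one collagen
#'   component.
#' @param annulus_um Annulus width used for collagen linkage and the
#'   structure collagen area.
#' @return Tibble with one row per structure: `structure_id`, `n_holes`,
#'   `total_hole_area_um2`, `max_hole_area_um2`, `collagen_area_um2`,
#'   `row`, `col`, `hole_ids` (list column).
#' @export
build_structures <- function(holes, collagen, link_distance_um = 50,
                             pixel_size = 200 / 512,
                             link_by_collagen = FALSE, annulus_um = 15) {
  labels <- attr(holes, "labels")
  h <- if ("hole_class" %in% names(holes)) {
    holes[holes$hole_class == "vessel_or_duct", , drop = FALSE]
  } else {
    holes
  }
  empty <- tibble(structure_id = integer(0), n_holes = integer(0),
                  total_hole_area_um2 = numeric(0),
                  max_hole_area_um2 = numeric(0),
                  collagen_area_um2 = numeric(0),
                  row = numeric(0), col = numeric(0), hole_ids = list())
  if (nrow(h) == 0) return(empty)

  n <- nrow(h)
  parent <- uf_new(n)
  if (n > 1) {
    d <- as.matrix(stats::dist(cbind(h$row, h$col))) * pixel_size
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        if (d[i, j] <= link_distance_um) {
          a <- uf_find(parent, i); b <- uf_find(parent, j)
          if (a != b) parent[max(a, b)] <- min(a, b)
        }
      }
    }
    if (link_by_collagen && !is.null(labels)) {
      col_lab <- label_components8(collagen)
      ann_px <- annulus_um / pixel_size
      touched <- lapply(seq_len(n), function(i) {
        m <- labels == h$hole_id[i]
        d2 <- distance_to(m)
        unique(col_lab[d2 > 0 & d2 <= ann_px & col_lab > 0])
      })
      for (i in seq_len(n - 1)) {
        for (j in seq(i + 1, n)) {
          if (length(intersect(touched[[i]], touched[[j]])) > 0) {
            a <- uf_find(parent, i); b <- uf_find(parent, j)
            if (a != b) parent[max(a, b)] <- min(a, b)
          }
        }
      }
    }
  }
  roots <- vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
  groups <- split(seq_len(n), roots)

  ann_px <- annulus_um / pixel_size
  rows <- lapply(seq_along(groups), function(g) {
    idx <- groups[[g]]
    coll_area <- NA_real_
    if (!is.null(labels)) {
      m <- matrix(labels %in% h$hole_id[idx], nrow(labels), ncol(labels))
      d2 <- distance_to(m)
      coll_area <- sum(collagen & d2 > 0 & d2 <= ann_px) * pixel_size^2
    }
    tibble(
      structure_id = g, n_holes = length(idx),
      total_hole_area_um2 = sum(h$area_um2[idx]),
      max_hole_area_um2 = max(h$area_um2[idx]),
      collagen_area_um2 = coll_area,
      row = mean(h$row[idx]), col = mean(h$col[idx]),
      hole_ids = list(h$hole_id[idx])
    )
  })
  dplyr::bind_rows(rows)
}

#' Assign the CV/PT/PS region map
#'
#' Each classified structure claims its member holes plus a halo of
#' `halo_radius_um`; where halos of different structures overlap, the pixel
#' goes to the nearer structure. All remaining tissue is perisinusoidal.
#' The labels partition the tissue exactly: every tissue pixel receives one
#' of CV (1), PT (2) or PS (3); non-tissue pixels are 0.
#'
#' @param structures Classified tibble from [classify_structures()] (column
#'   `class` in `"central_vein"`/`"portal_tract"`).
#' @param holes The hole tibble whose `"labels"` attribute locates the
#'   member holes.
#' @param tissue Logical tissue mask.
#' @param halo_radius_um Halo dilation radius.
#' @param pixel_size Micrometres per pixel.
#' @return Integer matrix (0 = background, 1 = CV, 2 = PT, 3 = PS).
#' @export
assign_regions <- function(structures, holes, tissue, halo_radius_um = 25,
                           pixel_size = 200 / 512) {
  nr <- nrow(tissue); nc <- ncol(tissue)
  out <- matrix(0L, nr, nc)
  out[tissue] <- REGION_CODES[["PS"]]
  if (nrow(structures) == 0) return(out)
  if (!"class" %in% names(structures)) {
    abort("Structures must be classified first; see classify_structures().")
  }
  labels <- attr(holes, "labels")
  if (is.null(labels)) abort("`holes` must carry its label matrix attribute.")
  halo_px <- halo_radius_um / pixel_size
  best_d <- matrix(Inf, nr, nc)
  for (i in seq_len(nrow(structures))) {
    m <- matrix(labels %in% structures$hole_ids[[i]], nr, nc)
    d <- distance_to(m)
    code <- if (structures$class[i] == "central_vein") {
      REGION_CODES[["CV"]]
    } else {
      REGION_CODES[["PT"]]
    }
    sel <- tissue & d <= halo_px & d < best_d
    out[sel] <- code
    best_d[sel] <- d[sel]
  }
  out
}

#' Pixel-level region agreement
#'
#' @param predicted,truth Integer region maps.
#' @param tissue Logical mask over which agreement is measured.
#' @return Proportion of tissue pixels with identical labels.
#' @export
region_accuracy <- function(predicted, truth, tissue = truth > 0) {
  if (!any(tissue)) abort("Empty tissue mask.")
  mean(predicted[tissue] == truth[tissue])
}
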