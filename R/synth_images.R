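# Synthetic SHG/TPEF tile generator with pixel-level ground truth.
#
# Emulates the stage-dependent geometry of NAFLD fibrosis on a 512 x 512
# two-channel tile: central-vein and portal-tract structures (vessel lumina
# with collagen rims, bile ducts beside portal veins), steatosis vacuoles and
# cracks as TPEF holes, and collagen strings whose layout follows the Brunt
# progression -- perisinusoidal short thin strings (stage 1), periportal
# aggregated collagen (stage 2), bridging strings between structures
# (stage 3), septa enclosing nodules (stage 4). It makes no attempt at
# optical realism; shapes are chosen so every downstream classifier is
# learnable from its stated features.

#' Specification of one synthetic tile
#'
#' @param stage Brunt fibrosis stage, integer 0-4.
#' @param n_portal_tracts,n_central_veins Structures per tile (at most 4 in
#'   total by default geometry).
#' @param steatosis_hole_density Steatosis vacuoles per square millimetre.
#' @param crack_probability Probability that the tile contains one crack.
#' @param collagen_density_scale Nonnegative multiplier on the number of
#'   collagen strings (vessel-wall rims are always present).
#' @param noise_sd Intensity noise standard deviation (16-bit units); the
#'   background offset scales with it, so at 0 the background is exactly 0.
#' @param seed Integer seed; a fixed seed gives bit-identical tiles.
#' @return A list of class `"tile_spec"`.
#' @export
tile_spec <- function(stage, n_portal_tracts = 2, n_central_veins = 2,
                      steatosis_hole_density = 75, crack_probability = 0.25,
                      collagen_density_scale = 1, noise_sd = 300,
                      seed = 1L) {
  if (length(stage) != 1 || !stage %in% 0:4) {
    abort("`stage` must be a single integer in 0..4.")
  }
  if (steatosis_hole_density < 0 || collagen_density_scale < 0 ||
      noise_sd < 0) {
    abort("Densities and noise must be nonnegative.")
  }
  if (crack_probability < 0 || crack_probability > 1) {
    abort("`crack_probability` must be in [0, 1].")
  }
  if (n_portal_tracts < 0 || n_central_veins < 0 ||
      n_portal_tracts + n_central_veins < 1) {
    abort("Need at least one structure per tile.")
  }
  structure(
    list(stage = as.integer(stage),
         n_portal_tracts = as.integer(n_portal_tracts),
         n_central_veins = as.integer(n_central_veins),
         steatosis_hole_density = steatosis_hole_density,
         crack_probability = crack_probability,
         collagen_density_scale = collagen_density_scale,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "tile_spec"
  )
}

# ---- drawing primitives (pixel index sets on an nr x nc grid) -------------

px_ellipse <- function(nr, nc, cr, cc, a, b, theta = 0) {
  ext <- max(a, b) + 1
  r0 <- max(1, floor(cr - ext)); r1 <- min(nr, ceiling(cr + ext))
  c0 <- max(1, floor(cc - ext)); c1 <- min(nc, ceiling(cc + ext))
  rr <- seq(r0, r1); cc2 <- seq(c0, c1)
  R <- matrix(rr - cr, length(rr), length(cc2))
  C <- matrix(cc2 - cc, length(rr), length(cc2), byrow = TRUE)
  u <- R * cos(theta) + C * sin(theta)
  v <- -R * sin(theta) + C * cos(theta)
  sel <- (u / a)^2 + (v / b)^2 <= 1
  as.integer((matrix(cc2, length(rr), length(cc2), byrow = TRUE)[sel] - 1L) * nr +
               matrix(rr, length(rr), length(cc2))[sel])
}

px_segment <- function(nr, nc, p0, p1, width) {
  hw <- width / 2
  r0 <- max(1, floor(min(p0[1], p1[1]) - hw - 1))
  r1 <- min(nr, ceiling(max(p0[1], p1[1]) + hw + 1))
  c0 <- max(1, floor(min(p0[2], p1[2]) - hw - 1))
  c1 <- min(nc, ceiling(max(p0[2], p1[2]) + hw + 1))
  rr <- seq(r0, r1); cc <- seq(c0, c1)
  R <- matrix(rr, length(rr), length(cc))
  C <- matrix(cc, length(rr), length(cc), byrow = TRUE)
  d <- p1 - p0
  len2 <- sum(d^2)
  t <- if (len2 == 0) 0 else pmin(pmax(((R - p0[1]) * d[1] + (C - p0[2]) * d[2]) / len2, 0), 1)
  dist2 <- (R - (p0[1] + t * d[1]))^2 + (C - (p0[2] + t * d[2]))^2
  sel <- dist2 <= hw^2
  as.integer((C[sel] - 1L) * nr + R[sel])
}

px_polyline <- function(nr, nc, pts, width) {
  out <- integer(0)
  for (i in seq_len(nrow(pts) - 1)) {
    out <- c(out, px_segment(nr, nc, pts[i, ], pts[i + 1, ], width))
  }
  unique(out)
}

# ---- generator ------------------------------------------------------------

structure_slots <- function(n_total) {
  if (n_total <= 4) {
    grid <- expand.grid(r = c(146, 366), c = c(146, 366))
  } else {
    grid <- expand.grid(r = c(96, 256, 416), c = c(96, 256, 416))
  }
  if (n_total > nrow(grid)) {
    abort(sprintf("At most %d structures fit on one tile.", nrow(grid)))
  }
  grid[sample.int(nrow(grid), n_total), , drop = FALSE]
}

#' Generate one synthetic SHG/TPEF tile with ground truth
#'
#' Renders a 512 x 512 two-channel tile according to a [tile_spec()] and
#' returns it together with its pixel-level ground truth: the CV/PT/PS
#' region map, the hole table with classes (vessel, bile duct, steatosis,
#' crack) and structure memberships, the drawn collagen mask and the
#' per-string labels (aggregated/distributed, region). Collagen amount
#' grows with stage; vessel walls always carry a collagen rim.
#'
#' @param spec A [tile_spec()].
#' @return List with elements `tile` (an [tile_image()]) and `truth` (list:
#'   `stage`, `region_map`, `tissue`, `collagen`, `holes`, `structures`,
#'   `strings`).
#' @export
#' @examples
#' out <- generate_tile(tile_spec(stage = 2, seed = 42))
#' table(out$truth$region_map)
generate_tile <- function(spec) {
  stopifnot(inherits(spec, "tile_spec"))
  set.seed(spec$seed)
  nr <- TILE_PX; nc <- TILE_PX
  ps <- PIXEL_SIZE_UM
  margin <- 14L
  tissue <- matrix(FALSE, nr, nc)
  tissue[(margin + 1):(nr - margin), (margin + 1):(nc - margin)] <- TRUE

  n_struct <- spec$n_central_veins + spec$n_portal_tracts
  slots <- structure_slots(n_struct)
  jit <- matrix(runif(2 * n_struct, -10, 10), ncol = 2)
  centers <- cbind(slots$r + jit[, 1], slots$c + jit[, 2])
  struct_class <- c(rep("central_vein", spec$n_central_veins),
                    rep("portal_tract", spec$n_portal_tracts))

  hole_lab <- matrix(0L, nr, nc)
  collagen <- matrix(FALSE, nr, nc)
  hole_rows <- list()
  hole_id <- 0L
  rim_strings <- list()   # vessel-wall rims recorded as strings too

  add_hole <- function(px, class, structure_id) {
    hole_id <<- hole_id + 1L
    hole_lab[px] <<- hole_id
    hole_rows[[hole_id]] <<- tibble(
      hole_id = hole_id, class = class,
      structure_id = structure_id,
      row = mean((px - 1L) %% nr + 1L), col = mean((px - 1L) %/% nr + 1L),
      n_pixels = length(px)
    )
    hole_id
  }
  add_rim <- function(cr, cc, a, b, theta, rim_w, hole_px) {
    ring <- setdiff(px_ellipse(nr, nc, cr, cc, a + rim_w, b + rim_w, theta),
                    hole_px)
    collagen[ring] <<- TRUE
    rim_strings[[length(rim_strings) + 1L]] <<- ring
    ring
  }

  for (s in seq_len(n_struct)) {
    cr <- centers[s, 1]; cc <- centers[s, 2]
    if (struct_class[s] == "central_vein") {
      a <- runif(1, 14, 20); b <- a * runif(1, 0.7, 1); th <- runif(1, 0, pi)
      hole_px <- px_ellipse(nr, nc, cr, cc, a, b, th)
      add_hole(hole_px, "vessel", s)
      add_rim(cr, cc, a, b, th, runif(1, 2.8, 4), hole_px)
    } else {
      a <- runif(1, 8, 13); b <- a * runif(1, 0.7, 1); th <- runif(1, 0, pi)
      hole_px <- px_ellipse(nr, nc, cr, cc, a, b, th)
      add_hole(hole_px, "vessel", s)
      add_rim(cr, cc, a, b, th, runif(1, 2.6, 3.6), hole_px)
      for (d in seq_len(1L + stats::rbinom(1, 1, 0.7))) {
        ang <- runif(1, 0, 2 * pi)
        dist <- runif(1, 22, 35)
        dr <- cr + dist * cos(ang); dc <- cc + dist * sin(ang)
        r_d <- runif(1, 4, 6)
        duct_px <- px_ellipse(nr, nc, dr, dc, r_d, r_d)
        duct_px <- setdiff(duct_px, which(hole_lab > 0))
        if (length(duct_px) < 20) next
        add_hole(duct_px, "bile_duct", s)
        add_rim(dr, dc, r_d, r_d, 0, runif(1, 3, 4), duct_px)
      }
    }
  }

  far_from_structures <- function(r, c, min_d) {
    all(sqrt((centers[, 1] - r)^2 + (centers[, 2] - c)^2) >= min_d)
  }

  # steatosis vacuoles: rimless circles in the parenchyma
  area_mm2 <- (nr * ps / 1000) * (nc * ps / 1000)
  n_ste <- stats::rpois(1, spec$steatosis_hole_density * area_mm2)
  placed <- matrix(numeric(0), ncol = 2)
  for (k in seq_len(n_ste)) {
    for (try in 1:20) {
      r <- runif(1, 60, nr - 60); c <- runif(1, 60, nc - 60)
      ok <- far_from_structures(r, c, 95) &&
        (nrow(placed) == 0 ||
           all(sqrt((placed[, 1] - r)^2 + (placed[, 2] - c)^2) > 25))
      if (ok) break
    }
    if (!ok) next
    placed <- rbind(placed, c(r, c))
    r_s <- runif(1, 4, 7)
    px <- px_ellipse(nr, nc, r, c, r_s, r_s)
    px <- setdiff(px, which(hole_lab > 0))
    if (length(px) >= 20) add_hole(px, "steatosis", NA_integer_)
  }

  # crack: elongated low-solidity polyline hole
  if (runif(1) < spec$crack_probability) {
    for (try in 1:30) {
      r <- runif(1, 90, nr - 90); c <- runif(1, 90, nc - 90)
      if (far_from_structures(r, c, 110) &&
          (nrow(placed) == 0 ||
             all(sqrt((placed[, 1] - r)^2 + (placed[, 2] - c)^2) > 70))) break
    }
    ang <- runif(1, 0, pi)
    pts <- matrix(c(r, c), 1, 2)
    for (seg in 1:3) {
      ang <- ang + runif(1, -0.5, 0.5)
      step <- runif(1, 28, 45)
      pts <- rbind(pts, pts[nrow(pts), ] + step * c(cos(ang), sin(ang)))
    }
    pts[, 1] <- pmin(pmax(pts[, 1], margin + 3), nr - margin - 3)
    pts[, 2] <- pmin(pmax(pts[, 2], margin + 3), nc - margin - 3)
    px <- px_polyline(nr, nc, pts, runif(1, 1.8, 2.6))
    px <- setdiff(px, which(hole_lab > 0))
    if (length(px) >= 20) add_hole(px, "crack", NA_integer_)
  }

  holes <- dplyr::bind_rows(hole_rows)
  holes$area_um2 <- holes$n_pixels * ps^2
  attr(holes, "labels") <- hole_lab

  gt_structures <- tibble(
    structure_id = seq_len(n_struct),
    class = struct_class,
    hole_ids = lapply(seq_len(n_struct), function(s) {
      holes$hole_id[!is.na(holes$structure_id) & holes$structure_id == s]
    })
  )
  region_map <- assign_regions(gt_structures, holes, tissue,
                               halo_radius_um = 25, pixel_size = ps)

  # ---- collagen strings by stage ------------------------------------------
  scale <- spec$collagen_density_scale
  stage <- spec$stage
  string_px <- list()
  n_count <- function(base) {
    n <- round(base * scale)
    if (scale > 0 && base > 0) max(n, 1L) else n
  }
  # perisinusoidal strings keep clear of structures and of fat vacuoles
  # (lipid droplets displace the sinusoidal collagen around them)
  rand_ps_point <- function(min_d = 100, min_d_steatosis = 60) {
    for (try in 1:30) {
      r <- runif(1, margin + 15, nr - margin - 15)
      c <- runif(1, margin + 15, nc - margin - 15)
      if (far_from_structures(r, c, min_d) &&
          (nrow(placed) == 0 ||
             all(sqrt((placed[, 1] - r)^2 + (placed[, 2] - c)^2) >=
                   min_d_steatosis))) {
        return(c(r, c))
      }
    }
    c(r, c)
  }

  if (stage >= 1) {
    for (k in seq_len(n_count(40))) {
      p <- rand_ps_point()
      L <- runif(1, 8, 20); ang <- runif(1, 0, pi)
      q <- p + L * c(cos(ang), sin(ang))
      string_px <- c(string_px,
                     list(px_segment(nr, nc, p, q, runif(1, 1, 1.8))))
    }
  }
  if (stage >= 2) {
    pt_idx <- which(struct_class == "portal_tract")
    for (s in pt_idx) {
      for (k in seq_len(n_count(4))) {
        ang <- runif(1, 0, 2 * pi)
        rad <- runif(1, 16, 30)
        p <- centers[s, ] + rad * c(cos(ang), sin(ang))
        L <- runif(1, 15, 30)
        q <- p + L * c(cos(ang), sin(ang))
        main <- px_segment(nr, nc, p, q, runif(1, 1.6, 2.4))
        mid <- (p + q) / 2
        br <- integer(0)
        for (bk in seq_len(1L + stats::rbinom(1, 1, 0.6))) {
          bang <- ang + sample(c(-1, 1), 1) * runif(1, 0.7, 1.2)
          bl <- runif(1, 8, 16)
          br <- c(br, px_segment(nr, nc, mid, mid + bl * c(cos(bang), sin(bang)),
                                 runif(1, 1.4, 2)))
        }
        string_px <- c(string_px, list(unique(c(main, br))))
      }
    }
  }
  bridge <- function(i, j, width = NULL) {
    p <- centers[i, ]; q <- centers[j, ]
    u <- (q - p) / sqrt(sum((q - p)^2))
    p <- p + u * 22; q <- q - u * 22
    mid <- (p + q) / 2 + runif(2, -20, 20)
    pts <- rbind(p, mid, q)
    w <- if (is.null(width)) runif(1, 2, 3) else width
    main <- px_polyline(nr, nc, pts, w)
    br <- integer(0)
    for (f in c(0.3, 0.7)) {
      b0 <- p + f * (q - p)
      bang <- atan2(q[2] - p[2], q[1] - p[1]) + sample(c(-1, 1), 1) * runif(1, 0.8, 1.3)
      bl <- runif(1, 10, 20)
      br <- c(br, px_segment(nr, nc, b0, b0 + bl * c(cos(bang), sin(bang)),
                             runif(1, 1.4, 2)))
    }
    unique(c(main, br))
  }
  if (stage >= 3 && n_struct >= 2) {
    pairs <- utils::combn(n_struct, 2)
    mixed <- which(struct_class[pairs[1, ]] != struct_class[pairs[2, ]])
    ord <- c(sample(mixed), sample(setdiff(seq_len(ncol(pairs)), mixed)))
    for (k in seq_len(min(n_count(2 + (stage == 4)), length(ord)))) {
      string_px <- c(string_px,
                     list(bridge(pairs[1, ord[k]], pairs[2, ord[k]])))
    }
  }
  if (stage >= 4) {
    cr <- nr / 2 + runif(1, -15, 15); cc <- nc / 2 + runif(1, -15, 15)
    rad <- runif(1, 110, 150)
    angs <- seq(0, 2 * pi, length.out = 15)
    pts <- cbind(cr + rad * cos(angs), cc + rad * sin(angs))
    ring <- px_polyline(nr, nc, pts, runif(1, 2.5, 3.5))
    br <- integer(0)
    for (bk in 1:4) {
      a0 <- runif(1, 0, 2 * pi)
      b0 <- c(cr + rad * cos(a0), cc + rad * sin(a0))
      bl <- runif(1, 15, 25) * sample(c(-1, 1), 1)
      br <- c(br, px_segment(nr, nc, b0,
                             b0 + bl * c(cos(a0), sin(a0)),
                             runif(1, 1.6, 2.2)))
    }
    string_px <- c(string_px, list(unique(c(ring, br))))
  }

  # clip strings to tissue outside holes; classify from emitted geometry
  in_hole <- which(hole_lab > 0)
  tissue_idx <- which(tissue)
  string_px <- lapply(c(rim_strings, string_px), function(px) {
    setdiff(intersect(px, tissue_idx), in_hole)
  })
  string_px <- Filter(function(px) length(px) >= 4, string_px)
  for (px in string_px) collagen[px] <- TRUE
  collagen[in_hole] <- FALSE
  collagen <- collagen & tissue

  region_names <- c("CV", "PT", "PS")
  strings <- dplyr::bind_rows(lapply(seq_along(string_px), function(i) {
    px <- string_px[[i]]
    rc <- cbind((px - 1L) %% nr + 1L, (px - 1L) %/% nr + 1L)
    r0 <- max(min(rc[, 1]) - 1L, 1L); c0 <- max(min(rc[, 2]) - 1L, 1L)
    sub <- matrix(FALSE, max(rc[, 1]) - r0 + 2L, max(rc[, 2]) - c0 + 2L)
    sub[cbind(rc[, 1] - r0 + 1L, rc[, 2] - c0 + 1L)] <- TRUE
    nb <- skeleton_branch_points(skeletonize(sub))
    rg <- region_map[px]; rg <- rg[rg %in% 1:3]
    tibble(string_id = i, n_pixels = length(px),
           aggregation = if (nb >= 1) "aggregated" else "distributed",
           region = if (length(rg) == 0) NA_character_ else
             region_names[which.max(tabulate(rg, nbins = 3))])
  }))
  attr(strings, "pixels") <- string_px

  # ---- render channels ----------------------------------------------------
  bg <- 3 * spec$noise_sd
  tpef <- matrix(bg, nr, nc)
  tpef[tissue] <- 20000
  tpef[in_hole] <- bg
  # one brightness per string (smooth within a string, so speckle
  # suppression never fires on genuine collagen)
  shg <- matrix(bg, nr, nc)
  for (px in string_px) shg[px] <- 15000 + runif(1, 0, 10000)
  if (spec$noise_sd > 0) {
    tpef <- tpef + rnorm(nr * nc, sd = spec$noise_sd)
    shg <- shg + rnorm(nr * nc, sd = spec$noise_sd)
    n_salt <- round(1e-4 * nr * nc)
    salt <- sample.int(nr * nc, n_salt)
    shg[salt] <- runif(n_salt, 55000, 63000)
  }
  tile <- tile_image(pmax(shg, 0), pmax(tpef, 0), pixel_size = ps)

  list(tile = tile,
       truth = list(stage = spec$stage, region_map = region_map,
                    tissue = tissue, collagen = collagen, holes = holes,
                    structures = gt_structures, strings = strings))
}

#' Generate a synthetic cohort of subjects with tiles and ground truth
#'
#' Draws each subject's Brunt stage from `stage_probabilities` and renders
#' `tiles_per_subject` tiles per subject with seeds derived
#' deterministically from the master seed.
#'
#' @param n Number of subjects (>= 1).
#' @param stage_probabilities Probabilities of stages 0-4 summing to 1;
#'   default is the reference NAFLD cohort distribution.
#' @param tiles_per_subject Tiles rendered per subject.
#' @param seed Master seed.
#' @param stages Optional explicit vector of `n` stages overriding the
#'   random draw (e.g. for stage-stratified experiments).
#' @param ... Further arguments passed to [tile_spec()] (e.g. `noise_sd`,
#'   `collagen_density_scale`).
#' @return Tibble with columns `subject_id`, `stage`, `tiles` (list column;
#'   each element a list of [generate_tile()] outputs).
#' @export
generate_cohort <- function(n, stage_probabilities = c(0.229, 0.301, 0.084,
                                                       0.169, 0.217),
                            tiles_per_subject = 2, seed = 1L, stages = NULL,
                            ...) {
  if (n < 1) abort("`n` must be >= 1.")
  check_stage_probabilities(stage_probabilities)
  set.seed(seed)
  if (is.null(stages)) {
    stages <- sample(0:4, n, replace = TRUE, prob = stage_probabilities)
  } else if (length(stages) != n || !all(stages %in% 0:4)) {
    abort("`stages` must be `n` values in 0..4.")
  }
  tiles <- lapply(seq_len(n), function(s) {
    lapply(seq_len(tiles_per_subject), function(t) {
      generate_tile(tile_spec(stage = stages[s], ...,
                              seed = seed + 7919L * (s - 1L) + 131L * (t - 1L)))
    })
  })
  tibble(subject_id = sprintf("S%03d", seq_len(n)), stage = stages,
         tiles = tiles)
}

#' Assemble tiles into a five-by-five multi-tile field
#'
#' @param tiles List of exactly 25 [tile_image()] objects with a common
#'   pixel size.
#' @return List of class `"multitile"` (fields `tiles`, `grid`,
#'   `pixel_size`).
#' @export
multitile <- function(tiles) {
  if (length(tiles) != 25) abort("A multi-tile field has exactly 25 tiles.")
  ps <- unique(vapply(tiles, function(t) t$pixel_size, numeric(1)))
  if (length(ps) != 1) abort("Tiles must share one pixel size.")
  structure(list(tiles = tiles, grid = 5L, pixel_size = ps),
            class = "multitile")
}

# ---- ground-truth labeling of detected objects ----------------------------

#' Label detected holes / structures with ground-truth classes
#'
#' Matches each detected hole to the ground-truth hole with the largest
#' pixel overlap and attaches its class, both as the four-way ground-truth
#' class (`gt_class`) and as the binary CART target `class`
#' (`"vessel_or_duct"` vs `"other"`). Unmatched holes are labeled
#' `"other"`. `gt_label_structures()` labels detected structures by the
#' majority ground-truth structure class of their member holes.
#'
#' @param detected Hole tibble from [detect_holes()] (with labels
#'   attribute).
#' @param truth Ground truth from [generate_tile()].
#' @return The tibble with ground-truth columns added.
#' @export
gt_label_holes <- function(detected, truth) {
  det_lab <- attr(detected, "labels")
  gt_lab <- attr(truth$holes, "labels")
  gt_class <- vapply(detected$hole_id, function(id) {
    overlap <- gt_lab[det_lab == id]
    overlap <- overlap[overlap > 0]
    if (length(overlap) == 0) return(NA_character_)
    truth$holes$class[which.max(tabulate(overlap, nbins = nrow(truth$holes)))]
  }, character(1))
  gt_sid <- vapply(detected$hole_id, function(id) {
    overlap <- gt_lab[det_lab == id]
    overlap <- overlap[overlap > 0]
    if (length(overlap) == 0) return(NA_integer_)
    gid <- which.max(tabulate(overlap, nbins = nrow(truth$holes)))
    truth$holes$structure_id[gid]
  }, integer(1))
  out <- dplyr::mutate(
    detected, gt_class = gt_class, gt_structure_id = gt_sid,
    class = ifelse(!is.na(gt_class) & gt_class %in% c("vessel", "bile_duct"),
                   "vessel_or_duct", "other")
  )
  attr(out, "labels") <- attr(detected, "labels")
  out
}

#' @rdname gt_label_holes
#' @param structures Structure tibble from [build_structures()].
#' @param labeled_holes Output of [gt_label_holes()].
#' @export
gt_label_structures <- function(structures, labeled_holes, truth) {
  cls <- vapply(structures$hole_ids, function(ids) {
    sid <- labeled_holes$gt_structure_id[match(ids, labeled_holes$hole_id)]
    sid <- sid[!is.na(sid)]
    if (length(sid) == 0) return(NA_character_)
    gid <- as.integer(names(which.max(table(sid))))
    truth$structures$class[truth$structures$structure_id == gid]
  }, character(1))
  dplyr::mutate(structures, class = cls)
}
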