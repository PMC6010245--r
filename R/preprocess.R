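# Reading and preprocessing of two-channel SHG/TPEF tiles: tile containers,
# background-noise removal, Otsu collagen segmentation, and random sampling
# of multi-tile fields.

#' Construct a two-channel image tile
#'
#' A tile holds registered SHG (collagen) and TPEF (tissue background)
#' intensity matrices of equal size, together with the physical pixel size.
#' The native acquisition geometry is 512 x 512 pixels covering
#' 200 x 200 micrometres (0.390625 um per pixel).
#'
#' @param shg,tpef Nonnegative numeric matrices of identical dimensions.
#' @param pixel_size Micrometres per pixel.
#' @return Object of class `"shg_tile"` (a list with `shg`, `tpef`,
#'   `pixel_size`).
#' @export
tile_image <- function(shg, tpef, pixel_size = 200 / 512) {
  if (!is.matrix(shg) || !is.matrix(tpef) || !all(dim(shg) == dim(tpef))) {
    abort("`shg` and `tpef` must be matrices of identical dimensions.")
  }
  if (any(shg < 0) || any(tpef < 0)) abort("Intensities must be nonnegative.")
  if (pixel_size <= 0) abort("`pixel_size` must be positive.")
  structure(list(shg = shg, tpef = tpef, pixel_size = pixel_size),
            class = "shg_tile")
}

#' @export
print.shg_tile <- function(x, ...) {
  cat(sprintf("SHG/TPEF tile: %d x %d px, %.6g um/px\n",
              nrow(x$shg), ncol(x$shg), x$pixel_size))
  invisible(x)
}

#' Write / read a tile as a two-page TIFF
#'
#' Page 1 holds the SHG channel and page 2 the TPEF channel, stored as 16-bit
#' grayscale. Intensities are assumed to lie in `[0, 65535]`.
#'
#' @param tile An [tile_image()].
#' @param path TIFF file path.
#' @param pixel_size Micrometres per pixel used when reading back.
#' @return `write_tile_tiff()` returns `path` invisibly; `read_tile_tiff()`
#'   returns the tile.
#' @export
write_tile_tiff <- function(tile, path) {
  stopifnot(inherits(tile, "shg_tile"))
  pages <- list(pmin(tile$shg, 65535) / 65535, pmin(tile$tpef, 65535) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_tile_tiff
#' @export
read_tile_tiff <- function(path, pixel_size = 200 / 512) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) < 2) abort("Expected a two-page TIFF (SHG, TPEF).")
  tile_image(round(pages[[1]] * 65535), round(pages[[2]] * 65535),
             pixel_size = pixel_size)
}

#' Sample multi-tile fields from a scan
#'
#' Chooses `n` five-by-five multi-tile fields uniformly without replacement
#' from the available candidate fields of a scan. With the native tile
#' geometry (200 um tiles, 5 x 5 grid) each field covers 1 mm x 1 mm, so the
#' default 10 fields sample 10 mm2 of tissue.
#'
#' @param fields List of candidate fields (each typically a list of 25
#'   tiles).
#' @param n Number of fields to sample (default 10).
#' @param seed Integer seed; the same seed selects the same fields.
#' @return A list of `n` fields. If fewer than `n` are available, all are
#'   returned with a warning.
#' @export
sample_multitiles <- function(fields, n = 10, seed = 1L) {
  if (length(fields) < n) {
    warn(sprintf("Only %d field(s) available; sampling all of them.",
                 length(fields)))
    return(fields)
  }
  set.seed(seed)
  fields[sort(sample.int(length(fields), n))]
}

#' Total sampled area of a multi-tile acquisition
#'
#' @param n_fields Number of multi-tile fields.
#' @param grid Tiles per side of a field (default 5).
#' @param tile_um Side length of one tile in micrometres (default 200).
#' @return Area in square millimetres.
#' @export
#' @examples
#' sampled_area_mm2()  # 10 fields of 5x5 200-um tiles -> 10 mm2
sampled_area_mm2 <- function(n_fields = 10, grid = 5, tile_um = 200) {
  n_fields * (grid * tile_um / 1000)^2
}

despeckle_channel <- function(x, margin_frac = 0.25) {
  rng <- max(x) - min(x)
  if (rng == 0) return(x)
  nb_max <- neighbor_max8(x, fill = min(x))
  speckle <- x > nb_max + margin_frac * rng
  x[speckle] <- nb_max[speckle]
  x
}

# Background level estimate: the modal intensity of the below-Otsu
# (background) class, taken as the lower edge of its modal 256-bin. After
# one subtraction the background mass sits at 0, which is the lower edge of
# the new modal bin, so a second application subtracts nothing.
modal_background <- function(x, levels = 256) {
  rng <- range(x)
  if (rng[1] == rng[2]) return(rng[1])
  t <- suppressWarnings(otsu_threshold(x, levels = levels))
  sub <- x[x <= t]
  rng <- range(sub)
  if (rng[1] == rng[2]) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = levels + 1)
  b <- findInterval(sub, breaks, rightmost.closed = TRUE)
  breaks[which.max(tabulate(b, nbins = levels))]  # lower edge of modal bin
}

#' Remove background noise from a tile
#'
#' Two steps per channel: (1) speckle suppression — a pixel exceeding the
#' maximum of its 8 neighbours by more than `margin_frac` of the channel's
#' dynamic range is replaced by that neighbourhood maximum, removing isolated
#' salt noise while leaving connected structures (including 1-pixel-wide
#' fiber tips) untouched; (2) background-offset removal — the lower edge of
#' the modal 256-bin intensity is subtracted and the result clipped at 0.
#' On images whose speckles are isolated single pixels the operation is
#' idempotent: a second application returns the input unchanged.
#'
#' @param tile An [tile_image()].
#' @param margin_frac Speckle margin as a fraction of the dynamic range.
#' @return A noise-removed [tile_image()].
#' @export
remove_noise <- function(tile, margin_frac = 0.25) {
  stopifnot(inherits(tile, "shg_tile"))
  clean <- function(x) {
    x <- despeckle_channel(x, margin_frac)
    pmax(x - modal_background(x), 0)
  }
  tile_image(clean(tile$shg), clean(tile$tpef), pixel_size = tile$pixel_size)
}

#' Otsu's threshold
#'
#' Bins the intensities into `levels` equal-width bins across the observed
#' range and returns the bin boundary maximizing the between-class variance
#' of the two-class split. Ties in the objective are broken toward the
#' lowest threshold, which is inclusive of faint collagen. Pixels are called
#' foreground when strictly above the returned threshold, so for 8-bit
#' integer images the result is the classical per-gray-level Otsu threshold.
#'
#' @param x Numeric matrix or vector of intensities.
#' @param levels Number of histogram bins (default 256).
#' @return Threshold in intensity units, or `NA` with a warning for a
#'   constant input (degenerate histogram).
#' @export
otsu_threshold <- function(x, levels = 256) {
  v <- as.numeric(x)
  rng <- range(v)
  if (rng[1] == rng[2]) {
    warn("Constant image: Otsu threshold undefined; returning NA.")
    return(NA_real_)
  }
  breaks <- seq(rng[1], rng[2], length.out = levels + 1)
  b <- findInterval(v, breaks, rightmost.closed = TRUE)  # 1..levels
  counts <- tabulate(b, nbins = levels)
  sums <- numeric(levels)
  bin_sums <- rowsum(v, b)
  sums[as.integer(rownames(bin_sums))] <- bin_sums
  W0 <- cumsum(as.numeric(counts))     # class-0 sizes for split after bin t
  S0 <- cumsum(sums)                   # class-0 intensity sums (exact)
  n_tot <- W0[levels]
  s_tot <- S0[levels]
  # between-class variance (up to a constant factor) for split after bin t
  t <- seq_len(levels - 1)
  valid <- W0[t] > 0 & W0[t] < n_tot
  sigma_b <- rep(-Inf, levels - 1)
  sigma_b[valid] <- (s_tot * W0[t][valid] - n_tot * S0[t][valid])^2 /
    (W0[t][valid] * (n_tot - W0[t][valid]))
  best <- which.max(sigma_b)           # which.max takes the first (lowest) tie
  breaks[best + 1]                     # upper edge of the last class-0 bin
}

#' Segment collagen from the SHG channel
#'
#' Thresholds the (noise-removed) SHG channel with [otsu_threshold()]; the
#' collagen mask contains the pixels strictly above the threshold. Adding a
#' constant to every pixel shifts the threshold by the same constant and
#' leaves the mask unchanged.
#'
#' @param shg Numeric matrix (noise-removed SHG intensities).
#' @param threshold Optional fixed threshold; `NULL` (default) uses Otsu.
#' @param levels Histogram bins for Otsu.
#' @return Object of class `"collagen_mask"`: list with `mask` (logical
#'   matrix) and `threshold`. A constant image yields an empty mask with a
#'   warning.
#' @export
detect_collagen <- function(shg, threshold = NULL, levels = 256) {
  if (is.null(threshold)) threshold <- otsu_threshold(shg, levels = levels)
  if (is.na(threshold)) {
    mask <- matrix(FALSE, nrow(shg), ncol(shg))
    return(structure(list(mask = mask, threshold = NA_real_),
                     class = "collagen_mask"))
  }
  structure(list(mask = shg > threshold, threshold = threshold),
            class = "collagen_mask")
}

#' @export
print.collagen_mask <- function(x, ...) {
  cat(sprintf("Collagen mask: %d x %d px, %.1f%% collagen, threshold %.4g\n",
              nrow(x$mask), ncol(x$mask), 100 * mean(x$mask), x$threshold))
  invisible(x)
}

#' Tissue extent from the TPEF channel
#'
#' Tissue is where the (noise-removed) TPEF signal exceeds `frac` of its
#' maximum; interior holes (vessels, ducts, steatosis, cracks) are filled so
#' the mask covers the full biopsy footprint, hole interiors included.
#'
#' @param tpef Numeric matrix.
#' @param frac Fraction of the maximum TPEF intensity delimiting tissue.
#' @return Logical matrix.
#' @export
tissue_mask <- function(tpef, frac = 0.2) {
  if (max(tpef) == 0) return(matrix(FALSE, nrow(tpef), ncol(tpef)))
  bright <- tpef > frac * max(tpef)
  storage.mode(bright) <- "double"
  filled <- EBImage::fillHull(bright)
  matrix(as.logical(filled), nrow(tpef), ncol(tpef))
}
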