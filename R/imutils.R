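# Low-level image helpers shared by preprocessing, region segmentation and
# morphometry. Images are plain numeric/logical matrices, row-major with
# 0-based pixel coordinates at the analysis level; physical scale enters only
# through pixel_size (micrometres per pixel).

TILE_PX <- 512L
TILE_UM <- 200
PIXEL_SIZE_UM <- TILE_UM / TILE_PX  # 0.390625 um per pixel

shift_mat <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- seq_len(nr) - dr
  cs <- seq_len(nc) - dc
  ok_r <- rs >= 1 & rs <= nr
  ok_c <- cs >= 1 & cs <= nc
  out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
  out
}

NEIGHBOR_OFFSETS_8 <- cbind(
  dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
  dc = c(-1, 0, 1, -1, 1, -1, 0, 1)
)

# sum of the 8 neighbors of each pixel
neighbor_sum8 <- function(m, fill = 0) {
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_len(8)) {
    out <- out + shift_mat(m, NEIGHBOR_OFFSETS_8[i, 1], NEIGHBOR_OFFSETS_8[i, 2],
                           fill = fill)
  }
  out
}

# elementwise max over the 8 neighbors
neighbor_max8 <- function(m, fill = -Inf) {
  out <- matrix(-Inf, nrow(m), ncol(m))
  for (i in seq_len(8)) {
    out <- pmax(out, shift_mat(m, NEIGHBOR_OFFSETS_8[i, 1],
                               NEIGHBOR_OFFSETS_8[i, 2], fill = fill))
  }
  out
}

# union-find over integer ids
uf_new <- function(n) seq_len(n)
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

# 8-connected component labeling. EBImage::bwlabel is 4-connective; labels
# touching diagonally are merged afterwards with union-find.
label_components8 <- function(mask) {
  storage.mode(mask) <- "double"
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(lab), nrow(lab), ncol(lab))
  n <- max(lab)
  if (n < 2) return(lab)
  parent <- uf_new(n)
  for (i in c(1, 3)) {  # two diagonal directions cover both diagonals
    sh <- shift_mat(lab, NEIGHBOR_OFFSETS_8[i, 1], NEIGHBOR_OFFSETS_8[i, 2])
    sel <- lab > 0 & sh > 0 & lab != sh
    if (!any(sel)) next
    pairs <- unique(cbind(lab[sel], as.integer(sh[sel])))
    for (k in seq_len(nrow(pairs))) {
      a <- uf_find(parent, pairs[k, 1])
      b <- uf_find(parent, pairs[k, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  roots <- vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
  relab <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

# list of pixel index vectors (1-based linear indices), one per label
component_pixels <- function(lab) {
  idx <- which(lab > 0)
  if (length(idx) == 0) return(list())
  unname(split(idx, lab[idx]))
}

# Euclidean distance (pixels) of every pixel to the nearest TRUE pixel
distance_to <- function(mask) {
  if (!any(mask)) return(matrix(Inf, nrow(mask), ncol(mask)))
  m <- matrix(1, nrow(mask), ncol(mask))
  m[mask] <- 0
  d <- EBImage::distmap(m)
  matrix(as.numeric(d), nrow(mask), ncol(mask))
}

as_matrix <- function(x) matrix(as.numeric(x), nrow(x), ncol(x))
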