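# Grey-level texture features over segmented structures (IBSI formulations).
#
# Texture is computed in 2D per short-axis slice (thick slices make
# through-plane co-occurrence physically inhomogeneous) and pooled across
# slices by voxel-weighted averaging.  Intensities are quantized to a fixed
# number of bins by min-max scaling within the structure at the given phase,
# which makes all features invariant to adding a constant to the image.
# Constant-intensity structures occupy a single bin; by convention contrast,
# difference entropy and cluster tendency are then 0 and coarseness takes its
# cap value.

# Min-max quantization within the structure.  The effective bin count is
# min(n_bins, number of distinct values): discrete low-level images (e.g. a
# two-level checkerboard) then occupy adjacent bins, while continuous data
# use the full fixed bin number.
quantize_structure <- function(img3, bin3, n_bins) {
  vals <- img3[bin3]
  lo <- min(vals); hi <- max(vals)
  q <- array(NA_real_, dim(img3))
  if (hi == lo) {
    q[bin3] <- 1
    return(list(q = q, n_levels = 1L))
  }
  B <- min(n_bins, length(unique(vals)))
  q[bin3] <- pmin(floor((img3[bin3] - lo) / (hi - lo) * B) + 1, B)
  list(q = q, n_levels = B)
}

# Symmetric co-occurrence counts of one quantized slice over the given
# (row, col) offsets.  Returns a B x B count matrix.
glcm_counts_slice <- function(Q, n_bins, offsets) {
  nr <- nrow(Q); nc <- ncol(Q)
  counts <- numeric(n_bins * n_bins)
  for (off in offsets) {
    dr <- off[1]; dc <- off[2]
    r1 <- max(1, 1 - dr):min(nr, nr - dr)
    c1 <- max(1, 1 - dc):min(nc, nc - dc)
    a <- Q[r1, c1, drop = FALSE]
    b <- Q[r1 + dr, c1 + dc, drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) next
    idx <- (a[ok] - 1) * n_bins + b[ok]
    t1 <- tabulate(idx, nbins = n_bins * n_bins)
    counts <- counts + t1
    idx2 <- (b[ok] - 1) * n_bins + a[ok]
    counts <- counts + tabulate(idx2, nbins = n_bins * n_bins)
  }
  matrix(counts, n_bins, n_bins)
}

glcm_stats <- function(P) {
  B <- nrow(P)
  i <- matrix(seq_len(B), B, B)
  j <- t(i)
  contrast <- sum((i - j)^2 * P)
  k <- abs(i - j)
  p_d <- vapply(0:(B - 1), function(kk) sum(P[k == kk]), 0)
  p_d <- p_d[p_d > 0]
  difference_entropy <- -sum(p_d * log2(p_d))
  mu_i <- sum(i * P)  # symmetric: row and column means coincide
  cluster_tendency <- sum((i + j - 2 * mu_i)^2 * P)
  c(contrast = contrast, difference_entropy = difference_entropy,
    cluster_tendency = cluster_tendency)
}

#' Grey-level co-occurrence features of a structure
#'
#' Symmetric normalized GLCM at distance 1 over the in-slice direction set
#' (0, 45, 90, 135 degrees), computed per slice restricted to structure
#' voxels, directions pooled by count accumulation and slices pooled by
#' voxel-weighted averaging.  Features: contrast `sum (i-j)^2 p(i,j)`,
#' difference entropy `-sum p_(|i-j|)(k) log2 p_(|i-j|)(k)`, cluster tendency
#' `sum (i+j-mu_i-mu_j)^2 p(i,j)`.
#'
#' @param image Numeric 4D array `[row, col, slice, phase]` or [image_volume()].
#' @param mask A [label_mask()] (or 4D label array) on the same grid.
#' @param structure Structure name or label value.
#' @param phase Cardiac phase (1-based).
#' @param n_bins Quantization bins (default 32, min-max within structure).
#' @param directions List of `(drow, dcol)` offsets (default the 4 standard
#'   in-plane directions at distance 1).
#' @return Named vector `contrast`, `difference_entropy`, `cluster_tendency`
#'   (all 0 for a constant-intensity structure; all `NA` if the structure has
#'   fewer than 2 voxels).
#' @export
glcm_features <- function(image, mask, structure, phase, n_bins = 32,
                          directions = list(c(0L, 1L), c(-1L, 1L), c(1L, 0L),
                                            c(1L, 1L))) {
  vox <- if (inherits(image, "image_volume")) image$voxels else image
  lab <- if (inherits(mask, "label_mask")) mask$labels else mask
  img3 <- vox[, , , phase, drop = FALSE]; dim(img3) <- dim(img3)[1:3]
  bin3 <- lab[, , , phase, drop = FALSE] == structure_label(structure)
  dim(bin3) <- dim(img3)
  if (sum(bin3) < 2) {
    return(c(contrast = NA_real_, difference_entropy = NA_real_,
             cluster_tendency = NA_real_))
  }
  qz <- quantize_structure(img3, bin3, n_bins)
  if (qz$n_levels == 1L) {
    return(c(contrast = 0, difference_entropy = 0, cluster_tendency = 0))
  }
  feats <- NULL; weights <- NULL
  for (s in seq_len(dim(img3)[3])) {
    w <- sum(bin3[, , s])
    if (w < 2) next
    counts <- glcm_counts_slice(qz$q[, , s], n_bins, directions)
    tot <- sum(counts)
    if (tot == 0) next
    feats <- rbind(feats, glcm_stats(counts / tot))
    weights <- c(weights, w)
  }
  if (is.null(feats)) {
    return(c(contrast = NA_real_, difference_entropy = NA_real_,
             cluster_tendency = NA_real_))
  }
  colSums(feats * weights) / sum(weights)
}

ngtdm_slice <- function(Q, n_bins) {
  nr <- nrow(Q); nc <- ncol(Q)
  Z <- Q; Z[is.na(Z)] <- 0
  M <- !is.na(Q)
  S <- matrix(0, nr, nc); C <- matrix(0, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    r1 <- max(1, 1 - dr):min(nr, nr - dr)
    c1 <- max(1, 1 - dc):min(nc, nc - dc)
    S[r1, c1] <- S[r1, c1] + Z[r1 + dr, c1 + dc]
    C[r1, c1] <- C[r1, c1] + M[r1 + dr, c1 + dc]
  }
  use <- M & C > 0
  if (!any(use)) return(NULL)
  A <- S[use] / C[use]
  lev <- Q[use]
  diffs <- abs(lev - A)
  n_i <- tabulate(lev, nbins = n_bins)
  s_i <- numeric(n_bins)
  agg <- rowsum(diffs, lev)
  s_i[as.integer(rownames(agg))] <- agg[, 1]
  list(n_i = n_i, s_i = s_i, n_vox = sum(use))
}

ngtdm_stats <- function(n_i, s_i, n_vox, cap = 1e6) {
  p_i <- n_i / n_vox
  denom <- sum(p_i * s_i)
  coarseness <- if (denom > 0) min(1 / denom, cap) else cap
  lev <- which(p_i > 0)
  complexity <- 0
  if (length(lev) > 1) {
    for (a in lev) for (b in lev) {
      complexity <- complexity +
        abs(a - b) * (p_i[a] * s_i[a] + p_i[b] * s_i[b]) / (p_i[a] + p_i[b])
    }
    complexity <- complexity / n_vox
  }
  c(coarseness = coarseness, complexity = complexity)
}

#' Neighbourhood grey-tone difference features of a structure
#'
#' IBSI NGTDM computed in 2D per slice with the full 8-neighbourhood
#' (neighbour averages use in-structure neighbours only), pooled across
#' slices by voxel-weighted averaging.  Coarseness `1 / sum p_i s_i` is
#' capped at `1e6` (the cap value is returned for constant structures);
#' complexity follows the IBSI formula.
#'
#' @inheritParams glcm_features
#' @param cap Coarseness cap (default `1e6`).
#' @return Named vector `coarseness`, `complexity` (`NA` if the structure has
#'   fewer than 2 voxels).
#' @export
ngtdm_features <- function(image, mask, structure, phase, n_bins = 32, cap = 1e6) {
  vox <- if (inherits(image, "image_volume")) image$voxels else image
  lab <- if (inherits(mask, "label_mask")) mask$labels else mask
  img3 <- vox[, , , phase, drop = FALSE]; dim(img3) <- dim(img3)[1:3]
  bin3 <- lab[, , , phase, drop = FALSE] == structure_label(structure)
  dim(bin3) <- dim(img3)
  if (sum(bin3) < 2) return(c(coarseness = NA_real_, complexity = NA_real_))
  qz <- quantize_structure(img3, bin3, n_bins)
  feats <- NULL; weights <- NULL
  for (s in seq_len(dim(img3)[3])) {
    if (!any(bin3[, , s])) next
    res <- ngtdm_slice(qz$q[, , s], n_bins)
    if (is.null(res)) next
    feats <- rbind(feats, ngtdm_stats(res$n_i, res$s_i, res$n_vox, cap))
    weights <- c(weights, res$n_vox)
  }
  if (is.null(feats)) return(c(coarseness = NA_real_, complexity = NA_real_))
  colSums(feats * weights) / sum(weights)
}

#' First-order intensity statistics of a structure
#'
#' @inheritParams glcm_features
#' @return Named vector `mean`, `sd` of the structure's voxel intensities
#'   (`NA` if absent; `sd` 0 for a single voxel).
#' @export
first_order_features <- function(image, mask, structure, phase) {
  vox <- if (inherits(image, "image_volume")) image$voxels else image
  lab <- if (inherits(mask, "label_mask")) mask$labels else mask
  vals <- vox[, , , phase][lab[, , , phase] == structure_label(structure)]
  if (!length(vals)) return(c(mean = NA_real_, sd = NA_real_))
  c(mean = mean(vals), sd = if (length(vals) > 1) sd(vals) else 0)
}
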