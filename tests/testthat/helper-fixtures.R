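# Shared fixtures: digitized analytic shapes, tiny phantom configs, and
# independent brute-force oracles for the texture features and AUC.

grid_coords <- function(n) seq(-(n - 1) / 2, (n - 1) / 2)

# Digitized ball of radius r (voxel units) in an n^3 array.
digitized_ball <- function(r = 10, n = 2 * r + 9) {
  g <- grid_coords(n)
  outer(outer(g^2, g^2, "+"), g^2, "+") <= r^2
}

# 4D single-phase label array with one structure.
mask4 <- function(bin3, value = 3L) {
  lab <- array(0L, c(dim(bin3), 1L))
  lab[, , , 1][bin3] <- value
  lab
}

# Concentric LV shell (endo r_endo, epi r_epi) + RV disc, one slice.
shell_slice <- function(n = 121, r_endo = 30, r_epi = 40, rv_offset = 55,
                        rv_radius = 12) {
  g <- grid_coords(n)
  D <- sqrt(outer(g^2, g^2, "+"))
  sl <- matrix(0L, n, n)
  sl[D <= r_epi] <- 2L
  sl[D <= r_endo] <- 3L
  Drv <- sqrt(outer(g^2, (g + rv_offset)^2, "+"))
  sl[Drv <= rv_radius & D > r_epi + 1.5] <- 1L
  sl
}

tiny_phantom_config <- function(n_cases = 4, seed = 11, ...) {
  phantom_config(n_cases = n_cases, phases = 6, slices = 5, grid = c(64, 64),
                 spacing_mm = c(8, 2, 2), seed = seed, ...)
}

dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# Smooth random texture image (for registration tests).
smooth_texture <- function(n, seed, sigma = 2) {
  set.seed(seed)
  cardioloop:::gauss2d(matrix(rnorm(n * n), n, n), sigma) * 50 + 100
}

# ---- independent brute-force texture oracles (O(n^2) loops) ----------------

oracle_quantize <- function(img, n_bins = 32) {
  lo <- min(img); hi <- max(img)
  if (hi == lo) return(matrix(1L, nrow(img), ncol(img)))
  B <- min(n_bins, length(unique(as.vector(img))))
  q <- floor((img - lo) / (hi - lo) * B) + 1
  q[q > B] <- B
  q
}

oracle_glcm <- function(img, n_bins = 32,
                        offsets = list(c(0, 1), c(-1, 1), c(1, 0), c(1, 1))) {
  q <- oracle_quantize(img, n_bins)
  B <- max(q)
  P <- matrix(0, B, B)
  for (r in seq_len(nrow(q))) for (cc in seq_len(ncol(q))) {
    for (off in offsets) {
      r2 <- r + off[1]; c2 <- cc + off[2]
      if (r2 >= 1 && r2 <= nrow(q) && c2 >= 1 && c2 <= ncol(q)) {
        P[q[r, cc], q[r2, c2]] <- P[q[r, cc], q[r2, c2]] + 1
        P[q[r2, c2], q[r, cc]] <- P[q[r2, c2], q[r, cc]] + 1
      }
    }
  }
  P <- P / sum(P)
  contrast <- 0; ct <- 0
  mu <- 0
  for (i in seq_len(B)) for (j in seq_len(B)) mu <- mu + i * P[i, j]
  pd <- numeric(B)
  for (i in seq_len(B)) for (j in seq_len(B)) {
    contrast <- contrast + (i - j)^2 * P[i, j]
    ct <- ct + (i + j - 2 * mu)^2 * P[i, j]
    pd[abs(i - j) + 1] <- pd[abs(i - j) + 1] + P[i, j]
  }
  de <- -sum(pd[pd > 0] * log2(pd[pd > 0]))
  c(contrast = contrast, difference_entropy = de, cluster_tendency = ct)
}

oracle_ngtdm <- function(img, n_bins = 32, cap = 1e6) {
  q <- oracle_quantize(img, n_bins)
  B <- max(q)
  n_i <- numeric(B); s_i <- numeric(B); n_vox <- 0
  for (r in seq_len(nrow(q))) for (cc in seq_len(ncol(q))) {
    nb <- c()
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- cc + dc
      if (r2 >= 1 && r2 <= nrow(q) && c2 >= 1 && c2 <= ncol(q)) {
        nb <- c(nb, q[r2, c2])
      }
    }
    if (!length(nb)) next
    n_vox <- n_vox + 1
    lev <- q[r, cc]
    n_i[lev] <- n_i[lev] + 1
    s_i[lev] <- s_i[lev] + abs(lev - mean(nb))
  }
  p_i <- n_i / n_vox
  denom <- sum(p_i * s_i)
  coarseness <- if (denom > 0) min(1 / denom, cap) else cap
  complexity <- 0
  for (a in which(p_i > 0)) for (b in which(p_i > 0)) {
    if (a == b && length(which(p_i > 0)) == 1) next
    complexity <- complexity +
      abs(a - b) * (p_i[a] * s_i[a] + p_i[b] * s_i[b]) / (p_i[a] + p_i[b])
  }
  if (length(which(p_i > 0)) <= 1) complexity <- 0
  c(coarseness = coarseness, complexity = complexity / n_vox)
}

# AUC oracle: explicit pair counting (Mann-Whitney U / (n1 * n0)).
oracle_auc <- function(scores, positive) {
  pos <- scores[positive]; neg <- scores[!positive]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# Wrap a 2D matrix as the single-slice image/mask pair used by the texture
# functions (whole slice = structure).
as_texture_pair <- function(img) {
  list(image = array(img, c(dim(img), 1, 1)),
       mask = array(2L, c(dim(img), 1, 1)))
}
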