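# Separable Gaussian smoothing on pixel grids. Kernels are truncated at
# 3 scales; near boundaries (and around missing pixels on ragged grids) the
# kernel mass is renormalized over the pixels actually present.

gaussian_kernel_matrix <- function(n, scale) {
  if (scale <= 0) return(diag(n))
  r <- ceiling(3 * scale)
  idx <- seq_len(n)
  K <- matrix(0, n, n)
  for (d in -r:r) {
    w <- exp(-d^2 / (2 * scale^2))
    i <- idx[idx + d >= 1 & idx + d <= n]
    K[cbind(i, i + d)] <- w
  }
  K / rowSums(K)
}

# Smooth many fields at once. `fields` is an (H*W) x F matrix, each column a
# grid in column-major order (y fastest, i.e. matrix(col, H, W)). Returns a
# matrix of the same shape. Full grids only; masked smoothing handles
# ragged tissue outlines.
smooth_fields <- function(fields, H, W, scale) {
  if (scale <= 0) return(fields)
  fields <- as.matrix(fields)
  F <- ncol(fields)
  KH <- gaussian_kernel_matrix(H, scale)
  KW <- gaussian_kernel_matrix(W, scale)
  # y-direction: one gemm across all fields
  A <- KH %*% matrix(fields, nrow = H)              # H x (W*F)
  # x-direction: transpose each grid, stack, one gemm
  arr <- array(A, dim = c(H, W, F))
  B <- matrix(aperm(arr, c(2, 1, 3)), nrow = W)     # W x (H*F)
  B <- KW %*% B
  out <- aperm(array(B, dim = c(W, H, F)), c(2, 1, 3))
  matrix(out, nrow = H * W, ncol = F)
}

# Smooth per-pixel values on a possibly ragged grid: values are placed on the
# bounding grid, smoothed, and renormalized by the smoothed presence mask so
# that missing pixels contribute no mass.
smooth_pixel_values <- function(values, coords, scale) {
  if (scale <= 0) return(values)
  x <- coords[, 1] - min(coords[, 1])
  y <- coords[, 2] - min(coords[, 2])
  W <- max(x) + 1L; H <- max(y) + 1L
  idx <- y + 1L + H * x
  grid <- numeric(H * W); present <- numeric(H * W)
  grid[idx] <- values; present[idx] <- 1
  sm <- smooth_fields(cbind(grid, present), H, W, scale)
  out <- sm[idx, 1] / sm[idx, 2]
  out
}

# Smooth each column of a pixel-by-k matrix (e.g. mixture responsibilities).
smooth_pixel_matrix <- function(mat, coords, scale) {
  if (scale <= 0) return(mat)
  apply(mat, 2, smooth_pixel_values, coords = coords, scale = scale)
}
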