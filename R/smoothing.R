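#' Gaussian smoothing of a 3D volume
#'
#' Separable Gaussian convolution with `sigma = fwhm / (2 sqrt(2 ln 2))`
#' per axis, expressed in mm and converted to voxels via the voxel size.
#' The kernel is truncated at 4 sigma and normalised to unit sum;
#' zero-padding is used at the edges, so total activity is conserved as long
#' as the signal does not touch the volume boundary.
#'
#' @param vol 3D numeric array.
#' @param fwhm_mm Full width at half maximum in mm; scalar (isotropic) or
#'   length 3 (per axis). 0 returns the input unchanged.
#' @param voxel_mm Voxel size in mm, scalar or length 3.
#' @return Smoothed 3D array.
#' @export
smooth_image <- function(vol, fwhm_mm, voxel_mm = c(1, 1, 1)) {
  stop_if_not_3d(vol)
  if (length(fwhm_mm) == 1L) fwhm_mm <- rep(fwhm_mm, 3L)
  if (length(voxel_mm) == 1L) voxel_mm <- rep(voxel_mm, 3L)
  if (any(fwhm_mm < 0)) stop("fwhm_mm must be >= 0")
  out <- vol
  for (axis in 1:3) {
    if (fwhm_mm[axis] == 0) next
    sigma_vox <- fwhm_mm[axis] / (2 * sqrt(2 * log(2))) / voxel_mm[axis]
    out <- convolve_axis(out, gaussian_kernel(sigma_vox), axis)
  }
  out
}

gaussian_kernel <- function(sigma_vox) {
  r <- max(1L, ceiling(4 * sigma_vox))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# 1D convolution of a 3D array along one axis via a banded matrix product;
# zero-padding beyond the edges.
convolve_axis <- function(vol, kernel, axis) {
  d <- dim(vol)
  n <- d[axis]
  r <- (length(kernel) - 1L) / 2L
  K <- matrix(0, n, n)
  for (j in seq(-r, r)) {
    idx <- seq_len(n)
    src <- idx + j
    ok <- src >= 1 & src <= n
    K[cbind(idx[ok], src[ok])] <- K[cbind(idx[ok], src[ok])] + kernel[j + r + 1L]
  }
  perm <- c(axis, setdiff(1:3, axis))
  v <- aperm(vol, perm)
  dd <- dim(v)
  dim(v) <- c(dd[1], dd[2] * dd[3])
  v <- K %*% v
  dim(v) <- dd
  aperm(v, order(perm))
}

# Binary erosion with a Euclidean ball: keep the voxels of `mask` whose
# centre lies at least `depth_mm` from the nearest voxel outside it.
erode_mask <- function(mask, depth_mm, voxel_mm = c(1, 1, 1)) {
  stop_if_not_3d(mask)
  out <- mask != 0
  if (depth_mm <= 0) return(out)
  out & distance_to_background_mm(out, voxel_mm) >= depth_mm
}

# Exact Euclidean distance (mm) from every voxel to the nearest voxel
# outside the mask, by the separable lower-envelope (parabola) squared
# distance transform applied axis by axis.
distance_to_background_mm <- function(mask, voxel_mm = c(1, 1, 1)) {
  stop_if_not_3d(mask)
  if (length(voxel_mm) == 1L) voxel_mm <- rep(voxel_mm, 3L)
  d <- dim(mask)
  f <- array(ifelse(mask != 0, Inf, 0), d)
  for (axis in 1:3) {
    perm <- c(axis, setdiff(1:3, axis))
    v <- aperm(f, perm)
    dd <- dim(v)
    dim(v) <- c(dd[1], dd[2] * dd[3])
    for (col in seq_len(ncol(v))) {
      if (any(is.finite(v[, col])) && any(v[, col] > 0)) {
        v[, col] <- dt_envelope_1d(v[, col], voxel_mm[axis])
      }
    }
    dim(v) <- dd
    f <- aperm(v, order(perm))
  }
  sqrt(f)
}

# 1D squared-distance lower envelope (Felzenszwalb & Huttenlocher):
# out[p] = min_q f[q] + (step * (p - q))^2.
dt_envelope_1d <- function(f, step) {
  n <- length(f)
  fin <- which(is.finite(f))
  if (!length(fin)) return(f)
  x <- fin * step
  g <- f[fin]
  v <- integer(length(fin)); z <- numeric(length(fin) + 1L)
  k <- 1L; v[1] <- 1L; z[1] <- -Inf; z[2] <- Inf
  for (q in seq_along(fin)[-1]) {
    repeat {
      s <- ((g[q] + x[q]^2) - (g[v[k]] + x[v[k]]^2)) / (2 * (x[q] - x[v[k]]))
      if (s <= z[k]) { k <- k - 1L } else break
    }
    k <- k + 1L
    v[k] <- q; z[k] <- s; z[k + 1L] <- Inf
  }
  out <- numeric(n)
  k <- 1L
  for (p in seq_len(n)) {
    xp <- p * step
    while (z[k + 1L] < xp) k <- k + 1L
    out[p] <- (xp - x[v[k]])^2 + g[v[k]]
  }
  out
}

# Shift a 3D array by `by` voxels along `axis`, filling vacated entries.
shift_array <- function(x, by, axis, fill = 0) {
  d <- dim(x)
  out <- array(fill, d)
  n <- d[axis]
  if (abs(by) >= n) return(out)
  src <- if (by >= 0) seq_len(n - by) else seq(1 - by, n)
  dst <- if (by >= 0) seq(1 + by, n) else seq_len(n + by)
  ix <- function(i, a) if (a == axis) i else TRUE
  if (axis == 1) out[dst, , ] <- x[src, , ]
  else if (axis == 2) out[, dst, ] <- x[, src, ]
  else out[, , dst] <- x[, , src]
  out
}
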