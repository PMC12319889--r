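# Tricubic (piecewise cubic Lagrange, 4-point stencil) interpolation on the
# voxel grid. Reproduces polynomials up to degree 3 exactly; stencil indices
# are clamped at the volume edges; points outside [0, dim-1] yield NA.

cubic_lagrange_weights <- function(u) {
  # nodes -1, 0, 1, 2; u in [0, 1)
  cbind(-u * (u - 1) * (u - 2) / 6,
        (u + 1) * (u - 1) * (u - 2) / 2,
        -(u + 1) * u * (u - 2) / 2,
        (u + 1) * u * (u - 1) / 6)
}

interp_stencil_1d <- function(p, d) {
  i0 <- floor(p)
  i0[i0 > d - 2] <- d - 2  # keep u in [0,1] at the top edge
  u <- p - i0
  idx <- outer(i0, c(-1, 0, 1, 2), `+`)
  idx[idx < 0] <- 0
  idx[idx > d - 1] <- d - 1
  list(idx = idx, w = cubic_lagrange_weights(u))
}

#' Tricubic interpolation of a 3D array at continuous voxel coordinates
#'
#' @param arr 3D numeric array.
#' @param pts n x 3 matrix of continuous 0-based voxel coordinates.
#' @return numeric vector of interpolated values; NA outside the volume.
#' @keywords internal
tricubic_interp <- function(arr, pts) {
  d <- dim(arr)
  pts <- matrix(pts, ncol = 3L)
  oob <- pts[, 1] < 0 | pts[, 1] > d[1] - 1 |
         pts[, 2] < 0 | pts[, 2] > d[2] - 1 |
         pts[, 3] < 0 | pts[, 3] > d[3] - 1
  sx <- interp_stencil_1d(pmin(pmax(pts[, 1], 0), d[1] - 1), d[1])
  sy <- interp_stencil_1d(pmin(pmax(pts[, 2], 0), d[2] - 1), d[2])
  sz <- interp_stencil_1d(pmin(pmax(pts[, 3], 0), d[3] - 1), d[3])
  val <- numeric(nrow(pts))
  for (a in 1:4) for (b in 1:4) for (cc in 1:4) {
    w <- sx$w[, a] * sy$w[, b] * sz$w[, cc]
    val <- val + w * arr[cbind(sx$idx[, a] + 1L, sy$idx[, b] + 1L,
                               sz$idx[, cc] + 1L)]
  }
  val[oob] <- NA_real_
  val
}

# Sparse interpolation operator: rows = sample points, cols = voxels (column-
# major linear index). Lets a fixed sampling scheme be applied to every frame
# of a 4D series with one sparse-dense product.
tricubic_matrix <- function(dims, pts) {
  pts <- matrix(pts, ncol = 3L)
  n <- nrow(pts)
  oob <- pts[, 1] < 0 | pts[, 1] > dims[1] - 1 |
         pts[, 2] < 0 | pts[, 2] > dims[2] - 1 |
         pts[, 3] < 0 | pts[, 3] > dims[3] - 1
  sx <- interp_stencil_1d(pmin(pmax(pts[, 1], 0), dims[1] - 1), dims[1])
  sy <- interp_stencil_1d(pmin(pmax(pts[, 2], 0), dims[2] - 1), dims[2])
  sz <- interp_stencil_1d(pmin(pmax(pts[, 3], 0), dims[3] - 1), dims[3])
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  keep <- which(!oob)
  for (a in 1:4) for (b in 1:4) for (cc in 1:4) {
    w <- sx$w[keep, a] * sy$w[keep, b] * sz$w[keep, cc]
    j <- sx$idx[keep, a] + dims[1] * (sy$idx[keep, b] +
           dims[2] * sz$idx[keep, cc]) + 1L
    ii <- c(ii, keep); jj <- c(jj, j); xx <- c(xx, w)
  }
  M <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(n, prod(dims)))
  attr(M, "oob") <- oob
  M
}
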