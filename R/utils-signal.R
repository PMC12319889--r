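# Shared signal-processing helpers: DCT high-pass basis, separable Gaussian
# smoothing, and the canonical double-gamma haemodynamic response function.

#' Discrete-cosine high-pass basis
#'
#' Returns the DCT-II regressors whose period exceeds `cutoff` seconds, the
#' standard drift basis for fMRI high-pass filtering. Component k over n
#' volumes has period 2*n*tr/k.
#'
#' @param n number of volumes.
#' @param tr volume repeat time, seconds.
#' @param cutoff cutoff period, seconds; components with longer periods are
#'   returned.
#' @return n x K matrix (possibly 0 columns), unit-norm columns.
#' @export
dct_highpass_basis <- function(n, tr, cutoff) {
  if (cutoff < 2 * tr) stop("cutoff period ", cutoff,
                            " s is shorter than 2*TRvol = ", 2 * tr, " s")
  k_max <- floor(2 * n * tr / cutoff)
  if (k_max < 1L) return(matrix(numeric(0), nrow = n, ncol = 0L))
  t0 <- seq_len(n) - 1L
  X <- vapply(seq_len(k_max), function(k)
    cos(pi * (2 * t0 + 1) * k / (2 * n)), numeric(n))
  X <- matrix(X, nrow = n)
  sweep(X, 2L, sqrt(colSums(X^2)), "/")
}

# Regress the DCT drift set out of each column of y, preserving the mean.
dct_highpass_filter <- function(y, tr, cutoff) {
  y <- as.matrix(y)
  X <- dct_highpass_basis(nrow(y), tr, cutoff)
  if (ncol(X) == 0L) return(y)
  mu <- colMeans(y)
  yc <- sweep(y, 2L, mu)
  res <- yc - X %*% crossprod(X, yc)
  sweep(res, 2L, mu, "+")
}

gaussian_kernel_1d <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k / sum(k)
}

# band operator with replicated (clamped) edges for one axis
conv_band_matrix <- function(d, kernel) {
  r <- (length(kernel) - 1L) / 2L
  off <- -r:r
  i <- rep(seq_len(d), each = length(off))
  j <- pmin(pmax(i + rep(off, times = d), 1L), d)
  Matrix::sparseMatrix(i = i, j = j, x = rep(kernel, times = d),
                       dims = c(d, d))
}

# Separable Gaussian smoothing of a 3D array; sigma per axis, voxels.
gaussian_smooth_3d <- function(arr, sigma) {
  d <- dim(arr)
  if (length(sigma) == 1L) sigma <- rep(sigma, 3L)
  x <- arr
  for (ax in 1:3) {
    if (sigma[ax] <= 0) next
    K <- conv_band_matrix(d[ax], gaussian_kernel_1d(sigma[ax]))
    perm <- c(ax, setdiff(1:3, ax))
    xp <- aperm(x, perm)
    m <- matrix(xp, nrow = d[ax])
    m <- as.matrix(K %*% m)
    xp <- array(m, dim = d[perm])
    x <- aperm(xp, order(perm))
  }
  x
}

gaussian_smooth_2d <- function(mat, sigma) {
  d <- dim(mat)
  Kr <- conv_band_matrix(d[1], gaussian_kernel_1d(sigma))
  Kc <- conv_band_matrix(d[2], gaussian_kernel_1d(sigma))
  as.matrix(Kr %*% mat %*% Matrix::t(Kc))
}

#' Canonical double-gamma haemodynamic response function
#'
#' Peak delay 6 s, undershoot delay 16 s, dispersions 1 s, peak:undershoot
#' ratio 6, 32 s support; scaled to unit peak.
#'
#' @param t time, seconds.
#' @return HRF values at `t`.
#' @export
canonical_hrf <- function(t) {
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h[t < 0 | t > 32] <- 0
  h / max(stats::dgamma(5, shape = 6, rate = 1) -
            stats::dgamma(5, shape = 16, rate = 1) / 6)
}

# Convolve per-condition boxcars with the canonical HRF on a fine time grid
# and sample at volume midpoints.
convolve_events <- function(onsets, durations, n_volumes, tr, dt = 0.05) {
  t_max <- n_volumes * tr + 32
  grid <- seq(0, t_max, by = dt)
  box <- numeric(length(grid))
  for (k in seq_along(onsets)) {
    box[grid >= onsets[k] & grid < onsets[k] + durations[k]] <- 1
  }
  h <- canonical_hrf(seq(0, 32, by = dt))
  conv <- stats::convolve(box, rev(h), type = "open")[seq_along(grid)] * dt
  mid <- (seq_len(n_volumes) - 0.5) * tr
  stats::approx(grid, conv, xout = mid, rule = 2)$y
}
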