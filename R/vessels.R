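# Vessel mapping: multiscale Hessian (Frangi) vesselness for dark veins on
# SWI, a Haar wavelet detail filter for bright arteries on TOF, [-100,100]
# rescaling, surface projection, density and masking.

voxel_sizes <- function(vol) sqrt(colSums(vol$affine[1:3, 1:3]^2))

# central second derivatives (mm units) of a 3D array
hessian_3d <- function(arr, h) {
  d <- dim(arr)
  ix <- function(n) list(lo = c(1L, seq_len(n - 1L)), hi = c(seq_len(n - 1L) + 1L, n))
  s1 <- ix(d[1]); s2 <- ix(d[2]); s3 <- ix(d[3])
  dxx <- (arr[s1$hi, , ] - 2 * arr + arr[s1$lo, , ]) / h[1]^2
  dyy <- (arr[, s2$hi, ] - 2 * arr + arr[, s2$lo, ]) / h[2]^2
  dzz <- (arr[, , s3$hi] - 2 * arr + arr[, , s3$lo]) / h[3]^2
  dxy <- (arr[s1$hi, s2$hi, ] - arr[s1$hi, s2$lo, ] -
          arr[s1$lo, s2$hi, ] + arr[s1$lo, s2$lo, ]) / (4 * h[1] * h[2])
  dxz <- (arr[s1$hi, , s3$hi] - arr[s1$hi, , s3$lo] -
          arr[s1$lo, , s3$hi] + arr[s1$lo, , s3$lo]) / (4 * h[1] * h[3])
  dyz <- (arr[, s2$hi, s3$hi] - arr[, s2$hi, s3$lo] -
          arr[, s2$lo, s3$hi] + arr[, s2$lo, s3$lo]) / (4 * h[2] * h[3])
  list(xx = dxx, yy = dyy, zz = dzz, xy = dxy, xz = dxz, yz = dyz)
}

# eigenvalues of a field of symmetric 3x3 matrices (trigonometric closed form)
eigen_sym3 <- function(H) {
  a11 <- as.numeric(H$xx); a22 <- as.numeric(H$yy); a33 <- as.numeric(H$zz)
  a12 <- as.numeric(H$xy); a13 <- as.numeric(H$xz); a23 <- as.numeric(H$yz)
  q <- (a11 + a22 + a33) / 3
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 +
    2 * (a12^2 + a13^2 + a23^2)
  p <- sqrt(p2 / 6)
  e1 <- e2 <- e3 <- q
  nz <- p > 1e-300
  b11 <- (a11 - q) / p; b22 <- (a22 - q) / p; b33 <- (a33 - q) / p
  b12 <- a12 / p; b13 <- a13 / p; b23 <- a23 / p
  r <- (b11 * b22 * b33 + 2 * b12 * b13 * b23 -
        b11 * b23^2 - b22 * b13^2 - b33 * b12^2) / 2
  r <- pmin(pmax(r, -1), 1)
  phi <- acos(r) / 3
  e1[nz] <- (q + 2 * p * cos(phi))[nz]
  e3[nz] <- (q + 2 * p * cos(phi + 2 * pi / 3))[nz]
  e2[nz] <- (3 * q - e1 - e3)[nz]
  # sort by |eigenvalue| ascending, vectorized compare-swap network
  swap <- function(a, b) {
    sw <- abs(a) > abs(b)
    t <- a[sw]; a[sw] <- b[sw]; b[sw] <- t
    list(a = a, b = b)
  }
  s <- swap(e1, e2); e1 <- s$a; e2 <- s$b
  s <- swap(e2, e3); e2 <- s$a; e3 <- s$b
  s <- swap(e1, e2); e1 <- s$a; e2 <- s$b
  list(l1 = e1, l2 = e2, l3 = e3)
}

#' Multiscale Frangi vesselness for dark tubular structures
#'
#' Standard Hessian-based vesselness with eigenvalue ratios R_A, R_B and
#' second-order structure norm S, alpha = beta = 0.5 and c set to half the
#' maximum Frobenius norm of the Hessian per scale; responses are restricted
#' to DARK tubes on a bright background (veins are hypointense on SWI:
#' both large eigenvalues positive) and maximized over scales.
#'
#' @param swi a 3D [volume_grid].
#' @param scales_mm Gaussian scales, mm.
#' @param alpha,beta Frangi plate/blob sensitivity parameters.
#' @return a [volume_grid] of vesselness (same grid).
#' @export
frangi_veins <- function(swi, scales_mm = c(0.3, 0.6, 0.9, 1.2),
                         alpha = 0.5, beta = 0.5) {
  stopifnot(inherits(swi, "volume_grid"))
  if (length(dim(swi$data)) != 3L) stop("frangi_veins expects a 3D volume")
  if (length(scales_mm) == 0L) stop("empty scale list")
  h <- voxel_sizes(swi)
  best <- array(0, dim = dim(swi$data))
  for (sg in scales_mm) {
    sm <- gaussian_smooth_3d(swi$data, sg / h)
    H <- hessian_3d(sm, h)
    for (nm in names(H)) H[[nm]] <- H[[nm]] * sg^2   # gamma normalization
    ev <- eigen_sym3(H)
    S2 <- ev$l1^2 + ev$l2^2 + ev$l3^2
    # ignore numerically flat regions (e.g. constant input)
    if (sqrt(max(S2)) <= 1e-8 * max(abs(swi$data))) next
    c2 <- (sqrt(max(S2)) / 2)^2
    tube <- ev$l2 > 0 & ev$l3 > 0                    # dark structure polarity
    Ra2 <- ifelse(tube, (ev$l2 / ev$l3)^2, 0)
    Rb2 <- ifelse(tube, ev$l1^2 / pmax(abs(ev$l2 * ev$l3), 1e-300), 0)
    v <- ifelse(tube,
                (1 - exp(-Ra2 / (2 * alpha^2))) * exp(-Rb2 / (2 * beta^2)) *
                  (1 - exp(-S2 / (2 * pmax(c2, 1e-300)))),
                0)
    v <- array(v, dim = dim(best))
    best <- pmax(best, v)
  }
  volume_grid(best, swi$affine)
}

haar_level <- function(a) {
  d <- dim(a)
  if (d[1] %% 2L) a <- rbind(a, a[d[1], ])
  if (d[2] %% 2L) a <- cbind(a, a[, d[2]])
  d <- dim(a)
  io <- seq(1L, d[1], by = 2L); jo <- seq(1L, d[2], by = 2L)
  p <- a[io, , drop = FALSE]; q <- a[io + 1L, , drop = FALSE]
  rs <- (p + q) / 2; rd <- (p - q) / 2
  ll <- (rs[, jo, drop = FALSE] + rs[, jo + 1L, drop = FALSE]) / 2
  lh <- (rs[, jo, drop = FALSE] - rs[, jo + 1L, drop = FALSE]) / 2
  hl <- (rd[, jo, drop = FALSE] + rd[, jo + 1L, drop = FALSE]) / 2
  hh <- (rd[, jo, drop = FALSE] - rd[, jo + 1L, drop = FALSE]) / 2
  list(ll = ll, detail = sqrt(lh^2 + hl^2 + hh^2))
}

#' Haar wavelet artery filter
#'
#' Slice-wise multi-level 2D Haar decomposition of a time-of-flight volume;
#' the arterialness score is the sum over levels of the upsampled detail
#' magnitudes (bright, small, high-frequency structures score high),
#' smoothed in-plane with a 1-voxel Gaussian so slices stay independent.
#'
#' @param tof a 3D [volume_grid].
#' @param levels decomposition levels.
#' @param slice_axis axis perpendicular to the slices (default 3).
#' @return a [volume_grid] of arterialness.
#' @export
haar_arteries <- function(tof, levels = 2L, slice_axis = 3L) {
  stopifnot(inherits(tof, "volume_grid"))
  if (length(dim(tof$data)) != 3L) stop("haar_arteries expects a 3D volume")
  d <- dim(tof$data)
  in_plane <- setdiff(1:3, slice_axis)
  if (2^levels > min(d[in_plane]))
    stop("levels = ", levels, " exceeds log2 of the slice size")
  perm <- c(in_plane, slice_axis)
  x <- aperm(tof$data, perm)
  out <- array(0, dim = dim(x))
  for (s in seq_len(dim(x)[3])) {
    a <- x[, , s]
    score <- array(0, dim = dim(a))
    for (lev in seq_len(levels)) {
      hl <- haar_level(a)
      up <- kronecker(hl$detail, matrix(1, 2^lev, 2^lev))
      score <- score + up[seq_len(nrow(score)), seq_len(ncol(score))]
      a <- hl$ll
    }
    out[, , s] <- gaussian_smooth_2d(score, 1)
  }
  volume_grid(aperm(out, order(perm)), tof$affine)
}

#' Rescale vesselness into the reporting interval
#'
#' Linear min-max rescaling over the masked voxels: arteries to `[0, 100]`,
#' veins negated into `[-100, 0]` (strongest vein = -100). Values outside the
#' masked range are clamped.
#'
#' @param vesselness a [volume_grid] of filter output.
#' @param kind `"vein"` or `"artery"`.
#' @param mask a [volume_grid] (nonzero = in mask) or logical array.
#' @return a [volume_grid] of rescaled values.
#' @export
rescale_vesselness <- function(vesselness, kind = c("vein", "artery"), mask) {
  kind <- match.arg(kind)
  m <- if (inherits(mask, "volume_grid")) mask$data != 0 else mask
  if (!any(m)) stop("mask is empty")
  vals <- vesselness$data[m]
  lo <- min(vals); hi <- max(vals)
  if (hi - lo < 1e-300) {
    warning("constant vesselness input; returning zeros")
    return(volume_grid(array(0, dim(vesselness$data)), vesselness$affine))
  }
  sc <- pmin(pmax((vesselness$data - lo) / (hi - lo), 0), 1) * 100
  if (kind == "vein") sc <- -sc
  volume_grid(array(sc, dim(vesselness$data)), vesselness$affine)
}

#' Project a volume onto a surface
#'
#' Tricubic sampling of the volume at each vertex coordinate, the package's
#' volume-to-surface mapping.
#'
#' @param volume a 3D [volume_grid].
#' @param vertices n x 3 world-mm vertex coordinates.
#' @param labels per-vertex subfield labels.
#' @param kind `"vein"` or `"artery"`.
#' @param surface_name `"inner"` or `"outer"`.
#' @return an object of class `vessel_surface_map`.
#' @export
project_to_surface <- function(volume, vertices, labels,
                               kind = c("vein", "artery"),
                               surface_name = c("inner", "outer")) {
  kind <- match.arg(kind); surface_name <- match.arg(surface_name)
  vx <- world_to_voxel(vertices, volume)
  vals <- tricubic_interp(volume$data, vx)
  if (kind == "vein") vals <- pmin(vals, 0) else vals <- pmax(vals, 0)
  structure(list(values = vals, labels = as.character(labels), kind = kind,
                 surface = surface_name),
            class = "vessel_surface_map")
}

#' Vessel density per subfield
#'
#' Fraction of vertices passing the detection threshold within each subfield:
#' strict `value < threshold` for veins (default -3 a.u.), strict
#' `value > threshold` for arteries (default 1 a.u.).
#'
#' @param map a [vessel_surface_map].
#' @param threshold detection threshold, a.u.
#' @return data.frame with `subfield`, `surface`, `rho`, `n_vertices`.
#' @export
vessel_density <- function(map, threshold = if (map$kind == "vein") -3 else 1) {
  stopifnot(inherits(map, "vessel_surface_map"))
  if (length(map$values) == 0L) stop("empty vessel map")
  pass <- if (map$kind == "vein") map$values < threshold
          else map$values > threshold
  sf <- sort(unique(map$labels))
  data.frame(subfield = sf,
             surface = map$surface,
             rho = vapply(sf, function(s) mean(pass[map$labels == s]),
                          numeric(1)),
             n_vertices = vapply(sf, function(s) sum(map$labels == s),
                                 integer(1)),
             row.names = NULL)
}

#' Inner-minus-outer vessel density table
#'
#' @param map_inner,map_outer [vessel_surface_map]s of the same kind on the
#'   inner and outer surface.
#' @param threshold detection threshold, a.u.
#' @return data.frame with `subfield`, `rho_inner`, `rho_outer`, `delta_rho`.
#' @export
vessel_density_table <- function(map_inner, map_outer,
                                 threshold = if (map_inner$kind == "vein") -3 else 1) {
  di <- vessel_density(map_inner, threshold)
  do <- vessel_density(map_outer, threshold)
  sf <- intersect(di$subfield, do$subfield)
  data.frame(subfield = sf,
             rho_inner = di$rho[match(sf, di$subfield)],
             rho_outer = do$rho[match(sf, do$subfield)],
             delta_rho = di$rho[match(sf, di$subfield)] -
               do$rho[match(sf, do$subfield)],
             row.names = NULL)
}

#' Vein exclusion mask
#'
#' Flags vertices whose rescaled vein value falls strictly below the
#' threshold (default -3 a.u.) as belonging to a vessel; the flags are
#' consumable by [aggregate_profiles()].
#'
#' @param map a vein-kind [vessel_surface_map].
#' @param threshold a.u.
#' @return logical vector, `TRUE` = excluded.
#' @export
make_vein_mask <- function(map, threshold = -3) {
  stopifnot(inherits(map, "vessel_surface_map"))
  if (map$kind != "vein") stop("make_vein_mask expects a vein-kind map")
  map$values < threshold
}
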