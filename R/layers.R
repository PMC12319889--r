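#' Build the depth-sampling scheme for all subfields
#'
#' For every vertex the piecewise-linear path outer -> midthickness -> inner
#' is split into `n_bins` coordinates equidistant in arc length (bin 0 = outer
#' boundary, bin `n_bins-1` = inner boundary). The bin nearest in arc length
#' to the midthickness point is then REPLACED by the midthickness point
#' itself (ties broken toward the outer side), so one bin always carries the
#' equivolume landmark bit-exactly. Subfields listed in `extension_bins`
#' (by default CA1 and CA2, 10 bins each) continue beyond the inner boundary
#' along the local mid -> inner direction at the last bin spacing, sampling
#' toward the hippocampal sulcus. CA4 and the DG get a two-bin scheme: all
#' DG vertices are treated as the "inner" bin and all CA4 vertices as the
#' "outer" bin, each sampled at its midthickness point.
#'
#' @param surface a [subfield_surface_set].
#' @param n_bins number of core bins between outer and inner (>= 2).
#' @param extension_bins named integer vector of extra bins beyond the inner
#'   boundary per subfield.
#' @return an object of class `depth_sampling_scheme`.
#' @export
build_sampling_scheme <- function(surface, n_bins = 20L,
                                  extension_bins = c(CA1 = 10L, CA2 = 10L)) {
  stopifnot(inherits(surface, "subfield_surface_set"))
  if (n_bins < 2L) stop("n_bins must be >= 2")
  out <- list()
  n_zero <- 0L
  for (sf in intersect(c("Subiculum", "CA1", "CA2", "CA3"),
                       unique(surface$labels))) {
    idx <- which(surface$labels == sf)
    po <- surface$vertices_outer[idx, , drop = FALSE]
    pm <- surface$vertices_mid[idx, , drop = FALSE]
    pi_ <- surface$vertices_inner[idx, , drop = FALSE]
    L1 <- sqrt(rowSums((pm - po)^2)); L2 <- sqrt(rowSums((pi_ - pm)^2))
    L <- L1 + L2
    n_ext <- if (sf %in% names(extension_bins)) extension_bins[[sf]] else 0L
    nb <- n_bins + n_ext
    nv <- length(idx)
    coords <- array(NA_real_, dim = c(nb, nv, 3L))
    dfrac <- matrix(NA_real_, nb, nv)
    midbin <- integer(nv)
    flagged <- L < 1e-12
    n_zero <- n_zero + sum(flagged)
    s_norm <- seq(0, 1, length.out = n_bins)           # arc-length fractions
    for (v in seq_len(nv)) {
      if (flagged[v]) {
        coords[, v, ] <- matrix(po[v, ], nb, 3L, byrow = TRUE)
        dfrac[, v] <- 0
        midbin[v] <- 1L
        next
      }
      s <- s_norm * L[v]
      dd <- abs(s - L1[v])
      j <- which(dd <= min(dd) + 1e-9 * L[v])[1L]      # first min = outer tie
      s[j] <- L1[v]
      on_first <- s <= L1[v]
      P <- matrix(NA_real_, n_bins, 3L)
      if (L1[v] > 1e-12) {
        u <- s[on_first] / L1[v]
        P[on_first, ] <- outer(1 - u, po[v, ]) + outer(u, pm[v, ])
      } else P[on_first, ] <- matrix(pm[v, ], sum(on_first), 3L, byrow = TRUE)
      if (any(!on_first)) {
        u <- (s[!on_first] - L1[v]) / L2[v]
        P[!on_first, ] <- outer(1 - u, pm[v, ]) + outer(u, pi_[v, ])
      }
      P[j, ] <- pm[v, ]                                 # bit-exact landmark
      if (n_ext > 0L) {
        dir <- (pi_[v, ] - pm[v, ]) / L2[v]
        step <- L[v] / (n_bins - 1)
        Pe <- outer(seq_len(n_ext) * step, dir) +
          matrix(pi_[v, ], n_ext, 3L, byrow = TRUE)
        P <- rbind(P, Pe)
        s <- c(s, L[v] + seq_len(n_ext) * step)
      }
      coords[, v, ] <- P
      dfrac[, v] <- s / L[v]
      midbin[v] <- j
    }
    out[[sf]] <- list(subfield = sf, vertex_idx = idx, coords = coords,
                      depth_frac = dfrac, midthickness_bin = midbin,
                      n_bins = nb, n_core = n_bins, flagged = flagged)
  }
  if (any(c("CA4", "DG") %in% surface$labels)) {
    i_ca4 <- which(surface$labels == "CA4")
    i_dg <- which(surface$labels == "DG")
    out[["CA4/DG"]] <- list(
      subfield = "CA4/DG", n_bins = 2L, n_core = 2L,
      outer = list(vertex_idx = i_ca4,
                   coords = surface$vertices_mid[i_ca4, , drop = FALSE]),
      inner = list(vertex_idx = i_dg,
                   coords = surface$vertices_mid[i_dg, , drop = FALSE]))
  }
  if (n_zero > 0L)
    warning(n_zero, " zero-thickness vertex/vertices: bins collapsed and flagged")
  structure(list(subfields = out, n_bins = n_bins,
                 extension_bins = extension_bins),
            class = "depth_sampling_scheme")
}

#' @export
print.depth_sampling_scheme <- function(x, ...) {
  cat("<depth_sampling_scheme>\n")
  for (sf in names(x$subfields))
    cat("  ", sf, ": ", x$subfields[[sf]]$n_bins, " bins\n", sep = "")
  invisible(x)
}

#' Sample laminar profiles from a volume
#'
#' Tricubic ("3rd-order polynomial") resampling of a 3D or 4D volume at every
#' scheme coordinate. For 4D input every frame is sampled with the same
#' scheme. Out-of-bounds coordinates become `NA` and flag their vertex; they
#' are never silently zeroed.
#'
#' @param volume a [volume_grid].
#' @param scheme a [build_sampling_scheme()] result.
#' @return an object of class `laminar_profiles`: per subfield, `values` is
#'   depth x vertex (x time).
#' @export
sample_profiles <- function(volume, scheme) {
  stopifnot(inherits(volume, "volume_grid"),
            inherits(scheme, "depth_sampling_scheme"))
  d <- dim(volume$data)
  is4d <- length(d) == 4L
  dims3 <- d[1:3]
  vol_mat <- if (is4d) matrix(volume$data, prod(dims3), d[4]) else NULL
  sample_pts <- function(pts) {
    vx <- world_to_voxel(pts, volume)
    if (is4d) {
      M <- tricubic_matrix(dims3, vx)
      vals <- as.matrix(M %*% vol_mat)
      vals[attr(M, "oob"), ] <- NA_real_
      vals
    } else tricubic_interp(volume$data, vx)
  }
  out <- list()
  for (sf in names(scheme$subfields)) {
    el <- scheme$subfields[[sf]]
    if (sf == "CA4/DG") {
      vo <- sample_pts(el$outer$coords)
      vi <- sample_pts(el$inner$coords)
      res <- el
      res$values_outer <- vo
      res$values_inner <- vi
      res$flag_outer <- if (is4d) rowSums(is.na(vo)) > 0 else is.na(vo)
      res$flag_inner <- if (is4d) rowSums(is.na(vi)) > 0 else is.na(vi)
      out[[sf]] <- res
      next
    }
    nb <- el$n_bins; nv <- length(el$vertex_idx)
    pts <- matrix(el$coords, nb * nv, 3L)
    vals <- sample_pts(pts)
    res <- el
    if (is4d) {
      res$values <- array(vals, dim = c(nb, nv, ncol(vals)))
      oob <- matrix(rowSums(is.na(vals)) > 0, nb, nv)
    } else {
      res$values <- matrix(vals, nb, nv)
      oob <- matrix(is.na(vals), nb, nv)
    }
    res$flagged <- el$flagged | colSums(oob) > 0
    out[[sf]] <- res
  }
  structure(list(subfields = out, source_dim = d),
            class = "laminar_profiles")
}

#' Aggregate laminar profiles over vertices
#'
#' Mean over included (unmasked, unflagged) vertices per depth, with the
#' standard error of the mean (SD/sqrt(n)) and the vertex count. For the
#' two-bin CA4/DG scheme the "outer" row is the mean over CA4 vertices and
#' the "inner" row the mean over DG vertices.
#'
#' @param profiles a [sample_profiles()] result.
#' @param vertex_mask optional logical vector over surface vertices; `TRUE`
#'   excludes the vertex (e.g. a vein mask from [make_vein_mask()]).
#' @return named list per subfield with `depth_fraction`, `mean`, `sem`
#'   (vectors, or depth x time matrices for 4D input) and `n_vertices`.
#' @export
aggregate_profiles <- function(profiles, vertex_mask = NULL) {
  stopifnot(inherits(profiles, "laminar_profiles"))
  agg_mat <- function(vals, keep) {
    # vals: depth x vertex (x time)
    if (length(dim(vals)) == 3L) {
      v <- vals[, keep, , drop = FALSE]
      m <- apply(v, c(1, 3), mean)
      s <- apply(v, c(1, 3), stats::sd) / sqrt(sum(keep))
      list(mean = m, sem = s)
    } else {
      v <- vals[, keep, drop = FALSE]
      list(mean = rowMeans(v),
           sem = apply(v, 1L, stats::sd) / sqrt(sum(keep)))
    }
  }
  out <- list()
  for (sf in names(profiles$subfields)) {
    el <- profiles$subfields[[sf]]
    if (sf == "CA4/DG") {
      keep_o <- !el$flag_outer
      keep_i <- !el$flag_inner
      if (!is.null(vertex_mask)) {
        keep_o <- keep_o & !vertex_mask[el$outer$vertex_idx]
        keep_i <- keep_i & !vertex_mask[el$inner$vertex_idx]
      }
      if (!any(keep_o) || !any(keep_i))
        stop("all vertices masked in CA4/DG")
      vo <- el$values_outer; vi <- el$values_inner
      row_of <- function(v, keep) {
        if (is.matrix(v)) list(mean = colMeans(v[keep, , drop = FALSE]),
                               sem = apply(v[keep, , drop = FALSE], 2L,
                                           stats::sd) / sqrt(sum(keep)))
        else list(mean = mean(v[keep]),
                  sem = stats::sd(v[keep]) / sqrt(sum(keep)))
      }
      ro <- row_of(vo, keep_o); ri <- row_of(vi, keep_i)
      out[[sf]] <- list(subfield = sf, depth_fraction = c(0, 1),
                        mean = rbind(ro$mean, ri$mean),
                        sem = rbind(ro$sem, ri$sem),
                        n_vertices = c(sum(keep_o), sum(keep_i)))
      if (!is.matrix(vo)) {
        out[[sf]]$mean <- c(ro$mean, ri$mean)
        out[[sf]]$sem <- c(ro$sem, ri$sem)
      }
      next
    }
    keep <- !el$flagged
    if (!is.null(vertex_mask)) keep <- keep & !vertex_mask[el$vertex_idx]
    if (!any(keep)) stop("all vertices masked in ", sf)
    a <- agg_mat(el$values, keep)
    out[[sf]] <- list(subfield = sf,
                      depth_fraction = rowMeans(el$depth_frac[, keep,
                                                             drop = FALSE]),
                      mean = a$mean, sem = a$sem, n_vertices = sum(keep))
  }
  out
}
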