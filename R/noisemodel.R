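#' Temporal signal-to-noise ratio
#'
#' Temporal mean over temporal SD, restricted to the selected volumes (the
#' mental-arithmetic control condition in the study design). Zero-SD series
#' yield `Inf` and are counted in the `n_infinite` attribute rather than
#' propagated silently.
#'
#' @param timeseries vector, or unit x time matrix.
#' @param condition_volumes indices of the volumes to include (>= 3).
#' @return tSNR vector with attribute `n_infinite`.
#' @export
tsnr <- function(timeseries, condition_volumes = NULL) {
  x <- if (is.null(dim(timeseries))) matrix(timeseries, nrow = 1L)
       else as.matrix(timeseries)
  if (is.null(condition_volumes)) condition_volumes <- seq_len(ncol(x))
  if (length(condition_volumes) < 3L) stop("need at least 3 included volumes")
  x <- x[, condition_volumes, drop = FALSE]
  mu <- rowMeans(x)
  sdv <- apply(x, 1L, stats::sd)
  out <- ifelse(sdv > 0, mu / sdv, Inf)
  attr(out, "n_infinite") <- sum(sdv == 0)
  out
}

#' Depth-resolved Weisskoff test
#'
#' For each depth and each subset size N, draws random vertex subsets
#' (without replacement), averages their time courses, and records the
#' temporal SD over the selected (math-condition) volumes, averaged over
#' draws. Pure thermal noise decays as `sigma/sqrt(N)`; a plateau at large N
#' reveals the structured (physiological) noise floor.
#'
#' @param values depth x vertex x time array (one subfield), or vertex x time
#'   matrix for a single depth.
#' @param n_grid subset sizes, increasing, max <= vertex count.
#' @param n_draws random subsets per (depth, N).
#' @param seed RNG seed for the subset draws.
#' @param condition_volumes indices of volumes entering the temporal SD.
#' @return data.frame with `depth`, `n`, `sd` (class `weisskoff_curve`).
#' @export
weisskoff_depthwise <- function(values, n_grid, n_draws = 50L, seed = 1L,
                                condition_volumes = NULL) {
  if (length(dim(values)) == 2L)
    values <- array(values, dim = c(1L, dim(values)))
  d <- dim(values)
  if (is.null(condition_volumes)) condition_volumes <- seq_len(d[3])
  n_grid <- sort(unique(as.integer(n_grid)))
  if (max(n_grid) > d[2])
    stop("subset size ", max(n_grid), " exceeds vertex count ", d[2])
  res <- with_seed(seed, {
    rows <- vector("list", d[1] * length(n_grid))
    k <- 0L
    for (dep in seq_len(d[1])) {
      V <- matrix(values[dep, , condition_volumes], nrow = d[2])
      for (N in n_grid) {
        sds <- vapply(seq_len(n_draws), function(i) {
          sel <- if (N == d[2]) seq_len(d[2]) else sample.int(d[2], N)
          stats::sd(colMeans(V[sel, , drop = FALSE]))
        }, numeric(1))
        k <- k + 1L
        rows[[k]] <- data.frame(depth = dep, n = N, sd = mean(sds))
      }
    }
    do.call(rbind, rows)
  })
  structure(res, class = c("weisskoff_curve", "data.frame"))
}

#' Log-log slope of a Weisskoff curve
#'
#' @param curve a [weisskoff_depthwise()] result (single depth or pooled).
#' @return OLS slope of log(sd) on log(n); -0.5 for pure thermal noise.
#' @export
weisskoff_slope <- function(curve) {
  unname(stats::coef(stats::lm(log(sd) ~ log(n), data = curve))[2])
}

#' Anatomical-component nuisance regressors (acompCor)
#'
#' Two noise ROIs feed principal-component nuisance regressors: ROI 1 is the
#' set of voxels whose first-pass GLM residual exceeds 3 SD of all residuals
#' (capturing respiratory/cardiac fluctuations); ROI 2 is a supplied
#' white-matter mask. Voxel time courses are linearly detrended and
#' standardized, components are the temporal principal components; ROI 1
#' keeps the smallest leading set explaining at least `var_fraction` of the
#' ROI variance, ROI 2 keeps exactly `wm_components`. All kept components
#' are orthogonalized with respect to the motion regressors (plus the
#' intercept and linear detrending term, so a pure motion span vanishes
#' exactly) and renormalized.
#'
#' @param data 4D [volume_grid] or voxel x time matrix.
#' @param residual_map 3D [volume_grid] or numeric vector of first-pass
#'   residual values per voxel.
#' @param wm_roi logical array/vector marking white-matter voxels.
#' @param motion a [motion_table] (or volumes x 6 matrix).
#' @param var_fraction cumulative-variance rule for ROI 1.
#' @param wm_components fixed component count for ROI 2.
#' @return an object of class `nuisance_set`: list with `regressors`
#'   (volumes x components), `variance_fraction`, `roi` provenance and
#'   `n_roi1`, `n_roi2`.
#' @export
acompcor <- function(data, residual_map, wm_roi, motion,
                     var_fraction = 0.5, wm_components = 5L) {
  Y <- if (inherits(data, "volume_grid"))
    matrix(data$data, prod(dim(data$data)[1:3])) else as.matrix(data)
  res <- if (inherits(residual_map, "volume_grid"))
    as.numeric(residual_map$data) else as.numeric(residual_map)
  if (length(res) != nrow(Y))
    stop("residual map and data do not share a grid")
  wm <- as.logical(wm_roi)
  n_vol <- ncol(Y)
  thr <- 3 * stats::sd(res)
  roi1 <- which(res > thr & !wm)
  roi2 <- which(wm)

  pca_components <- function(voxels, rule_k = NULL, rule_var = NULL) {
    X <- t(Y[voxels, , drop = FALSE])            # time x voxel
    tt <- seq_len(n_vol)
    X <- as.matrix(stats::lm.fit(cbind(1, tt), X)$residuals) # detrend
    sds <- apply(X, 2L, stats::sd)
    keep <- sds > 1e-12
    X <- sweep(X[, keep, drop = FALSE], 2L, sds[keep], "/")
    if (ncol(X) == 0L) return(NULL)
    sv <- svd(X, nu = min(dim(X)), nv = 0)
    varfrac <- sv$d^2 / sum(sv$d^2)
    k <- if (!is.null(rule_k)) min(rule_k, ncol(sv$u))
         else which(cumsum(varfrac) >= rule_var)[1]
    if (k < 1L) return(NULL)
    list(comp = sv$u[, seq_len(k), drop = FALSE],
         varfrac = varfrac[seq_len(k)])
  }

  comps <- list(); vfr <- list(); prov <- character(0)
  if (length(roi1) > 0L) {
    p1 <- pca_components(roi1, rule_var = var_fraction)
    if (!is.null(p1)) {
      comps$roi1 <- p1$comp; vfr$roi1 <- p1$varfrac
      prov <- c(prov, rep("high-residual", ncol(p1$comp)))
    }
  } else {
    warning("empty high-residual ROI; returning white-matter components only")
  }
  if (length(roi2) > 0L && wm_components > 0L) {
    p2 <- pca_components(roi2, rule_k = wm_components)
    if (!is.null(p2)) {
      comps$roi2 <- p2$comp; vfr$roi2 <- p2$varfrac
      prov <- c(prov, rep("white-matter", ncol(p2$comp)))
    }
  }
  if (length(comps) == 0L)
    return(structure(list(regressors = matrix(numeric(0), n_vol, 0L),
                          variance_fraction = numeric(0), roi = character(0),
                          n_roi1 = length(roi1), n_roi2 = length(roi2),
                          dropped = 0L),
                     class = "nuisance_set"))
  C <- do.call(cbind, comps)
  # orthogonalize against intercept, the detrending basis and the motion set
  M <- cbind(1, seq_len(n_vol), as.matrix(as.data.frame(motion)))
  Q <- qr.Q(qr(M))
  C <- C - Q %*% crossprod(Q, C)
  nrm <- sqrt(colSums(C^2))
  keep <- nrm > 1e-8
  C <- sweep(C[, keep, drop = FALSE], 2L, nrm[keep], "/")
  structure(list(regressors = C,
                 variance_fraction = unlist(vfr)[keep],
                 roi = prov[keep],
                 n_roi1 = length(roi1), n_roi2 = length(roi2),
                 dropped = sum(!keep)),
            class = "nuisance_set")
}
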