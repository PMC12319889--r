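#' Full single-subject analysis of a task run
#'
#' The two-pass procedure on one (simulated or measured) task acquisition:
#' a first voxel-space GLM with task, motion and drift regressors yields a
#' residual map; [acompcor()] extracts nuisance components from the
#' high-residual ROI and a noise ROI; the second-pass design adds them; depth
#' profiles are extracted with the sampling scheme, baseline z-transformed
#' over the math-condition volumes, fitted with robust weighted least
#' squares, and reduced to the two laminar contrasts.
#'
#' @param am list with `bold`, `events`, `motion` (as returned by
#'   [make_am_timeseries()]).
#' @param scheme a [build_sampling_scheme()] result.
#' @param noise_roi logical vector over voxels (column-major) marking the
#'   anatomical noise ROI (white matter in vivo; non-sheet background in the
#'   phantom). `NULL` disables the fixed-component ROI.
#' @param vein_mask optional per-vertex exclusion flags.
#' @param hp_cutoff high-pass cutoff period, seconds.
#' @param drop_initial initial volumes to discard.
#' @param math_shift hemodynamic shift (volumes) for the math-volume rule.
#' @param use_acompcor include the nuisance set in the second pass.
#' @return list with `contrasts` (data.frame: subfield, depth_fraction,
#'   memory_gt_math, pre_gt_post), `nuisance`, `design`, `math_volumes`.
#' @export
am_subject_analysis <- function(am, scheme, noise_roi = NULL,
                                vein_mask = NULL, hp_cutoff = 128,
                                drop_initial = 3L, math_shift = 2L,
                                use_acompcor = TRUE) {
  nv <- attr(am$events, "n_volumes")
  keep <- (drop_initial + 1L):nv
  d3 <- dim(am$bold$data)[1:3]
  Yv <- matrix(am$bold$data, prod(d3))[, keep, drop = FALSE]
  design0 <- build_design(am$events, am$motion, NULL, hp_cutoff = hp_cutoff,
                          drop_initial = drop_initial)
  nuisance <- NULL
  design <- design0
  if (use_acompcor) {
    B0 <- qr.solve(design0$X, t(Yv))
    resid_sd <- sqrt(colMeans((t(Yv) - design0$X %*% B0)^2))
    # centre the residual-SD map so the 3-SD rule picks out its high tail
    resid_map <- resid_sd - mean(resid_sd)
    roi <- if (is.null(noise_roi)) rep(FALSE, nrow(Yv)) else as.logical(noise_roi)
    nuisance <- acompcor(Yv, resid_map, roi,
                         as.matrix(as.data.frame(am$motion))[keep, ,
                                                             drop = FALSE])
    design <- build_design(am$events, am$motion, nuisance,
                           hp_cutoff = hp_cutoff, drop_initial = drop_initial)
  }
  mvol <- condition_volumes(am$events, "math", math_shift, drop_initial)
  agg <- aggregate_profiles(sample_profiles(am$bold, scheme), vein_mask)
  rows <- list()
  for (sf in names(agg)) {
    Z <- baseline_z(agg[[sf]]$mean[, keep, drop = FALSE], mvol)
    fit <- rwls_fit(Z, design)
    ctr <- laminar_contrasts(fit$coefficients)
    rows[[sf]] <- data.frame(subfield = sf,
                             depth_fraction = agg[[sf]]$depth_fraction,
                             memory_gt_math = ctr$memory_gt_math,
                             pre_gt_post = ctr$pre_gt_post)
  }
  list(contrasts = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       nuisance = nuisance, design = design, math_volumes = mvol)
}
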