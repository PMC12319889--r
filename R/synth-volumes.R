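# Rasterization of the synthetic sheet and the volume/time-series generators.

# Regular grid enclosing a set of world points with a margin (voxels).
enclosing_grid <- function(points, voxel_mm, margin = 4L) {
  lo <- apply(points, 2L, min) - margin * voxel_mm
  hi <- apply(points, 2L, max) + margin * voxel_mm
  dims <- pmax(ceiling((hi - lo) / voxel_mm) + 1L, 8L)
  affine <- diag(c(voxel_mm, voxel_mm, voxel_mm, 1))
  affine[1:3, 4] <- lo
  list(dims = as.integer(dims), affine = affine)
}

# Paint per-voxel ground-truth maps (T2*, S0, laminar response amplitudes,
# depth fraction) by stepping along each vertex column outer -> inner.
sheet_raster <- function(surface, truth, voxel_mm, n_steps = 12L,
                         conditions = character(0)) {
  pts_all <- rbind(surface$vertices_outer, surface$vertices_inner)
  g <- enclosing_grid(pts_all, voxel_mm)
  nvox <- prod(g$dims)
  t2s <- numeric(nvox); s0 <- numeric(nvox); depth <- rep(NA_real_, nvox)
  resp <- lapply(conditions, function(cc) numeric(nvox))
  names(resp) <- conditions
  fr <- seq(0, 1, length.out = n_steps)
  for (sf in unique(surface$labels)) {
    sel <- which(surface$labels == sf)
    t2s_d <- truth_t2star_at(truth, sf, fr)
    amp_d <- lapply(conditions, function(cc) truth_response_at(truth, sf, cc, fr))
    names(amp_d) <- conditions
    for (j in seq_along(fr)) {
      w <- surface$vertices_outer[sel, , drop = FALSE] * (1 - fr[j]) +
        surface$vertices_inner[sel, , drop = FALSE] * fr[j]
      vx <- round(world_to_voxel(w, g$affine))
      ok <- vx[, 1] >= 0 & vx[, 1] < g$dims[1] & vx[, 2] >= 0 &
        vx[, 2] < g$dims[2] & vx[, 3] >= 0 & vx[, 3] < g$dims[3]
      lin <- vx[ok, 1] + g$dims[1] * (vx[ok, 2] + g$dims[2] * vx[ok, 3]) + 1
      t2s[lin] <- t2s_d[j]
      s0[lin] <- truth$s0
      depth[lin] <- fr[j]
      for (cc in conditions) resp[[cc]][lin] <- amp_d[[cc]][j]
    }
  }
  c(g, list(t2s = t2s, s0 = s0, depth = depth, resp = resp,
            voxel_mm = voxel_mm))
}

# Sample vessel centerlines at ~0.2 mm and return the minimum distance (mm)
# from each queried world point to any centerline of the given type.
vessel_distance <- function(points, vessels, type = "vein", step = 0.2) {
  cl <- NULL
  for (v in vessels) {
    if (v$type != type) next
    p <- v$points
    if (nrow(p) < 2L) { cl <- rbind(cl, p); next }
    seg_len <- sqrt(rowSums((p[-1, , drop = FALSE] -
                             p[-nrow(p), , drop = FALSE])^2))
    for (s in seq_len(nrow(p) - 1L)) {
      k <- max(2L, ceiling(seg_len[s] / step))
      u <- seq(0, 1, length.out = k)
      cl <- rbind(cl, cbind(p[s, 1] + u * (p[s + 1, 1] - p[s, 1]),
                            p[s, 2] + u * (p[s + 1, 2] - p[s, 2]),
                            p[s, 3] + u * (p[s + 1, 3] - p[s, 3])))
    }
  }
  if (is.null(cl)) return(rep(Inf, nrow(points)))
  out <- numeric(nrow(points))
  chunk <- 2000L
  for (i0 in seq(1L, nrow(points), by = chunk)) {
    i1 <- min(i0 + chunk - 1L, nrow(points))
    d2 <- outer(points[i0:i1, 1], cl[, 1], `-`)^2 +
      outer(points[i0:i1, 2], cl[, 2], `-`)^2 +
      outer(points[i0:i1, 3], cl[, 3], `-`)^2
    out[i0:i1] <- sqrt(apply(d2, 1L, min))
  }
  out
}

#' Breath-hold paradigm event table
#'
#' One volume per condition label: `n_blocks` repetitions of (rest,
#' transition, active) followed by a final rest volume, each of duration
#' `tr_vol` (the long volume TR of the multi-echo FLASH acquisition).
#'
#' @param n_blocks number of rest/transition/active blocks (>= 1).
#' @param tr_vol volume repeat time, seconds.
#' @return a [paradigm_events] table with `3*n_blocks + 1` rows.
#' @export
make_breathhold_events <- function(n_blocks = 6L, tr_vol = 40.992) {
  if (n_blocks < 1L) stop("n_blocks must be >= 1")
  cond <- c(rep(c("rest", "transition", "active"), n_blocks), "rest")
  n <- length(cond)
  paradigm_events(onset = (seq_len(n) - 1L) * tr_vol,
                  duration = rep(tr_vol, n), condition = cond,
                  tr_vol = tr_vol, n_volumes = n)
}

#' Simulate a multi-echo FLASH breath-hold acquisition
#'
#' Voxel signal follows the mono-exponential forward model
#' `S(TE) = S0 exp(-TE/T2*)` with the depth/subfield T2* map of the ground
#' truth. During `active` volumes T2* is lengthened multiplicatively near
#' vein centerlines by `1 + bias_amp * exp(-d/lambda)` (kernel truncated at
#' `4*lambda`), the venous-bias ground truth; `transition` volumes carry half
#' the effect. Gaussian thermal noise is added at the stated SD.
#'
#' @param surface a [subfield_surface_set].
#' @param truth a [ground_truth].
#' @param tes echo times, ms, strictly increasing.
#' @param paradigm a [paradigm_events] table from [make_breathhold_events()].
#' @param seed RNG seed.
#' @param voxel_mm isotropic voxel size of the simulated grid, mm.
#' @return list with `echoes` (list of 4D [volume_grid], one per TE),
#'   `events`, `truth`, and the painted truth maps (`raster`).
#' @export
make_multiecho_breathhold <- function(surface, truth, tes = c(2, 6, 10, 14, 17, 21),
                                      paradigm = make_breathhold_events(),
                                      seed = 1L, voxel_mm = 0.8) {
  if (any(diff(tes) <= 0) || any(tes <= 0))
    stop("tes must be strictly increasing and positive")
  ras <- sheet_raster(surface, truth, voxel_mm)
  if (any(ras$t2s < 0)) stop("non-positive T2* in the ground truth")
  sheet <- which(ras$s0 > 0)
  centers_vox <- cbind((sheet - 1L) %% ras$dims[1],
                       ((sheet - 1L) %/% ras$dims[1]) %% ras$dims[2],
                       (sheet - 1L) %/% (ras$dims[1] * ras$dims[2]))
  centers <- voxel_to_world(centers_vox, ras$affine)
  dist_vein <- vessel_distance(centers, truth$vessels, "vein")
  lam <- truth$noise_spec$bias_lambda
  amp <- truth$noise_spec$bias_amp
  kern <- ifelse(dist_vein <= 4 * lam, amp * exp(-dist_vein / lam), 0)
  cond <- paradigm$condition
  n_vol <- length(cond)
  sd_th <- truth$noise_spec$thermal_sd
  echoes <- with_seed(seed, lapply(tes, function(te) {
    arr <- array(0, dim = c(ras$dims, n_vol))
    for (v in seq_len(n_vol)) {
      fac <- switch(cond[v], active = 1, transition = 0.5, 0)
      t2s_v <- ras$t2s[sheet] * (1 + fac * kern)
      frame <- numeric(prod(ras$dims))
      frame[sheet] <- ras$s0[sheet] * exp(-te / t2s_v)
      if (sd_th > 0) frame <- frame + stats::rnorm(length(frame), sd = sd_th)
      arr[, , , v] <- frame
    }
    volume_grid(arr, ras$affine, axis4 = "time")
  }))
  list(echoes = echoes, tes = tes, events = paradigm, truth = truth,
       raster = ras)
}

#' Simulate synthetic SWI and TOF vascular volumes
#'
#' SWI: bright parenchyma with hypointense (dark) tubes at vein centerlines.
#' TOF: dim background with hyperintense (bright) tubes at artery
#' centerlines. Both lightly smoothed to emulate the point-spread function.
#'
#' @param surface a [subfield_surface_set] (defines the field of view).
#' @param truth a [ground_truth] carrying the vessel centerlines.
#' @param voxel_mm isotropic voxel size, mm.
#' @param seed RNG seed for the additive noise.
#' @param noise_sd additive Gaussian noise SD, a.u.
#' @return list with `swi`, `tof` ([volume_grid]s) and `mask` (brain-mask
#'   [volume_grid] of 0/1).
#' @export
make_vascular_volumes <- function(surface, truth, voxel_mm = 0.4, seed = 1L,
                                  noise_sd = 1) {
  pts_all <- rbind(surface$vertices_outer, surface$vertices_inner)
  g <- enclosing_grid(pts_all, voxel_mm, margin = 6L)
  nvox <- prod(g$dims)
  vox <- cbind((seq_len(nvox) - 1L) %% g$dims[1],
               ((seq_len(nvox) - 1L) %/% g$dims[1]) %% g$dims[2],
               (seq_len(nvox) - 1L) %/% (g$dims[1] * g$dims[2]))
  centers <- voxel_to_world(vox, g$affine)
  d_vein <- vessel_distance(centers, truth$vessels, "vein")
  d_art <- vessel_distance(centers, truth$vessels, "artery")
  r_vein <- max(c(0.4, vapply(truth$vessels, function(v)
    if (v$type == "vein") v$radius else 0, numeric(1))))
  r_art <- max(c(0.3, vapply(truth$vessels, function(v)
    if (v$type == "artery") v$radius else 0, numeric(1))))
  swi <- array(100, dim = g$dims)
  swi[array(d_vein <= r_vein, dim = g$dims)] <- 20
  tof <- array(50, dim = g$dims)
  tof[array(d_art <= r_art, dim = g$dims)] <- 150
  swi <- gaussian_smooth_3d(swi, 0.5)
  tof <- gaussian_smooth_3d(tof, 0.5)
  with_seed(seed, {
    if (noise_sd > 0) {
      swi <- swi + array(stats::rnorm(nvox, sd = noise_sd), dim = g$dims)
      tof <- tof + array(stats::rnorm(nvox, sd = noise_sd), dim = g$dims)
    }
  })
  mask <- array(1, dim = g$dims)
  list(swi = volume_grid(swi, g$affine), tof = volume_grid(tof, g$affine),
       mask = volume_grid(mask, g$affine))
}

#' Simulate an autobiographical-memory task run
#'
#' Generates an event schedule of `n_trials` 17.6 s trials (autobiographical
#' memory and mental arithmetic randomly interleaved, inter-trial fixation of
#' 2.2 or 4.4 s chosen uniformly), with the AM trials split at a simulated
#' button press (lognormal latency, median ~4 s, truncated to
#' `[1, trial - 2]` s) into construction and elaboration phases. The voxel
#' time series is baseline + laminar response amplitudes convolved with the
#' canonical HRF + polynomial drift + low-rank structured noise (shared
#' sinusoids with smooth spatial loadings) + thermal noise; the motion table
#' is a slow random walk.
#'
#' @param surface a [subfield_surface_set].
#' @param truth a [ground_truth].
#' @param n_volumes volumes per run.
#' @param tr volume repeat time, seconds.
#' @param seed RNG seed.
#' @param n_trials trials per run.
#' @param voxel_mm isotropic voxel size, mm.
#' @return list with `bold` (4D [volume_grid]), `events`, `motion`, `truth`,
#'   and the painted truth maps (`raster`).
#' @export
make_am_timeseries <- function(surface, truth, n_volumes = 489, tr = 2.21,
                               seed = 1L, n_trials = 44L, voxel_mm = 0.9) {
  if (tr <= 0) stop("tr must be positive")
  trial_len <- 17.6
  with_seed(seed, {
    is_am <- sample(rep(c(TRUE, FALSE), length.out = n_trials))
    iti <- sample(c(2.2, 4.4), n_trials, replace = TRUE)
    onsets <- 8.8 + cumsum(c(0, (trial_len + iti)[-n_trials]))
    run_len <- n_volumes * tr
    if (max(onsets) + trial_len > run_len)
      stop("run too short for the event schedule: needs ",
           round(max(onsets) + trial_len, 1), " s, run is ", round(run_len, 1), " s")
    press <- pmin(pmax(stats::rlnorm(n_trials, log(4), 0.42), 1),
                  trial_len - 2)
    ev_on <- c(); ev_du <- c(); ev_co <- c()
    for (k in seq_len(n_trials)) {
      if (is_am[k]) {
        ev_on <- c(ev_on, onsets[k], onsets[k] + press[k])
        ev_du <- c(ev_du, press[k], trial_len - press[k])
        ev_co <- c(ev_co, "AM_construction", "AM_elaboration")
      } else {
        ev_on <- c(ev_on, onsets[k]); ev_du <- c(ev_du, trial_len)
        ev_co <- c(ev_co, "math")
      }
    }
    events <- paradigm_events(ev_on, ev_du, ev_co, tr, n_volumes)

    conds <- c("AM_construction", "AM_elaboration", "math")
    ras <- sheet_raster(surface, truth, voxel_mm, conditions = conds)
    nvox <- prod(ras$dims)
    X <- vapply(conds, function(cc) {
      sel <- events$condition == cc
      convolve_events(events$onset[sel], events$duration[sel], n_volumes, tr)
    }, numeric(n_volumes))
    Y <- matrix(0, nrow = nvox, ncol = n_volumes)
    base <- ras$s0
    Y <- Y + base
    for (cc in conds) Y <- Y + ras$resp[[cc]] %o% X[, cc]
    ns <- truth$noise_spec
    tt <- (seq_len(n_volumes) - 0.5) * tr
    if (ns$drift_order > 0) {
      for (k in seq_len(ns$drift_order)) {
        coef <- stats::rnorm(nvox, sd = 2)
        Y <- Y + coef %o% ((tt / max(tt))^k)
      }
    }
    for (comp in ns$structured) {
      if (comp$amplitude <= 0) next
      loading <- gaussian_smooth_3d(array(stats::rnorm(nvox), dim = ras$dims), 2)
      loading <- comp$amplitude * as.numeric(loading) / stats::sd(loading)
      phase <- stats::runif(1, 0, 2 * pi)
      Y <- Y + loading %o% sin(2 * pi * comp$freq * tt + phase)
    }
    if (ns$thermal_sd > 0)
      Y <- Y + matrix(stats::rnorm(nvox * n_volumes, sd = ns$thermal_sd),
                      nrow = nvox)
    motion <- motion_table(apply(matrix(stats::rnorm(n_volumes * 6,
                                                     sd = c(rep(0.02, 3), rep(2e-4, 3))),
                                        ncol = 6, byrow = TRUE), 2L, cumsum))
    list(bold = volume_grid(array(Y, dim = c(ras$dims, n_volumes)),
                            ras$affine, axis4 = "time"),
         events = events, motion = motion, truth = truth, raster = ras)
  })
}
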