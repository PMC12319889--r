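test_that("flat slab places the midthickness exactly halfway", {
  s <- make_surface_sheet(n_long = 4, n_trans = 12, fold_turns = 0)
  expect_equal(s$vertices_mid, (s$vertices_inner + s$vertices_outer) / 2,
               tolerance = 1e-12)
})

test_that("curved sheet midthickness obeys the equivolume principle", {
  # brute-force oracle: integrate strip areas of the cross-section polygon;
  # equal volume means equal area between outer->mid and mid->inner
  s <- make_surface_sheet(n_long = 4, n_trans = 200, fold_turns = 0.75,
                          thickness = 2)
  sel <- 1:200                       # one cross-section (first x station)
  quad_area <- function(a, b, d, cc) {
    # planar quad in (y,z), shoelace over the a -> b -> d -> cc loop
    p <- rbind(a, b, d, cc)
    abs(sum(p[, 1] * c(p[-1, 2], p[1, 2]) - p[, 2] * c(p[-1, 1], p[1, 1]))) / 2
  }
  area_band <- function(v1, v2) {
    v1 <- v1[, 2:3]; v2 <- v2[, 2:3]  # (y,z) cross-section plane
    sum(vapply(seq_len(199), function(i)
      quad_area(v1[i, ], v1[i + 1, ], v2[i + 1, ], v2[i, ]), numeric(1)))
  }
  a_out_mid <- area_band(s$vertices_outer[sel, ], s$vertices_mid[sel, ])
  a_mid_in <- area_band(s$vertices_mid[sel, ], s$vertices_inner[sel, ])
  expect_lt(abs(a_out_mid / a_mid_in - 1), 0.02)
  # and the arithmetic midpoint would NOT split the area equally here
  mid_arith <- (s$vertices_outer + s$vertices_inner) / 2
  a1 <- area_band(s$vertices_outer[sel, ], mid_arith[sel, ])
  a2 <- area_band(mid_arith[sel, ], s$vertices_inner[sel, ])
  expect_gt(abs(a1 / a2 - 1), 0.05)
})

test_that("degenerate subfield fractions label every vertex subiculum", {
  s <- make_surface_sheet(n_long = 4, n_trans = 12,
                          subfield_fractions = c(1, 0, 0, 0, 0, 0))
  expect_true(all(s$labels == "Subiculum"))
})

test_that("a fold too tight for the thickness is rejected", {
  expect_error(make_surface_sheet(n_long = 4, n_trans = 24, fold_turns = 1.5,
                                  thickness = 4, r0 = 5),
               "self-intersecting")
})

test_that("breath-hold paradigm has the study's block structure", {
  ev <- make_breathhold_events(6)
  expect_equal(nrow(ev), 19)
  ev1 <- make_breathhold_events(1)
  expect_equal(ev1$condition, c("rest", "transition", "active", "rest"))
  for (nb in c(2, 4, 6)) {
    e <- make_breathhold_events(nb)
    expect_equal(sum(e$condition == "rest"), nb + 1)
    expect_equal(sum(e$condition == "transition"), nb)
    expect_equal(sum(e$condition == "active"), nb)
  }
  expect_error(make_breathhold_events(0), ">= 1")
})

test_that("multi-echo generator follows the noiseless forward model", {
  surf <- make_surface_sheet(n_long = 4, n_trans = 12)
  truth <- default_ground_truth(surf, thermal_sd = 0, seed = 2)
  tes <- c(2, 6, 10, 14, 17, 21)
  sim <- make_multiecho_breathhold(surf, truth, tes,
                                   make_breathhold_events(1), seed = 7)
  expect_length(sim$echoes, 6)
  sheet <- which(sim$raster$s0 > 0)
  # signals at rest equal S0 exp(-TE/T2*) at machine precision
  for (e in c(1, 4, 6)) {
    frame <- as.numeric(sim$echoes[[e]]$data[, , , 1])
    expect_equal(frame[sheet],
                 sim$raster$s0[sheet] * exp(-tes[e] / sim$raster$t2s[sheet]),
                 tolerance = 1e-12)
  }
  # rest vs active identical beyond the vein kernel support
  d3 <- sim$raster$dims
  vox <- cbind((sheet - 1L) %% d3[1], ((sheet - 1L) %/% d3[1]) %% d3[2],
               (sheet - 1L) %/% (d3[1] * d3[2]))
  dist <- hippolaminar:::vessel_distance(voxel_to_world(vox, sim$raster$affine),
                                         truth$vessels, "vein")
  far <- sheet[dist > 4 * truth$noise_spec$bias_lambda]
  rest <- as.numeric(sim$echoes[[1]]$data[, , , 1])
  act <- as.numeric(sim$echoes[[1]]$data[, , , 3])
  expect_equal(act[far], rest[far], tolerance = 1e-12)
  # near-vein voxels do change
  near <- sheet[dist < 1]
  expect_gt(min(abs(act[near] - rest[near])), 0)
})

test_that("generators are reproducible from the seed", {
  surf <- make_surface_sheet(n_long = 4, n_trans = 12)
  truth <- default_ground_truth(surf, thermal_sd = 3, seed = 2)
  a <- make_multiecho_breathhold(surf, truth, paradigm = make_breathhold_events(1),
                                 seed = 5)
  b <- make_multiecho_breathhold(surf, truth, paradigm = make_breathhold_events(1),
                                 seed = 5)
  cc <- make_multiecho_breathhold(surf, truth, paradigm = make_breathhold_events(1),
                                  seed = 6)
  expect_identical(a$echoes[[1]]$data, b$echoes[[1]]$data)
  expect_false(identical(a$echoes[[1]]$data, cc$echoes[[1]]$data))

  am1 <- make_am_timeseries(surf, truth, n_volumes = 120, seed = 9,
                            n_trials = 5)
  am2 <- make_am_timeseries(surf, truth, n_volumes = 120, seed = 9,
                            n_trials = 5)
  expect_identical(am1$bold$data, am2$bold$data)
  expect_identical(as.data.frame(am1$events), as.data.frame(am2$events))
})

test_that("task generator honours the trial structure and noise spec", {
  surf <- make_surface_sheet(n_long = 4, n_trans = 12)
  truth <- default_ground_truth(surf, thermal_sd = 0, seed = 2)
  # null generator: zero response, zero noise -> constant at baseline
  truth0 <- truth
  truth0$laminar_response <- list()
  truth0$noise_spec <- list(thermal_sd = 0, structured = list(),
                            drift_order = 0, bias_amp = 0, bias_lambda = 1)
  am0 <- make_am_timeseries(surf, truth0, n_volumes = 120, seed = 3,
                            n_trials = 5)
  Y <- matrix(am0$bold$data, prod(dim(am0$bold$data)[1:3]))
  expect_equal(max(apply(Y, 1L, function(r) diff(range(r)))), 0)

  # 44 trials per run at full length
  am <- make_am_timeseries(surf, truth0, seed = 4)
  n_trials <- sum(am$events$condition == "math") +
    sum(am$events$condition == "AM_construction")
  expect_equal(n_trials, 44)
  expect_equal(sum(am$events$condition == "AM_construction"),
               sum(am$events$condition == "AM_elaboration"))
  expect_error(make_am_timeseries(surf, truth0, n_volumes = 50, seed = 1),
               "run too short")

  # thermal-only noise: voxelwise temporal SD matches the stated SD within
  # 5 % when averaged over many voxels at ~486 usable volumes
  truth_t <- truth0
  truth_t$noise_spec$thermal_sd <- 6
  amt <- make_am_timeseries(surf, truth_t, seed = 5)
  Yt <- matrix(amt$bold$data, prod(dim(amt$bold$data)[1:3]))
  sds <- apply(Yt[sample.int(nrow(Yt), 300), ], 1L, stats::sd)
  expect_lt(abs(mean(sds) / 6 - 1), 0.05)
})

test_that("structured noise is exactly low-rank", {
  surf <- make_surface_sheet(n_long = 4, n_trans = 12)
  truth <- default_ground_truth(surf, thermal_sd = 0, seed = 2)
  truth$laminar_response <- list()
  truth$noise_spec <- list(thermal_sd = 0,
                           structured = list(list(freq = 0.3, amplitude = 5),
                                             list(freq = 0.11, amplitude = 3)),
                           drift_order = 0, bias_amp = 0, bias_lambda = 1)
  am <- make_am_timeseries(surf, truth, n_volumes = 120, seed = 3,
                           n_trials = 5)
  Y <- matrix(am$bold$data, prod(dim(am$bold$data)[1:3]))
  Yc <- Y - rowMeans(Y)
  sv <- svd(Yc, nu = 0, nv = 0)$d
  expect_equal(sum(sv > 1e-6 * sv[1]), 2)
})

test_that("ground-truth invariants are enforced", {
  t2s <- data.frame(subfield = "CA1", t2s_outer = -1, t2s_inner = 30)
  expect_error(ground_truth(t2s), "positive")
  t2s_ok <- data.frame(subfield = "CA1", t2s_outer = 30, t2s_inner = 30)
  expect_error(ground_truth(t2s_ok,
                            vessels = list(list(points = diag(3), radius = 0,
                                                type = "vein"))),
               "radius")
  expect_error(
    ground_truth(t2s_ok, noise_spec = list(structured = list(
      list(freq = 0.3, amplitude = -1)))),
    "amplitudes")
})
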