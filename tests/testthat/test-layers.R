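test_that("straight column scheme matches the 20-point grid arithmetic", {
  surf <- straight_column_surface(xm = 0.5)
  sch <- build_sampling_scheme(surf)
  el <- sch$subfields$CA3
  expect_equal(el$n_bins, 20L)
  # bins k = 0..19 at x = k/19, except the bin nearest arc 0.5: both k = 9
  # and k = 10 are equidistant, the outer-side tie-break replaces k = 9
  expect_equal(el$midthickness_bin, 10L)       # 1-based index of k = 9
  expect_identical(el$coords[10, 1, 1], 0.5)   # bit-exact landmark
  k <- (0:19) / 19
  expect_equal(el$coords[-10, 1, 1], k[-10], tolerance = 1e-12)
  expect_true(all(diff(el$depth_frac[, 1]) > 0))

  # mid exactly on a grid point: replacement changes nothing but the label
  surf2 <- straight_column_surface(xm = 5 / 19)
  el2 <- build_sampling_scheme(surf2)$subfields$CA3
  expect_equal(el2$coords[, 1, 1], k, tolerance = 1e-12)
  expect_equal(el2$midthickness_bin, 6L)
})

test_that("CA1/CA2 extension continues beyond the inner surface", {
  surf <- straight_column_surface(xm = 0.4, label = "CA1")
  el <- build_sampling_scheme(surf)$subfields$CA1
  expect_equal(el$n_bins, 30L)
  x <- el$coords[, 1, 1]
  step <- 1 / 19
  expect_equal(x[21:30], 1 + (1:10) * step, tolerance = 1e-12)
  expect_equal(diff(x[21:30]), rep(step, 9), tolerance = 1e-12)
  expect_true(all(el$depth_frac[21:30, 1] > 1))
})

test_that("scheme bin counts follow the subfield rules on a full sheet", {
  sch <- build_sampling_scheme(small_sheet())
  expect_equal(sch$subfields$Subiculum$n_bins, 20L)
  expect_equal(sch$subfields$CA3$n_bins, 20L)
  expect_equal(sch$subfields$CA1$n_bins, 30L)
  expect_equal(sch$subfields$CA2$n_bins, 30L)
  expect_equal(sch$subfields[["CA4/DG"]]$n_bins, 2L)
})

test_that("every vertex carries the midthickness point bit-exactly and depths increase", {
  s <- small_sheet()
  sch <- build_sampling_scheme(s)
  for (sf in c("Subiculum", "CA1", "CA2", "CA3")) {
    el <- sch$subfields[[sf]]
    for (v in seq_along(el$vertex_idx)) {
      mb <- el$midthickness_bin[v]
      expect_identical(el$coords[mb, v, ], s$vertices_mid[el$vertex_idx[v], ])
      expect_true(all(diff(el$depth_frac[, v]) > 0))
    }
  }
})

test_that("zero-thickness vertices collapse with a warning and are flagged", {
  surf <- suppressWarnings(subfield_surface_set(
    vertices_inner = rbind(c(0, 0, 0), c(1, 0, 1)),
    vertices_mid = rbind(c(0, 0, 0), c(1, 0, 0.5)),
    vertices_outer = rbind(c(0, 0, 0), c(1, 0, 0)),
    triangles = matrix(c(1, 2, 1), 1), labels = c("CA3", "CA3")))
  expect_warning(sch <- build_sampling_scheme(surf), "zero-thickness")
  el <- sch$subfields$CA3
  expect_true(el$flagged[1])
  expect_false(el$flagged[2])
  expect_equal(el$coords[1, 1, ], el$coords[20, 1, ])
})

test_that("tricubic sampling reproduces polynomial fields", {
  d <- c(14, 14, 14)
  co <- as.matrix(expand.grid(x = 0:13, y = 0:13, z = 0:13))
  vol_lin <- volume_grid(array(2 * co[, 1] + 3 * co[, 2] - co[, 3] + 5, d))
  vol_one <- volume_grid(array(1, d))

  surf <- subfield_surface_set(
    vertices_inner = matrix(c(10, 6, 6), 1),
    vertices_mid = matrix(c(6.5, 6, 6), 1),
    vertices_outer = matrix(c(3, 6, 6), 1),
    triangles = matrix(c(1, 1, 1), 1), labels = "CA3")
  sch <- build_sampling_scheme(surf)
  prof <- sample_profiles(vol_lin, sch)
  x <- sch$subfields$CA3$coords[, 1, 1]
  expect_lt(max(abs(prof$subfields$CA3$values[, 1] - (2 * x + 3 * 6 - 6 + 5))),
            1e-9)
  prof1 <- sample_profiles(vol_one, sch)
  expect_equal(unname(prof1$subfields$CA3$values[, 1]), rep(1, 20))
})

test_that("tricubic sampling tracks a smooth Gaussian blob to < 1 %", {
  d <- c(24, 24, 24)
  aff <- diag(c(0.8, 0.8, 0.8, 1))
  co <- as.matrix(expand.grid(x = 0:23, y = 0:23, z = 0:23)) * 0.8
  ctr <- c(9.6, 9.6, 9.6)
  amp <- 100
  f <- function(p) amp * exp(-rowSums(sweep(p, 2, ctr)^2) / (2 * 3^2))
  vol <- volume_grid(array(f(co), d), aff)
  set.seed(3)
  pts <- sweep(matrix(runif(300 * 3, -4, 4), ncol = 3), 2, ctr, `+`)
  vals <- hippolaminar:::tricubic_interp(vol$data, world_to_voxel(pts, vol))
  expect_lt(max(abs(vals - f(pts))), 0.01 * amp)
})

test_that("out-of-bounds coordinates become NA and flag the vertex", {
  vol <- volume_grid(array(1, c(8, 8, 8)))
  surf <- subfield_surface_set(
    vertices_inner = matrix(c(30, 4, 4), 1),   # far outside
    vertices_mid = matrix(c(15, 4, 4), 1),
    vertices_outer = matrix(c(2, 4, 4), 1),
    triangles = matrix(c(1, 1, 1), 1), labels = "CA3")
  sch <- build_sampling_scheme(surf)
  prof <- sample_profiles(vol, sch)
  expect_true(any(is.na(prof$subfields$CA3$values)))
  expect_true(prof$subfields$CA3$flagged[1])
  expect_error(aggregate_profiles(prof), "all vertices masked in CA3")
})

test_that("aggregation computes masked means, SEM and counts", {
  s <- flat_slab(n = 6)
  sch <- build_sampling_scheme(s)
  vol <- volume_grid(array(7, c(14, 14, 6)))   # constant field
  prof <- sample_profiles(vol, sch)
  agg <- aggregate_profiles(prof)
  expect_equal(unname(agg$CA3$mean), rep(7, 20))
  expect_equal(unname(agg$CA3$sem), rep(0, 20))

  # masking half the vertices leaves the mean over the remaining half
  el <- prof$subfields$CA3
  nv <- length(el$vertex_idx)
  el$values <- el$values + matrix(rep(seq_len(nv), each = 20), 20, nv)
  prof$subfields$CA3 <- el
  mask <- rep(FALSE, nrow(s$vertices_outer))
  mask[el$vertex_idx[seq(1, nv, by = 2)]] <- TRUE
  agg2 <- aggregate_profiles(prof, mask)
  keep <- seq(2, nv, by = 2)
  expect_equal(unname(agg2$CA3$mean), unname(rowMeans(el$values[, keep])))
  expect_equal(agg2$CA3$n_vertices, length(keep))
})

test_that("SEM follows the sampling distribution of the vertex mean", {
  set.seed(11)
  sigma <- 2; nv <- 40
  sems <- replicate(200, {
    vals <- matrix(rnorm(nv, sd = sigma), 1, nv)
    sd(vals) / sqrt(nv)
  })
  expect_lt(abs(mean(sems) / (sigma / sqrt(nv)) - 1), 0.1)
})

test_that("flat slab with an analytic depth ramp is recovered to 1e-6", {
  s <- flat_slab(n = 8, thickness = 1)
  # world volume encoding f = depth fraction = z - 1, exact for cubics
  d <- c(14, 14, 12)
  co <- as.matrix(expand.grid(x = 0:13, y = 0:13, z = 0:11))
  vol <- volume_grid(array(co[, 3] * 0.5 - 1, d), diag(c(1, 1, 0.5, 1)))
  sch <- build_sampling_scheme(s)
  agg <- aggregate_profiles(sample_profiles(vol, sch))
  for (sf in c("Subiculum", "CA3")) {
    expect_lt(max(abs(agg[[sf]]$mean - agg[[sf]]$depth_fraction)), 1e-6)
  }
})
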