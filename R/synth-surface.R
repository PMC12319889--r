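# Synthetic folded subfield sheet. The transverse cross-section is a piece of
# a spiral (the hippocampal crescent), extruded along the longitudinal axis.
# The inner surface is offset from the outer along the local cross-section
# normal; the midthickness is placed at the EQUIVOLUME depth given the local
# curvature: for a cross-section annulus with radii r_in, r_out the
# equal-volume radius is r_eq = sqrt((r_in^2 + r_out^2)/2), which collapses to
# the arithmetic midpoint as curvature vanishes.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# equivolume depth offset (mm from the outer point) for thickness h and
# signed curvature kappa (positive = centre of curvature on the inner side)
equivolume_offset <- function(kappa, h) {
  s <- rep(h / 2, length(kappa))
  pos <- which(kappa > 1e-8)
  if (length(pos)) {
    R0 <- 1 / kappa[pos]
    s[pos] <- R0 - sqrt((R0^2 + (R0 - h)^2) / 2)
  }
  neg <- which(kappa < -1e-8)
  if (length(neg)) {
    R0 <- -1 / kappa[neg]
    s[neg] <- sqrt((R0^2 + (R0 + h)^2) / 2) - R0
  }
  s
}

#' Generate a synthetic folded subfield sheet
#'
#' Builds a two-boundary triangulated sheet standing in for unfolding-derived
#' hippocampal surfaces: a spiral cross-section extruded longitudinally, with
#' the inner surface offset by `thickness` along local normals, the
#' midthickness at the local equivolume depth, and subfield labels assigned by
#' transverse arc-length fractions in the order subiculum, CA1-CA4, DG.
#'
#' @param n_long vertices along the longitudinal axis (>= 4).
#' @param n_trans vertices along the transverse (cross-section) axis (>= 4).
#' @param fold_turns fraction of a full spiral turn (0 = flat slab).
#' @param thickness sheet thickness, mm.
#' @param subfield_fractions six transverse arc-length proportions summing
#'   to 1, ordered Subiculum, CA1, CA2, CA3, CA4, DG.
#' @param length_mm longitudinal extent, mm.
#' @param r0 outer spiral radius at the subicular end, mm.
#' @return a [subfield_surface_set].
#' @export
make_surface_sheet <- function(n_long = 16, n_trans = 48, fold_turns = 0.75,
                               thickness = 2.5,
                               subfield_fractions = c(0.25, 0.30, 0.08,
                                                      0.12, 0.12, 0.13),
                               length_mm = 30, r0 = 10) {
  if (n_long < 4 || n_trans < 4) stop("n_long and n_trans must be >= 4")
  if (thickness <= 0) stop("thickness must be positive")
  if (length(subfield_fractions) != 6L ||
      abs(sum(subfield_fractions) - 1) > 1e-8)
    stop("subfield_fractions must be 6 proportions summing to 1")

  t <- seq(0, 1, length.out = n_trans)
  shrink <- 0.45
  theta <- 2 * pi * fold_turns * t
  r <- r0 * (1 - shrink * t)
  y <- r * cos(theta); z <- r * sin(theta)
  rp <- -r0 * shrink; thp <- 2 * pi * fold_turns
  yp <- rp * cos(theta) - r * thp * sin(theta)
  zp <- rp * sin(theta) + r * thp * cos(theta)
  ypp <- -2 * rp * thp * sin(theta) - r * thp^2 * cos(theta)
  zpp <- 2 * rp * thp * cos(theta) - r * thp^2 * sin(theta)
  speed <- sqrt(yp^2 + zp^2)
  kappa <- (yp * zpp - zp * ypp) / speed^3   # signed, left-normal convention
  ny <- -zp / speed; nz <- yp / speed        # left normal = inner direction

  if (any(kappa > 1e-8 & thickness >= 1 / kappa - 1e-9))
    stop("self-intersecting fold: thickness ", thickness,
         " mm exceeds the local curvature radius")
  s_mid <- equivolume_offset(kappa, thickness)

  x_long <- seq(0, length_mm, length.out = n_long)
  outer_v <- cbind(rep(x_long, each = n_trans), rep(y, n_long), rep(z, n_long))
  off_in <- cbind(0, rep(ny, n_long), rep(nz, n_long))
  inner_v <- outer_v + thickness * off_in
  mid_v <- outer_v + rep(s_mid, n_long) * off_in

  # transverse arc-length fractions -> subfield labels
  seg <- c(0, cumsum(sqrt(diff(y)^2 + diff(z)^2)))
  frac <- if (seg[n_trans] > 0) seg / seg[n_trans] else t
  cuts <- cumsum(subfield_fractions)
  # first subfield whose cumulative fraction reaches the vertex (closed on
  # the right, so zero-width subfields get no vertices)
  lab_idx <- rowSums(outer(frac, cuts[-6], `>`)) + 1L
  labels <- rep(names(subfield_codes())[lab_idx], n_long)

  # grid triangulation (vertex id = (i_long-1)*n_trans + i_trans)
  tri <- NULL
  idx <- function(il, it) (il - 1L) * n_trans + it
  il <- rep(seq_len(n_long - 1L), each = n_trans - 1L)
  it <- rep(seq_len(n_trans - 1L), times = n_long - 1L)
  a <- idx(il, it); b <- idx(il, it + 1L)
  cc <- idx(il + 1L, it); d <- idx(il + 1L, it + 1L)
  tri <- rbind(cbind(a, b, d), cbind(a, d, cc))

  subfield_surface_set(inner_v, mid_v, outer_v, tri, labels)
}
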