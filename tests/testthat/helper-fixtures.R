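# Shared fixtures and independent oracles, built in code at test time.

# single straight vertex column: outer (0,0,0), mid (xm,0,0), inner (1,0,0)
straight_column_surface <- function(xm = 0.5, label = "CA3") {
  subfield_surface_set(
    vertices_inner = matrix(c(1, 0, 0), 1),
    vertices_mid = matrix(c(xm, 0, 0), 1),
    vertices_outer = matrix(c(0, 0, 0), 1),
    triangles = matrix(c(1, 1, 1), 1),
    labels = label)
}

# small folded sheet reused across tests (cached per session)
small_sheet <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_surface_sheet(n_long = 8, n_trans = 24)
    cache
  }
})

# flat slab: vertex columns along +z starting at z = 1 (clear of the volume
# edge so interpolation stencils are never clamped), all six subfields
flat_slab <- function(n = 10, thickness = 1) {
  g <- expand.grid(x = seq(2, 9, length.out = n), y = seq(2, 9, length.out = n))
  outer_v <- cbind(g$x, g$y, 1)
  inner_v <- cbind(g$x, g$y, 1 + thickness)
  mid_v <- (outer_v + inner_v) / 2
  labs <- rep(names(subfield_codes()), length.out = n * n)
  subfield_surface_set(inner_v, mid_v, outer_v,
                       matrix(c(1, 2, 3), 1), labs)
}

# brute-force exact signed-rank two-sided p over all 2^n sign assignments
enum_signrank_p <- function(W, n) {
  signs <- as.matrix(expand.grid(rep(list(c(0L, 1L)), n)))
  Ws <- signs %*% seq_len(n)
  p_le <- mean(Ws <= W)
  p_ge <- mean(Ws >= W)
  min(1, 2 * min(p_le, p_ge))
}

# direct formula for the Hochberg step-up adjustment (independent of p.adjust)
hochberg_formula <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- vapply(seq_len(m), function(i)
    min(1, min((m - seq(i, m) + 1) * ps[seq(i, m)])), numeric(1))
  out <- numeric(m)
  out[o] <- adj
  out
}
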