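#' Ground truth for the synthetic generators
#'
#' Collects everything the simulated data are built from, so downstream tests
#' can compare recovered quantities against known values: a depth-linear T2*
#' map per subfield (ms), equilibrium signal S0, vein/artery centerlines with
#' radii, laminar response amplitudes per condition as quadratic polynomials
#' in depth fraction, and a noise specification.
#'
#' @param t2star data.frame with columns `subfield`, `t2s_outer`, `t2s_inner`
#'   (ms); T2* at depth fraction d is linearly interpolated.
#' @param s0 equilibrium signal, a.u.
#' @param vessels list of centerlines: each `list(points = n x 3 world-mm
#'   polyline, radius = mm, type = "vein"|"artery")`.
#' @param laminar_response named list (by subfield) of named lists (by
#'   condition) of quadratic coefficients `c(a0, a1, a2)`: amplitude at depth
#'   d is `a0 + a1 d + a2 d^2`, a.u.
#' @param noise_spec list with `thermal_sd` (a.u.), `structured` (list of
#'   `list(freq` Hz`, amplitude` a.u.`)`), `drift_order` (polynomial order),
#'   `bias_amp` (fractional T2* lengthening at a vein wall during breath-hold)
#'   and `bias_lambda` (kernel length constant, mm).
#' @return an object of class `ground_truth`.
#' @export
ground_truth <- function(t2star, s0 = 1000, vessels = list(),
                         laminar_response = list(),
                         noise_spec = list(thermal_sd = 0, structured = list(),
                                           drift_order = 0, bias_amp = 0.15,
                                           bias_lambda = 1)) {
  stopifnot(all(c("subfield", "t2s_outer", "t2s_inner") %in% names(t2star)))
  if (any(t2star$t2s_outer <= 0) || any(t2star$t2s_inner <= 0))
    stop("T2* must be positive everywhere")
  for (v in vessels) {
    if (v$radius <= 0) stop("vessel radius must be positive")
    if (!v$type %in% c("vein", "artery")) stop("vessel type must be vein|artery")
  }
  for (comp in noise_spec$structured)
    if (comp$amplitude < 0) stop("structured-component amplitudes must be >= 0")
  structure(list(t2star = t2star, s0 = s0, vessels = vessels,
                 laminar_response = laminar_response,
                 noise_spec = noise_spec),
            class = "ground_truth")
}

#' Query the ground truth at given depths
#'
#' `truth_t2star_at` returns the T2* (ms) and `truth_response_at` the task
#' response amplitude (a.u.) of a [ground_truth] for one subfield at the
#' given depth fractions.
#'
#' @param truth a [ground_truth].
#' @param subfield subfield name.
#' @param depth depth fractions (0 = outer, 1 = inner).
#' @return numeric vector along `depth`.
#' @export
truth_t2star_at <- function(truth, subfield, depth) {
  row <- truth$t2star[truth$t2star$subfield == subfield, ]
  if (nrow(row) == 0L) stop("no T2* entry for subfield ", subfield)
  row$t2s_outer * (1 - depth) + row$t2s_inner * depth
}

#' @param condition condition name (e.g. `"AM_construction"`).
#' @rdname truth_t2star_at
#' @export
truth_response_at <- function(truth, subfield, condition, depth) {
  lr <- truth$laminar_response[[subfield]]
  if (is.null(lr) || is.null(lr[[condition]])) return(rep(0, length(depth)))
  a <- lr[[condition]]
  a[1] + a[2] * depth + a[3] * depth^2
}

#' Default ground truth mirroring the study's qualitative structure
#'
#' T2* in the 24-36 ms range with the subiculum shortest; veins concentrated
#' at the inner surface of subiculum/CA1 and at the outer surface of CA3 (the
#' vascular asymmetry the breath-hold analysis is meant to recover); a
#' CA1 memory response peaking at depth fraction 0.75; respiratory (~0.3 Hz)
#' and aliased cardiac structured noise.
#'
#' @param surface a [subfield_surface_set] used to place vessel centerlines;
#'   `NULL` for no vessels.
#' @param thermal_sd thermal noise SD, a.u.
#' @param seed RNG seed for vessel placement.
#' @return a [ground_truth].
#' @export
default_ground_truth <- function(surface = NULL, thermal_sd = 30, seed = 1L) {
  t2s <- data.frame(
    subfield = c("Subiculum", "CA1", "CA2", "CA3", "CA4", "DG"),
    t2s_outer = c(24, 30, 30, 32, 34, 33),
    t2s_inner = c(28, 36, 34, 36, 34, 33))
  # amplitudes in a.u. against a baseline of 1000: peak memory responses of
  # ~1-2 % signal change, the realistic 7T GRE-BOLD range
  resp <- list(
    Subiculum = list(AM_construction = c(6, 8, 0), AM_elaboration = c(6, 8, 0),
                     math = c(2, 0, 0)),
    CA1 = list(AM_construction = c(2, 32, -21.33), # peak at d = 0.75
               AM_elaboration = c(2, 32, -21.33), math = c(2, 0, 0)),
    CA2 = list(AM_construction = c(5, 5, 0), AM_elaboration = c(3, 5, 0),
               math = c(2, 0, 0)),
    CA3 = list(AM_construction = c(3, 40, -40), AM_elaboration = c(3, 20, -20),
               math = c(2, 0, 0)),
    CA4 = list(AM_construction = c(5, 0, 0), AM_elaboration = c(4, 0, 0),
               math = c(2, 0, 0)),
    DG = list(AM_construction = c(7, 0, 0), AM_elaboration = c(5, 0, 0),
              math = c(2, 0, 0)))
  vessels <- if (!is.null(surface)) synth_vessels(surface, seed) else list()
  ground_truth(
    t2star = t2s, s0 = 1000, vessels = vessels, laminar_response = resp,
    noise_spec = list(thermal_sd = thermal_sd,
                      structured = list(list(freq = 0.3, amplitude = 8),
                                        list(freq = 0.11, amplitude = 6)),
                      drift_order = 1, bias_amp = 0.15, bias_lambda = 1))
}

# Vein centerlines hugging the inner surface for Subiculum/CA1 and the outer
# surface for CA3; a couple of arteries near the outer subicular surface.
synth_vessels <- function(surface, seed = 1L) {
  with_seed(seed, {
    vessels <- list()
    place <- function(side, subfield, n_lines, type, radius = 0.4) {
      v <- if (side == "inner") surface$vertices_inner else surface$vertices_outer
      nrm <- surface$vertices_inner - surface$vertices_outer
      nrm <- nrm / pmax(sqrt(rowSums(nrm^2)), 1e-9)
      sel <- which(surface$labels == subfield)
      if (length(sel) < 2L) return(invisible(NULL))
      for (k in seq_len(n_lines)) {
        # one longitudinal polyline at a random transverse station, just
        # outside the boundary surface
        xs <- sort(unique(round(v[sel, 1], 6)))
        station <- sample(seq_along(sel), 1L)
        p0 <- v[sel[station], ]
        along <- sel[abs(v[sel, 2] - p0[2]) < 0.6 & abs(v[sel, 3] - p0[3]) < 2]
        pts <- v[along, , drop = FALSE] +
          (if (side == "inner") 0.3 else -0.3) * nrm[along, , drop = FALSE]
        pts <- pts[order(pts[, 1]), , drop = FALSE]
        if (nrow(pts) >= 2L)
          vessels[[length(vessels) + 1L]] <<- list(points = pts,
                                                   radius = radius, type = type)
      }
      invisible(NULL)
    }
    place("inner", "Subiculum", 3, "vein")
    place("inner", "CA1", 3, "vein")
    place("outer", "CA3", 2, "vein")
    place("outer", "Subiculum", 1, "artery", radius = 0.3)
    place("outer", "CA1", 1, "artery", radius = 0.3)
    vessels
  })
}
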