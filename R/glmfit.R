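#' Volumes belonging to a condition, with hemodynamic shift
#'
#' A volume belongs to a condition if its acquisition midpoint, shifted back
#' by `shift` volumes to absorb the hemodynamic delay, falls inside one of
#' the condition's trial windows. Used to pick the math-condition baseline
#' volumes for tSNR, the Weisskoff SD and the baseline z-transform.
#'
#' @param events a [paradigm_events] table.
#' @param condition condition name (default `"math"`).
#' @param shift hemodynamic shift, volumes (default 2, about 4.4 s at the
#'   task TR).
#' @param drop_initial volumes discarded at the run start; returned indices
#'   refer to the retained series.
#' @return integer volume indices (1-based into the retained series).
#' @export
condition_volumes <- function(events, condition = "math", shift = 2L,
                              drop_initial = 0L) {
  tr <- attr(events, "tr_vol"); nv <- attr(events, "n_volumes")
  vols <- seq_len(nv)
  mid <- (vols - 0.5) * tr - shift * tr
  sel <- events$condition == condition
  inside <- rep(FALSE, nv)
  for (k in which(sel)) {
    inside <- inside | (mid >= events$onset[k] &
                        mid < events$onset[k] + events$duration[k])
  }
  idx <- which(inside)
  idx <- idx[idx > drop_initial] - drop_initial
  idx
}

#' Build the task design matrix
#'
#' Condition boxcars (AM construction: cue to button press; AM elaboration:
#' press to trial end; math: whole trial) are convolved with the canonical
#' double-gamma HRF and sampled at volume midpoints. A discrete-cosine
#' high-pass basis with the given cutoff period is appended as regressors
#' (equivalent to pre-filtering both sides of the model), followed by the six
#' motion parameters and any nuisance set, unconvolved. The first
#' `drop_initial` volumes are discarded.
#'
#' @param events a [paradigm_events] table.
#' @param motion a [motion_table] or `NULL`.
#' @param nuisance a [acompcor()] result or a volumes x k matrix or `NULL`.
#' @param tr volume repeat time, seconds (defaults to the events' TR).
#' @param hp_cutoff high-pass cutoff period, seconds.
#' @param drop_initial initial volumes to discard.
#' @return an object of class `design_matrix`: list with `X` (volumes x
#'   regressors, named), `task_cols`, `tr`.
#' @export
build_design <- function(events, motion = NULL, nuisance = NULL,
                         tr = attr(events, "tr_vol"), hp_cutoff = 128,
                         drop_initial = 3L) {
  nv <- attr(events, "n_volumes")
  conds <- intersect(c("AM_construction", "AM_elaboration", "math"),
                     unique(events$condition))
  Xtask <- vapply(conds, function(cc) {
    sel <- events$condition == cc
    convolve_events(events$onset[sel], events$duration[sel], nv, tr)
  }, numeric(nv))
  Xtask <- matrix(Xtask, nrow = nv, dimnames = list(NULL, conds))
  keep <- seq_len(nv) > drop_initial
  n_keep <- sum(keep)
  Xhp <- dct_highpass_basis(n_keep, tr, hp_cutoff)
  if (ncol(Xhp) > 0L)
    colnames(Xhp) <- paste0("dct", seq_len(ncol(Xhp)))
  Xm <- NULL
  if (!is.null(motion)) {
    Xm <- as.matrix(as.data.frame(motion))[keep, , drop = FALSE]
    Xm <- scale(Xm, scale = FALSE)
  }
  Xn <- NULL
  if (!is.null(nuisance)) {
    Xn <- if (inherits(nuisance, "nuisance_set")) nuisance$regressors
          else as.matrix(nuisance)
    if (nrow(Xn) == nv) Xn <- Xn[keep, , drop = FALSE]
    if (nrow(Xn) != n_keep)
      stop("nuisance regressors have ", nrow(Xn), " rows; expected ", n_keep)
    if (ncol(Xn) > 0L) colnames(Xn) <- paste0("acomp", seq_len(ncol(Xn)))
  }
  X <- cbind(intercept = 1, Xtask[keep, , drop = FALSE], Xhp, Xm, Xn)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("design is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  structure(list(X = X, task_cols = conds, tr = tr,
                 drop_initial = drop_initial),
            class = "design_matrix")
}

#' Robust weighted least-squares GLM
#'
#' Iterative per-volume variance weighting: an OLS pass estimates residuals,
#' the residual variance of each volume is pooled over depths/voxels, and a
#' weighted fit with inverse-variance volume weights follows; iterate until
#' the weights change by less than `tol` (relative) or `max_iter` passes.
#' Volumes corrupted by motion or physiology receive small weights;
#' homoscedastic data converge to OLS.
#'
#' @param Y depth (or voxel) x time response matrix.
#' @param design a [build_design()] result (or plain matrix).
#' @param tol relative weight-change convergence tolerance.
#' @param max_iter iteration cap.
#' @return list with `coefficients` (regressor x depth, named rows),
#'   `weights` (per volume), `residuals` (depth x time), `iterations`.
#' @export
rwls_fit <- function(Y, design, tol = 1e-6, max_iter = 50L) {
  X <- if (inherits(design, "design_matrix")) design$X else as.matrix(design)
  Y <- as.matrix(Y)
  if (ncol(Y) != nrow(X))
    stop("Y has ", ncol(Y), " volumes but the design has ", nrow(X), " rows")
  n_vol <- nrow(X)
  w <- rep(1, n_vol)
  B <- NULL
  for (it in seq_len(max_iter)) {
    sw <- sqrt(w)
    Xw <- X * sw
    Yw <- t(Y) * sw
    B <- qr.solve(Xw, Yw)                      # coef x depth
    E <- t(Y) - X %*% B                        # time x depth
    v <- rowMeans(E^2)
    med <- stats::median(v)
    if (med <= 1e-12) {
      warning("per-volume variance estimates degenerate; floored at 1e-12")
      med <- 1e-12
    }
    # relative floor keeps single volumes from being interpolated exactly,
    # which would send their weight (and the iteration) to infinity
    v <- pmax(v, 1e-4 * med)
    w_new <- 1 / v
    w_new <- w_new / mean(w_new)
    if (max(abs(w_new - w) / pmax(w, 1e-12)) < tol) {
      w <- w_new
      break
    }
    w <- w_new
  }
  rownames(B) <- colnames(X)
  list(coefficients = B, weights = w, residuals = t(t(Y) - X %*% B),
       iterations = it)
}

#' Baseline z-transform of laminar time courses
#'
#' Standardizes each depth's time course by the mean and SD computed from the
#' math-condition volumes only, so z is expressed in units of
#' baseline variability.
#'
#' @param Y depth x time matrix.
#' @param math_volumes indices of the math-condition volumes (>= 3).
#' @return z-transformed matrix of the same shape.
#' @export
baseline_z <- function(Y, math_volumes) {
  Y <- as.matrix(Y)
  if (length(math_volumes) < 3L) stop("need at least 3 math volumes")
  mu <- rowMeans(Y[, math_volumes, drop = FALSE])
  sd0 <- apply(Y[, math_volumes, drop = FALSE], 1L, stats::sd)
  if (any(sd0 <= 0)) stop("zero SD over the math volumes at some depth")
  (Y - mu) / sd0
}

#' Laminar task contrasts
#'
#' `memory_gt_math` = mean of the two AM phases minus math;
#' `pre_gt_post` = construction minus elaboration, per depth.
#'
#' @param coefficients regressor x depth matrix with named rows (from
#'   [rwls_fit()]).
#' @return data.frame with `depth`, `memory_gt_math`, `pre_gt_post`.
#' @export
laminar_contrasts <- function(coefficients) {
  need <- c("AM_construction", "AM_elaboration", "math")
  missing_c <- setdiff(need, rownames(coefficients))
  if (length(missing_c) > 0L)
    stop("missing coefficient(s): ", paste(missing_c, collapse = ", "))
  bc <- coefficients["AM_construction", ]
  be <- coefficients["AM_elaboration", ]
  bm <- coefficients["math", ]
  data.frame(depth = seq_along(bc),
             memory_gt_math = (bc + be) / 2 - bm,
             pre_gt_post = bc - be)
}
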