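#' Echo-resolved laminar time series
#'
#' @param profiles depth x echo x volume array, a.u.
#' @param tes echo times, ms, strictly increasing and positive.
#' @param condition condition label per volume (`rest`, `transition`,
#'   `active`).
#' @param tr_vol volume repeat time, seconds.
#' @param depth_fraction per-depth fractions (0 = outer, 1 = inner).
#' @return an object of class `multi_echo_series`.
#' @export
multi_echo_series <- function(profiles, tes, condition, tr_vol,
                              depth_fraction = NULL) {
  profiles <- as.array(profiles)
  if (length(dim(profiles)) != 3L)
    stop("profiles must be depth x echo x volume")
  if (dim(profiles)[2] != length(tes))
    stop("echo axis length ", dim(profiles)[2], " != length(tes) ",
         length(tes))
  if (any(tes <= 0) || any(diff(tes) <= 0))
    stop("tes must be strictly increasing and positive")
  if (dim(profiles)[3] != length(condition))
    stop("need one condition label per volume")
  if (is.null(depth_fraction))
    depth_fraction <- seq(0, 1, length.out = dim(profiles)[1])
  structure(list(profiles = profiles, tes = tes,
                 condition = as.character(condition), tr_vol = tr_vol,
                 depth_fraction = depth_fraction),
            class = "multi_echo_series")
}

#' Assemble a multi-echo laminar series from a simulated acquisition
#'
#' Samples every echo's 4D volume with the scheme, aggregates over a
#' subfield's vertices, and stacks the per-depth mean time courses.
#'
#' @param sim result of [make_multiecho_breathhold()].
#' @param scheme a [build_sampling_scheme()] result.
#' @param subfield subfield name (a scheme entry, e.g. `"CA1"` or
#'   `"CA4/DG"`).
#' @param vertex_mask optional exclusion flags for [aggregate_profiles()].
#' @return a [multi_echo_series].
#' @export
multiecho_from_sim <- function(sim, scheme, subfield, vertex_mask = NULL) {
  mats <- lapply(sim$echoes, function(vol) {
    agg <- aggregate_profiles(sample_profiles(vol, scheme), vertex_mask)
    agg[[subfield]]
  })
  nb <- nrow(mats[[1]]$mean); nt <- ncol(mats[[1]]$mean)
  arr <- array(NA_real_, dim = c(nb, length(mats), nt))
  for (e in seq_along(mats)) arr[, e, ] <- mats[[e]]$mean
  multi_echo_series(arr, sim$tes, sim$events$condition,
                    attr(sim$events, "tr_vol"),
                    depth_fraction = mats[[1]]$depth_fraction)
}

#' High-pass filter and edge-trim a laminar multi-echo series
#'
#' Removes discrete-cosine drift components with period longer than
#' `cutoff_period` from every depth x echo time course (the mean is removed
#' and re-added, so condition differences are unaffected), then drops the
#' first and last `drop_edges` volumes of the run to discard filter edge
#' effects.
#'
#' @param series a [multi_echo_series].
#' @param cutoff_period high-pass cutoff period, seconds.
#' @param drop_edges volumes to drop at each end of the run.
#' @return a trimmed [multi_echo_series].
#' @export
highpass_trim <- function(series, cutoff_period = 246, drop_edges = 1L) {
  stopifnot(inherits(series, "multi_echo_series"))
  d <- dim(series$profiles)
  if (d[3] < 4L) stop("need at least 4 volumes")
  Y <- matrix(aperm(series$profiles, c(3, 1, 2)), nrow = d[3])
  Yf <- dct_highpass_filter(Y, series$tr_vol, cutoff_period)
  prof <- aperm(array(Yf, dim = c(d[3], d[1], d[2])), c(2, 3, 1))
  keep <- seq_len(d[3])
  if (drop_edges > 0L)
    keep <- keep[-c(seq_len(drop_edges), d[3] - seq_len(drop_edges) + 1L)]
  multi_echo_series(prof[, , keep, drop = FALSE], series$tes,
                    series$condition[keep], series$tr_vol,
                    series$depth_fraction)
}

#' Mono-exponential T2* fit per depth
#'
#' Fits `S(TE) = S0 exp(-TE/T2*)` by Levenberg-Marquardt nonlinear least
#' squares, initialized from the log-linear fit. Depths where the nonlinear
#' fit fails to converge keep the log-linear estimate and are flagged.
#'
#' @param signals depth x echo matrix of (positive) echo-mean signals, or a
#'   vector for a single depth.
#' @param tes echo times, ms (>= 3).
#' @return data.frame with `s0`, `t2star` (ms), `resid_norm`, `converged`.
#' @export
fit_t2star <- function(signals, tes) {
  if (length(tes) < 3L) stop("need at least 3 echoes")
  signals <- if (is.null(dim(signals))) matrix(signals, nrow = 1L)
             else as.matrix(signals)
  if (ncol(signals) != length(tes))
    stop("signals must have one column per echo")
  if (any(signals <= 0)) stop("signals must be positive")
  fit_one <- function(s) {
    ll <- stats::lm.fit(cbind(1, tes), log(s))
    t2_0 <- -1 / min(ll$coefficients[2], -1e-6)
    s0_0 <- exp(ll$coefficients[1])
    df <- data.frame(te = tes, s = s)
    fit <- tryCatch(
      minpack.lm::nlsLM(s ~ s0 * exp(-te / t2), data = df,
                        start = list(s0 = s0_0, t2 = t2_0),
                        lower = c(1e-6, 1e-3),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) {
      res <- s - s0_0 * exp(-tes / t2_0)
      return(c(s0_0, t2_0, sqrt(sum(res^2)), 0))
    }
    cf <- stats::coef(fit)
    c(cf[["s0"]], cf[["t2"]], sqrt(sum(stats::resid(fit)^2)), 1)
  }
  res <- t(apply(signals, 1L, fit_one))
  data.frame(s0 = res[, 1], t2star = res[, 2], resid_norm = res[, 3],
             converged = res[, 4] == 1)
}

#' Inverse-TE echo combination weights
#'
#' `w_i = TE_i^-1 / sum_j TE_j^-1`: echo averages are weighted with a penalty
#' on longer echo times, which carry stronger off-resonance artifacts.
#'
#' @param tes echo times, ms.
#' @return weights summing to 1.
#' @export
echo_weights <- function(tes) {
  if (any(tes <= 0)) stop("echo times must be positive")
  w <- 1 / tes
  w / sum(w)
}

#' Breath-hold induced signal change profile
#'
#' Per depth and echo, the mean signal over `active` volumes minus the mean
#' over `rest` volumes (breath-hold minus normal breathing); echoes are then
#' combined with the supplied weights. `normalize = "percent"` divides by
#' the weighted rest mean and scales by 100.
#'
#' @param series a [multi_echo_series].
#' @param weights echo combination weights (default [echo_weights()] of the
#'   series' TEs).
#' @param normalize `"none"` (raw difference) or `"percent"`.
#' @return an object of class `signal_change_profile`: data.frame with
#'   `depth_fraction` and `ds`, plus the per-echo matrix as attribute
#'   `per_echo`.
#' @export
breathhold_change <- function(series, weights = echo_weights(series$tes),
                              normalize = c("none", "percent")) {
  stopifnot(inherits(series, "multi_echo_series"))
  normalize <- match.arg(normalize)
  act <- series$condition == "active"
  rst <- series$condition == "rest"
  if (!any(act) || !any(rst))
    stop("need at least one 'active' and one 'rest' volume")
  m_act <- apply(series$profiles[, , act, drop = FALSE], c(1, 2), mean)
  m_rst <- apply(series$profiles[, , rst, drop = FALSE], c(1, 2), mean)
  per_echo <- m_act - m_rst
  ds <- as.numeric(per_echo %*% weights)
  if (normalize == "percent") ds <- 100 * ds / as.numeric(m_rst %*% weights)
  structure(data.frame(depth_fraction = series$depth_fraction, ds = ds),
            per_echo = per_echo, normalize = normalize,
            class = c("signal_change_profile", "data.frame"))
}

#' Linear slope of a signal-change profile
#'
#' Ordinary least-squares slope of the signal change against depth fraction
#' (0 = outer, 1 = inner), over the core bins only (extension bins beyond the
#' inner surface are excluded).
#'
#' @param profile a [breathhold_change()] result (or any data.frame with
#'   `depth_fraction` and `ds`).
#' @return named vector `c(slope, se)`.
#' @export
profile_slope <- function(profile) {
  core <- profile$depth_fraction <= 1 + 1e-9
  d <- profile$depth_fraction[core]; y <- profile$ds[core]
  if (length(d) < 3L) stop("need at least 3 depths")
  fit <- stats::lm(y ~ d)
  sm <- summary(fit)$coefficients
  c(slope = unname(sm["d", "Estimate"]), se = unname(sm["d", "Std. Error"]))
}
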