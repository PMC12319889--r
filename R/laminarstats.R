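#' Exact Wilcoxon signed-rank test
#'
#' W is the sum of the ranks of the positive differences; the exact two-sided
#' p-value is `2 * min(P(W <= w), P(W >= w))` capped at 1, computed from the
#' exact null distribution over all 2^n sign assignments. Zero differences
#' are dropped with a warning; ties are not supported (the laminar families
#' here are continuous-valued).
#'
#' @param differences paired differences (n <= 20 after dropping zeros).
#' @return list with `W`, `n`, `p_exact` (class `paired_test`).
#' @export
wilcoxon_exact <- function(differences) {
  d <- differences[is.finite(differences)]
  if (any(d == 0)) {
    warning(sum(d == 0), " zero difference(s) dropped")
    d <- d[d != 0]
  }
  n <- length(d)
  if (n == 0L) stop("no nonzero differences")
  if (n > 20L)
    stop("n > 20: use a normal approximation (out of scope here)")
  r <- rank(abs(d))
  if (anyDuplicated(r)) stop("tied absolute differences are not supported")
  W <- sum(r[d > 0])
  list(W = W, n = n, p_exact = wilcoxon_exact_p(W, n))
}

# exact two-sided p from the signed-rank null distribution
wilcoxon_exact_p <- function(W, n) {
  p_le <- stats::psignrank(W, n)
  p_ge <- 1 - stats::psignrank(W - 1, n)
  min(1, 2 * min(p_le, p_ge))
}

#' Hochberg step-up adjustment
#'
#' Family-wise error-controlling step-up procedure: with sorted p-values
#' p(1) <= ... <= p(m), adjusted(i) = min over j >= i of (m - j + 1) * p(j),
#' capped at 1, mapped back to input order.
#'
#' @param p_values p-value family.
#' @return adjusted p-values in input order.
#' @export
hochberg_stepup <- function(p_values) {
  stopifnot(length(p_values) > 0L, all(p_values >= 0 & p_values <= 1))
  stats::p.adjust(p_values, method = "hochberg")
}

#' Benjamini-Hochberg FDR adjustment
#'
#' @param p_values p-value family.
#' @return BH-adjusted p-values in input order.
#' @export
bh_fdr <- function(p_values) {
  stopifnot(length(p_values) > 0L, all(p_values >= 0 & p_values <= 1))
  stats::p.adjust(p_values, method = "BH")
}

#' Marginal and conditional R-squared of a mixed model
#'
#' Variance-decomposition definition: marginal R2 is the fixed-effect
#' variance share, conditional R2 adds the random-intercept variances,
#' both over fixed + random + residual variance.
#'
#' @param model a fitted `lme4::lmer` model.
#' @return named vector `c(marginal, conditional)`.
#' @export
lme_r2 <- function(model) {
  var_fix <- stats::var(as.numeric(stats::model.matrix(model) %*%
                                     lme4::fixef(model)))
  vc <- lme4::VarCorr(model)
  var_ran <- sum(vapply(vc, function(v) v[1, 1], numeric(1)))
  var_res <- attr(vc, "sc")^2
  tot <- var_fix + var_ran + var_res
  c(marginal = var_fix / tot, conditional = (var_fix + var_ran) / tot)
}

#' Kenward-Roger approximated F-test between nested mixed models
#'
#' Small-sample F-test for the fixed effects added by the larger model, with
#' the Kenward-Roger adjusted covariance and denominator degrees of freedom.
#'
#' @param model_small,model_big nested REML `lmer` fits on the same data with
#'   the same random structure.
#' @return list with `F`, `df1`, `df2`, `p` (class `model_comparison`).
#' @export
kr_f_test <- function(model_small, model_big) {
  tf_small <- attr(stats::terms(model_small, fixed.only = TRUE), "term.labels")
  tf_big <- attr(stats::terms(model_big, fixed.only = TRUE), "term.labels")
  if (!all(tf_small %in% tf_big))
    stop("models are not nested: ", paste(setdiff(tf_small, tf_big),
                                          collapse = ", "),
         " only in the smaller model")
  if (setequal(tf_small, tf_big))
    return(structure(list(F = 0, df1 = 0, df2 = NA_real_, p = 1),
                     class = "model_comparison"))
  kr <- pbkrtest::KRmodcomp(model_big, model_small)
  st <- kr$stats
  structure(list(F = st$Fstat, df1 = st$ndf, df2 = st$ddf, p = st$p.value),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("F(%g, %.1f) = %.3f, p = %.4g\n", x$df1, x$df2, x$F, x$p))
  invisible(x)
}

#' Fit the baseline / linear / quadratic depth models
#'
#' REML random-intercept fits of z ~ (1|subject), z ~ depth + (1|subject) and
#' z ~ depth + depth^2 + (1|subject); depth is rescaled to [0, 1] before the
#' polynomial expansion. Singular fits (zero intercept variance) are flagged
#' but retained.
#'
#' @param data data.frame with columns `z`, `depth`, `subject`.
#' @return list with `baseline`, `linear`, `quadratic` fits, `r2` per model
#'   and `singular` flags.
#' @export
fit_depth_models <- function(data) {
  stopifnot(all(c("z", "depth", "subject") %in% names(data)))
  if (length(unique(data$subject)) < 2L) stop("need >= 2 subjects")
  if (length(unique(data$depth)) < 3L) stop("need >= 3 depths")
  rng <- range(data$depth)
  data$d <- if (diff(rng) > 0) (data$depth - rng[1]) / diff(rng) else data$depth
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  m0 <- lme4::lmer(z ~ (1 | subject), data = data, REML = TRUE, control = ctrl)
  m1 <- lme4::lmer(z ~ d + (1 | subject), data = data, REML = TRUE,
                   control = ctrl)
  m2 <- lme4::lmer(z ~ d + I(d^2) + (1 | subject), data = data, REML = TRUE,
                   control = ctrl)
  fits <- list(baseline = m0, linear = m1, quadratic = m2)
  list(fits = fits,
       r2 = lapply(fits, lme_r2),
       singular = vapply(fits, lme4::isSingular, logical(1)))
}

#' Depth-model comparison ladder with Kenward-Roger F-tests
#'
#' Baseline vs linear, then linear vs quadratic, with BH-FDR adjustment of
#' the two p-values.
#'
#' @param data as in [fit_depth_models()].
#' @return data.frame with `comparison`, `F`, `df1`, `df2`, `p`, `p_fdr`.
#' @export
compare_depth_models <- function(data) {
  fits <- fit_depth_models(data)$fits
  t01 <- kr_f_test(fits$baseline, fits$linear)
  t12 <- kr_f_test(fits$linear, fits$quadratic)
  p <- c(t01$p, t12$p)
  data.frame(comparison = c("baseline_vs_linear", "linear_vs_quadratic"),
             F = c(t01$F, t12$F), df1 = c(t01$df1, t12$df1),
             df2 = c(t01$df2, t12$df2), p = p, p_fdr = bh_fdr(p))
}

#' Venous-bias model: signal-change slope against vessel-density change
#'
#' Fits slope ~ delta_rho + (1|subject) + (1|subfield) against the
#' random-effects-only model, compares them with a Kenward-Roger F-test, and
#' reports marginal/conditional R2 of the full model.
#'
#' @param data data.frame with columns `slope`, `delta_rho`, `subject`,
#'   `subfield`.
#' @return list with `coef` (delta_rho estimate and SE), `test`
#'   (a `model_comparison`), `r2`, `fit`.
#' @export
slope_density_model <- function(data) {
  stopifnot(all(c("slope", "delta_rho", "subject", "subfield") %in%
                  names(data)))
  data <- data[stats::complete.cases(data[c("slope", "delta_rho")]), ]
  if (length(unique(data$subject)) < 2L || length(unique(data$subfield)) < 2L)
    stop("need at least 2 subjects and 2 subfields")
  if (nrow(data) < 10L) stop("need >= 10 complete cases")
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  m0 <- lme4::lmer(slope ~ (1 | subject) + (1 | subfield), data = data,
                   REML = TRUE, control = ctrl)
  m1 <- lme4::lmer(slope ~ delta_rho + (1 | subject) + (1 | subfield),
                   data = data, REML = TRUE, control = ctrl)
  sm <- summary(m1)$coefficients
  list(coef = c(estimate = sm["delta_rho", "Estimate"],
                se = sm["delta_rho", "Std. Error"]),
       test = kr_f_test(m0, m1),
       r2 = lme_r2(m1),
       fit = m1)
}

#' Depth-by-factor interaction model with Type III Kenward-Roger tests
#'
#' For a two-level factor (functional contrast, or vein masking on/off) the
#' model z ~ depth + factor + depth:factor + (1|subject) is fitted with
#' sum-to-zero factor coding, and marginal (Type III) F-tests for each main
#' effect and the interaction are computed by Kenward-Roger comparisons
#' against the model dropping that term.
#'
#' @param data data.frame with columns `z`, `depth`, `level` (two-level
#'   factor), `subject`.
#' @return data.frame with `effect`, `F`, `df1`, `df2`, `p`.
#' @export
contrast_interaction_model <- function(data) {
  stopifnot(all(c("z", "depth", "level", "subject") %in% names(data)))
  data$level <- factor(data$level)
  if (nlevels(data$level) != 2L) stop("factor must have exactly 2 levels")
  tab <- table(data$subject, data$level)
  if (any(tab == 0L)) stop("both factor levels must be present for every subject")
  rng <- range(data$depth)
  data$d <- if (diff(rng) > 0) (data$depth - rng[1]) / diff(rng) - 0.5
            else data$depth
  # sum coding makes the dropped-term comparisons marginal (Type III)
  data$g <- ifelse(data$level == levels(data$level)[1], -0.5, 0.5)
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  full <- lme4::lmer(z ~ d + g + d:g + (1 | subject), data = data,
                     REML = TRUE, control = ctrl)
  drops <- list(depth = z ~ g + d:g + (1 | subject),
                level = z ~ d + d:g + (1 | subject),
                interaction = z ~ d + g + (1 | subject))
  rows <- lapply(names(drops), function(nm) {
    m <- lme4::lmer(drops[[nm]], data = data, REML = TRUE, control = ctrl)
    kr <- pbkrtest::KRmodcomp(full, m)$stats
    data.frame(effect = nm, F = kr$Fstat, df1 = kr$ndf, df2 = kr$ddf,
               p = kr$p.value)
  })
  do.call(rbind, rows)
}
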