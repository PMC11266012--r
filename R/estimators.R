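# Univariable two-sample MR estimators. All operate on a harmonized_set and
# return mr_result objects on the log-odds (beta) scale for binary outcomes;
# OR and its 95% CI are exp-transformed from beta +/- 1.96 se.

mr_result <- function(method, k, beta, se, pval, extra = list()) {
  stopifnot(se > 0 || is.na(se))
  structure(
    list(
      method = method, k = as.integer(k), beta = beta, se = se, pval = pval,
      or_ = exp(beta), ci_low = exp(beta - 1.96 * se),
      ci_high = exp(beta + 1.96 * se), extra = extra
    ),
    class = "mr_result"
  )
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf(
    "<mr_result> %s (k = %d): beta %.4f (se %.4f), OR %.3f [%.3f, %.3f], p = %.3g\n",
    x$method, x$k, x$beta, x$se, x$or_, x$ci_low, x$ci_high, x$pval
  ))
  invisible(x)
}

hset_vectors <- function(h) {
  stopifnot(inherits(h, "harmonized_set"))
  r <- h$records
  list(bx = r$beta_exp, sx = r$se_exp, by = r$beta_out, sy = r$se_out,
       k = nrow(r))
}

#' Wald ratio for a single instrument
#'
#' The per-SNP causal estimate beta_out / beta_exp with the first-order
#' delta-method standard error se_out / |beta_exp| (the exposure uncertainty
#' is ignored, which is standard for strong instruments). A second-order SE
#' that propagates se_exp is available via `second_order = TRUE`.
#'
#' @param beta_exp,se_exp Exposure association and its SE.
#' @param beta_out,se_out Outcome association and its SE.
#' @param second_order Add the exposure-uncertainty term
#'   `beta_out^2 se_exp^2 / beta_exp^4` to the variance.
#' @return An `mr_result` with `method = "wald"`.
#' @export
wald_ratio <- function(beta_exp, se_exp, beta_out, se_out,
                       second_order = FALSE) {
  if (beta_exp == 0) stop("Wald ratio undefined for beta_exp = 0")
  beta <- beta_out / beta_exp
  v <- se_out^2 / beta_exp^2
  if (second_order) v <- v + beta_out^2 * se_exp^2 / beta_exp^4
  se <- sqrt(v)
  p <- 2 * stats::pnorm(-abs(beta / se))
  mr_result("wald", 1L, beta, se, p)
}

#' Inverse-variance weighted (IVW) estimator
#'
#' Weighted regression of outcome on exposure effects through the origin
#' with weights 1/se_out^2; equivalently the inverse-variance meta-analysis
#' of per-SNP Wald ratios. The default multiplicative random-effects model
#' inflates the fixed-effects SE by `sqrt(Q / (k - 1))` whenever Cochran's Q
#' exceeds its degrees of freedom, and never deflates it. P-values use the
#' normal reference.
#'
#' @param h A `harmonized_set` with at least 2 instruments.
#' @param effects_model `"multiplicative_random"` (default) or `"fixed"`.
#' @return An `mr_result` with `method = "ivw"`; `extra` carries `Q`,
#'   `Q_df`, `Q_pval`, and `se_fixed`.
#' @export
mr_ivw <- function(h, effects_model = c("multiplicative_random", "fixed")) {
  effects_model <- match.arg(effects_model)
  v <- hset_vectors(h)
  if (v$k < 2L) {
    stop("IVW needs at least 2 instruments; use wald_ratio() for k = 1")
  }
  w <- 1 / v$sy^2
  denom <- sum(w * v$bx^2)
  beta <- sum(w * v$bx * v$by) / denom
  se_fixed <- 1 / sqrt(denom)
  Q <- sum(w * (v$by - beta * v$bx)^2)
  df <- v$k - 1L
  scale <- if (effects_model == "multiplicative_random") {
    max(1, sqrt(Q / df))
  } else 1
  se <- se_fixed * scale
  p <- 2 * stats::pnorm(-abs(beta / se))
  mr_result("ivw", v$k, beta, se, p,
            extra = list(Q = Q, Q_df = df,
                         Q_pval = stats::pchisq(Q, df, lower.tail = FALSE),
                         se_fixed = se_fixed,
                         effects_model = effects_model))
}

# Weighted least squares of by on bx with intercept, instruments oriented so
# bx >= 0. Returns coefficients, unscaled covariance, and the residual Q.
egger_fit <- function(bx, by, sy) {
  flip <- bx < 0
  bx[flip] <- -bx[flip]
  by[flip] <- -by[flip]
  w <- 1 / sy^2
  X <- cbind(intercept = 1, slope = bx)
  fit <- stats::lm.wfit(X, by, w)
  coefs <- fit$coefficients
  XtWX_inv <- chol2inv(chol(crossprod(X * sqrt(w))))
  Q <- sum(w * fit$residuals^2)
  list(intercept = unname(coefs[1]), slope = unname(coefs[2]),
       cov_unscaled = XtWX_inv, Q = Q)
}

#' MR-Egger regression
#'
#' Weighted linear regression of outcome on exposure effects with a free
#' intercept (weights 1/se_out^2), after orienting every instrument so its
#' exposure effect is non-negative. The slope estimates the causal effect
#' under the InSIDE assumption; a non-zero intercept indicates directional
#' horizontal pleiotropy. Standard errors are inflated by
#' `max(1, sqrt(Q_egger / (k - 2)))` and p-values use the t distribution
#' with k - 2 degrees of freedom, which is conservative at small k.
#'
#' @param h A `harmonized_set` with at least 3 instruments.
#' @return An `mr_result` with `method = "egger"`; `extra` carries
#'   `intercept`, `intercept_se`, `intercept_p`, `Q`, `Q_df`, `Q_pval`.
#' @export
mr_egger <- function(h) {
  v <- hset_vectors(h)
  if (v$k < 3L) stop("MR-Egger needs at least 3 instruments")
  fit <- egger_fit(v$bx, v$by, v$sy)
  df <- v$k - 2L
  scale <- max(1, sqrt(fit$Q / df))
  se_slope <- sqrt(fit$cov_unscaled[2, 2]) * scale
  se_int <- sqrt(fit$cov_unscaled[1, 1]) * scale
  p_slope <- 2 * stats::pt(-abs(fit$slope / se_slope), df)
  p_int <- 2 * stats::pt(-abs(fit$intercept / se_int), df)
  mr_result("egger", v$k, fit$slope, se_slope, p_slope,
            extra = list(intercept = fit$intercept, intercept_se = se_int,
                         intercept_p = p_int, Q = fit$Q, Q_df = df,
                         Q_pval = stats::pchisq(fit$Q, df,
                                                lower.tail = FALSE)))
}

# Weighted median of x with weights w (normalized internally): sort x, form
# cumulative mid-weights p_i = cumsum(w)_i - w_i/2, linearly interpolate x
# at p = 0.5.
weighted_median_point <- function(x, w) {
  ord <- order(x)
  x <- x[ord]
  w <- w[ord] / sum(w)
  p <- cumsum(w) - w / 2
  if (0.5 <= p[1]) return(x[1])
  if (0.5 >= p[length(p)]) return(x[length(x)])
  stats::approx(p, x, xout = 0.5, ties = "ordered")$y
}

# Parametric bootstrap SE shared by the median and mode estimators: redraw
# each beta from normal(beta, se), recompute the point estimate, take the SD.
bootstrap_se <- function(bx, sx, by, sy, point_fn, n_boot, seed) {
  if (n_boot < 2L) return(NA_real_)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  k <- length(bx)
  est <- vapply(seq_len(n_boot), function(b) {
    bxb <- stats::rnorm(k, bx, sx)
    byb <- stats::rnorm(k, by, sy)
    point_fn(bxb, byb)
  }, numeric(1))
  stats::sd(est)
}

#' Weighted median estimator
#'
#' The weighted median of per-SNP Wald ratios with weights proportional to
#' beta_exp^2 / se_out^2 (the inverse variance of each ratio, first order).
#' Consistent when instruments contributing at least half the weight are
#' valid. The standard error comes from a seeded parametric bootstrap:
#' exposure and outcome betas are redrawn from normal(beta, se), the
#' estimate recomputed, and the SD over replicates taken.
#'
#' @param h A `harmonized_set` with at least 3 instruments.
#' @param n_boot Bootstrap replicates for the SE (default 1000).
#' @param seed Seed for the bootstrap.
#' @return An `mr_result` with `method = "weighted_median"`.
#' @export
mr_weighted_median <- function(h, n_boot = 1000L, seed = 1L) {
  v <- hset_vectors(h)
  if (v$k < 3L) stop("weighted median needs at least 3 instruments")
  point <- function(bx, by) {
    weighted_median_point(by / bx, bx^2 / v$sy^2)
  }
  beta <- point(v$bx, v$by)
  se <- bootstrap_se(v$bx, v$sx, v$by, v$sy, point, n_boot, seed)
  p <- if (is.na(se)) NA_real_ else 2 * stats::pnorm(-abs(beta / se))
  mr_result("weighted_median", v$k, beta, if (is.na(se)) NA else se, p)
}

# Weighted Gaussian KDE argmax over a fixed grid; the mode-based estimator's
# point routine. Bandwidth: modified Silverman rule scaled by phi.
mode_point <- function(r, w, phi, grid_n = 512L) {
  w <- w / sum(w)
  s <- stats::sd(r)
  if (!is.finite(s) || s == 0) return(r[1])
  h <- phi * 0.9 * min(s, stats::IQR(r) / 1.349) * length(r)^(-1 / 5)
  if (h <= 0) h <- phi * 0.9 * s * length(r)^(-1 / 5)
  grid <- seq(mean(r) - 4 * s, mean(r) + 4 * s, length.out = grid_n)
  dens <- vapply(grid, function(g) sum(w * stats::dnorm(g, r, h)), numeric(1))
  grid[which.max(dens)]
}

#' Mode-based estimator (simple and weighted mode)
#'
#' The mode of the smoothed empirical density of per-SNP Wald ratios,
#' located as the argmax of a weighted Gaussian kernel density over a
#' 512-point grid spanning mean(ratio) +/- 4 SD. Weights are equal for the
#' simple mode and inverse-variance (beta_exp^2 / se_out^2) for the weighted
#' mode. Bandwidth is `phi * 0.9 * min(sd, IQR/1.349) * k^(-1/5)`.
#' Consistent when the largest group of instruments sharing a ratio value is
#' valid. SE by seeded parametric bootstrap, as for the weighted median.
#'
#' @param h A `harmonized_set` with at least 3 instruments.
#' @param weighted Use inverse-variance weights (`TRUE`) or equal weights.
#' @param phi Bandwidth multiplier (default 1).
#' @param n_boot Bootstrap replicates for the SE (default 1000).
#' @param seed Seed for the bootstrap.
#' @return An `mr_result` with `method` `"weighted_mode"` or
#'   `"simple_mode"`.
#' @export
mr_mode <- function(h, weighted = TRUE, phi = 1, n_boot = 1000L, seed = 1L) {
  v <- hset_vectors(h)
  if (v$k < 3L) stop("mode estimator needs at least 3 instruments")
  wts <- function(bx) if (weighted) bx^2 / v$sy^2 else rep(1, length(bx))
  point <- function(bx, by) {
    r <- by / bx
    if (max(r) - min(r) == 0) return(r[1])
    mode_point(r, wts(bx), phi)
  }
  beta <- point(v$bx, v$by)
  se <- bootstrap_se(v$bx, v$sx, v$by, v$sy, point, n_boot, seed)
  p <- if (is.na(se)) NA_real_ else 2 * stats::pnorm(-abs(beta / se))
  mr_result(if (weighted) "weighted_mode" else "simple_mode",
            v$k, beta, if (is.na(se)) NA else se, p)
}

#' Run the five-method univariable MR panel
#'
#' Applies IVW, MR-Egger, weighted median, simple mode, and weighted mode to
#' one harmonized exposure-outcome pair and flags whether all five causal
#' estimates share a sign (direction consistency, a common credibility
#' check). With only 2 instruments the panel degrades to IVW alone; with 1,
#' to the Wald ratio; both degradations are flagged.
#'
#' @param h A `harmonized_set`.
#' @param seed Seed for the bootstrap SEs of the median and mode methods.
#' @param n_boot Bootstrap replicates (default 1000).
#' @return A list: `results` (named list of `mr_result`),
#'   `direction_consistent` (logical; `NA` when fewer than five methods
#'   ran), `degraded` (logical).
#' @export
run_all_methods <- function(h, seed = 1L, n_boot = 1000L) {
  v <- hset_vectors(h)
  if (v$k == 0L) stop("empty harmonized set")
  if (v$k == 1L) {
    r <- h$records
    res <- list(wald = wald_ratio(r$beta_exp, r$se_exp, r$beta_out, r$se_out))
    return(list(results = res, direction_consistent = NA, degraded = TRUE))
  }
  if (v$k == 2L) {
    return(list(results = list(ivw = mr_ivw(h)),
                direction_consistent = NA, degraded = TRUE))
  }
  res <- list(
    ivw = mr_ivw(h),
    egger = mr_egger(h),
    weighted_median = mr_weighted_median(h, n_boot, seed),
    simple_mode = mr_mode(h, weighted = FALSE, n_boot = n_boot,
                          seed = seed + 1L),
    weighted_mode = mr_mode(h, weighted = TRUE, n_boot = n_boot,
                            seed = seed + 2L)
  )
  betas <- vapply(res, function(x) x$beta, numeric(1))
  list(results = res,
       direction_consistent = all(betas > 0) || all(betas < 0),
       degraded = FALSE)
}

#' Classify an IVW result as risk factor, protective factor, or null
#'
#' The screening rule for a binary outcome: a causal relationship is called
#' when the IVW p-value is below 0.05; OR > 1 labels the exposure a risk
#' factor and OR < 1 a protective factor. An IVW p-value between 0.04 and
#' 0.05 additionally triggers a leave-one-out sensitivity analysis
#' (`loo_required`).
#'
#' @param ivw_result An `mr_result` with `method = "ivw"`.
#' @return A list: `label` (`"risk_factor"`, `"protective_factor"`, or
#'   `"null"`), `loo_required`, and `basis` (the input result).
#' @export
classify_effect <- function(ivw_result) {
  stopifnot(inherits(ivw_result, "mr_result"))
  if (ivw_result$method != "ivw") {
    stop("classification is defined on the IVW result only")
  }
  label <- if (ivw_result$pval < 0.05) {
    if (ivw_result$or_ > 1) "risk_factor" else "protective_factor"
  } else "null"
  list(label = label,
       loo_required = ivw_result$pval > 0.04 && ivw_result$pval < 0.05,
       basis = ivw_result)
}

#' Flatten MR results to a data frame
#'
#' Tabular serialization of one or more `mr_result` objects, matching the
#' columns of a forest-plot table: exposure, outcome, method, nsnp, beta,
#' se, or, ci_low, ci_high, pval.
#'
#' @param results An `mr_result` or list of them.
#' @param exposure,outcome Trait labels for the leading columns.
#' @return A data frame, one row per result.
#' @export
mr_result_table <- function(results, exposure = NA_character_,
                            outcome = NA_character_) {
  if (inherits(results, "mr_result")) results <- list(results)
  do.call(rbind, lapply(results, function(x) {
    data.frame(
      exposure = exposure, outcome = outcome, method = x$method,
      nsnp = x$k, beta = x$beta, se = x$se, or = x$or_,
      ci_low = x$ci_low, ci_high = x$ci_high, pval = x$pval
    )
  }))
}
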