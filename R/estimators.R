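#' Construct an MR estimate
#'
#' @param method method label.
#' @param theta causal effect per 1 SD of the exposure (log-odds for a
#'   binary outcome).
#' @param se standard error (after any overdispersion scaling).
#' @param n_snps number of instruments used.
#' @param q_stat heterogeneity statistic (NA when not defined).
#' @param scale_factor multiplicative overdispersion applied to `se`
#'   (at least 1).
#' @param exposure_name exposure label.
#' @param outcome_scale `"sd_units"` or `"log_odds"`; governs odds-ratio
#'   reporting.
#' @param ci_low,ci_high optional explicit 95% CI (e.g. a profile-likelihood
#'   interval); defaults to the normal interval `theta +/- 1.959964 se`.
#' @param pval optional explicit p-value; defaults to the two-sided normal
#'   p from `theta/se`.
#' @return an object of class `mr_estimate`.
#' @export
mr_estimate <- function(method, theta, se, n_snps, q_stat = NA_real_,
                        scale_factor = 1, exposure_name = "exposure",
                        outcome_scale = "log_odds",
                        ci_low = NULL, ci_high = NULL, pval = NULL) {
  stopifnot(se >= 0, scale_factor >= 1 - 1e-12)
  est <- list(method = method, theta = theta, se = se,
              ci_low = ci_low %||% (theta - Z95 * se),
              ci_high = ci_high %||% (theta + Z95 * se),
              pval = pval %||% (if (se > 0) pval_from_z(theta / se) else
                                as.numeric(theta == 0)),
              n_snps = n_snps, q_stat = q_stat, scale_factor = scale_factor,
              exposure_name = exposure_name, outcome_scale = outcome_scale)
  class(est) <- "mr_estimate"
  est
}

#' @export
print.mr_estimate <- function(x, digits = 4, ...) {
  cat(x$method, " estimate (", x$exposure_name, ", ", x$n_snps, " SNPs): ",
      signif(x$theta, digits), " (95% CI ", signif(x$ci_low, digits), " to ",
      signif(x$ci_high, digits), "), p = ", format(x$pval, digits = 3),
      "\n", sep = "")
  if (identical(x$outcome_scale, "log_odds"))
    cat("  OR = ", signif(exp(x$theta), digits), " (", signif(exp(x$ci_low), digits),
        " to ", signif(exp(x$ci_high), digits), ")\n", sep = "")
  invisible(x)
}

#' Odds-ratio view of an MR estimate
#'
#' @param est an `mr_estimate` on the log-odds scale.
#' @return named vector `or`, `or_low`, `or_high`.
#' @export
as_or <- function(est) {
  c(or = exp(est$theta), or_low = exp(est$ci_low), or_high = exp(est$ci_high))
}

#' Flip the sign of an MR estimate
#'
#' Re-expresses an estimate per 1 SD *lower* exposure (mimicking
#' pharmacological inhibition of the target) by negating the effect and
#' mirroring the confidence interval.
#'
#' @param est an `mr_estimate`.
#' @return the re-oriented estimate.
#' @export
flip_sign <- function(est) {
  new_low <- -est$ci_high; new_high <- -est$ci_low
  est$theta <- -est$theta
  est$ci_low <- new_low
  est$ci_high <- new_high
  est
}

single_exposure <- function(h) {
  if (ncol(h$beta_exposure) != 1)
    stop("this estimator requires a single exposure; use mr_mvivw()")
  list(bx = h$beta_exposure[, 1], sx = h$se_exposure[, 1],
       by = h$beta_outcome, sy = h$se_outcome)
}

#' Per-variant ratio (Wald) estimates
#'
#' The building block of the median and contamination-mixture estimators:
#' `theta_j = beta_Yj / beta_Xj` with the first-order standard error
#' `se_Yj / |beta_Xj|` (uncertainty in the instrument-exposure association
#' is ignored, the usual approximation for strong instruments).
#'
#' @param h a single-exposure [harmonized_set].
#' @return data.frame with columns `variant_id`, `ratio`, `se_ratio`.
#' @export
ratio_estimates <- function(h) {
  d <- single_exposure(h)
  if (any(d$bx == 0)) stop("zero instrument-exposure association; ratio undefined")
  data.frame(variant_id = h$variant_ids, ratio = d$by / d$bx,
             se_ratio = d$sy / abs(d$bx), stringsAsFactors = FALSE)
}

#' Inverse-variance weighted estimator with multiplicative random effects
#'
#' Weighted least squares of the variant-outcome on the variant-exposure
#' associations through the origin, weights `1/se_Y^2`. The fixed-effect
#' standard error is inflated by `max(1, sqrt(Q/(J-1)))` - the
#' multiplicative random-effects model, which widens the interval under
#' heterogeneity but never narrows it. A single instrument gives the ratio
#' estimate with its fixed-effect standard error.
#'
#' @param h a single-exposure [harmonized_set].
#' @return an `mr_estimate` (method `"ivw_mre"`).
#' @export
mr_ivw <- function(h) {
  d <- single_exposure(h)
  if (all(d$bx == 0)) stop("irrelevant_instruments: all exposure betas are zero")
  w <- 1 / d$sy^2
  J <- length(d$bx)
  sxx <- sum(w * d$bx^2)
  theta <- sum(w * d$bx * d$by) / sxx
  se_fixed <- 1 / sqrt(sxx)
  Q <- sum(w * (d$by - theta * d$bx)^2)
  scale <- if (J >= 2) max(1, sqrt(Q / (J - 1))) else 1
  mr_estimate("ivw_mre", theta, se_fixed * scale, J, q_stat = Q,
              scale_factor = scale, exposure_name = h$exposure_names[1],
              outcome_scale = h$outcome_scale)
}

#' IVW estimator adjusted for correlated instruments
#'
#' Generalized least squares with outcome covariance `Omega = D rho D`,
#' where `rho` is the signed LD correlation matrix and `D = diag(se_Y)`.
#' Used when residual LD among cis instruments would otherwise understate
#' the uncertainty. The overdispersion scale uses the GLS residual form of
#' the heterogeneity statistic.
#'
#' @param h a single-exposure [harmonized_set] with `ld` attached.
#' @return an `mr_estimate` (method `"ivw_ld"`).
#' @export
mr_ivw_ld <- function(h) {
  if (is.null(h$ld)) stop("LD matrix required; attach one with set_ld()")
  d <- single_exposure(h)
  J <- length(d$bx)
  Omega <- diag(d$sy, J) %*% unclass(h$ld) %*% diag(d$sy, J)
  ch <- tryCatch(chol(Omega), error = function(e) NULL)
  if (is.null(ch) || min(diag(ch)) < 1e-8 * max(diag(ch)))
    stop("singular_ld: LD matrix is singular or near-singular")
  Oi <- chol2inv(ch)
  sxx <- as.numeric(t(d$bx) %*% Oi %*% d$bx)
  theta <- as.numeric(t(d$bx) %*% Oi %*% d$by) / sxx
  r <- d$by - theta * d$bx
  Q <- as.numeric(t(r) %*% Oi %*% r)
  scale <- if (J >= 2) max(1, sqrt(Q / (J - 1))) else 1
  mr_estimate("ivw_ld", theta, scale / sqrt(sxx), J, q_stat = Q,
              scale_factor = scale, exposure_name = h$exposure_names[1],
              outcome_scale = h$outcome_scale)
}

#' MR-Egger regression
#'
#' Weighted regression of the variant-outcome on the variant-exposure
#' associations *with* an intercept, after orienting every variant so its
#' exposure association is non-negative. The slope estimates the causal
#' effect under the InSIDE assumption; the intercept estimates directional
#' pleiotropy. Standard errors carry the multiplicative overdispersion
#' `max(1, sqrt(Q/(J-2)))`.
#'
#' @param h a single-exposure [harmonized_set] with at least 3 variants.
#' @return list with `mr_estimate` elements `slope` (method `"egger"`) and
#'   `intercept` (method `"egger_intercept"`).
#' @export
mr_egger <- function(h) {
  d <- single_exposure(h)
  J <- length(d$bx)
  if (J < 3) stop("Egger regression requires at least 3 instruments")
  neg <- d$bx < 0
  bx <- abs(d$bx)
  by <- ifelse(neg, -d$by, d$by)
  if (max(bx) - min(bx) < 1e-12 * max(bx, 1e-300))
    stop("unidentified: no variation in exposure associations")
  w <- 1 / d$sy^2
  X <- cbind(intercept = 1, slope = bx)
  XtWX <- crossprod(X, w * X)
  coef <- solve(XtWX, crossprod(X, w * by))
  covm <- solve(XtWX)
  res <- by - as.numeric(X %*% coef)
  Q <- sum(w * res^2)
  scale <- max(1, sqrt(Q / (J - 2)))
  mk <- function(i, method) {
    mr_estimate(method, coef[i], sqrt(covm[i, i]) * scale, J, q_stat = Q,
                scale_factor = scale, exposure_name = h$exposure_names[1],
                outcome_scale = h$outcome_scale)
  }
  list(slope = mk(2, "egger"), intercept = mk(1, "egger_intercept"))
}

# Weighted median of ratio estimates: sort, place each ratio at the centre
# of its weight band, interpolate the 50% point.
weighted_median_point <- function(ratio, weight) {
  o <- order(ratio)
  r <- ratio[o]
  w <- weight[o] / sum(weight)
  s <- cumsum(w) - w / 2
  stats::approx(s, r, xout = 0.5, rule = 2, ties = "ordered")$y
}

#' Weighted median estimator
#'
#' Consistent when at least half the weight lies on valid instruments.
#' The point estimate interpolates the weighted median of the per-variant
#' ratio estimates (weights inverse ratio variance); the standard error
#' comes from a seeded parametric bootstrap that resamples both the
#' exposure and outcome associations from normals with their reported
#' standard errors.
#'
#' @param h a single-exposure [harmonized_set] with at least 3 variants.
#' @param n_boot bootstrap draws (default 5000).
#' @param seed optional RNG seed for reproducibility.
#' @return an `mr_estimate` (method `"weighted_median"`).
#' @export
mr_weighted_median <- function(h, n_boot = 5000, seed = NULL) {
  d <- single_exposure(h)
  J <- length(d$bx)
  if (J < 3) stop("weighted median requires at least 3 instruments")
  re <- ratio_estimates(h)
  theta <- weighted_median_point(re$ratio, 1 / re$se_ratio^2)
  if (!is.null(seed)) set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(i) {
    bx <- stats::rnorm(J, d$bx, d$sx)
    by <- stats::rnorm(J, d$by, d$sy)
    bad <- bx == 0
    if (all(bad)) return(NA_real_)
    r <- by[!bad] / bx[!bad]
    weighted_median_point(r, (abs(bx[!bad]) / d$sy[!bad])^2)
  }, numeric(1))
  se <- stats::sd(boots, na.rm = TRUE)
  mr_estimate("weighted_median", theta, se, J,
              exposure_name = h$exposure_names[1],
              outcome_scale = h$outcome_scale)
}

#' Contamination mixture estimator
#'
#' Profiles a grid of candidate causal effects; at each candidate, every
#' variant is classified valid (ratio estimate drawn from
#' `N(theta, se_j^2)`) or invalid (drawn from `N(0, psi^2 + se_j^2)`),
#' whichever has the higher likelihood, and the profile log-likelihood sums
#' the winning terms. The estimate is the grid argmax; the 95% confidence
#' set collects grid points within `qchisq(0.95, 1)/2 = 1.920729` of the
#' maximum. When that set is not contiguous the enclosing hull is reported
#' and `multimodal` is flagged.
#'
#' @param h a single-exposure [harmonized_set] with at least 3 variants.
#' @param psi scale of invalid-instrument pleiotropy; defaults to 1.5 times
#'   the SD of the ratio estimates.
#' @param grid_halfwidth_se grid extension beyond the ratio range, in units
#'   of the largest ratio standard error (default 5).
#' @param grid_points number of grid points (default 1001).
#' @return an `mr_estimate` (method `"conmix"`) with extra elements
#'   `valid` (logical classification at the estimate), `psi` and
#'   `multimodal`.
#' @export
mr_conmix <- function(h, psi = NULL, grid_halfwidth_se = 5, grid_points = 1001) {
  d <- single_exposure(h)
  if (length(d$bx) < 3) stop("contamination mixture requires at least 3 instruments")
  re <- ratio_estimates(h)
  r <- re$ratio; s <- re$se_ratio
  if (is.null(psi)) psi <- 1.5 * stats::sd(r)
  if (!is.finite(psi) || psi <= 0) psi <- 1
  pad <- grid_halfwidth_se * max(s)
  lo <- min(r) - pad; hi <- max(r) + pad
  if (hi - lo < 1e-14) {  # degenerate: all ratios identical with zero spread
    est <- mr_estimate("conmix", r[1], 0, length(r), ci_low = r[1],
                       ci_high = r[1], pval = NA_real_,
                       exposure_name = h$exposure_names[1],
                       outcome_scale = h$outcome_scale)
    est$valid <- rep(TRUE, length(r)); est$psi <- psi; est$multimodal <- FALSE
    return(est)
  }
  grid <- seq(lo, hi, length.out = grid_points)
  s_inv <- sqrt(psi^2 + s^2)
  ll_invalid <- stats::dnorm(r, 0, s_inv, log = TRUE)
  ll_valid <- stats::dnorm(matrix(r, length(r), grid_points),
                           matrix(grid, length(r), grid_points, byrow = TRUE),
                           matrix(s, length(r), grid_points), log = TRUE)
  prof <- colSums(pmax(ll_valid, ll_invalid))
  best <- which.max(prof)
  theta <- grid[best]
  inset <- prof >= prof[best] - 1.920729
  idx <- which(inset)
  ci_low <- grid[min(idx)]; ci_high <- grid[max(idx)]
  multimodal <- any(diff(idx) > 1)
  se <- (ci_high - ci_low) / (2 * Z95)
  est <- mr_estimate("conmix", theta, se, length(r), ci_low = ci_low,
                     ci_high = ci_high, exposure_name = h$exposure_names[1],
                     outcome_scale = h$outcome_scale)
  est$valid <- ll_valid[, best] >= ll_invalid
  est$psi <- psi
  est$multimodal <- multimodal
  est
}

# Leave-one-out IVW point estimates (fixed-effect), one per variant, for
# observed or simulated outcome associations (columns of `by_mat`).
loo_theta <- function(bx, by_mat, w) {
  sxx <- sum(w * bx^2)
  sxy <- colSums(w * bx * by_mat)
  num <- matrix(sxy, nrow = length(bx), ncol = ncol(by_mat), byrow = TRUE) -
    w * bx * by_mat
  num / (sxx - w * bx^2)
}

#' MR-PRESSO global heterogeneity and outlier test
#'
#' The global test compares the observed weighted residual sum of squares
#' (each variant measured against the IVW estimate that leaves it out) with
#' its parametric null distribution, simulated by redrawing outcome
#' associations from `N(theta_loo_j * beta_Xj, se_Yj^2)` and recomputing the
#' statistic. Each variant's residual term gets a simulated p-value,
#' Bonferroni-corrected across variants; flagged outliers are removed and
#' the IVW estimate recomputed.
#'
#' @param h a single-exposure [harmonized_set] with at least 4 variants.
#' @param n_sim simulated null datasets (default 1000).
#' @param outlier_alpha familywise outlier significance level (default 0.05).
#' @param seed optional RNG seed.
#' @return list with `global_p`, logical `outlier_flags` (named by variant),
#'   `rss_obs` and `corrected` (an `mr_estimate`, method
#'   `"presso_corrected"`).
#' @export
mr_presso <- function(h, n_sim = 1000, outlier_alpha = 0.05, seed = NULL) {
  d <- single_exposure(h)
  J <- length(d$bx)
  if (J < 4) stop("MR-PRESSO requires at least 4 instruments")
  if (!is.null(seed)) set.seed(seed)
  w <- 1 / d$sy^2
  th_loo <- loo_theta(d$bx, matrix(d$by, J, 1), w)[, 1]
  obs_terms <- w * (d$by - th_loo * d$bx)^2
  rss_obs <- sum(obs_terms)
  mu <- th_loo * d$bx
  ystar <- matrix(stats::rnorm(J * n_sim, mu, d$sy), J, n_sim)
  th_star <- loo_theta(d$bx, ystar, w)
  sim_terms <- w * (ystar - th_star * d$bx)^2
  rss_sim <- colSums(sim_terms)
  global_p <- mean(rss_sim >= rss_obs)
  p_out <- (rowSums(sim_terms >= obs_terms) + 1) / (n_sim + 1)
  flags <- stats::setNames(p_out < outlier_alpha / J, h$variant_ids)
  if (all(flags)) stop("no_instruments_remain: every variant flagged as outlier")
  keep <- !flags
  h_kept <- harmonized_set(h$beta_exposure[keep, , drop = FALSE],
                           h$se_exposure[keep, , drop = FALSE],
                           d$by[keep], d$sy[keep],
                           variant_ids = h$variant_ids[keep],
                           exposure_names = h$exposure_names,
                           outcome_name = h$outcome_name,
                           outcome_scale = h$outcome_scale)
  corrected <- mr_ivw(h_kept)
  corrected$method <- "presso_corrected"
  list(global_p = global_p, outlier_flags = flags, rss_obs = rss_obs,
       corrected = corrected)
}

#' Multivariable IVW estimator
#'
#' Weighted least squares of the variant-outcome associations on the matrix
#' of variant-exposure associations (no intercept), weights `1/se_Y^2`.
#' Each coefficient is the direct effect of its exposure conditional on the
#' others; standard errors carry the overdispersion scale
#' `max(1, sqrt(Q/(J-k)))`.
#'
#' @param h a [harmonized_set] with `k >= 1` exposures and `J > k` variants.
#' @return list of `mr_estimate` objects (method `"mvmr_ivw"`), one per
#'   exposure, in column order.
#' @export
mr_mvivw <- function(h) {
  X <- h$beta_exposure
  k <- ncol(X); J <- nrow(X)
  if (J <= k) stop("more instruments than exposures required")
  w <- 1 / h$se_outcome^2
  XtWX <- crossprod(X, w * X)
  if (rcond(XtWX) < 1e-12) stop("collinear_exposures")
  coef <- solve(XtWX, crossprod(X, w * h$beta_outcome))
  covm <- solve(XtWX)
  res <- h$beta_outcome - as.numeric(X %*% coef)
  Q <- sum(w * res^2)
  scale <- if (J > k) max(1, sqrt(Q / (J - k))) else 1
  lapply(seq_len(k), function(i) {
    mr_estimate("mvmr_ivw", coef[i], sqrt(covm[i, i]) * scale, J, q_stat = Q,
                scale_factor = scale, exposure_name = h$exposure_names[i],
                outcome_scale = h$outcome_scale)
  })
}
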