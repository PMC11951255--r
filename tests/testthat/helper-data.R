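# Builders for small summary-statistic fixtures and independent
# weighted-least-squares oracles used across the suite.

make_records <- function(id, beta, se, chrom = "1", pos = seq_along(id) * 1000,
                         ea = "A", oa = "G", eaf = 0.3, pval = NA_real_,
                         n = 10000) {
  data.frame(variant_id = id, chrom = chrom, pos = pos, effect_allele = ea,
             other_allele = oa, eaf = eaf, beta = beta, se = se, pval = pval,
             n = n, stringsAsFactors = FALSE)
}

toy_sumstats <- function(..., trait_name = "trait",
                         trait_scale = "sd_units") {
  sumstats(make_records(...), trait_name = trait_name,
           trait_scale = trait_scale)
}

toy_h <- function(bx, by, sy, sx = rep(0.01, length(bx)), ...) {
  harmonized_set(bx, sx, by, sy, ...)
}

# Oracle: weighted regression through the origin via stats::lm. The
# fixed-design standard error is recovered by dividing out lm's residual
# scale; the heterogeneity statistic is the weighted RSS.
oracle_wls_origin <- function(bx, by, w) {
  fit <- stats::lm(by ~ bx - 1, weights = w)
  s <- summary(fit)
  sigma <- s$sigma
  list(theta = unname(stats::coef(fit)[1]),
       se_fixed = unname(s$coefficients[1, 2]) / sigma,
       Q = sum(w * stats::resid(fit)^2))
}

oracle_wls_intercept <- function(bx, by, w) {
  fit <- stats::lm(by ~ bx, weights = w)
  s <- summary(fit)
  sigma <- s$sigma
  list(intercept = unname(stats::coef(fit)[1]),
       slope = unname(stats::coef(fit)[2]),
       se_intercept_fixed = unname(s$coefficients[1, 2]) / sigma,
       se_slope_fixed = unname(s$coefficients[2, 2]) / sigma,
       Q = sum(w * stats::resid(fit)^2))
}

oracle_wls_multi <- function(X, by, w) {
  fit <- stats::lm(by ~ X - 1, weights = w)
  s <- summary(fit)
  list(coef = unname(stats::coef(fit)),
       se_fixed = unname(s$coefficients[, 2]) / s$sigma,
       Q = sum(w * stats::resid(fit)^2))
}

# A small harmonized set with consistent data: every ratio equals theta0.
consistent_h <- function(theta0, J = 6, seed = 1) {
  set.seed(seed)
  bx <- stats::runif(J, 0.05, 0.3)
  toy_h(bx, theta0 * bx, sy = stats::runif(J, 0.005, 0.02))
}

random_h <- function(J, seed, sx_scale = 0.01) {
  set.seed(seed)
  bx <- stats::rnorm(J, 0, 0.2)
  bx[abs(bx) < 0.02] <- 0.05
  toy_h(bx, stats::rnorm(J, 0.2 * bx, 0.05),
        sy = stats::runif(J, 0.01, 0.1),
        sx = rep(sx_scale, J))
}
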