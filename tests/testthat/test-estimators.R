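test_that("IVW reproduces hand-computed and single-instrument cases", {
  # single variant: ratio estimate with first-order se
  h1 <- toy_h(0.5, 0.25, sy = 0.1)
  e1 <- mr_ivw(h1)
  expect_equal(e1$theta, 0.5)
  expect_equal(e1$se, 0.2)
  expect_equal(e1$scale_factor, 1)

  # two variants, hand-run WLS through the origin
  h2 <- toy_h(c(1, 1), c(0.1, 0.3), sy = c(0.1, 0.1))
  e2 <- mr_ivw(h2)
  expect_equal(e2$theta, 0.2)
  expect_equal(e2$q_stat, 2)
  expect_equal(e2$scale_factor, sqrt(2))
  expect_equal(e2$se, sqrt(1 / 200) * sqrt(2))  # = 0.1

  expect_error(mr_ivw(toy_h(c(0, 0), c(0.1, 0.2), sy = c(0.1, 0.1))),
               "irrelevant_instruments")
})

test_that("IVW and Egger match the lm weighted-regression oracle", {
  for (seed in 1:25) {
    h <- random_h(J = sample(5:50, 1), seed = seed)
    w <- 1 / h$se_outcome^2
    bx <- h$beta_exposure[, 1]

    o <- oracle_wls_origin(bx, h$beta_outcome, w)
    e <- mr_ivw(h)
    expect_equal(e$theta, o$theta, tolerance = 1e-12)
    expect_equal(e$q_stat, o$Q, tolerance = 1e-10)
    expect_equal(e$se, o$se_fixed * max(1, sqrt(o$Q / (e$n_snps - 1))),
                 tolerance = 1e-12)

    # Egger after orienting exposure betas positive
    flip <- bx < 0
    bxo <- abs(bx); byo <- ifelse(flip, -h$beta_outcome, h$beta_outcome)
    oe <- oracle_wls_intercept(bxo, byo, w)
    eg <- mr_egger(h)
    scale <- max(1, sqrt(oe$Q / (e$n_snps - 2)))
    expect_equal(eg$slope$theta, oe$slope, tolerance = 1e-10)
    expect_equal(eg$intercept$theta, oe$intercept, tolerance = 1e-10)
    expect_equal(eg$slope$se, oe$se_slope_fixed * scale, tolerance = 1e-10)
    expect_equal(eg$intercept$se, oe$se_intercept_fixed * scale,
                 tolerance = 1e-10)
  }
})

test_that("Egger recovers an exact linear law and rejects degenerate designs", {
  bx <- c(0.1, 0.2, 0.3, 0.4)
  h <- toy_h(bx, 0.05 + 0.4 * bx, sy = rep(0.01, 4))
  eg <- mr_egger(h)
  expect_equal(eg$slope$theta, 0.4, tolerance = 1e-12)
  expect_equal(eg$intercept$theta, 0.05, tolerance = 1e-12)
  expect_equal(eg$slope$q_stat, 0, tolerance = 1e-20)
  expect_equal(eg$slope$scale_factor, 1)

  expect_error(mr_egger(toy_h(c(0.2, 0.2, 0.2), c(0.1, 0.1, 0.2),
                              sy = rep(0.1, 3))), "unidentified")
  # sign orientation: negating a variant's exposure and outcome is a no-op
  h_neg <- toy_h(c(-0.1, 0.2, 0.3, 0.4), c(-0.09, 0.13, 0.17, 0.21),
                 sy = rep(0.01, 4))
  h_pos <- toy_h(c(0.1, 0.2, 0.3, 0.4), c(0.09, 0.13, 0.17, 0.21),
                 sy = rep(0.01, 4))
  expect_equal(mr_egger(h_neg)$slope$theta, mr_egger(h_pos)$slope$theta)
})

test_that("LD-adjusted IVW reduces to IVW under identity and rejects singular LD", {
  h <- random_h(10, seed = 3)
  h_id <- set_ld(h, ld_matrix(diag(10), h$variant_ids))
  plain <- mr_ivw(h)
  gls <- mr_ivw_ld(h_id)
  expect_equal(gls$theta, plain$theta, tolerance = 1e-12)
  expect_equal(gls$se, plain$se, tolerance = 1e-12)
  expect_equal(gls$q_stat, plain$q_stat, tolerance = 1e-10)

  # duplicated variant (r = 1) is a fatal singularity, not a pseudo-inverse
  r <- diag(10); r[1, 2] <- r[2, 1] <- 1
  h_dup <- h
  h_dup$ld <- structure(r, dimnames = list(h$variant_ids, h$variant_ids),
                        class = c("ld_matrix", "matrix"))
  expect_error(mr_ivw_ld(h_dup), "singular_ld")
})

test_that("LD-adjusted IVW is unbiased under AR(1)-correlated instruments", {
  set.seed(14)
  theta0 <- -0.2
  J <- 10
  ld <- simulate_ld(J, 0.5, paste0("v", 1:J))
  ch <- chol(unclass(ld))
  ests <- replicate(400, {
    bx <- runif(J, 0.05, 0.15)
    sy <- rep(0.02, J)
    noise <- as.numeric(crossprod(ch, rnorm(J))) * sy
    h <- toy_h(bx, theta0 * bx + noise, sy = sy,
               variant_ids = paste0("v", 1:J))
    mr_ivw_ld(set_ld(h, ld))$theta
  })
  expect_lt(abs(mean(ests) - theta0), 0.01)
})

test_that("weighted median interpolates the 50% weight point", {
  # exact hit: cumulative positions 1/6, 1/2, 5/6
  h <- toy_h(c(1, 1, 1), c(0.1, 0.2, 0.6), sy = c(1, 1, 1))
  expect_equal(mr_weighted_median(h, n_boot = 50, seed = 1)$theta, 0.2)

  # interpolation between 0.25 and 0.75 positions
  # two equally weighted ratios sit at positions 0.25 and 0.75, so the
  # median interpolates halfway between them
  expect_equal(cismr:::weighted_median_point(c(0.1, 0.3), c(1, 1)), 0.2)

  # reproducible bootstrap se
  h2 <- random_h(12, seed = 5)
  m1 <- mr_weighted_median(h2, n_boot = 300, seed = 9)
  m2 <- mr_weighted_median(h2, n_boot = 300, seed = 9)
  expect_equal(m1$se, m2$se)
  expect_gt(m1$se, 0)
})

test_that("weighted median resists up to half the weight being invalid", {
  set.seed(21)
  theta0 <- 0.25
  wins <- replicate(60, {
    J <- 11
    bx <- runif(J, 0.08, 0.15)
    sy <- rep(0.01, J)
    pleio <- c(rep(0.4, 5), rep(0, 6))  # 45% of weight invalid, large offset
    by <- theta0 * bx + pleio + rnorm(J, 0, sy)
    h <- toy_h(bx, by, sy = sy, sx = rep(0.002, J))
    med <- mr_weighted_median(h, n_boot = 200, seed = 2)
    ivw <- mr_ivw(h)
    c(med_err = abs(med$theta - theta0), ivw_err = abs(ivw$theta - theta0),
      med_cover = abs(med$theta - theta0) < 2 * med$se)
  })
  expect_gt(mean(wins["med_cover", ]), 0.9)
  expect_lt(mean(wins["med_err", ]), mean(wins["ivw_err", ]))
})

test_that("contamination mixture matches the exhaustive assignment search", {
  set.seed(31)
  J <- 7
  ratio <- c(0.29, 0.31, 0.30, 0.28, 1.5, 1.52, 0.32)
  se_r <- rep(0.05, J)
  bx <- rep(1, J)
  h <- toy_h(bx, ratio, sy = se_r)
  psi <- 0.6
  cm <- mr_conmix(h, psi = psi)

  # oracle: maximize over all 2^J valid/invalid assignments; for a fixed
  # assignment the optimal theta is the precision-weighted mean of the
  # valid ratios
  best <- -Inf; best_theta <- NA
  for (mask in 0:(2^J - 1)) {
    valid <- as.logical(bitwAnd(mask, 2^(0:(J - 1))))
    if (!any(valid)) next
    th <- sum(ratio[valid] / se_r[valid]^2) / sum(1 / se_r[valid]^2)
    ll <- sum(dnorm(ratio[valid], th, se_r[valid], log = TRUE)) +
      sum(dnorm(ratio[!valid], 0, sqrt(psi^2 + se_r[!valid]^2), log = TRUE))
    if (ll > best) { best <- ll; best_theta <- th }
  }
  grid_step <- (max(ratio) - min(ratio) + 10 * max(se_r)) / 1000
  expect_equal(cm$theta, best_theta, tolerance = 2 * grid_step)
  expect_equal(unname(cm$valid), ratio < 1)  # the three outliers invalid

  # psi -> infinity: everything classified valid, IVW-like consensus.
  # (checked on an instance with moderate spread so the limit is reachable
  # at a finite psi)
  r_mild <- c(0.25, 0.3, 0.35, 0.4, 0.45)
  h_mild <- toy_h(rep(1, 5), r_mild, sy = rep(0.1, 5))
  cm_inf <- mr_conmix(h_mild, psi = 1e4)
  expect_true(all(cm_inf$valid))
  consensus <- mean(r_mild)  # equal weights
  step_mild <- (max(r_mild) - min(r_mild) + 10 * 0.1) / 1000
  expect_equal(cm_inf$theta, consensus, tolerance = 2 * step_mild)

  # consensus case: tight CI around the shared ratio
  h_c <- toy_h(rep(1, 10), rep(0.3, 10), sy = rep(0.01, 10))
  cm_c <- mr_conmix(h_c)
  expect_equal(cm_c$theta, 0.3, tolerance = 1e-3)
  expect_true(cm_c$ci_low <= 0.3 && cm_c$ci_high >= 0.3)
  expect_lt(cm_c$ci_high - cm_c$ci_low, 0.05)
})

test_that("MR-PRESSO flags a planted outlier and is seed-deterministic", {
  set.seed(17)
  J <- 8
  bx <- runif(J, 0.08, 0.15)
  sy <- rep(0.01, J)
  by <- 0.2 * bx + rnorm(J, 0, sy)
  by[3] <- by[3] + 10 * sy[3]
  h <- toy_h(bx, by, sy = sy, variant_ids = paste0("v", 1:J))

  p1 <- mr_presso(h, n_sim = 500, seed = 11)
  p2 <- mr_presso(h, n_sim = 500, seed = 11)
  expect_identical(p1$global_p, p2$global_p)
  expect_identical(p1$outlier_flags, p2$outlier_flags)

  expect_true(p1$outlier_flags[["v3"]])
  expect_lt(p1$global_p, 0.05)
  truth <- 0.2
  expect_lt(abs(p1$corrected$theta - truth), abs(mr_ivw(h)$theta - truth))
  expect_equal(p1$corrected$method, "presso_corrected")
})

test_that("multivariable IVW reduces to IVW and decomposes orthogonal blocks", {
  h <- random_h(12, seed = 6)
  mv <- mr_mvivw(h)
  uv <- mr_ivw(h)
  expect_equal(mv[[1]]$theta, uv$theta, tolerance = 1e-12)
  expect_equal(mv[[1]]$se, uv$se, tolerance = 1e-12)

  # orthogonal instrument blocks: each coefficient equals its block's IVW
  set.seed(23)
  J1 <- 6; J2 <- 6
  b1 <- runif(J1, 0.08, 0.2); b2 <- runif(J2, 0.08, 0.2)
  sy <- rep(0.02, J1 + J2)
  X <- rbind(cbind(b1, 0), cbind(0, b2))
  by <- as.numeric(X %*% c(0.3, -0.1)) + rnorm(J1 + J2, 0, sy)
  h2 <- harmonized_set(X, matrix(0.01, J1 + J2, 2), by, sy,
                       exposure_names = c("e1", "e2"))
  mv2 <- mr_mvivw(h2)
  ivw1 <- mr_ivw(toy_h(b1, by[1:J1], sy = sy[1:J1]))
  ivw2 <- mr_ivw(toy_h(b2, by[J1 + 1:J2], sy = sy[J1 + 1:J2]))
  expect_equal(mv2[[1]]$theta, ivw1$theta, tolerance = 1e-8)
  expect_equal(mv2[[2]]$theta, ivw2$theta, tolerance = 1e-8)

  o <- oracle_wls_multi(X, by, 1 / sy^2)
  expect_equal(c(mv2[[1]]$theta, mv2[[2]]$theta), o$coef, tolerance = 1e-12)

  expect_error(mr_mvivw(harmonized_set(cbind(b1, 2 * b1),
                                       matrix(0.01, J1, 2), by[1:J1],
                                       sy[1:J1])),
               "collinear_exposures")
})

test_that("multivariable IVW attributes outcome signal to the causal mediator", {
  # outcome depends only on the mediator; the correlated exposure's
  # coefficient should vanish
  set.seed(29)
  gamma <- 0.3
  bias <- replicate(300, {
    J <- 30
    bm <- rnorm(J, 0, 0.1)
    bx <- 0.8 * bm + rnorm(J, 0, 0.05)  # correlated exposure
    sy <- rep(0.02, J)
    by <- gamma * bm + rnorm(J, 0, sy)
    h <- harmonized_set(cbind(x = bx, m = bm), matrix(0.01, J, 2), by, sy,
                        exposure_names = c("x", "m"))
    mv <- mr_mvivw(h)
    c(x = mv[[1]]$theta, m = mv[[2]]$theta)
  })
  expect_lt(abs(mean(bias["x", ])), 0.02)
  expect_lt(abs(mean(bias["m", ]) - gamma), 0.02)
})

test_that("all estimators agree exactly on consistent noiseless data", {
  theta0 <- -0.3
  h <- consistent_h(theta0, J = 8)
  expect_equal(mr_ivw(h)$theta, theta0, tolerance = 1e-12)
  expect_equal(mr_ivw(h)$q_stat, 0, tolerance = 1e-20)
  expect_equal(mr_ivw(h)$scale_factor, 1)
  eg <- mr_egger(h)
  expect_equal(eg$slope$theta, theta0, tolerance = 1e-10)
  expect_equal(eg$intercept$theta, 0, tolerance = 1e-10)
  expect_equal(mr_weighted_median(h, n_boot = 50, seed = 1)$theta, theta0)
  expect_equal(mr_conmix(h)$theta, theta0, tolerance = 1e-3)
  expect_equal(mr_mvivw(h)[[1]]$theta, theta0, tolerance = 1e-12)
  h_ld <- set_ld(h, ld_matrix(diag(8), h$variant_ids))
  expect_equal(mr_ivw_ld(h_ld)$theta, theta0, tolerance = 1e-12)
})

test_that("multiplicative random effects never shrink the interval", {
  for (seed in 1:20) {
    h <- random_h(sample(3:30, 1), seed = 100 + seed)
    e <- mr_ivw(h)
    se_fixed <- 1 / sqrt(sum(h$beta_exposure[, 1]^2 / h$se_outcome^2))
    expect_gte(e$se, se_fixed - 1e-15)
    expect_gte(e$scale_factor, 1)
    # odds-ratio transform is monotone
    expect_lt(exp(e$ci_low), exp(e$ci_high))
  }
})
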