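theta_of <- function(x) if (inherits(x, "mr_estimate")) x$theta else as.numeric(x)
se_of <- function(x) if (inherits(x, "mr_estimate")) x$se else 0

#' Indirect (mediated) effect by the product of coefficients
#'
#' The exposure-to-outcome path through the mediator: the exposure's effect
#' on the mediator multiplied by the mediator's total effect on the outcome.
#'
#' @param theta_xm exposure-to-mediator estimate (`mr_estimate` or numeric),
#'   SD mediator per SD exposure.
#' @param theta_my mediator-to-outcome estimate, log-odds (or SD) per SD
#'   mediator, from genome-wide two-sample MR.
#' @return the indirect effect (numeric).
#' @export
indirect_product <- function(theta_xm, theta_my) {
  theta_of(theta_xm) * theta_of(theta_my)
}

#' Direct effect by the difference of coefficients
#'
#' @param theta_total total exposure-to-outcome estimate (`mr_estimate` or
#'   numeric).
#' @param indirect indirect effect from [indirect_product()].
#' @return `total - indirect`; by construction
#'   `direct + indirect = total` exactly.
#' @export
direct_difference <- function(theta_total, indirect) {
  theta_of(theta_total) - indirect
}

#' Proportion of the total effect that is mediated
#'
#' `indirect / total` on the estimation scale (log-odds for a binary
#' outcome). Sampling variation can push the proportion outside `[0, 1]`;
#' such values are returned as-is. Opposite signs of the indirect and total
#' effects are flagged with attribute `inconsistent_mediation`.
#'
#' @param total,indirect effect estimates (`mr_estimate` or numeric).
#' @return the proportion mediated (numeric scalar).
#' @export
proportion_mediated <- function(total, indirect) {
  tot <- theta_of(total); ind <- theta_of(indirect)
  if (tot == 0) stop("undefined_proportion: total effect is zero")
  p <- ind / tot
  if (ind != 0 && sign(ind) != sign(tot))
    attr(p, "inconsistent_mediation") <- TRUE
  p
}

#' Variant-level mediator-adjusted MR estimate
#'
#' The two-step cis-MR "adjusted" estimate: each instrument's outcome
#' association is decomposed into the path through the mediator and the
#' residual direct path, `beta_Yj' = beta_Yj - theta_MY * beta_Mj`, with the
#' uncertainty in `theta_MY` propagated into
#' `se_j' = sqrt(se_Yj^2 + beta_Mj^2 se_thetaMY^2)`. IVW on the adjusted
#' associations estimates the direct effect of the exposure on the outcome.
#'
#' @param cis_set a [harmonized_set] carrying `beta_mediator`/`se_mediator`
#'   for every instrument (see [harmonize_mediation()]).
#' @param theta_my mediator-to-outcome `mr_estimate` (its `se` is used for
#'   error propagation; a bare numeric is treated as exact).
#' @return an `mr_estimate` (method `"ivw_adjusted"`).
#' @export
adjusted_outcome_mr <- function(cis_set, theta_my) {
  bm <- cis_set$beta_mediator
  if (is.null(bm))
    stop("missing mediator association for instruments: ",
         paste(cis_set$variant_ids, collapse = ", "))
  if (anyNA(bm))
    stop("missing mediator association for instruments: ",
         paste(cis_set$variant_ids[is.na(bm)], collapse = ", "))
  tm <- theta_of(theta_my); sm <- se_of(theta_my)
  h <- cis_set
  h$beta_outcome <- cis_set$beta_outcome - tm * bm
  h$se_outcome <- sqrt(cis_set$se_outcome^2 + bm^2 * sm^2)
  est <- mr_ivw(h)
  est$method <- "ivw_adjusted"
  est
}

#' Assemble the inputs of a two-step mediation decomposition
#'
#' @param theta_total cis-MR exposure-to-outcome estimate.
#' @param theta_xm cis-MR exposure-to-mediator estimate (same instruments).
#' @param theta_my genome-wide MR mediator-to-outcome estimate.
#' @param cis_set optional [harmonized_set] with per-variant mediator
#'   associations, enabling the variant-level adjusted estimate.
#' @return an object of class `mediation_inputs`.
#' @export
mediation_inputs <- function(theta_total, theta_xm, theta_my, cis_set = NULL) {
  structure(list(theta_total = theta_total, theta_xm = theta_xm,
                 theta_my = theta_my, cis_set = cis_set),
            class = "mediation_inputs")
}

#' Two-step mediation decomposition with parametric bootstrap
#'
#' Point decomposition: `indirect = theta_XM * theta_MY`,
#' `direct = theta_total - indirect`, `proportion = indirect / theta_total`.
#' Uncertainty comes from a parametric bootstrap that redraws the three
#' component estimates independently from normals centred at their point
#' estimates with their standard errors (the two-sample design motivates
#' independence), recomputing every quantity per draw. Confidence intervals
#' are percentile (2.5%/97.5%); standard errors are draw standard
#' deviations. Proportion draws whose total effect falls within
#' `total_guard` of zero are rejected (the ratio explodes there) and
#' counted; more than 1% rejections triggers a warning.
#'
#' @param inputs a [mediation_inputs].
#' @param n_boot bootstrap draws (default one million).
#' @param seed optional RNG seed.
#' @param total_guard rejection guard on `|theta_total*|` (default 1e-6).
#' @return an object of class `mediation_result` with elements `total`,
#'   `indirect_product`, `direct_difference`, `proportion_mediated`,
#'   `direct_variant_level` (when `cis_set` permits), per-quantity `se` and
#'   `ci`, `n_boot`, `seed` and `guard_rejections`.
#' @export
bootstrap_mediation <- function(inputs, n_boot = 1e6, seed = NULL,
                                total_guard = 1e-6) {
  if (!is.null(seed)) set.seed(seed)
  tT <- theta_of(inputs$theta_total); sT <- se_of(inputs$theta_total)
  tX <- theta_of(inputs$theta_xm);    sX <- se_of(inputs$theta_xm)
  tM <- theta_of(inputs$theta_my);    sM <- se_of(inputs$theta_my)
  ind <- indirect_product(tX, tM)
  dir <- direct_difference(tT, ind)
  prop <- proportion_mediated(tT, ind)

  dT <- stats::rnorm(n_boot, tT, sT)
  dX <- stats::rnorm(n_boot, tX, sX)
  dM <- stats::rnorm(n_boot, tM, sM)
  d_ind <- dX * dM
  d_dir <- dT - d_ind
  ok <- abs(dT) > total_guard
  rejections <- sum(!ok)
  d_prop <- d_ind[ok] / dT[ok]
  if (rejections > 0.01 * n_boot)
    warning("unstable_proportion_ci: ", rejections, " of ", n_boot,
            " bootstrap draws had a total effect within the guard of zero")
  qci <- function(x) unname(stats::quantile(x, c(0.025, 0.975), names = FALSE))
  res <- list(
    total = tT, indirect_product = ind, direct_difference = dir,
    proportion_mediated = as.numeric(prop),
    se = c(total = sT, indirect = stats::sd(d_ind), direct = stats::sd(d_dir),
           proportion = stats::sd(d_prop)),
    ci = list(total = qci(dT), indirect = qci(d_ind), direct = qci(d_dir),
              proportion = qci(d_prop)),
    n_boot = n_boot, seed = seed, guard_rejections = rejections)
  if (!is.null(inputs$cis_set) && !is.null(inputs$cis_set$beta_mediator))
    res$direct_variant_level <- adjusted_outcome_mr(inputs$cis_set,
                                                    inputs$theta_my)
  if (isTRUE(attr(prop, "inconsistent_mediation")))
    res$inconsistent_mediation <- TRUE
  class(res) <- "mediation_result"
  res
}

#' @export
print.mediation_result <- function(x, digits = 3, ...) {
  cat("Two-step mediation decomposition (", x$n_boot, " bootstrap draws)\n",
      sep = "")
  row <- function(name, est, ci)
    cat(sprintf("  %-22s %8s  [%s, %s]\n", name, signif(est, digits),
                signif(ci[1], digits), signif(ci[2], digits)))
  row("total", x$total, x$ci$total)
  row("indirect (product)", x$indirect_product, x$ci$indirect)
  row("direct (difference)", x$direct_difference, x$ci$direct)
  row("proportion mediated", x$proportion_mediated, x$ci$proportion)
  if (!is.null(x$direct_variant_level))
    cat("  variant-level adjusted estimate: ",
        signif(x$direct_variant_level$theta, digits), "\n", sep = "")
  if (x$guard_rejections > 0)
    cat("  proportion draws rejected near zero total:", x$guard_rejections, "\n")
  invisible(x)
}
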