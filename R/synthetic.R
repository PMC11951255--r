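#' Configuration for the two-sample summary-statistic simulator
#'
#' Defines a mediation data-generating process on the summary-statistic
#' scale: cis variants affect a circulating protein (per-allele effects
#' `b_j` in SD units), the protein affects a lipid mediator
#' (`alpha`, SD/SD), the mediator affects a binary outcome on the log-odds
#' scale (`gamma`), and the protein retains a direct outcome path
#' (`delta`). Genome-wide mediator instruments, independent of the cis
#' block, carry the mediator-to-outcome signal. Observed associations equal
#' the truth plus sampling noise with per-variant standard error
#' `1/sqrt(2 maf (1-maf) n)` for the respective study; the three studies
#' draw independent noise (two-sample design).
#'
#' Defaults emulate the motivating drug-target study: 8 cis instruments
#' with per-variant F around 80 at the protein GWAS sample size,
#' `alpha = 0.46`, `gamma = -0.30`, `delta = -0.062`, hence a total effect
#' of `-0.2` and a true proportion mediated of 0.69.
#'
#' @param j_cis number of cis instruments.
#' @param j_gw number of genome-wide mediator instruments.
#' @param n_exp,n_med,n_out GWAS sample sizes for protein, mediator and
#'   outcome.
#' @param b_mean,b_sd mean and SD of cis variant-to-protein effect
#'   magnitudes (signs random).
#' @param gw_b_mean,gw_b_sd same for genome-wide variant-to-mediator
#'   effects.
#' @param alpha protein-to-mediator effect (SD/SD).
#' @param gamma mediator-to-outcome effect (log-odds/SD).
#' @param delta protein-to-outcome direct effect (log-odds/SD).
#' @param pleio_mean,pleio_sd pleiotropy added to the variant-to-outcome
#'   path of affected cis variants, oriented relative to the
#'   exposure-increasing allele (a nonzero mean is directional pleiotropy;
#'   mean zero with positive sd is balanced).
#' @param pleio_frac fraction of cis variants carrying pleiotropy.
#' @param ld_rho AR(1) LD coefficient of the cis block (post-clumping
#'   instruments are treated as independent, so the default is 0).
#' @param maf_range minor-allele-frequency interval to draw from.
#' @param outcome_case_fraction case fraction of the binary outcome GWAS.
#'   Log-odds standard errors scale with the effective sample size
#'   `n_out * frac * (1 - frac)`, not the participant count; the default
#'   mirrors a large CAD meta-analysis (181 522 cases among 1 165 690).
#' @param overlap_rho correlation between the mediator and outcome studies'
#'   sampling noise, emulating shared participants; 0 (the default)
#'   enforces the two-sample design.
#' @param seed RNG seed; [simulate_study()] is bit-reproducible given it.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(j_cis = 8, j_gw = 50,
                       n_exp = 35365, n_med = 114999, n_out = 1165690,
                       b_mean = 0.074, b_sd = 0.015,
                       gw_b_mean = 0.03, gw_b_sd = 0.01,
                       alpha = 0.46, gamma = -0.30, delta = -0.062,
                       pleio_mean = 0, pleio_sd = 0, pleio_frac = 0,
                       ld_rho = 0, maf_range = c(0.1, 0.5),
                       outcome_case_fraction = 181522 / 1165690,
                       overlap_rho = 0, seed = 1L) {
  stopifnot(j_cis >= 1, n_exp > 0, n_med > 0, n_out > 0,
            abs(ld_rho) < 1, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2], pleio_frac >= 0, pleio_frac <= 1,
            outcome_case_fraction > 0, outcome_case_fraction < 1,
            abs(overlap_rho) <= 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Non-fasting attenuation scenario
#'
#' Returns a copy of the configuration with the protein-to-mediator effect
#' multiplied by `factor`, emulating the weaker protein association with
#' triglyceride-rich lipoprotein measures observed in non-fasted samples
#' (roughly half the fasted-sample association).
#'
#' @param config a [sim_config].
#' @param factor multiplier on `alpha` (default 0.5).
#' @return the modified [sim_config].
#' @export
config_nonfasting <- function(config, factor = 0.5) {
  stopifnot(inherits(config, "sim_config"), factor > 0)
  config$alpha <- config$alpha * factor
  config
}

#' Truth implied by a simulation configuration
#'
#' @param config a [sim_config].
#' @return list with `theta_total_true = delta + alpha * gamma`,
#'   `theta_xm_true = alpha`, `theta_my_true = gamma` and
#'   `proportion_true = alpha * gamma / theta_total_true`.
#' @export
sim_truth <- function(config) {
  total <- config$delta + config$alpha * config$gamma
  list(theta_total_true = total, theta_xm_true = config$alpha,
       theta_my_true = config$gamma,
       proportion_true = config$alpha * config$gamma / total)
}

#' AR(1) LD correlation matrix
#'
#' `r_ik = rho^|i-k|`, positive definite for `|rho| < 1`.
#'
#' @param j number of variants.
#' @param rho AR(1) coefficient.
#' @param ids optional variant ids.
#' @return an [ld_matrix].
#' @export
simulate_ld <- function(j, rho, ids = NULL) {
  if (abs(rho) >= 1) stop("|rho| must be below 1")
  m <- rho^abs(outer(seq_len(j), seq_len(j), "-"))
  ld_matrix(m, ids %||% paste0("cis_", seq_len(j)))
}

# Correlated noise: D (L z) with L the Cholesky factor of the correlation.
correlated_noise <- function(se, corr_chol) {
  z <- stats::rnorm(length(se))
  se * as.numeric(crossprod(corr_chol, z))
}

sim_records <- function(ids, chrom, pos, ea, oa, eaf, beta, se, n) {
  data.frame(variant_id = ids, chrom = chrom, pos = pos,
             effect_allele = ea, other_allele = oa, eaf = eaf, beta = beta,
             se = se, pval = pval_from_z(beta / se), n = n,
             stringsAsFactors = FALSE)
}

#' Simulate two-sample GWAS summary statistics with known mediation truth
#'
#' Draws cis and genome-wide variants per the configuration, constructs the
#' true association structure of the mediation DAG, and adds independent
#' per-study sampling noise (LD-correlated within the cis block when
#' `ld_rho != 0`). All outputs satisfy the summary-statistic invariants and
#' are bit-reproducible from `config$seed`.
#'
#' @param config a [sim_config].
#' @return list with [sumstats] elements `exposure` (cis variants),
#'   `mediator` and `outcome` (cis plus genome-wide variants), the cis
#'   [ld_matrix] `ld`, the cis `region` ([gene_region]) and `truth` (the
#'   [sim_truth()] quantities plus per-variant true effects and the seed).
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  jc <- config$j_cis; jg <- config$j_gw
  # non-palindromic allele pair to keep harmonization exercised but exact
  draw_maf <- function(j) stats::runif(j, config$maf_range[1], config$maf_range[2])
  maf_c <- draw_maf(jc)
  eaf_c <- ifelse(stats::rbinom(jc, 1, 0.5) == 1, maf_c, 1 - maf_c)
  b <- sample(c(-1, 1), jc, replace = TRUE) *
    stats::rnorm(jc, config$b_mean, config$b_sd)
  pleio <- rep(0, jc)
  n_pleio <- round(config$pleio_frac * jc)
  if (n_pleio > 0) {
    idx <- sample.int(jc, n_pleio)
    pleio[idx] <- stats::rnorm(n_pleio, config$pleio_mean, config$pleio_sd)
  }
  bm_c <- config$alpha * b
  # pleiotropy is directional relative to the exposure-increasing allele;
  # with arbitrary allele orientation a fixed offset would be balanced
  by_c <- config$delta * b + config$gamma * bm_c + pleio * sign(b)

  maf_g <- draw_maf(jg)
  eaf_g <- if (jg) ifelse(stats::rbinom(jg, 1, 0.5) == 1, maf_g, 1 - maf_g) else numeric()
  g <- if (jg) sample(c(-1, 1), jg, replace = TRUE) *
    stats::rnorm(jg, config$gw_b_mean, config$gw_b_sd) else numeric()
  by_g <- config$gamma * g

  se_for <- function(maf, n) 1 / sqrt(2 * maf * (1 - maf) * n)
  ld <- simulate_ld(jc, config$ld_rho)
  ch <- chol(unclass(ld))
  # standardized noise per study; the overlap knob correlates the mediator
  # and outcome draws (shared participants), zero under the two-sample
  # default
  ov <- config$overlap_rho %||% 0
  z_exp_c <- stats::rnorm(jc)
  z_med_c <- stats::rnorm(jc)
  z_out_c <- ov * z_med_c + sqrt(1 - ov^2) * stats::rnorm(jc)
  mix_cis <- function(z, se) se * as.numeric(crossprod(ch, z))
  z_med_g <- stats::rnorm(jg)
  z_out_g <- ov * z_med_g + sqrt(1 - ov^2) * stats::rnorm(jg)

  cis_ids <- ld_ids(ld)
  gw_ids <- if (jg) paste0("gw_", seq_len(jg)) else character()
  region <- gene_region("TARGET", "11", 116700000, 116703000, flank = 100000)
  cis_pos <- sort(round(stats::runif(jc, region$start - 90000,
                                     region$end + 90000)))
  gw_chrom <- if (jg) as.character(rep_len(c(1:10, 12:22), jg)) else character()
  gw_pos <- if (jg) round(stats::runif(jg, 1e6, 2e8)) else numeric()

  # binary outcome: precision is governed by the effective sample size
  phi <- config$outcome_case_fraction
  n_out_eff <- config$n_out * phi * (1 - phi)
  se_exp_c <- se_for(maf_c, config$n_exp)
  se_med_c <- se_for(maf_c, config$n_med)
  se_out_c <- se_for(maf_c, n_out_eff)
  se_med_g <- se_for(maf_g, config$n_med)
  se_out_g <- se_for(maf_g, n_out_eff)

  exposure <- sumstats(
    sim_records(cis_ids, region$chrom, cis_pos, "A", "G", eaf_c,
                b + mix_cis(z_exp_c, se_exp_c), se_exp_c, config$n_exp),
    trait_name = "protein", trait_scale = "sd_units")
  gw_med_rec <- if (jg) sim_records(gw_ids, gw_chrom, gw_pos, "A", "G", eaf_g,
                                    g + z_med_g * se_med_g,
                                    se_med_g, config$n_med)
  mediator <- sumstats(
    rbind(sim_records(cis_ids, region$chrom, cis_pos, "A", "G", eaf_c,
                      bm_c + mix_cis(z_med_c, se_med_c), se_med_c,
                      config$n_med),
          gw_med_rec),
    trait_name = "mediator", trait_scale = "sd_units")
  gw_out_rec <- if (jg) sim_records(gw_ids, gw_chrom, gw_pos, "A", "G", eaf_g,
                                    by_g + z_out_g * se_out_g,
                                    se_out_g, config$n_out)
  outcome <- sumstats(
    rbind(sim_records(cis_ids, region$chrom, cis_pos, "A", "G", eaf_c,
                      by_c + mix_cis(z_out_c, se_out_c), se_out_c,
                      config$n_out),
          gw_out_rec),
    trait_name = "outcome", trait_scale = "log_odds")

  truth <- c(sim_truth(config),
             list(b_cis = b, beta_mediator_cis = bm_c, beta_outcome_cis = by_c,
                  pleiotropy_cis = pleio, b_gw = g, beta_outcome_gw = by_g,
                  seed = config$seed))
  list(exposure = exposure, mediator = mediator, outcome = outcome,
       ld = ld, region = region, truth = truth, config = config)
}

#' Run an analysis over simulation replicates
#'
#' Generates `n_reps` independent studies (seeds `config$seed + 1 ... + n_reps`)
#' and applies `analysis` to each. The callback receives the
#' [simulate_study()] result and returns a data.frame with columns
#' `quantity`, `estimate`, `se`, `ci_low`, `ci_high`, `truth`. Per-replicate
#' failures are captured as flagged rows, not propagated.
#'
#' @param config a [sim_config]; its seed anchors the replicate seeds.
#' @param n_reps number of replicates.
#' @param analysis callback function of one argument.
#' @return tidy data.frame (`replicate`, `quantity`, `estimate`, `se`,
#'   `ci_low`, `ci_high`, `truth`, `covered`, `error`).
#' @export
simulate_replicates <- function(config, n_reps, analysis) {
  stopifnot(n_reps >= 1)
  out <- vector("list", n_reps)
  for (i in seq_len(n_reps)) {
    cfg <- config
    cfg$seed <- config$seed + i
    res <- tryCatch({
      tab <- analysis(simulate_study(cfg))
      tab$replicate <- i
      tab$covered <- tab$truth >= tab$ci_low & tab$truth <= tab$ci_high
      tab$error <- NA_character_
      tab
    }, error = function(e) {
      data.frame(quantity = NA_character_, estimate = NA_real_, se = NA_real_,
                 ci_low = NA_real_, ci_high = NA_real_, truth = NA_real_,
                 replicate = i, covered = NA, error = conditionMessage(e),
                 stringsAsFactors = FALSE)
    })
    out[[i]] <- res
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[c("replicate", "quantity", "estimate", "se", "ci_low", "ci_high",
        "truth", "covered", "error")]
}
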