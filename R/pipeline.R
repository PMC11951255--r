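# Config-driven orchestration of the drug-target MR analysis: instrument
# selection -> harmonization -> estimation -> mediation, with tabular
# reports. Inputs may be in-memory objects or file paths.

resolve_sumstats <- function(x, trait_scale = "sd_units") {
  if (inherits(x, "sumstats")) x
  else read_sumstats(x, trait_scale = trait_scale)
}

resolve_ld <- function(x) {
  if (is.null(x) || inherits(x, "ld_matrix")) x else read_ld_matrix(x)
}

#' Read and validate an analysis configuration from YAML
#'
#' Thin wrapper around `yaml::read_yaml` that rejects unknown top-level keys
#' (fail-fast against typos) and checks that referenced paths exist.
#'
#' @param path YAML file path.
#' @return the configuration list.
#' @export
read_analysis_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required to read YAML configurations")
  cfg <- yaml::read_yaml(path)
  known <- c("exposure", "outcomes", "mediators", "outcome", "methods",
             "ld", "consequences", "per_sd_lower", "gw_p_max", "gw_clump_r2",
             "gw_clump_window", "gw_ld", "theta_my_override", "n_boot",
             "seed", "out_dir")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  for (p in c(cfg$exposure$sumstats, cfg$ld, cfg$consequences))
    if (is.character(p) && !file.exists(p)) stop("path does not exist: ", p)
  cfg
}

# Select, filter and clump the cis instruments described by an exposure spec.
select_instruments <- function(spec, ld = NULL, consequences = NULL) {
  stats <- resolve_sumstats(spec$sumstats)
  stats <- select_cis(stats, spec$region,
                      maf_min = spec$maf_min %||% 0.01,
                      p_max = spec$p_max %||% 5e-8)
  if (!is.null(consequences)) stats <- exclude_coding(stats, consequences)
  ld <- resolve_ld(spec$ld %||% ld)
  if (!is.null(ld))
    stats <- clump(stats, ld, r2_max = spec$clump_r2 %||% 0.1,
                   window_bp = spec$clump_window %||% 1e7)
  stats
}

estimate_row <- function(exposure, target, adjustment, est) {
  log_odds <- identical(est$outcome_scale, "log_odds")
  data.frame(exposure = exposure, target = target, adjustment = adjustment,
             method = est$method, n_snps = est$n_snps, estimate = est$theta,
             se = est$se, ci_low = est$ci_low, ci_high = est$ci_high,
             pval = est$pval,
             or = if (log_odds) exp(est$theta) else NA_real_,
             or_low = if (log_odds) exp(est$ci_low) else NA_real_,
             or_high = if (log_odds) exp(est$ci_high) else NA_real_,
             stringsAsFactors = FALSE)
}

na_row <- function(exposure, target, adjustment, method, msg) {
  data.frame(exposure = exposure, target = target, adjustment = adjustment,
             method = method, n_snps = NA_integer_, estimate = NA_real_,
             se = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
             pval = NA_real_, or = NA_real_, or_low = NA_real_,
             or_high = NA_real_, stringsAsFactors = FALSE)
}

run_methods <- function(h, methods, seed = NULL) {
  ests <- list()
  for (m in methods) {
    ests[[m]] <- switch(
      m,
      ivw = mr_ivw(h),
      ivw_ld = mr_ivw_ld(h),
      egger = mr_egger(h)$slope,
      egger_intercept = mr_egger(h)$intercept,
      weighted_median = mr_weighted_median(h, seed = seed),
      conmix = mr_conmix(h),
      presso = mr_presso(h, seed = seed)$corrected,
      stop("unknown MR method: ", m))
  }
  ests
}

#' Run the exposure-by-trait panel
#'
#' For every target trait, selects cis instruments for the exposure,
#' harmonizes, and applies the requested estimators. Estimates are reported
#' per 1 SD *lower* exposure by default (a final sign flip), matching the
#' drug-inhibition framing. Per-cell failures become NA rows with the error
#' message attached, not aborts.
#'
#' @param config list with elements `exposure` (list: `name`, `sumstats`,
#'   `region`, optional `maf_min`, `p_max`, `clump_r2`, `clump_window`,
#'   `ld`), `outcomes` (named list of [sumstats] or paths), `methods`
#'   (character vector), and optional `ld`, `consequences`, `per_sd_lower`
#'   (default TRUE), `seed`.
#' @return a report data.frame, one row per target x method; attribute
#'   `instruments` holds the selected instrument set.
#' @export
run_exposure_panel <- function(config) {
  if (!length(config$methods)) stop("configuration error: empty methods list")
  instr <- select_instruments(config$exposure, ld = config$ld,
                              consequences = config$consequences)
  per_sd_lower <- config$per_sd_lower %||% TRUE
  rows <- list()
  for (target in names(config$outcomes)) {
    out_stats <- resolve_sumstats(config$outcomes[[target]])
    rows[[target]] <- tryCatch({
      h <- harmonize(instr, out_stats)
      if (!is.null(config$ld) && "ivw_ld" %in% config$methods)
        h <- set_ld(h, resolve_ld(config$ld))
      ests <- run_methods(h, config$methods, seed = config$seed)
      do.call(rbind, lapply(names(ests), function(m) {
        est <- ests[[m]]
        if (per_sd_lower && !grepl("intercept", m)) est <- flip_sign(est)
        estimate_row(config$exposure$name, target, "none", est)
      }))
    }, error = function(e) {
      r <- na_row(config$exposure$name, target, "none",
                  paste(config$methods, collapse = "+"), conditionMessage(e))
      attr(r, "error") <- conditionMessage(e)
      r
    })
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  attr(report, "instruments") <- instrument_set(instr)
  report
}

# Genome-wide instruments for a mediator: significant, common, outside the
# cis region, clumped when LD is available (simulated genome-wide variants
# are mutually independent, so absence of an LD panel means no clumping).
gw_instruments <- function(mediator, region, p_max = 5e-8, maf_min = 0.01,
                           clump_r2 = 0.01, clump_window = 1e6, ld = NULL) {
  rec <- mediator$records
  maf <- pmin(rec$eaf, 1 - rec$eaf)
  in_cis <- rec$chrom == region$chrom &
    rec$pos >= region$start - region$flank &
    rec$pos <= region$end + region$flank
  keep <- !in_cis & maf > maf_min & rec$pval < p_max
  if (!any(keep)) stop("no genome-wide instruments for ", mediator$trait_name)
  mediator$records <- rec[keep, , drop = FALSE]
  rownames(mediator$records) <- NULL
  if (!is.null(ld)) mediator <- clump(mediator, ld, clump_r2, clump_window)
  mediator
}

#' Run the two-step cis-MR mediation panel
#'
#' For each candidate mediator: the unadjusted cis-MR exposure-to-outcome
#' estimate, the variant-level mediator-adjusted estimate, and the full
#' bootstrap decomposition (indirect, direct, proportion mediated).
#' Mediator-to-outcome effects use genome-wide instruments selected at
#' `gw_p_max` and clumped at `gw_clump_r2` when an LD panel is supplied.
#'
#' @param config as for [run_exposure_panel()], plus `mediators` (named list
#'   of [sumstats] containing both cis and genome-wide variants), `outcome`
#'   (a [sumstats]), and optional `gw_p_max` (default 5e-8), `gw_clump_r2`
#'   (default 0.01), `gw_clump_window` (default 1e6), `gw_ld`, `n_boot`
#'   (default 1e5), `seed`.
#' @return list with `table` (report rows: unadjusted, adjusted and
#'   proportion-mediated per mediator, proportions as percentages) and
#'   `mediation` (named list of `mediation_result`).
#' @export
run_mediation_panel <- function(config) {
  instr <- select_instruments(config$exposure, ld = config$ld,
                              consequences = config$consequences)
  outcome <- resolve_sumstats(config$outcome, trait_scale = "log_odds")
  per_sd_lower <- config$per_sd_lower %||% TRUE
  rows <- list(); meds <- list()
  for (mname in names(config$mediators)) {
    mediator <- resolve_sumstats(config$mediators[[mname]])
    res <- tryCatch({
      cis_set <- harmonize_mediation(instr, mediator, outcome)
      theta_total <- mr_ivw(harmonize(instr, outcome))
      theta_xm <- mr_ivw(harmonize(instr, mediator))
      theta_my <- if (!is.null(config$theta_my_override)) {
        # fix the mediator-to-outcome effect (e.g. 0 for a no-mediation check)
        mr_estimate("override", config$theta_my_override, 0, 0L,
                    outcome_scale = outcome$trait_scale)
      } else {
        gw <- gw_instruments(mediator, config$exposure$region,
                             p_max = config$gw_p_max %||% 5e-8,
                             clump_r2 = config$gw_clump_r2 %||% 0.01,
                             clump_window = config$gw_clump_window %||% 1e6,
                             ld = resolve_ld(config$gw_ld))
        mr_ivw(harmonize(gw, outcome))
      }
      adjusted <- adjusted_outcome_mr(cis_set, theta_my)
      med <- bootstrap_mediation(
        mediation_inputs(theta_total, theta_xm, theta_my, cis_set),
        n_boot = config$n_boot %||% 1e5, seed = config$seed)
      rep_total <- if (per_sd_lower) flip_sign(theta_total) else theta_total
      rep_adj <- if (per_sd_lower) flip_sign(adjusted) else adjusted
      tab <- rbind(
        estimate_row(config$exposure$name, outcome$trait_name, "none", rep_total),
        estimate_row(config$exposure$name, outcome$trait_name, mname, rep_adj))
      tab$proportion_mediated_pct <- c(NA_real_, 100 * med$proportion_mediated)
      tab$proportion_ci_low_pct <- c(NA_real_, 100 * med$ci$proportion[1])
      tab$proportion_ci_high_pct <- c(NA_real_, 100 * med$ci$proportion[2])
      list(tab = tab, med = med)
    }, error = function(e) {
      r <- na_row(config$exposure$name, "outcome", mname, "ivw",
                  conditionMessage(e))
      r$proportion_mediated_pct <- NA_real_
      r$proportion_ci_low_pct <- NA_real_
      r$proportion_ci_high_pct <- NA_real_
      attr(r, "error") <- conditionMessage(e)
      list(tab = r, med = NULL)
    })
    rows[[mname]] <- res$tab
    meds[[mname]] <- res$med
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  list(table = table, mediation = meds)
}

#' Rescale a per-SD estimate to natural units
#'
#' Converts an effect per 1 SD of a trait to an effect per 1 measurement
#' unit by dividing the estimate, its standard error and confidence limits
#' by the trait SD expressed in those units; z-scores and p-values are
#' unchanged. On the log-odds scale, `exp()` of the result is the odds
#' ratio per unit.
#'
#' @param estimate an `mr_estimate` on the per-SD scale.
#' @param sd_in_units the trait SD in the desired units (e.g. mg/dL).
#' @return the rescaled `mr_estimate`.
#' @export
rescale_per_unit <- function(estimate, sd_in_units) {
  if (!is.numeric(sd_in_units) || sd_in_units <= 0)
    stop("sd_in_units must be positive")
  estimate$theta <- estimate$theta / sd_in_units
  estimate$se <- estimate$se / sd_in_units
  estimate$ci_low <- estimate$ci_low / sd_in_units
  estimate$ci_high <- estimate$ci_high / sd_in_units
  estimate
}

#' Write a report table with provenance
#'
#' Writes the table as TSV together with a JSON sidecar carrying the seed
#' and package version, so that reruns are auditable.
#'
#' @param report a report data.frame.
#' @param path output TSV path.
#' @param seed seed used for the run (recorded in the sidecar).
#' @export
write_report <- function(report, path, seed = NULL) {
  utils::write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(seed = seed,
               package_version = as.character(utils::packageVersion("cismr")),
               n_rows = nrow(report))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
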