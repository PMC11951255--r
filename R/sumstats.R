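#' GWAS summary statistics for one trait
#'
#' Validated container for per-variant association statistics from a single
#' genome-wide association study. Effects (`beta`) are per copy of the effect
#' allele, in standard-deviation units for quantitative traits and log-odds
#' for binary traits. Rows violating the per-variant invariants (non-positive
#' standard error, allele frequency outside (0,1), identical alleles,
#' non-SNP alleles, p-value outside (0,1], non-positive sample size,
#' duplicated id) are dropped and recorded in the drop log rather than
#' raising an error, so that dirty public files can be ingested and audited.
#'
#' @param records data.frame with columns `variant_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`.
#'   `pval` may be `NA`, in which case it is recomputed from `beta/se`
#'   under a standard normal.
#' @param trait_name label for the trait.
#' @param trait_scale `"sd_units"` or `"log_odds"`.
#' @param ancestry_tag free-text ancestry label.
#' @param fasting_tag optional `"fasted"`, `"nonfasted"` or `"mixed"`.
#' @return an object of class `sumstats`: a list with elements `trait_name`,
#'   `trait_scale`, `records`, `ancestry_tag`, `fasting_tag` and `drop_log`.
#' @export
sumstats <- function(records, trait_name, trait_scale = c("sd_units", "log_odds"),
                     ancestry_tag = "EUR", fasting_tag = NULL) {
  trait_scale <- match.arg(trait_scale)
  required <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
                "eaf", "beta", "se", "pval", "n")
  if (!"pval" %in% names(records)) records$pval <- NA_real_
  missing <- setdiff(required, names(records))
  if (length(missing))
    stop("missing summary-statistic columns: ", paste(missing, collapse = ", "))
  records <- records[required]
  records$variant_id <- as.character(records$variant_id)
  records$chrom <- as.character(records$chrom)
  records$effect_allele <- toupper(as.character(records$effect_allele))
  records$other_allele <- toupper(as.character(records$other_allele))
  for (col in c("pos", "eaf", "beta", "se", "pval", "n"))
    records[[col]] <- as.numeric(records[[col]])

  log <- empty_log()
  drop <- function(bad, reason) {
    log <<- add_log(log, records$variant_id[bad], "read", reason)
    records <<- records[!bad, , drop = FALSE]
  }
  snp <- records$effect_allele %in% names(.COMPLEMENT) &
    records$other_allele %in% names(.COMPLEMENT)
  drop(!snp, "not_snp")
  drop(records$effect_allele == records$other_allele, "allele_identical")
  drop(!is.finite(records$se) | records$se <= 0, "nonpositive_se")
  drop(!is.finite(records$eaf) | records$eaf <= 0 | records$eaf >= 1,
       "eaf_out_of_range")
  drop(!is.finite(records$beta), "missing_beta")
  drop(!is.finite(records$n) | records$n <= 0, "nonpositive_n")
  # stored p-value wins when present; recompute from z = beta/se when absent
  miss_p <- !is.finite(records$pval)
  records$pval[miss_p] <- pval_from_z(records$beta[miss_p] / records$se[miss_p])
  drop(records$pval <= 0 | records$pval > 1, "invalid_pval")
  drop(duplicated(records$variant_id), "duplicate_id")

  rownames(records) <- NULL
  structure(list(trait_name = trait_name, trait_scale = trait_scale,
                 records = records, ancestry_tag = ancestry_tag,
                 fasting_tag = fasting_tag, drop_log = log),
            class = "sumstats")
}

#' @export
print.sumstats <- function(x, ...) {
  cat("GWAS summary statistics: ", x$trait_name,
      " (", x$trait_scale, ", ", nrow(x$records), " variants)\n", sep = "")
  if (nrow(x$drop_log)) cat("  dropped at read:", nrow(x$drop_log), "rows\n")
  invisible(x)
}

n_variants <- function(x) nrow(x$records)

#' Read GWAS summary statistics from a tab-delimited file
#'
#' @param path path to a tab-delimited file with a header row.
#' @param column_map optional named character vector mapping canonical column
#'   names (`variant_id`, `chrom`, `pos`, `effect_allele`, `other_allele`,
#'   `eaf`, `beta`, `se`, `pval`, `n`) to the file's own header names.
#'   Unmapped canonical names are looked up verbatim.
#' @param trait_scale `"sd_units"` or `"log_odds"`.
#' @param trait_name trait label; defaults to the file name.
#' @param ... passed on to [sumstats()].
#' @return a [sumstats] object; malformed rows are dropped and logged.
#' @export
read_sumstats <- function(path, column_map = NULL,
                          trait_scale = c("sd_units", "log_odds"),
                          trait_name = NULL, ...) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!nrow(raw)) stop("empty summary-statistics file: ", path)
  canonical <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
                 "eaf", "beta", "se", "pval", "n")
  map <- stats::setNames(canonical, canonical)
  if (!is.null(column_map)) map[names(column_map)] <- column_map
  needed <- if ("pval" %in% names(column_map)) canonical else
    setdiff(canonical, "pval")  # pval is optional unless explicitly mapped
  absent <- setdiff(unname(map[needed]), names(raw))
  if (length(absent))
    stop("mapped columns absent from ", path, ": ", paste(absent, collapse = ", "))
  out <- data.frame(row.names = seq_len(nrow(raw)))
  for (cn in canonical)
    out[[cn]] <- if (map[[cn]] %in% names(raw)) raw[[map[[cn]]]] else NA
  sumstats(out, trait_name = trait_name %||% basename(path),
           trait_scale = match.arg(trait_scale), ...)
}

#' Write summary statistics as a canonical tab-delimited file
#'
#' Numeric columns are written with 15 significant digits so that a
#' write/read round trip preserves values well beyond 12 significant digits.
#'
#' @param x a [sumstats] object.
#' @param path output path.
#' @export
write_sumstats <- function(x, path) {
  rec <- x$records
  for (col in c("eaf", "beta", "se", "pval"))
    rec[[col]] <- formatC(rec[[col]], digits = 15, format = "g")
  utils::write.table(rec, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Harmonized exposure-outcome association set
#'
#' Direct constructor for an allele-aligned set of instrument associations,
#' the input to every estimator. Usually produced by [harmonize()]; the
#' constructor is exported so that multivariable designs and simulations can
#' assemble one directly.
#'
#' @param beta_exposure numeric matrix (variants x exposures) or vector.
#' @param se_exposure matching standard errors.
#' @param beta_outcome,se_outcome per-variant outcome associations.
#' @param variant_ids optional ids; defaults to `snp_1 ... snp_J`.
#' @param exposure_names optional exposure labels.
#' @param eaf_exposure optional effect-allele frequencies (exposure study).
#' @param ld optional [ld_matrix] covering `variant_ids`.
#' @param beta_mediator,se_mediator optional per-variant mediator
#'   associations aligned to the same effect alleles (used by two-step
#'   cis-MR mediation).
#' @param outcome_name,outcome_scale outcome labels.
#' @param drop_log data.frame of harmonization drops.
#' @return an object of class `harmonized_set`.
#' @export
harmonized_set <- function(beta_exposure, se_exposure, beta_outcome, se_outcome,
                           variant_ids = NULL, exposure_names = NULL,
                           eaf_exposure = NULL, ld = NULL,
                           beta_mediator = NULL, se_mediator = NULL,
                           outcome_name = "outcome", outcome_scale = "log_odds",
                           drop_log = empty_log()) {
  beta_exposure <- as.matrix(beta_exposure)
  se_exposure <- as.matrix(se_exposure)
  J <- nrow(beta_exposure)
  if (is.null(variant_ids)) variant_ids <- paste0("snp_", seq_len(J))
  if (is.null(exposure_names))
    exposure_names <- paste0("exposure_", seq_len(ncol(beta_exposure)))
  stopifnot(nrow(se_exposure) == J, length(beta_outcome) == J,
            length(se_outcome) == J, length(variant_ids) == J,
            ncol(se_exposure) == ncol(beta_exposure),
            length(exposure_names) == ncol(beta_exposure),
            all(se_outcome > 0), all(se_exposure > 0))
  if (!is.null(ld)) ld <- ld_subset(ld, variant_ids)
  if (!is.null(beta_mediator))
    stopifnot(length(beta_mediator) == J, length(se_mediator) == J)
  structure(list(variant_ids = variant_ids, exposure_names = exposure_names,
                 beta_exposure = beta_exposure, se_exposure = se_exposure,
                 beta_outcome = as.numeric(beta_outcome),
                 se_outcome = as.numeric(se_outcome),
                 eaf_exposure = eaf_exposure, ld = ld,
                 beta_mediator = beta_mediator, se_mediator = se_mediator,
                 outcome_name = outcome_name, outcome_scale = outcome_scale,
                 drop_log = drop_log),
            class = "harmonized_set")
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat("Harmonized set: ", paste(x$exposure_names, collapse = " + "),
      " -> ", x$outcome_name, " (", length(x$variant_ids), " variants",
      if (!is.null(x$ld)) ", LD attached", ")\n", sep = "")
  invisible(x)
}

#' Attach an LD matrix to a harmonized set
#'
#' @param h a [harmonized_set].
#' @param ld an [ld_matrix] covering the set's variants.
#' @return the set with `ld` subset and ordered to its variants.
#' @export
set_ld <- function(h, ld) {
  h$ld <- ld_subset(ld, h$variant_ids)
  h
}

# Resolve the allele orientation of one outcome record against the exposure
# record. Returns list(action = "keep"/"drop", flip = logical, reason).
align_alleles <- function(ea_x, oa_x, ea_y, oa_y, eaf_x, eaf_y, limit) {
  if (is_palindromic(ea_x, oa_x)) {
    if (!setequal(c(ea_y, oa_y), c(ea_x, oa_x)))
      return(list(action = "drop", reason = "allele_mismatch"))
    # strand is unresolvable from labels; use allele frequency, and only
    # when it is informative in both datasets and consistent between them
    if (min(eaf_x, 1 - eaf_x) >= limit || min(eaf_y, 1 - eaf_y) >= limit)
      return(list(action = "drop", reason = "palindromic_ambiguous"))
    if ((eaf_x < 0.5) != (eaf_y < 0.5))
      return(list(action = "drop", reason = "palindromic_ambiguous"))
    return(list(action = "keep", flip = FALSE))
  }
  if (ea_y == ea_x && oa_y == oa_x) return(list(action = "keep", flip = FALSE))
  if (ea_y == oa_x && oa_y == ea_x) return(list(action = "keep", flip = TRUE))
  fea <- flip_alleles(ea_y); foa <- flip_alleles(oa_y)
  if (fea == ea_x && foa == oa_x) return(list(action = "keep", flip = FALSE))
  if (fea == oa_x && foa == ea_x) return(list(action = "keep", flip = TRUE))
  list(action = "drop", reason = "allele_mismatch")
}

#' Harmonize two summary-statistic sets onto common effect alleles
#'
#' Aligns the outcome study's effects to the exposure study's effect alleles
#' over their shared variants. Swapped alleles have the outcome beta negated
#' and the allele frequency complemented; strand flips (allele complements)
#' are resolved through the complementary alleles. Palindromic (A/T, C/G)
#' variants, whose strand cannot be read from the labels, are retained only
#' when the allele frequency is informative (minor-allele frequency below
#' `palindrome_eaf_limit`) in both studies and falls on the same side of 0.5
#' in both; otherwise they are dropped with reason `palindromic_ambiguous`.
#' Incompatible allele pairs are dropped with reason `allele_mismatch`.
#'
#' @param exposure,outcome [sumstats] objects.
#' @param palindrome_eaf_limit minor-allele-frequency threshold above which a
#'   palindromic variant's strand is considered unresolvable (default 0.42,
#'   a common two-sample MR convention).
#' @return a single-exposure [harmonized_set]. The aligned outcome records
#'   are kept in the `outcome_aligned` element (a [sumstats]) so that
#'   harmonization can be audited and shown to be idempotent; all drops are
#'   in `drop_log`.
#' @export
harmonize <- function(exposure, outcome, palindrome_eaf_limit = 0.42) {
  stopifnot(inherits(exposure, "sumstats"), inherits(outcome, "sumstats"))
  shared <- intersect(exposure$records$variant_id, outcome$records$variant_id)
  if (!length(shared))
    stop("no shared variants between '", exposure$trait_name, "' and '",
         outcome$trait_name, "'")
  ex <- exposure$records[match(shared, exposure$records$variant_id), ]
  ou <- outcome$records[match(shared, outcome$records$variant_id), ]
  log <- empty_log()
  keep <- logical(length(shared))
  for (i in seq_along(shared)) {
    res <- align_alleles(ex$effect_allele[i], ex$other_allele[i],
                         ou$effect_allele[i], ou$other_allele[i],
                         ex$eaf[i], ou$eaf[i], palindrome_eaf_limit)
    if (res$action == "drop") {
      log <- add_log(log, shared[i], "harmonize", res$reason)
      next
    }
    keep[i] <- TRUE
    if (res$flip) {
      ou$beta[i] <- -ou$beta[i]
      ou$eaf[i] <- 1 - ou$eaf[i]
    }
    ou$effect_allele[i] <- ex$effect_allele[i]
    ou$other_allele[i] <- ex$other_allele[i]
  }
  if (!any(keep))
    stop("no variants remain after harmonization: ", length(shared),
         " shared, ", sum(log$reason == "palindromic_ambiguous"),
         " palindromic_ambiguous, ", sum(log$reason == "allele_mismatch"),
         " allele_mismatch")
  ex <- ex[keep, , drop = FALSE]
  ou <- ou[keep, , drop = FALSE]
  h <- harmonized_set(
    beta_exposure = matrix(ex$beta, dimnames = list(NULL, exposure$trait_name)),
    se_exposure = matrix(ex$se), beta_outcome = ou$beta, se_outcome = ou$se,
    variant_ids = ex$variant_id, exposure_names = exposure$trait_name,
    eaf_exposure = ex$eaf, outcome_name = outcome$trait_name,
    outcome_scale = outcome$trait_scale, drop_log = log)
  h$exposure_records <- ex
  h$outcome_aligned <- sumstats(ou, trait_name = outcome$trait_name,
                                trait_scale = outcome$trait_scale,
                                ancestry_tag = outcome$ancestry_tag,
                                fasting_tag = outcome$fasting_tag)
  h
}

#' Harmonize exposure, mediator and outcome onto common effect alleles
#'
#' Builds the cis instrument set needed by two-step mediation: exposure,
#' mediator and outcome effects all aligned to the exposure study's effect
#' alleles. Instruments missing from the mediator study are dropped with
#' reason `no_mediator_association`.
#'
#' @inheritParams harmonize
#' @param mediator a [sumstats] object for the candidate mediator.
#' @return a [harmonized_set] with `beta_mediator` and `se_mediator` filled.
#' @export
harmonize_mediation <- function(exposure, mediator, outcome,
                                palindrome_eaf_limit = 0.42) {
  h <- harmonize(exposure, outcome, palindrome_eaf_limit)
  hm <- harmonize(exposure, mediator, palindrome_eaf_limit)
  common <- intersect(h$variant_ids, hm$variant_ids)
  lost <- setdiff(h$variant_ids, common)
  idx <- match(common, h$variant_ids)
  midx <- match(common, hm$variant_ids)
  out <- harmonized_set(
    beta_exposure = h$beta_exposure[idx, , drop = FALSE],
    se_exposure = h$se_exposure[idx, , drop = FALSE],
    beta_outcome = h$beta_outcome[idx], se_outcome = h$se_outcome[idx],
    variant_ids = common, exposure_names = h$exposure_names,
    eaf_exposure = h$eaf_exposure[idx],
    beta_mediator = hm$beta_outcome[midx], se_mediator = hm$se_outcome[midx],
    outcome_name = h$outcome_name, outcome_scale = h$outcome_scale,
    drop_log = add_log(rbind(h$drop_log, hm$drop_log), lost,
                       "harmonize_mediation", "no_mediator_association"))
  out$mediator_name <- mediator$trait_name
  out
}

#' Find LD proxies for instruments missing from the outcome dataset
#'
#' For each missing instrument, proposes the outcome-present variant with the
#' highest squared LD correlation, provided it reaches `r2_min`. Ties on r2
#' are broken by the smaller outcome p-value and then by lexicographic id.
#' The signed correlation is returned so that a negative-r proxy can have its
#' outcome effect re-aligned (sign flipped) by the caller.
#'
#' @param missing character vector of instrument ids absent from the outcome.
#' @param outcome a [sumstats] object providing candidate proxies.
#' @param ld an [ld_matrix] covering the missing variants and candidates.
#' @param r2_min minimum squared correlation for an acceptable proxy.
#' @return data.frame with columns `variant_id`, `proxy_id`, `r2`, `r`;
#'   attribute `unproxied` lists variants for which no proxy reached
#'   `r2_min`.
#' @export
find_proxies <- function(missing, outcome, ld, r2_min = 0.8) {
  cand <- intersect(outcome$records$variant_id, ld_ids(ld))
  cand <- setdiff(cand, missing)
  out <- data.frame(variant_id = character(), proxy_id = character(),
                    r2 = numeric(), r = numeric(), stringsAsFactors = FALSE)
  unproxied <- character()
  pvals <- outcome$records$pval[match(cand, outcome$records$variant_id)]
  for (id in missing) {
    if (!(id %in% ld_ids(ld)) || !length(cand)) {
      unproxied <- c(unproxied, id)
      next
    }
    r <- unclass(ld)[id, cand]
    r2 <- r^2
    ok <- r2 >= r2_min
    if (!any(ok)) {
      unproxied <- c(unproxied, id)
      next
    }
    ord <- order(-r2, pvals, cand)
    best <- ord[ok[ord]][1]
    out <- rbind(out, data.frame(variant_id = id, proxy_id = cand[best],
                                 r2 = r2[best], r = r[best],
                                 stringsAsFactors = FALSE))
  }
  attr(out, "unproxied") <- unproxied
  out
}

#' Estimate the phenotypic SD of a trait from its summary statistics
#'
#' For a quantitative trait analysed on its raw scale, the identity
#' `var(beta_j) ~ sdY^2 / (2 n_j p_j (1 - p_j))` links each variant's
#' standard error to the trait SD. The estimator regresses
#' `2 n_j p_j (1 - p_j)` on `1 / se_j^2` through the origin; the slope is
#' `sdY^2`. Deterministic given the input.
#'
#' @param stats a [sumstats] object with at least two variants.
#' @return the estimated trait standard deviation (positive scalar).
#' @export
estimate_trait_sd <- function(stats) {
  rec <- stats$records
  if (nrow(rec) < 2) stop("at least 2 variants required to estimate trait SD")
  x <- 1 / rec$se^2
  y <- 2 * rec$n * rec$eaf * (1 - rec$eaf)
  sqrt(sum(x * y) / sum(x * x))
}

#' Rescale summary statistics to standard-deviation units
#'
#' Divides betas and standard errors by the trait SD, leaving z-scores and
#' p-values unchanged.
#'
#' @param stats a [sumstats] object.
#' @param sd positive trait standard deviation, e.g. from
#'   [estimate_trait_sd()].
#' @return the rescaled [sumstats] with `trait_scale = "sd_units"`.
#' @export
rescale_to_sd <- function(stats, sd) {
  if (!is.numeric(sd) || length(sd) != 1 || sd <= 0)
    stop("sd must be a positive scalar")
  stats$records$beta <- stats$records$beta / sd
  stats$records$se <- stats$records$se / sd
  stats$trait_scale <- "sd_units"
  stats
}
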