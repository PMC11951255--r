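#' Gene region for cis-instrument selection
#'
#' @param gene_name gene symbol.
#' @param chrom chromosome (character, matched against summary statistics).
#' @param start,end 1-based gene coordinates in base pairs.
#' @param flank symmetric flank in base pairs added to either side of the
#'   gene when defining the cis window (default 100 kb). The window is the
#'   closed interval `[start - flank, end + flank]`.
#' @return an object of class `gene_region`.
#' @export
gene_region <- function(gene_name, chrom, start, end, flank = 100000L) {
  stopifnot(start <= end, flank >= 0)
  structure(list(gene_name = gene_name, chrom = as.character(chrom),
                 start = as.numeric(start), end = as.numeric(end),
                 flank = as.numeric(flank)),
            class = "gene_region")
}

#' Select cis variants for a gene region
#'
#' Retains common variants (minor allele frequency strictly above `maf_min`)
#' inside the closed cis window `[start - flank, end + flank]` whose
#' association p-value is strictly below `p_max`. Every exclusion is logged
#' with its stage (`chrom`, `window`, `maf`, `pval`).
#'
#' @param stats a [sumstats] object.
#' @param region a [gene_region].
#' @param maf_min minor-allele-frequency threshold (exclusive, default 0.01).
#' @param p_max genome-wide significance threshold (exclusive, default 5e-8).
#' @return the filtered [sumstats]; the cumulative selection log is kept in
#'   the `selection_log` element.
#' @export
select_cis <- function(stats, region, maf_min = 0.01, p_max = 5e-8) {
  rec <- stats$records
  log <- stats$selection_log %||% empty_log()
  lo <- region$start - region$flank
  hi <- region$end + region$flank
  bad_chrom <- rec$chrom != region$chrom
  bad_window <- !bad_chrom & (rec$pos < lo | rec$pos > hi)
  maf <- pmin(rec$eaf, 1 - rec$eaf)
  bad_maf <- !bad_chrom & !bad_window & maf <= maf_min
  bad_p <- !bad_chrom & !bad_window & !bad_maf & rec$pval >= p_max
  log <- add_log(log, rec$variant_id[bad_chrom], "select_cis", "chrom")
  log <- add_log(log, rec$variant_id[bad_window], "select_cis", "window")
  log <- add_log(log, rec$variant_id[bad_maf], "select_cis", "maf")
  log <- add_log(log, rec$variant_id[bad_p], "select_cis", "pval")
  keep <- !(bad_chrom | bad_window | bad_maf | bad_p)
  if (!any(keep))
    stop("no cis variants survive selection for ", region$gene_name,
         " (of ", nrow(rec), ": ", sum(bad_chrom), " off-chromosome, ",
         sum(bad_window), " outside window, ", sum(bad_maf), " below MAF, ",
         sum(bad_p), " above p threshold)")
  stats$records <- rec[keep, , drop = FALSE]
  rownames(stats$records) <- NULL
  stats$selection_log <- log
  stats
}

# Variant consequences excluded to avoid epitope-binding artefacts in
# aptamer-based protein measurements.
CODING_CONSEQUENCES <- c("missense_variant", "stop_gained", "stop_lost",
                         "start_gained", "start_lost", "frameshift_variant")

#' Exclude protein-coding consequence variants
#'
#' Removes variants annotated as missense, stop gained/lost, start
#' gained/lost or frameshift, which can distort affinity-based protein
#' quantification and thereby invalidate a pQTL instrument. Variants absent
#' from the annotation table are retained.
#'
#' @param stats a [sumstats] object.
#' @param consequences named character vector (or two-column data.frame of
#'   `variant_id`, `consequence`) mapping variant ids to consequence labels.
#' @return the filtered [sumstats] with exclusions logged.
#' @export
exclude_coding <- function(stats, consequences) {
  if (is.data.frame(consequences))
    consequences <- stats::setNames(as.character(consequences[[2]]),
                                    as.character(consequences[[1]]))
  rec <- stats$records
  lab <- consequences[rec$variant_id]
  bad <- !is.na(lab) & lab %in% CODING_CONSEQUENCES
  stats$selection_log <- add_log(stats$selection_log %||% empty_log(),
                                 rec$variant_id[bad], "exclude_coding",
                                 "coding_consequence")
  stats$records <- rec[!bad, , drop = FALSE]
  rownames(stats$records) <- NULL
  stats
}

#' Greedy LD clumping by significance
#'
#' Repeatedly keeps the remaining variant with the lowest p-value (ties are
#' broken by the larger absolute z-statistic, then lexicographic id) and
#' removes all remaining variants whose squared LD correlation with it is at
#' least `r2_max` and whose position is within `window_bp` of it. Variants
#' without LD information are dropped up front with reason `no_ld`. The
#' result is deterministic and invariant to the input row order.
#'
#' @param stats a [sumstats] object.
#' @param ld an [ld_matrix].
#' @param r2_max clumping threshold on squared correlation (default 0.1, the
#'   usual choice for cis-pQTL instruments; genome-wide lipid instruments
#'   conventionally use 0.01).
#' @param window_bp clumping window in base pairs (default 10 Mb).
#' @return the clumped [sumstats] with records in selection order.
#' @export
clump <- function(stats, ld, r2_max = 0.1, window_bp = 1e7) {
  rec <- stats$records
  log <- stats$selection_log %||% empty_log()
  no_ld <- !(rec$variant_id %in% ld_ids(ld))
  log <- add_log(log, rec$variant_id[no_ld], "clump", "no_ld")
  rec <- rec[!no_ld, , drop = FALSE]
  ord <- order(rec$pval, -abs(rec$beta / rec$se), rec$variant_id)
  rec <- rec[ord, , drop = FALSE]
  r2 <- unclass(ld)[rec$variant_id, rec$variant_id, drop = FALSE]^2
  keep <- character()
  active <- seq_len(nrow(rec))
  while (length(active)) {
    i <- active[1]
    keep <- c(keep, rec$variant_id[i])
    prune <- r2[active, i] >= r2_max &
      abs(rec$pos[active] - rec$pos[i]) <= window_bp &
      rec$chrom[active] == rec$chrom[i]
    prune[1] <- TRUE
    log <- add_log(log, rec$variant_id[active[prune & active != i]],
                   "clump", "ld_with_index")
    active <- active[!prune]
  }
  stats$records <- rec[match(keep, rec$variant_id), , drop = FALSE]
  rownames(stats$records) <- NULL
  stats$selection_log <- log
  stats
}

#' Per-variant F statistic
#'
#' The squared z-statistic `(beta/se)^2`, the single-instrument F measure of
#' instrument strength.
#'
#' @param beta,se per-variant effect and standard error (vectorized).
#' @return numeric vector of F statistics.
#' @export
per_variant_f <- function(beta, se) {
  if (any(se <= 0)) stop("se must be positive")
  (beta / se)^2
}

#' Variance in the exposure explained by a set of instruments
#'
#' Under SD-standardized traits and (post-clumping) independent instruments,
#' each variant explains `2 p (1 - p) beta^2` of the trait variance; the
#' total is their sum, clamped to `[0, 1)`. Residual LD below the clumping
#' threshold slightly inflates this sum; no correction is applied.
#'
#' @param x an `instrument_set`, a [sumstats] object, or a data.frame with
#'   columns `eaf` and `beta`.
#' @return fraction of variance explained.
#' @export
variance_explained <- function(x) {
  if (inherits(x, "instrument_set")) {
    eaf <- x$eaf; beta <- x$beta_exposure
  } else if (inherits(x, "sumstats")) {
    eaf <- x$records$eaf; beta <- x$records$beta
  } else {
    eaf <- x$eaf; beta <- x$beta
  }
  min(max(sum(2 * eaf * (1 - eaf) * beta^2), 0), 1 - 1e-12)
}

#' Bundle selected instruments with strength diagnostics
#'
#' @param stats a [sumstats] object holding the final instruments.
#' @return an object of class `instrument_set` with per-variant F
#'   statistics, their mean, and the variance explained.
#' @export
instrument_set <- function(stats) {
  rec <- stats$records
  f <- per_variant_f(rec$beta, rec$se)
  structure(list(variant_ids = rec$variant_id, beta_exposure = rec$beta,
                 se_exposure = rec$se, eaf = rec$eaf, pval = rec$pval,
                 n = rec$n, per_variant_F = f, mean_F = mean(f),
                 r2_explained = variance_explained(rec),
                 trait_name = stats$trait_name,
                 selection_log = stats$selection_log %||% empty_log()),
            class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  cat("Instrument set for ", x$trait_name, ": ", length(x$variant_ids),
      " variants, R2 = ", signif(x$r2_explained, 3),
      ", mean F = ", signif(x$mean_F, 4), "\n", sep = "")
  invisible(x)
}

#' Cragg-Donald F statistic for a univariable instrument set
#'
#' `F = R2 (n - J - 1) / (J (1 - R2))` where `J` is the number of
#' instruments and `R2` the variance they explain in the exposure. With a
#' single instrument this reduces to the per-variant F.
#'
#' @param instruments an `instrument_set`.
#' @param n exposure GWAS sample size; must exceed `J + 1`.
#' @return the F statistic.
#' @export
cragg_donald_f <- function(instruments, n) {
  J <- length(instruments$variant_ids)
  if (n <= J + 1) stop("sample size must exceed J + 1")
  R2 <- instruments$r2_explained
  R2 * (n - J - 1) / (J * (1 - R2))
}

#' Conditional F statistic for one exposure in a multivariable design
#'
#' Instrument strength for the indexed exposure conditional on the other
#' exposures, in the two-sample summary-statistic form: the indexed
#' exposure's instrument associations are regressed (no intercept, weights
#' `1/se^2` of the indexed exposure) on the other exposures' instrument
#' associations, and the weighted residual sum of squares is divided by
#' `J - k_other` degrees of freedom, where `k_other` is the number of
#' conditioning exposures. Cross-GWAS covariance is taken to be zero
#' (non-overlapping samples).
#'
#' @param harmonized a [harmonized_set] with at least two exposures and more
#'   instruments than exposures.
#' @param exposure_index column of `beta_exposure` to evaluate.
#' @return the conditional F statistic.
#' @export
conditional_f <- function(harmonized, exposure_index) {
  B <- harmonized$beta_exposure
  k <- ncol(B); J <- nrow(B)
  if (k < 2) stop("conditional F requires at least two exposures")
  if (J < k + 1) stop("more instruments than exposures required")
  bx <- B[, exposure_index]
  Bo <- B[, -exposure_index, drop = FALSE]
  w <- 1 / harmonized$se_exposure[, exposure_index]^2
  XtWX <- crossprod(Bo, w * Bo)
  if (rcond(XtWX) < 1e-12) stop("conditionally_weak: collinear exposure associations")
  gamma <- solve(XtWX, crossprod(Bo, w * bx))
  delta <- bx - as.numeric(Bo %*% gamma)
  Qx <- sum(w * delta^2)
  if (Qx < 1e-10 * sum(w * bx^2))
    stop("conditionally_weak: exposure associations are collinear")
  Qx / (J - (k - 1))
}
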