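# Shared internal helpers.

# 97.5% normal quantile used for all 95% confidence intervals.
Z95 <- 1.959964

# Two-sided p-value from a z-statistic, floored at the smallest positive
# normal double so that extreme associations keep a representable p > 0.
pval_from_z <- function(z) pmax(2 * stats::pnorm(-abs(z)), .Machine$double.xmin)

`%||%` <- function(a, b) if (is.null(a)) b else a

.COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

#' Complement alleles to the opposite strand
#'
#' @param x character vector of single-nucleotide alleles (A, C, G, T).
#' @return complemented alleles.
#' @keywords internal
flip_alleles <- function(x) unname(.COMPLEMENT[x])

#' Is a variant palindromic (strand-ambiguous)?
#'
#' A/T and C/G variants read the same on both strands, so the strand of an
#' external dataset cannot be resolved from the allele labels alone.
#'
#' @param a1,a2 effect and other allele.
#' @return logical vector.
#' @keywords internal
is_palindromic <- function(a1, a2) flip_alleles(a1) == a2

# Build an empty drop log.
empty_log <- function() {
  data.frame(variant_id = character(), stage = character(),
             reason = character(), stringsAsFactors = FALSE)
}

add_log <- function(log, ids, stage, reason) {
  if (!length(ids)) return(log)
  rbind(log, data.frame(variant_id = ids, stage = stage, reason = reason,
                        stringsAsFactors = FALSE))
}
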