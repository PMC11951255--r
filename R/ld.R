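#' Signed LD correlation matrix
#'
#' Container for a linkage-disequilibrium correlation matrix among variants.
#' Correlations are signed relative to each variant's stated effect allele,
#' as produced by reference-panel tools. The matrix must be symmetric with a
#' unit diagonal and positive semi-definite within a small tolerance.
#'
#' @param r square numeric matrix of correlations.
#' @param variant_ids character vector of variant identifiers, one per
#'   row/column of `r`. Taken from `dimnames(r)` when missing.
#' @param tol eigenvalue tolerance for the positive semi-definite check.
#' @return an object of class `ld_matrix`: the matrix with ids as dimnames.
#' @export
ld_matrix <- function(r, variant_ids = NULL, tol = 1e-8) {
  r <- as.matrix(r)
  if (is.null(variant_ids)) variant_ids <- rownames(r)
  if (is.null(variant_ids)) stop("variant_ids required")
  if (nrow(r) != ncol(r) || nrow(r) != length(variant_ids))
    stop("LD matrix must be square with one id per row")
  if (anyDuplicated(variant_ids)) stop("duplicate variant ids in LD matrix")
  if (max(abs(r - t(r))) > 1e-10) stop("LD matrix must be symmetric")
  r <- (r + t(r)) / 2
  if (max(abs(diag(r) - 1)) > 1e-10) stop("LD matrix must have unit diagonal")
  if (max(abs(r)) > 1 + 1e-10) stop("correlations must lie in [-1, 1]")
  ev <- eigen(r, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol) stop("LD matrix is not positive semi-definite")
  dimnames(r) <- list(variant_ids, variant_ids)
  class(r) <- c("ld_matrix", "matrix")
  r
}

ld_ids <- function(ld) rownames(ld)

# Subset an ld_matrix to the given ids, in order.
ld_subset <- function(ld, ids) {
  missing <- setdiff(ids, ld_ids(ld))
  if (length(missing))
    stop("variants absent from LD matrix: ", paste(missing, collapse = ", "))
  ld_matrix(unclass(ld)[ids, ids, drop = FALSE], ids)
}

#' Read an LD matrix from a text file
#'
#' Two layouts are accepted: a square whitespace-delimited matrix whose first
#' line is a header of variant ids, or a long-format triplet table
#' `(id1, id2, r)` from which the symmetric matrix is assembled (missing
#' pairs default to 0, the diagonal to 1).
#'
#' @param path file path.
#' @return an [ld_matrix].
#' @export
read_ld_matrix <- function(path) {
  first <- strsplit(trimws(readLines(path, n = 1)), "[ \t,]+")[[1]]
  long <- length(first) == 3 &&
    !is.na(suppressWarnings(as.numeric(first[3]))) &&
    is.na(suppressWarnings(as.numeric(first[1])))
  if (long) {
    tr <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                            col.names = c("id1", "id2", "r"))
    ids <- sort(unique(c(tr$id1, tr$id2)))
    m <- diag(length(ids))
    dimnames(m) <- list(ids, ids)
    for (i in seq_len(nrow(tr))) {
      m[tr$id1[i], tr$id2[i]] <- tr$r[i]
      m[tr$id2[i], tr$id1[i]] <- tr$r[i]
    }
    return(ld_matrix(m, ids))
  }
  m <- as.matrix(utils::read.table(path, header = TRUE, check.names = FALSE))
  ld_matrix(m, colnames(m))
}

#' Write an LD matrix as a square text table
#'
#' @param ld an [ld_matrix].
#' @param path file path.
#' @export
write_ld_matrix <- function(ld, path) {
  utils::write.table(format(unclass(ld), digits = 15, trim = TRUE),
                     path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
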