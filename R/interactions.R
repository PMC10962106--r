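#' Number of unordered SNP pairs
#'
#' `p * (p - 1) / 2`, the number of columns of the interaction design
#' `Z = X (*) X` (face-splitting product excluding self-products). Computed
#' in double precision, which is exact here: the products involved stay far
#' below 2^53 for any realistic `p` (hundreds of thousands of SNPs give
#' counts in the tens of billions).
#'
#' @param p number of SNPs (vectorized).
#' @return Exact pair count as a double.
#' @examples
#' n_pairs(346094) # 59,890,355,371 interactions
#' @export
n_pairs <- function(p) {
  if (any(p < 0)) stopf("p must be non-negative")
  p <- as.double(p)
  p * (p - 1) / 2
}

#' Canonical pair indexing
#'
#' Bijection between ordered pairs `(i, j)` with `1 <= i < j <= p` and linear
#' column indices `1 .. p(p-1)/2` of the interaction design, in row-major
#' upper-triangle order: `(1,2), (1,3), ..., (1,p), (2,3), ...`.
#'
#' @param i,j SNP indices (1-based, `i < j`); vectorized.
#' @param p number of SNPs.
#' @param k linear index in `1 .. p(p-1)/2`; vectorized.
#' @return `pair_to_index` returns linear indices (doubles, exact);
#'   `index_to_pair` returns a data frame with columns `i`, `j`.
#' @examples
#' pair_to_index(1, 2, p = 3) # 1
#' index_to_pair(3, p = 3)    # pair (2, 3)
#' @export
pair_to_index <- function(i, j, p) {
  if (any(i >= j)) stopf("pair indices require i < j")
  if (any(i < 1) || any(j > p)) stopf("pair indices out of range")
  i <- as.double(i); j <- as.double(j); p <- as.double(p)
  (i - 1) * p - i * (i - 1) / 2 + (j - i)
}

#' @rdname pair_to_index
#' @export
index_to_pair <- function(k, p) {
  if (any(k < 1) || any(k > n_pairs(p))) stopf("pair index out of range")
  k <- as.double(k); p <- as.double(p)
  # first index: largest i with (i-1)p - i(i-1)/2 < k, via the quadratic root
  i <- floor(p + 0.5 - sqrt((p - 0.5)^2 - 2 * (k - 1)))
  # guard against floating-point boundary slips
  base <- function(i) (i - 1) * p - i * (i - 1) / 2
  i <- ifelse(base(i) >= k, i - 1, i)
  i <- ifelse(base(i + 1) < k, i + 1, i)
  j <- k - base(i) + i
  data.frame(i = i, j = j)
}

#' Interaction column of a SNP pair
#'
#' Element-wise product of the raw dosage columns `i` and `j` of the
#' genotype matrix (before any standardization). Self-products are excluded
#' from the interaction design and rejected here.
#'
#' @param X a [genotype_matrix()] or plain dosage matrix.
#' @param i,j SNP indices with `i < j`.
#' @return Numeric length-`n` vector.
#' @export
interaction_column <- function(X, i, j) {
  v <- if (inherits(X, "genotype_matrix")) X$values else X
  if (i == j) stopf("self-products are excluded from the interaction design")
  if (i > j) stopf("pair indices require i < j")
  v[, i] * v[, j]
}

#' Minor allele frequency per SNP
#'
#' `min(f, 1 - f)` with `f` = mean dosage / ploidy (ploidy 1 for inbred
#' coding, 2 for outbred).
#'
#' @param X a [genotype_matrix()].
#' @return Numeric length-`p` vector in `[0, 0.5]`.
#' @export
compute_maf <- function(X) {
  f <- colMeans(X$values) / ploidy(X)
  pmin(f, 1 - f)
}

#' Minor interaction allele frequency (MIAF) of a SNP pair
#'
#' The analog of MAF for the interaction column: `min(f, 1 - f)` with `f`
#' the mean of the product column scaled by its maximum (`ploidy^2`). In
#' inbred coding this is the carrier frequency of the `(1, 1)` combination,
#' bounded above by both parents' carrier frequencies — the reason low-MAF
#' SNPs make interaction effects unobservable.
#'
#' @inheritParams interaction_column
#' @return A scalar in `[0, 0.5]`.
#' @export
compute_miaf <- function(X, i, j) {
  z <- interaction_column(X, i, j)
  f <- mean(z) / ploidy(X)^2
  min(f, 1 - f)
}

#' Filter SNPs by minor allele frequency
#'
#' Keeps SNPs with MAF strictly greater than `threshold` (the scan's default
#' prefilter is `MAF > 0.3`), preserving marker order. Idempotent.
#'
#' @param X a [genotype_matrix()].
#' @param threshold strict MAF cutoff in `[0, 0.5)`.
#' @return List with `genotypes` (filtered [genotype_matrix()]) and
#'   `report`, a `maf_report`: `maf` (all input SNPs), `kept` (indices into
#'   the input), `index_map` (original -> filtered position, `NA` if
#'   dropped).
#' @export
filter_by_maf <- function(X, threshold = 0.3) {
  if (threshold < 0 || threshold >= 0.5) stopf("threshold must be in [0, 0.5)")
  maf <- compute_maf(X)
  kept <- which(maf > threshold)
  if (length(kept) == 0)
    stopf("no SNPs survive the MAF > %g filter", threshold)
  index_map <- rep(NA_integer_, length(maf))
  index_map[kept] <- seq_along(kept)
  out <- genotype_matrix(X$values[, kept, drop = FALSE],
                         markers = X$markers[kept, , drop = FALSE],
                         individuals = X$individuals, mode = X$mode)
  report <- structure(list(maf = maf, kept = kept, index_map = index_map,
                           threshold = threshold), class = "maf_report")
  list(genotypes = out, report = report)
}

#' Write a MAF report as TSV
#'
#' @param report a `maf_report` from [filter_by_maf()].
#' @param X the genotype matrix the report was computed from (for marker ids).
#' @param path output file.
#' @export
write_maf_report <- function(report, X, path) {
  df <- data.frame(id = X$markers$id, chrom = X$markers$chrom,
                   pos = X$markers$pos, maf = report$maf,
                   kept = !is.na(report$index_map),
                   filtered_index = report$index_map)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
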