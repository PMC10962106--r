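#' Genotype matrix container
#'
#' A light container for an `n` individuals by `p` SNPs dosage matrix with
#' marker metadata. Two codings are supported: `"inbred"` (homozygous lines,
#' dosages in \{0, 1\}, ploidy treated as 1 for frequency purposes) and
#' `"outbred"` (diploid dosages in \{0, 1, 2\}).
#'
#' @param values integer matrix, `n x p`, entries in the declared coding set.
#' @param markers data frame with columns `chrom`, `pos` (1-based), `id`;
#'   defaults to a single synthetic chromosome.
#' @param individuals character vector of individual ids.
#' @param mode `"inbred"` or `"outbred"`.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `values`, `markers`, `individuals`, `mode`.
#' @export
genotype_matrix <- function(values, markers = NULL, individuals = NULL,
                            mode = c("inbred", "outbred")) {
  mode <- match.arg(mode)
  if (!is.matrix(values)) stopf("`values` must be a matrix")
  n <- nrow(values); p <- ncol(values)
  coding <- if (mode == "inbred") 0:1 else 0:2
  if (!all(values %in% coding))
    stopf("genotype entries outside the %s coding set {%s}",
          mode, paste(coding, collapse = ","))
  if (is.null(markers))
    markers <- data.frame(chrom = rep("1", p), pos = seq_len(p),
                          id = sprintf("snp%05d", seq_len(p)))
  if (nrow(markers) != p) stopf("markers rows (%d) != p (%d)", nrow(markers), p)
  if (any(markers$pos < 0)) stopf("marker positions must be non-negative")
  if (is.null(individuals)) individuals <- sprintf("ind%05d", seq_len(n))
  if (length(individuals) != n) stopf("individuals length != n")
  structure(list(values = values, markers = markers,
                 individuals = individuals, mode = mode),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d SNPs (%s coding)\n",
              nrow(x$values), ncol(x$values), x$mode))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$values)

ploidy <- function(X) if (X$mode == "inbred") 1L else 2L

#' Simulate a genotype matrix
#'
#' Draws dosages independently per entry: Bernoulli(`allele_freq`) in inbred
#' mode, Binomial(2, `allele_freq`) in outbred mode. With the default
#' frequency 0.5 this is the binomial 0.5 genotype model used throughout the
#' package's simulation studies.
#'
#' @param n,p number of individuals / SNPs.
#' @param allele_freq scalar or length-`p` vector of allele frequencies,
#'   strictly between 0 and 1.
#' @param mode coding, see [genotype_matrix()].
#' @param seed integer seed; generation is bit-reproducible given
#'   `(seed, n, p, allele_freq, mode)`.
#' @return A [genotype_matrix()].
#' @examples
#' X <- sample_genotypes(100, 20, seed = 1)
#' range(X$values)
#' @export
sample_genotypes <- function(n, p, allele_freq = 0.5,
                             mode = c("inbred", "outbred"), seed = 1) {
  mode <- match.arg(mode)
  if (!is_count(n) || !is_count(p) || n < 1 || p < 1)
    stopf("n and p must be positive counts")
  if (any(allele_freq <= 0) || any(allele_freq >= 1))
    stopf("allele_freq must lie strictly in (0, 1)")
  if (!length(allele_freq) %in% c(1L, p))
    stopf("allele_freq must be scalar or length p")
  size <- if (mode == "inbred") 1L else 2L
  freq <- rep(allele_freq, length.out = p)
  vals <- with_seed(seed, {
    matrix(rbinom(n * p, size, rep(freq, each = n)), nrow = n, ncol = p)
  })
  genotype_matrix(vals, mode = mode)
}

# ---- file formats ----------------------------------------------------------

#' Write / read a genotype matrix as a delimited table
#'
#' Layout: three marker header rows (`chrom`, `pos`, `id`) above the integer
#' dosage matrix, one row per individual, first column the individual id.
#'
#' @param X a [genotype_matrix()].
#' @param path output file.
#' @return `write_genotypes_tsv` returns `path` invisibly;
#'   `read_genotypes_tsv` returns a [genotype_matrix()].
#' @export
write_genotypes_tsv <- function(X, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste(c("#chrom", X$markers$chrom), collapse = "\t"),
    paste(c("#pos", X$markers$pos), collapse = "\t"),
    paste(c("#id", X$markers$id), collapse = "\t"),
    paste(c("#mode", X$mode, rep("", ncol(X$values) - 1)), collapse = "\t")
  ), con)
  write.table(cbind(X$individuals, as.data.frame(X$values)), con,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_genotypes_tsv
#' @export
read_genotypes_tsv <- function(path) {
  hdr <- readLines(path, n = 4)
  parts <- strsplit(hdr, "\t", fixed = TRUE)
  stopifnot(parts[[1]][1] == "#chrom")
  markers <- data.frame(chrom = parts[[1]][-1],
                        pos = as.integer(parts[[2]][-1]),
                        id = parts[[3]][-1])
  mode <- parts[[4]][2]
  body <- read.table(path, sep = "\t", skip = 4, header = FALSE,
                     colClasses = c("character", rep("integer", nrow(markers))))
  vals <- as.matrix(body[, -1, drop = FALSE])
  dimnames(vals) <- NULL
  genotype_matrix(vals, markers = markers,
                  individuals = body[[1]], mode = mode)
}

#' Write a minimal VCF
#'
#' One biallelic record per marker (REF `A`, ALT `T`), GT-only FORMAT;
#' inbred dosages are written as haploid genotypes, outbred as diploid.
#'
#' @inheritParams write_genotypes_tsv
#' @export
write_genotypes_vcf <- function(X, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", X$individuals), collapse = "\t")), con)
  gt <- if (X$mode == "inbred") {
    matrix(as.character(X$values), nrow = nrow(X$values))
  } else {
    m <- c("0/0", "0/1", "1/1")[X$values + 1L]
    matrix(m, nrow = nrow(X$values))
  }
  recs <- cbind(X$markers$chrom, X$markers$pos, X$markers$id, "A", "T", ".",
                ".", ".", "GT", t(gt))
  write.table(recs, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read genotypes from a VCF file
#'
#' Parses the GT field into dosages via \pkg{vcfR}. Multiallelic sites are
#' rejected. Haploid or fully homozygous calls yield inbred coding, otherwise
#' outbred.
#'
#' @param path a VCF file (uncompressed or gzipped).
#' @return A [genotype_matrix()].
#' @export
read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stopf("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- vcfR::getALT(v)
  if (any(grepl(",", alt, fixed = TRUE)))
    stopf("multiallelic sites are not supported")
  gt <- vcfR::extract.gt(v, element = "GT")
  count_alt <- function(g) {
    if (is.na(g)) return(NA_integer_)
    sum(strsplit(g, "[/|]")[[1]] == "1")
  }
  alleles <- vapply(gt, function(g) {
    if (is.na(g)) return(NA_integer_)
    length(strsplit(g, "[/|]")[[1]])
  }, integer(1))
  dose <- vapply(gt, count_alt, integer(1))
  dm <- matrix(dose, nrow = nrow(gt), dimnames = dimnames(gt))
  mode <- if (all(alleles == 1, na.rm = TRUE)) "inbred" else "outbred"
  if (mode == "outbred" && all(dm %in% c(0L, 2L, NA))) {
    dm <- dm / 2L
    mode <- "inbred"
  }
  fix <- vcfR::getFIX(v)
  markers <- data.frame(chrom = fix[, "CHROM"],
                        pos = as.integer(fix[, "POS"]), id = fix[, "ID"])
  if (anyNA(dm)) { # mean imputation, rounded back onto the coding grid
    for (j in seq_len(ncol(dm))) {
      miss <- is.na(dm[, j])
      if (any(miss)) dm[miss, j] <- round(mean(dm[, j], na.rm = TRUE))
    }
  }
  genotype_matrix(t(dm), markers = markers, individuals = colnames(gt),
                  mode = mode)
}

#' Write / read a phenotype table
#'
#' Two tab-separated columns: individual id and value. `NA` marks missing.
#'
#' @param y named numeric vector (names are individual ids).
#' @param path file path.
#' @param name phenotype name used as the value column header.
#' @export
write_phenotype <- function(y, path, name = "trait") {
  df <- data.frame(id = if (is.null(names(y))) seq_along(y) else names(y),
                   value = as.numeric(y))
  names(df)[2] <- name
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotype
#' @export
read_phenotype <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE)
  y <- as.numeric(df[[2]])
  names(y) <- as.character(df[[1]])
  y
}
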