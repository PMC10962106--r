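#' Random sketch matrix
#'
#' A seeded `m x d` random projection used to compress the normal equations
#' of the interaction regression. Entries are i.i.d. `N(0, 1/m)`
#' (`"gaussian"`), `+/- 1/sqrt(m)` (`"rademacher"`), or the exact identity
#' (`"identity"`, requires `m == d`; used to recover the uncompressed solver
#' in tests). The scaling makes `E[A'A] = I_d`, so decompressed estimates
#' are unbiased up to sketch distortion. The matrix is never stored: any
#' column subset is regenerated on demand from a counter-based per-column
#' RNG, so access is deterministic, random-order safe, and O(memory of the
#' requested chunk).
#'
#' @param m sketch (compressed) dimension, `1 <= m <= d`.
#' @param d number of columns (model terms) being sketched.
#' @param kind `"gaussian"`, `"rademacher"` or `"identity"`.
#' @param seed integer seed; the same seed reproduces the same matrix.
#' @return An object of class `sketch_matrix` (fields `m`, `d`, `kind`,
#'   `seed`).
#' @export
make_sketch <- function(m, d, kind = c("gaussian", "rademacher", "identity"),
                        seed = 1) {
  kind <- match.arg(kind)
  if (!is_count(m) || !is_count(d) || m < 1) stopf("m and d must be counts")
  if (m > d) stopf("sketch dimension m = %d exceeds d = %d", m, d)
  if (kind == "identity" && m != d) stopf("identity sketch requires m == d")
  structure(list(m = as.integer(m), d = as.double(d), kind = kind,
                 seed = as.integer(seed)), class = "sketch_matrix")
}

#' Materialize columns of a sketch matrix
#'
#' @param A a [make_sketch()] object.
#' @param cols column indices in `1 .. d`.
#' @return `m x length(cols)` numeric matrix.
#' @export
sketch_columns <- function(A, cols) {
  if (any(cols < 1) || any(cols > A$d)) stopf("sketch column out of range")
  if (A$kind == "identity") {
    out <- matrix(0, A$m, length(cols))
    out[cbind(as.integer(cols), seq_along(cols))] <- 1
    return(out)
  }
  .sketch_fill_cpp(A$m, as.double(cols) - 1, as.double(A$seed), A$kind,
                   FALSE)
}

#' @export
as.matrix.sketch_matrix <- function(x, ...) sketch_columns(x, seq_len(x$d))

#' @export
print.sketch_matrix <- function(x, ...) {
  cat(sprintf("sketch_matrix: %d x %.0f (%s, seed %d)\n",
              x$m, x$d, x$kind, x$seed))
  invisible(x)
}

# M A' for M given as an n x d matrix or as a column generator
# function(cols) -> n x |cols| matrix. Chunked so A is never materialized.
sketch_apply <- function(A, M, d = NULL, chunk = 2048L) {
  gen <- if (is.function(M)) M else function(cols) M[, cols, drop = FALSE]
  if (is.null(d)) {
    if (is.function(M)) stopf("d must be given with a column generator")
    d <- ncol(M)
  }
  if (d != A$d) stopf("sketch width (%.0f) does not match d (%.0f)", A$d, d)
  W <- NULL
  for (lo in seq(1, d, by = chunk)) {
    cols <- lo:min(lo + chunk - 1, d)
    Wc <- tcrossprod(gen(cols), sketch_columns(A, cols))
    W <- if (is.null(W)) Wc else W + Wc
  }
  W
}

#' Sketched Gram matrix
#'
#' Computes `A M'M A'` (the compressed Gram / kinship-style matrix of the
#' design block `M`) without materializing the `d x d` matrix `M'M`:
#' `W = M A'` is formed first at cost `O(n d m)`, then `W'W`.
#'
#' @param A a [make_sketch()] object with `A$d == ncol(M)`.
#' @param M `n x d` design block (or column generator, with `d` supplied).
#' @param d number of columns when `M` is a generator.
#' @param chunk column chunk size for the implicit product.
#' @return Symmetric positive semidefinite `m x m` matrix.
#' @export
sketch_gram <- function(A, M, d = NULL, chunk = 2048L) {
  crossprod(sketch_apply(A, M, d = d, chunk = chunk))
}
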