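#' Truth keys of an architecture
#'
#' Canonical term identifiers of all non-null effects of a simulated
#' architecture (quadratic terms map to their SNP's single key).
#'
#' @param arch an [architecture()].
#' @return Character vector of term ids (`"s<i>"`, `"p<i>:<j>"`).
#' @export
truth_keys <- function(arch) {
  unique(c(term_id("single", arch$simple$i), term_id("single", arch$quad$i),
           term_id("pair", arch$pairs$i, arch$pairs$j)))
}

#' Recall of the true terms among the top-k estimates
#'
#' `|top-k terms of the map that are true| / |truth|`. Ties at the top-k
#' boundary are resolved by the effect map's deterministic ordering; a truth
#' pair counts only on an exact `(i, j)` match.
#'
#' @param em an `effect_map`.
#' @param truth character vector of term ids (see [truth_keys()]) or an
#'   [architecture()].
#' @param k number of top-ranked terms considered (default 10).
#' @return Recall in `[0, 1]`.
#' @export
recall_top_k <- function(em, truth, k = 10L) {
  if (k < 1) stopf("k must be >= 1")
  if (inherits(truth, "architecture")) truth <- truth_keys(truth)
  if (length(truth) == 0) stopf("empty truth set")
  ids <- term_id(em$kind, em$i, em$j)[effect_order(em)]
  top <- ids[seq_len(min(k, length(ids)))]
  length(intersect(top, truth)) / length(truth)
}

#' Percent of true signals recovered in the top-k
#'
#' `100 * recall_top_k(em, truth, k)`, with the top-100 default used for
#' recovery summaries.
#'
#' @inheritParams recall_top_k
#' @export
recovery_percent <- function(em, truth, k = 100L) {
  100 * recall_top_k(em, truth, k)
}

#' Brute-force ranking oracle
#'
#' Exact regularized least squares on the fully materialized design of a
#' (small) term set: standardized columns, ridge solve of the `d x d`
#' normal equations (OLS when `lambda = 0`), estimates rescaled to the raw
#' coding and ranked by `|coefficient|`. Used as the uncompressed reference
#' for the sketched solver.
#'
#' @inheritParams solve_block
#' @param lambda ridge penalty on the standardized scale (default 0, i.e.
#'   OLS, which requires `n > d`).
#' @return An `effect_map` (same shape as [solve_block()] output).
#' @export
brute_force_rank <- function(X, Y, terms = NULL, lambda = 0) {
  v <- X$values
  if (nrow(v) < 2) stopf("need at least two individuals")
  if (is.null(terms)) {
    p <- ncol(v)
    ij <- index_to_pair(seq_len(n_pairs(p)), p)
    terms <- make_terms(singles = seq_len(p), pairs = ij)
  }
  if (nrow(terms) > 1e5) stopf("term set too large for brute force")
  M <- term_cols(v, terms)
  sds <- apply(M, 2, sd)
  keep <- sds > 0
  Ms <- scale(M[, keep, drop = FALSE])
  Yc <- Y - mean(Y)
  G <- crossprod(Ms)
  diag(G) <- diag(G) + lambda
  th_std <- drop(solve(G, crossprod(Ms, Yc)))
  theta <- numeric(nrow(terms))
  theta[keep] <- th_std / sds[keep]
  new_effect_map(data.frame(kind = terms$kind, i = terms$i, j = terms$j,
                            theta = theta), p = ncol(v))
}

#' Evaluate a scan against a truth sidecar
#'
#' @param em an `effect_map`.
#' @param truth an [architecture()], truth JSON path, or term-id vector.
#' @param top k values at which recall is reported.
#' @return Data frame with columns `k`, `recall`, `recovery_percent`.
#' @export
evaluate_scan <- function(em, truth, top = c(5L, 10L, 100L)) {
  if (is.character(truth) && length(truth) == 1 && file.exists(truth))
    truth <- read_architecture(truth)
  if (inherits(truth, "architecture")) truth <- truth_keys(truth)
  data.frame(k = top,
             recall = vapply(top, function(k) recall_top_k(em, truth, k),
                             numeric(1)),
             recovery_percent = vapply(top, function(k)
               recovery_percent(em, truth, k), numeric(1)))
}
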