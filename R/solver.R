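#' Solver configuration
#'
#' Parameters of the sketched (model-compressed) ridge solver.
#'
#' * `sketch_dim` (m): compressed dimension. When `NULL`, each block uses
#'   `min(d, ceil(c_sketch * k_max * log(d)))` for its own term count `d` —
#'   the standard compressed-sensing budget `m ~ k log(d)` with default
#'   `c_sketch = 8` and sparsity budget `k_max = 50`.
#' * `n_sketches` (S): independent sketches averaged; the averaging breaks
#'   sketch-specific aliasing between coordinates and shrinks its variance
#'   like `1/S`.
#' * `lambda`: ridge penalty in the compressed space; `NULL` uses
#'   `0.1 * trace(A M'M A') / m`, i.e. a tenth of the mean compressed
#'   eigenvalue, recomputed per sketch.
#' * `n_star`: retained top effects (the sparsity budget of the final
#'   support).
#' * `block_size`: SNPs per block axis in genome-scale scans.
#'
#' @param block_size SNPs per block axis (default 500).
#' @param sketch_dim compressed dimension m, or `NULL` for the formula above.
#' @param n_sketches number of averaged sketches S (default 2).
#' @param lambda ridge penalty; `NULL` for the trace heuristic, or `"cv"`
#'   for 5-fold cross-validated selection by held-out prediction error in
#'   the compressed space.
#' @param n_star retained top effects (default 50).
#' @param standardize center/scale term columns before solving (default TRUE;
#'   estimates are always reported on the raw dosage scale).
#' @param sketch_kind `"gaussian"` (default) or `"rademacher"`.
#' @param decompress read-out mode of [solve_compressed_ridge()]:
#'   `"exact"` (default; the sketch compresses only the Gram/kinship
#'   computation, estimates are exact correlations with the dual weights)
#'   or `"sketch"` (back-projection `A'c`).
#' @param c_sketch,k_max constants of the default sketch-dimension formula.
#' @param chunk term-column chunk size for implicit products.
#' @param seed root seed; per-sketch and per-permutation seeds are derived
#'   deterministically from it.
#' @return A list of class `solver_config`.
#' @export
solver_config <- function(block_size = 500L, sketch_dim = NULL,
                          n_sketches = 2L, lambda = NULL, n_star = 50L,
                          standardize = TRUE, sketch_kind = "gaussian",
                          decompress = c("exact", "sketch"),
                          c_sketch = 8, k_max = 50L, chunk = 4096L,
                          seed = 1L) {
  decompress <- match.arg(decompress)
  stopifnot(block_size >= 1, n_sketches >= 1, n_star >= 1, chunk >= 1)
  if (!is.null(lambda) && !identical(lambda, "cv") && lambda < 0)
    stopf("lambda must be >= 0")
  structure(list(block_size = as.integer(block_size), sketch_dim = sketch_dim,
                 n_sketches = as.integer(n_sketches), lambda = lambda,
                 n_star = as.integer(n_star), standardize = standardize,
                 sketch_kind = sketch_kind, decompress = decompress,
                 c_sketch = c_sketch,
                 k_max = as.integer(k_max), chunk = as.integer(chunk),
                 seed = as.integer(seed)), class = "solver_config")
}

default_sketch_dim <- function(d, config) {
  m <- config$sketch_dim
  if (is.null(m)) m <- ceiling(config$c_sketch * config$k_max * log(d))
  as.integer(min(m, d))
}

#' Sketched ridge solve in the compressed space
#'
#' Solves the regularized least-squares problem after random projection:
#' computes `c = (A M'M A' + lambda I_m)^{-1} A M' Y` in the m-dimensional
#' compressed space and decompresses `theta = A' c`. The Gram factor is
#' formed implicitly through `W = M A'` (cost `O(n d m)`); when `m > n` the
#' algebraically identical dual form `c = W'(W W' + lambda I_n)^{-1} Y` is
#' used so the linear solve is `O(n^3)` instead of `O(m^3)`.
#'
#' Two decompression modes exist. `"sketch"` (the default) returns
#' `theta = A'c`: cheap, but each coordinate picks up zero-mean cross-talk
#' from every other coordinate through `A'A`, with standard deviation of
#' order `|theta|_2 / sqrt(m)` summed over the solved term set. `"exact"`
#' exploits the dual weights `alpha = (W W' + lambda I)^{-1} Y` of the
#' sketched-kinship system (`W W'` is the compressed Gram/kinship estimate)
#' and returns `theta = M' alpha` in one exact `O(n d)` pass: the sketch
#' then only approximates the kinship matrix, not the read-out, which is
#' what makes genome-scale term sets feasible. The dual weights are
#' computed by ridge restricted to the rank-`m` captured subspace (via the
#' eigendecomposition of `W'W`), which reduces to ordinary ridge exactly in
#' the identity-sketch limit.
#'
#' @param M `n x d` design matrix, or a column generator `function(cols)`
#'   returning `n x |cols|` blocks (then `d` must be given).
#' @param Y response vector (centered by the caller when appropriate).
#' @param A a [make_sketch()] with `A$d == d`.
#' @param lambda ridge penalty; `NULL` uses `0.1 * trace(W'W) / m`. A
#'   singular system with `lambda = 0` raises an error.
#' @param d number of model terms when `M` is a generator.
#' @param chunk chunk size for implicit products.
#' @param decompress `"sketch"` (`theta = A'c`) or `"exact"`
#'   (`theta = M' alpha`).
#' @return Length-`d` estimate `theta`, with attributes `compressed` (the
#'   m-vector `c`) and `lambda`.
#' @export
solve_compressed_ridge <- function(M, Y, A, lambda = NULL, d = NULL,
                                   chunk = 2048L,
                                   decompress = c("sketch", "exact")) {
  decompress <- match.arg(decompress)
  gen <- if (is.function(M)) M else function(cols) M[, cols, drop = FALSE]
  if (is.null(d)) d <- if (is.function(M)) A$d else ncol(M)
  fit <- compressed_fit(gen, Y, A, lambda, d, chunk, decompress)
  theta <- numeric(d)
  if (decompress == "exact") {
    for (lo in seq(1, d, by = chunk)) {
      cols <- lo:min(lo + chunk - 1, d)
      theta[cols] <- drop(crossprod(gen(cols), fit$alpha))
    }
  } else {
    for (lo in seq(1, d, by = chunk)) {
      cols <- lo:min(lo + chunk - 1, d)
      theta[cols] <- drop(crossprod(sketch_columns(A, cols), fit$cvec))
    }
  }
  attr(theta, "compressed") <- fit$cvec
  attr(theta, "lambda") <- fit$lambda
  attr(theta, "alpha") <- fit$alpha
  theta
}

# compressed-space fit: forms W = M A' and solves for the compressed
# coefficients c and (exact mode) the dual weights alpha
compressed_fit <- function(gen, Y, A, lambda, d, chunk, decompress) {
  n <- length(Y)
  W <- sketch_apply(A, gen, d = d, chunk = chunk)
  m <- A$m
  if (identical(lambda, "cv")) lambda <- cv_lambda(W, Y, A$seed)
  if (is.null(lambda)) lambda <- 0.1 * sum(W * W) / m
  alpha <- NULL
  cvec <- tryCatch({
    if (decompress == "exact") {
      # ridge restricted to the sketch-captured subspace: with W = U S V'
      # the dual weights are alpha = U (S^2 + lambda)^{-1} U' Y, so the null
      # space of the rank-limited kernel estimate never contributes (it
      # would otherwise inject Y_perp / lambda noise). Closed forms by rank
      # side: m >= n, W W' is full rank and alpha = (W W' + lambda I)^{-1} Y;
      # m < n, alpha = W (G (G + lambda I))^{-1} W'Y with G = W'W.
      alpha <- if (m >= n) {
        K <- tcrossprod(W)
        diag(K) <- diag(K) + lambda
        drop(solve(K, Y))
      } else {
        G <- crossprod(W)
        Gl <- G
        diag(Gl) <- diag(Gl) + lambda
        drop(W %*% solve(G, solve(Gl, crossprod(W, Y))))
      }
      drop(crossprod(W, alpha)) # c = W' alpha
    } else if (m <= n) {
      G <- crossprod(W)
      diag(G) <- diag(G) + lambda
      solve(G, crossprod(W, Y))
    } else {
      K <- tcrossprod(W)
      diag(K) <- diag(K) + lambda
      crossprod(W, solve(K, Y))
    }
  }, error = function(e) {
    stopf("compressed system is singular (lambda = %g): %s; use lambda > 0",
          lambda, conditionMessage(e))
  })
  list(cvec = drop(cvec), alpha = alpha, lambda = lambda)
}

# 5-fold cross-validated ridge penalty, selected by held-out prediction
# error entirely in the compressed space (the sketched features W), so the
# selection costs O(n m^2) regardless of d. Grid: multiples of the mean
# compressed eigenvalue trace(W'W)/m.
cv_lambda <- function(W, Y, seed, grid_mult = c(0.01, 0.03, 0.1, 0.3, 1, 3,
                                               10)) {
  n <- length(Y)
  m <- ncol(W)
  base <- sum(W * W) / m
  grid <- base * grid_mult
  folds <- with_seed(derive_seed(seed, 777L), sample(rep_len(1:5, n)))
  err <- numeric(length(grid))
  for (f in 1:5) {
    tr <- folds != f
    G <- crossprod(W[tr, , drop = FALSE])
    wty <- crossprod(W[tr, , drop = FALSE], Y[tr])
    for (g in seq_along(grid)) {
      Gl <- G
      diag(Gl) <- diag(Gl) + grid[g]
      cv <- tryCatch(solve(Gl, wty), error = function(e) NULL)
      err[g] <- err[g] + if (is.null(cv)) Inf else
        sum((Y[!tr] - W[!tr, , drop = FALSE] %*% cv)^2)
    }
  }
  grid[which.min(err)]
}

#' Average the sketched estimate over independent sketches
#'
#' Runs [solve_compressed_ridge()] under `S = config$n_sketches` independent
#' sketches (seeds derived from `config$seed`) and returns the coordinate-wise
#' mean. Averaging suppresses the zero-mean cross-talk each single sketch
#' introduces between coordinates. When the configured sketch dimension
#' reaches `d` there is nothing to compress and the exact (identity-sketch)
#' ridge solution is returned directly.
#'
#' @inheritParams solve_compressed_ridge
#' @param config a [solver_config()].
#' @return Length-`d` averaged estimate.
#' @export
average_over_sketches <- function(M, Y, config, d = NULL) {
  if (is.null(d)) {
    if (is.function(M)) stopf("d must be given with a column generator")
    d <- ncol(M)
  }
  m <- default_sketch_dim(d, config)
  if (m >= d) { # no compression needed: solve exactly, once
    A <- make_sketch(d, d, kind = "identity")
    return(as.numeric(solve_compressed_ridge(M, Y, A, lambda = config$lambda,
                                             d = d, chunk = config$chunk)))
  }
  gen <- if (is.function(M)) M else function(cols) M[, cols, drop = FALSE]
  if (config$decompress == "exact") {
    # the read-out is linear in the dual weights, so S sketches need only
    # one O(n d) decompression pass over the mean weights
    abar <- numeric(length(Y))
    for (s in seq_len(config$n_sketches)) {
      A <- make_sketch(m, d, kind = config$sketch_kind,
                       seed = derive_seed(config$seed, 101L, s))
      fit <- compressed_fit(gen, Y, A, config$lambda, d, config$chunk,
                            "exact")
      abar <- abar + fit$alpha
    }
    abar <- abar / config$n_sketches
    theta <- numeric(d)
    for (lo in seq(1, d, by = config$chunk)) {
      cols <- lo:min(lo + config$chunk - 1, d)
      theta[cols] <- drop(crossprod(gen(cols), abar))
    }
    return(theta)
  }
  acc <- numeric(d)
  for (s in seq_len(config$n_sketches)) {
    A <- make_sketch(m, d, kind = config$sketch_kind,
                     seed = derive_seed(config$seed, 101L, s))
    th <- solve_compressed_ridge(M, Y, A, lambda = config$lambda, d = d,
                                 chunk = config$chunk,
                                 decompress = config$decompress)
    acc <- acc + as.numeric(th)
  }
  acc / config$n_sketches
}

# ---- term sets and effect maps --------------------------------------------

#' Term set constructor
#'
#' A term set is a data frame with columns `kind` (`"single"`/`"pair"`),
#' `i`, `j` (`NA` for singles) enumerating the model terms a block solves.
#'
#' @param singles vector of SNP indices entering as additive terms.
#' @param pairs data frame with columns `i`, `j` (`i < j`).
#' @return Term set data frame.
#' @export
make_terms <- function(singles = integer(), pairs = NULL) {
  a <- if (length(singles))
    data.frame(kind = "single", i = as.integer(singles), j = NA_integer_)
  else NULL
  b <- if (!is.null(pairs) && nrow(pairs))
    data.frame(kind = "pair", i = as.integer(pairs$i), j = as.integer(pairs$j))
  else NULL
  out <- rbind(a, b)
  if (is.null(out)) stopf("term set is empty")
  if (any(out$kind == "pair" & out$i >= out$j)) stopf("pairs require i < j")
  if (anyDuplicated(term_id(out$kind, out$i, out$j))) stopf("duplicate terms")
  out
}

# raw term columns for a slice of a term set (C++ kernel; v must be double)
term_cols <- function(v, tt) {
  if (!is.double(v)) storage.mode(v) <- "double"
  j <- ifelse(tt$kind == "pair", tt$j, 0L)
  .term_chunk_cpp(v, as.integer(tt$i), as.integer(j),
                  numeric(nrow(tt)), numeric(nrow(tt)), FALSE)
}

# column means and sds over a term set. For moderate p the pair moments
# come from two p x p crossprods (mean(x_i x_j) = (X'X)_ij / n and
# mean((x_i x_j)^2) = (V'V)_ij / n with V = X^2), avoiding a full pass over
# the materialized columns; otherwise fall back to chunked accumulation.
term_stats <- function(v, ivec, jvec, chunk) {
  d <- length(ivec)
  n <- nrow(v)
  p <- ncol(v)
  if (p <= 3000) {
    C1 <- crossprod(v) / n
    v2 <- v * v
    C2 <- crossprod(v2) / n
    m1 <- colMeans(v); m2 <- colMeans(v2)
    single <- jvec == 0L
    mu <- ifelse(single, m1[ivec], C1[cbind(ivec, pmax(jvec, 1L))])
    s2 <- ifelse(single, m2[ivec], C2[cbind(ivec, pmax(jvec, 1L))])
  } else {
    mu <- numeric(d); s2 <- numeric(d)
    zero <- numeric(chunk)
    for (lo in seq(1, d, by = chunk)) {
      cols <- lo:min(lo + chunk - 1, d)
      Z <- .term_chunk_cpp(v, ivec[cols], jvec[cols], zero, zero, FALSE)
      mu[cols] <- colMeans(Z)
      s2[cols] <- colMeans(Z * Z)
    }
  }
  list(mean = mu, sd = sqrt(pmax(0, (s2 - mu^2) * n / (n - 1))))
}

new_effect_map <- function(df, p, config = NULL) {
  rownames(df) <- NULL
  structure(df, class = c("effect_map", "data.frame"), p = p, config = config)
}

#' @export
print.effect_map <- function(x, ...) {
  cat(sprintf("effect_map: %d terms (%d singles, %d pairs), p = %d\n",
              nrow(x), sum(x$kind == "single"), sum(x$kind == "pair"),
              attr(x, "p")))
  print(head(as.data.frame(x[order(-abs(x$theta)), ]), 10))
  invisible(x)
}

# deterministic ranking: by |theta| descending, ties by (kind, i, j)
effect_order <- function(em) {
  order(-abs(em$theta), em$kind, em$i, em$j)
}

#' Solve one block of terms with the sketched ridge estimator
#'
#' Standardizes the term columns (centering and unit variance), centers `Y`,
#' runs [average_over_sketches()], and reports the per-term signed estimates
#' rescaled to the raw dosage coding (so `theta` reads as the effect of the
#' variant, or variant combination, against the reference coding).
#' All-constant term columns are excluded with a message and reported with
#' `theta = 0`.
#'
#' @param X a [genotype_matrix()].
#' @param Y phenotype vector aligned with the rows of `X`.
#' @param terms a term set from [make_terms()]; `NULL` means all singles
#'   plus all pairs of `X`.
#' @param config a [solver_config()].
#' @return An `effect_map`: data frame `(kind, i, j, theta)` with attribute
#'   `p`.
#' @export
solve_block <- function(X, Y, terms = NULL, config = solver_config()) {
  v <- X$values
  if (!is.double(v)) storage.mode(v) <- "double"
  if (length(Y) != nrow(v)) stopf("Y length does not match individuals")
  if (var(Y) == 0) stopf("constant phenotype")
  if (is.null(terms)) {
    p <- ncol(v)
    ij <- index_to_pair(seq_len(n_pairs(p)), p)
    terms <- make_terms(singles = seq_len(p), pairs = ij)
  }
  ivec <- as.integer(terms$i)
  jvec <- as.integer(ifelse(terms$kind == "pair", terms$j, 0L))
  st <- term_stats(v, ivec, jvec, config$chunk)
  keep <- st$sd > 0
  if (!all(keep))
    message(sprintf("solve_block: excluding %d constant term column(s)",
                    sum(!keep)))
  ik <- ivec[keep]; jk <- jvec[keep]
  Yc <- Y - mean(Y)
  gen <- if (config$standardize) {
    mu <- st$mean[keep]; sds <- st$sd[keep]
    function(cols) .term_chunk_cpp(v, ik[cols], jk[cols], mu[cols],
                                   sds[cols], TRUE)
  } else {
    zero <- numeric(config$chunk)
    function(cols) .term_chunk_cpp(v, ik[cols], jk[cols], zero, zero, FALSE)
  }
  th_std <- average_over_sketches(gen, Yc, config, d = sum(keep))
  theta <- numeric(nrow(terms))
  theta[keep] <- if (config$standardize) th_std / st$sd[keep] else th_std
  new_effect_map(data.frame(kind = terms$kind, i = terms$i, j = terms$j,
                            theta = theta),
                 p = ncol(v), config = config)
}

#' Top-N* support selection
#'
#' Restricts an effect map to its `n_star` largest effects by `|theta|`
#' (ties broken lexicographically by `(kind, i, j)`), attaching
#' `support_score = |theta|` on the selected terms — the "support times
#' absolute effect" display used for scan results.
#'
#' @param em an `effect_map`.
#' @param n_star number of retained effects (default 50, the sparsity budget
#'   under which estimates in the very-high-dimensional regime stay
#'   reliable).
#' @return An `effect_map` with at most `n_star` rows, ranked, with a
#'   `support_score` column.
#' @export
top_n_support <- function(em, n_star = 50L) {
  if (n_star < 1) stopf("n_star must be >= 1")
  if (n_star > nrow(em)) {
    warning(sprintf("n_star = %d exceeds the %d available terms; keeping all",
                    n_star, nrow(em)), call. = FALSE)
    n_star <- nrow(em)
  }
  out <- em[effect_order(em), , drop = FALSE][seq_len(n_star), , drop = FALSE]
  out$support_score <- abs(out$theta)
  new_effect_map(out, attr(em, "p"), attr(em, "config"))
}

#' Permutation threshold on |theta|
#'
#' Null calibration of the scan: permutes `Y` `n_perm` times, re-runs the
#' block solver, records the maximum `|theta|` per permutation, and returns
#' the requested quantile of these maxima. Observed effects above the
#' threshold are "emerging from the noise".
#'
#' @inheritParams solve_block
#' @param n_perm number of permutations (>= 20).
#' @param q quantile of the permutation maxima (default 0.95).
#' @return Scalar threshold, with attribute `maxima` (the `n_perm` maxima).
#' @export
permutation_threshold <- function(X, Y, terms = NULL,
                                  config = solver_config(), n_perm = 100L,
                                  q = 0.95) {
  if (n_perm < 20) stopf("n_perm must be >= 20")
  n <- length(Y)
  maxima <- vapply(seq_len(n_perm), function(b) {
    Yp <- with_seed(derive_seed(config$seed, 555L, b), Y[sample.int(n)])
    em <- solve_block(X, Yp, terms = terms, config = config)
    max(abs(em$theta))
  }, numeric(1))
  out <- unname(quantile(maxima, q))
  attr(out, "maxima") <- maxima
  out
}

#' Serialize an effect map as TSV
#'
#' Columns: term kind, the two marker coordinates (1-based positions,
#' written with `(chrom_i, pos_i) <= (chrom_j, pos_j)`; singles leave the
#' second coordinate empty), `theta` and `support_score`.
#'
#' @param em an `effect_map` (ranked rows are written as ranked).
#' @param X the genotype matrix the scan ran on (marker coordinates).
#' @param path output file.
#' @export
write_effect_map <- function(em, X, path) {
  mk <- X$markers
  df <- data.frame(kind = em$kind, idx_i = em$i, idx_j = em$j,
                   chrom_i = mk$chrom[em$i], pos_i = mk$pos[em$i],
                   id_i = mk$id[em$i],
                   chrom_j = ifelse(is.na(em$j), "", mk$chrom[em$j]),
                   pos_j = ifelse(is.na(em$j), NA, mk$pos[em$j]),
                   id_j = ifelse(is.na(em$j), "", mk$id[em$j]),
                   theta = em$theta)
  if (!is.null(em$support_score)) df$support_score <- em$support_score
  swap <- df$kind == "pair" &
    (df$chrom_j < df$chrom_i |
       (df$chrom_j == df$chrom_i & df$pos_j < df$pos_i))
  if (any(swap)) {
    tmp <- df[swap, c("chrom_i", "pos_i", "id_i")]
    df[swap, c("chrom_i", "pos_i", "id_i")] <-
      df[swap, c("chrom_j", "pos_j", "id_j")]
    df[swap, c("chrom_j", "pos_j", "id_j")] <- tmp
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an effect map written by [write_effect_map()]
#'
#' @param path TSV file.
#' @param p number of SNPs of the originating scan.
#' @return An `effect_map`.
#' @export
read_effect_map <- function(path, p) {
  df <- read.table(path, sep = "\t", header = TRUE)
  em <- data.frame(kind = df$kind, i = df$idx_i, j = df$idx_j,
                   theta = df$theta)
  if (!is.null(df$support_score)) em$support_score <- df$support_score
  new_effect_map(em, p = p)
}
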