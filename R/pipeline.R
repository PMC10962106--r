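#' Block decomposition of the upper-triangle scan
#'
#' Splits the `p` SNPs into contiguous blocks of at most `block_size` SNPs.
#' The scan is then organized as diagonal pieces (a block's singles plus its
#' intra-block pairs, solved jointly) and off-diagonal pieces (all cross
#' pairs between two blocks), covering every SNP pair exactly once.
#'
#' @param p number of SNPs.
#' @param block_size SNPs per block axis.
#' @return A `block_plan`: list with `blocks` (list of index vectors),
#'   `off` (data frame of block-pair indices `a < b`), `p`, `block_size`.
#' @export
plan_blocks <- function(p, block_size = 500L) {
  if (block_size < 1) stopf("block_size must be >= 1")
  nb <- ceiling(p / block_size)
  blocks <- split(seq_len(p), ceiling(seq_len(p) / block_size))
  off <- if (nb > 1) {
    ij <- index_to_pair(seq_len(n_pairs(nb)), nb)
    data.frame(a = ij$i, b = ij$j)
  } else data.frame(a = integer(), b = integer())
  structure(list(blocks = unname(blocks), off = off, p = p,
                 block_size = as.integer(block_size)), class = "block_plan")
}

block_pairs_within <- function(idx) {
  if (length(idx) < 2) return(data.frame(i = integer(), j = integer()))
  cmb <- utils::combn(idx, 2)
  data.frame(i = cmb[1, ], j = cmb[2, ])
}

block_pairs_cross <- function(ia, ib) {
  eg <- expand.grid(i = ia, j = ib)
  eg[order(eg$i, eg$j), , drop = FALSE]
}

#' One-dimensional (additive) scan
#'
#' Sketched ridge estimates for all single-SNP terms jointly.
#'
#' @param X a MAF-filtered [genotype_matrix()].
#' @param Y phenotype aligned to the rows of `X`.
#' @param config a [solver_config()].
#' @return An `effect_map` over the `p` singles.
#' @export
run_1d <- function(X, Y, config = solver_config()) {
  solve_block(X, Y, make_terms(singles = seq_len(ncol(X$values))), config)
}

#' Full two-dimensional scan
#'
#' Three stages:
#' \enumerate{
#' \item a genome-wide singles pass (identical to [run_1d()]) supplies the
#'   diagonal estimates — estimating singles jointly with the far more
#'   numerous pair columns would let the minimum-norm solution spread a
#'   single SNP's signal over its `~p` correlated product columns;
#' \item the block plan is iterated for pairs: each diagonal block solves
#'   its intra-block pairs, each off-diagonal block its cross pairs, in
#'   both cases with the involved SNPs' singles included as covariate terms
#'   (absorbing the main-effect content of the raw-coding products) but
#'   reported only from the singles pass, so every term is reported exactly
#'   once;
#' \item the pooled top-`n_star` support is re-estimated by a joint
#'   hierarchical least-squares debiasing fit on the materialized support
#'   columns (`debias = TRUE`, the default; see [debias_support()]),
#'   putting singles and pairs on one unbiased scale.
#' }
#'
#' @inheritParams run_1d
#' @param floor_keep retain at most this many terms, by `|theta|` (maps at
#'   the full genome scale are otherwise too large to persist); default 1e6.
#' @param debias re-estimate the pooled top-`n_star` support by joint OLS.
#' @return An `effect_map` over all singles and pairs (up to `floor_keep`).
#' @export
run_2d <- function(X, Y, config = solver_config(), floor_keep = 1e6,
                   debias = TRUE) {
  p <- ncol(X$values)
  if (length(Y) != nrow(X$values)) stopf("Y length does not match individuals")
  plan <- plan_blocks(p, config$block_size)
  frags <- vector("list", 1 + length(plan$blocks) + nrow(plan$off))
  frags[[1]] <- as.data.frame(run_1d(X, Y, config))
  for (b in seq_along(plan$blocks)) {
    idx <- plan$blocks[[b]]
    prs <- block_pairs_within(idx)
    if (nrow(prs) == 0) next
    terms <- make_terms(singles = idx, pairs = prs)
    cfg <- config; cfg$seed <- derive_seed(config$seed, 11L, b)
    em <- as.data.frame(solve_block(X, Y, terms, cfg))
    frags[[1 + b]] <- em[em$kind == "pair", , drop = FALSE]
  }
  for (r in seq_len(nrow(plan$off))) {
    ia <- plan$blocks[[plan$off$a[r]]]
    ib <- plan$blocks[[plan$off$b[r]]]
    terms <- make_terms(singles = c(ia, ib), pairs = block_pairs_cross(ia, ib))
    cfg <- config; cfg$seed <- derive_seed(config$seed, 13L, r)
    em <- as.data.frame(solve_block(X, Y, terms, cfg))
    frags[[1 + length(plan$blocks) + r]] <- em[em$kind == "pair", ,
                                               drop = FALSE]
  }
  out <- do.call(rbind, frags)
  em <- new_effect_map(out, p = p, config = config)
  if (debias) em <- debias_support(X, Y, em, config$n_star)
  if (nrow(em) > floor_keep) {
    ord <- effect_order(em)
    em <- new_effect_map(as.data.frame(em)[sort(ord[seq_len(floor_keep)]), ],
                         p = p, config = config)
  }
  em
}

#' Joint re-estimation of the selected support
#'
#' Replaces the sketched estimates of the top-`n_star` singles and the
#' top-`n_star` pairs of a map (pooled per kind, because the two passes are
#' on different noise scales) with coefficients from one joint hierarchical
#' least-squares fit on the materialized support columns: pair columns are
#' first residualized against the support singles, then `Y` is regressed on
#' singles plus residualized pairs. Singles therefore report total main
#' effects (including the main-effect content of raw-coding interactions)
#' and pairs report pure interaction coefficients — for a planted raw
#' product effect `theta * x_i * x_j` the pair coefficient is `theta`
#' itself. The residualization also keeps the fit well-conditioned when the
#' selected pairs crowd around one strong SNP's product columns, where a
#' naive joint OLS would be nearly collinear. Selection bias ("winner's
#' curse") and compression attenuation are removed for the retained terms;
#' non-selected terms keep their sketched values.
#'
#' @inheritParams run_1d
#' @param em an `effect_map`.
#' @param n_star support size per term kind to re-estimate.
#' @return The `effect_map` with debiased `theta` on the support.
#' @export
debias_support <- function(X, Y, em, n_star = 50L) {
  v <- X$values
  if (!is.double(v)) storage.mode(v) <- "double"
  df <- as.data.frame(em)[effect_order(em), ]
  sing <- df[df$kind == "single", ][seq_len(min(n_star,
                                                sum(df$kind == "single"))), ]
  prs <- df[df$kind == "pair", ][seq_len(min(n_star,
                                             sum(df$kind == "pair"))), ]
  Xs <- cbind(1, v[, sing$i, drop = FALSE])
  th_s <- numeric(nrow(sing))
  th_p <- numeric(0)
  if (nrow(prs)) {
    P <- v[, prs$i, drop = FALSE] * v[, prs$j, drop = FALSE]
    Pres <- lm.fit(Xs, P)$residuals
    if (is.null(dim(Pres))) Pres <- matrix(Pres, ncol = 1)
    fit <- lm.fit(cbind(Xs, Pres), Y)
    cf <- fit$coefficients
    cf[is.na(cf)] <- 0
    th_s <- cf[1 + seq_len(nrow(sing))]
    th_p <- cf[1 + nrow(sing) + seq_len(nrow(prs))]
  } else {
    cf <- lm.fit(Xs, Y)$coefficients
    cf[is.na(cf)] <- 0
    th_s <- cf[-1]
  }
  ids_em <- term_id(em$kind, em$i, em$j)
  em$theta[match(term_id("single", sing$i), ids_em)] <- unname(th_s)
  if (nrow(prs))
    em$theta[match(term_id("pair", prs$i, prs$j), ids_em)] <- unname(th_p)
  em
}

#' Max-pooled interaction-map pyramid
#'
#' Multi-resolution tiling of the `|theta|` map for visualization: level 0
#' is the `p x p` grid with pair effects in the upper triangle and single
#' effects on the diagonal; each higher level halves both axes, every pixel
#' taking the maximum of its (at most) 2 x 2 children, so a level-`l` pixel
#' reports the maximum intensity over `4^l` SNP/SNP cells (at level 11,
#' 4,194,304 interactions per pixel). Cells absent from a sparse map count
#' as zero.
#'
#' @param em an `effect_map`, or a dense numeric matrix of `|theta|` tiles.
#' @param L number of pooling levels; default enough to reach a single apex
#'   pixel.
#' @return A `pyramid`: list with `levels` (list of dense matrices, element
#'   1 being level 0) and `L`.
#' @export
build_pyramid <- function(em, L = NULL) {
  base <- if (is.matrix(em)) abs(em) else {
    p <- attr(em, "p")
    M <- matrix(0, p, p)
    sing <- em$kind == "single"
    if (any(sing)) M[cbind(em$i[sing], em$i[sing])] <- abs(em$theta[sing])
    prs <- em$kind == "pair"
    if (any(prs)) M[cbind(em$i[prs], em$j[prs])] <- abs(em$theta[prs])
    M
  }
  if (is.null(L)) L <- max(1L, ceiling(log2(max(dim(base)))))
  if (L < 1) stopf("L must be >= 1")
  levels <- vector("list", L + 1)
  levels[[1]] <- base
  cur <- base
  for (l in seq_len(L)) {
    cur <- pool_max2(cur)
    levels[[l + 1]] <- cur
  }
  structure(list(levels = levels, L = L), class = "pyramid")
}

pool_max2 <- function(M) {
  r <- nrow(M); cc <- ncol(M)
  if (r %% 2) { M <- rbind(M, 0); r <- r + 1 }
  if (cc %% 2) { M <- cbind(M, 0); cc <- cc + 1 }
  pmax(M[seq(1, r, 2), seq(1, cc, 2), drop = FALSE],
       M[seq(2, r, 2), seq(1, cc, 2), drop = FALSE],
       M[seq(1, r, 2), seq(2, cc, 2), drop = FALSE],
       M[seq(2, r, 2), seq(2, cc, 2), drop = FALSE])
}

#' @export
print.pyramid <- function(x, ...) {
  cat(sprintf("pyramid: %d levels, base %d x %d, apex max = %g\n",
              x$L + 1, nrow(x$levels[[1]]), ncol(x$levels[[1]]),
              max(x$levels[[x$L + 1]])))
  invisible(x)
}

#' Export pyramid levels as delimited tiles
#'
#' Writes one TSV per level (`level00.tsv`, `level01.tsv`, ...) under `dir`.
#'
#' @param pyr a [build_pyramid()] result.
#' @param dir output directory (created if needed).
#' @export
write_pyramid <- function(pyr, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (l in seq_along(pyr$levels)) {
    write.table(pyr$levels[[l]],
                file.path(dir, sprintf("level%02d.tsv", l - 1)),
                sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  invisible(dir)
}
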