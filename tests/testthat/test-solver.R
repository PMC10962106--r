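test_that("solve_block in identity mode equals OLS on raw columns", {
  fx <- fixture_planted(n = 500, p = 12, seed = 3)
  terms <- all_terms(12)
  cfg <- solver_config(sketch_dim = nrow(terms), lambda = 0, seed = 1)
  em <- solve_block(fx$X, fx$y, terms, cfg)
  M <- cbind(fx$X$values,
             sapply(seq_len(n_pairs(12)), function(k) {
               ij <- index_to_pair(k, 12)
               interaction_column(fx$X, ij$i, ij$j)
             }))
  ols <- unname(coef(lm(fx$y ~ M)))[-1]
  expect_equal(em$theta, ols, tolerance = 1e-8)
  expect_effect_map(em, 12)
})

test_that("solve_block excludes constant term columns and reports zero", {
  vals <- cbind(rep(1L, 40), rbinom(40, 1, 0.5), rbinom(40, 1, 0.5))
  vals[, 2] <- c(rep(0L, 20), rep(1L, 20))
  X <- genotype_matrix(vals)
  terms <- make_terms(singles = 1:3)
  cfg <- solver_config(sketch_dim = 3L, lambda = 1)
  expect_message(em <- solve_block(X, rnorm(40), terms, cfg), "constant")
  expect_equal(em$theta[1], 0)
  expect_error(solve_block(X, rep(2, 40), terms, cfg), "constant phenotype")
  expect_error(solve_block(X, rnorm(39), terms, cfg), "length")
})

test_that("a planted strong pair ranks first among thousands of nulls", {
  hits <- 0
  for (s in 1:20) {
    fx <- fixture_planted(n = 1500, p = 60, seed = 100 + s, h2 = 0.5,
                          pair = c(11L, 47L), single = "none", theta_pair = 1)
    terms <- make_terms(pairs = index_to_pair(seq_len(n_pairs(60)), 60))
    cfg <- solver_config(sketch_dim = 512L, n_sketches = 2L, seed = s)
    em <- solve_block(fx$X, fx$y, terms, cfg)
    top1 <- as.data.frame(em)[episketch:::effect_order(em)[1], ]
    if (top1$i == 11 && top1$j == 47) hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("permuted phenotypes destroy the planted pair's rank", {
  fx <- fixture_planted(n = 1500, p = 60, seed = 9, h2 = 0.5,
                        pair = c(11L, 47L), single = "none", theta_pair = 1)
  terms <- make_terms(pairs = index_to_pair(seq_len(n_pairs(60)), 60))
  cfg <- solver_config(sketch_dim = 512L, n_sketches = 2L, seed = 5)
  ranks <- vapply(1:10, function(b) {
    yp <- episketch:::with_seed(b, sample(fx$y))
    em <- solve_block(fx$X, yp, terms, cfg)
    ids <- episketch:::term_id(em$kind, em$i, em$j)
    match("p11:47", ids[episketch:::effect_order(em)])
  }, numeric(1))
  # under the null the planted pair's rank is essentially uniform
  expect_gt(median(ranks), 50)
})

test_that("estimates are invariant to individual (row) ordering", {
  fx <- fixture_planted(n = 400, p = 10, seed = 21)
  terms <- all_terms(10)
  cfg <- solver_config(sketch_dim = 32L, n_sketches = 2L, seed = 3)
  em1 <- solve_block(fx$X, fx$y, terms, cfg)
  perm <- episketch:::with_seed(99, sample(400))
  Xp <- genotype_matrix(fx$X$values[perm, , drop = FALSE],
                        markers = fx$X$markers)
  em2 <- solve_block(Xp, fx$y[perm], terms, cfg)
  expect_equal(em1$theta, em2$theta, tolerance = 1e-10)
})

test_that("duplicate columns split the effect but sums match OLS", {
  # two identical predictors under ridge share the weight equally;
  # their sum recovers the single-column effect as lambda -> 0 would
  set.seed(13)
  x <- rnorm(300)
  M <- cbind(x, x, rnorm(300))
  Y <- 2 * x + rnorm(300, 0, 0.1)
  A <- make_sketch(3, 3, "identity")
  th <- as.numeric(solve_compressed_ridge(M, Y - mean(Y), A, lambda = 1e-4))
  single <- unname(coef(lm(Y ~ x + M[, 3])))[2]
  expect_equal(th[1], th[2], tolerance = 1e-6)
  expect_equal(th[1] + th[2], single, tolerance = 0.02)
})

test_that("top_n_support ranks, caps and breaks ties deterministically", {
  em <- episketch:::new_effect_map(
    data.frame(kind = c("single", "single", "pair", "pair"),
               i = c(1L, 2L, 1L, 1L), j = c(NA, NA, 2L, 3L),
               theta = c(3, -5, 1, 5)), p = 3)
  top2 <- top_n_support(em, 2)
  # |−5| ties |5|: pair sorts before single lexicographically on kind
  expect_equal(top2$kind, c("pair", "single"))
  expect_equal(top2$theta, c(5, -5))
  expect_equal(top2$support_score, c(5, 5))
  expect_warning(all4 <- top_n_support(em, 10), "exceeds")
  expect_equal(nrow(all4), 4)
  expect_error(top_n_support(em, 0), "n_star")
})

test_that("permutation threshold calibrates the null maximum", {
  fx <- fixture_planted(n = 300, p = 8, seed = 31, h2 = 0.6,
                        pair = c(2L, 7L), single = "none", theta_pair = 1.5)
  terms <- all_terms(8)
  cfg <- solver_config(sketch_dim = nrow(terms), lambda = 1, seed = 2)
  thr <- permutation_threshold(fx$X, fx$y, terms, cfg, n_perm = 20, q = 1.0)
  maxima <- attr(thr, "maxima")
  expect_equal(length(maxima), 20)
  expect_equal(as.numeric(thr), max(maxima)) # q = 1 is the max of the maxima
  # the observed planted signal clears the null threshold
  em <- solve_block(fx$X, fx$y, terms, cfg)
  expect_gt(max(abs(em$theta)), unname(quantile(maxima, 0.95)))
  expect_error(permutation_threshold(fx$X, fx$y, terms, cfg, n_perm = 5),
               "n_perm")
})

test_that("effect maps serialize to TSV and round-trip", {
  fx <- fixture_planted(n = 200, p = 6, seed = 41)
  terms <- all_terms(6)
  cfg <- solver_config(sketch_dim = nrow(terms), lambda = 1)
  em <- top_n_support(solve_block(fx$X, fx$y, terms, cfg), 10)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_effect_map(em, fx$X, path)
  tab <- read.table(path, header = TRUE, sep = "\t")
  expect_equal(nrow(tab), 10)
  expect_true(all(tab$pos_j[tab$kind == "pair"] >=
                    tab$pos_i[tab$kind == "pair"]))
  back <- read_effect_map(path, 6)
  expect_equal(back$theta, em$theta)
  expect_equal(episketch:::term_id(back$kind, back$i, back$j),
               episketch:::term_id(em$kind, em$i, em$j))
})
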