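test_that("two-locus groups partition individuals by joint genotype", {
  X <- genotype_matrix(matrix(c(0, 0, 1, 1, 0, 1, 0, 1), nrow = 4))
  gr <- two_locus_groups(X, c(1, 2, 3, 4), 1, 2)
  expect_equal(sum(gr$cells$n), 4)
  expect_true(all(gr$cells$n == 1))
  expect_equal(gr$cells$mean[gr$cells$dosage_i == 1 &
                               gr$cells$dosage_j == 1], 4)
  expect_error(two_locus_groups(X, 1:4, 2, 1), "i < j")
})

test_that("additive traits give additive cell means; threshold traits do not", {
  X <- sample_genotypes(4000, 6, seed = 3)
  # additive: cell mean ~ sum of marginal deviations
  y_add <- X$values[, 1] + X$values[, 2] + rnorm(4000, 0, 0.3)
  gr <- two_locus_groups(X, y_add, 1, 2)
  cells <- gr$cells
  mu <- mean(y_add)
  for (r in seq_len(nrow(cells))) {
    pred <- mu +
      (gr$marginal_i$mean[gr$marginal_i$dosage == cells$dosage_i[r]] - mu) +
      (gr$marginal_j$mean[gr$marginal_j$dosage == cells$dosage_j[r]] - mu)
    se <- 3 * 0.5 / sqrt(cells$n[r])
    expect_lt(abs(cells$mean[r] - pred), max(4 * se, 0.1))
  }
  # threshold epistasis: only the both-carrier cell shifts
  arch <- architecture(pairs = data.frame(i = 3, j = 5, theta = 2,
                                          type = "marchini3"), p = 6)
  y_thr <- genetic_value(X, arch)
  gr2 <- two_locus_groups(X, y_thr, 3, 5)
  c2 <- gr2$cells
  on <- c2$dosage_i >= 1 & c2$dosage_j >= 1
  expect_gt(min(c2$mean[on & c2$n > 0]), max(c2$mean[!on & c2$n > 0]))
})

test_that("quantile classes band the empirical distribution", {
  expect_equal(quantile_classes(1:10, 5L), rep(0:4, each = 2))
  expect_equal(quantile_classes(10:1, 5L), rep(4:0, each = 2))
  set.seed(2)
  y <- rnorm(1000)
  cl <- quantile_classes(y, 3L)
  expect_true(all(abs(table(cl) - 1000 / 3) <= 1))
  # boundary ties go to the lower class
  expect_equal(quantile_classes(c(1, 2, 2, 3), 3L), c(0, 0, 0, 2))
  expect_error(quantile_classes(rep(1, 10), 3L), "distinct")
  expect_error(quantile_classes(1:10, 4L), "3 or 5")
})

test_that("train/test splits are disjoint, exhaustive, stratified, seeded", {
  sp <- split_train_test(100, 0.5, seed = 3)
  expect_equal(length(sp$train), 50)
  expect_equal(sort(c(sp$train, sp$test)), 1:100)
  expect_identical(sp, split_train_test(100, 0.5, seed = 3))
  labels <- rep(0:4, each = 20)
  sps <- split_train_test(100, 0.5, seed = 4, labels = labels)
  for (l in 0:4)
    expect_equal(sum(labels[sps$train] == l), 10)
  expect_error(split_train_test(3), "at least 4")
})

test_that("feature tables materialize dosages and products by key order", {
  X <- sample_genotypes(50, 10, seed = 5)
  t1 <- make_terms(singles = c(3L, 7L))
  t2 <- make_terms(pairs = data.frame(i = c(1L, 2L), j = c(9L, 5L)))
  M <- build_feature_table(X, t1, t2)
  expect_equal(dim(M), c(50, 4))
  expect_equal(colnames(M), c("s3", "s7", "p1:9", "p2:5"))
  expect_equal(M[, "p1:9"], X$values[, 1] * X$values[, 9])
  expect_error(build_feature_table(X, t1, t1), "duplicate")
})

test_that("random pair sampling avoids exclusions and is near-uniform", {
  excl <- make_terms(pairs = data.frame(i = 1:5, j = 6:10))
  rp <- sample_random_pairs(100, 30, exclude = excl, seed = 2)
  expect_equal(nrow(rp), 30)
  expect_equal(anyDuplicated(episketch:::term_id(rp$kind, rp$i, rp$j)), 0)
  expect_equal(length(intersect(
    episketch:::term_id(rp$kind, rp$i, rp$j),
    episketch:::term_id(excl$kind, excl$i, excl$j))), 0)
  expect_identical(sample_random_pairs(100, 30, excl, seed = 2), rp)
  # chi-square goodness of fit for uniformity on a small universe
  counts <- integer(n_pairs(8))
  for (s in 1:2000) {
    rp <- sample_random_pairs(8, 3, seed = s)
    k <- pair_to_index(rp$i, rp$j, 8)
    counts[k] <- counts[k] + 1
  }
  expect_gt(chisq.test(counts)$p.value, 0.001)
  expect_error(sample_random_pairs(5, 11), "exceeds")
})

test_that("per-class F1 matches a hand-computed confusion matrix", {
  # confusion fixture: rows truth, cols prediction
  #          pred a b c
  # truth a       5 2 0
  # truth b       1 6 1
  # truth c       0 3 4
  truth <- factor(rep(c("a", "b", "c"), times = c(7, 8, 7)))
  pred <- factor(c(rep("a", 5), rep("b", 2),
                   "a", rep("b", 6), "c",
                   rep("b", 3), rep("c", 4)), levels = c("a", "b", "c"))
  f1 <- episketch:::f1_per_class(truth, pred)
  expect_equal(unname(f1["a"]), 2 * 5 / (2 * 5 + 1 + 2))
  expect_equal(unname(f1["b"]), 2 * 6 / (2 * 6 + 5 + 2))
  expect_equal(unname(f1["c"]), 2 * 4 / (2 * 4 + 1 + 3))
})

test_that("classifiers separate a clean synthetic signal and chance-level noise", {
  set.seed(6)
  n <- 300
  centers <- rep(c(-4, 0, 4), each = n / 3)
  feats <- cbind(centers + rnorm(n, 0, 0.3), rnorm(n))
  labels <- rep(0:2, each = n / 3)
  sp <- split_train_test(n, 0.5, seed = 1, labels = labels)
  runs <- evaluate_classifiers(feats, labels, sp,
                               models = c("multinom", "random_forest"))
  expect_true(all(runs$max_f1 > 0.95))
  # label permutation: best-class F1 falls to near chance for 3 classes
  perm_labels <- episketch:::with_seed(8, sample(labels))
  runs0 <- evaluate_classifiers(feats, perm_labels, sp, models = "multinom")
  expect_lt(runs0$max_f1, 0.6)
})

test_that("true vs random comparison pairs runs and counts strict wins", {
  a <- data.frame(model = c("m1", "m2"), n_classes = 3L, n_features = 4L,
                  max_f1 = c(0.7, 0.5))
  b <- data.frame(model = c("m1", "m2"), n_classes = 3L, n_features = 4L,
                  max_f1 = c(0.6, 0.5))
  cmp <- compare_true_vs_random(a, b)
  expect_equal(cmp$fraction_improved, 0.5) # one win, one tie
  expect_equal(compare_true_vs_random(a, a)$fraction_improved, 0)
  expect_warning(compare_true_vs_random(a, b[1, ]), "unpaired")
})

test_that("epistatic features beat random ones for classification on average", {
  set.seed(31)
  frac <- replicate(6, {
    n <- 400; p <- 40
    X <- sample_genotypes(n, p, seed = sample.int(1e6, 1))
    prs <- make_terms(pairs = data.frame(i = c(3L, 11L), j = c(25L, 33L)))
    g <- interaction_column(X, 3, 25) + interaction_column(X, 11, 33)
    y <- drop(scale(g)) * sqrt(0.4) + rnorm(n, 0, sqrt(0.6))
    labels <- quantile_classes(y, 3L)
    sp <- split_train_test(n, 0.5, seed = 1, labels = labels)
    rnd <- sample_random_pairs(p, 2, exclude = prs, seed = 7)
    f2d <- build_feature_table(X, NULL, prs)
    frnd <- build_feature_table(X, NULL, rnd)
    r2d <- evaluate_classifiers(f2d, labels, sp, models = "multinom",
                                meta = list(features = "true"))
    rrnd <- evaluate_classifiers(frnd, labels, sp, models = "multinom",
                                 meta = list(features = "rnd"))
    r2d$max_f1 > rrnd$max_f1
  })
  expect_gt(mean(frac), 0.5)
})

test_that("feature selection on the train half does not leak the test half", {
  fx <- fixture_planted(n = 600, p = 30, seed = 41, h2 = 0.4)
  sp <- split_train_test(600, 0.5, seed = 2)
  cfg <- solver_config(block_size = 30L, sketch_dim = 128L, seed = 3)
  Xtr <- genotype_matrix(fx$X$values[sp$train, , drop = FALSE])
  Xte <- genotype_matrix(fx$X$values[sp$test, , drop = FALSE])
  em_tr <- run_2d(Xtr, fx$y[sp$train], cfg)
  em_te <- run_2d(Xte, fx$y[sp$test], cfg)
  top_tr <- top_n_support(em_tr, 20)
  top_te <- top_n_support(em_te, 20)
  ids_tr <- episketch:::term_id(top_tr$kind, top_tr$i, top_tr$j)
  ids_te <- episketch:::term_id(top_te$kind, top_te$i, top_te$j)
  # the two halves agree on the strong truth but not on the noise tail
  expect_lt(length(intersect(ids_tr, ids_te)), 20)
})
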