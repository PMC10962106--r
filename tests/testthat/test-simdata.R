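test_that("genotype sampling respects coding sets and is reproducible", {
  Xi <- sample_genotypes(2, 3, 0.5, "inbred", seed = 5)
  expect_true(all(Xi$values %in% 0:1))
  Xo <- sample_genotypes(5, 4, 0.5, "outbred", seed = 5)
  expect_true(all(Xo$values %in% 0:2))
  expect_identical(sample_genotypes(20, 10, seed = 3)$values,
                   sample_genotypes(20, 10, seed = 3)$values)
  expect_false(identical(sample_genotypes(20, 10, seed = 3)$values,
                         sample_genotypes(20, 10, seed = 4)$values))
  expect_error(sample_genotypes(5, 5, allele_freq = 1.2), "allele_freq")
})

test_that("genotype frequencies concentrate at the target allele frequency", {
  # Binomial tail: for n = 10000, P(|mean - 0.5| > 0.05) < 2e-23 per SNP
  X <- sample_genotypes(10000, 100, 0.5, seed = 9)
  cm <- colMeans(X$values)
  expect_true(all(cm > 0.45 & cm < 0.55))
})

test_that("architecture sampling dispatches distinct canonical terms", {
  a <- sample_architecture(100, 2, 3, 0, target_h2 = 0.5, seed = 2)
  expect_equal(nrow(a$simple) + nrow(a$pairs) + nrow(a$quad), 5)
  expect_true(all(a$pairs$i < a$pairs$j))
  expect_equal(anyDuplicated(truth_keys(a)), 0)
  b <- sample_architecture(1000, 0, 10, 0, target_h2 = 0.2, seed = 3)
  expect_equal(nrow(b$pairs), 10)
  expect_error(sample_architecture(3, 0, 4, 0), "exceeds")
  expect_error(sample_architecture(10, 0, 0, 0), "at least one term")
  # inbred coding: quadratic terms alias with simple effects and are merged
  expect_warning(q <- sample_architecture(50, 1, 0, 2, seed = 1,
                                          inbred_mode = TRUE), "alias")
  expect_equal(nrow(q$simple), 3)
})

test_that("Marchini tables follow the three two-locus models", {
  t1 <- marchini_table(1, mu = 1, theta_m = 1)
  expect_equal(t1$table[3, 3], 16) # (1+1)^(2+2)
  expect_equal(t1$table[1, 1], 1)
  t3 <- marchini_table(3, mu = 1, theta_m = 1)
  expect_equal(unique(as.vector(t3$table)), c(1, 2))
  expect_true(all(t3$table[2:3, 2:3] == 2))
  expect_true(all(t3$table[1, ] == 1) && all(t3$table[, 1] == 1))
  # theta_m = 0 collapses all three types to a constant table
  for (ty in 1:3)
    expect_equal(marchini_table(ty, 1, 0)$table, marchini_table(2, 1, 0)$table)
  expect_error(marchini_table(4), "type_id")
})

test_that("genetic values combine simple, product and threshold terms", {
  X1 <- genotype_matrix(matrix(c(0, 1, 1), ncol = 1))
  a1 <- architecture(simple = data.frame(i = 1, theta = 2), p = 1)
  expect_equal(genetic_value(X1, a1), c(0, 2, 2))
  X2 <- genotype_matrix(matrix(c(1, 1, 0, 1, 0, 1), nrow = 3))
  a2 <- architecture(pairs = data.frame(i = 1, j = 2, theta = 1,
                                        type = "product"), p = 2)
  expect_equal(genetic_value(X2, a2), c(1, 0, 0))
  # threshold interaction: only the (1,1) combination shifts
  X3 <- genotype_matrix(matrix(c(0, 0, 1, 1, 0, 1, 0, 1), nrow = 4))
  a3 <- architecture(pairs = data.frame(i = 1, j = 2, theta = 1,
                                        type = "marchini3"), p = 2)
  g3 <- genetic_value(X3, a3)
  expect_true(g3[4] > 0)
  expect_equal(g3[1:3], rep(0, 3))
})

test_that("noise calibration hits the target heritability", {
  expect_equal(add_noise_for_h2(c(1, 2, 3), 1), c(1, 2, 3),
               ignore_attr = TRUE)
  # realized heritability concentrates near the target at n = 10^4
  set.seed(1)
  g <- rnorm(10000)
  y <- add_noise_for_h2(g, 0.5, seed = 2)
  expect_equal(var(g) / var(y), 0.5, tolerance = 0.02)
  y2 <- add_noise_for_h2(g, 0.2, seed = 3)
  expect_equal(var(g) / var(y2), 0.2, tolerance = 0.02)
  expect_error(add_noise_for_h2(rep(1, 5), 0.5), "degenerate")
  expect_error(add_noise_for_h2(g, 0), "target_h2")
  # random mode jitters sigma but stays in the declared band
  y3 <- add_noise_for_h2(g, 0.5, "random", seed = 4)
  s0 <- sqrt(var(g))
  expect_lt(abs(sd(y3 - g) / s0 - 1), 0.25)
})

test_that("the sigma formula var(g)(1-h2)/h2 is used exactly", {
  g <- c(-1, 0, 1) * sqrt(3 / 2) # var(g) = 1... times (n-1)/n handled by var()
  vg <- var(g)
  many <- replicate(400, {
    y <- add_noise_for_h2(g, 0.5, seed = sample.int(1e6, 1))
    var(y - g)
  })
  # sigma^2 = vg * (1-0.5)/0.5 = vg
  expect_equal(mean(many), vg, tolerance = 0.15 * vg)
})

test_that("simulation replays byte-identically and round-trips JSON", {
  a <- sample_architecture(50, 1, 2, 0, target_h2 = 0.4, seed = 8)
  X <- sample_genotypes(100, 50, seed = 8)
  t1 <- simulate_trait(X, a)
  t2 <- simulate_trait(X, a)
  expect_identical(t1$y, t2$y)
  path <- withr::local_tempfile(fileext = ".json")
  write_architecture(a, path)
  b <- read_architecture(path)
  expect_equal(a$pairs, b$pairs)
  expect_equal(a$simple, b$simple)
  expect_equal(a$target_h2, b$target_h2)
  expect_equal(genetic_value(X, a), genetic_value(X, b), tolerance = 1e-12)
})

test_that("theta_m = 0 Marchini architectures carry no signal", {
  X <- sample_genotypes(200, 20, mode = "outbred", seed = 3)
  a <- architecture(pairs = data.frame(i = c(2, 5), j = c(9, 11),
                                       theta = c(1, 1),
                                       type = c("marchini1", "marchini2")),
                    p = 20, theta_m = 0)
  expect_equal(var(genetic_value(X, a)), 0)
})
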