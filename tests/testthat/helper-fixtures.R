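# Small deterministic fixtures shared across test files. Everything is
# generated in code; nothing is stored on disk.

fixture_planted <- function(n = 600, p = 25, seed = 42, h2 = 0.6,
                            pair = NULL, single = NULL,
                            theta_pair = 1.5, theta_single = 1) {
  if (is.null(pair)) pair <- c(max(1L, round(p * 0.2)), max(2L, round(p * 0.7)))
  if (identical(single, "none")) single <- NULL
  else if (is.null(single)) single <- round(p * 0.4)
  X <- sample_genotypes(n, p, seed = seed)
  arch <- architecture(
    simple = if (is.null(single)) NULL else
      data.frame(i = single, theta = theta_single),
    pairs = data.frame(i = pair[1], j = pair[2], theta = theta_pair,
                       type = "product"),
    target_h2 = h2, p = p)
  tr <- simulate_trait(X, arch, seed = seed + 1)
  list(X = X, y = tr$y, g = tr$g, arch = arch)
}

all_terms <- function(p) {
  make_terms(singles = seq_len(p),
             pairs = index_to_pair(seq_len(n_pairs(p)), p))
}

expect_effect_map <- function(em, p) {
  expect_s3_class(em, "effect_map")
  expect_true(all(em$kind %in% c("single", "pair")))
  prs <- em$kind == "pair"
  expect_true(all(em$i[prs] < em$j[prs]))
  expect_true(all(em$i >= 1 & em$i <= p))
}
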