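#' Two-locus Marchini interaction tables
#'
#' Quantitative-trait analogs of the three canonical two-locus epistasis
#' models of Marchini et al. (2005). With baseline `mu` and multiplier
#' `theta_m`, the 3 x 3 table of genetic values indexed by the two dosages
#' `(a, b)` in \{0, 1, 2\} is
#' \itemize{
#'   \item type 1 (multiplicative within and between loci):
#'     `mu * (1 + theta_m)^(a + b)`
#'   \item type 2 (two-locus interaction multiplicative effect):
#'     `mu * (1 + theta_m)^(a * b)`
#'   \item type 3 (two-locus interaction threshold effect):
#'     `mu * (1 + theta_m)` when both dosages are >= 1, else `mu`.
#' }
#' `theta_m = 0` collapses all three types to a constant (null) table.
#'
#' @param type_id 1, 2 or 3.
#' @param mu baseline genetic value, default 1.
#' @param theta_m interaction multiplier, default 1.
#' @return An object of class `marchini_table`: list with `type_id`, `mu`,
#'   `theta_m` and the 3 x 3 `table` (rows/cols indexed by dosage 0..2).
#' @export
marchini_table <- function(type_id, mu = 1, theta_m = 1) {
  if (!type_id %in% 1:3) stopf("type_id must be 1, 2 or 3")
  a <- 0:2
  tab <- switch(type_id,
    outer(a, a, function(i, j) mu * (1 + theta_m)^(i + j)),
    outer(a, a, function(i, j) mu * (1 + theta_m)^(i * j)),
    outer(a, a, function(i, j) ifelse(i >= 1 & j >= 1, mu * (1 + theta_m), mu))
  )
  dimnames(tab) <- list(dosage_i = a, dosage_j = a)
  structure(list(type_id = type_id, mu = mu, theta_m = theta_m, table = tab),
            class = "marchini_table")
}

pair_types <- c("product", "marchini1", "marchini2", "marchini3")

#' Simulated genetic architecture
#'
#' The truth object of a simulation: sparse sets of simple (additive), pair
#' (epistatic) and quadratic effects, plus the target narrow-sense
#' heritability and noise mode.
#'
#' @param simple data frame with columns `i`, `theta` (may have 0 rows).
#' @param pairs data frame with columns `i`, `j` (`i < j`), `theta`, `type`
#'   (one of `"product"`, `"marchini1"`, `"marchini2"`, `"marchini3"`).
#' @param quad data frame with columns `i`, `theta`.
#' @param target_h2 target narrow-sense heritability in (0, 1].
#' @param noise_mode `"fixed"` or `"random"` (see [add_noise_for_h2()]).
#' @param p number of SNPs the indices refer to.
#' @param theta_m,mu Marchini table parameters used by marchini-type pairs.
#' @param seed integer seed recorded with the architecture.
#' @return An object of class `architecture`.
#' @export
architecture <- function(simple = NULL, pairs = NULL, quad = NULL,
                         target_h2 = 0.5, noise_mode = c("fixed", "random"),
                         p, theta_m = 1, mu = 1, seed = 1L) {
  noise_mode <- match.arg(noise_mode)
  empty1 <- data.frame(i = integer(), theta = numeric())
  empty2 <- data.frame(i = integer(), j = integer(), theta = numeric(),
                       type = character())
  if (is.null(simple)) simple <- empty1
  if (is.null(quad)) quad <- empty1
  if (is.null(pairs)) pairs <- empty2
  if (nrow(pairs) && any(pairs$i >= pairs$j))
    stopf("pair indices must satisfy i < j")
  idx <- c(simple$i, quad$i, pairs$i, pairs$j)
  if (length(idx) && (any(idx < 1) || any(idx > p)))
    stopf("term indices must lie in [1, p]")
  if (nrow(pairs) && !all(pairs$type %in% pair_types))
    stopf("unknown pair interaction type")
  if (anyDuplicated(c(term_id("single", simple$i),
                      term_id("pair", pairs$i, pairs$j))) ||
      anyDuplicated(quad$i))
    stopf("duplicate terms in architecture")
  k <- nrow(simple) + nrow(pairs) + nrow(quad)
  if (k < 1) stopf("architecture must contain at least one non-null term")
  if (target_h2 <= 0 || target_h2 > 1) stopf("target_h2 must be in (0, 1]")
  structure(list(simple = simple, pairs = pairs, quad = quad,
                 target_h2 = target_h2, noise_mode = noise_mode, p = p,
                 theta_m = theta_m, mu = mu, seed = as.integer(seed)),
            class = "architecture")
}

#' @export
print.architecture <- function(x, ...) {
  cat(sprintf(
    "architecture: %d simple + %d pair + %d quadratic effects, h2 = %g (%s noise)\n",
    nrow(x$simple), nrow(x$pairs), nrow(x$quad), x$target_h2, x$noise_mode))
  invisible(x)
}

#' Sample a sparse genetic architecture
#'
#' Dispatches non-null coordinates among simple, pairwise and quadratic
#' effects at distinct positions. Effect sizes default to magnitudes uniform
#' on `[0.5, 1.5]` with random sign.
#'
#' @param p number of SNPs.
#' @param k_simple,k_pair,k_quad term counts (total must be >= 1).
#' @param types interaction types assigned (recycled) to the pair terms.
#' @param target_h2,noise_mode,theta_m,mu see [architecture()].
#' @param effect_dist function `(k) -> k` signed effect sizes; default
#'   uniform magnitude in `[0.5, 1.5]` with random sign.
#' @param seed integer seed.
#' @param inbred_mode if `TRUE`, quadratic terms alias with simple effects
#'   (dosage^2 = dosage on \{0,1\}); they are merged into simple terms with a
#'   warning.
#' @param distinct_loci if `TRUE`, planted terms occupy pairwise-disjoint
#'   SNPs (no pair shares a parent with another term). A SNP parenting two
#'   raw-coding product pairs carries a genuine main effect of the truths'
#'   own size, which makes exact-match recall ill-defined; disjoint
#'   planting keeps the labeled truth set separable. Default `FALSE`
#'   (positions only need to be distinct as terms).
#' @return An [architecture()].
#' @export
sample_architecture <- function(p, k_simple = 0, k_pair = 0, k_quad = 0,
                                types = "product", target_h2 = 0.5,
                                noise_mode = "fixed", effect_dist = NULL,
                                theta_m = 1, mu = 1, seed = 1,
                                inbred_mode = TRUE, distinct_loci = FALSE) {
  if (k_simple + k_pair + k_quad < 1) stopf("need at least one term")
  if (k_pair > n_pairs(p)) stopf("k_pair exceeds p(p-1)/2 available pairs")
  if (k_simple + k_quad > p) stopf("not enough distinct SNPs for the singles")
  if (distinct_loci && k_simple + k_quad + 2 * k_pair > p)
    stopf("not enough SNPs for disjoint planted loci")
  if (is.null(effect_dist))
    effect_dist <- function(k) runif(k, 0.5, 1.5) * sample(c(-1, 1), k, TRUE)
  if (inbred_mode && k_quad > 0) {
    warning("inbred coding: quadratic effects alias with simple effects; merging",
            call. = FALSE)
    k_simple <- k_simple + k_quad
    k_quad <- 0
  }
  with_seed(seed, {
    if (distinct_loci) {
      loci <- sample.int(p, k_simple + k_quad + 2 * k_pair)
      singles <- loci[seq_len(k_simple + k_quad)]
      ij <- if (k_pair > 0) {
        prs <- matrix(loci[k_simple + k_quad + seq_len(2 * k_pair)], ncol = 2)
        data.frame(i = pmin(prs[, 1], prs[, 2]),
                   j = pmax(prs[, 1], prs[, 2]))
      } else data.frame(i = integer(), j = integer())
    } else {
      singles <- sample.int(p, k_simple + k_quad)
      pk <- if (k_pair > 0) sort(sample(n_pairs(p), k_pair)) else numeric()
      ij <- index_to_pair(pk, p)
    }
    th <- effect_dist(k_simple + k_quad + k_pair)
    architecture(
      simple = data.frame(i = head(singles, k_simple),
                          theta = head(th, k_simple)),
      quad = if (k_quad > 0)
        data.frame(i = singles[k_simple + seq_len(k_quad)],
                   theta = th[k_simple + seq_len(k_quad)]) else NULL,
      pairs = if (k_pair > 0)
        data.frame(i = ij$i, j = ij$j,
                   theta = th[k_simple + k_quad + seq_len(k_pair)],
                   type = rep_len(types, k_pair)) else NULL,
      target_h2 = target_h2, noise_mode = noise_mode, p = p,
      theta_m = theta_m, mu = mu, seed = seed)
  })
}

#' Genetic value of each individual under an architecture
#'
#' `g = sum theta_s x_i + sum theta_q x_i^2 + sum pair contributions`.
#' Product-type pairs contribute `theta * x_i * x_j` on the raw dosage
#' coding. Marchini-type pairs contribute the table lookup centered at the
#' baseline `mu` and scaled so the realized per-term standard deviation
#' equals `|theta|` (matched signal variance across types); a degenerate
#' (constant) lookup contributes zero.
#'
#' @param X a [genotype_matrix()].
#' @param arch an [architecture()] with indices valid for `X`.
#' @return Numeric length-`n` vector of genetic values.
#' @export
genetic_value <- function(X, arch) {
  v <- X$values
  if (arch$p != ncol(v)) stopf("architecture p does not match genotypes")
  g <- numeric(nrow(v))
  for (r in seq_len(nrow(arch$simple)))
    g <- g + arch$simple$theta[r] * v[, arch$simple$i[r]]
  for (r in seq_len(nrow(arch$quad)))
    g <- g + arch$quad$theta[r] * v[, arch$quad$i[r]]^2
  for (r in seq_len(nrow(arch$pairs))) {
    i <- arch$pairs$i[r]; j <- arch$pairs$j[r]
    th <- arch$pairs$theta[r]; ty <- arch$pairs$type[r]
    if (ty == "product") {
      g <- g + th * v[, i] * v[, j]
    } else {
      tid <- as.integer(sub("marchini", "", ty))
      tab <- marchini_table(tid, mu = arch$mu, theta_m = arch$theta_m)$table
      cc <- tab[cbind(v[, i] + 1L, v[, j] + 1L)] - arch$mu
      s <- sd(cc)
      if (s > 0) g <- g + th * cc / s
    }
  }
  g
}

#' Add Gaussian noise calibrated to a target heritability
#'
#' Returns `Y = g + eps` with `eps ~ N(0, sigma^2)` and
#' `sigma^2 = var(g) * (1 - h2) / h2`, so the realized narrow-sense
#' heritability `var(g) / var(Y)` converges to `target_h2`. In `"fixed"`
#' mode `sigma` is computed once from the realized `var(g)`; in `"random"`
#' mode it is additionally jittered uniformly in `[0.8, 1.2] * sigma`
#' per call, emulating replicate-to-replicate environmental variation.
#' `target_h2 = 1` returns `g` unchanged.
#'
#' @param g genetic values with positive variance.
#' @param target_h2 heritability target in (0, 1].
#' @param noise_mode `"fixed"` or `"random"`.
#' @param seed integer seed.
#' @param name phenotype name attached as an attribute.
#' @return Numeric phenotype vector with attribute `name`.
#' @export
add_noise_for_h2 <- function(g, target_h2, noise_mode = c("fixed", "random"),
                             seed = 1, name = "trait") {
  noise_mode <- match.arg(noise_mode)
  if (target_h2 <= 0 || target_h2 > 1) stopf("target_h2 must be in (0, 1]")
  vg <- var(g)
  if (!is.finite(vg) || vg <= 0) stopf("degenerate signal: var(g) = 0")
  y <- if (target_h2 == 1) g else with_seed(seed, {
    sigma <- sqrt(vg * (1 - target_h2) / target_h2)
    if (noise_mode == "random") sigma <- sigma * runif(1, 0.8, 1.2)
    g + rnorm(length(g), 0, sigma)
  })
  attr(y, "name") <- name
  y
}

#' Simulate a phenotype from genotypes and an architecture
#'
#' Convenience wrapper: [genetic_value()] then [add_noise_for_h2()] at the
#' architecture's target heritability and noise mode.
#'
#' @inheritParams genetic_value
#' @param seed seed for the noise draw; defaults to the architecture's seed.
#' @return List with `y` (phenotype), `g` (genetic values) and the realized
#'   heritability `h2 = var(g) / var(y)`.
#' @export
simulate_trait <- function(X, arch, seed = arch$seed) {
  g <- genetic_value(X, arch)
  y <- add_noise_for_h2(g, arch$target_h2, arch$noise_mode,
                        seed = derive_seed(seed, 7L))
  list(y = y, g = g, h2 = var(g) / var(y))
}

#' Write / read the true architecture as a JSON sidecar
#'
#' @param arch an [architecture()].
#' @param path JSON file path.
#' @export
write_architecture <- function(arch, path) {
  jsonlite::write_json(unclass(arch), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_architecture
#' @export
read_architecture <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  architecture(simple = as.data.frame(x$simple), pairs = as.data.frame(x$pairs),
               quad = as.data.frame(x$quad), target_h2 = x$target_h2,
               noise_mode = x$noise_mode, p = x$p, theta_m = x$theta_m,
               mu = x$mu, seed = x$seed)
}
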