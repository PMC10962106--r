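#' Two-locus haplogroup decomposition
#'
#' Partitions individuals by their joint genotype at a SNP pair — the
#' "2D-haplogroup" display — and summarizes the phenotype within each
#' `(dosage_i, dosage_j)` cell, plus the two marginal single-SNP groupings.
#' Cell means that cannot be predicted from the two marginal effects are the
#' visual signature of an epistatic pair.
#'
#' @param X a [genotype_matrix()].
#' @param Y phenotype vector.
#' @param i,j SNP indices with `i < j`.
#' @return A `two_locus_groups` object: `cells` (data frame with
#'   `dosage_i`, `dosage_j`, `n`, `mean`, `median`, `q1`, `q3`), `values`
#'   (list of per-cell phenotype vectors), and `marginal_i` / `marginal_j`
#'   (same summaries for each SNP alone). Empty cells are reported with
#'   `n = 0`.
#' @export
two_locus_groups <- function(X, Y, i, j) {
  if (i >= j) stopf("pair indices require i < j")
  v <- X$values
  doses <- 0:(if (X$mode == "inbred") 1 else 2)
  cell_summary <- function(vals) {
    if (length(vals) == 0)
      return(c(n = 0, mean = NA, median = NA, q1 = NA, q3 = NA))
    qs <- unname(quantile(vals, c(0.25, 0.75)))
    c(n = length(vals), mean = mean(vals), median = median(vals),
      q1 = qs[1], q3 = qs[2])
  }
  grid <- expand.grid(dosage_i = doses, dosage_j = doses)
  vals <- lapply(seq_len(nrow(grid)), function(r)
    Y[v[, i] == grid$dosage_i[r] & v[, j] == grid$dosage_j[r]])
  names(vals) <- paste0(grid$dosage_i, ":", grid$dosage_j)
  cells <- cbind(grid, t(vapply(vals, cell_summary, numeric(5))))
  marg <- function(col) {
    do.call(rbind, lapply(doses, function(a) {
      s <- cell_summary(Y[v[, col] == a])
      data.frame(dosage = a, t(s))
    }))
  }
  structure(list(i = i, j = j, cells = cells, values = vals,
                 marginal_i = marg(i), marginal_j = marg(j)),
            class = "two_locus_groups")
}

#' @export
print.two_locus_groups <- function(x, ...) {
  cat(sprintf("two_locus_groups for pair (%d, %d):\n", x$i, x$j))
  print(x$cells, row.names = FALSE)
  invisible(x)
}

#' Quantile-based phenotype classes
#'
#' Ranks phenotypes into `n_classes` (3 or 5) bands of the empirical
#' distribution: class `c` holds values in the `[c/k, (c+1)/k)` quantile
#' band, with boundary ties assigned to the lower class.
#'
#' @param Y phenotype vector.
#' @param n_classes 3 or 5.
#' @return Integer class labels `0 .. n_classes - 1`.
#' @export
quantile_classes <- function(Y, n_classes) {
  if (!n_classes %in% c(3L, 5L)) stopf("n_classes must be 3 or 5")
  if (length(unique(Y)) < n_classes)
    stopf("fewer distinct values than classes")
  r <- rank(Y, ties.method = "min") - 1
  pmin(as.integer(floor(n_classes * r / length(Y))), n_classes - 1L)
}

#' Train/test split
#'
#' Disjoint exhaustive split, stratified by class label when provided.
#' Scans and feature selection must use the train half only.
#'
#' @param n number of individuals (>= 4).
#' @param fraction train fraction (default 0.5).
#' @param seed integer seed.
#' @param labels optional class labels for stratification.
#' @return List with integer index vectors `train` and `test`.
#' @export
split_train_test <- function(n, fraction = 0.5, seed = 1, labels = NULL) {
  if (n < 4) stopf("need at least 4 individuals")
  with_seed(seed, {
    train <- if (is.null(labels)) {
      sort(sample.int(n, round(fraction * n)))
    } else {
      stopifnot(length(labels) == n)
      sort(unlist(lapply(split(seq_len(n), labels), function(idx)
        sample(idx, round(fraction * length(idx))))))
    }
    list(train = train, test = setdiff(seq_len(n), train))
  })
}

#' Feature table from selected terms
#'
#' Single-SNP keys contribute their dosage column; pair keys contribute
#' their interaction (product) column. Column order follows the key order.
#'
#' @param X a [genotype_matrix()].
#' @param top1d term set (from [make_terms()] or an `effect_map`) of single
#'   terms.
#' @param top2d term set of pair terms.
#' @return `n x (k1 + k2)` numeric matrix with term-id column names.
#' @export
build_feature_table <- function(X, top1d = NULL, top2d = NULL) {
  as_tt <- function(x) if (is.null(x)) NULL else
    data.frame(kind = x$kind, i = x$i, j = x$j)
  tt <- rbind(as_tt(top1d), as_tt(top2d))
  if (is.null(tt) || nrow(tt) == 0) stopf("no features requested")
  ids <- term_id(tt$kind, tt$i, tt$j)
  if (anyDuplicated(ids)) stopf("duplicate feature keys")
  M <- term_cols(X$values, tt)
  colnames(M) <- ids
  M
}

#' Sample random interaction pairs
#'
#' Uniform without replacement over all pairs not in `exclude` — the
#' "2D_random" control features.
#'
#' @param p number of SNPs.
#' @param k number of pairs to draw.
#' @param exclude term set or `effect_map` of pairs to avoid.
#' @param seed integer seed.
#' @return Term set data frame of `k` pair terms.
#' @export
sample_random_pairs <- function(p, k, exclude = NULL, seed = 1) {
  total <- n_pairs(p)
  excl <- numeric()
  if (!is.null(exclude)) {
    pr <- exclude[exclude$kind == "pair", , drop = FALSE]
    if (nrow(pr)) excl <- pair_to_index(pr$i, pr$j, p)
  }
  if (k > total - length(excl)) stopf("k exceeds the available pairs")
  ks <- with_seed(seed, {
    picked <- numeric(0)
    while (length(picked) < k) {
      cand <- sample(total, min(total, k + length(excl) + 8))
      picked <- unique(c(picked, setdiff(cand, excl)))
    }
    sort(picked[seq_len(k)])
  })
  ij <- index_to_pair(ks, p)
  make_terms(pairs = ij)
}

# ---- classifier registry ---------------------------------------------------

fit_predict <- list(
  multinom = function(xtr, ytr, xte) {
    df <- data.frame(.y = ytr, xtr)
    fit <- nnet::multinom(.y ~ ., data = df, trace = FALSE, MaxNWts = 20000)
    predict(fit, newdata = data.frame(xte))
  },
  svm_rbf = function(xtr, ytr, xte) {
    fit <- e1071::svm(xtr, ytr)
    predict(fit, xte)
  },
  random_forest = function(xtr, ytr, xte) {
    df <- data.frame(.y = ytr, xtr)
    fit <- ranger::ranger(.y ~ ., data = df, num.trees = 200, seed = 1)
    predict(fit, data = data.frame(xte))$predictions
  },
  lasso = function(xtr, ytr, xte) {
    fit <- glmnet::cv.glmnet(xtr, ytr, family = "multinomial", nfolds = 4,
                             alpha = 1)
    factor(drop(predict(fit, xte, s = "lambda.min", type = "class")),
           levels = levels(ytr))
  }
)

#' Names of the available classifier families
#' @export
classifier_registry <- function() names(fit_predict)

f1_per_class <- function(truth, pred) {
  lv <- levels(truth)
  vapply(lv, function(cl) {
    tp <- sum(pred == cl & truth == cl)
    fp <- sum(pred == cl & truth != cl)
    fn <- sum(pred != cl & truth == cl)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
}

#' Fit classifiers and record the best-predicted-class F1
#'
#' Fits each model family on the train half, computes per-class
#' (one-vs-rest) F1 on the test half, and records the maximum per-class F1
#' — the "best-predicted class" statistic. Degenerate single-class training
#' labels skip the run with a message.
#'
#' @param features `n x q` feature matrix.
#' @param labels integer/factor class labels, length `n`.
#' @param split a [split_train_test()] result.
#' @param models character vector of registry names
#'   (see [classifier_registry()]).
#' @param meta named list of annotations copied onto each row (phenotype
#'   name, feature mode, ...).
#' @return Data frame of runs: `model`, `n_classes`, `n_features`,
#'   `max_f1`, plus any `meta` columns.
#' @export
evaluate_classifiers <- function(features, labels, split,
                                 models = c("multinom", "svm_rbf",
                                            "random_forest"),
                                 meta = list()) {
  stopifnot(all(models %in% names(fit_predict)))
  labels <- factor(labels)
  ytr <- droplevels(labels[split$train])
  if (nlevels(ytr) < 2) {
    message("single-class training labels; skipping")
    return(NULL)
  }
  xtr <- features[split$train, , drop = FALSE]
  xte <- features[split$test, , drop = FALSE]
  yte <- labels[split$test]
  rows <- lapply(models, function(mname) {
    pred <- factor(fit_predict[[mname]](xtr, ytr, xte), levels = levels(labels))
    data.frame(model = mname, n_classes = nlevels(labels),
               n_features = ncol(features),
               max_f1 = max(f1_per_class(yte, pred)))
  })
  out <- do.call(rbind, rows)
  for (nm in names(meta)) out[[nm]] <- meta[[nm]]
  out
}

#' Paired comparison of true against random interaction features
#'
#' Pairs prediction runs by `(model, n_classes, n_features, ...)` and
#' reports the fraction of pairs where the true-interaction feature set
#' strictly beats the random-interaction control on max F1.
#'
#' @param runs_2d runs from [evaluate_classifiers()] with true pair
#'   features.
#' @param runs_random matching runs with random pair features.
#' @return List with `pairs` (merged table, columns `max_f1_2d`,
#'   `max_f1_random`) and `fraction_improved`.
#' @export
compare_true_vs_random <- function(runs_2d, runs_random) {
  keys <- setdiff(intersect(names(runs_2d), names(runs_random)), "max_f1")
  merged <- merge(runs_2d, runs_random, by = keys,
                  suffixes = c("_2d", "_random"))
  dropped <- nrow(runs_2d) - nrow(merged)
  if (dropped > 0)
    warning(sprintf("%d unpaired run(s) excluded", dropped), call. = FALSE)
  list(pairs = merged,
       fraction_improved = mean(merged$max_f1_2d > merged$max_f1_random))
}
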