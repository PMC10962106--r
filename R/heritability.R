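#' Adjusted coefficient of determination
#'
#' `1 - (1 - R^2) (n - 1) / (n - q - 1)` with `R^2` the ordinary coefficient
#' of determination of `yhat` against `y` and `q` the number of fitted
#' predictors. The adjustment penalizes dimensionality, which matters here
#' because feature counts approach the sample size; it is the plug-in proxy
#' used for narrow-sense heritability throughout the package.
#'
#' @param y observed phenotype.
#' @param yhat fitted values.
#' @param q number of predictors used for the fit (`n > q + 1`).
#' @return Adjusted R-squared (can be negative).
#' @export
adjusted_r2 <- function(y, yhat, q) {
  n <- length(y)
  if (n <= q + 1) stopf("adjusted R2 requires n > q + 1")
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  1 - (1 - r2) * (n - 1) / (n - q - 1)
}

#' Principal-component-regression heritability curve
#'
#' PCA on the column-standardized feature matrix (via singular value
#' decomposition; components ranked by singular value, sign fixed so the
#' largest-magnitude loading is positive), followed by OLS of `y` on the
#' top `c` component scores for each `c` in `component_grid`. Reports the
#' adjusted R-squared with `q = c` — the variance-explained proxy for
#' heritability at that model size.
#'
#' @param features `n x q` numeric feature matrix (constant columns are
#'   dropped).
#' @param y phenotype vector.
#' @param component_grid component counts; entries beyond the feature rank
#'   are truncated with a warning. Default `c(1, 2, 5, 10, 20, 30, 50)`.
#' @param label curve label stored alongside.
#' @return A `pcr_curve` data frame: `n_components`, `r2`, `adj_r2`.
#' @export
pcr_curve <- function(features, y, component_grid = c(1, 2, 5, 10, 20, 30, 50),
                      label = "features") {
  features <- as.matrix(features)
  sds <- apply(features, 2, sd)
  Fs <- scale(features[, sds > 0, drop = FALSE])
  sv <- svd(Fs)
  pos <- apply(sv$v, 2, function(v) v[which.max(abs(v))] >= 0)
  flip <- ifelse(pos, 1, -1)
  scores <- sv$u %*% diag(sv$d, length(sv$d)) * rep(flip, each = nrow(Fs))
  rank <- sum(sv$d > max(dim(Fs)) * .Machine$double.eps * sv$d[1])
  grid <- sort(unique(pmin(component_grid, rank)))
  if (any(component_grid > rank))
    warning(sprintf("component grid truncated to rank %d", rank),
            call. = FALSE)
  grid <- grid[grid >= 1 & grid < length(y) - 1]
  res <- lapply(grid, function(cc) {
    fit <- lm.fit(cbind(1, scores[, seq_len(cc), drop = FALSE]), y)
    yhat <- y - fit$residuals
    r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
    data.frame(n_components = cc, r2 = r2,
               adj_r2 = adjusted_r2(y, yhat, cc))
  })
  out <- do.call(rbind, res)
  attr(out, "label") <- label
  class(out) <- c("pcr_curve", "data.frame")
  out
}

#' Variance explained by 1D, 1D+2D, and 1D+random-2D feature sets
#'
#' The heritability-recovery comparison: PCR curves for the selected single
#' SNPs alone, augmented by the selected interaction columns, and augmented
#' by an equal number of random (non-selected) interaction columns as a
#' negative control. The reported `retrieved_h2` is the gap between the
#' best (max over the component grid) adjusted R-squared of the 1D+2D
#' curve and that of the 1D curve — the variance the interaction features
#' explain beyond everything the selected singles can.
#'
#' @param X_selected `n x k1` matrix of selected single-SNP dosage columns.
#' @param Z_selected `n x k2` matrix of selected interaction columns.
#' @param Z_random matrix with `ncol(Z_selected)` random interaction
#'   columns sampled from non-selected pairs.
#' @param y phenotype vector.
#' @param component_grid see [pcr_curve()].
#' @return List with `curves` (named list of three `pcr_curve`s:
#'   `"1D"`, `"1D+2D"`, `"1D+2D_random"`), `retrieved_h2`, and
#'   `retrieved_h2_random` (the same gap for the control).
#' @export
compare_feature_sets <- function(X_selected, Z_selected, Z_random, y,
                                 component_grid = c(1, 2, 5, 10, 20, 30, 50)) {
  if (ncol(Z_random) != ncol(Z_selected))
    stopf("Z_random must have the same column count as Z_selected")
  fit <- function(feats, label) {
    grid <- component_grid[component_grid <= ncol(feats)]
    if (length(grid) == 0) grid <- ncol(feats)
    pcr_curve(feats, y, grid, label = label)
  }
  c1 <- fit(X_selected, "1D")
  c2 <- fit(cbind(X_selected, Z_selected), "1D+2D")
  c3 <- fit(cbind(X_selected, Z_random), "1D+2D_random")
  gap <- function(b, a) max(b$adj_r2) - max(a$adj_r2)
  list(curves = list("1D" = c1, "1D+2D" = c2, "1D+2D_random" = c3),
       retrieved_h2 = gap(c2, c1), retrieved_h2_random = gap(c3, c1))
}
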