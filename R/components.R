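#' Inter-item correlation screen
#'
#' Reports the absolute pairwise correlations of a facet matrix and the share
#' at or above a threshold; facet batteries feeding a superordinate component
#' are conventionally expected to clear |r| >= .3 for most pairs.
#'
#' @param M numeric matrix or data frame of facet columns (>= 2).
#' @param threshold absolute-correlation threshold.
#' @return list with `fraction_above`, `pairs` (data frame of item pairs and
#'   |r|), and `flagged` (pairs below the threshold).
#' @export
interitem_screen <- function(M, threshold = 0.3) {
  M <- as.matrix(M)
  if (ncol(M) < 2L) stop("need at least 2 columns", call. = FALSE)
  sds <- apply(M, 2L, sd)
  if (any(sds == 0)) {
    stop("constant column(s): ", paste(colnames(M)[sds == 0], collapse = ", "),
         call. = FALSE)
  }
  R <- cor(M)
  ut <- upper.tri(R)
  idx <- which(ut, arr.ind = TRUE)
  pairs <- data.frame(item1 = colnames(R)[idx[, 1L]],
                      item2 = colnames(R)[idx[, 2L]],
                      abs_r = abs(R[ut]),
                      stringsAsFactors = FALSE)
  list(fraction_above = mean(pairs$abs_r >= threshold),
       pairs = pairs,
       flagged = pairs[pairs$abs_r < threshold, , drop = FALSE])
}

#' Kaiser-Meyer-Olkin measure of sampling adequacy
#'
#' \deqn{KMO = \frac{\sum_{i \ne j} r_{ij}^2}
#'                  {\sum_{i \ne j} r_{ij}^2 + \sum_{i \ne j} p_{ij}^2}}
#' where \eqn{r} are simple correlations and \eqn{p} the anti-image partial
#' correlations obtained from the inverse correlation matrix,
#' \eqn{p_{ij} = -s_{ij} / \sqrt{s_{ii} s_{jj}}} with \eqn{S = R^{-1}}.
#' For two columns the partial correlation equals the simple one, so KMO is
#' exactly 0.5 whenever r is nonzero.
#'
#' @param M numeric matrix or data frame of facet columns.
#' @return KMO value in `[0, 1]`.
#' @export
kmo <- function(M) {
  R <- cor(as.matrix(M))
  S <- tryCatch(solve(R), error = function(e) {
    stop("correlation matrix is singular", call. = FALSE)
  })
  d <- sqrt(diag(S))
  P <- -S / outer(d, d)
  off <- upper.tri(R)
  r2 <- sum(R[off]^2)
  p2 <- sum(P[off]^2)
  r2 / (r2 + p2)
}

#' Cronbach's alpha
#'
#' \eqn{\alpha = k/(k-1) \, (1 - \sum_i V_i / V_{total})} where \eqn{V_i} are
#' item variances and \eqn{V_{total}} the variance of row sums. For
#' exchangeable items with common correlation r this equals
#' \eqn{k r / (1 + (k-1) r)}.
#'
#' @param M numeric matrix or data frame of items (>= 2 columns).
#' @return alpha (<= 1; can be negative for discordant items).
#' @export
cronbach <- function(M) {
  M <- as.matrix(M)
  k <- ncol(M)
  if (k < 2L) stop("need at least 2 columns", call. = FALSE)
  vt <- var(rowSums(M))
  if (vt == 0) stop("zero total-score variance", call. = FALSE)
  k / (k - 1) * (1 - sum(apply(M, 2L, var)) / vt)
}

#' Principal components with eigenvalue-above-1 retention
#'
#' Eigendecomposition of the correlation matrix; components with eigenvalue
#' strictly greater than 1 are retained (Kaiser criterion — ties at exactly 1
#' are excluded). Loadings are the eigenvectors with the sign convention that
#' each component's largest-magnitude loading is positive. Because the
#' analysis is correlation-based, retention is invariant to column order and
#' to any rescaling of individual columns.
#'
#' @param M numeric matrix or data frame of facet columns (>= 2), no missing
#'   cells (apply listwise deletion upstream).
#' @return an object of class `component_model` with `eigenvalues`
#'   (descending; they sum to the column count), `loadings`, `retained`,
#'   `variance_explained`, `kmo`, `cronbach_alpha`, and the fitting `center`
#'   and `scale`.
#' @export
pca_retain <- function(M) {
  M <- as.matrix(M)
  if (ncol(M) < 2L) stop("need at least 2 columns", call. = FALSE)
  if (anyNA(M)) stop("missing cells; apply listwise deletion first", call. = FALSE)
  kmo_val <- kmo(M)
  R <- cor(M)
  eg <- eigen(R, symmetric = TRUE)
  vec <- eg$vectors
  for (j in seq_len(ncol(vec))) {
    imax <- which.max(abs(vec[, j]))
    if (vec[imax, j] < 0) vec[, j] <- -vec[, j]
  }
  dimnames(vec) <- list(colnames(M), paste0("PC", seq_len(ncol(vec))))
  # strict "greater than 1" rule; the tolerance keeps eigenvalues that are 1
  # up to floating-point noise (e.g. an exactly spherical battery) excluded
  retained <- sum(eg$values > 1 + 1e-8)
  structure(list(
    eigenvalues = eg$values,
    loadings = vec,
    retained = retained,
    variance_explained = sum(eg$values[seq_len(retained)]) / ncol(M),
    kmo = kmo_val,
    cronbach_alpha = cronbach(M),
    center = colMeans(M),
    scale = apply(M, 2L, sd)), class = "component_model")
}

#' @export
print.component_model <- function(x, ...) {
  cat(sprintf(
    "Component model: %d/%d retained (eigenvalues > 1), %.0f%% of variance\n",
    x$retained, length(x$eigenvalues), 100 * x$variance_explained))
  cat(sprintf("  eigenvalues: %s\n",
              paste(sprintf("%.2f", x$eigenvalues), collapse = ", ")))
  cat(sprintf("  KMO %.2f, Cronbach alpha %.2f\n", x$kmo, x$cronbach_alpha))
  invisible(x)
}

#' Component scores
#'
#' Projects standardized data on the retained eigenvectors. On the fitting
#' sample the scores have zero mean, are mutually uncorrelated, and each
#' score's variance equals its eigenvalue.
#'
#' @param model a [pca_retain()] fit.
#' @param M data with the same columns the model was fitted on.
#' @return numeric matrix, one column per retained component.
#' @export
component_scores <- function(model, M) {
  stopifnot(inherits(model, "component_model"))
  M <- as.matrix(M)
  if (!identical(colnames(M), rownames(model$loadings))) {
    stop("column mismatch with the fitted model", call. = FALSE)
  }
  Z <- sweep(sweep(M, 2L, model$center), 2L, model$scale, "/")
  Z %*% model$loadings[, seq_len(model$retained), drop = FALSE]
}
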