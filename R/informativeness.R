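#' Principal component analysis of a region-by-complex abundance matrix
#'
#' Columns are centered by their across-region means and NOT variance-scaled
#' (all abundances share one unit; scaling would inflate rare-complex noise).
#' The decomposition is computed from the singular values of the centered
#' matrix; eigenvalue `i` is `sigma_i^2 / (n_regions - 1)`, the variance
#' explained by principal component `i`. At most `min(n - 1, p)` components
#' carry variance.
#'
#' @param x numeric matrix, regions in rows, complexes in columns.
#' @param tol relative singular-value cutoff below which components are
#'   dropped as numerically zero.
#' @return object of class `psd_pca`: `eigenvalues` (descending), `loadings`
#'   (`p x k`, orthonormal columns), `scores` (`n x k`), `center`,
#'   `total_variance` (sum of column variances of the centered matrix).
#' @export
pca_abundance <- function(x, tol = 1e-10) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2) stop("PCA needs at least 2 regions (rows)")
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  sv <- svd(xc)
  keep <- sv$d > tol * max(sv$d, 0) & sv$d > 0
  if (!any(keep)) keep <- seq_len(min(1, length(sv$d)))  # degenerate: keep 1
  d <- sv$d[keep]
  lambda <- d^2 / (n - 1)
  loadings <- sv$v[, keep, drop = FALSE]
  rownames(loadings) <- colnames(x)
  scores <- xc %*% loadings
  structure(list(eigenvalues = lambda, loadings = loadings, scores = scores,
                 center = mu, total_variance = sum(xc^2) / (n - 1),
                 keys = colnames(x)),
            class = "psd_pca")
}

#' @export
print.psd_pca <- function(x, ...) {
  fr <- x$eigenvalues / sum(x$eigenvalues)
  cat(sprintf("<psd_pca: %d components; PC1 %.1f%%, PC2 %.1f%% of variance>\n",
              length(x$eigenvalues), 100 * fr[1],
              if (length(fr) > 1) 100 * fr[2] else 0))
  invisible(x)
}

#' Per-complex relevance: variance-weighted absolute PCA loadings
#'
#' The relevance of complex `j` combines (1) the variance explained by each
#' principal component and (2) the contribution of complex `j` to that
#' component:
#' `r_j = sum_i lambda_i * |u_ij| / sum_k |u_ik|`, normalized so that
#' `sum_j r_j = 1`. Each eigenvector enters through its L1-normalized
#' absolute coordinates, so relevance is invariant to loading sign flips and
#' the mean relevance over `n` complexes is exactly `1/n`.
#'
#' @param pca a [pca_abundance()] decomposition.
#' @return named numeric vector `r` (complex key -> relevance), summing to 1.
#' @export
relevance <- function(pca) {
  stopifnot(inherits(pca, "psd_pca"))
  lambda <- pca$eigenvalues
  if (sum(lambda) <= 0) stop("all-zero spectrum: matrix has no variance")
  au <- abs(pca$loadings)
  w <- lambda / colSums(au)
  r <- as.vector(au %*% w)
  r <- r / sum(r)
  names(r) <- pca$keys
  r
}

#' The most informative complex
#'
#' The complex with the highest relevance over all principal components.
#' Exact ties are broken toward the smallest catalog numeric id (or the
#' first column if no catalog is given) and flagged.
#'
#' @param r relevance vector from [relevance()].
#' @param catalog optional [complex_catalog()] used for tie-breaking ids.
#' @return list with `key`, `relevance`, `numeric_id` (if catalog given),
#'   `tie` flag.
#' @export
most_informative <- function(r, catalog = NULL) {
  if (!length(r)) stop("empty relevance vector")
  mx <- max(r)
  cand <- which(r == mx)
  tie <- length(cand) > 1
  if (tie && !is.null(catalog)) {
    ids <- vapply(names(r)[cand], function(k) register(catalog, k)$numeric_id,
                  integer(1))
    cand <- cand[which.min(ids)]
  } else {
    cand <- cand[1]
  }
  out <- list(key = names(r)[cand], relevance = unname(mx), tie = tie)
  if (!is.null(catalog))
    out$numeric_id <- register(catalog, out$key)$numeric_id
  out
}

#' Relevance table for reporting
#'
#' @inheritParams most_informative
#' @return data frame (`key`, `composition`, `relevance`, `rank`), sorted by
#'   decreasing relevance.
#' @export
relevance_table <- function(r) {
  ord <- order(r, decreasing = TRUE)
  data.frame(key = names(r)[ord],
             composition = vapply(names(r)[ord], composition_string,
                                  character(1)),
             relevance = unname(r[ord]),
             rank = seq_along(r))
}

#' Wild-type/mutant distances in principal-component space
#'
#' Fits the PCA on the wild-type matrix and projects both scenarios into its
#' first `k` axes (one common basis, so the two scenarios are directly
#' comparable); both are centered with the wild-type column means. Returns
#' the per-region Euclidean distance between the paired points and its
#' mean +/- SD.
#'
#' @param wt_matrix,mut_matrix matrices from [assemble_matrix()] with
#'   identical regions and columns.
#' @param k number of principal components (default 2; `Inf` for all).
#' @return list with `distances` (named per region), `mean`, `sd`, `k`,
#'   `pca` (the wild-type decomposition).
#' @export
project_and_distance <- function(wt_matrix, mut_matrix, k = 2) {
  if (!identical(dim(wt_matrix), dim(mut_matrix)) ||
      !identical(colnames(wt_matrix), colnames(mut_matrix)) ||
      !identical(rownames(wt_matrix), rownames(mut_matrix)))
    stop("wild-type and mutant matrices must have identical regions and columns")
  pca <- pca_abundance(wt_matrix)
  k <- min(k, ncol(pca$loadings))
  v <- pca$loadings[, seq_len(k), drop = FALSE]
  s_wt <- sweep(wt_matrix, 2, pca$center) %*% v
  s_mut <- sweep(mut_matrix, 2, pca$center) %*% v
  d <- sqrt(rowSums((s_wt - s_mut)^2))
  list(distances = d, mean = mean(d), sd = stats::sd(d), k = k, pca = pca)
}
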