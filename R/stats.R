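#' Paired t-test on replicate abundances
#'
#' For paired replicate arrays `a` (wild-type) and `b` (mutant),
#' `t = mean(a - b) / SE` with `SE = sd(a - b) / sqrt(n)` (sample SD, `n - 1`
#' denominator) and the two-sided p-value `p = 2 * F_t(-|t|)` on `n - 1`
#' degrees of freedom (39 for the default 40 replicates).
#'
#' Zero-variance differences arise for rare complexes whose integer counts
#' coincide in every replicate: with zero mean difference the result is the
#' null (`t = 0`, `p = 1`); with a nonzero mean difference the statistic is
#' degenerate and is flagged (`p = 0` with a warning).
#'
#' @param a,b numeric vectors of equal length `n >= 2`.
#' @return list with `t`, `p`, `df`, `degenerate`.
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must have equal length")
  n <- length(a)
  if (n < 2) stop("need at least 2 replicates")
  d <- a - b
  m <- mean(d)
  s <- stats::sd(d)
  if (s == 0) {
    if (m == 0) return(list(t = 0, p = 1, df = n - 1, degenerate = FALSE))
    warning("zero-variance paired differences with nonzero mean; p set to 0")
    return(list(t = sign(m) * Inf, p = 0, df = n - 1, degenerate = TRUE))
  }
  t <- m / (s / sqrt(n))
  list(t = t, p = 2 * stats::pt(-abs(t), df = n - 1), df = n - 1,
       degenerate = FALSE)
}

#' Benjamini-Hochberg step-up significance
#'
#' Standard step-up procedure: sort the p-values ascending, find the largest
#' `i` with `p_(i) <= i * alpha / m`; everything at or below `p_(i)` is
#' significant and `p_(i)` is the data-dependent threshold (0 when nothing
#' is significant).
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param alpha target false-discovery rate (default 0.05).
#' @return list with `significant` (logical, same order as `p`),
#'   `threshold` (the BH p-value cutoff), `alpha`.
#' @export
bh_adjust <- function(p, alpha = 0.05) {
  if (!length(p))
    return(list(significant = logical(0), threshold = 0, alpha = alpha))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  m <- length(p)
  ps <- sort(p)
  ok <- which(ps <= seq_len(m) * alpha / m)
  thr <- if (length(ok)) ps[max(ok)] else 0
  list(significant = p <= thr & length(ok) > 0, threshold = thr,
       alpha = alpha)
}

#' Shapiro-Wilk normality screen across regions
#'
#' Tests each replicate array for normality and applies Benjamini-Hochberg
#' control across regions; constant or too-short arrays cannot be tested and
#' are flagged degenerate (excluded from the BH family).
#'
#' @param replicates named list of numeric vectors (one per region).
#' @param alpha false-discovery rate for the BH step (default 0.05).
#' @return data frame with `id`, `W`, `p`, `degenerate`, `reject`.
#' @export
normality_check <- function(replicates, alpha = 0.05) {
  ids <- names(replicates)
  if (is.null(ids)) ids <- as.character(seq_along(replicates))
  W <- p <- rep(NA_real_, length(replicates))
  degenerate <- logical(length(replicates))
  for (i in seq_along(replicates)) {
    x <- replicates[[i]]
    if (length(x) < 3 || length(unique(x)) == 1) {
      degenerate[i] <- TRUE
      next
    }
    sw <- stats::shapiro.test(x)
    W[i] <- unname(sw$statistic)
    p[i] <- sw$p.value
  }
  reject <- logical(length(replicates))
  idx <- which(!degenerate)
  if (length(idx)) {
    bh <- bh_adjust(p[idx], alpha)
    reject[idx] <- bh$significant
  }
  data.frame(id = ids, W = W, p = p, degenerate = degenerate, reject = reject)
}

#' Paired wild-type/mutant comparison across all regions and complexes
#'
#' Runs [paired_t()] for every (region, complex) with the complex observed in
#' at least one scenario in that region; complexes never seen in a region are
#' excluded (no test). If a focus complex is given, Benjamini-Hochberg
#' control is applied across regions for that complex (the single-threshold
#' family used when reporting the most informative complex), and the
#' threshold is attached as an attribute.
#'
#' @param pairs list of `scenario_pair` objects from [run_region()].
#' @param focus optional canonical complex key to single out.
#' @param alpha false-discovery rate for the focus family (default 0.05).
#' @return data frame with `region_id`, `region_type`, `key`, `mean_wt`,
#'   `mean_mut`, `t`, `p`, `degenerate` and (focus rows only) `bh_significant`;
#'   attributes `bh_threshold` and `focus` when a focus is given.
#' @export
compare_all <- function(pairs, focus = NULL, alpha = 0.05) {
  rows <- lapply(pairs, function(pr) {
    K <- length(pr$keys)
    if (!K) return(NULL)
    # vectorized paired t over all complexes of the region (same statistic
    # as paired_t(), column-wise)
    n <- nrow(pr$wt)
    d <- pr$wt - pr$mut
    mdiff <- colMeans(d)
    s <- sqrt(colSums(sweep(d, 2, mdiff)^2) / (n - 1))
    zero <- s == 0
    t <- ifelse(zero, ifelse(mdiff == 0, 0, sign(mdiff) * Inf),
                mdiff / (s / sqrt(n)))
    p <- ifelse(zero, ifelse(mdiff == 0, 1, 0),
                2 * stats::pt(-abs(ifelse(zero, 0, t)), df = n - 1))
    dg <- zero & mdiff != 0
    data.frame(region_id = pr$region_id, region_type = pr$region_type,
               key = pr$keys, mean_wt = colMeans(pr$wt),
               mean_mut = colMeans(pr$mut), t = t, p = p,
               degenerate = dg, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(focus)) {
    out$bh_significant <- NA
    idx <- which(out$key == focus)
    if (!length(idx))
      warning("focus complex not observed in any region: ", focus)
    else {
      bh <- bh_adjust(out$p[idx], alpha)
      out$bh_significant[idx] <- bh$significant
      attr(out, "bh_threshold") <- bh$threshold
      attr(out, "focus") <- focus
    }
  }
  out
}

#' Complexes appearing in exactly one scenario
#'
#' For large supercomplexes with very low formation probability even the
#' appearance (or disappearance) of a single complex is informative; this is
#' reported descriptively, not tested. A complex "appears" in a scenario
#' when its replicate-mean abundance is positive.
#'
#' @param pairs list of `scenario_pair` objects.
#' @return data frame (`region_id`, `key`, `scenario`, `mean_abundance`)
#'   listing complexes observed in one scenario only.
#' @export
appearance_report <- function(pairs) {
  rows <- lapply(pairs, function(pr) {
    mw <- colMeans(pr$wt)
    mm <- colMeans(pr$mut)
    only_wt <- which(mw > 0 & mm == 0)
    only_mut <- which(mm > 0 & mw == 0)
    rbind(
      if (length(only_wt))
        data.frame(region_id = pr$region_id, key = pr$keys[only_wt],
                   scenario = "wt", mean_abundance = unname(mw[only_wt])),
      if (length(only_mut))
        data.frame(region_id = pr$region_id, key = pr$keys[only_mut],
                   scenario = "mut", mean_abundance = unname(mm[only_mut])))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(region_id = character(0), key = character(0),
                      scenario = character(0), mean_abundance = numeric(0))
  rownames(out) <- NULL
  out
}
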