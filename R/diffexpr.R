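# Normalization and differential expression: trimmed mean of M-values,
# log-CPM with precision weights from a mean-variance trend, and an
# empirical-Bayes moderated t-test with Benjamini-Hochberg adjustment.

#' TMM normalization factors
#'
#' Trimmed mean of M-values: for each sample against a reference column, the
#' log-ratios (M) and average log-intensities (A) of features expressed in
#' both are computed; the most extreme 30% of M and 5% of A are trimmed and
#' the remaining M values averaged with inverse asymptotic-variance weights.
#' Factors are scaled to have geometric mean 1, so sequencing depth itself is
#' carried by the library sizes, not the factors.
#'
#' @param counts Nonnegative count matrix, features x samples (>= 2 samples).
#' @param logratio_trim,sum_trim Trim fractions on M and A.
#' @return Numeric vector of per-sample scale factors, geometric mean 1.
#' @export
tmm_factors <- function(counts, logratio_trim = 0.30, sum_trim = 0.05) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("need >= 2 samples", call. = FALSE)
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  lib <- colSums(counts)
  if (any(lib == 0)) stop("sample with all-zero counts", call. = FALSE)
  # reference: sample whose upper-quartile CPM is closest to the mean UQ
  uq <- apply(sweep(counts, 2, lib, "/"), 2, quantile, probs = 0.75)
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(counts)), function(k) {
    .tmm_pair(counts[, k], counts[, ref], lib[k], lib[ref],
              logratio_trim, sum_trim)
  }, numeric(1))
  unname(.geo_centre(f))
}

.tmm_pair <- function(obs, ref, n_obs, n_ref, logratio_trim, sum_trim) {
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  if (!length(obs)) return(1)
  m <- log2((obs / n_obs) / (ref / n_ref))
  a <- 0.5 * log2((obs / n_obs) * (ref / n_ref))
  # inverse asymptotic variance of M under binomial sampling
  v <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  fin <- is.finite(m) & is.finite(a)
  m <- m[fin]; a <- a[fin]; v <- v[fin]
  if (max(abs(m)) < 1e-6) return(1)  # identical profiles
  n <- length(m)
  lo_m <- floor(n * logratio_trim) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * sum_trim) + 1; hi_a <- n + 1 - lo_a
  keep <- rank(m) >= lo_m & rank(m) <= hi_m &
          rank(a) >= lo_a & rank(a) <= hi_a
  if (!any(keep)) return(1)
  2^(sum(m[keep] / v[keep]) / sum(1 / v[keep]))
}

#' Log2-CPM with precision weights from the mean-variance trend
#'
#' Converts counts to `log2((count + 0.5) / (effective library size + 1) *
#' 1e6)` where the effective library size is the raw size times its TMM
#' factor, fits the group-wise residual standard deviation against average
#' log2 count with lowess, and returns inverse predicted-variance weights
#' for each observation.
#'
#' @param counts Count matrix, features x samples.
#' @param factors TMM factors from [tmm_factors()].
#' @param group Factor of sample groups (defaults to one group).
#' @param span Lowess span for the trend.
#' @return List with `logcpm`, `weights` (both features x samples) and
#'   `lib_effective`.
#' @export
log_cpm_with_weights <- function(counts, factors = NULL, group = NULL,
                                 span = 0.5) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("need >= 2 samples in total", call. = FALSE)
  if (is.null(factors)) factors <- rep(1, ncol(counts))
  if (is.null(group)) group <- factor(rep("all", ncol(counts)))
  group <- as.factor(group)
  lib <- colSums(counts) * factors
  y <- t(log2(t(counts + 0.5) / (lib + 1) * 1e6))

  fitted <- y
  for (g in levels(group)) {
    j <- group == g
    fitted[, j] <- rowMeans(y[, j, drop = FALSE])
  }
  df_resid <- ncol(y) - nlevels(group)
  if (df_resid < 1) stop("no residual degrees of freedom", call. = FALSE)
  s <- sqrt(rowSums((y - fitted)^2) / df_resid)
  # trend of sqrt-sd against average log2 count
  sx <- rowMeans(y) + mean(log2(lib + 1)) - log2(1e6)
  sy <- sqrt(s)
  lw <- lowess(sx, sy, f = span)
  pred <- function(x) {
    p <- approx(lw$x, lw$y, xout = x, rule = 2, ties = mean)$y
    pmax(p, 1e-3)
  }
  fitted_count <- fitted + matrix(rep(log2(lib + 1) - log2(1e6), each =
    nrow(y)), nrow(y))
  w <- 1 / pred(as.vector(fitted_count))^4
  weights <- matrix(w, nrow(y), ncol(y), dimnames = dimnames(y))
  list(logcpm = y, weights = weights, lib_effective = lib)
}

#' Moderated two-group test with empirical-Bayes variance shrinkage
#'
#' Fits weighted group means per feature, shrinks the residual variances
#' toward a common prior estimated by method-of-moments on the
#' log-variances, and tests the log2 fold change with a moderated t on
#' augmented degrees of freedom. P-values are Benjamini-Hochberg adjusted
#' over all tested features.
#'
#' @param logcpm Matrix of log2-CPM, features x samples.
#' @param weights Precision weights of the same shape (or `NULL` for 1).
#' @param group Factor with exactly two levels; fold change is level 2 minus
#'   level 1 on the log2 scale.
#' @param prior_df_fallback Prior degrees of freedom used when the
#'   method-of-moments estimate fails.
#' @return `data.frame` with `id`, `logFC`, `t`, `p`, `adj_p`.
#' @export
moderated_test <- function(logcpm, weights = NULL, group,
                           prior_df_fallback = 4) {
  logcpm <- as.matrix(logcpm)
  group <- as.factor(group)
  if (nlevels(group) != 2) stop("group must have two levels", call. = FALSE)
  if (any(table(group) < 2)) stop("need >= 2 replicates per group",
                                  call. = FALSE)
  if (is.null(weights)) weights <- matrix(1, nrow(logcpm), ncol(logcpm))
  j1 <- group == levels(group)[1]; j2 <- !j1
  w1 <- weights[, j1, drop = FALSE]; w2 <- weights[, j2, drop = FALSE]
  y1 <- logcpm[, j1, drop = FALSE]; y2 <- logcpm[, j2, drop = FALSE]
  m1 <- rowSums(w1 * y1) / rowSums(w1)
  m2 <- rowSums(w2 * y2) / rowSums(w2)
  logfc <- m2 - m1
  resid2 <- rowSums(w1 * (y1 - m1)^2) + rowSums(w2 * (y2 - m2)^2)
  df <- ncol(logcpm) - 2
  s2 <- resid2 / df
  unscaled <- 1 / rowSums(w1) + 1 / rowSums(w2)

  mom <- .fit_prior_var(s2, df, prior_df_fallback)
  s2_post <- (mom$df0 * mom$s02 + df * s2) / (mom$df0 + df)
  tt <- logfc / sqrt(s2_post * unscaled)
  p <- 2 * pt(-abs(tt), df = mom$df0 + df)
  ids <- rownames(logcpm)
  if (is.null(ids)) ids <- sprintf("f%05d", seq_along(p))
  data.frame(id = ids, logFC = logfc, t = tt, p = p,
             adj_p = p.adjust(p, "BH"), row.names = NULL,
             stringsAsFactors = FALSE)
}

# method-of-moments fit of the scaled inverse-chisq prior on residual
# variances, on the log scale (Smyth-style moment matching)
.fit_prior_var <- function(s2, df, fallback) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 10)
    return(list(df0 = fallback, s02 = stats::median(s2[ok], na.rm = TRUE)))
  e <- log(s2[ok]) - digamma(df / 2) + log(df / 2)
  excess <- var(e) - trigamma(df / 2)
  if (!is.finite(excess) || excess <= 1e-8) {
    df0 <- 4 * df + 100  # variances essentially exchangeable
  } else {
    df0 <- 2 * .trigamma_inverse(excess)
    if (!is.finite(df0) || df0 <= 0) df0 <- fallback
  }
  s02 <- exp(mean(e) + digamma(df0 / 2) - log(df0 / 2))
  if (!is.finite(s02) || s02 <= 0)
    return(list(df0 = fallback, s02 = stats::median(s2[ok])))
  list(df0 = df0, s02 = s02)
}

# Newton solve of trigamma(y) = x
.trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif / y) < 1e-8) break
  }
  y
}

#' Flag significant features under the study thresholds
#'
#' Transposon families are called at fold change strictly above 2 and genes
#' strictly above 4, both with BH-adjusted p below `alpha` (0.05 by default;
#' an `alpha = 0.01` variant is used in some per-figure gene analyses).
#'
#' @param results `data.frame` from [moderated_test()].
#' @param feature_type `"transposon"` or `"gene"`, recycled over rows.
#' @param alpha Adjusted-p threshold.
#' @param te_fc,gene_fc Fold-change thresholds (natural scale).
#' @return Logical vector of significance flags.
#' @export
call_significant <- function(results, feature_type, alpha = 0.05,
                             te_fc = 2, gene_fc = 4) {
  feature_type <- rep_len(feature_type, nrow(results))
  if (!all(feature_type %in% c("transposon", "gene")))
    stop("feature_type must be 'transposon' or 'gene'", call. = FALSE)
  fc_thr <- ifelse(feature_type == "gene", gene_fc, te_fc)
  abs(results$logFC) > log2(fc_thr) & results$adj_p < alpha
}

#' Log2 expression relative to the time-point mean
#'
#' The heatmap transform: each feature's expression at a time point on a
#' log2 scale relative to the average over all time points. A pseudocount
#' guards zeros.
#'
#' @param mat Matrix, features x time points, nonnegative.
#' @param pseudocount Added to every value before the ratio (default 0.5).
#' @return Matrix of the same shape; constant rows map to zero.
#' @export
log2_relative_to_mean <- function(mat, pseudocount = 0.5) {
  mat <- as.matrix(mat) + pseudocount
  log2(mat / rowMeans(mat))
}
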