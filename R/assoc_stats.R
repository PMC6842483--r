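#' Spearman rank correlation as Pearson-on-ranks
#'
#' Computes the Spearman coefficient as the Pearson correlation of the two
#' rank vectors, with average (mid-)ranks for ties. Pairs with a missing
#' value in either vector are removed first. Undefined (returns `NA`) when
#' fewer than 3 complete pairs remain or either rank vector is constant.
#'
#' @param x,y Numeric vectors of equal length.
#' @return The correlation, or `NA_real_` when undefined.
#' @examples
#' spearman_rho(1:3, c(2, 4, 6))   # 1
#' spearman_rho(1:4, c(1, 3, 2, 4)) # 0.8
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("spearman_rho(): unequal lengths")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) return(NA_real_)
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) return(NA_real_)
  stats::cor(rx, ry)
}

#' Ordinary least-squares line through per-level median Z-scores
#'
#' For each observed copy-number level c in -2..2 with at least one defined
#' Z-score, the median Z at that level is computed; an unweighted OLS line of
#' median Z on c is then fitted over the observed levels (one point per
#' level, regardless of per-level sample counts), returning the slope,
#' intercept and the Pearson correlation of the fitted points. Undefined
#' when fewer than 3 distinct levels are observed.
#'
#' @param calls_row Integer vector of discrete calls for one gene.
#' @param z_row Numeric vector of Z-scores (or expression values) for the
#'   same samples.
#' @return List with `slope`, `intercept`, `r`, `n_levels`, `levels`,
#'   `medians`. When undefined, the first three are `NA` and `levels` /
#'   `medians` hold whatever levels were observed.
#' @export
median_z_fit <- function(calls_row, z_row) {
  if (length(calls_row) != length(z_row)) {
    stop("median_z_fit(): unequal lengths")
  }
  ok <- !is.na(calls_row) & !is.na(z_row)
  cc <- as.numeric(calls_row[ok]); zz <- z_row[ok]
  levels <- sort(unique(cc))
  medians <- vapply(levels, function(l) stats::median(zz[cc == l]), numeric(1))
  if (length(levels) < 3L) {
    return(list(slope = NA_real_, intercept = NA_real_, r = NA_real_,
                n_levels = length(levels), levels = levels, medians = medians))
  }
  mx <- mean(levels); my <- mean(medians)
  sxx <- sum((levels - mx)^2)
  sxy <- sum((levels - mx) * (medians - my))
  syy <- sum((medians - my)^2)
  slope <- sxy / sxx
  r <- if (syy == 0) NA_real_ else sxy / sqrt(sxx * syy)
  list(slope = slope, intercept = my - slope * mx, r = r,
       n_levels = length(levels), levels = levels, medians = medians)
}

#' Welch's two-sample t-test
#'
#' `t = (mean(a) - mean(b)) / sqrt(var(a)/n_a + var(b)/n_b)` with sample
#' variances; degrees of freedom by Welch-Satterthwaite; two-sided p from the
#' Student t distribution. Degenerate inputs: when both groups have zero
#' variance and equal means, `t = 0, p = 1`; zero combined variance with
#' unequal means yields a flagged infinite t with `p = 0`.
#'
#' @param a,b Numeric vectors with at least 2 non-missing values each.
#' @return List with `t`, `df`, `p`, `mean_a`, `mean_b`, `var_a`, `var_b`,
#'   `n_a`, `n_b` and logical `degenerate`.
#' @export
welch_t <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L) {
    stop("welch_t(): each group needs at least 2 non-missing values")
  }
  na <- length(a); nb <- length(b)
  ma <- mean(a); mb <- mean(b)
  va <- stats::var(a); vb <- stats::var(b)
  se2 <- va / na + vb / nb
  if (se2 == 0) {
    if (ma == mb) {
      return(list(t = 0, df = NA_real_, p = 1, mean_a = ma, mean_b = mb,
                  var_a = va, var_b = vb, n_a = na, n_b = nb,
                  degenerate = TRUE))
    }
    return(list(t = sign(ma - mb) * Inf, df = NA_real_, p = 0, mean_a = ma,
                mean_b = mb, var_a = va, var_b = vb, n_a = na, n_b = nb,
                degenerate = TRUE))
  }
  t <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p, mean_a = ma, mean_b = mb, var_a = va,
       var_b = vb, n_a = na, n_b = nb, degenerate = FALSE)
}

#' Per-gene association between discrete calls and Z-scores
#'
#' For every valid gene: the Spearman correlation between its calls and
#' Z-scores across samples, and the median-Z-per-level linear fit
#' ([median_z_fit()]). Invalid genes are reported with `NA` statistics so
#' percentage denominators can exclude them explicitly.
#'
#' @param zmat A [compute_z()] result.
#' @param calls The matching integer call matrix.
#' @return Data frame with columns `gene`, `valid`, `rho`, `n_pairs`,
#'   `fit_slope`, `fit_intercept`, `fit_r`, `n_levels`.
#' @export
gene_association <- function(zmat, calls) {
  if (!inherits(zmat, "zscore_matrix")) {
    stop("gene_association(): `zmat` must come from compute_z()")
  }
  calls <- calls[rownames(zmat$z), colnames(zmat$z), drop = FALSE]
  genes <- rownames(zmat$z)
  out <- data.frame(gene = genes, valid = unname(zmat$valid[genes]),
                    rho = NA_real_, n_pairs = 0L, fit_slope = NA_real_,
                    fit_intercept = NA_real_, fit_r = NA_real_,
                    n_levels = 0L, stringsAsFactors = FALSE)
  for (i in seq_along(genes)) {
    if (!out$valid[i]) next
    cr <- calls[i, ]; zr <- zmat$z[i, ]
    ok <- !is.na(cr) & !is.na(zr)
    out$n_pairs[i] <- sum(ok)
    out$rho[i] <- spearman_rho(as.numeric(cr), zr)
    fit <- median_z_fit(cr, zr)
    out$fit_slope[i] <- fit$slope
    out$fit_intercept[i] <- fit$intercept
    out$fit_r[i] <- fit$r
    out$n_levels[i] <- fit$n_levels
  }
  out
}

#' Cohort-level median-Z regression on copy-number level
#'
#' Pools the Z-scores of all valid genes by discrete call level, computes the
#' pooled median Z per level, and fits the unweighted OLS line of median Z on
#' level, with the Pearson r of the fitted points and the regression p-value
#' (t-test on the slope over the level points).
#'
#' @param zmat A [compute_z()] result.
#' @param calls The matching integer call matrix.
#' @return List with `levels`, `medians`, `n_obs` (observations pooled per
#'   level), `slope`, `intercept`, `r`, `p`.
#' @export
cohort_fit <- function(zmat, calls) {
  if (!inherits(zmat, "zscore_matrix")) {
    stop("cohort_fit(): `zmat` must come from compute_z()")
  }
  calls <- calls[rownames(zmat$z), colnames(zmat$z), drop = FALSE]
  keep <- zmat$valid[rownames(zmat$z)]
  cc <- as.numeric(calls[keep, , drop = FALSE])
  zz <- as.numeric(zmat$z[keep, , drop = FALSE])
  ok <- !is.na(cc) & !is.na(zz)
  cc <- cc[ok]; zz <- zz[ok]
  levels <- sort(unique(cc))
  if (length(levels) < 3L) {
    stop("cohort_fit(): fewer than 3 observed call levels pooled over genes")
  }
  medians <- vapply(levels, function(l) stats::median(zz[cc == l]), numeric(1))
  n_obs <- vapply(levels, function(l) sum(cc == l), integer(1))
  fit <- stats::lm(medians ~ levels)
  sm <- summary(fit)
  r <- unname(sign(stats::coef(fit)[2L]) * sqrt(sm$r.squared))
  p <- unname(sm$coefficients[2L, 4L])
  list(levels = levels, medians = medians, n_obs = n_obs,
       slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]), r = r, p = p)
}

#' Welch comparison of amplified versus deleted Z-scores
#'
#' Pools Z-scores of valid genes at call +2 (amplified) and call -2
#' (deleted) and compares the two groups with [welch_t()].
#'
#' @inheritParams cohort_fit
#' @return The [welch_t()] result (`a` = amplified, `b` = deleted).
#' @export
amplified_vs_deleted <- function(zmat, calls) {
  if (!inherits(zmat, "zscore_matrix")) {
    stop("amplified_vs_deleted(): `zmat` must come from compute_z()")
  }
  calls <- calls[rownames(zmat$z), colnames(zmat$z), drop = FALSE]
  keep <- zmat$valid[rownames(zmat$z)]
  cc <- calls[keep, , drop = FALSE]
  zz <- zmat$z[keep, , drop = FALSE]
  a <- zz[!is.na(cc) & cc == 2L]
  b <- zz[!is.na(cc) & cc == -2L]
  welch_t(a[!is.na(a)], b[!is.na(b)])
}

#' Cross-dataset agreement of per-gene Spearman correlations
#'
#' Joins two [gene_association()] tables on shared gene symbols and reports
#' the fractions of shared defined genes whose correlations are positive in
#' both, negative in both, or mixed.
#'
#' @param assoc_a,assoc_b Data frames from [gene_association()].
#' @return List with `n_shared`, `frac_both_positive`, `frac_both_negative`,
#'   `frac_mixed`.
#' @export
rho_agreement <- function(assoc_a, assoc_b) {
  m <- merge(assoc_a[, c("gene", "rho")], assoc_b[, c("gene", "rho")],
             by = "gene", suffixes = c("_a", "_b"))
  m <- m[!is.na(m$rho_a) & !is.na(m$rho_b), , drop = FALSE]
  n <- nrow(m)
  if (n == 0L) {
    return(list(n_shared = 0L, frac_both_positive = NA_real_,
                frac_both_negative = NA_real_, frac_mixed = NA_real_))
  }
  bp <- mean(m$rho_a > 0 & m$rho_b > 0)
  bn <- mean(m$rho_a < 0 & m$rho_b < 0)
  list(n_shared = n, frac_both_positive = bp, frac_both_negative = bn,
       frac_mixed = 1 - bp - bn)
}
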