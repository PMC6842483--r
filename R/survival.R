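#' Kaplan-Meier product-limit estimator
#'
#' At each distinct observed time t with d events among n at risk, the
#' survival probability multiplies by (1 - d/n); censored observations
#' reduce the risk set only. Ties between events and censorings at the same
#' time are resolved with events first (the standard convention), which the
#' risk-set bookkeeping here realises automatically because censorings at t
#' are still at risk at t.
#'
#' @param time Positive observation times.
#' @param event 0/1 event indicators (1 = death observed).
#' @return Data frame of class `"km_curve"` with one row per distinct
#'   observed time: `time`, `n_risk`, `n_event`, `n_censor`, `surv`. The
#'   estimate is 1 before the first row.
#' @examples
#' km_estimate(c(1, 2, 3), c(1, 1, 1))$surv # 2/3, 1/3, 0
#' @export
km_estimate <- function(time, event) {
  if (length(time) < 1L) stop("km_estimate(): need at least one observation")
  if (length(time) != length(event)) stop("km_estimate(): unequal lengths")
  if (anyNA(time) || anyNA(event)) stop("km_estimate(): missing values")
  if (any(time <= 0)) stop("km_estimate(): times must be positive")
  if (!all(event %in% c(0, 1))) stop("km_estimate(): `event` must be 0/1")
  times <- sort(unique(time))
  n_risk <- n_event <- n_censor <- integer(length(times))
  surv <- numeric(length(times))
  s <- 1
  for (i in seq_along(times)) {
    t <- times[i]
    n_risk[i] <- sum(time >= t)
    n_event[i] <- sum(time == t & event == 1)
    n_censor[i] <- sum(time == t & event == 0)
    s <- s * (1 - n_event[i] / n_risk[i])
    surv[i] <- s
  }
  structure(data.frame(time = times, n_risk = n_risk, n_event = n_event,
                       n_censor = n_censor, surv = surv),
            class = c("km_curve", "data.frame"))
}

#' Two-group log-rank test
#'
#' At each distinct event time the observed number of events in group A is
#' compared with its hypergeometric expectation given the margins; the
#' chi-square statistic is `(O - E)^2 / V` summed over event times, with the
#' variance `d (n_A/n) (n_B/n) (n - d) / (n - 1)` per time, referred to a
#' chi-square distribution with 1 degree of freedom (two-sided). The
#' statistic is symmetric in the group labels.
#'
#' @param time Positive observation times.
#' @param event 0/1 event indicators.
#' @param group Two-level factor or character/logical vector.
#' @return List with `chisq`, `df`, `p`, `observed`, `expected` (per group),
#'   `n` (group sizes) and `groups`. `chisq` and `p` are `NA` (flagged via
#'   `defined = FALSE`) when no events occurred.
#' @export
logrank_test <- function(time, event, group) {
  if (length(time) != length(event) || length(time) != length(group)) {
    stop("logrank_test(): unequal lengths")
  }
  if (any(time <= 0)) stop("logrank_test(): times must be positive")
  g <- as.character(group)
  lev <- sort(unique(g))
  if (length(lev) != 2L) {
    stop("logrank_test(): `group` must have exactly 2 non-empty levels (got ",
         length(lev), ")")
  }
  in_a <- g == lev[1L]
  o_a <- sum(event[in_a]); o_b <- sum(event[!in_a])
  if (o_a + o_b == 0) {
    return(list(chisq = NA_real_, df = 1L, p = NA_real_,
                observed = stats::setNames(c(0, 0), lev),
                expected = stats::setNames(c(NA_real_, NA_real_), lev),
                n = stats::setNames(c(sum(in_a), sum(!in_a)), lev),
                groups = lev, defined = FALSE))
  }
  etimes <- sort(unique(time[event == 1]))
  e_a <- 0; v <- 0
  for (t in etimes) {
    at <- time >= t
    n <- sum(at); n_a <- sum(at & in_a)
    d <- sum(time == t & event == 1)
    e_a <- e_a + d * n_a / n
    if (n > 1) v <- v + d * (n_a / n) * (1 - n_a / n) * (n - d) / (n - 1)
  }
  chisq <- if (v > 0) (o_a - e_a)^2 / v else NA_real_
  p <- if (is.na(chisq)) NA_real_ else stats::pchisq(chisq, 1, lower.tail = FALSE)
  list(chisq = chisq, df = 1L, p = p,
       observed = stats::setNames(c(o_a, o_b), lev),
       expected = stats::setNames(c(e_a, o_a + o_b - e_a), lev),
       n = stats::setNames(c(sum(in_a), sum(!in_a)), lev),
       groups = lev, defined = !is.na(chisq))
}

#' Split a cohort into tendency carriers and non-carriers for one gene
#'
#' Carriers are the samples labelled with the chosen tendency (AU or DD) for
#' the gene; all other samples with clinical records are non-carriers (the
#' "N-A&U" / "N-D&D" groups). Samples without clinical records are excluded
#' with a message.
#'
#' @param tt A [classify_tendency()] result.
#' @param clinical Data frame with columns `sample`, `os_time`, `os_event`.
#' @param gene Gene symbol (must be valid in `tt`).
#' @param tendency `"AU"` or `"DD"`.
#' @return Data frame (sample, time, event, group) with `group` in
#'   `c("carrier", "non-carrier")`.
#' @export
tendency_groups <- function(tt, clinical, gene, tendency = c("AU", "DD")) {
  tendency <- match.arg(tendency)
  if (!inherits(tt, "tendency_table")) {
    stop("tendency_groups(): `tt` must come from classify_tendency()")
  }
  if (!gene %in% rownames(tt$label)) {
    stop("tendency_groups(): gene not in cohort: ", gene)
  }
  if (!isTRUE(tt$valid[[gene]])) {
    stop("tendency_groups(): gene has no valid Z-scores: ", gene)
  }
  lab <- tt$label[gene, ]
  samples <- colnames(tt$label)
  with_clin <- samples %in% clinical$sample
  if (any(!with_clin)) {
    message("tendency_groups(): excluding ", sum(!with_clin),
            " sample(s) without clinical records")
  }
  samples <- samples[with_clin]
  lab <- lab[with_clin]
  carrier <- !is.na(lab) & lab == tendency
  if (sum(carrier) == 0L) {
    stop("tendency_groups(): empty carrier group for gene ", gene,
         ", tendency ", tendency)
  }
  idx <- match(samples, clinical$sample)
  data.frame(sample = samples,
             time = clinical$os_time[idx],
             event = clinical$os_event[idx],
             group = ifelse(carrier, "carrier", "non-carrier"),
             stringsAsFactors = FALSE)
}

#' Log-rank survival screen over tendency-stratified genes
#'
#' For each (gene, tendency) pair, splits the cohort with
#' [tendency_groups()] and runs [logrank_test()]; raw p-values are reported
#' alongside Benjamini-Hochberg adjusted ones across all tested genes. Genes
#' whose carrier group is empty (or that are invalid) are skipped with a
#' note in the `note` column.
#'
#' @param tt A [classify_tendency()] result.
#' @param clinical Clinical data frame (`sample`, `os_time`, `os_event`).
#' @param genes Character vector of gene symbols to test.
#' @param tendencies Character vector (recycled against `genes`) of
#'   tendencies, `"AU"` or `"DD"`.
#' @return Data frame with one row per tested gene: `gene`, `tendency`,
#'   `n_carrier`, `n_other`, `chisq`, `p`, `p_adj`, `note`.
#' @export
survival_by_tendency <- function(tt, clinical, genes,
                                 tendencies = "AU") {
  tendencies <- rep_len(tendencies, length(genes))
  rows <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    res <- tryCatch({
      grp <- suppressMessages(
        tendency_groups(tt, clinical, genes[i], tendencies[i]))
      lr <- logrank_test(grp$time, grp$event, grp$group)
      data.frame(gene = genes[i], tendency = tendencies[i],
                 n_carrier = sum(grp$group == "carrier"),
                 n_other = sum(grp$group == "non-carrier"),
                 chisq = lr$chisq, p = lr$p, note = "",
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(gene = genes[i], tendency = tendencies[i],
                 n_carrier = NA_integer_, n_other = NA_integer_,
                 chisq = NA_real_, p = NA_real_, note = conditionMessage(e),
                 stringsAsFactors = FALSE)
    })
    rows[[i]] <- res
  }
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out[, c("gene", "tendency", "n_carrier", "n_other", "chisq", "p", "p_adj",
          "note")]
}

#' Empirical type-I error of the log-rank test under the null
#'
#' Simulates `n_rep` two-group cohorts with identical exponential event
#' hazards in both groups (hazard ratio 1) and independent exponential
#' censoring, and reports the fraction of replicates with log-rank
#' p < `alpha`.
#'
#' @param n_rep Number of replicates.
#' @param n Samples per replicate.
#' @param os_mean,censor_mean Means of the exponential event and censoring
#'   time distributions.
#' @param p_carrier Probability a sample falls in the carrier group.
#' @param alpha Nominal level.
#' @param seed Optional integer seed.
#' @return List with `rejection_rate`, `n_rep`, `n_used` (replicates with a
#'   defined test).
#' @export
logrank_null_calibration <- function(n_rep = 1000, n = 200, os_mean = 50,
                                     censor_mean = 80, p_carrier = 0.3,
                                     alpha = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  reject <- logical(n_rep)
  used <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    t_event <- stats::rexp(n, 1 / os_mean)
    t_cens <- stats::rexp(n, 1 / censor_mean)
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
    grp <- ifelse(stats::runif(n) < p_carrier, "carrier", "non-carrier")
    if (length(unique(grp)) < 2L) next
    lr <- logrank_test(time, event, grp)
    if (isTRUE(lr$defined)) {
      used[r] <- TRUE
      reject[r] <- lr$p < alpha
    }
  }
  list(rejection_rate = sum(reject) / sum(used), n_rep = n_rep,
       n_used = sum(used))
}
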