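#' Classify the four CNV/expression variation tendencies
#'
#' Combines variant status (+2 amplified / -2 deleted; see
#' [variant_status()]) with differential-expression status into the four
#' tendencies: AU (amplified and upregulated), AD (amplified and
#' downregulated), DU (deleted and upregulated), DD (deleted and
#' downregulated); every other (gene, sample) pair is "none". Genes whose
#' Z-scores are undefined (invalid reference) contribute no labels and are
#' excluded from the variant-event totals.
#'
#' @param calls Integer call matrix.
#' @param degs A [call_degs()] result computed from the same calls (same
#'   diploid reference).
#' @return An object of class `"tendency_table"`: list with `label`
#'   (character matrix; `NA` rows for invalid genes), `variant` (character
#'   matrix of variant status, `NA` for invalid genes), `counts` (data frame
#'   with per-gene `n_AU`, `n_AD`, `n_DU`, `n_DD`, `n_amp`, `n_del`),
#'   `totals` (list with per-tendency totals and `total_variant_cn`, the
#'   count of variant events among valid genes) and `valid`.
#' @export
classify_tendency <- function(calls, degs) {
  if (!inherits(degs, "deg_calls")) {
    stop("classify_tendency(): `degs` must come from call_degs()")
  }
  if (!setequal(rownames(calls), rownames(degs$status)) ||
      !setequal(colnames(calls), colnames(degs$status))) {
    stop("classify_tendency(): `calls` and `degs` must share gene and sample indices")
  }
  calls <- calls[rownames(degs$status), colnames(degs$status), drop = FALSE]
  genes <- rownames(calls)
  vs <- matrix(variant_status(calls), nrow(calls), ncol(calls),
               dimnames = dimnames(calls))
  valid <- degs$valid[genes]
  vs[!valid, ] <- NA_character_

  label <- matrix("none", nrow(calls), ncol(calls), dimnames = dimnames(calls))
  st <- degs$status
  label[vs == "amplified" & st == "up"] <- "AU"
  label[vs == "amplified" & st == "down"] <- "AD"
  label[vs == "deleted" & st == "up"] <- "DU"
  label[vs == "deleted" & st == "down"] <- "DD"
  label[!valid, ] <- NA_character_

  cnt <- function(what) rowSums(label == what, na.rm = TRUE)
  counts <- data.frame(gene = genes,
                       n_AU = cnt("AU"), n_AD = cnt("AD"),
                       n_DU = cnt("DU"), n_DD = cnt("DD"),
                       n_amp = rowSums(vs == "amplified", na.rm = TRUE),
                       n_del = rowSums(vs == "deleted", na.rm = TRUE),
                       row.names = NULL, stringsAsFactors = FALSE)
  totals <- list(n_AU = sum(counts$n_AU), n_AD = sum(counts$n_AD),
                 n_DU = sum(counts$n_DU), n_DD = sum(counts$n_DD),
                 total_variant_cn = sum(counts$n_amp) + sum(counts$n_del))
  structure(list(label = label, variant = vs, counts = counts,
                 totals = totals, valid = valid),
            class = "tendency_table")
}

#' @export
print.tendency_table <- function(x, ...) {
  cat(sprintf("Variation tendencies: %d genes x %d samples (%d valid genes)\n",
              nrow(x$label), ncol(x$label), sum(x$valid)))
  cat(sprintf("  events: AU %d, AD %d, DU %d, DD %d of %d variant CN events\n",
              x$totals$n_AU, x$totals$n_AD, x$totals$n_DU, x$totals$n_DD,
              x$totals$total_variant_cn))
  invisible(x)
}

#' Per-cohort tendency fractions of the total variant copy-number count
#'
#' For each cohort of samples, the fraction of its variant copy-number events
#' (+-2 calls among valid genes, whether or not a differential-expression
#' event co-occurs) that are AU, AD, DU or DD. A cohort with no variant
#' events gets `NA` fractions and is flagged.
#'
#' @param tt A [classify_tendency()] result.
#' @param grouping Named character vector mapping every sample to a cohort;
#'   `NULL` places all samples in a single cohort `"all"`.
#' @return Data frame with one row per cohort: `cohort`, `n_variant`,
#'   `frac_AU`, `frac_AD`, `frac_DU`, `frac_DD` and `defined` (FALSE when the
#'   cohort had no variant events).
#' @export
cohort_tendency_fractions <- function(tt, grouping = NULL) {
  if (!inherits(tt, "tendency_table")) {
    stop("cohort_tendency_fractions(): `tt` must come from classify_tendency()")
  }
  samples <- colnames(tt$label)
  if (is.null(grouping)) {
    grouping <- stats::setNames(rep("all", length(samples)), samples)
  }
  missing_s <- setdiff(samples, names(grouping))
  if (length(missing_s) > 0L) {
    stop("cohort_tendency_fractions(): sample(s) not mapped to a cohort: ",
         paste(utils::head(missing_s, 5L), collapse = ", "))
  }
  grouping <- grouping[samples]
  cohorts <- sort(unique(grouping))
  rows <- lapply(cohorts, function(ch) {
    cols <- samples[grouping == ch]
    lab <- tt$label[, cols, drop = FALSE]
    vs <- tt$variant[, cols, drop = FALSE]
    n_var <- sum(vs %in% c("amplified", "deleted"))
    frac <- function(what) {
      if (n_var == 0) NA_real_ else sum(lab == what, na.rm = TRUE) / n_var
    }
    data.frame(cohort = ch, n_variant = n_var,
               frac_AU = frac("AU"), frac_AD = frac("AD"),
               frac_DU = frac("DU"), frac_DD = frac("DD"),
               defined = n_var > 0, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Long-format table of tendency events
#'
#' @param tt A [classify_tendency()] result.
#' @return Data frame (gene, sample, label) with one row per non-"none"
#'   tendency event.
#' @export
tendency_events <- function(tt) {
  if (!inherits(tt, "tendency_table")) {
    stop("tendency_events(): `tt` must come from classify_tendency()")
  }
  idx <- which(!is.na(tt$label) & tt$label != "none", arr.ind = TRUE)
  out <- data.frame(gene = rownames(tt$label)[idx[, 1L]],
                    sample = colnames(tt$label)[idx[, 2L]],
                    label = tt$label[idx],
                    stringsAsFactors = FALSE)
  out[order(out$gene, out$sample), , drop = FALSE]
}
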