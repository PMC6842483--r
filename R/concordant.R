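#' Concordance ratios from AU/DD event counts
#'
#' Adds `au_ratio = n_AU / (n_AU + n_DD)` and `dd_ratio = 1 - au_ratio` to a
#' per-gene count table; genes with no concordant events get `NA` ratios.
#' This is the arithmetic behind dominance statements such as "73% of a
#' gene's concordant events are deletion-with-downregulation".
#'
#' @param counts Data frame with columns `gene`, `n_AU`, `n_DD`.
#' @return The input with `au_ratio` and `dd_ratio` columns appended.
#' @export
concordance_ratios <- function(counts) {
  need <- c("gene", "n_AU", "n_DD")
  if (!all(need %in% names(counts))) {
    stop("concordance_ratios(): `counts` needs columns ",
         paste(need, collapse = ", "))
  }
  tot <- counts$n_AU + counts$n_DD
  counts$au_ratio <- ifelse(tot > 0, counts$n_AU / tot, NA_real_)
  counts$dd_ratio <- ifelse(tot > 0, counts$n_DD / tot, NA_real_)
  counts
}

#' Per-gene concordance table
#'
#' Joins the tendency event counts with the per-gene association statistics
#' and derives the concordance ratios: `au_ratio = n_AU / (n_AU + n_DD)` and
#' `dd_ratio = 1 - au_ratio` (the denominator is the concordant event count
#' only, not all variant events).
#'
#' @param tt A [classify_tendency()] result.
#' @param assoc A [gene_association()] data frame on the same cohort.
#' @return Data frame with columns `gene`, `n_AU`, `n_DD`, `au_ratio`,
#'   `dd_ratio`, `rho`, `n_amp`, `n_del`, `valid`.
#' @export
concordance_table <- function(tt, assoc) {
  if (!inherits(tt, "tendency_table")) {
    stop("concordance_table(): `tt` must come from classify_tendency()")
  }
  gc <- merge(tt$counts[, c("gene", "n_AU", "n_DD", "n_amp", "n_del")],
              assoc[, c("gene", "rho", "valid")], by = "gene")
  gc <- concordance_ratios(gc)
  gc[, c("gene", "n_AU", "n_DD", "au_ratio", "dd_ratio", "rho",
         "n_amp", "n_del", "valid")]
}

#' Calibrate AUG/DDG thresholds from reference gene lists
#'
#' The count and correlation thresholds are the medians over the reference
#' oncogene list (for the AUG criteria: median n_AU and median rho) and the
#' reference tumor-suppressor list (for the DDG criteria: median n_DD and
#' median rho). The median of an even-length list is the mean of the two
#' central order statistics, which is how half-integer count thresholds
#' arise. Reference genes absent from the table are dropped with a message.
#'
#' @param gc A [concordance_table()] data frame.
#' @param oncogenes,tsgs Character vectors of reference gene symbols.
#' @param ratio_min Concordance-ratio cutoff (default 0.5).
#' @return An object of class `"concordance_thresholds"`.
#' @export
calibrate_thresholds <- function(gc, oncogenes, tsgs, ratio_min = 0.5) {
  if (ratio_min <= 0 || ratio_min >= 1) {
    stop("calibrate_thresholds(): `ratio_min` must lie in (0, 1)")
  }
  use <- function(ref, what) {
    present <- intersect(ref, gc$gene)
    absent <- setdiff(ref, gc$gene)
    if (length(absent) > 0L) {
      message("calibrate_thresholds(): dropping ", length(absent), " ", what,
              " absent from the table: ",
              paste(utils::head(absent, 5L), collapse = ", "))
    }
    if (length(present) == 0L) {
      stop("calibrate_thresholds(): no usable ", what,
           " in the table; use fixed_thresholds() instead")
    }
    gc[match(present, gc$gene), , drop = FALSE]
  }
  og <- use(oncogenes, "reference oncogene(s)")
  ts <- use(tsgs, "reference tumor suppressor gene(s)")
  structure(list(rho_min_aug = stats::median(og$rho, na.rm = TRUE),
                 count_min_aug = stats::median(og$n_AU),
                 rho_min_ddg = stats::median(ts$rho, na.rm = TRUE),
                 count_min_ddg = stats::median(ts$n_DD),
                 ratio_min = ratio_min, mode = "calibrated",
                 n_oncogenes = nrow(og), n_tsgs = nrow(ts)),
            class = "concordance_thresholds")
}

#' Fixed AUG/DDG thresholds
#'
#' Verbatim threshold mode: by default the values calibrated on the 9,159
#' TCGA tumor samples (rho > 0.4 and n_AU > 146.5 for AUGs; rho > 0.41 and
#' n_DD > 18.5 for DDGs). Intended for cohorts of comparable size; for other
#' cohorts prefer [calibrate_thresholds()].
#'
#' @param rho_min_aug,count_min_aug,rho_min_ddg,count_min_ddg Threshold
#'   values (strict lower bounds).
#' @param ratio_min Concordance-ratio cutoff (default 0.5).
#' @return An object of class `"concordance_thresholds"`.
#' @export
fixed_thresholds <- function(rho_min_aug = 0.4, count_min_aug = 146.5,
                             rho_min_ddg = 0.41, count_min_ddg = 18.5,
                             ratio_min = 0.5) {
  if (ratio_min <= 0 || ratio_min >= 1) {
    stop("fixed_thresholds(): `ratio_min` must lie in (0, 1)")
  }
  if (count_min_aug < 0 || count_min_ddg < 0) {
    stop("fixed_thresholds(): count thresholds must be >= 0")
  }
  structure(list(rho_min_aug = rho_min_aug, count_min_aug = count_min_aug,
                 rho_min_ddg = rho_min_ddg, count_min_ddg = count_min_ddg,
                 ratio_min = ratio_min, mode = "fixed"),
            class = "concordance_thresholds")
}

#' @export
print.concordance_thresholds <- function(x, ...) {
  cat(sprintf("Concordance thresholds (%s mode):\n", x$mode))
  cat(sprintf("  AUG: rho > %.4g and n_AU > %.4g\n", x$rho_min_aug,
              x$count_min_aug))
  cat(sprintf("  DDG: rho > %.4g and n_DD > %.4g\n", x$rho_min_ddg,
              x$count_min_ddg))
  cat(sprintf("  concordance ratio > %.2g\n", x$ratio_min))
  invisible(x)
}

#' Identify AUGs and DDGs
#'
#' A gene is an AUG when its AU concordance ratio strictly exceeds
#' `ratio_min`, its Spearman rho strictly exceeds `rho_min_aug` and its AU
#' event count strictly exceeds `count_min_aug`; symmetrically for DDGs with
#' the DD ratio, `rho_min_ddg` and `count_min_ddg`. Rho enters as the signed
#' call-versus-Z correlation for both classes: a true DDG has positive rho,
#' since deletion with downregulation is a positive dosage relationship.
#' Genes with no concordant events (`n_AU + n_DD = 0`) or undefined rho are
#' "neither". The two classes are mutually exclusive because the AU and DD
#' ratios cannot both exceed 0.5.
#'
#' @param gc A [concordance_table()] data frame.
#' @param thresholds A `"concordance_thresholds"` object.
#' @return `gc` with an added `status` column in `c("AUG", "DDG",
#'   "neither")`.
#' @export
identify_aug_ddg <- function(gc, thresholds) {
  if (!inherits(thresholds, "concordance_thresholds")) {
    stop("identify_aug_ddg(): `thresholds` must be a concordance_thresholds object")
  }
  rho_ok <- !is.na(gc$rho)
  has_ratio <- !is.na(gc$au_ratio)
  aug <- has_ratio & rho_ok &
    gc$au_ratio > thresholds$ratio_min &
    gc$rho > thresholds$rho_min_aug &
    gc$n_AU > thresholds$count_min_aug
  ddg <- has_ratio & rho_ok &
    gc$dd_ratio > thresholds$ratio_min &
    gc$rho > thresholds$rho_min_ddg &
    gc$n_DD > thresholds$count_min_ddg
  gc$status <- "neither"
  gc$status[aug] <- "AUG"
  gc$status[ddg] <- "DDG"
  gc
}

#' Rank top concordant genes
#'
#' AUGs are sorted by their AU event count descending and DDGs by their DD
#' event count descending; ties are broken by rho descending, then by gene
#' symbol lexicographically, so the order is deterministic.
#'
#' @param gc An [identify_aug_ddg()] data frame.
#' @param k Number of genes to return (the full list when `k` exceeds it).
#' @param status `"AUG"` or `"DDG"`.
#' @return Character vector of gene symbols, best first.
#' @export
rank_top_concordant <- function(gc, k, status = c("AUG", "DDG")) {
  status <- match.arg(status)
  if (!is.numeric(k) || length(k) != 1L || k < 1) {
    stop("rank_top_concordant(): `k` must be >= 1")
  }
  sel <- gc[gc$status == status, , drop = FALSE]
  count <- if (status == "AUG") sel$n_AU else sel$n_DD
  rho <- ifelse(is.na(sel$rho), -Inf, sel$rho)
  ord <- order(-count, -rho, sel$gene)
  utils::head(sel$gene[ord], k)
}

#' Chromosome distribution of concordant genes
#'
#' Fraction of all identified AUG and DDG genes located on each chromosome.
#' Unannotated concordant genes are dropped (with a message) and excluded
#' from the denominator; the reported fractions sum to 1 over annotated
#' genes.
#'
#' @param gc An [identify_aug_ddg()] data frame.
#' @param annotation Data frame with columns `gene` and `chromosome`.
#' @return Data frame (chromosome, n, fraction) sorted by fraction
#'   descending; zero rows when no AUG/DDG was identified.
#' @export
chromosome_distribution <- function(gc, annotation) {
  conc <- gc$gene[gc$status %in% c("AUG", "DDG")]
  if (length(conc) == 0L) {
    return(data.frame(chromosome = character(0), n = integer(0),
                      fraction = numeric(0)))
  }
  chr <- annotation$chromosome[match(conc, annotation$gene)]
  drop <- is.na(chr)
  if (any(drop)) {
    message("chromosome_distribution(): dropping ", sum(drop),
            " unannotated concordant gene(s)")
  }
  chr <- chr[!drop]
  tab <- table(chr)
  out <- data.frame(chromosome = names(tab), n = as.integer(tab),
                    fraction = as.numeric(tab) / sum(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$fraction, out$chromosome), , drop = FALSE]
  rownames(out) <- NULL
  out
}
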