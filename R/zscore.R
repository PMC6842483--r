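#' Diploid-referenced expression Z-scores
#'
#' For each gene the reference set is the samples that are copy-number
#' diploid (call 0) for that gene. With u and o the mean and sample
#' (n-1 denominator) standard deviation of the gene's expression over that
#' reference set, `z(g, s) = (x(g, s) - u) / o` for every sample s. Genes
#' with fewer than `min_diploid` diploid reference samples or with zero
#' reference variance are flagged invalid: their z-values stay undefined and
#' they are excluded downstream, with the reason recorded.
#'
#' @param expression Non-negative gene-by-sample expression matrix (RSEM-like
#'   values, used as-is unless `log2_offset` is set).
#' @param calls Integer call matrix from [calls_from_gistic()] or
#'   [calls_from_picnic()], sharing the gene/sample index sets of
#'   `expression` (order may differ).
#' @param min_diploid Minimum diploid reference size for a gene to be valid
#'   (default 3; a 1-2 sample reference makes o meaningless).
#' @param log2_offset Optional pseudo-count; when non-`NULL`, expression is
#'   transformed to `log2(x + log2_offset)` before referencing. Off by
#'   default.
#' @return An object of class `"zscore_matrix"`: list with `z` (numeric
#'   matrix, `NA` where undefined), `diploid_n`, `valid`, `u`, `o`, `reason`
#'   (per-gene vectors) and `min_diploid`.
#' @examples
#' expr <- rbind(g1 = c(1, 2, 3, 4))
#' calls <- rbind(g1 = c(0L, 0L, 0L, 2L))
#' colnames(expr) <- colnames(calls) <- paste0("s", 1:4)
#' compute_z(expr, calls)$z # reference mean 2, sd 1 -> z = (x - 2)/1
#' @export
compute_z <- function(expression, calls, min_diploid = 3, log2_offset = NULL) {
  if (!is.matrix(expression) || length(expression) == 0L) {
    stop("compute_z(): `expression` must be a non-empty matrix")
  }
  if (min_diploid < 2) stop("compute_z(): `min_diploid` must be >= 2")
  if (is.null(rownames(expression)) || is.null(colnames(expression)) ||
      is.null(rownames(calls)) || is.null(colnames(calls))) {
    stop("compute_z(): both matrices need gene rownames and sample colnames")
  }
  if (!setequal(rownames(expression), rownames(calls)) ||
      !setequal(colnames(expression), colnames(calls))) {
    stop("compute_z(): `expression` and `calls` must share gene and sample index sets")
  }
  calls <- calls[rownames(expression), colnames(expression), drop = FALSE]
  if (!is.null(log2_offset)) expression <- log2(expression + log2_offset)

  genes <- rownames(expression)
  ng <- length(genes)
  z <- matrix(NA_real_, ng, ncol(expression), dimnames = dimnames(expression))
  diploid_n <- integer(ng)
  u <- o <- rep(NA_real_, ng)
  valid <- logical(ng)
  reason <- rep("", ng)
  for (i in seq_len(ng)) {
    ref <- !is.na(calls[i, ]) & calls[i, ] == 0L & !is.na(expression[i, ])
    n <- sum(ref)
    diploid_n[i] <- n
    if (n < min_diploid) {
      reason[i] <- "too_few_diploid"
      next
    }
    xi <- expression[i, ref]
    ui <- mean(xi)
    oi <- stats::sd(xi)
    u[i] <- ui
    o[i] <- oi
    if (!is.finite(oi) || oi <= 0) {
      reason[i] <- "zero_variance"
      next
    }
    valid[i] <- TRUE
    z[i, ] <- (expression[i, ] - ui) / oi
  }
  names(diploid_n) <- names(u) <- names(o) <- names(valid) <- names(reason) <- genes
  structure(list(z = z, diploid_n = diploid_n, valid = valid, u = u, o = o,
                 reason = reason, min_diploid = min_diploid),
            class = "zscore_matrix")
}

#' @export
print.zscore_matrix <- function(x, ...) {
  cat(sprintf("Diploid-referenced Z-scores: %d genes x %d samples (%d valid genes)\n",
              nrow(x$z), ncol(x$z), sum(x$valid)))
  if (any(!x$valid)) {
    tab <- table(x$reason[!x$valid])
    cat("  excluded:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Call per-(gene, sample) differential-expression events from Z-scores
#'
#' A sample is upregulated for a gene when its Z-score is strictly greater
#' than `threshold` and downregulated when strictly less than `-threshold`
#' (boundary values are "none"). Undefined Z-scores (invalid genes) yield
#' "none".
#'
#' @param zmat A [compute_z()] result.
#' @param threshold Positive Z cutoff (default 2).
#' @return An object of class `"deg_calls"`: list with `status` (character
#'   matrix in up/down/none), per-gene counts `n_up`, `n_down`, the per-gene
#'   `valid` flags carried over from `zmat`, and `threshold`.
#' @export
call_degs <- function(zmat, threshold = 2) {
  if (!inherits(zmat, "zscore_matrix")) {
    stop("call_degs(): `zmat` must come from compute_z()")
  }
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0) {
    stop("call_degs(): `threshold` must be a positive scalar")
  }
  status <- matrix("none", nrow(zmat$z), ncol(zmat$z),
                   dimnames = dimnames(zmat$z))
  status[!is.na(zmat$z) & zmat$z > threshold] <- "up"
  status[!is.na(zmat$z) & zmat$z < -threshold] <- "down"
  structure(list(status = status,
                 n_up = rowSums(status == "up"),
                 n_down = rowSums(status == "down"),
                 valid = zmat$valid,
                 threshold = threshold),
            class = "deg_calls")
}
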