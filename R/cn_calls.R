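#' Classify absolute copy number under the PICNIC ploidy-conditional criteria
#'
#' PICNIC-style callers (as used for the COSMIC Cell Lines Project) report an
#' absolute total DNA segment copy number per gene together with the sample's
#' average genome ploidy. Amplification and deletion are then defined relative
#' to ploidy:
#'
#' * amplified: ploidy <= 2.7 and total copy number >= 5, or ploidy > 2.7 and
#'   total copy number >= 9;
#' * deleted: ploidy <= 2.7 and total copy number = 0, or ploidy > 2.7 and
#'   total copy number < ploidy - 2.7;
#' * neutral otherwise.
#'
#' The ploidy = 2.7 boundary belongs to the near-diploid branch; the
#' high-ploidy deletion inequality is strict and `ploidy - 2.7` is not
#' rounded. Amplification takes precedence in the (unrealistic, ploidy > 11.7)
#' corner where both printed inequalities could hold, so the two classes are
#' mutually exclusive.
#'
#' @param total_cn Non-negative integer vector of total segment copy numbers.
#' @param ploidy Positive numeric vector of per-sample average genome ploidy,
#'   recycled against `total_cn`.
#' @return Character vector in `c("amplified", "deleted", "neutral")`.
#' @examples
#' classify_picnic(c(5, 0, 2), c(2.0, 2.0, 2.0))
#' classify_picnic(0, 3.0) # 0 < 3.0 - 2.7, deleted
#' @export
classify_picnic <- function(total_cn, ploidy) {
  if (length(total_cn) == 0L) return(character(0))
  n <- max(length(total_cn), length(ploidy))
  total_cn <- rep_len(as.numeric(total_cn), n)
  ploidy <- rep_len(as.numeric(ploidy), n)
  if (anyNA(total_cn) || anyNA(ploidy) || any(!is.finite(total_cn)) ||
      any(!is.finite(ploidy))) {
    stop("classify_picnic(): total_cn and ploidy must be finite and non-missing")
  }
  if (any(total_cn < 0)) {
    stop("classify_picnic(): negative total_cn (first offending value: ",
         total_cn[which(total_cn < 0)[1L]], ")")
  }
  if (any(ploidy <= 0)) {
    stop("classify_picnic(): ploidy must be positive (first offending value: ",
         ploidy[which(ploidy <= 0)[1L]], ")")
  }
  low <- ploidy <= 2.7
  amplified <- (low & total_cn >= 5) | (!low & total_cn >= 9)
  deleted <- !amplified &
    ((low & total_cn == 0) | (!low & total_cn < ploidy - 2.7))
  out <- rep("neutral", n)
  out[amplified] <- "amplified"
  out[deleted] <- "deleted"
  out
}

#' Validate a GISTIC-style discrete copy-number call matrix
#'
#' Checks that every entry is an integer on the five-level GISTIC scale
#' (-2 homozygous deletion, -1 hemizygous deletion, 0 neutral, +1 gain,
#' +2 high-level amplification) or `NA`. Missing entries stay missing — they
#' are treated as "not evaluable" downstream rather than imputed to neutral,
#' which would inflate the diploid reference sets.
#'
#' @param mat Numeric gene-by-sample matrix with rownames (genes) and
#'   colnames (samples); entries in `-2:2` or `NA`.
#' @return Integer matrix with the same dimnames.
#' @export
calls_from_gistic <- function(mat) {
  if (!is.matrix(mat)) stop("calls_from_gistic(): `mat` must be a matrix")
  if (is.null(rownames(mat)) || is.null(colnames(mat))) {
    stop("calls_from_gistic(): `mat` must have gene rownames and sample colnames")
  }
  vals <- suppressWarnings(as.numeric(mat))
  bad <- which(!is.na(vals) & (vals != round(vals) | vals < -2 | vals > 2))
  if (length(bad) > 0L) {
    i <- bad[1L]
    r <- ((i - 1L) %% nrow(mat)) + 1L
    c <- ((i - 1L) %/% nrow(mat)) + 1L
    stop(sprintf(
      "calls_from_gistic(): call out of range {-2..2} for gene '%s', sample '%s': %s",
      rownames(mat)[r], colnames(mat)[c], format(vals[i])))
  }
  out <- matrix(as.integer(round(vals)), nrow(mat), ncol(mat),
                dimnames = dimnames(mat))
  out
}

#' Derive discrete calls from absolute copy number and ploidy
#'
#' Applies [classify_picnic()] column-wise and maps amplified to +2, deleted
#' to -2 and neutral to 0. The PICNIC thresholds define only amplification and
#' deletion, so the intermediate GISTIC levels (+1 gain, -1 hemizygous
#' deletion) are not recoverable on this path; neutral covers them.
#'
#' @param total_cn Non-negative integer gene-by-sample matrix with dimnames.
#' @param ploidy Named numeric vector of per-sample average genome ploidy;
#'   names must cover `colnames(total_cn)`.
#' @return Integer call matrix in `{-2, 0, 2}` with the dimnames of
#'   `total_cn`.
#' @export
calls_from_picnic <- function(total_cn, ploidy) {
  if (!is.matrix(total_cn)) stop("calls_from_picnic(): `total_cn` must be a matrix")
  if (is.null(colnames(total_cn))) {
    stop("calls_from_picnic(): `total_cn` must have sample colnames")
  }
  if (is.null(names(ploidy))) stop("calls_from_picnic(): `ploidy` must be named")
  missing_s <- setdiff(colnames(total_cn), names(ploidy))
  if (length(missing_s) > 0L) {
    stop("calls_from_picnic(): no ploidy for sample(s): ",
         paste(utils::head(missing_s, 5L), collapse = ", "))
  }
  p <- ploidy[colnames(total_cn)]
  pm <- matrix(p, nrow(total_cn), ncol(total_cn), byrow = TRUE)
  status <- classify_picnic(as.numeric(total_cn), as.numeric(pm))
  call <- integer(length(status))
  call[status == "amplified"] <- 2L
  call[status == "deleted"] <- -2L
  matrix(call, nrow(total_cn), ncol(total_cn), dimnames = dimnames(total_cn))
}

#' Variant status of a discrete copy-number call
#'
#' Only the extreme levels count as variant events for tendency
#' classification: +2 (high-level amplification) is amplified and -2
#' (homozygous deletion) is deleted; -1, 0 and +1 are neutral. All five
#' levels still serve as regression abscissae in the association statistics.
#'
#' @param call Integer vector with values in `-2:2` (or `NA`).
#' @return Character vector in `c("amplified", "deleted", "neutral")`, `NA`
#'   where `call` is `NA`.
#' @export
variant_status <- function(call) {
  call <- as.numeric(call)
  ok <- is.na(call) | (call %in% c(-2, -1, 0, 1, 2))
  if (!all(ok)) {
    stop("variant_status(): call outside {-2..2}: ", call[which(!ok)[1L]])
  }
  out <- rep(NA_character_, length(call))
  out[!is.na(call)] <- "neutral"
  out[!is.na(call) & call == 2] <- "amplified"
  out[!is.na(call) & call == -2] <- "deleted"
  out
}
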