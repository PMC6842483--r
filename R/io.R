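cohort_files <- c("calls.tsv", "absolute_cn.tsv", "expression.tsv",
                  "ploidy.tsv", "clinical.tsv", "annotation.tsv", "truth.tsv",
                  "ref_oncogenes.txt", "ref_tsgs.txt")

write_gene_matrix <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_gene_matrix <- function(path, integer = FALSE) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1L] != "gene") {
    stop("read_gene_matrix(): first column of ", path, " must be 'gene'")
  }
  mat <- as.matrix(df[, -1L, drop = FALSE])
  rownames(mat) <- df$gene
  if (integer) storage.mode(mat) <- "integer" else storage.mode(mat) <- "double"
  mat
}

#' Write a synthetic cohort to tab-delimited files
#'
#' Emits `calls.tsv`, `absolute_cn.tsv` and `expression.tsv` (genes as rows,
#' samples as columns, first column `gene`), `ploidy.tsv` (sample, ploidy),
#' `clinical.tsv` (sample, os_time, os_event), `annotation.tsv`
#' (gene, chromosome), `truth.tsv` (gene, label, planted, dosage) and the
#' reference lists `ref_oncogenes.txt` / `ref_tsgs.txt` (one symbol per
#' line). All files are UTF-8 TSV with '.' as the decimal separator;
#' reading them back reproduces the cohort exactly for integer fields and to
#' within 1e-9 relative error for reals.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param directory Output directory (created if absent).
#' @param overwrite Logical; if `FALSE` (default) an existing cohort file in
#'   `directory` aborts the write.
#' @return Invisibly, the character vector of file paths written.
#' @export
write_cohort <- function(cohort, directory, overwrite = FALSE) {
  if (!inherits(cohort, "cn_cohort")) {
    stop("write_cohort(): `cohort` must be a cn_cohort")
  }
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("write_cohort(): cannot create directory ", directory)
  }
  paths <- file.path(directory, cohort_files)
  names(paths) <- cohort_files
  if (!overwrite) {
    clash <- paths[file.exists(paths)]
    if (length(clash) > 0L) {
      stop("write_cohort(): file exists and overwrite = FALSE: ", clash[1L])
    }
  }
  write_gene_matrix(cohort$calls, paths[["calls.tsv"]])
  write_gene_matrix(cohort$absolute_cn, paths[["absolute_cn.tsv"]])
  write_gene_matrix(cohort$expression, paths[["expression.tsv"]])
  utils::write.table(data.frame(sample = names(cohort$ploidy),
                                ploidy = unname(cohort$ploidy)),
                     paths[["ploidy.tsv"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cohort$clinical, paths[["clinical.tsv"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$annotation, paths[["annotation.tsv"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$truth, paths[["truth.tsv"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(cohort$ref_oncogenes, paths[["ref_oncogenes.txt"]])
  writeLines(cohort$ref_tsgs, paths[["ref_tsgs.txt"]])
  invisible(unname(paths))
}

#' Read a cohort previously written by [write_cohort()]
#'
#' @param directory Directory containing the cohort TSV files.
#' @return A `"cn_cohort"` list (without the originating `config`).
#' @export
read_cohort <- function(directory) {
  need <- file.path(directory, cohort_files)
  missing <- need[!file.exists(need)]
  if (length(missing) > 0L) {
    stop("read_cohort(): missing cohort file: ", missing[1L])
  }
  pl <- utils::read.delim(file.path(directory, "ploidy.tsv"),
                          stringsAsFactors = FALSE)
  ploidy <- stats::setNames(pl$ploidy, pl$sample)
  truth <- utils::read.delim(file.path(directory, "truth.tsv"),
                             stringsAsFactors = FALSE)
  structure(list(
    calls = read_gene_matrix(file.path(directory, "calls.tsv"), integer = TRUE),
    absolute_cn = read_gene_matrix(file.path(directory, "absolute_cn.tsv"),
                                   integer = TRUE),
    ploidy = ploidy,
    expression = read_gene_matrix(file.path(directory, "expression.tsv")),
    clinical = utils::read.delim(file.path(directory, "clinical.tsv"),
                                 stringsAsFactors = FALSE),
    annotation = utils::read.delim(file.path(directory, "annotation.tsv"),
                                   stringsAsFactors = FALSE),
    truth = truth,
    ref_oncogenes = readLines(file.path(directory, "ref_oncogenes.txt")),
    ref_tsgs = readLines(file.path(directory, "ref_tsgs.txt")),
    survival_gene = {
      aug <- truth$gene[truth$planted == "aug"]
      if (length(aug) > 0) sort(aug)[1L] else NA_character_
    },
    config = NULL), class = "cn_cohort")
}
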