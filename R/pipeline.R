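#' Build a validated pipeline configuration
#'
#' @param cohort_dir Directory with the input TSV files (as written by
#'   [write_cohort()]; for GISTIC mode only `calls.tsv`, `expression.tsv`,
#'   `annotation.tsv` and `clinical.tsv` are required, for PICNIC mode
#'   `absolute_cn.tsv` and `ploidy.tsv` replace `calls.tsv`).
#' @param out_dir Output directory for the run.
#' @param cn_mode `"gistic"` (discrete five-level calls) or `"picnic"`
#'   (absolute copy number + ploidy).
#' @param min_diploid Minimum diploid reference size per gene.
#' @param deg_threshold Z cutoff for differential-expression events.
#' @param threshold_mode `"calibrated"` (medians of the reference lists) or
#'   `"fixed"`.
#' @param fixed A list passed to [fixed_thresholds()] when
#'   `threshold_mode = "fixed"`.
#' @param oncogene_file,tsg_file Reference list files (one symbol per line);
#'   default to `ref_oncogenes.txt` / `ref_tsgs.txt` inside `cohort_dir`.
#' @param grouping_file Optional TSV (sample, cohort) mapping samples to
#'   cohorts for the tendency-fraction summary.
#' @param survival_top_k Number of top AUGs and DDGs screened for survival
#'   association.
#' @param seed Integer recorded in the run manifest (the pipeline itself is
#'   deterministic given its inputs).
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(cohort_dir, out_dir,
                            cn_mode = c("gistic", "picnic"),
                            min_diploid = 3, deg_threshold = 2,
                            threshold_mode = c("calibrated", "fixed"),
                            fixed = list(),
                            oncogene_file = NULL, tsg_file = NULL,
                            grouping_file = NULL,
                            survival_top_k = 10, seed = 1L) {
  cn_mode <- match.arg(cn_mode)
  threshold_mode <- match.arg(threshold_mode)
  need <- c("expression.tsv", "annotation.tsv", "clinical.tsv",
            if (cn_mode == "gistic") "calls.tsv"
            else c("absolute_cn.tsv", "ploidy.tsv"))
  paths <- file.path(cohort_dir, need)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0L) {
    stop("pipeline_config(): missing input file: ", missing[1L])
  }
  if (is.null(oncogene_file)) oncogene_file <- file.path(cohort_dir,
                                                         "ref_oncogenes.txt")
  if (is.null(tsg_file)) tsg_file <- file.path(cohort_dir, "ref_tsgs.txt")
  if (threshold_mode == "calibrated") {
    for (f in c(oncogene_file, tsg_file)) {
      if (!file.exists(f)) {
        stop("pipeline_config(): reference list not found: ", f)
      }
    }
  }
  if (!is.null(grouping_file) && !file.exists(grouping_file)) {
    stop("pipeline_config(): grouping file not found: ", grouping_file)
  }
  structure(list(cohort_dir = cohort_dir, out_dir = out_dir,
                 cn_mode = cn_mode, min_diploid = min_diploid,
                 deg_threshold = deg_threshold,
                 threshold_mode = threshold_mode, fixed = fixed,
                 oncogene_file = oncogene_file, tsg_file = tsg_file,
                 grouping_file = grouping_file,
                 survival_top_k = survival_top_k, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()].
#'
#' @param path YAML file path.
#' @return List of class `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("read_pipeline_config(): no such file: ", path)
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full concordance pipeline on a cohort directory
#'
#' Stage order: copy-number harmonisation, diploid-referenced Z-scores and
#' DEG calls, tendency classification, per-gene and cohort association
#' statistics, AUG/DDG identification with chromosome distribution, and
#' tendency-stratified survival screening of the top concordant genes. All
#' tabular outputs land in `config$out_dir` together with `manifest.tsv`
#' listing each file with its MD5 checksum; rerunning on the same inputs
#' reproduces identical checksums.
#'
#' @param config A [pipeline_config()] (or path to a YAML file for
#'   [read_pipeline_config()]).
#' @return Invisibly, the manifest data frame (file, md5).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config")) {
    stop("run_pipeline(): `config` must come from pipeline_config()")
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  calls <- stage("cn_calls", {
    if (config$cn_mode == "gistic") {
      calls_from_gistic(read_gene_matrix(file.path(config$cohort_dir,
                                                   "calls.tsv")))
    } else {
      acn <- read_gene_matrix(file.path(config$cohort_dir, "absolute_cn.tsv"),
                              integer = TRUE)
      pl <- utils::read.delim(file.path(config$cohort_dir, "ploidy.tsv"),
                              stringsAsFactors = FALSE)
      calls_from_picnic(acn, stats::setNames(pl$ploidy, pl$sample))
    }
  })
  expression <- stage("expression", {
    read_gene_matrix(file.path(config$cohort_dir, "expression.tsv"))
  })
  annotation <- utils::read.delim(file.path(config$cohort_dir,
                                            "annotation.tsv"),
                                  stringsAsFactors = FALSE)
  clinical <- utils::read.delim(file.path(config$cohort_dir, "clinical.tsv"),
                                stringsAsFactors = FALSE)

  zmat <- stage("expression_z", compute_z(expression, calls,
                                          min_diploid = config$min_diploid))
  degs <- stage("expression_z", call_degs(zmat, config$deg_threshold))
  tt <- stage("tendency_concordance", classify_tendency(calls, degs))
  grouping <- if (!is.null(config$grouping_file)) {
    g <- utils::read.delim(config$grouping_file, stringsAsFactors = FALSE)
    stats::setNames(g$cohort, g$sample)
  } else NULL
  fractions <- stage("tendency_concordance",
                     cohort_tendency_fractions(tt, grouping))
  assoc <- stage("correlation_stats", gene_association(zmat, calls))
  cfit <- stage("correlation_stats", cohort_fit(zmat, calls))
  avd <- stage("correlation_stats", amplified_vs_deleted(zmat, calls))
  gc <- stage("concordant_genes", concordance_table(tt, assoc))
  thresholds <- stage("concordant_genes", {
    if (config$threshold_mode == "fixed") {
      do.call(fixed_thresholds, config$fixed)
    } else {
      calibrate_thresholds(gc, readLines(config$oncogene_file),
                           readLines(config$tsg_file))
    }
  })
  gc <- stage("concordant_genes", identify_aug_ddg(gc, thresholds))
  chrdist <- stage("concordant_genes",
                   suppressMessages(chromosome_distribution(gc, annotation)))
  surv <- stage("survival_analysis", {
    top_aug <- rank_top_concordant(gc, config$survival_top_k, "AUG")
    top_ddg <- rank_top_concordant(gc, config$survival_top_k, "DDG")
    genes <- c(top_aug, top_ddg)
    if (length(genes) == 0L) {
      data.frame(gene = character(0), tendency = character(0),
                 n_carrier = integer(0), n_other = integer(0),
                 chisq = numeric(0), p = numeric(0), p_adj = numeric(0),
                 note = character(0))
    } else {
      survival_by_tendency(tt, clinical, genes,
                           c(rep("AU", length(top_aug)),
                             rep("DD", length(top_ddg))))
    }
  })

  out <- config$out_dir
  files <- character(0)
  zdf <- data.frame(gene = rownames(zmat$z),
                    round(zmat$z, 9), check.names = FALSE)
  files <- c(files, write_tsv(zdf, file.path(out, "zscores.tsv")))
  files <- c(files, write_tsv(
    data.frame(gene = names(zmat$valid), diploid_n = zmat$diploid_n,
               valid = zmat$valid, reason = zmat$reason, row.names = NULL),
    file.path(out, "gene_validity.tsv")))
  files <- c(files, write_tsv(tendency_events(tt),
                              file.path(out, "tendency_long.tsv")))
  files <- c(files, write_tsv(tt$counts, file.path(out, "gene_counts.tsv")))
  files <- c(files, write_tsv(fractions, file.path(out, "cohort_summary.tsv")))
  files <- c(files, write_tsv(
    assoc[, c("gene", "rho", "fit_r", "fit_slope", "fit_intercept",
              "n_levels")],
    file.path(out, "gene_association.tsv")))
  files <- c(files, write_tsv(
    data.frame(level = cfit$levels, median_z = cfit$medians,
               n_obs = cfit$n_obs, slope = cfit$slope,
               intercept = cfit$intercept, r = cfit$r, p = cfit$p),
    file.path(out, "cohort_fit.tsv")))
  files <- c(files, write_tsv(
    data.frame(t = avd$t, df = avd$df, p = avd$p, mean_amplified = avd$mean_a,
               mean_deleted = avd$mean_b, n_amplified = avd$n_a,
               n_deleted = avd$n_b),
    file.path(out, "amp_vs_del.tsv")))
  files <- c(files, write_tsv(
    gc[, c("gene", "n_AU", "n_DD", "au_ratio", "dd_ratio", "rho", "status")],
    file.path(out, "concordant_genes.tsv")))
  files <- c(files, write_tsv(chrdist,
                              file.path(out, "chromosome_distribution.tsv")))
  files <- c(files, write_tsv(surv, file.path(out, "survival_results.tsv")))
  files <- c(files, write_tsv(
    data.frame(key = c("cn_mode", "min_diploid", "deg_threshold",
                       "threshold_mode", "rho_min_aug", "count_min_aug",
                       "rho_min_ddg", "count_min_ddg", "seed"),
               value = c(config$cn_mode, config$min_diploid,
                         config$deg_threshold, config$threshold_mode,
                         thresholds$rho_min_aug, thresholds$count_min_aug,
                         thresholds$rho_min_ddg, thresholds$count_min_ddg,
                         config$seed)),
    file.path(out, "run_info.tsv")))

  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  write_tsv(manifest, file.path(out, "manifest.tsv"))
  invisible(manifest)
}

#' Numeric summary of a completed pipeline run
#'
#' Reads the tables a [run_pipeline()] call wrote and compiles the headline
#' quantities: the fraction of defined genes with positive Spearman rho, the
#' distribution of per-gene fit r, the per-cohort tendency fractions, the
#' AUG/DDG counts, the amplified-versus-deleted Welch comparison and the
#' cohort-level median-Z fit. Also written to `summary.json` in the run
#' directory.
#'
#' @param run_dir Directory written by [run_pipeline()].
#' @return The summary as a list.
#' @export
summary_report <- function(run_dir) {
  need <- c("gene_association.tsv", "cohort_summary.tsv",
            "concordant_genes.tsv", "cohort_fit.tsv", "amp_vs_del.tsv",
            "gene_validity.tsv")
  paths <- file.path(run_dir, need)
  missing <- need[!file.exists(paths)]
  if (length(missing) > 0L) {
    stop("summary_report(): incomplete run, missing: ",
         paste(missing, collapse = ", "))
  }
  assoc <- utils::read.delim(paths[1L], stringsAsFactors = FALSE)
  fractions <- utils::read.delim(paths[2L], stringsAsFactors = FALSE)
  gc <- utils::read.delim(paths[3L], stringsAsFactors = FALSE)
  cfit <- utils::read.delim(paths[4L], stringsAsFactors = FALSE)
  avd <- utils::read.delim(paths[5L], stringsAsFactors = FALSE)
  validity <- utils::read.delim(paths[6L], stringsAsFactors = FALSE)

  rho_def <- assoc$rho[!is.na(assoc$rho)]
  fit_def <- assoc$fit_r[!is.na(assoc$fit_r)]
  out <- list(
    n_genes = nrow(validity),
    n_valid_genes = sum(validity$valid),
    frac_rho_positive = if (length(rho_def)) mean(rho_def > 0) else NA_real_,
    fit_r_quartiles = if (length(fit_def)) {
      as.list(stats::setNames(
        stats::quantile(fit_def, c(0.25, 0.5, 0.75), names = FALSE),
        c("q25", "median", "q75")))
    } else NULL,
    tendency_fractions = fractions,
    n_aug = sum(gc$status == "AUG"),
    n_ddg = sum(gc$status == "DDG"),
    amp_vs_del = as.list(avd[1L, ]),
    cohort_fit = list(r = cfit$r[1L], slope = cfit$slope[1L],
                      p = cfit$p[1L]))
  jsonlite::write_json(out, file.path(run_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 6, dataframe = "rows")
  out
}
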