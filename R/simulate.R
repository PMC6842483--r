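#' Configuration for the synthetic paired CNV/expression cohort generator
#'
#' The generator emulates the statistical structure the downstream analysis
#' assumes: a linear copy-number dosage effect on expression for most genes, a
#' dosage-insensitive gene fraction, rare discordant events, amplification
#' events more frequent than deletion events, planted strongly concordant
#' genes (AUG/DDG analogues) plus moderately concordant reference
#' oncogene/tumor-suppressor genes used for threshold calibration, and
#' survival times whose hazard depends on a planted gene's tendency status.
#'
#' Calls are sampled independently per (gene, sample); there is no chromosomal
#' segment correlation, because every downstream procedure is gene-wise.
#'
#' @param n_genes,n_samples Cohort dimensions (`n_samples >= 4`, so at least
#'   three diploid reference samples remain plausible downstream).
#' @param dosage_fraction Fraction of background genes with a linear
#'   copy-number-to-expression effect; planted and reference genes are always
#'   dosage sensitive.
#' @param slope_mean,slope_sd Normal distribution of the per-gene dosage slope
#'   for background dosage-sensitive genes (expression units per copy-number
#'   unit).
#' @param noise_sd Residual expression noise standard deviation.
#' @param amp_rate,del_rate Background per-(gene, sample) probabilities of
#'   calls +2 and -2; the default asymmetry (0.02 vs 0.005) emulates selection
#'   against deletions.
#' @param gain_rate,hemiloss_rate Probabilities of calls +1 and -1.
#' @param discord_rate Probability that a variant (+-2) event's expression
#'   effect is sign-flipped.
#' @param seed Integer random seed; identical configurations produce
#'   bit-identical cohorts.
#' @param survival_hazard_ratio Multiplicative hazard for samples carrying the
#'   planted survival gene's concordant amplified-and-upregulated event.
#' @param n_aug,n_ddg Numbers of strongly planted concordant genes (high
#'   amplification / deletion rates with strong slopes).
#' @param n_ref_onco,n_ref_tsg Numbers of reference oncogenes / tumor
#'   suppressor genes: moderately concordant genes whose medians calibrate the
#'   AUG/DDG thresholds.
#' @param planted_amp_rate,planted_del_rate Per-(gene, sample) +2 / -2 rates
#'   for the strongly planted AUG / DDG genes.
#' @param ref_amp_rate,ref_del_rate +2 / -2 rates for reference oncogenes /
#'   TSGs (between the background and planted rates).
#' @param planted_slope_mean,planted_slope_sd Dosage-slope distribution for
#'   planted and reference genes.
#' @param baseline_min,baseline_max Uniform range of per-gene baseline
#'   (diploid) expression.
#' @param os_mean Mean of the exponential baseline overall-survival time.
#' @param censor_mean Mean of the independent exponential censoring time.
#' @return A validated list of class `"simulation_config"`.
#' @export
simulation_config <- function(n_genes = 2000, n_samples = 500,
                              dosage_fraction = 0.85,
                              slope_mean = 0.5, slope_sd = 0.15,
                              noise_sd = 1,
                              amp_rate = 0.02, del_rate = 0.005,
                              gain_rate = 0.05, hemiloss_rate = 0.03,
                              discord_rate = 0.005,
                              seed = 1L,
                              survival_hazard_ratio = 2,
                              n_aug = 50, n_ddg = 30,
                              n_ref_onco = 30, n_ref_tsg = 10,
                              planted_amp_rate = 0.2, planted_del_rate = 0.15,
                              ref_amp_rate = 0.06, ref_del_rate = 0.05,
                              planted_slope_mean = 2, planted_slope_sd = 0.25,
                              baseline_min = 8, baseline_max = 16,
                              os_mean = 50, censor_mean = 80) {
  cfg <- list(n_genes = n_genes, n_samples = n_samples,
              dosage_fraction = dosage_fraction,
              slope_mean = slope_mean, slope_sd = slope_sd,
              noise_sd = noise_sd,
              amp_rate = amp_rate, del_rate = del_rate,
              gain_rate = gain_rate, hemiloss_rate = hemiloss_rate,
              discord_rate = discord_rate,
              seed = as.integer(seed),
              survival_hazard_ratio = survival_hazard_ratio,
              n_aug = n_aug, n_ddg = n_ddg,
              n_ref_onco = n_ref_onco, n_ref_tsg = n_ref_tsg,
              planted_amp_rate = planted_amp_rate,
              planted_del_rate = planted_del_rate,
              ref_amp_rate = ref_amp_rate, ref_del_rate = ref_del_rate,
              planted_slope_mean = planted_slope_mean,
              planted_slope_sd = planted_slope_sd,
              baseline_min = baseline_min, baseline_max = baseline_max,
              os_mean = os_mean, censor_mean = censor_mean)
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  need_scalar <- function(name, lo = -Inf, hi = Inf) {
    v <- cfg[[name]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < lo || v > hi) {
      stop(sprintf("simulation_config(): invalid `%s` (got %s; allowed [%s, %s])",
                   name, format(v), format(lo), format(hi)))
    }
  }
  need_scalar("n_genes", 1)
  need_scalar("n_samples", 4) # downstream needs >= 3 diploid samples
  for (r in c("dosage_fraction", "amp_rate", "del_rate", "gain_rate",
              "hemiloss_rate", "discord_rate", "planted_amp_rate",
              "planted_del_rate", "ref_amp_rate", "ref_del_rate")) {
    need_scalar(r, 0, 1)
  }
  need_scalar("slope_sd", 0); need_scalar("noise_sd", 0)
  need_scalar("planted_slope_sd", 0)
  need_scalar("survival_hazard_ratio", 0)
  need_scalar("os_mean", 1e-12); need_scalar("censor_mean", 1e-12)
  for (k in c("n_aug", "n_ddg", "n_ref_onco", "n_ref_tsg")) need_scalar(k, 0)
  need_scalar("seed", -.Machine$integer.max, .Machine$integer.max)
  tot <- cfg$n_aug + cfg$n_ddg + cfg$n_ref_onco + cfg$n_ref_tsg
  if (tot > cfg$n_genes) {
    stop("simulation_config(): n_aug + n_ddg + n_ref_onco + n_ref_tsg exceeds n_genes")
  }
  base_other <- cfg$gain_rate + cfg$hemiloss_rate
  combos <- c(background = cfg$amp_rate + cfg$del_rate,
              planted_aug = cfg$planted_amp_rate + cfg$del_rate,
              planted_ddg = cfg$amp_rate + cfg$planted_del_rate,
              ref_onco = cfg$ref_amp_rate + cfg$del_rate,
              ref_tsg = cfg$amp_rate + cfg$ref_del_rate)
  bad <- names(combos)[combos + base_other > 1]
  if (length(bad) > 0L) {
    stop("simulation_config(): call probabilities for gene class '", bad[1L],
         "' sum above 1 (amp_rate/del_rate/gain_rate/hemiloss_rate)")
  }
  invisible(cfg)
}

#' Simulate a paired copy-number / expression / clinical cohort
#'
#' Expression of a dosage-sensitive gene g in sample s is
#' `baseline_g + slope_g * call(g, s) + noise`, floored at 0 (RSEM-like
#' values are non-negative); dosage-insensitive genes draw expression
#' independently of their calls. With probability `discord_rate` a variant
#' (+-2) event's slope contribution is negated. Absolute copy number and
#' per-sample average genome ploidy are generated by inverting the PICNIC
#' criteria, so the discrete calls round-trip through [classify_picnic()]
#' (for the +-2 / 0 levels; the +-1 levels are neutral under PICNIC).
#' Overall-survival times are exponential with the hazard multiplied by
#' `survival_hazard_ratio` for samples carrying the planted survival gene's
#' concordant amplification event, with independent exponential censoring.
#'
#' @param config A [simulation_config()].
#' @return An object of class `"cn_cohort"`: a list with elements `calls`,
#'   `absolute_cn`, `ploidy`, `expression`, `clinical`, `annotation`, `truth`,
#'   `ref_oncogenes`, `ref_tsgs`, `survival_gene` and `config`. `truth` has
#'   one row per gene with columns `gene`, `label` (AUG/DDG/neither),
#'   `planted` (aug/ddg/ref_oncogene/ref_tsg/background) and `dosage`
#'   (sensitive/insensitive).
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "simulation_config")) {
    stop("simulate_cohort(): `config` must come from simulation_config()")
  }
  validate_simulation_config(config)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  ng <- as.integer(config$n_genes)
  ns <- as.integer(config$n_samples)
  gw <- max(4L, nchar(as.character(ng)))
  sw <- max(3L, nchar(as.character(ns)))
  genes <- sprintf(paste0("g%0", gw, "d"), seq_len(ng))
  samples <- sprintf(paste0("s%0", sw, "d"), seq_len(ns))

  # gene classes: planted AUG/DDG, reference oncogene/TSG, background
  planted <- rep("background", ng)
  n_special <- config$n_aug + config$n_ddg + config$n_ref_onco + config$n_ref_tsg
  if (n_special > 0) {
    idx <- sample.int(ng, n_special)
    take <- function(k) {
      out <- idx[seq_len(k)]
      idx <<- idx[-seq_len(k)]
      out
    }
    aug_idx <- take(config$n_aug)
    ddg_idx <- take(config$n_ddg)
    onco_idx <- take(config$n_ref_onco)
    tsg_idx <- take(config$n_ref_tsg)
    planted[aug_idx] <- "aug"; planted[ddg_idx] <- "ddg"
    planted[onco_idx] <- "ref_oncogene"; planted[tsg_idx] <- "ref_tsg"
  } else {
    aug_idx <- ddg_idx <- onco_idx <- tsg_idx <- integer(0)
  }
  special <- planted != "background"

  sensitive <- special | (stats::runif(ng) < config$dosage_fraction)
  slope <- numeric(ng)
  slope[sensitive] <- stats::rnorm(sum(sensitive), config$slope_mean,
                                   config$slope_sd)
  slope[special] <- stats::rnorm(sum(special), config$planted_slope_mean,
                                 config$planted_slope_sd)

  amp_g <- rep(config$amp_rate, ng)
  del_g <- rep(config$del_rate, ng)
  amp_g[aug_idx] <- config$planted_amp_rate
  amp_g[onco_idx] <- config$ref_amp_rate
  del_g[ddg_idx] <- config$planted_del_rate
  del_g[tsg_idx] <- config$ref_del_rate

  # discrete calls: i.i.d. per (gene, sample) from per-gene class rates
  u <- matrix(stats::runif(ng * ns), ng, ns)
  c1 <- amp_g
  c2 <- c1 + del_g
  c3 <- c2 + config$gain_rate
  c4 <- c3 + config$hemiloss_rate
  call <- ifelse(u < c1, 2, ifelse(u < c2, -2, ifelse(u < c3, 1,
                 ifelse(u < c4, -1, 0))))
  calls <- matrix(as.integer(call), ng, ns, dimnames = list(genes, samples))

  # expression: linear dosage model with rare sign-flipped variant events
  flip <- matrix(stats::runif(ng * ns) < config$discord_rate, ng, ns) &
    abs(calls) == 2
  eff_sign <- 1 - 2 * flip
  baseline <- stats::runif(ng, config$baseline_min, config$baseline_max)
  noise <- matrix(stats::rnorm(ng * ns, 0, config$noise_sd), ng, ns)
  expression <- baseline + slope * calls * eff_sign + noise
  expression[expression < 0] <- 0 # RSEM-like values are non-negative
  dimnames(expression) <- list(genes, samples)

  # ploidy: near-diploid majority with a tetraploid-like minority
  hi <- stats::runif(ns) < 0.25
  ploidy <- ifelse(hi,
                   pmin(pmax(stats::rnorm(ns, 3.6, 0.25), 2.9), 4.4),
                   pmin(pmax(stats::rnorm(ns, 2.05, 0.15), 1.6), 2.7))
  names(ploidy) <- samples

  # absolute copy number consistent with calls under the PICNIC criteria
  pm <- matrix(ploidy, ng, ns, byrow = TRUE)
  low <- pm <= 2.7
  acn <- matrix(0, ng, ns)
  acn[calls == 0] <- ifelse(low[calls == 0], 2, round(pm[calls == 0]))
  acn[calls == 1] <- ifelse(low[calls == 1], 3, round(pm[calls == 1]) + 1)
  acn[calls == -1] <- ifelse(low[calls == -1], 1, round(pm[calls == -1]) - 1)
  amp_sel <- calls == 2
  acn[amp_sel] <- ifelse(low[amp_sel], 5, 9) +
    stats::rpois(sum(amp_sel), 1)
  del_sel <- calls == -2
  k_del <- ceiling(pm[del_sel] - 2.7) # allowed integers: 0 .. k-1 (< ploidy-2.7)
  k_del[low[del_sel]] <- 1            # near-diploid deletion must be exactly 0
  acn[del_sel] <- floor(stats::runif(sum(del_sel)) * k_del)
  absolute_cn <- matrix(as.integer(acn), ng, ns,
                        dimnames = list(genes, samples))

  # clinical outcome tied to the planted survival gene's concordant events
  survival_gene <- if (config$n_aug >= 1) genes[sort(aug_idx)[1L]] else NA_character_
  carrier <- if (!is.na(survival_gene)) {
    calls[survival_gene, ] == 2L & !flip[match(survival_gene, genes), ]
  } else rep(FALSE, ns)
  hazard <- (1 / config$os_mean) * config$survival_hazard_ratio^carrier
  t_event <- stats::rexp(ns, rate = hazard)
  t_cens <- stats::rexp(ns, rate = 1 / config$censor_mean)
  clinical <- data.frame(sample = samples,
                         os_time = pmin(t_event, t_cens),
                         os_event = as.integer(t_event <= t_cens),
                         stringsAsFactors = FALSE)

  annotation <- data.frame(gene = genes,
                           chromosome = paste0("chr", sample.int(22L, ng,
                                                                 replace = TRUE)),
                           stringsAsFactors = FALSE)
  label <- rep("neither", ng)
  label[planted %in% c("aug", "ref_oncogene")] <- "AUG"
  label[planted %in% c("ddg", "ref_tsg")] <- "DDG"
  truth <- data.frame(gene = genes, label = label, planted = planted,
                      dosage = ifelse(sensitive, "sensitive", "insensitive"),
                      stringsAsFactors = FALSE)

  structure(list(calls = calls,
                 absolute_cn = absolute_cn,
                 ploidy = ploidy,
                 expression = expression,
                 clinical = clinical,
                 annotation = annotation,
                 truth = truth,
                 ref_oncogenes = genes[sort(onco_idx)],
                 ref_tsgs = genes[sort(tsg_idx)],
                 survival_gene = survival_gene,
                 config = config),
            class = "cn_cohort")
}

#' @export
print.cn_cohort <- function(x, ...) {
  cat(sprintf("Synthetic CNV/expression cohort: %d genes x %d samples\n",
              nrow(x$calls), ncol(x$calls)))
  cat(sprintf("  planted: %d AUG, %d DDG, %d ref oncogenes, %d ref TSGs\n",
              sum(x$truth$planted == "aug"), sum(x$truth$planted == "ddg"),
              length(x$ref_oncogenes), length(x$ref_tsgs)))
  cat(sprintf("  dosage-sensitive genes: %d (%.1f%%)\n",
              sum(x$truth$dosage == "sensitive"),
              100 * mean(x$truth$dosage == "sensitive")))
  invisible(x)
}
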