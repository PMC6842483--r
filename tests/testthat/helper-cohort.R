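# Shared fixtures, built in code. The memoised recovery cohort is the
# parameter-recovery scenario (strong planted concordant genes plus
# calibration reference genes) reused by several test files.

.fixture_env <- new.env(parent = emptyenv())

small_config <- function(...) {
  args <- list(n_genes = 60, n_samples = 40,
               n_aug = 0, n_ddg = 0, n_ref_onco = 0, n_ref_tsg = 0,
               seed = 42L)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(simulation_config, args)
}

recovery_cohort <- function() {
  if (is.null(.fixture_env$recovery)) {
    cfg <- simulation_config(seed = 20260923L, discord_rate = 0.01)
    .fixture_env$recovery <- simulate_cohort(cfg)
  }
  .fixture_env$recovery
}

recovery_results <- function() {
  if (is.null(.fixture_env$recovery_res)) {
    co <- recovery_cohort()
    zm <- compute_z(co$expression, co$calls)
    degs <- call_degs(zm)
    tt <- classify_tendency(co$calls, degs)
    assoc <- gene_association(zm, co$calls)
    gc <- concordance_table(tt, assoc)
    th <- calibrate_thresholds(gc, co$ref_oncogenes, co$ref_tsgs)
    gc <- identify_aug_ddg(gc, th)
    .fixture_env$recovery_res <- list(zmat = zm, degs = degs, tt = tt,
                                      assoc = assoc, gc = gc, thresholds = th)
  }
  .fixture_env$recovery_res
}

# independent midrank construction for the Spearman oracle
oracle_rank <- function(x) {
  vapply(seq_along(x),
         function(i) sum(x < x[i]) + (sum(x == x[i]) + 1) / 2,
         numeric(1))
}

oracle_pearson <- function(a, b) {
  n <- length(a)
  num <- sum(a * b) - n * mean(a) * mean(b)
  den <- sqrt((sum(a^2) - n * mean(a)^2) * (sum(b^2) - n * mean(b)^2))
  if (den == 0) NA_real_ else num / den
}

oracle_spearman <- function(x, y) {
  oracle_pearson(oracle_rank(x), oracle_rank(y))
}
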