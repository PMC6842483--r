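test_that("configuration invariants are enforced with named parameters", {
  expect_s3_class(small_config(), "simulation_config")
  expect_error(small_config(n_samples = 3), "n_samples")
  expect_error(small_config(amp_rate = 1.2), "amp_rate")
  expect_error(small_config(discord_rate = -0.1), "discord_rate")
  expect_error(small_config(amp_rate = 0.5, del_rate = 0.3, gain_rate = 0.2,
                            hemiloss_rate = 0.1), "sum above 1")
  expect_error(small_config(n_genes = 10, n_aug = 20), "exceeds n_genes")
  expect_error(simulate_cohort(list(n_genes = 5)), "simulation_config")
})

test_that("identical seeds give element-wise identical cohorts", {
  a <- simulate_cohort(small_config(seed = 7L))
  b <- simulate_cohort(small_config(seed = 7L))
  expect_identical(a$calls, b$calls)
  expect_identical(a$expression, b$expression)
  expect_identical(a$absolute_cn, b$absolute_cn)
  expect_identical(a$ploidy, b$ploidy)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$truth, b$truth)
  d <- simulate_cohort(small_config(seed = 8L))
  expect_false(identical(a$calls, d$calls))
})

test_that("noiseless fully dosage-sensitive cohorts are exactly linear", {
  co <- simulate_cohort(small_config(noise_sd = 0, discord_rate = 0,
                                     dosage_fraction = 1, seed = 3L))
  # expression - baseline is slope * call for every gene: recover per-gene
  # slope from two distinct call levels and check exact linearity
  for (g in rownames(co$calls)) {
    x <- co$calls[g, ]; y <- co$expression[g, ]
    if (length(unique(x)) < 2) next
    fit <- lm(y ~ x)
    expect_lt(max(abs(residuals(fit))), 1e-9)
  }
  # per-gene median fit r = 1 for genes observing >= 3 distinct levels
  for (g in rownames(co$calls)) {
    if (length(unique(co$calls[g, ])) < 3) next
    f <- median_z_fit(co$calls[g, ], co$expression[g, ])
    expect_equal(f$r, 1, tolerance = 1e-9)
  }
})

test_that("dosage-insensitive cohorts have call/expression correlations centred at 0", {
  co <- simulate_cohort(small_config(n_genes = 300, n_samples = 60,
                                     dosage_fraction = 0, seed = 5L))
  rho <- vapply(seq_len(nrow(co$calls)), function(i) {
    spearman_rho(as.numeric(co$calls[i, ]), co$expression[i, ])
  }, numeric(1))
  expect_lt(abs(mean(rho, na.rm = TRUE)), 0.05)
})

test_that("empirical variant rates recover the configured probabilities", {
  cfg <- small_config(n_genes = 400, n_samples = 300, seed = 9L)
  co <- simulate_cohort(cfg)
  n <- length(co$calls)
  expect_gte(n, 1e5)
  for (pair in list(c(2, cfg$amp_rate), c(-2, cfg$del_rate),
                    c(1, cfg$gain_rate), c(-1, cfg$hemiloss_rate))) {
    p <- pair[2]
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(mean(co$calls == pair[1]) - p), 3 * se)
  }
})

test_that("absolute copy number and ploidy round-trip through the PICNIC rules", {
  co <- simulate_cohort(small_config(n_genes = 150, n_samples = 80, seed = 2L,
                                     n_aug = 5, n_ddg = 5, n_ref_onco = 4,
                                     n_ref_tsg = 2))
  pm <- matrix(co$ploidy, nrow(co$calls), ncol(co$calls), byrow = TRUE)
  status <- matrix(classify_picnic(as.numeric(co$absolute_cn),
                                   as.numeric(pm)),
                   nrow(co$calls))
  expect_true(all(status[co$calls == 2L] == "amplified"))
  expect_true(all(status[co$calls == -2L] == "deleted"))
  expect_true(all(status[abs(co$calls) < 2L] == "neutral"))
  # the matrix entry point agrees
  derived <- calls_from_picnic(co$absolute_cn, co$ploidy)
  collapsed <- co$calls; collapsed[abs(collapsed) == 1L] <- 0L
  expect_identical(derived, collapsed)
})

test_that("truth labels partition genes and planted classes are sensitive", {
  co <- recovery_cohort()
  expect_identical(sort(co$truth$gene), sort(rownames(co$calls)))
  expect_true(all(co$truth$label %in% c("AUG", "DDG", "neither")))
  expect_true(all(co$truth$dosage[co$truth$planted != "background"] ==
                    "sensitive"))
  expect_setequal(co$ref_oncogenes,
                  co$truth$gene[co$truth$planted == "ref_oncogene"])
  expect_identical(table(co$truth$planted)[["aug"]], 50L)
  expect_identical(table(co$truth$planted)[["ddg"]], 30L)
})

test_that("cohorts survive a write/read round trip and respect overwrite", {
  co <- simulate_cohort(small_config(seed = 13L, n_aug = 3, n_ref_onco = 2,
                                     n_ref_tsg = 2))
  dir <- withr::local_tempdir()
  paths <- write_cohort(co, dir)
  expect_length(paths, 9)
  expect_true(all(file.exists(paths)))
  back <- read_cohort(dir)
  expect_identical(back$calls, co$calls)
  expect_identical(back$absolute_cn, co$absolute_cn)
  expect_equal(back$expression, co$expression, tolerance = 1e-9)
  expect_equal(back$ploidy, co$ploidy, tolerance = 1e-9)
  expect_equal(back$clinical$os_time, co$clinical$os_time, tolerance = 1e-9)
  expect_identical(back$clinical$os_event, co$clinical$os_event)
  expect_identical(back$truth, co$truth)
  expect_identical(back$survival_gene, co$survival_gene)
  # collision without the explicit flag leaves the directory untouched
  before <- tools::md5sum(paths)
  expect_error(write_cohort(co, dir), "overwrite = FALSE")
  expect_identical(tools::md5sum(paths), before)
  expect_silent(write_cohort(co, dir, overwrite = TRUE))
  expect_identical(tools::md5sum(paths), before) # same seed, same bytes
})

test_that("tiny cohorts have the documented file shapes", {
  co <- simulate_cohort(small_config(n_genes = 2, n_samples = 4, seed = 1L))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  calls <- read.delim(file.path(dir, "calls.tsv"), check.names = FALSE)
  expect_identical(names(calls)[1], "gene")
  expect_identical(dim(calls), c(2L, 5L))
  expr <- read.delim(file.path(dir, "expression.tsv"), check.names = FALSE)
  expect_identical(dim(expr), c(2L, 5L))
})
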