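test_that("spearman rho reproduces hand values and handles ties", {
  expect_equal(spearman_rho(1:3, c(2, 4, 6)), 1)
  expect_equal(spearman_rho(1:3, c(6, 4, 2)), -1)
  # tie-free closed form: 1 - 6 * sum(d^2) / (n (n^2 - 1)) = 1 - 12/60
  expect_equal(spearman_rho(1:4, c(1, 3, 2, 4)), 0.8)
  expect_true(is.na(spearman_rho(1:2, 2:3)))          # too short
  expect_true(is.na(spearman_rho(c(1, 1, 1), 1:3)))   # constant ranks
  expect_error(spearman_rho(1:3, 1:4), "unequal")
})

test_that("spearman rho equals the brute-force midrank oracle on tied data", {
  set.seed(99)
  for (i in 1:1000) {
    n <- sample(3:12, 1)
    x <- sample(-3:3, n, replace = TRUE)
    y <- sample(-3:3, n, replace = TRUE) + 0.5 * x
    got <- spearman_rho(x, y)
    want <- oracle_spearman(x, y)
    if (is.na(want)) expect_true(is.na(got)) else {
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
})

test_that("spearman rho is invariant under strictly increasing transforms", {
  set.seed(7)
  for (i in 1:50) {
    x <- rnorm(20); y <- rnorm(20) + x
    base <- spearman_rho(x, y)
    expect_equal(spearman_rho(exp(x), y), base, tolerance = 1e-12)
    expect_equal(spearman_rho(x, y^3 + 2 * y), base, tolerance = 1e-12)
  }
})

test_that("median-level fits match a closed-form OLS oracle", {
  # collinear medians give |r| = 1
  up <- median_z_fit(c(-2, -2, 0, 0, 2, 2), c(-1, -1, 0, 0, 1, 1))
  expect_equal(up$r, 1)
  expect_equal(up$slope, 0.5)
  down <- median_z_fit(c(-2, 0, 2), c(1, 0, -1))
  expect_equal(down$r, -1)
  # three levels, medians off the line: compare against lm()
  f <- median_z_fit(c(-2, 0, 2), c(-1.0, 0.0, 0.8))
  o <- lm(y ~ x, data = data.frame(x = c(-2, 0, 2), y = c(-1, 0, 0.8)))
  expect_equal(f$slope, unname(coef(o)[2]), tolerance = 1e-12)
  expect_equal(f$intercept, unname(coef(o)[1]), tolerance = 1e-12)
  expect_equal(f$r, cor(c(-2, 0, 2), c(-1, 0, 0.8)), tolerance = 1e-12)
  # fewer than 3 observed levels -> undefined, recorded
  few <- median_z_fit(c(0, 0, 2, 2), c(1, 2, 3, 4))
  expect_true(is.na(few$r))
  expect_equal(few$n_levels, 2)
})

test_that("median-level fits ignore per-level sample counts", {
  calls <- c(-2, 0, 0, 2)
  z <- c(-1, 0.1, -0.1, 1)
  base <- median_z_fit(calls, z)
  dup <- median_z_fit(c(calls, 0, 0, 2, 2, 2),
                      c(z, 0.1, -0.1, 1, 1, 1))
  expect_equal(dup$slope, base$slope, tolerance = 1e-12)
  expect_equal(dup$r, base$r, tolerance = 1e-12)
})

test_that("welch t matches the closed form and t.test on random inputs", {
  w <- welch_t(c(1, 2, 3), c(2, 4, 6))
  expect_equal(w$t, -2 / sqrt(1 / 3 + 4 / 3), tolerance = 1e-12)
  set.seed(5)
  for (i in 1:200) {
    a <- rnorm(sample(2:15, 1)); b <- rnorm(sample(2:15, 1), sd = 2)
    w <- welch_t(a, b)
    # closed form
    se2 <- var(a) / length(a) + var(b) / length(b)
    expect_equal(w$t, (mean(a) - mean(b)) / sqrt(se2), tolerance = 1e-12)
    expect_equal(w$df, se2^2 / ((var(a) / length(a))^2 / (length(a) - 1) +
                                  (var(b) / length(b))^2 / (length(b) - 1)),
                 tolerance = 1e-12)
    expect_gt(w$p, 0); expect_lte(w$p, 1)
    # independent route through stats::t.test
    tt <- t.test(a, b)
    expect_equal(w$t, unname(tt$statistic), tolerance = 1e-10)
    expect_equal(w$df, unname(tt$parameter), tolerance = 1e-10)
    expect_equal(w$p, tt$p.value, tolerance = 1e-10)
  }
})

test_that("welch t degenerate contracts hold", {
  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0); expect_equal(same$p, 1)
  flat <- welch_t(c(2, 2), c(2, 2))
  expect_equal(flat$t, 0); expect_equal(flat$p, 1)
  expect_true(flat$degenerate)
  apart <- welch_t(c(2, 2), c(5, 5))
  expect_equal(apart$t, -Inf); expect_equal(apart$p, 0)
  expect_true(apart$degenerate)
  expect_error(welch_t(1, c(1, 2)), "at least 2")
})

test_that("per-gene association statistics are bounded and defined as documented", {
  res <- recovery_results()
  assoc <- res$assoc
  ok <- !is.na(assoc$rho)
  expect_true(all(abs(assoc$rho[ok]) <= 1 + 1e-12))
  okr <- !is.na(assoc$fit_r)
  expect_true(all(abs(assoc$fit_r[okr]) <= 1 + 1e-12))
  expect_true(all(assoc$n_levels[okr] >= 3))
  expect_false(any(assoc$valid & assoc$n_pairs == 0))
})

test_that("cohort-level fit recovers linear dosage and vanishes without it", {
  co <- simulate_cohort(small_config(n_genes = 300, n_samples = 80,
                                     dosage_fraction = 1, discord_rate = 0,
                                     slope_mean = 2, slope_sd = 0.1,
                                     noise_sd = 0.2, seed = 51L))
  zm <- compute_z(co$expression, co$calls)
  cf <- cohort_fit(zm, co$calls)
  expect_gt(cf$r, 0.97)
  expect_gt(cf$slope, 0)
  expect_lt(cf$p, 0.01)
  co0 <- simulate_cohort(small_config(n_genes = 300, n_samples = 80,
                                      dosage_fraction = 0, seed = 53L))
  zm0 <- compute_z(co0$expression, co0$calls)
  cf0 <- cohort_fit(zm0, co0$calls)
  expect_lt(abs(cf0$slope), 0.15)
})

test_that("amplified z-scores exceed deleted z-scores under strong dosage", {
  res <- recovery_results()
  co <- recovery_cohort()
  avd <- amplified_vs_deleted(res$zmat, co$calls)
  expect_lt(avd$p, 0.05)
  expect_gt(avd$mean_a, avd$mean_b)
})

test_that("cross-dataset rho agreement reports quadrant fractions", {
  a <- data.frame(gene = c("g1", "g2", "g3", "g4"),
                  rho = c(0.5, -0.2, 0.3, NA))
  b <- data.frame(gene = c("g2", "g3", "g4", "g5"),
                  rho = c(-0.1, 0.6, 0.2, 0.9))
  ag <- rho_agreement(a, b)
  expect_equal(ag$n_shared, 2) # g2, g3 (g4 NA in a)
  expect_equal(ag$frac_both_positive, 0.5)
  expect_equal(ag$frac_both_negative, 0.5)
})
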