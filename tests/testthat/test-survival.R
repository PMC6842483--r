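test_that("the product-limit estimator matches hand computations", {
  # three events, no censoring: S steps 2/3, 1/3, 0
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0), tolerance = 1e-12)
  expect_equal(km$n_risk, c(3L, 2L, 1L))
  # all censored: S = 1 everywhere
  flat <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_equal(flat$surv, c(1, 1, 1))
  # single sample with an event at t = 5
  one <- km_estimate(5, 1)
  expect_equal(one$surv, 0)
  expect_equal(one$time, 5)
  # censoring reduces the risk set only: events at 1 and 3, censor at 2
  mix <- km_estimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(mix$surv, c(2 / 3, 2 / 3, 0), tolerance = 1e-12)
  expect_error(km_estimate(c(0, 1), c(1, 1)), "positive")
  expect_error(km_estimate(numeric(0), numeric(0)), "at least one")
})

test_that("the KM curve is a proper non-increasing survival function", {
  set.seed(61)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    time <- rexp(n, 0.1) + 0.01
    event <- rbinom(n, 1, 0.7)
    km <- km_estimate(time, event)
    expect_true(all(diff(km$surv) <= 1e-12))
    expect_true(all(km$surv >= -1e-12 & km$surv <= 1))
  }
})

test_that("KM agrees with the survival package on random cohorts", {
  skip_if_not_installed("survival")
  set.seed(71)
  for (i in 1:20) {
    n <- sample(5:50, 1)
    time <- round(rexp(n, 0.05), 1) + 0.1 # force ties
    event <- rbinom(n, 1, 0.6)
    km <- km_estimate(time, event)
    sf <- survival::survfit(survival::Surv(time, event) ~ 1)
    expect_equal(km$surv, unname(summary(sf, times = km$time)$surv),
                 tolerance = 1e-12)
  }
})

test_that("the log-rank statistic matches a six-sample hand computation", {
  # group A: events at 1, 3; censored 5.  group B: events at 2, 4; censored 6
  time <- c(1, 3, 5, 2, 4, 6)
  event <- c(1, 1, 0, 1, 1, 0)
  group <- c("A", "A", "A", "B", "B", "B")
  # exhaustive O-E and V per event time:
  # t=1: n=6, nA=3, d=1 -> eA = 0.5,    v = 1*(3/6)*(3/6)*(5/5) = 0.25
  # t=2: n=5, nA=2, d=1 -> eA = 0.4,    v = (2/5)*(3/5)*1       = 0.24
  # t=3: n=4, nA=2, d=1 -> eA = 0.5,    v = 0.25
  # t=4: n=3, nA=1, d=1 -> eA = 1/3,    v = (1/3)*(2/3)         = 2/9
  # O_A = 2, E_A = 0.5+0.4+0.5+1/3 = 1.7333..., V = 0.96222...
  lr <- logrank_test(time, event, group)
  e_a <- 0.5 + 0.4 + 0.5 + 1 / 3
  v <- 0.25 + 0.24 + 0.25 + 2 / 9
  expect_equal(unname(lr$expected["A"]), e_a, tolerance = 1e-12)
  expect_equal(lr$chisq, (2 - e_a)^2 / v, tolerance = 1e-12)
  expect_equal(lr$p, pchisq((2 - e_a)^2 / v, 1, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("log-rank is symmetric in group labels and handles degenerate input", {
  time <- c(1, 2, 3, 4, 5, 6)
  event <- c(1, 0, 1, 1, 0, 1)
  group <- c("A", "A", "A", "B", "B", "B")
  lr1 <- logrank_test(time, event, group)
  lr2 <- logrank_test(time, event, rev(group))
  expect_equal(lr1$chisq, lr2$chisq, tolerance = 1e-12)
  expect_equal(lr1$p, lr2$p, tolerance = 1e-12)
  # identical groups: interleave the same survival experience
  same <- logrank_test(c(1, 1, 2, 2), c(1, 1, 1, 1),
                       c("A", "B", "A", "B"))
  expect_equal(same$chisq, 0, tolerance = 1e-12)
  expect_equal(same$p, 1, tolerance = 1e-12)
  # zero events: undefined and flagged
  none <- logrank_test(c(1, 2), c(0, 0), c("A", "B"))
  expect_false(none$defined)
  expect_true(is.na(none$p))
  expect_error(logrank_test(1:3, c(1, 1, 1), c("A", "A", "A")),
               "2 non-empty levels")
})

test_that("log-rank agrees with survival::survdiff on random cohorts", {
  skip_if_not_installed("survival")
  set.seed(81)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    time <- round(rexp(n, 0.05), 1) + 0.1
    event <- rbinom(n, 1, 0.6)
    group <- sample(c("A", "B"), n, replace = TRUE)
    if (length(unique(group)) < 2 || sum(event) == 0) next
    lr <- logrank_test(time, event, group)
    sd <- survival::survdiff(survival::Surv(time, event) ~ group)
    expect_equal(lr$chisq, unname(sd$chisq), tolerance = 1e-8)
  }
})

test_that("tendency grouping splits carriers from non-carriers", {
  co <- recovery_cohort()
  res <- recovery_results()
  g <- co$survival_gene
  grp <- tendency_groups(res$tt, co$clinical, g, "AU")
  expect_setequal(unique(grp$group), c("carrier", "non-carrier"))
  expect_equal(nrow(grp), nrow(co$clinical))
  # carriers are exactly the AU-labelled samples for that gene
  au_samples <- colnames(res$tt$label)[res$tt$label[g, ] == "AU"]
  expect_setequal(grp$sample[grp$group == "carrier"], au_samples)
  expect_error(tendency_groups(res$tt, co$clinical, "no_such_gene"),
               "not in cohort")
  # samples without clinical rows are excluded with a message
  expect_message(
    grp2 <- tendency_groups(res$tt, co$clinical[-1, ], g, "AU"),
    "without clinical")
  expect_equal(nrow(grp2), nrow(co$clinical) - 1)
})

test_that("a planted hazard ratio is detected and carriers fare worse", {
  co <- recovery_cohort()
  res <- recovery_results()
  grp <- tendency_groups(res$tt, co$clinical, co$survival_gene, "AU")
  lr <- logrank_test(grp$time, grp$event, grp$group)
  expect_lt(lr$p, 0.05)
  km_c <- km_estimate(grp$time[grp$group == "carrier"],
                      grp$event[grp$group == "carrier"])
  km_n <- km_estimate(grp$time[grp$group == "non-carrier"],
                      grp$event[grp$group == "non-carrier"])
  # carriers reach the median survival probability earlier
  med_c <- min(km_c$time[km_c$surv <= 0.5])
  med_n <- min(km_n$time[km_n$surv <= 0.5])
  expect_lt(med_c, med_n)
})

test_that("the survival screen reports raw and BH-adjusted p-values", {
  co <- recovery_cohort()
  res <- recovery_results()
  genes <- c(co$survival_gene, rank_top_concordant(res$gc, 3, "DDG"))
  out <- survival_by_tendency(res$tt, co$clinical, genes,
                              c("AU", rep("DD", 3)))
  expect_equal(nrow(out), 4)
  expect_true(all(out$p_adj >= out$p, na.rm = TRUE))
  expect_true(all(out$p_adj <= 1, na.rm = TRUE))
  # an absent gene is skipped with a note, not an error
  out2 <- survival_by_tendency(res$tt, co$clinical, "no_such_gene", "AU")
  expect_true(nzchar(out2$note[1]))
  expect_true(is.na(out2$p[1]))
})

test_that("log-rank type-I error is near nominal under the null", {
  cal <- logrank_null_calibration(n_rep = 300, n = 200, seed = 91L)
  expect_gte(cal$rejection_rate, 0.02)
  expect_lte(cal$rejection_rate, 0.08)
})
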