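test_that("contamination probabilities follow the read-mass decomposition", {
  sums <- tibble::tibble(timepoint = 0, sum_e = 100, sum_m = 100)
  pr <- contamination_probabilities(sums, sigma_e = 0.1, sigma_m = 0.1)
  expect_equal(pr$E, 90)
  expect_equal(pr$E_prime, 10)
  expect_equal(pr$pC_e, 0.1, tolerance = 1e-12)
  expect_equal(pr$pC_m, 0.1, tolerance = 1e-12)

  none <- contamination_probabilities(sums, sigma_e = 0.1, sigma_m = 0)
  expect_equal(none$pC_e, 0)  # no mis-sorted epithelial reads exist

  zero <- contamination_probabilities(sums, 0, 0)
  expect_equal(c(zero$pC_e, zero$pC_m), c(0, 0))

  expect_error(
    contamination_probabilities(tibble::tibble(timepoint = 0, sum_e = 0,
                                               sum_m = 0), 0.1, 0.1),
    "zero read mass"
  )
})

test_that("bi-lineage binomial tail matches the oracle and drives calls", {
  # upper tail includes the observed count: P(X >= 3 | n = 103, p = 0.01)
  probs <- tibble::tibble(timepoint = 0, pC_e = 0.01, pC_m = 0.01)
  reads <- tibble::tibble(clone = "c", timepoint = 0, r_e = 100, r_m = 3)
  res <- bilineage_test(reads, probs)
  oracle <- 1 - pbinom(2, 103, 0.01)
  expect_equal(res$per_timepoint$p_all_e, oracle, tolerance = 1e-12)
  expect_lt(abs(oracle - 0.085), 1e-3)
  # the 3 mesenchymal reads are explainable by contamination: the
  # all-epithelial null stands while the all-mesenchymal null falls
  expect_false(res$per_timepoint$reject_all_e)
  expect_true(res$per_timepoint$reject_all_m)
  expect_equal(res$calls$call, "mono_E")

  # balanced clone at both tails' extremes is called bi-lineage
  probs5 <- tibble::tibble(timepoint = 0, pC_e = 0.05, pC_m = 0.05)
  both <- bilineage_test(
    tibble::tibble(clone = "c", timepoint = 0, r_e = 500, r_m = 500), probs5
  )
  expect_lt(both$per_timepoint$p_all_e, 1e-10)
  expect_equal(both$calls$call, "bilineage")

  # r_m = 0 at every time point: the all-epithelial null can never be
  # rejected (P(X >= 0) = 1) and the clone is mono-epithelial
  mono <- bilineage_test(
    tibble::tibble(clone = "c", timepoint = 0:2, r_e = 100, r_m = 0),
    tibble::tibble(timepoint = 0:2, pC_e = 0.02, pC_m = 0.02)
  )
  expect_equal(mono$per_timepoint$p_all_e, rep(1, 3))
  expect_equal(mono$calls$call, "mono_E")

  # zero-read time points are excluded and flagged
  gap <- bilineage_test(
    tibble::tibble(clone = "c", timepoint = 0:1, r_e = c(0, 200), r_m = c(0, 200)),
    tibble::tibble(timepoint = 0:1, pC_e = 0.02, pC_m = 0.02)
  )
  expect_true(gap$per_timepoint$excluded[1])
  expect_equal(gap$calls$call, "bilineage")
})

test_that("sigma = 0 turns every mixed clone bi-lineage", {
  probs <- tibble::tibble(timepoint = 0, pC_e = 0, pC_m = 0)
  res <- bilineage_test(
    tibble::tibble(clone = c("a", "b"), timepoint = 0,
                   r_e = c(50, 400), r_m = c(50, 1)),
    probs
  )
  expect_true(all(res$calls$call == "bilineage"))
})

test_that("chi-squared bias statistic matches hand arithmetic and scales", {
  # two clones so totals define the population proportions 60:40
  reads <- tibble::tibble(
    clone = c("big", "probe"), timepoint = 0,
    r_e = c(60000 - 80, 80), r_m = c(40000 - 20, 20)
  )
  res <- bias_test(reads)
  probe <- res$per_timepoint[res$per_timepoint$clone == "probe", ]
  expect_equal(probe$exp_e, 60, tolerance = 1e-2)
  expect_equal(probe$statistic, (80 - 60)^2 / 60 + (20 - 40)^2 / 40,
               tolerance = 1e-2)
  expect_equal(probe$p, pchisq(probe$statistic, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_lt(abs(probe$p - 4.5e-5), 1e-6)

  # doubling all counts doubles the statistic
  doubled <- bias_test(dplyr::mutate(reads, r_e = r_e * 2, r_m = r_m * 2))
  p2 <- doubled$per_timepoint[doubled$per_timepoint$clone == "probe", ]
  expect_equal(p2$statistic / probe$statistic, 2, tolerance = 1e-6)

  # clone exactly at population proportions scores zero
  at <- bias_test(tibble::tibble(clone = c("a", "b"), timepoint = 0,
                                 r_e = c(600, 6000), r_m = c(400, 4000)))
  expect_equal(at$per_timepoint$statistic, c(0, 0), tolerance = 1e-12)
  expect_equal(at$per_timepoint$p, c(1, 1))
  expect_equal(at$calls$call, rep("population_like", 2))
})

test_that("BH step-up matches the hand-worked rejection set", {
  expect_equal(bh_fdr(0.01, 0.05), TRUE)
  # step-up by hand: thresholds i/m * alpha = (.0125, .025, .0375, .05);
  # p3 = 0.04 > 0.0375 and p4 = 0.9 > 0.05, so only the first two fall
  expect_equal(bh_fdr(c(0.01, 0.02, 0.04, 0.9), 0.05),
               c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(bh_fdr(rep(1, 5), 0.05), rep(FALSE, 5))
  expect_length(bh_fdr(numeric(0), 0.05), 0)
  # monotone in the raw p-values
  p <- sort(runif(20))
  r <- bh_fdr(p, 0.1)
  expect_true(all(diff(as.integer(r)) <= 0))
})

test_that("type-I error of both tests is controlled under the null", {
  set.seed(101)
  n_clones <- 1500
  sigma <- 0.05
  tot <- rpois(n_clones, 300) + 50
  # truly mono-epithelial clones observed through mis-sorting only:
  # each read lands in the M-sorted pool with probability ~pC_e
  reads <- tibble::tibble(
    clone = sprintf("c%04d", seq_len(n_clones)), timepoint = 0,
    r_m = rbinom(n_clones, tot, sigma), r_e = NA_real_
  )
  reads$r_e <- tot - reads$r_m
  probs <- contamination_probabilities(
    tibble::tibble(timepoint = 0, sum_e = sum(reads$r_e), sum_m = 1e6),
    sigma_e = 0, sigma_m = sum(reads$r_m) / 1e6
  )
  # pC_e equals the per-read mis-call rate by construction
  expect_equal(probs$pC_e, sum(reads$r_m) / sum(tot), tolerance = 1e-12)
  res <- bilineage_test(reads, probs)
  false_bilineage <- mean(res$calls$call == "bilineage")
  expect_lte(false_bilineage, 0.05)

  # clones drawn exactly at population proportions: bias test rejects <= 5%
  set.seed(202)
  tot2 <- rpois(2000, 400) + 100
  r_e2 <- rbinom(2000, tot2, 0.6)
  null_reads <- tibble::tibble(clone = sprintf("n%04d", 1:2000), timepoint = 0,
                               r_e = r_e2, r_m = tot2 - r_e2)
  bres <- bias_test(null_reads)
  expect_lte(mean(bres$calls$call == "biased"), 0.05)
})

test_that("permutation p matches exhaustive enumeration at small n", {
  x <- c(1, 2, 3, 4)
  y <- c(1.2, 1.9, 3.4, 3.9)
  perms <- matrix(unlist(all_perms(4)), ncol = 4, byrow = TRUE)
  rho_all <- apply(perms, 1, function(ix) cor(x, y[ix]))
  rho_obs <- cor(x, y)
  exact <- mean(rho_all >= rho_obs)   # 1/24: only identity reaches rho_obs
  res <- permutation_correlation(x, y, reps = 20000, seed = 3)
  expect_equal(res$rho, rho_obs)
  se <- sqrt(exact * (1 - exact) / 20000)
  expect_lt(abs(res$exceed / res$reps - exact), 4 * se)
  expect_gte(res$p, 1 / (res$reps + 1))

  expect_error(permutation_correlation(1:2, 1:2), "length >= 3")
  expect_error(permutation_correlation(rep(1, 5), 1:5), "zero variance")
})

test_that("perfect correlation sits at the permutation floor", {
  x <- rnorm(28)
  res <- permutation_correlation(x, x, reps = 5000, seed = 9)
  expect_equal(res$rho, 1)
  # ties can occur only if a permutation reproduces the identity ordering
  expect_lte(res$exceed, 1)
  expect_lte(res$p, 2 / 5001)
})

test_that("permutation p is calibrated under independence", {
  set.seed(44)
  ps <- replicate(40, {
    permutation_correlation(rnorm(12), rnorm(12), reps = 400)$p
  })
  # uniform p-values: mean ~0.5, spread across the unit interval
  expect_lt(abs(mean(ps) - 0.5), 0.2)
  # discrete permutation p-values tie occasionally; the KS check is
  # approximate by construction
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif")$p.value), 0.01)
})

test_that("heritability matches Pearson on matched pairs and recovers truth", {
  pooled <- tibble::tibble(clone_id = sprintf("c%02d", 1:10),
                           log2_em = seq(-2, 2.5, by = 0.5))
  sub <- dplyr::mutate(pooled, log2_em = log2_em)  # perfect transmission
  h <- heritability(pooled, sub, reps = 200, seed = 1)
  expect_equal(h$rho, 1)

  # analytic attenuation: rho = sd^2 / (sd^2 + tau^2) under two-sided noise
  set.seed(7)
  sd_true <- 2; tau <- 1
  reps <- 40; n <- 200
  rhos <- replicate(reps, {
    tr <- rnorm(n, 0, sd_true)
    cor(tr + rnorm(n, 0, tau), tr + rnorm(n, 0, tau))
  })
  expected <- sd_true^2 / (sd_true^2 + tau^2)
  expect_lt(abs(mean(rhos) - expected), 3 * sd(rhos) / sqrt(reps))

  # unmatched clones are dropped with a warning
  extra <- dplyr::bind_rows(sub, tibble::tibble(clone_id = "zz", log2_em = 0))
  expect_warning(heritability(pooled, extra, reps = 100, seed = 2), "unmatched")
})
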