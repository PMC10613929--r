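test_that("auroc matches brute-force pair counting and handles ties", {
  expect_equal(auroc(c(0, 1, 1, 0), c(0.1, 0.9, 0.4, 0.5)),
               auroc_bruteforce(c(0, 1, 1, 0), c(0.1, 0.9, 0.4, 0.5)))
  # perfectly separating scores
  expect_equal(auroc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1)
  set.seed(42)
  for (i in 1:20) {
    n <- sample(10:200, 1)
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    s <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)  # many ties
    expect_equal(auroc(y, s), auroc_bruteforce(y, s), tolerance = 1e-12)
  }
  # chance level for independent scores
  set.seed(1)
  y <- rbinom(5000, 1, 0.3)
  expect_lt(abs(auroc(y, runif(5000)) - 0.5), 0.03)
  expect_error(auroc(rep(1, 5), runif(5)), "both outcome classes")
})

test_that("auprc follows the precision-recall step integral", {
  # perfect ranking: precision 1 everywhere
  expect_equal(auprc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1)
  # single positive ranked worst of n: AP = 1/n
  expect_equal(auprc(c(1, 0, 0, 0), c(0.1, 0.5, 0.6, 0.7)), 0.25)
  # uninformative scores approach prevalence
  set.seed(2)
  y <- rbinom(5000, 1, 0.3)
  expect_lt(abs(auprc(y, runif(5000)) - 0.3), 0.05)
  # bounded in [0, 1] on random inputs
  set.seed(3)
  for (i in 1:10) {
    y <- rbinom(50, 1, 0.5)
    if (length(unique(y)) < 2) next
    v <- auprc(y, runif(50))
    expect_gte(v, 0)
    expect_lte(v, 1)
  }
})

test_that("adjusted Rand index agrees with brute-force pair counting on
           all partitions of small item sets", {
  parts5 <- all_partitions(5)
  for (a in parts5[seq(1, length(parts5), by = 3)]) {
    for (b in parts5[seq(2, length(parts5), by = 5)]) {
      expect_equal(adjusted_rand_index(a, b), ari_bruteforce(a, b),
                   tolerance = 1e-12)
    }
  }
  set.seed(9)
  for (i in 1:50) {
    a <- sample(1:3, 8, replace = TRUE)
    b <- sample(1:4, 8, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), ari_bruteforce(a, b),
                 tolerance = 1e-12)
  }
})

test_that("adjusted Rand index is 1 exactly for relabelings and at most
           1 always", {
  expect_equal(adjusted_rand_index(c(0, 0, 1, 1), c(1, 1, 0, 0)), 1)
  expect_equal(adjusted_rand_index(letters[c(1, 2, 1, 3)],
                                   c(9, 5, 9, 7)), 1)
  set.seed(10)
  for (i in 1:100) {
    a <- sample(1:4, 12, replace = TRUE)
    b <- sample(1:4, 12, replace = TRUE)
    v <- adjusted_rand_index(a, b)
    expect_lte(v, 1)
    if (v == 1) {
      expect_equal(length(unique(paste(a, b))), length(unique(a)))
    }
  }
  # chance level for independent partitions
  set.seed(11)
  a <- sample(1:3, 1000, replace = TRUE)
  b <- sample(1:3, 1000, replace = TRUE)
  expect_lt(abs(adjusted_rand_index(a, b)), 0.02)
})

test_that("adjusted Rand index matches the reference implementation", {
  skip_if_not_installed("mclust")
  set.seed(12)
  for (i in 1:20) {
    a <- sample(1:4, 30, replace = TRUE)
    b <- sample(1:3, 30, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
})

test_that("mean pairwise ARI zeroes pairs that involve a singular
           partition", {
  p <- list(c(1, 1, 2, 2), c(1, 1, 2, 2), c(2, 2, 1, 1),
            c(1, 1, 2, 2), c(1, 1, 2, 2))
  expect_equal(mean_pairwise_ari(p)$mean, 1)
  # one all-same-label partition among five: its 4 pairs contribute 0
  p[[3]] <- c(1, 1, 1, 1)
  res <- mean_pairwise_ari(p)
  expect_equal(sum(res$pairs$singular), 4)
  expect_equal(res$pairs$ari[res$pairs$singular], rep(0, 4))
  expect_equal(res$mean, 6 / 10)
  # chance level for independent random partitions
  set.seed(13)
  parts <- replicate(5, sample(1:3, 1000, replace = TRUE),
                     simplify = FALSE)
  expect_lt(abs(mean_pairwise_ari(parts)$mean), 0.02)
  expect_error(mean_pairwise_ari(list(c(1, 2))), "at least 2")
})

test_that("Clopper-Pearson matches direct binomial tail inversion for
           all k with n up to 50", {
  for (n in c(1, 2, 5, 17, 50)) {
    for (k in 0:n) {
      got <- clopper_pearson_interval(k, n)
      want <- cp_bruteforce(k, n)
      expect_equal(got$lower, unname(want["lower"]), tolerance = 1e-9)
      expect_equal(got$upper, unname(want["upper"]), tolerance = 1e-9)
    }
  }
})

test_that("Clopper-Pearson bounds are monotone in k and handle the
           boundaries", {
  ci <- clopper_pearson_interval(0:30, 30)
  expect_true(all(diff(ci$lower) >= 0))
  expect_true(all(diff(ci$upper) >= 0))
  expect_equal(ci$lower[1], 0)
  expect_equal(ci$upper[31], 1)
  expect_error(clopper_pearson_interval(5, 0), "at least 1")
  expect_error(clopper_pearson_interval(6, 5), "0 <= k <= n")
})

test_that("Clopper-Pearson intervals are conservative: empirical coverage
           at least the nominal level", {
  set.seed(14)
  k <- rbinom(10000, 75, 0.1)
  ci <- clopper_pearson_interval(k, 75)
  coverage <- mean(ci$lower <= 0.1 & 0.1 <= ci$upper)
  expect_gte(coverage, 0.95)
})

test_that("Brier decomposition satisfies the binned identity and the
           textbook special cases", {
  set.seed(15)
  y <- rbinom(2000, 1, 0.3)
  p <- pmin(pmax(rbeta(2000, 2, 4), 0), 1)
  bd <- brier_decomposition(y, p)
  # identity holds exactly under bin-mean forecasts
  expect_equal(bd$reliability - bd$resolution + bd$uncertainty,
               bd$brier_binned, tolerance = 1e-9)
  # raw-forecast Brier differs only by within-bin variance (order
  # bin-width squared)
  expect_lt(abs(bd$brier - bd$brier_binned), (1 / bd$n_bins)^2)
  # perfect sharp forecasts: reliability 0, resolution = uncertainty
  bd2 <- brier_decomposition(y, as.numeric(y))
  expect_equal(bd2$reliability, 0, tolerance = 1e-12)
  expect_equal(bd2$resolution, bd2$uncertainty, tolerance = 1e-12)
  # climatology forecast: resolution 0, reliability ~ 0
  bd3 <- brier_decomposition(y, rep(mean(y), length(y)))
  expect_equal(bd3$resolution, 0, tolerance = 1e-12)
  expect_equal(bd3$reliability, 0, tolerance = 1e-12)
  # uncertainty is the outcome variance
  expect_equal(bd$uncertainty, mean(y) * (1 - mean(y)))
})
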