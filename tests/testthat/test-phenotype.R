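test_that("experts are ordered by weight with deterministic ties", {
  # already-sorted shares keep their order and get labels A..E
  g <- matrix(rep(c(0.77, 0.122, 0.085, 0.021, 0.002), each = 10), 10, 5)
  ord <- order_experts_by_weight(g)
  expect_equal(ord$order, 1:5)
  expect_equal(ord$labels, c("A", "B", "C", "D", "E"))
  # unsorted shares
  g2 <- matrix(rep(c(0.2, 0.5, 0.3), each = 4), 4, 3)
  ord2 <- order_experts_by_weight(g2)
  expect_equal(ord2$order, c(2, 3, 1))
  expect_equal(ord2$labels, c("C", "A", "B"))
  # uniform shares: identity permutation by the tie rule
  g3 <- matrix(1 / 3, 5, 3)
  expect_equal(order_experts_by_weight(g3)$order, 1:3)
  # invariance to row permutation
  set.seed(40)
  g4 <- matrix(stats::rgamma(60, 1), 20, 3)
  g4 <- g4 / rowSums(g4)
  expect_equal(order_experts_by_weight(g4)$order,
               order_experts_by_weight(g4[sample(20), ])$order)
})

test_that("weight contributions are the mean gate mass", {
  one_hot <- matrix(0, 6, 4)
  one_hot[, 3] <- 1
  expect_equal(weight_contribution(one_hot), c(0, 0, 1, 0))
  expect_equal(weight_contribution(matrix(1 / 3, 7, 3)), rep(1 / 3, 3))
  expect_equal(weight_contribution(rbind(c(1, 0), c(0, 1))), c(0.5, 0.5))
  expect_equal(sum(weight_contribution(matrix(runif(30), 10, 3))), 1,
               tolerance = 1e-9)
})

test_that("worked Clopper-Pearson examples reproduce the published
           tabulated intervals", {
  # 0 events in 1 trial: upper bound 97.5%
  ci <- clopper_pearson_interval(0, 1)
  expect_equal(round(100 * ci$upper, 1), 97.5)
  expect_equal(ci$lower, 0)
  # 8 deaths among 75: 10.7% (4.7-19.9)
  ci2 <- clopper_pearson_interval(8, 75)
  expect_equal(round(100 * ci2$lower, 1), 4.7)
  expect_equal(round(100 * ci2$upper, 1), 19.9)
  # all events: upper bound 1
  expect_equal(clopper_pearson_interval(12, 12)$upper, 1)
})

test_that("cluster characteristics reduce to cohort statistics for a
           single cluster and split binary features exactly", {
  co <- fixture_cohort()
  one <- cluster_characteristics(co, rep(1L, cohort_size(co)))
  age_row <- one[one$feature == "age", ]
  expect_equal(age_row$raw, mean(co$features$age), tolerance = 1e-9)
  n_row <- one[one$feature == "n", ]
  expect_equal(n_row$raw, cohort_size(co))
  # two clusters split on a binary feature give 100% / 0%
  labels <- ifelse(co$features$stemi == 1, 1L, 2L)
  two <- cluster_characteristics(co, labels)
  stemi <- two[two$feature == "stemi", ]
  expect_equal(stemi$raw[stemi$cluster == "A"], 100)
  expect_equal(stemi$raw[stemi$cluster == "B"], 0)
})

test_that("per-group continuous means recover the generating means", {
  spec <- default_amics_spec()
  co <- generate_cohort(spec, 20000, seed = 8)
  chars <- cluster_characteristics(co, co$latent)
  for (g in 1:3) {
    n_g <- sum(co$latent == g)
    for (nm in colnames(spec$pres_mean)) {
      row <- chars[chars$feature == nm & chars$cluster == LETTERS[g], ]
      se <- spec$noise_sd / sqrt(n_g)
      expect_lt(abs(row$raw - spec$pres_mean[g, nm]), 2 * se + 0.02)
    }
  }
})

test_that("outcome-rate tables carry exact intervals, closed-form
           zero-event bounds, and the non-significance flag", {
  set.seed(41)
  # cluster of 75 with 8 deaths reproduces the worked interval
  labels <- rep(c(1L, 2L), c(75, 925))
  outcome <- c(rep(c(1L, 0L), c(8, 67)), rbinom(925, 1, 0.25))
  tab <- cluster_outcome_rates(labels, outcome)
  row <- tab[tab$cluster == "A" & tab$group == "entire", ]
  expect_equal(row$display, "10.7 (4.7-19.9)")
  # all-survivor cluster: upper bound has the closed form 1-0.025^(1/n)
  labels2 <- rep(c(1L, 2L), c(40, 200))
  outcome2 <- c(rep(0L, 40), rbinom(200, 1, 0.5))
  tab2 <- cluster_outcome_rates(labels2, outcome2)
  row2 <- tab2[tab2$cluster == "A" & tab2$group == "entire", ]
  expect_equal(row2$ci_high_pct / 100, 1 - 0.025^(1 / 40),
               tolerance = 1e-9)
  # a cluster at exactly the population rate is flagged non-significant
  labels3 <- rep(c(1L, 2L), c(100, 100))
  outcome3 <- rep(c(1L, 0L, 1L, 0L), c(25, 75, 25, 75))
  tab3 <- cluster_outcome_rates(labels3, outcome3)
  expect_true(all(tab3$non_significant[tab3$cluster %in% c("A", "B")]))
  # empty treatment-group cell is reported as no data
  groups <- rep(c("only_iabp", "none"), c(100, 100))
  tab4 <- cluster_outcome_rates(labels3, outcome3, groups)
  cellB <- tab4[tab4$cluster == "B" & tab4$group == "only_iabp", ]
  expect_equal(cellB$display, "no data")
  expect_true(is.na(cellB$rate_pct))
})

test_that("treatment groups are derived mutually exclusively from the
           device indicators", {
  co <- fixture_cohort()
  g <- treatment_groups(co)
  expect_setequal(unique(g),
                  intersect(c("only_iabp", "only_lvad", "none",
                              "other_mcs"), unique(g)))
  f <- co$features
  expect_true(all(g[f$mcs_iabp == 1 & f$mcs_lvad == 0 &
                      f$mcs_ecmo == 0 & f$mcs_other == 0] == "only_iabp"))
  expect_true(all(g[f$mcs_iabp == 0 & f$mcs_lvad == 0 &
                      f$mcs_ecmo == 0 & f$mcs_other == 0] == "none"))
  expect_length(g, cohort_size(co))
})
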