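test_that("imputation follows the binary-to-no and continuous-to-mean
           rules", {
  schema <- cohort_schema(
    data.frame(name = c("b", "c", "t1"),
               kind = c("binary", "continuous", "continuous"),
               tier = c("presentation", "presentation", "treatment")),
    outcome = "y")
  co <- moe_cohort(
    data.frame(b = c(1, NA, 0), c = c(2, 4, NA), t1 = c(0, 1, 2)),
    c(0, 1, 0), schema)
  imp <- impute_missing(co)
  expect_equal(imp$cohort$features$b, c(1, 0, 0))
  expect_equal(imp$cohort$features$c, c(2, 4, 3))
  expect_equal(imp$means[["c"]], 3)
  # stored means reapply to a new table
  co2 <- moe_cohort(
    data.frame(b = c(NA, 1), c = c(NA, 10), t1 = c(1, 1)),
    c(1, 0), schema)
  imp2 <- impute_missing(co2, means = imp$means)
  expect_equal(imp2$cohort$features$c[1], 3)
  # tables without missing values pass through unchanged
  imp3 <- impute_missing(imp$cohort)
  expect_identical(imp3$cohort$features, imp$cohort$features)
  # entirely-missing continuous column without stored means fails
  co3 <- moe_cohort(
    data.frame(b = c(0, 1), c = c(NA_real_, NA_real_), t1 = c(1, 2)),
    c(0, 1), schema)
  expect_error(impute_missing(co3), "entirely missing")
})

test_that("model construction respects the preset sizes, expert count,
           and seeding contract", {
  schema <- amics_schema()
  m5 <- build_moe(moe_config(n_experts = 5, seed = 2), schema)
  expect_equal(ncol(m5$params$gate$W), 5)
  expect_length(m5$params$experts, 5)
  # large preset: selector has 3 hidden layers of width 50
  big <- build_moe(moe_config(n_experts = 2, size_preset = "large",
                              seed = 2), schema)
  expect_length(big$params$selector, 3)
  expect_equal(vapply(big$params$selector, function(l) ncol(l$W),
                      numeric(1)), c(50, 50, 50))
  # small preset: single prediction layer per expert
  expect_length(m5$params$experts[[1]], 1)
  # mid preset: two hidden layers of 24 in both parts
  mid <- build_moe(moe_config(n_experts = 2, size_preset = "mid",
                              seed = 2), schema)
  expect_length(mid$params$selector, 2)
  expect_length(mid$params$experts[[1]], 3)
  expect_equal(ncol(mid$params$selector[[1]]$W), 24)
  # identical seeds give identical initial parameters
  m5b <- build_moe(moe_config(n_experts = 5, seed = 2), schema)
  expect_identical(m5$params, m5b$params)
  expect_error(moe_config(n_experts = 11), "between 2 and 10")
  expect_error(moe_config(n_experts = 1), "between 2 and 10")
})

test_that("forward pass keeps gates on the simplex and the vote inside
           the expert range", {
  co <- fixture_cohort()
  model <- fixture_model()
  pred <- moe_forward(model, cohort_subset(co, 1:500))
  expect_true(all(pred$gates >= 0))
  expect_equal(rowSums(pred$gates), rep(1, 500), tolerance = 1e-6)
  expect_true(all(pred$final_risk >= apply(pred$expert_risks, 1, min) - 1e-9))
  expect_true(all(pred$final_risk <= apply(pred$expert_risks, 1, max) + 1e-9))
  expect_equal(pred$final_risk,
               rowSums(pred$gates * pred$expert_risks),
               tolerance = 1e-9)
})

test_that("degenerate mixtures behave like single experts", {
  # one-hot gates reproduce the selected expert; identical experts make
  # the vote independent of the gates
  model <- fixture_model()
  co <- fixture_cohort()
  prep <- moephen:::moe_preprocess(model, cohort_subset(co, 1:200))
  params <- model$params
  # force all experts to share the first expert's parameters
  for (k in seq_along(params$experts)) {
    params$experts[[k]] <- params$experts[[1]]
  }
  fw <- moephen:::moe_forward_raw(params, model$config$connection_variant,
                                  prep$Xp, prep$Xt)
  expect_equal(fw$final_risk, fw$expert_risks[, 1], tolerance = 1e-9)
  # one-hot gates: push the gate bias hard toward expert 2
  params2 <- model$params
  params2$gate$W[] <- 0
  params2$gate$b <- c(-50, 50, -50)
  fw2 <- moephen:::moe_forward_raw(params2,
                                   model$config$connection_variant,
                                   prep$Xp, prep$Xt)
  expect_equal(fw2$final_risk, fw2$expert_risks[, 2], tolerance = 1e-9)
})

test_that("gating penalty has the exact extremes and is Schur-convex", {
  expect_equal(gating_penalty(c(1, 0, 0, 0, 0), 1), 1)
  expect_equal(gating_penalty(rep(1 / 5, 5), 1), 0.2)
  expect_equal(gating_penalty(c(0.5, 0.5, 0, 0, 0), 0.01), 0.005)
  expect_error(gating_penalty(c(0.5, 0.5), -1), "nonnegative")
  # Schur-convexity: moving mass from a smaller to a larger entry (a
  # majorisation step) never decreases the penalty
  set.seed(31)
  for (i in 1:50) {
    g <- as.numeric(stats::rgamma(4, 1))
    g <- g / sum(g)
    hi <- which.max(g)
    lo <- which.min(g)
    eps <- runif(1, 0, g[lo] / 2)
    g2 <- g
    g2[hi] <- g2[hi] + eps
    g2[lo] <- g2[lo] - eps
    expect_gte(gating_penalty(g2, 1), gating_penalty(g, 1) - 1e-12)
  }
})

test_that("training loss equals cross-entropy plus penalty, computed by
           hand on a fixed batch", {
  y <- c(1, 0, 1)
  pred <- list(
    final_risk = c(0.8, 0.3, 0.6),
    gates = rbind(c(0.5, 0.5), c(0.9, 0.1), c(0.2, 0.8)),
    initial_risk = NULL)
  manual_bce <- -mean(log(c(0.8, 0.7, 0.6)))
  manual_pen <- 0.01 * mean(c(0.5, 0.82, 0.68))
  expect_equal(training_loss(y, pred, 0.01), manual_bce + manual_pen,
               tolerance = 1e-12)
  # penalty off reduces to plain cross-entropy
  expect_equal(training_loss(y, pred, 0), manual_bce, tolerance = 1e-12)
  # perfect prediction with no penalty is (numerically) zero
  perfect <- list(final_risk = c(1, 0, 1),
                  gates = rbind(c(1, 0), c(1, 0), c(1, 0)),
                  initial_risk = NULL)
  expect_lt(training_loss(y, perfect, 0), 1e-6)
  # the auxiliary initial-risk term adds weighted cross-entropy
  pred$initial_risk <- c(0.7, 0.4, 0.5)
  aux <- -mean(log(c(0.7, 0.6, 0.5)))
  expect_equal(training_loss(y, pred, 0, aux_weight = 0.1),
               manual_bce + 0.1 * aux, tolerance = 1e-12)
})

test_that("hard assignments take the argmax with ties to the lowest
           index", {
  cl <- assign_clusters(rbind(c(0.7, 0.2, 0.1),
                              c(0.5, 0.5, 0.0),
                              c(0.0, 0.0, 1.0)))
  expect_equal(cl$hard, c(1, 1, 3))
  one_hot <- diag(4)[c(3, 1, 4, 2), ]
  expect_equal(assign_clusters(one_hot)$hard, c(3, 1, 4, 2))
})

test_that("training is deterministic given the seed and learns a
           separable cohort", {
  spec <- separable_spec()
  co <- generate_cohort(spec, 5000, seed = 1)
  set.seed(2)
  idx <- sample.int(5000)
  tr <- cohort_subset(co, idx[1:3500])
  va <- cohort_subset(co, idx[3501:4300])
  cfg <- moe_config(n_experts = 2, gating_l2 = 0.01, seed = 1,
                    epochs = 80, patience = 10)
  m1 <- train_moe(build_moe(cfg, co$schema), tr, va)
  m2 <- train_moe(build_moe(cfg, co$schema), tr, va)
  expect_identical(m1$params, m2$params)
  pred <- moe_forward(m1, tr)
  expect_gt(auroc(tr$outcome, pred$final_risk), 0.9)
  expect_error(train_moe(build_moe(cfg, co$schema), tr,
                         cohort_subset(co, integer(0))),
               "non-empty")
})

test_that("connection variants and the initial-risk head train and
           predict", {
  co <- fixture_cohort()
  set.seed(4)
  idx <- sample.int(cohort_size(co))
  tr <- cohort_subset(co, idx[1:1200])
  va <- cohort_subset(co, idx[1201:1500])
  te <- cohort_subset(co, idx[1501:1800])
  for (variant in c("later_hidden", "no_hidden")) {
    cfg <- moe_config(n_experts = 2, connection_variant = variant,
                      seed = 1, epochs = 30, patience = 5)
    m <- train_moe(build_moe(cfg, co$schema), tr, va)
    p <- moe_forward(m, te)
    expect_equal(rowSums(p$gates), rep(1, 300), tolerance = 1e-6)
    expect_gt(auroc(te$outcome, p$final_risk), 0.55)
  }
  cfg <- moe_config(n_experts = 2, initial_risk = TRUE, seed = 1,
                    epochs = 80, patience = 10)
  m <- train_moe(build_moe(cfg, co$schema), tr, va)
  p <- moe_forward(m, te)
  expect_length(p$initial_risk, 300)
  expect_true(all(p$initial_risk >= 0 & p$initial_risk <= 1))
  # the pre-treatment risk head alone carries the between-subgroup
  # signal (within a subgroup the generator's risk is presentation-flat,
  # so its ceiling is the between-group rate difference)
  pfull <- moe_forward(m, co)
  expect_gt(auroc(co$outcome, pfull$initial_risk), 0.55)
})

test_that("models round-trip exactly through the text save format", {
  model <- fixture_model()
  co <- fixture_cohort()
  dir <- withr::local_tempdir()
  save_moe(model, dir)
  reloaded <- load_moe(dir)
  p1 <- moe_forward(model, cohort_subset(co, 1:100))
  p2 <- moe_forward(reloaded, cohort_subset(co, 1:100))
  expect_equal(p1$final_risk, p2$final_risk, tolerance = 1e-12)
  expect_equal(p1$gates, p2$gates, tolerance = 1e-12)
})
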