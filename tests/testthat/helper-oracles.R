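# Independent brute-force oracles used to validate the fast
# implementations. These deliberately avoid the code paths they check.

# AUROC by explicit positive-negative pair counting (ties = 1/2)
auroc_bruteforce <- function(y, s) {
  pos <- s[y == 1]
  neg <- s[y == 0]
  total <- 0
  for (p in pos) {
    total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  }
  total / (length(pos) * length(neg))
}

# ARI from explicit agreement counting over all item pairs
ari_bruteforce <- function(a, b) {
  n <- length(a)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      same_a <- a[i] == a[j]
      same_b <- b[i] == b[j]
      if (same_a && same_b) n11 <- n11 + 1
      else if (!same_a && !same_b) n00 <- n00 + 1
      else if (same_a) n10 <- n10 + 1
      else n01 <- n01 + 1
    }
  }
  total <- n11 + n00 + n10 + n01
  expected <- (n11 + n10) * (n11 + n01) / total
  max_index <- ((n11 + n10) + (n11 + n01)) / 2
  if (max_index == expected) return(0)
  (n11 - expected) / (max_index - expected)
}

# Clopper-Pearson bounds by direct inversion of binomial tail sums
# (bisection over p)
cp_bruteforce <- function(k, n, conf = 0.95) {
  alpha <- 1 - conf
  upper_tail <- function(p) sum(dbinom(k:n, n, p))   # P(X >= k), increasing in p
  lower_tail <- function(p) sum(dbinom(0:k, n, p))   # P(X <= k), decreasing in p
  bisect_increasing <- function(f, target) {
    lo <- 0; hi <- 1
    for (i in 1:100) {
      mid <- (lo + hi) / 2
      if (f(mid) > target) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }
  # lower bound solves P(X >= k | p) = alpha/2;
  # upper bound solves P(X <= k | p) = alpha/2
  lower <- if (k == 0) 0 else bisect_increasing(upper_tail, alpha / 2)
  upper <- if (k == n) 1 else
    bisect_increasing(function(p) 1 - lower_tail(p), 1 - alpha / 2)
  c(lower = lower, upper = upper)
}

# all set partitions of n items as label vectors (restricted growth)
all_partitions <- function(n) {
  out <- list()
  grow <- function(labels, next_max) {
    if (length(labels) == n) {
      out[[length(out) + 1]] <<- labels
      return(invisible())
    }
    for (v in seq_len(next_max + 1)) {
      grow(c(labels, v), max(next_max, v))
    }
  }
  grow(integer(0), 0L)
  out
}

# a tiny single-subgroup specification for degenerate-mixture tests
single_group_spec <- function() {
  schema <- cohort_schema(
    data.frame(name = c("x1", "b1", "t1", "tb1"),
               kind = c("continuous", "binary", "continuous", "binary"),
               tier = c("presentation", "presentation", "treatment",
                        "treatment")),
    outcome = "event"
  )
  treat <- c("t1", "tb1")
  pres <- c("x1", "b1")
  tm <- list(intercept = c(t1 = 0, tb1 = 0),
             coef = matrix(0, 2, 2, dimnames = list(treat, pres)))
  om <- list(intercept = -1,
             coef = c(x1 = 1, b1 = 0.5, t1 = 0.5, tb1 = 0))
  synthetic_spec(schema, mixing = 1,
                 pres_mean = matrix(0, 1, 1, dimnames = list(NULL, "x1")),
                 pres_prev = matrix(0.5, 1, 1,
                                    dimnames = list(NULL, "b1")),
                 treat_model = list(tm), outcome_model = list(om))
}

# a strongly separable two-group specification: outcome driven by a
# single large-coefficient feature so that even a small model reaches
# high discrimination
separable_spec <- function() {
  schema <- cohort_schema(
    data.frame(name = c("x1", "b1", "t1", "tb1"),
               kind = c("continuous", "binary", "continuous", "binary"),
               tier = c("presentation", "presentation", "treatment",
                        "treatment")),
    outcome = "event"
  )
  treat <- c("t1", "tb1")
  pres <- c("x1", "b1")
  tm <- list(intercept = c(t1 = 0, tb1 = 0),
             coef = matrix(c(0.5, 0, 0, 0), 2, 2,
                           dimnames = list(treat, pres)))
  om <- function(icpt) list(
    intercept = icpt, coef = c(x1 = 3, b1 = 0.5, t1 = 1, tb1 = 0))
  synthetic_spec(
    schema, mixing = c(0.5, 0.5),
    pres_mean = matrix(c(-1, 1), 2, 1, dimnames = list(NULL, "x1")),
    pres_prev = matrix(c(0.3, 0.7), 2, 1, dimnames = list(NULL, "b1")),
    treat_model = list(tm, tm),
    outcome_model = list(om(-1.5), om(-1.5))
  )
}

# shared small fixtures: one modest synthetic cohort and one trained
# model, built once per test run
fixture_env <- new.env()

fixture_cohort <- function() {
  if (is.null(fixture_env$cohort)) {
    fixture_env$cohort <- generate_cohort(default_amics_spec(), 3000,
                                          seed = 7)
  }
  fixture_env$cohort
}

fixture_model <- function() {
  if (is.null(fixture_env$model)) {
    co <- fixture_cohort()
    set.seed(3)
    idx <- sample.int(cohort_size(co))
    cfg <- moe_config(n_experts = 3, seed = 1, epochs = 120,
                      patience = 12)
    m <- build_moe(cfg, co$schema)
    fixture_env$model <- train_moe(
      m, cohort_subset(co, idx[1:2400]),
      cohort_subset(co, idx[2401:3000]))
  }
  fixture_env$model
}
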