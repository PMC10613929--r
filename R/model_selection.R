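#' Stratified five-fold cross-validation plan
#'
#' Splits patients into \code{n_folds} disjoint test folds stratified on
#' the outcome; within each fold's training remainder, a further
#' stratified fraction (\code{val_frac}, default 20\%) is set aside as the
#' internal validation split used for early stopping and tuning.
#'
#' @param outcome Binary outcome vector (length = cohort size).
#' @param n_folds Number of outer folds (default 5).
#' @param val_frac Fraction of each fold's training remainder reserved for
#'   internal validation (default 0.2).
#' @param seed Integer seed; identical inputs give identical plans.
#' @return An object of class \code{"moe_fold_plan"}: a list with
#'   \code{folds} (each having \code{test}, \code{train}, \code{val}
#'   index vectors), \code{n}, and \code{seed}.
#' @export
make_fold_plan <- function(outcome, n_folds = 5L, val_frac = 0.2,
                           seed = 1L) {
  y <- check_binary_outcome(outcome)
  n <- length(y)
  if (n < 10L) stop("need at least 10 patients", call. = FALSE)
  stopifnot(n_folds >= 2L, val_frac > 0, val_frac < 1)
  set.seed(seed)
  fold_of <- integer(n)
  for (cls in c(0L, 1L)) {
    idx <- sample(which(y == cls))
    fold_of[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  folds <- lapply(seq_len(n_folds), function(f) {
    test <- which(fold_of == f)
    rest <- which(fold_of != f)
    val <- integer(0)
    for (cls in c(0L, 1L)) {
      cls_idx <- sample(rest[y[rest] == cls])
      n_val <- round(val_frac * length(cls_idx))
      val <- c(val, cls_idx[seq_len(n_val)])
    }
    val <- sort(val)
    list(test = test, train = setdiff(rest, val), val = val)
  })
  for (f in folds) {
    for (part in f) {
      if (length(unique(y[part])) < 2L) {
        stop("a fold split contains a single outcome class; ",
             "use fewer folds or more data", call. = FALSE)
      }
    }
  }
  structure(list(folds = folds, n = n, seed = as.integer(seed)),
            class = "moe_fold_plan")
}

#' @export
print.moe_fold_plan <- function(x, ...) {
  cat("Fold plan: ", length(x$folds), " folds over ", x$n,
      " patients (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

# train one MoE on a fold of the cohort; returns model + test metrics +
# the fold's hard partition of the FULL cohort. With restarts > 1 the
# model is retrained from different initialisations and the restart with
# the best validation loss is kept.
fit_fold <- function(cohort, config, fold, restarts = 1L) {
  train <- cohort_subset(cohort, fold$train)
  val <- cohort_subset(cohort, fold$val)
  model <- NULL
  for (r in seq_len(restarts)) {
    cfg_r <- config
    cfg_r$seed <- config$seed + (r - 1L) * 101L
    cand <- train_moe(build_moe(cfg_r, cohort$schema), train, val)
    if (is.null(model) ||
        cand$history$best_val_loss < model$history$best_val_loss) {
      model <- cand
    }
  }
  test <- cohort_subset(cohort, fold$test)
  pred <- moe_forward(model, test)
  full_pred <- moe_forward(model, cohort)
  bd <- brier_decomposition(test$outcome, pred$final_risk)
  list(model = model,
       auroc = auroc(test$outcome, pred$final_risk),
       auprc = auprc(test$outcome, pred$final_risk),
       uncertainty = bd$uncertainty,
       resolution = bd$resolution,
       reliability = bd$reliability,
       partition = assign_clusters(full_pred)$hard)
}

#' Hyperparameter grid search over (lambda, K)
#'
#' For every combination of gating penalty and expert count, trains one
#' model per outer fold, scores AUROC/AUPRC and the Brier components on
#' the fold's held-out test set, applies each fold's selector to the full
#' cohort, and summarises partition stability as the mean pairwise
#' adjusted Rand index over all fold pairs (singular partitions counting
#' as 0). Fold partitions are compared on the full cohort so that every
#' pair shares an item set; set \code{partition_on = "test"} to compare
#' only held-out assignments on pairwise intersections (which are empty
#' for disjoint folds and therefore score 0 — provided for completeness).
#'
#' @param cohort A \code{moe_cohort}.
#' @param config Template [moe_config()]; its \code{gating_l2} and
#'   \code{n_experts} are overridden by the grid, and its seed is offset
#'   per fold.
#' @param lambda_grid Numeric vector of penalty weights. The default is
#'   the standard search grid
#'   \{0.001, 0.002, 0.004, 0.006, 0.008, 0.01, 0.05, 0.1\}.
#' @param k_grid Integer vector of expert counts (default 2..10).
#' @param fold_plan A [make_fold_plan()] over the cohort.
#' @param restarts Random restarts per fold; the restart with the best
#'   validation loss is kept (default 1).
#' @param partition_on \code{"full"} (default) or \code{"test"}.
#' @return An object of class \code{"moe_grid"}: a long-format data.frame
#'   with columns \code{metric}, \code{lambda}, \code{k}, \code{mean},
#'   \code{ci_low}, \code{ci_high} (mean +/- 1.96 standard errors over
#'   folds), plus the per-fold values in \code{attr(, "folds")}.
#' @export
run_grid <- function(cohort, config,
                     lambda_grid = c(0.001, 0.002, 0.004, 0.006, 0.008,
                                     0.01, 0.05, 0.1),
                     k_grid = 2:10,
                     fold_plan = NULL,
                     restarts = 1L,
                     partition_on = c("full", "test")) {
  stopifnot(inherits(cohort, "moe_cohort"), inherits(config, "moe_config"),
            length(lambda_grid) >= 1, length(k_grid) >= 1)
  partition_on <- match.arg(partition_on)
  if (is.null(fold_plan)) {
    fold_plan <- make_fold_plan(cohort$outcome, seed = config$seed)
  }
  stopifnot(inherits(fold_plan, "moe_fold_plan"),
            fold_plan$n == cohort_size(cohort))
  rows <- list()
  fold_rows <- list()
  for (lambda in lambda_grid) {
    for (k in k_grid) {
      cfg <- config
      cfg$gating_l2 <- lambda
      cfg$n_experts <- as.integer(k)
      fits <- lapply(seq_along(fold_plan$folds), function(f) {
        cfg$seed <- config$seed + 1000L * f
        tryCatch(
          fit_fold(cohort, cfg, fold_plan$folds[[f]], restarts),
          error = function(e) {
            stop("grid cell (lambda=", lambda, ", K=", k, "), fold ", f,
                 ": ", conditionMessage(e), call. = FALSE)
          }
        )
      })
      partitions <- lapply(fits, `[[`, "partition")
      if (partition_on == "test") {
        tests <- lapply(fold_plan$folds, `[[`, "test")
        partitions <- lapply(seq_along(partitions), function(f) {
          p <- rep(NA_integer_, fold_plan$n)
          p[tests[[f]]] <- partitions[[f]][tests[[f]]]
          p
        })
        ari_mean <- mean_pairwise_ari_masked(partitions)
      } else {
        ari_mean <- mean_pairwise_ari(partitions)$mean
      }
      per_fold <- data.frame(
        lambda = lambda, k = k,
        fold = seq_along(fits),
        auroc = vapply(fits, `[[`, numeric(1), "auroc"),
        auprc = vapply(fits, `[[`, numeric(1), "auprc"),
        uncertainty = vapply(fits, `[[`, numeric(1), "uncertainty"),
        resolution = vapply(fits, `[[`, numeric(1), "resolution"),
        reliability = vapply(fits, `[[`, numeric(1), "reliability")
      )
      fold_rows[[length(fold_rows) + 1L]] <- per_fold
      summarise <- function(metric, values) {
        se <- stats::sd(values) / sqrt(length(values))
        data.frame(metric = metric, lambda = lambda, k = k,
                   mean = mean(values),
                   ci_low = mean(values) - 1.96 * se,
                   ci_high = mean(values) + 1.96 * se)
      }
      rows[[length(rows) + 1L]] <- rbind(
        data.frame(metric = "pairwise_ari", lambda = lambda, k = k,
                   mean = ari_mean, ci_low = NA_real_, ci_high = NA_real_),
        summarise("auroc", per_fold$auroc),
        summarise("auprc", per_fold$auprc),
        summarise("uncertainty", per_fold$uncertainty),
        summarise("resolution", per_fold$resolution),
        summarise("reliability", per_fold$reliability)
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "folds") <- do.call(rbind, fold_rows)
  class(out) <- c("moe_grid", class(out))
  out
}

# mean pairwise ARI when partitions carry NA outside their own items:
# pairs are compared on the intersection of labelled items
mean_pairwise_ari_masked <- function(partitions) {
  m <- length(partitions)
  idx <- utils::combn(m, 2)
  vals <- vapply(seq_len(ncol(idx)), function(c) {
    a <- partitions[[idx[1, c]]]
    b <- partitions[[idx[2, c]]]
    both <- !is.na(a) & !is.na(b)
    if (sum(both) < 2L) return(0)
    if (length(unique(a[both])) == 1L || length(unique(b[both])) == 1L) {
      return(0)
    }
    adjusted_rand_index(a[both], b[both])
  }, numeric(1))
  mean(vals)
}

#' Two-stage configuration choice: stability, then discrimination
#'
#' Stage 1 ranks grid cells by mean pairwise ARI: penalty values whose
#' best ARI comes within one confidence half-width of the global best are
#' shortlisted, and the expert count is fixed to the modal ARI-maximising
#' K among the shortlisted penalties. Stage 2 picks, among shortlisted
#' penalties at the chosen K, the penalty with the highest mean AUROC,
#' breaking ties toward the smaller penalty.
#'
#' @param grid A \code{moe_grid} from [run_grid()].
#' @return A list with \code{k}, \code{lambda}, the stage-1
#'   \code{shortlist}, and the stage tables.
#' @export
select_configuration <- function(grid) {
  stopifnot(inherits(grid, "moe_grid"))
  ari <- grid[grid$metric == "pairwise_ari", ]
  au <- grid[grid$metric == "auroc", ]
  if (!nrow(ari) || !nrow(au)) stop("grid is incomplete", call. = FALSE)
  best_by_lambda <- do.call(rbind, lapply(split(ari, ari$lambda),
    function(d) d[which.max(d$mean), ]))
  best <- best_by_lambda[which.max(best_by_lambda$mean), ]
  # one CI half-width of the best cell's AUROC-style uncertainty: use the
  # spread of fold AUROCs as scale where the ARI itself has no CI (single
  # number over one set of folds); fall back to a 10% relative band
  halfwidth <- if (is.finite(best$ci_high) && is.finite(best$ci_low)) {
    (best$ci_high - best$ci_low) / 2
  } else {
    0.1 * max(abs(best$mean), .Machine$double.eps)
  }
  shortlist <- best_by_lambda[best_by_lambda$mean >=
                                best$mean - halfwidth, ]
  k_choice <- as.integer(names(which.max(table(shortlist$k))))
  cand <- au[au$k == k_choice & au$lambda %in% shortlist$lambda, ]
  cand <- cand[order(-cand$mean, cand$lambda), ]
  list(k = k_choice, lambda = cand$lambda[1], shortlist = shortlist,
       stage1 = best_by_lambda, stage2 = cand)
}

#' Minimum-size and minimum-weight check for clusters
#'
#' A cluster passes when its population is at least \code{size_frac} of
#' the largest cluster's population and its share of the total gate mass
#' exceeds \code{weight_frac}.
#'
#' @param labels Hard cluster labels (1..K).
#' @param weight_shares Per-cluster weight shares summing to 1 (see
#'   [weight_contribution()]).
#' @param size_frac Minimum size relative to the largest cluster
#'   (default 0.10).
#' @param weight_frac Minimum weight share, strict (default 0.10).
#' @return A data.frame with one row per cluster: \code{cluster},
#'   \code{size}, \code{weight_share}, \code{size_ok}, \code{weight_ok},
#'   \code{pass}.
#' @export
cluster_size_check <- function(labels, weight_shares, size_frac = 0.10,
                               weight_frac = 0.10) {
  k <- length(weight_shares)
  sizes <- tabulate(labels, nbins = k)
  size_ok <- sizes >= size_frac * max(sizes)
  weight_ok <- weight_shares > weight_frac
  data.frame(cluster = seq_len(k), size = sizes,
             weight_share = as.numeric(weight_shares),
             size_ok = size_ok, weight_ok = weight_ok,
             pass = size_ok & weight_ok)
}

#' Ridge-penalised logistic baseline
#'
#' The standard clinical reference model: L2-regularised logistic
#' regression on all features pooled (both tiers), with the penalty
#' strength chosen on each fold's internal validation split.
#'
#' @param cohort An imputed \code{moe_cohort} (missing values are imputed
#'   per training fold if present).
#' @param fold_plan A [make_fold_plan()] over the cohort.
#' @return A data.frame with one row per fold: \code{fold}, \code{auroc},
#'   \code{lambda} (the chosen ridge penalty).
#' @export
logistic_baseline <- function(cohort, fold_plan) {
  stopifnot(inherits(cohort, "moe_cohort"),
            inherits(fold_plan, "moe_fold_plan"),
            fold_plan$n == cohort_size(cohort))
  res <- lapply(seq_along(fold_plan$folds), function(f) {
    fold <- fold_plan$folds[[f]]
    tr <- cohort_subset(cohort, fold$train)
    imp <- impute_missing(tr)
    Xtr <- as.matrix(imp$cohort$features)
    ytr <- imp$cohort$outcome
    if (length(unique(ytr)) < 2L) {
      stop("training fold ", f, " has a single outcome class",
           call. = FALSE)
    }
    prep_part <- function(idx) {
      part <- impute_missing(cohort_subset(cohort, idx),
                             means = imp$means)$cohort
      list(X = as.matrix(part$features), y = part$outcome)
    }
    va <- prep_part(fold$val)
    te <- prep_part(fold$test)
    fit <- glmnet::glmnet(Xtr, ytr, family = "binomial", alpha = 0)
    val_scores <- stats::predict(fit, va$X, type = "response")
    val_auc <- apply(val_scores, 2, function(s) auroc(va$y, s))
    s_best <- fit$lambda[which.max(val_auc)]
    test_scores <- stats::predict(fit, te$X, s = s_best,
                                  type = "response")[, 1]
    data.frame(fold = f, auroc = auroc(te$y, test_scores),
               lambda = s_best)
  })
  do.call(rbind, res)
}

#' Write a grid result as long-format CSV
#'
#' @param grid A \code{moe_grid}.
#' @param path CSV path.
#' @return \code{path}, invisibly.
#' @export
write_grid <- function(grid, path) {
  utils::write.csv(as.data.frame(grid), path, row.names = FALSE)
  invisible(path)
}
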