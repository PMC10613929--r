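#' Order experts by total gate weight
#'
#' Experts are ranked by the total gate mass they receive over the cohort
#' and labelled alphabetically, so that "A" is always the most heavily
#' weighted expert (shown bottom-right in the ternary plots), "B" the
#' second, and so on. Ties keep the original expert index order.
#'
#' @param gates n x K gate matrix on the simplex.
#' @return A list with \code{order} (permutation of 1..K, heaviest
#'   first), \code{labels} (letters indexed by original expert:
#'   \code{labels[j]} is the letter of expert j), and \code{shares}
#'   (weight share per original expert).
#' @export
order_experts_by_weight <- function(gates) {
  gates <- as.matrix(gates)
  shares <- colMeans(gates)
  shares <- shares / sum(shares)
  ord <- order(-shares)  # stable: ties keep original index order
  labels <- character(length(shares))
  labels[ord] <- LETTERS[seq_along(ord)]
  list(order = ord, labels = labels, shares = shares)
}

#' Weight contribution of each expert
#'
#' The share of the total gate mass assigned to each expert:
#' \eqn{\mathrm{share}_k = \sum_i g_{ik} / n}. Because only three experts
#' can be shown in a ternary plot, these shares quantify how much
#' probability mass truncation discards.
#'
#' @param gates n x K gate matrix on the simplex.
#' @return Numeric vector of length K summing to 1.
#' @export
weight_contribution <- function(gates) {
  gates <- as.matrix(gates)
  shares <- colMeans(gates)
  shares / sum(shares)
}

#' Per-cluster feature summaries
#'
#' Summarises every schema feature within each hard cluster: mean and
#' standard deviation for continuous features, percentage for binary
#' indicators, plus cluster sizes — the layout of a clinical
#' cluster-characteristics table.
#'
#' @param cohort A \code{moe_cohort}.
#' @param labels Hard cluster labels (1..K), aligned to cohort rows.
#' @param cluster_names Optional display names (default "A", "B", ... in
#'   label order 1..K).
#' @return A data.frame with one row per (feature x cluster) plus a
#'   \code{n} row per cluster; columns \code{feature}, \code{cluster},
#'   \code{value} (formatted), \code{raw}.
#' @export
cluster_characteristics <- function(cohort, labels,
                                    cluster_names = NULL) {
  stopifnot(inherits(cohort, "moe_cohort"),
            length(labels) == cohort_size(cohort))
  k <- max(labels)
  if (is.null(cluster_names)) cluster_names <- LETTERS[seq_len(k)]
  feats <- cohort$schema$features
  rows <- list()
  for (cl in seq_len(k)) {
    idx <- labels == cl
    rows[[length(rows) + 1L]] <- data.frame(
      feature = "n", cluster = cluster_names[cl],
      value = format(sum(idx)), raw = sum(idx))
    for (j in seq_len(nrow(feats))) {
      nm <- feats$name[j]
      v <- cohort$features[[nm]][idx]
      if (!sum(idx)) {
        rows[[length(rows) + 1L]] <- data.frame(
          feature = nm, cluster = cluster_names[cl], value = "",
          raw = NA_real_)
      } else if (feats$kind[j] == "continuous") {
        rows[[length(rows) + 1L]] <- data.frame(
          feature = nm, cluster = cluster_names[cl],
          value = sprintf("%.1f (%.1f)", mean(v), stats::sd(v)),
          raw = mean(v))
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          feature = nm, cluster = cluster_names[cl],
          value = sprintf("%.1f%%", 100 * mean(v)),
          raw = 100 * mean(v))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Mechanical-support treatment groups
#'
#' Derives the mutually exclusive treatment categories used in the
#' per-cluster mortality tables from the device indicator columns:
#' \code{"only_iabp"} (balloon pump and no other device),
#' \code{"only_lvad"} (microaxial pump and no other device),
#' \code{"none"} (no device), and \code{"other_mcs"} for the remaining
#' combinations.
#'
#' @param cohort A \code{moe_cohort} whose schema includes the
#'   \code{mcs_iabp}, \code{mcs_lvad}, \code{mcs_ecmo}, \code{mcs_other}
#'   indicator columns.
#' @return Character vector of group names, one per patient.
#' @export
treatment_groups <- function(cohort) {
  f <- cohort$features
  need <- c("mcs_iabp", "mcs_lvad", "mcs_ecmo", "mcs_other")
  if (!all(need %in% names(f))) {
    stop("cohort lacks MCS indicator columns: ",
         paste(setdiff(need, names(f)), collapse = ", "), call. = FALSE)
  }
  iabp <- f$mcs_iabp == 1
  lvad <- f$mcs_lvad == 1
  other <- f$mcs_ecmo == 1 | f$mcs_other == 1
  out <- rep("other_mcs", nrow(f))
  out[!iabp & !lvad & !other] <- "none"
  out[iabp & !lvad & !other] <- "only_iabp"
  out[lvad & !iabp & !other] <- "only_lvad"
  out
}

#' Per-cluster outcome rates with exact confidence intervals
#'
#' For every cluster, and within each treatment group, reports the
#' outcome rate as a percentage with its exact Clopper-Pearson 95\%
#' confidence interval, plus a non-significance flag: a cell is flagged
#' when its interval contains the corresponding whole-population rate
#' (the weakest reading of "no significant difference"; a two-proportion
#' exact test is available via \code{flag = "fisher"}).
#'
#' @param labels Hard cluster labels (1..K).
#' @param outcome Binary outcome vector.
#' @param treat_groups Character vector of treatment-group names (see
#'   [treatment_groups()]); pass \code{NULL} for overall rates only.
#' @param conf Confidence level (default 0.95).
#' @param flag Non-significance criterion: \code{"ci"} (default; CI
#'   contains the population rate) or \code{"fisher"} (two-sided exact
#'   test at \code{1 - conf}).
#' @param cluster_names Optional display names.
#' @return A data.frame with columns \code{cluster}, \code{group},
#'   \code{n}, \code{deaths}, \code{rate_pct}, \code{ci_low_pct},
#'   \code{ci_high_pct}, \code{non_significant}, \code{display} (the
#'   "rate (low-high)" cell text, one decimal place); clusters include a
#'   final \code{"All"} row and groups an \code{"entire"} column-group.
#'   Cells with no patients carry \code{NA} rates.
#' @export
cluster_outcome_rates <- function(labels, outcome, treat_groups = NULL,
                                  conf = 0.95,
                                  flag = c("ci", "fisher"),
                                  cluster_names = NULL) {
  flag <- match.arg(flag)
  y <- check_binary_outcome(outcome)
  stopifnot(length(labels) == length(y))
  k <- max(labels)
  if (is.null(cluster_names)) cluster_names <- LETTERS[seq_len(k)]
  groups <- if (is.null(treat_groups)) rep("entire", length(y))
            else as.character(treat_groups)
  stopifnot(length(groups) == length(y))
  group_levels <- c("entire", setdiff(unique(groups), "entire"))
  cluster_levels <- c(seq_len(k), 0L)  # 0 = whole cohort ("All")
  rows <- list()
  for (cl in cluster_levels) {
    in_cl <- if (cl == 0L) rep(TRUE, length(y)) else labels == cl
    cl_name <- if (cl == 0L) "All" else cluster_names[cl]
    for (g in group_levels) {
      in_g <- if (g == "entire") rep(TRUE, length(y)) else groups == g
      idx <- in_cl & in_g
      n <- sum(idx)
      if (n == 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          cluster = cl_name, group = g, n = 0L, deaths = 0L,
          rate_pct = NA_real_, ci_low_pct = NA_real_,
          ci_high_pct = NA_real_, non_significant = NA,
          display = "no data")
        next
      }
      deaths <- sum(y[idx])
      ci <- clopper_pearson_interval(deaths, n, conf)
      pop_idx <- in_g
      pop_rate <- mean(y[pop_idx])
      nonsig <- if (cl == 0L) {
        NA
      } else if (flag == "ci") {
        ci$lower <= pop_rate && pop_rate <= ci$upper
      } else {
        other <- pop_idx & !in_cl
        if (!sum(other)) NA else {
          tab <- matrix(c(deaths, n - deaths,
                          sum(y[other]), sum(other) - sum(y[other])),
                        nrow = 2, byrow = TRUE)
          stats::fisher.test(tab)$p.value >= (1 - conf)
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = cl_name, group = g, n = n, deaths = deaths,
        rate_pct = 100 * deaths / n,
        ci_low_pct = 100 * ci$lower, ci_high_pct = 100 * ci$upper,
        non_significant = nonsig,
        display = sprintf("%.1f (%.1f-%.1f)", 100 * deaths / n,
                          100 * ci$lower, 100 * ci$upper))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
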