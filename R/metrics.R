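#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) estimator of the area under the receiver
#' operating characteristic curve. Tied scores receive their midrank, so the
#' result equals the probability that a randomly chosen event outranks a
#' randomly chosen non-event, counting ties as 1/2.
#'
#' @param y Binary outcome vector (0/1, or logical).
#' @param scores Numeric risk scores, higher meaning more likely an event.
#' @return A single number in \[0, 1\].
#' @examples
#' auroc(c(0, 1, 1, 0), c(0.1, 0.9, 0.4, 0.5))
#' @export
auroc <- function(y, scores) {
  y <- check_binary_outcome(y)
  stopifnot(length(y) == length(scores), !anyNA(scores))
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop("auroc() needs both outcome classes present", call. = FALSE)
  }
  r <- rank(scores)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Step-function integral of precision over recall, evaluated at every
#' distinct score threshold (average-precision form). Tied scores enter the
#' curve as one block.
#'
#' @inheritParams auroc
#' @return A single number in \[0, 1\].
#' @export
auprc <- function(y, scores) {
  y <- check_binary_outcome(y)
  stopifnot(length(y) == length(scores), !anyNA(scores))
  n1 <- sum(y == 1L)
  if (n1 == 0L || n1 == length(y)) {
    stop("auprc() needs both outcome classes present", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]
  ss <- scores[ord]
  # collapse tied thresholds: cumulative counts at each distinct score
  last <- cumsum(rle(ss)$lengths)
  tp <- cumsum(ys)[last]
  fp <- cumsum(1 - ys)[last]
  prec <- tp / (tp + fp)
  rec <- tp / n1
  sum(diff(c(0, rec)) * prec)
}

#' Brier score decomposition
#'
#' Splits the mean squared error of probability forecasts into uncertainty,
#' resolution, and reliability using equal-width probability bins:
#' uncertainty is the outcome variance \eqn{\bar y (1 - \bar y)}, resolution
#' is the bin-weighted variance of observed event rates around the base
#' rate, and reliability is the bin-weighted squared gap between mean
#' forecast and observed event rate within each bin. When each forecast is
#' replaced by its bin mean the identity
#' \code{reliability - resolution + uncertainty == brier} holds exactly;
#' for raw forecasts it holds up to a within-bin variance term of order
#' (bin width)^2.
#'
#' @param y Binary outcome vector.
#' @param p Forecast probabilities in \[0, 1\].
#' @param n_bins Number of equal-width bins on \[0, 1\] (default 10).
#' @return An object of class \code{"brier_decomposition"}: a list with
#'   \code{uncertainty}, \code{resolution}, \code{reliability},
#'   \code{brier} (mean squared error of the raw forecasts),
#'   \code{brier_binned} (mean squared error after replacing forecasts by
#'   their bin means), \code{n_bins}, and the per-bin table \code{bins}.
#' @export
brier_decomposition <- function(y, p, n_bins = 10) {
  y <- check_binary_outcome(y)
  stopifnot(length(y) == length(p), !anyNA(p))
  if (length(y) == 0L) stop("empty input", call. = FALSE)
  if (any(p < 0 | p > 1)) stop("forecasts must lie in [0, 1]", call. = FALSE)
  n_bins <- as.integer(n_bins)
  stopifnot(n_bins >= 1L)
  bin <- pmin(pmax(floor(p * n_bins), 0L), n_bins - 1L) + 1L
  n <- length(y)
  ybar <- mean(y)
  nb <- tabulate(bin, nbins = n_bins)
  occupied <- nb > 0L
  yb <- vapply(which(occupied), function(b) mean(y[bin == b]), numeric(1))
  pb <- vapply(which(occupied), function(b) mean(p[bin == b]), numeric(1))
  w <- nb[occupied] / n
  uncertainty <- ybar * (1 - ybar)
  resolution <- sum(w * (yb - ybar)^2)
  reliability <- sum(w * (pb - yb)^2)
  bins <- data.frame(
    bin = which(occupied),
    lower = (which(occupied) - 1) / n_bins,
    upper = which(occupied) / n_bins,
    n = nb[occupied],
    mean_forecast = pb,
    event_rate = yb
  )
  structure(
    list(
      uncertainty = uncertainty,
      resolution = resolution,
      reliability = reliability,
      brier = mean((p - y)^2),
      brier_binned = mean((pb[match(bin, bins$bin)] - y)^2),
      n_bins = n_bins,
      bins = bins
    ),
    class = "brier_decomposition"
  )
}

#' @export
print.brier_decomposition <- function(x, ...) {
  cat("Brier decomposition (", x$n_bins, " equal-width bins)\n", sep = "")
  cat(sprintf("  uncertainty: %.6f\n", x$uncertainty))
  cat(sprintf("  resolution:  %.6f\n", x$resolution))
  cat(sprintf("  reliability: %.6f\n", x$reliability))
  cat(sprintf("  Brier score: %.6f\n", x$brier))
  invisible(x)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items,
#' computed from the contingency table under the permutation model. Equals
#' 1 for identical partitions (up to relabeling) and is close to 0 for
#' independent partitions.
#'
#' @param labels_a,labels_b Label vectors of equal length (any atomic type).
#' @return A single number, at most 1.
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    stop("partitions must label the same items", call. = FALSE)
  }
  if (length(labels_a) < 2L) stop("need at least 2 items", call. = FALSE)
  tab <- table(labels_a, labels_b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_i <- sum(choose(rowSums(tab), 2))
  sum_j <- sum(choose(colSums(tab), 2))
  expected <- sum_i * sum_j / choose(n, 2)
  max_index <- (sum_i + sum_j) / 2
  if (max_index == expected) {
    # both partitions singular (or both all-singletons): define as 0
    return(0)
  }
  (sum_ij - expected) / (max_index - expected)
}

#' Mean pairwise adjusted Rand index across partitions
#'
#' Averages the adjusted Rand index over all unordered pairs of partitions.
#' Any pair in which either partition is singular (assigns every item to a
#' single cluster) contributes 0, so a degenerate run cannot inflate the
#' apparent stability.
#'
#' @param partitions A list of two or more label vectors over the same items.
#' @return A list with \code{mean} and a data.frame \code{pairs}
#'   (\code{i}, \code{j}, \code{ari}, \code{singular}).
#' @export
mean_pairwise_ari <- function(partitions) {
  stopifnot(is.list(partitions))
  m <- length(partitions)
  if (m < 2L) stop("need at least 2 partitions", call. = FALSE)
  len <- lengths(partitions)
  if (length(unique(len)) != 1L) {
    stop("all partitions must cover the same items", call. = FALSE)
  }
  is_singular <- vapply(
    partitions,
    function(p) length(unique(p)) == 1L,
    logical(1)
  )
  idx <- utils::combn(m, 2)
  ari <- numeric(ncol(idx))
  singular <- logical(ncol(idx))
  for (c in seq_len(ncol(idx))) {
    i <- idx[1, c]
    j <- idx[2, c]
    if (is_singular[i] || is_singular[j]) {
      ari[c] <- 0
      singular[c] <- TRUE
    } else {
      ari[c] <- adjusted_rand_index(partitions[[i]], partitions[[j]])
    }
  }
  list(
    mean = mean(ari),
    pairs = data.frame(i = idx[1, ], j = idx[2, ], ari = ari,
                       singular = singular)
  )
}

#' Exact Clopper-Pearson binomial confidence interval
#'
#' Exact two-sided confidence interval for a binomial proportion, obtained
#' by inverting the binomial tail probabilities (equivalently, from the
#' quantiles of the corresponding Beta distributions). The lower bound is 0
#' when no events are observed and the upper bound is 1 when every trial is
#' an event.
#'
#' @param k Number of events (successes); vectorised.
#' @param n Number of trials; vectorised (recycled against \code{k}).
#' @param conf Confidence level (default 0.95).
#' @return A data.frame with columns \code{k}, \code{n}, \code{estimate},
#'   \code{lower}, \code{upper} (all proportions).
#' @examples
#' clopper_pearson_interval(8, 75)
#' clopper_pearson_interval(0, 1) # upper bound 0.975
#' @export
clopper_pearson_interval <- function(k, n, conf = 0.95) {
  stopifnot(length(conf) == 1L, conf > 0, conf < 1)
  res <- data.frame(k = as.numeric(k), n = as.numeric(n))
  if (any(res$n < 1)) stop("n must be at least 1", call. = FALSE)
  if (any(res$k < 0 | res$k > res$n)) {
    stop("k must satisfy 0 <= k <= n", call. = FALSE)
  }
  alpha <- 1 - conf
  res$estimate <- res$k / res$n
  res$lower <- ifelse(
    res$k == 0, 0,
    stats::qbeta(alpha / 2, res$k, res$n - res$k + 1)
  )
  res$upper <- ifelse(
    res$k == res$n, 1,
    stats::qbeta(1 - alpha / 2, res$k + 1, res$n - res$k)
  )
  res
}

# internal: coerce/validate a binary outcome vector
check_binary_outcome <- function(y) {
  if (is.logical(y)) y <- as.integer(y)
  if (anyNA(y) || !all(y %in% c(0, 1))) {
    stop("outcome must be binary (0/1) with no missing values",
         call. = FALSE)
  }
  as.integer(y)
}
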