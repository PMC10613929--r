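#' Project gate vectors onto the top-3 expert simplex
#'
#' For models with more than three experts, keeps the gate mass on the
#' three globally heaviest experts (labelled A, B, C by
#' [order_experts_by_weight()]), renormalises it to the 2-simplex for
#' ternary plotting, and records the truncated mass per patient. With
#' exactly three experts the embedding is the (reordered) gate vector
#' itself. Patients with zero mass on all three selected experts cannot
#' be placed and are returned in an exclusion list instead of being
#' guessed.
#'
#' @param gates n x K gate matrix (K >= 3).
#' @param expert_order Optional result of [order_experts_by_weight()];
#'   computed from \code{gates} when missing.
#' @param renormalize If \code{TRUE} (default) the kept mass is rescaled
#'   to sum to 1; if \code{FALSE} the raw truncated coordinates are
#'   returned (they then sum to 1 minus the truncated mass).
#' @return An object of class \code{"moe_ternary"}: a list with
#'   \code{coords} (n x 3, columns A/B/C), \code{selected} (original
#'   indices of the three plotted experts, heaviest first),
#'   \code{truncated_mass} (length n), \code{excluded} (row indices with
#'   undefined coordinates), and \code{expert_order}.
#' @export
ternary_project <- function(gates, expert_order = NULL,
                            renormalize = TRUE) {
  gates <- as.matrix(gates)
  if (ncol(gates) < 3L) {
    stop("ternary projection needs at least 3 experts", call. = FALSE)
  }
  if (is.null(expert_order)) expert_order <- order_experts_by_weight(gates)
  top3 <- expert_order$order[1:3]
  kept <- gates[, top3, drop = FALSE]
  colnames(kept) <- c("A", "B", "C")
  total <- rowSums(kept)
  truncated <- 1 - total
  excluded <- which(total <= 0)
  coords <- kept
  if (renormalize) {
    ok <- total > 0
    coords[ok, ] <- kept[ok, , drop = FALSE] / total[ok]
    coords[!ok, ] <- NA_real_
  }
  structure(
    list(coords = coords, selected = top3,
         truncated_mass = truncated, excluded = excluded,
         expert_order = expert_order, renormalized = renormalize),
    class = "moe_ternary"
  )
}

#' @export
print.moe_ternary <- function(x, ...) {
  cat("Ternary embedding of ", nrow(x$coords), " patients; experts ",
      paste(x$selected, collapse = ", "), " shown as A/B/C; mean ",
      "truncated mass ", sprintf("%.4f", mean(x$truncated_mass)), "\n",
      sep = "")
  if (length(x$excluded)) {
    cat("  ", length(x$excluded), " patients excluded (no mass on ",
        "plotted experts)\n", sep = "")
  }
  invisible(x)
}

#' Confusion classes at a probability threshold
#'
#' Labels each patient TP/FP/TN/FN given predicted risks and a threshold;
#' a prediction equal to the threshold counts as predicted-positive.
#'
#' @param y Binary outcomes.
#' @param risk Predicted probabilities.
#' @param threshold Decision threshold (default 0.5).
#' @return Factor with levels \code{TP}, \code{FP}, \code{TN}, \code{FN}.
#' @export
classify_threshold <- function(y, risk, threshold = 0.5) {
  y <- check_binary_outcome(y)
  stopifnot(length(y) == length(risk), all(risk >= 0 & risk <= 1))
  pred <- risk >= threshold
  out <- ifelse(pred & y == 1L, "TP",
         ifelse(pred & y == 0L, "FP",
         ifelse(!pred & y == 0L, "TN", "FN")))
  factor(out, levels = c("TP", "FP", "TN", "FN"))
}

# enumeration of the r^2 triangular cells of the uniform barycentric
# subdivision: upward cells (i, j, k >= 0, i+j+k = r-1) and downward
# cells (i+j+k = r-2), in a fixed deterministic order
ternary_cells_table <- function(r) {
  rows <- list()
  for (i in 0:(r - 1L)) {
    for (j in 0:(r - 1L - i)) {
      rows[[length(rows) + 1L]] <- data.frame(i = i, j = j, up = TRUE)
      if (j <= r - 2L - i) {
        rows[[length(rows) + 1L]] <- data.frame(i = i, j = j, up = FALSE)
      }
    }
  }
  tab <- do.call(rbind, rows)
  tab$id <- seq_len(nrow(tab))
  tab
}

# map barycentric coordinates to a triangular cell id; half-open
# boundaries with the upper corner closed, so every point on the simplex
# has exactly one cell
ternary_cell <- function(coords, resolution) {
  a <- coords[, 1]; b <- coords[, 2]; c <- coords[, 3]
  r <- resolution
  i <- pmin(floor(a * r), r - 1L)
  j <- pmin(floor(b * r), r - 1L)
  k <- pmin(floor(c * r), r - 1L)
  # floor rounding can overshoot the sub-triangle sum by one near edges;
  # clamp k so (i, j, k) indexes a valid cell
  k <- pmin(k, r - 1L - i - j)
  k <- pmax(k, r - 2L - i - j)
  up <- (i + j + k) == (r - 1L)
  tab <- ternary_cells_table(r)
  key <- paste(i, j, up)
  cell <- tab$id[match(key, paste(tab$i, tab$j, tab$up))]
  cell[is.na(a)] <- NA_integer_
  cell
}

#' Local metric heatmap over the ternary latent space
#'
#' Partitions the 2-simplex into \code{resolution^2} triangular cells by
#' uniform barycentric subdivision and computes, for every cell holding
#' at least \code{min_per_cell} patients of both outcome classes, the
#' chosen metric over that cell's patients. Cells that cannot be scored
#' are assigned the metric's fill value: 0.5 for AUROC (chance level) and
#' 0 for AUPRC.
#'
#' @param embedding A \code{moe_ternary} from [ternary_project()].
#' @param y Binary outcomes aligned to the embedding.
#' @param risk Predicted probabilities aligned to the embedding.
#' @param metric \code{"auroc"} or \code{"auprc"}.
#' @param resolution Cells per triangle edge (default 10).
#' @param min_per_cell Minimum patients per scorable cell (default 10).
#' @return An object of class \code{"moe_metric_grid"}: a data.frame with
#'   one row per cell (\code{cell}, \code{n}, \code{scored},
#'   \code{value}) and attributes \code{metric}, \code{resolution},
#'   \code{fill}.
#' @export
local_metric_grid <- function(embedding, y, risk,
                              metric = c("auroc", "auprc"),
                              resolution = 10L, min_per_cell = 10L) {
  stopifnot(inherits(embedding, "moe_ternary"))
  metric <- match.arg(metric)
  resolution <- as.integer(resolution)
  if (resolution < 1L) stop("resolution must be at least 1", call. = FALSE)
  y <- check_binary_outcome(y)
  stopifnot(length(y) == nrow(embedding$coords),
            length(risk) == length(y))
  fill <- if (metric == "auroc") 0.5 else 0
  fn <- if (metric == "auroc") auroc else auprc
  cells <- ternary_cell(embedding$coords, resolution)
  n_cells <- resolution^2
  out <- data.frame(cell = seq_len(n_cells),
                    n = tabulate(cells[!is.na(cells)], nbins = n_cells),
                    scored = FALSE, value = fill)
  for (cell_id in unique(cells[!is.na(cells)])) {
    idx <- which(cells == cell_id)
    if (length(idx) >= min_per_cell &&
        length(unique(y[idx])) == 2L) {
      out$value[cell_id] <- fn(y[idx], risk[idx])
      out$scored[cell_id] <- TRUE
    }
  }
  attr(out, "metric") <- metric
  attr(out, "resolution") <- resolution
  attr(out, "fill") <- fill
  class(out) <- c("moe_metric_grid", class(out))
  out
}

# Cartesian coordinates of barycentric points for plotting: A bottom
# right, B top, C bottom left
ternary_xy <- function(coords) {
  a <- coords[, 1]; b <- coords[, 2]; c <- coords[, 3]
  data.frame(x = a + b / 2, y = b * sqrt(3) / 2)
}

#' Ternary scatter of the latent space
#'
#' Plots patients inside the simplex triangle (expert A bottom right,
#' B top, C bottom left), optionally coloured by their confusion class at
#' a 50\% threshold.
#'
#' @param embedding A \code{moe_ternary}.
#' @param colour Optional per-patient grouping (e.g. the result of
#'   [classify_threshold()]).
#' @param alpha Point transparency.
#' @return A \code{ggplot} object.
#' @export
plot_ternary <- function(embedding, colour = NULL, alpha = 0.4) {
  stopifnot(inherits(embedding, "moe_ternary"))
  ok <- stats::complete.cases(embedding$coords)
  xy <- ternary_xy(embedding$coords[ok, , drop = FALSE])
  if (!is.null(colour)) xy$colour <- colour[ok]
  tri <- data.frame(x = c(0, 1, 0.5, 0), y = c(0, 0, sqrt(3) / 2, 0))
  p <- ggplot2::ggplot() +
    ggplot2::geom_path(data = tri, ggplot2::aes(x = x, y = y)) +
    ggplot2::annotate("text", x = c(1.03, 0.5, -0.03),
                      y = c(-0.03, sqrt(3) / 2 + 0.04, -0.03),
                      label = c("A", "B", "C")) +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
  if (is.null(colour)) {
    p + ggplot2::geom_point(data = xy,
                            ggplot2::aes(x = x, y = y),
                            alpha = alpha, size = 0.6)
  } else {
    p + ggplot2::geom_point(
      data = xy,
      ggplot2::aes(x = x, y = y, colour = colour),
      alpha = alpha, size = 0.6) +
      ggplot2::labs(colour = NULL)
  }
}

#' Heatmap of a local metric grid
#'
#' Draws the triangular cells of [local_metric_grid()] filled by the
#' local metric value.
#'
#' @param grid A \code{moe_metric_grid}.
#' @return A \code{ggplot} object.
#' @export
plot_local_metrics <- function(grid) {
  stopifnot(inherits(grid, "moe_metric_grid"))
  r <- attr(grid, "resolution")
  tab <- ternary_cells_table(r)
  polys <- list()
  for (row in seq_len(nrow(grid))) {
    cell <- grid$cell[row]
    i <- tab$i[cell]
    j <- tab$j[cell]
    up <- tab$up[cell]
    k <- (if (up) r - 1L else r - 2L) - i - j
    if (up) {
      corners <- rbind(c(i + 1, j, k), c(i, j + 1, k), c(i, j, k + 1)) / r
    } else {
      corners <- rbind(c(i + 1, j + 1, k), c(i, j + 1, k + 1),
                       c(i + 1, j, k + 1)) / r
    }
    xy <- ternary_xy(corners)
    polys[[length(polys) + 1L]] <- data.frame(
      id = cell, x = xy$x, y = xy$y, value = grid$value[row])
  }
  dat <- do.call(rbind, polys)
  ggplot2::ggplot(dat, ggplot2::aes(x = x, y = y, group = id, fill = value)) +
    ggplot2::geom_polygon(colour = "grey70", linewidth = 0.1) +
    ggplot2::scale_fill_viridis_c(name = toupper(attr(grid, "metric"))) +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}

#' Write the cell table of a metric grid as CSV
#'
#' @param grid A \code{moe_metric_grid}.
#' @param path CSV path.
#' @return \code{path}, invisibly.
#' @export
write_metric_grid <- function(grid, path) {
  out <- as.data.frame(grid)
  out$metric <- attr(grid, "metric")
  out$resolution <- attr(grid, "resolution")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
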