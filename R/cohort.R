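#' Construct a cohort table
#'
#' A cohort couples a numeric feature matrix (one row per patient, columns
#' as declared in the schema), a binary outcome vector, and optionally the
#' latent subgroup labels of a synthetic cohort. Missing feature values are
#' represented as \code{NA} and can be filled with [impute_missing()].
#'
#' @param features Data.frame or matrix of features; column names must
#'   cover the schema's feature names.
#' @param outcome Binary outcome vector (1 = in-hospital death).
#' @param schema A \code{moe_schema}.
#' @param latent Optional integer vector of planted subgroup labels
#'   (1-based; synthetic cohorts only).
#' @return An object of class \code{"moe_cohort"}.
#' @export
moe_cohort <- function(features, outcome, schema, latent = NULL) {
  stopifnot(inherits(schema, "moe_schema"))
  features <- as.data.frame(features)
  missing_cols <- setdiff(schema$features$name, names(features))
  if (length(missing_cols)) {
    stop("cohort is missing schema columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  features <- features[, schema$features$name, drop = FALSE]
  outcome <- check_binary_outcome(outcome)
  if (nrow(features) != length(outcome)) {
    stop("features and outcome disagree on the number of patients",
         call. = FALSE)
  }
  for (nm in schema_names(schema, kind = "binary")) {
    v <- features[[nm]]
    if (!all(v[!is.na(v)] %in% c(0, 1))) {
      stop("binary feature '", nm, "' has values outside {0, 1}",
           call. = FALSE)
    }
  }
  if (!is.null(latent)) {
    latent <- as.integer(latent)
    stopifnot(length(latent) == length(outcome), all(latent >= 1L))
  }
  structure(
    list(features = features, outcome = outcome, schema = schema,
         latent = latent),
    class = "moe_cohort"
  )
}

#' @export
print.moe_cohort <- function(x, ...) {
  cat("MoE cohort: ", nrow(x$features), " patients, ",
      nrow(x$schema$features), " features, outcome rate ",
      sprintf("%.3f", mean(x$outcome)), sep = "")
  if (!is.null(x$latent)) {
    cat(", ", length(unique(x$latent)), " latent subgroups", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Number of patients in a cohort
#' @param cohort A \code{moe_cohort}.
#' @return Integer row count.
#' @export
cohort_size <- function(cohort) {
  stopifnot(inherits(cohort, "moe_cohort"))
  nrow(cohort$features)
}

#' Subset a cohort by row indices
#' @param cohort A \code{moe_cohort}.
#' @param idx Integer or logical row index.
#' @return A \code{moe_cohort} with the selected patients.
#' @export
cohort_subset <- function(cohort, idx) {
  stopifnot(inherits(cohort, "moe_cohort"))
  moe_cohort(cohort$features[idx, , drop = FALSE],
             cohort$outcome[idx], cohort$schema,
             latent = if (!is.null(cohort$latent)) cohort$latent[idx])
}

#' Impute missing feature values
#'
#' Missing binary indicators are set to 0 ("no"); missing continuous
#' values are set to the column mean. Means default to those of the given
#' table and are returned so that statistics learned on a training split
#' can be reapplied to validation and test splits.
#'
#' @param cohort A \code{moe_cohort} (may contain \code{NA}s).
#' @param means Optional named numeric vector of stored continuous-column
#'   means from a previous call (training data).
#' @return A list with \code{cohort} (no missing values) and \code{means}.
#' @export
impute_missing <- function(cohort, means = NULL) {
  stopifnot(inherits(cohort, "moe_cohort"))
  feats <- cohort$features
  cont <- schema_names(cohort$schema, kind = "continuous")
  bin <- schema_names(cohort$schema, kind = "binary")
  if (is.null(means)) {
    means <- vapply(cont, function(nm) {
      v <- feats[[nm]]
      if (all(is.na(v))) {
        stop("continuous feature '", nm,
             "' is entirely missing and no stored mean is available",
             call. = FALSE)
      }
      mean(v, na.rm = TRUE)
    }, numeric(1))
  } else {
    stopifnot(all(cont %in% names(means)))
  }
  for (nm in bin) {
    v <- feats[[nm]]
    v[is.na(v)] <- 0
    feats[[nm]] <- v
  }
  for (nm in cont) {
    v <- feats[[nm]]
    v[is.na(v)] <- means[[nm]]
    feats[[nm]] <- v
  }
  list(
    cohort = moe_cohort(feats, cohort$outcome, cohort$schema,
                        latent = cohort$latent),
    means = means
  )
}

#' Inject missingness completely at random
#'
#' Blanks each feature cell independently with the given probability;
#' useful for exercising the imputation rules on synthetic data.
#'
#' @param cohort A \code{moe_cohort}.
#' @param rate Per-cell missingness probability in \[0, 1).
#' @param seed Integer seed.
#' @return A \code{moe_cohort} with \code{NA}s inserted.
#' @export
inject_missing <- function(cohort, rate, seed = 1L) {
  stopifnot(inherits(cohort, "moe_cohort"), rate >= 0, rate < 1)
  if (rate == 0) return(cohort)
  feats <- cohort$features
  set.seed(seed)
  for (nm in names(feats)) {
    hit <- stats::runif(nrow(feats)) < rate
    feats[[nm]][hit] <- NA
  }
  moe_cohort(feats, cohort$outcome, cohort$schema, latent = cohort$latent)
}

#' Write a cohort to CSV (plus schema sidecar)
#'
#' The CSV holds one row per patient with a header: feature columns in
#' schema order, the outcome column, and, for synthetic cohorts, a final
#' \code{latent_subgroup} column that is marked as a non-feature by its
#' absence from the schema sidecar. Missing values are written as empty
#' fields.
#'
#' @param cohort A \code{moe_cohort}.
#' @param path CSV file path.
#' @param schema_path Optional sidecar path; defaults to
#'   \code{paste0(path, ".schema.tsv")}.
#' @return \code{path}, invisibly.
#' @export
write_cohort <- function(cohort, path, schema_path = NULL) {
  stopifnot(inherits(cohort, "moe_cohort"))
  if (is.null(schema_path)) schema_path <- paste0(path, ".schema.tsv")
  tab <- cohort$features
  tab[[cohort$schema$outcome]] <- cohort$outcome
  if (!is.null(cohort$latent)) tab$latent_subgroup <- cohort$latent
  utils::write.csv(tab, path, row.names = FALSE, na = "")
  write_schema(cohort$schema, schema_path)
  invisible(path)
}

#' Read a cohort from CSV (plus schema sidecar)
#'
#' @param path CSV file path written by [write_cohort()] (or any CSV whose
#'   header matches the schema).
#' @param schema_path Sidecar path; defaults to
#'   \code{paste0(path, ".schema.tsv")}.
#' @return A \code{moe_cohort}; empty CSV fields become \code{NA}.
#' @export
read_cohort <- function(path, schema_path = NULL) {
  if (is.null(schema_path)) schema_path <- paste0(path, ".schema.tsv")
  schema <- read_schema(schema_path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(c(schema$features$name, schema$outcome),
                          names(tab))
  if (length(missing_cols)) {
    stop("cohort file is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  outcome <- tab[[schema$outcome]]
  if (anyNA(outcome) || !all(outcome %in% c(0, 1))) {
    stop("outcome column '", schema$outcome, "' must be binary",
         call. = FALSE)
  }
  latent <- if ("latent_subgroup" %in% names(tab)) tab$latent_subgroup
  moe_cohort(tab[, schema$features$name, drop = FALSE], outcome, schema,
             latent = latent)
}
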