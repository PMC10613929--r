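#' Cohort schema
#'
#' A schema declares, for every feature column of a cohort table, its kind
#' (\code{"binary"} or \code{"continuous"}) and its tier
#' (\code{"presentation"} for pre-treatment data used by the selector
#' network, \code{"treatment"} for treatment-time data seen only by the
#' experts), plus the name of the binary outcome column.
#'
#' @param features A data.frame with columns \code{name}, \code{kind},
#'   \code{tier}.
#' @param outcome Name of the binary outcome column (not itself a feature).
#' @return An object of class \code{"moe_schema"}.
#' @export
cohort_schema <- function(features, outcome) {
  stopifnot(is.data.frame(features),
            all(c("name", "kind", "tier") %in% names(features)))
  features <- data.frame(
    name = as.character(features$name),
    kind = as.character(features$kind),
    tier = as.character(features$tier),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(features$name)) {
    stop("feature names must be unique", call. = FALSE)
  }
  bad_kind <- setdiff(unique(features$kind), c("binary", "continuous"))
  if (length(bad_kind)) {
    stop("unknown feature kind: ", paste(bad_kind, collapse = ", "),
         call. = FALSE)
  }
  bad_tier <- setdiff(unique(features$tier), c("presentation", "treatment"))
  if (length(bad_tier)) {
    stop("unknown feature tier: ", paste(bad_tier, collapse = ", "),
         call. = FALSE)
  }
  stopifnot(is.character(outcome), length(outcome) == 1L)
  if (outcome %in% features$name) {
    stop("the outcome column cannot also be a feature", call. = FALSE)
  }
  structure(list(features = features, outcome = outcome),
            class = "moe_schema")
}

#' @export
print.moe_schema <- function(x, ...) {
  np <- sum(x$features$tier == "presentation")
  nt <- sum(x$features$tier == "treatment")
  cat("Cohort schema: ", np, " presentation + ", nt,
      " treatment features; outcome '", x$outcome, "'\n", sep = "")
  invisible(x)
}

# internal helpers to pull feature names by tier / kind
schema_names <- function(schema, tier = NULL, kind = NULL) {
  f <- schema$features
  keep <- rep(TRUE, nrow(f))
  if (!is.null(tier)) keep <- keep & f$tier == tier
  if (!is.null(kind)) keep <- keep & f$kind == kind
  f$name[keep]
}

#' Write a schema sidecar file
#'
#' The sidecar is a tab-separated text file with columns \code{name},
#' \code{kind}, \code{tier}, \code{outcome}; the outcome row carries
#' \code{outcome = TRUE} and empty kind/tier are not allowed for features.
#'
#' @param schema A \code{moe_schema}.
#' @param path File path to write.
#' @return \code{path}, invisibly.
#' @export
write_schema <- function(schema, path) {
  stopifnot(inherits(schema, "moe_schema"))
  out <- rbind(
    data.frame(name = schema$features$name, kind = schema$features$kind,
               tier = schema$features$tier, outcome = FALSE),
    data.frame(name = schema$outcome, kind = "binary", tier = "outcome",
               outcome = TRUE)
  )
  utils::write.table(out, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a schema sidecar file
#'
#' @param path File path written by [write_schema()].
#' @return A \code{moe_schema}.
#' @export
read_schema <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("name", "kind", "tier", "outcome")
  if (!all(need %in% names(tab))) {
    stop("schema file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  is_outcome <- as.logical(tab$outcome)
  if (sum(is_outcome) != 1L) {
    stop("schema must declare exactly one outcome column", call. = FALSE)
  }
  cohort_schema(tab[!is_outcome, c("name", "kind", "tier")],
                outcome = tab$name[is_outcome])
}

#' Schema of the bundled synthetic AMI-CS-like cohort
#'
#' Twelve presentation features (demographics, arrest history, initial
#' vitals and labs, infarct anatomy) and fifteen treatment features
#' (procedural course, complications, and mechanical-circulatory-support
#' device indicators), mirroring the two-tier feature split used for
#' phenotyping acute myocardial infarction complicated by cardiogenic
#' shock. The outcome is in-hospital death.
#'
#' @return A \code{moe_schema}.
#' @export
amics_schema <- function() {
  pres <- data.frame(
    name = c("age", "sex_male", "arrest_first_contact",
             "arrest_prehospital", "arrest_outside_facility",
             "sbp_first_contact", "stemi", "left_main_stenosis",
             "prox_lad_stenosis", "multivessel_disease",
             "creatinine_initial", "troponin_initial"),
    kind = c("continuous", "binary", "binary", "binary", "binary",
             "continuous", "binary", "binary", "binary", "binary",
             "continuous", "continuous"),
    tier = "presentation"
  )
  treat <- data.frame(
    name = c("mcs_need", "troponin_peak", "dialysis_required", "dialysis",
             "afib", "vt_vf", "lvef", "cva", "length_of_stay",
             "vascular_complication", "mcs_none", "mcs_ecmo", "mcs_iabp",
             "mcs_lvad", "mcs_other"),
    kind = c("binary", "continuous", "binary", "binary", "binary",
             "binary", "continuous", "binary", "continuous", "binary",
             "binary", "binary", "binary", "binary", "binary"),
    tier = "treatment"
  )
  cohort_schema(rbind(pres, treat), outcome = "died_in_hospital")
}
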