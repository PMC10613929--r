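#' Specification of a synthetic two-tier cohort
#'
#' Describes a mixture of latent patient subgroups: mixing proportions,
#' per-group presentation-feature distributions (normal for continuous
#' features on a standardised scale, Bernoulli for binary indicators),
#' a per-group treatment-assignment model mapping presentation features
#' to treatment-feature means/log-odds (confounding by indication), and a
#' per-group logistic outcome model over all features.
#'
#' @param schema A \code{moe_schema}.
#' @param mixing Subgroup mixing proportions (sum to 1).
#' @param pres_mean K x (number of continuous presentation features)
#'   matrix of per-group means, columns named.
#' @param pres_prev K x (number of binary presentation features) matrix
#'   of per-group prevalences in \[0, 1\], columns named.
#' @param treat_model List of K lists, each with \code{intercept} (named
#'   vector over treatment features) and \code{coef} (treatment x
#'   presentation coefficient matrix).
#' @param outcome_model List of K lists, each with \code{intercept}
#'   (scalar) and \code{coef} (named vector over all schema features).
#' @param noise_sd Standard deviation of continuous-feature noise.
#' @param expected_prevalence The overall outcome rate the specification
#'   was calibrated to (documentation field; checked by tests via
#'   simulation).
#' @return An object of class \code{"moe_synth_spec"}.
#' @export
synthetic_spec <- function(schema, mixing, pres_mean, pres_prev,
                           treat_model, outcome_model, noise_sd = 1,
                           expected_prevalence = NA_real_) {
  stopifnot(inherits(schema, "moe_schema"))
  k <- length(mixing)
  stopifnot(k >= 1L)
  if (abs(sum(mixing) - 1) > 1e-9) {
    stop("mixing proportions must sum to 1", call. = FALSE)
  }
  if (any(mixing < 0)) stop("mixing proportions must be nonnegative",
                            call. = FALSE)
  cont_p <- schema_names(schema, tier = "presentation",
                         kind = "continuous")
  bin_p <- schema_names(schema, tier = "presentation", kind = "binary")
  treat <- schema_names(schema, tier = "treatment")
  all_feats <- schema$features$name
  pres_mean <- as.matrix(pres_mean)
  pres_prev <- as.matrix(pres_prev)
  stopifnot(nrow(pres_mean) == k, nrow(pres_prev) == k,
            identical(colnames(pres_mean), cont_p),
            identical(colnames(pres_prev), bin_p),
            length(treat_model) == k, length(outcome_model) == k,
            noise_sd >= 0)
  if (any(pres_prev < 0 | pres_prev > 1)) {
    stop("presentation prevalences must lie in [0, 1]", call. = FALSE)
  }
  for (g in seq_len(k)) {
    tm <- treat_model[[g]]
    stopifnot(identical(names(tm$intercept), treat),
              identical(rownames(tm$coef), treat),
              identical(colnames(tm$coef),
                        schema_names(schema, tier = "presentation")))
    om <- outcome_model[[g]]
    if (!identical(names(om$coef), all_feats)) {
      stop("outcome coefficients of group ", g,
           " must cover every schema feature", call. = FALSE)
    }
  }
  structure(
    list(schema = schema, k_true = k, mixing = as.numeric(mixing),
         pres_mean = pres_mean, pres_prev = pres_prev,
         treat_model = treat_model, outcome_model = outcome_model,
         noise_sd = noise_sd,
         expected_prevalence = expected_prevalence),
    class = "moe_synth_spec"
  )
}

#' @export
print.moe_synth_spec <- function(x, ...) {
  cat("Synthetic cohort spec: ", x$k_true, " subgroups, mixing (",
      paste(sprintf("%.2f", x$mixing), collapse = ", "),
      "), calibrated outcome rate ~",
      sprintf("%.2f", x$expected_prevalence), "\n", sep = "")
  invisible(x)
}

#' Default synthetic AMI-CS-like cohort specification
#'
#' Three latent subgroups over the [amics_schema()] features, emulating a
#' cardiogenic-shock cohort in which phenotypes differ both in risk level
#' and in which factors drive that risk:
#'
#' * Group 1: older, hypotensive patients with renal strain and the
#'   highest mortality (~33\%).
#' * Group 2: younger patients with large infarcts, frequent arrest
#'   history, and intermediate mortality (~24\%).
#' * Group 3: less acute presentations with the lowest mortality
#'   (~16\%).
#'
#' Subgroups mix in equal proportions and are well separated in
#' presentation space (a nonlinear group-posterior classifier exceeds
#' 98\% accuracy), while the outcome models are deliberately
#' heterogeneous: within each subgroup the risk is flat in the
#' presentation features, but the treatment-tier coefficients for the
#' mechanical-support devices and post-treatment labs flip sign between
#' subgroups in a pairwise pattern (each such feature separates a
#' different pair of groups, with mixture-weighted means near zero).
#' A pooled linear model therefore averages real effects away, while a
#' model that routes patients to subgroup-specific experts recovers
#' them; because every pairwise merge of subgroups loses a distinct part
#' of the signal, the routing must be three-way. Treatment intensity
#' differs by subgroup (practice-style intercepts) but is independent of
#' presentation within a subgroup. Continuous features are generated on
#' a standardised (z-score-like) scale; marginal realism is out of
#' scope.
#'
#' The overall outcome prevalence is calibrated near 0.25.
#'
#' @return A \code{moe_synth_spec} with \code{k_true = 3}.
#' @export
default_amics_spec <- function() {
  schema <- amics_schema()
  cont_p <- schema_names(schema, tier = "presentation",
                         kind = "continuous")
  bin_p <- schema_names(schema, tier = "presentation", kind = "binary")
  pres <- schema_names(schema, tier = "presentation")
  treat <- schema_names(schema, tier = "treatment")
  k <- 3L
  mixing <- c(1, 1, 1) / 3

  pres_mean <- rbind(
    c( 1.8, -1.5,  1.3,  0.8),   # older, hypotensive, renal strain
    c(-1.5,  0.8, -0.7,  1.6),   # younger, large infarct
    c(-0.7,  1.6, -0.5, -1.6))   # less acute
  colnames(pres_mean) <- cont_p
  pres_prev <- rbind(
    c(0.50, 0.35, 0.30, 0.15, 0.90, 0.25, 0.45, 0.70),
    c(0.95, 0.65, 0.55, 0.35, 0.80, 0.50, 0.75, 0.70),
    c(0.80, 0.03, 0.05, 0.02, 0.40, 0.05, 0.20, 0.15))
  colnames(pres_prev) <- bin_p

  # treatment assignment varies by subgroup through the intercepts below
  # (practice-style differences); within a subgroup it is independent of
  # presentation, so subgroup identity is the only link between the tiers
  coef0 <- matrix(0, length(treat), length(pres),
                  dimnames = list(treat, pres))
  ic0 <- c(mcs_need = -0.3, troponin_peak = 0.3,
           dialysis_required = -1.6, dialysis = -1.8, afib = -1.0,
           vt_vf = -0.7, lvef = -0.4, cva = -2.5, length_of_stay = 0.2,
           vascular_complication = -1.8, mcs_none = 0.3,
           mcs_ecmo = -3.0, mcs_iabp = -0.6, mcs_lvad = -1.6,
           mcs_other = -2.8)
  ic_shift <- list(
    c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0),
    c(0.5, 0.6, 0.2, 0.2, -0.3, 0.5, -0.6, 0, 0.2, 0.2,
      -0.8, 0.5, 0.9, 0.8, 0.3),
    c(-0.8, -0.8, -0.4, -0.4, 0.2, -0.6, 0.7, 0, -0.3, -0.2,
      0.8, -0.5, -0.9, -0.7, -0.3)
  )
  treat_model <- lapply(1:k, function(g) {
    ic <- ic0 + ic_shift[[g]]
    names(ic) <- treat
    list(intercept = ic, coef = coef0)
  })

  all_feats <- schema$features$name
  beta <- matrix(0, k, length(all_feats),
                 dimnames = list(NULL, all_feats))
  # shared treatment-course effects
  beta[, "dialysis"] <- 0.8
  beta[, "mcs_need"] <- 0.3
  beta[, "vt_vf"] <- 0.3
  beta[, "lvef"] <- -0.3
  beta[, "troponin_peak"] <- 0.2
  # No presentation-tier outcome coefficients: within a subgroup the
  # risk surface is flat in presentation, so subgroup identity (through
  # the intercepts below) is the only presentation-addressable signal.
  # Treatment-tier flips: each feature separates a different pair of
  # groups (mixture-weighted means ~ 0), so every merge of two subgroups
  # loses a distinct part of the signal and routing must be three-way.
  beta[, "mcs_iabp"]      <- c( 1.4, -1.4,  0.0)
  beta[, "troponin_peak"] <- beta[, "troponin_peak"] +
                             c( 0.0,  1.5, -1.5)
  beta[, "lvef"]          <- beta[, "lvef"] +
                             c(-1.0,  0.0,  1.0)
  beta[, "mcs_lvad"]      <- c( 1.1, -1.1,  0.0)
  # intercepts calibrated so the overall outcome rate sits near 0.25
  # with subgroup rates roughly 0.33 / 0.24 / 0.16, approximately
  # equidistant on the logit scale
  b0 <- c(-2.60, -2.95, -3.32)
  outcome_model <- lapply(1:k, function(g) {
    list(intercept = b0[g], coef = beta[g, ])
  })

  synthetic_spec(schema, mixing, pres_mean, pres_prev, treat_model,
                 outcome_model, noise_sd = 1,
                 expected_prevalence = 0.25)
}

#' Generate a synthetic cohort
#'
#' Draws, per patient: a subgroup from the mixing proportions;
#' presentation features from that subgroup's distributions; treatment
#' features from the subgroup's treatment model given the presentation
#' features (binary via logistic assignment, continuous with additive
#' noise); and the outcome from the subgroup's logistic outcome model.
#' Fully reproducible given the seed.
#'
#' @param spec A \code{moe_synth_spec}.
#' @param n Number of patients (>= 1).
#' @param seed Integer seed.
#' @return A \code{moe_cohort} with \code{latent} labels (1..K)
#'   populated; the exact per-patient event probability is stored in
#'   \code{attr(, "bayes_risk")}.
#' @export
generate_cohort <- function(spec, n, seed = 1L) {
  stopifnot(inherits(spec, "moe_synth_spec"))
  n <- as.integer(n)
  if (n < 1L) stop("n must be at least 1", call. = FALSE)
  set.seed(seed)
  schema <- spec$schema
  k <- spec$k_true
  z <- sample.int(k, n, replace = TRUE, prob = spec$mixing)
  feats <- matrix(0, n, nrow(schema$features),
                  dimnames = list(NULL, schema$features$name))
  for (nm in colnames(spec$pres_mean)) {
    feats[, nm] <- stats::rnorm(n, spec$pres_mean[z, nm], spec$noise_sd)
  }
  for (nm in colnames(spec$pres_prev)) {
    feats[, nm] <- stats::rbinom(n, 1L, spec$pres_prev[z, nm])
  }
  pres <- schema_names(schema, tier = "presentation")
  treat <- schema$features[schema$features$tier == "treatment", ]
  Xp <- feats[, pres, drop = FALSE]
  for (g in seq_len(k)) {
    idx <- which(z == g)
    if (!length(idx)) next
    tm <- spec$treat_model[[g]]
    lin <- Xp[idx, , drop = FALSE] %*% t(tm$coef)
    lin <- sweep(lin, 2, tm$intercept, "+")
    for (j in seq_len(nrow(treat))) {
      nm <- treat$name[j]
      if (treat$kind[j] == "binary") {
        feats[idx, nm] <- stats::rbinom(length(idx), 1L,
                                        stats::plogis(lin[, j]))
      } else {
        feats[idx, nm] <- lin[, j] +
          stats::rnorm(length(idx), 0, spec$noise_sd)
      }
    }
  }
  risk <- numeric(n)
  for (g in seq_len(k)) {
    idx <- which(z == g)
    if (!length(idx)) next
    om <- spec$outcome_model[[g]]
    risk[idx] <- stats::plogis(
      feats[idx, , drop = FALSE] %*% om$coef + om$intercept)
  }
  y <- stats::rbinom(n, 1L, risk)
  out <- moe_cohort(as.data.frame(feats), y, schema, latent = z)
  attr(out, "bayes_risk") <- risk
  out
}

#' Exact event probability under the generating model
#'
#' The oracle risk: the inverse-logit of the given subgroup's outcome
#' linear predictor at the given feature values. Ranking patients by this
#' quantity attains the maximum possible AUROC on data generated from the
#' specification, so it serves as the ceiling against which trained
#' models are judged.
#'
#' @param spec A \code{moe_synth_spec}.
#' @param presentation Named numeric vector (or 1-row data.frame) of
#'   presentation-feature values.
#' @param treatment Named numeric vector (or 1-row data.frame) of
#'   treatment-feature values.
#' @param group Subgroup index in 1..K.
#' @return Event probability in \[0, 1\].
#' @export
bayes_risk <- function(spec, presentation, treatment, group) {
  stopifnot(inherits(spec, "moe_synth_spec"))
  group <- as.integer(group)
  if (group < 1L || group > spec$k_true) {
    stop("group must lie in 1..", spec$k_true, call. = FALSE)
  }
  presentation <- unlist(presentation)
  treatment <- unlist(treatment)
  x <- c(presentation, treatment)[spec$schema$features$name]
  if (anyNA(x)) {
    stop("presentation/treatment values must cover every schema feature",
         call. = FALSE)
  }
  om <- spec$outcome_model[[group]]
  stats::plogis(sum(om$coef * x) + om$intercept)
}
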