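#' Mixture-of-experts configuration
#'
#' Bundles the architecture and training settings of the deep mixture of
#' experts. Three size presets are available: \code{"large"} uses three
#' fully connected layers of 50 units in both the selector and each
#' expert; \code{"mid"} uses two layers of 24 units in both; and
#' \code{"small"} keeps the mid-sized selector but reduces each expert to
#' a single prediction layer. The number of experts is capped at 10 so
#' that each expert keeps seeing a usable share of every batch (the
#' shrinking-batch problem) and the discovered phenotypes stay
#' interpretable.
#'
#' @param n_experts Number of experts K, between 2 and 10.
#' @param size_preset One of \code{"small"}, \code{"mid"}, \code{"large"}.
#' @param connection_variant How experts are wired to the selector:
#'   \code{"standard"} passes the selector's final hidden layer to each
#'   expert alongside the treatment features; \code{"later_hidden"} feeds
#'   experts the treatment features only and injects the selector's first
#'   hidden layer into each expert's final prediction layer;
#'   \code{"no_hidden"} gives experts the raw presentation plus treatment
#'   features with no learned pass-through.
#' @param initial_risk If \code{TRUE}, the selector also emits a
#'   pre-treatment risk estimate trained with an auxiliary cross-entropy
#'   term (weight \code{aux_weight}).
#' @param gating_l2 Nonnegative L2 penalty weight \eqn{\lambda} on the
#'   selector's gate output (see [gating_penalty()]).
#' @param penalty_on Penalise the post-softmax \code{"gates"} (default) or
#'   the pre-softmax \code{"scores"}.
#' @param aux_weight Weight of the auxiliary initial-risk loss term.
#' @param epochs Maximum training epochs.
#' @param batch_size Minibatch size.
#' @param learning_rate Adam step size for selector and expert weights.
#' @param gate_optimizer Update rule for the gating layer:
#'   \code{"adam"} (default, shared with the rest of the network) or
#'   \code{"sgd"} (plain momentum SGD; see Details).
#' @param gate_learning_rate Step size of the momentum-SGD gate update
#'   (used only when \code{gate_optimizer = "sgd"}).
#' @param adam_epsilon Denominator offset of the Adam update; values well
#'   above machine precision make near-zero-gradient parameters move
#'   proportionally to their gradient rather than at a normalised step
#'   size.
#' @param patience Early-stopping patience, in epochs without validation
#'   improvement.
#' @param seed Integer seed controlling initialisation and shuffling.
#'
#' @details
#' The default trains every layer with Adam, which gives the most
#' reliable convergence of the joint clustering-and-risk objective.
#' Adam's per-parameter step normalisation, however, also rescues
#' starved experts, which damps the classic pathologies of gating
#' mixtures: full collapse onto one expert when the gating penalty is
#' absent, and forced even utilisation when it is heavy. To study those
#' regimes in their sharpest form, set \code{gate_optimizer = "sgd"}
#' (non-adaptive gate updates) together with a larger
#' \code{adam_epsilon} (for example \code{5e-4}), which preserves
#' starvation dynamics at the price of occasionally trapping moderately
#' penalised runs in partially collapsed states.
#'
#' @return An object of class \code{"moe_config"}.
#' @export
moe_config <- function(n_experts = 3L,
                       size_preset = c("small", "mid", "large"),
                       connection_variant = c("standard", "later_hidden",
                                              "no_hidden"),
                       initial_risk = FALSE,
                       gating_l2 = 0.01,
                       penalty_on = c("gates", "scores"),
                       aux_weight = 0.1,
                       epochs = 400L,
                       batch_size = 128L,
                       learning_rate = 1e-3,
                       gate_optimizer = c("adam", "sgd"),
                       gate_learning_rate = 2,
                       adam_epsilon = 1e-8,
                       patience = 30L,
                       seed = 1L) {
  size_preset <- match.arg(size_preset)
  connection_variant <- match.arg(connection_variant)
  penalty_on <- match.arg(penalty_on)
  gate_optimizer <- match.arg(gate_optimizer)
  n_experts <- as.integer(n_experts)
  if (n_experts < 2L || n_experts > 10L) {
    stop("n_experts must be between 2 and 10", call. = FALSE)
  }
  if (gating_l2 < 0) stop("gating_l2 must be nonnegative", call. = FALSE)
  stopifnot(epochs >= 1, batch_size >= 1, learning_rate > 0,
            gate_learning_rate > 0, adam_epsilon > 0, patience >= 1)
  structure(
    list(n_experts = n_experts, size_preset = size_preset,
         connection_variant = connection_variant,
         initial_risk = isTRUE(initial_risk), gating_l2 = gating_l2,
         penalty_on = penalty_on, aux_weight = aux_weight,
         epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         learning_rate = learning_rate,
         gate_optimizer = gate_optimizer,
         gate_learning_rate = gate_learning_rate,
         adam_epsilon = adam_epsilon, patience = as.integer(patience),
         seed = as.integer(seed)),
    class = "moe_config"
  )
}

#' @export
print.moe_config <- function(x, ...) {
  cat(sprintf(
    "MoE config: K=%d, preset=%s, variant=%s, lambda=%g%s, seed=%d\n",
    x$n_experts, x$size_preset, x$connection_variant, x$gating_l2,
    if (x$initial_risk) ", with initial risk" else "", x$seed))
  invisible(x)
}

# hidden-layer widths of selector / experts per preset
preset_widths <- function(preset) {
  switch(preset,
    small = list(selector = c(24L, 24L), expert = integer(0)),
    mid = list(selector = c(24L, 24L), expert = c(24L, 24L)),
    large = list(selector = c(50L, 50L, 50L), expert = c(50L, 50L, 50L))
  )
}

# He-style layer initialisation; gain scales the weight standard deviation
init_layer <- function(d_in, d_out, gain = sqrt(2)) {
  list(W = matrix(stats::rnorm(d_in * d_out, 0, gain / sqrt(d_in)),
                  d_in, d_out),
       b = rep(0, d_out))
}

#' Build an untrained mixture-of-experts model
#'
#' Creates the selector network over the schema's presentation features,
#' the gating layer (zero-initialised, so training starts from exactly
#' uniform gates), and \code{n_experts} expert networks wired according to
#' the configured connection variant. All random initialisation is
#' governed by the configuration seed.
#'
#' @param config A [moe_config()].
#' @param schema A \code{moe_schema} with at least one presentation and
#'   one treatment feature.
#' @return An object of class \code{"moe_model"}.
#' @export
build_moe <- function(config, schema) {
  stopifnot(inherits(config, "moe_config"), inherits(schema, "moe_schema"))
  pres <- schema_names(schema, tier = "presentation")
  treat <- schema_names(schema, tier = "treatment")
  if (!length(pres) || !length(treat)) {
    stop("schema needs at least one presentation and one treatment feature",
         call. = FALSE)
  }
  widths <- preset_widths(config$size_preset)
  K <- config$n_experts
  set.seed(config$seed)
  selector <- list()
  d <- length(pres)
  for (w in widths$selector) {
    selector[[length(selector) + 1L]] <- init_layer(d, w)
    d <- w
  }
  d_hidden <- d
  d_first <- widths$selector[1L]
  # zero gate: training starts from uniform expert utilisation
  gate <- list(W = matrix(0, d_hidden, K), b = rep(0, K))
  risk_head <- if (config$initial_risk) init_layer(d_hidden, 1L, gain = 0.1)
  d_expert_in <- switch(config$connection_variant,
    standard = d_hidden + length(treat),
    no_hidden = length(pres) + length(treat),
    later_hidden = length(treat)
  )
  d_inject <- if (config$connection_variant == "later_hidden") d_first else 0L
  experts <- lapply(seq_len(K), function(k) {
    set.seed(config$seed * 1000L + k)
    layers <- list()
    d <- d_expert_in
    for (w in widths$expert) {
      layers[[length(layers) + 1L]] <- init_layer(d, w)
      d <- w
    }
    # small output gain keeps initial expert opinions close together
    layers[[length(layers) + 1L]] <- init_layer(d + d_inject, 1L,
                                                gain = 0.1)
    layers
  })
  structure(
    list(params = list(selector = selector, gate = gate,
                       risk_head = risk_head, experts = experts),
         config = config, schema = schema,
         presentation = pres, treatment = treat,
         preprocess = NULL, history = NULL),
    class = "moe_model"
  )
}

#' @export
print.moe_model <- function(x, ...) {
  cat("Deep mixture of experts (",
      if (is.null(x$preprocess)) "untrained" else "trained", ")\n",
      sep = "")
  print(x$config)
  invisible(x)
}

relu <- function(x) (x > 0) * x

# Standardise features: continuous columns centred/scaled with training
# statistics, binary columns passed through. Imputation happens first.
moe_preprocess <- function(model, cohort, fit = FALSE) {
  stopifnot(inherits(cohort, "moe_cohort"))
  if (fit) {
    imp <- impute_missing(cohort)
    cont <- schema_names(model$schema, kind = "continuous")
    centre <- vapply(cont, function(nm) mean(imp$cohort$features[[nm]]),
                     numeric(1))
    scale_ <- vapply(cont, function(nm) {
      s <- stats::sd(imp$cohort$features[[nm]])
      if (!is.finite(s) || s == 0) 1 else s
    }, numeric(1))
    model$preprocess <- list(impute_means = imp$means, centre = centre,
                             scale = scale_)
    cohort <- imp$cohort
  } else {
    if (is.null(model$preprocess)) {
      stop("model has no stored preprocessing statistics; train it first",
           call. = FALSE)
    }
    cohort <- impute_missing(cohort, means = model$preprocess$impute_means)$cohort
  }
  feats <- cohort$features
  pp <- model$preprocess
  for (nm in names(pp$centre)) {
    feats[[nm]] <- (feats[[nm]] - pp$centre[[nm]]) / pp$scale[[nm]]
  }
  Xp <- as.matrix(feats[, model$presentation, drop = FALSE])
  Xt <- as.matrix(feats[, model$treatment, drop = FALSE])
  rownames(Xp) <- NULL
  rownames(Xt) <- NULL
  list(model = model, Xp = Xp, Xt = Xt, y = cohort$outcome)
}

# Core forward pass on prepared matrices. Returns gates, per-expert risks,
# the blended risk, and (optionally) every intermediate activation needed
# for backpropagation.
moe_forward_raw <- function(params, variant, Xp, Xt, keep = FALSE) {
  n <- nrow(Xp)
  acts <- vector("list", length(params$selector) + 1L)
  acts[[1L]] <- Xp
  for (l in seq_along(params$selector)) {
    lay <- params$selector[[l]]
    acts[[l + 1L]] <- relu(sweep(acts[[l]] %*% lay$W, 2, lay$b, "+"))
  }
  h <- acts[[length(acts)]]
  h_first <- acts[[2L]]
  scores <- sweep(h %*% params$gate$W, 2, params$gate$b, "+")
  shifted <- scores - apply(scores, 1, max)
  G <- exp(shifted)
  G <- G / rowSums(G)
  r0 <- NULL
  if (!is.null(params$risk_head)) {
    r0 <- stats::plogis(
      sweep(h %*% params$risk_head$W, 2, params$risk_head$b, "+"))[, 1]
  }
  expert_in <- switch(variant,
    standard = cbind(h, Xt),
    no_hidden = cbind(Xp, Xt),
    later_hidden = Xt
  )
  inject <- if (variant == "later_hidden") h_first
  K <- length(params$experts)
  P <- matrix(0, n, K)
  expert_acts <- if (keep) vector("list", K)
  for (k in seq_len(K)) {
    layers <- params$experts[[k]]
    L <- length(layers)
    ak <- vector("list", L)
    ak[[1L]] <- expert_in
    if (L > 1L) {
      for (l in seq_len(L - 1L)) {
        lay <- layers[[l]]
        ak[[l + 1L]] <- relu(sweep(ak[[l]] %*% lay$W, 2, lay$b, "+"))
      }
    }
    final_in <- ak[[L]]
    if (!is.null(inject)) final_in <- cbind(final_in, inject)
    out <- layers[[L]]
    P[, k] <- stats::plogis(sweep(final_in %*% out$W, 2, out$b, "+"))[, 1]
    if (keep) expert_acts[[k]] <- ak
  }
  res <- list(gates = G, scores = scores, expert_risks = P,
              final_risk = rowSums(G * P), initial_risk = r0)
  if (keep) {
    res$selector_acts <- acts
    res$expert_acts <- expert_acts
    res$expert_in <- expert_in
    res$inject <- inject
  }
  res
}

#' Forward pass of a mixture-of-experts model
#'
#' Computes, for every patient, the selector's gate vector on the
#' K-simplex, each expert's risk estimate, and the final weighted-vote
#' risk \eqn{\hat y = \sum_k g_k p_k}.
#'
#' @param model A trained (or at least preprocessed) \code{moe_model}.
#' @param cohort A \code{moe_cohort}.
#' @return An object of class \code{"moe_prediction"}: a list with
#'   \code{gates} (n x K), \code{expert_risks} (n x K), \code{final_risk}
#'   (length n), and \code{initial_risk} (length n or \code{NULL}).
#' @export
moe_forward <- function(model, cohort) {
  stopifnot(inherits(model, "moe_model"))
  prep <- moe_preprocess(model, cohort, fit = FALSE)
  fw <- moe_forward_raw(model$params, model$config$connection_variant,
                        prep$Xp, prep$Xt)
  structure(
    list(gates = fw$gates, expert_risks = fw$expert_risks,
         final_risk = fw$final_risk, initial_risk = fw$initial_risk),
    class = "moe_prediction"
  )
}

#' @export
#' @rdname moe_forward
#' @param object,... Standard predict-method arguments; \code{...} must
#'   contain or name the cohort.
predict.moe_model <- function(object, cohort, ...) {
  moe_forward(object, cohort)
}

#' @export
print.moe_prediction <- function(x, ...) {
  cat("MoE prediction for ", length(x$final_risk), " patients, K = ",
      ncol(x$gates), "\n", sep = "")
  invisible(x)
}

#' Gating utilisation penalty
#'
#' The L2 penalty applied to the selector's gate output:
#' \eqn{\lambda \cdot \mathrm{mean}_i \sum_k g_{ik}^2}. On the simplex this
#' is smallest (\eqn{\lambda/K}) for uniform gates and largest
#' (\eqn{\lambda}) for one-hot gates, so increasing \eqn{\lambda} pushes
#' the model toward even expert utilisation while \eqn{\lambda = 0} lets
#' it concentrate on a single expert.
#'
#' @param gates Matrix (n x K) or vector of gate values on the simplex.
#' @param lambda Nonnegative penalty weight.
#' @return A single nonnegative number.
#' @export
gating_penalty <- function(gates, lambda) {
  if (lambda < 0) stop("lambda must be nonnegative", call. = FALSE)
  if (is.null(dim(gates))) gates <- matrix(gates, nrow = 1)
  lambda * mean(rowSums(gates^2))
}

bce <- function(y, p) {
  p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Training loss of a batch
#'
#' Binary cross-entropy of the final weighted-vote risk against the
#' outcome, plus the gating penalty, plus (when the model is configured
#' with an initial-risk head) an auxiliary cross-entropy of the selector's
#' pre-treatment risk weighted by \code{aux_weight}.
#'
#' @param y Binary outcome vector.
#' @param prediction A \code{moe_prediction} (or any list with
#'   \code{final_risk}, \code{gates}, and optionally
#'   \code{initial_risk}).
#' @param lambda Gating penalty weight.
#' @param aux_weight Weight of the auxiliary initial-risk term.
#' @return A single number.
#' @export
training_loss <- function(y, prediction, lambda, aux_weight = 0.1) {
  y <- check_binary_outcome(y)
  loss <- bce(y, prediction$final_risk) +
    gating_penalty(prediction$gates, lambda)
  if (!is.null(prediction$initial_risk)) {
    loss <- loss + aux_weight * bce(y, prediction$initial_risk)
  }
  loss
}

#' Cluster assignments from gate vectors
#'
#' The soft membership of a patient is the gate vector itself; the hard
#' phenotype label is the index of the largest gate, with ties broken
#' deterministically toward the lowest expert index.
#'
#' @param prediction A \code{moe_prediction}, or a gate matrix.
#' @return A list with \code{hard} (integer labels in 1..K) and
#'   \code{soft} (the n x K gate matrix).
#' @export
assign_clusters <- function(prediction) {
  gates <- if (inherits(prediction, "moe_prediction")) prediction$gates
           else as.matrix(prediction)
  list(hard = max.col(gates, ties.method = "first"), soft = gates)
}
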