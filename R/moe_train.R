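# Training backend: manual backpropagation through the two-tier
# architecture, minibatch Adam (optionally momentum SGD for the gating
# layer; see ?moe_config).

# Gradient of the batch loss wrt every parameter. `fw` must come from
# moe_forward_raw(..., keep = TRUE).
moe_backward <- function(params, variant, fw, Xp, Xt, y, lambda,
                         penalty_on, aux_weight) {
  n <- length(y)
  G <- fw$gates
  P <- fw$expert_risks
  K <- ncol(G)
  yh <- pmin(pmax(fw$final_risk, 1e-7), 1 - 1e-7)
  d_yh <- (yh - y) / (yh * (1 - yh)) / n
  d_P <- d_yh * G
  d_G <- d_yh * P
  if (penalty_on == "gates") d_G <- d_G + 2 * lambda * G / n
  # softmax backprop
  d_scores <- G * (d_G - rowSums(d_G * G))
  if (penalty_on == "scores") d_scores <- d_scores + 2 * lambda * fw$scores / n
  grads <- list(selector = vector("list", length(params$selector)),
                gate = NULL, risk_head = NULL,
                experts = vector("list", K))
  h <- fw$selector_acts[[length(fw$selector_acts)]]
  grads$gate <- list(W = crossprod(h, d_scores), b = colSums(d_scores))
  d_h <- d_scores %*% t(params$gate$W)
  if (!is.null(params$risk_head)) {
    d_zr <- matrix(aux_weight * (fw$initial_risk - y) / n, ncol = 1)
    grads$risk_head <- list(W = crossprod(h, d_zr), b = colSums(d_zr))
    d_h <- d_h + d_zr %*% t(params$risk_head$W)
  }
  d_h_first <- NULL
  d_expert_in <- 0
  for (k in seq_len(K)) {
    layers <- params$experts[[k]]
    L <- length(layers)
    ak <- fw$expert_acts[[k]]
    d_z <- matrix(d_P[, k] * P[, k] * (1 - P[, k]), ncol = 1)
    final_in <- ak[[L]]
    if (!is.null(fw$inject)) final_in <- cbind(final_in, fw$inject)
    gk <- vector("list", L)
    gk[[L]] <- list(W = crossprod(final_in, d_z), b = colSums(d_z))
    d_fin <- d_z %*% t(layers[[L]]$W)
    if (!is.null(fw$inject)) {
      d_hidden <- ncol(ak[[L]])
      inj_cols <- (d_hidden + 1L):ncol(d_fin)
      d_h_first <- if (is.null(d_h_first)) d_fin[, inj_cols, drop = FALSE]
                   else d_h_first + d_fin[, inj_cols, drop = FALSE]
      d_fin <- d_fin[, seq_len(d_hidden), drop = FALSE]
    }
    d_a <- d_fin
    if (L > 1L) {
      for (l in (L - 1L):1L) {
        d_a <- d_a * (ak[[l + 1L]] > 0)
        gk[[l]] <- list(W = crossprod(ak[[l]], d_a), b = colSums(d_a))
        d_a <- d_a %*% t(layers[[l]]$W)
      }
    }
    d_expert_in <- d_expert_in + d_a
    grads$experts[[k]] <- gk
  }
  if (variant == "standard") {
    d_h <- d_h + d_expert_in[, seq_len(ncol(h)), drop = FALSE]
  }
  # selector backprop (relu derivative uses the stored activations)
  d_a <- d_h
  for (l in rev(seq_along(params$selector))) {
    d_a <- d_a * (fw$selector_acts[[l + 1L]] > 0)
    if (l == 1L && !is.null(d_h_first)) {
      # later_hidden injection enters after the first layer's relu, so its
      # gradient joins before differentiating that relu: recompute
      d_a <- d_a + d_h_first * (fw$selector_acts[[2L]] > 0)
    }
    grads$selector[[l]] <- list(W = crossprod(fw$selector_acts[[l]], d_a),
                                b = colSums(d_a))
    d_a <- d_a %*% t(params$selector[[l]]$W)
  }
  grads
}

# flatten parameter / gradient trees into a named list of arrays
flatten_params <- function(p) {
  out <- list()
  for (l in seq_along(p$selector)) {
    out[[paste0("sel", l, ".W")]] <- p$selector[[l]]$W
    out[[paste0("sel", l, ".b")]] <- p$selector[[l]]$b
  }
  out[["gate.W"]] <- p$gate$W
  out[["gate.b"]] <- p$gate$b
  if (!is.null(p$risk_head)) {
    out[["risk.W"]] <- p$risk_head$W
    out[["risk.b"]] <- p$risk_head$b
  }
  for (k in seq_along(p$experts)) {
    for (l in seq_along(p$experts[[k]])) {
      out[[paste0("exp", k, "_", l, ".W")]] <- p$experts[[k]][[l]]$W
      out[[paste0("exp", k, "_", l, ".b")]] <- p$experts[[k]][[l]]$b
    }
  }
  out
}

unflatten_params <- function(flat, template) {
  p <- template
  for (l in seq_along(p$selector)) {
    p$selector[[l]]$W <- flat[[paste0("sel", l, ".W")]]
    p$selector[[l]]$b <- flat[[paste0("sel", l, ".b")]]
  }
  p$gate$W <- flat[["gate.W"]]
  p$gate$b <- flat[["gate.b"]]
  if (!is.null(p$risk_head)) {
    p$risk_head$W <- flat[["risk.W"]]
    p$risk_head$b <- flat[["risk.b"]]
  }
  for (k in seq_along(p$experts)) {
    for (l in seq_along(p$experts[[k]])) {
      p$experts[[k]][[l]]$W <- flat[[paste0("exp", k, "_", l, ".W")]]
      p$experts[[k]][[l]]$b <- flat[[paste0("exp", k, "_", l, ".b")]]
    }
  }
  p
}

#' Train a mixture-of-experts model
#'
#' Minimises the training loss (cross-entropy of the weighted vote, plus
#' the gating penalty, plus the optional auxiliary initial-risk term) by
#' minibatch gradient descent with early stopping on the validation loss.
#' Imputation and standardisation statistics are computed from the
#' training cohort only and stored in the returned model. Runs are
#' deterministic given the configuration seed.
#'
#' @param model An untrained \code{moe_model} from [build_moe()].
#' @param train_cohort Training \code{moe_cohort}.
#' @param val_cohort Validation \code{moe_cohort}, disjoint from training;
#'   must be non-empty.
#' @return The trained \code{moe_model}; \code{$history} holds the
#'   per-epoch validation loss and the epoch whose weights were kept.
#' @export
train_moe <- function(model, train_cohort, val_cohort) {
  stopifnot(inherits(model, "moe_model"))
  if (is.null(val_cohort) || cohort_size(val_cohort) == 0L) {
    stop("validation cohort must be non-empty", call. = FALSE)
  }
  cfg <- model$config
  prep <- moe_preprocess(model, train_cohort, fit = TRUE)
  model <- prep$model
  vprep <- moe_preprocess(model, val_cohort, fit = FALSE)
  Xp <- prep$Xp; Xt <- prep$Xt; y <- prep$y
  variant <- cfg$connection_variant
  theta <- flatten_params(model$params)
  m1 <- lapply(theta, function(x) x * 0)
  m2 <- m1
  t_step <- 0L
  gate_names <- c("gate.W", "gate.b")
  best_loss <- Inf
  best_theta <- theta
  best_epoch <- 0L
  wait <- 0L
  history <- numeric(0)
  n <- length(y)
  set.seed(cfg$seed + 7L)
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    for (start in seq(1L, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
      params <- unflatten_params(theta, model$params)
      fw <- moe_forward_raw(params, variant,
                            Xp[idx, , drop = FALSE],
                            Xt[idx, , drop = FALSE], keep = TRUE)
      grads <- moe_backward(params, variant, fw,
                            Xp[idx, , drop = FALSE],
                            Xt[idx, , drop = FALSE],
                            y[idx], cfg$gating_l2, cfg$penalty_on,
                            cfg$aux_weight)
      gflat <- flatten_params(list(selector = grads$selector,
                                   gate = grads$gate,
                                   risk_head = grads$risk_head,
                                   experts = grads$experts))
      t_step <- t_step + 1L
      for (nm in names(theta)) {
        g <- gflat[[nm]]
        m1[[nm]] <- 0.9 * m1[[nm]] + 0.1 * g
        if (cfg$gate_optimizer == "sgd" && nm %in% gate_names) {
          theta[[nm]] <- theta[[nm]] - cfg$gate_learning_rate * m1[[nm]]
        } else {
          m2[[nm]] <- 0.999 * m2[[nm]] + 0.001 * g^2
          mh <- m1[[nm]] / (1 - 0.9^t_step)
          vh <- m2[[nm]] / (1 - 0.999^t_step)
          theta[[nm]] <- theta[[nm]] -
            cfg$learning_rate * mh / (sqrt(vh) + cfg$adam_epsilon)
        }
      }
    }
    params <- unflatten_params(theta, model$params)
    vfw <- moe_forward_raw(params, variant, vprep$Xp, vprep$Xt)
    vloss <- training_loss(vprep$y,
                           list(final_risk = vfw$final_risk,
                                gates = vfw$gates,
                                initial_risk = vfw$initial_risk),
                           cfg$gating_l2, cfg$aux_weight)
    history <- c(history, vloss)
    if (vloss < best_loss - 1e-5) {
      best_loss <- vloss
      best_theta <- theta
      best_epoch <- epoch
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= cfg$patience) break
    }
  }
  model$params <- unflatten_params(best_theta, model$params)
  model$history <- list(val_loss = history, best_epoch = best_epoch,
                        best_val_loss = best_loss)
  model
}

#' Save a trained model as a text directory
#'
#' Writes the configuration, schema, preprocessing statistics, and every
#' parameter array to plain-text files so a model round-trips exactly.
#'
#' @param model A \code{moe_model}.
#' @param dir Directory to create/overwrite.
#' @return \code{dir}, invisibly.
#' @export
save_moe <- function(model, dir) {
  stopifnot(inherits(model, "moe_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pp <- model$preprocess
  jsonlite::write_json(
    list(config = unclass(model$config),
         preprocess = if (!is.null(pp)) list(
           impute_means = as.list(pp$impute_means),
           centre = as.list(pp$centre),
           scale = as.list(pp$scale)),
         presentation = model$presentation,
         treatment = model$treatment),
    file.path(dir, "model.json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  write_schema(model$schema, file.path(dir, "schema.tsv"))
  flat <- flatten_params(model$params)
  dims <- lapply(flat, function(x) if (is.matrix(x)) dim(x) else length(x))
  jsonlite::write_json(dims, file.path(dir, "shapes.json"), digits = NA)
  con <- file(file.path(dir, "params.txt"), "w")
  on.exit(close(con))
  for (nm in names(flat)) {
    writeLines(nm, con)
    writeLines(paste(sprintf("%.17g", as.numeric(flat[[nm]])),
                     collapse = " "), con)
  }
  invisible(dir)
}

#' Load a model saved with [save_moe()]
#'
#' @param dir Directory written by [save_moe()].
#' @return A \code{moe_model}.
#' @export
load_moe <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model.json"),
                              simplifyVector = TRUE)
  schema <- read_schema(file.path(dir, "schema.tsv"))
  cfg <- do.call(moe_config, meta$config[
    setdiff(names(meta$config), character(0))])
  model <- build_moe(cfg, schema)
  pp <- meta$preprocess
  if (!is.null(pp)) {
    model$preprocess <- list(
      impute_means = unlist(pp$impute_means),
      centre = unlist(pp$centre),
      scale = unlist(pp$scale)
    )
  }
  shapes <- jsonlite::read_json(file.path(dir, "shapes.json"),
                                simplifyVector = TRUE)
  lines <- readLines(file.path(dir, "params.txt"))
  flat <- list()
  for (i in seq(1, length(lines), by = 2)) {
    nm <- lines[i]
    vals <- as.numeric(strsplit(trimws(lines[i + 1]), " +")[[1]])
    d <- shapes[[nm]]
    flat[[nm]] <- if (length(d) == 2) matrix(vals, d[1], d[2]) else vals
  }
  model$params <- unflatten_params(flat, model$params)
  model
}
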