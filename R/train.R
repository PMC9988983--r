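#' Training configuration
#'
#' One iteration is `batches_per_iteration` Adam steps followed by one full
#' validation evaluation. Training stops when the validation macro F1 has
#' not strictly exceeded the best value for `patience` consecutive
#' iterations, or after `max_iterations`; the state at the best-validation
#' checkpoint is returned.
#'
#' @param lr Adam learning rate.
#' @param patience iterations without strict improvement before stopping.
#' @param max_iterations iteration cap.
#' @param batches_per_iteration optimizer steps per iteration.
#' @param beta1,beta2,eps Adam moment parameters.
#' @param seed integer seed driving batch sampling and any stochastic
#'   layers.
#' @export
train_config <- function(lr = 1e-5, patience = 100, max_iterations = 1000,
                         batches_per_iteration = 25, beta1 = 0.9,
                         beta2 = 0.999, eps = 1e-8, seed = 1L) {
  stopifnot(lr > 0, patience >= 1, max_iterations >= 1,
            batches_per_iteration >= 1)
  structure(list(lr = lr, patience = as.integer(patience),
                 max_iterations = as.integer(max_iterations),
                 batches_per_iteration = as.integer(batches_per_iteration),
                 beta1 = beta1, beta2 = beta2, eps = eps,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Masked cross-entropy loss
#'
#' Mean negative log-probability of the true stage over unmasked epochs.
#' Epochs whose label is the mask sentinel (-1) do not contribute. Returns
#' 0 (with a warning) when every epoch is masked. Probabilities are clamped
#' at 1e-12.
#'
#' @param probs L x K probability matrix (or B x L x K array).
#' @param labels integer labels in \{-1, 0, ..., K-1\} (vector or B x L).
#' @param mask logical, TRUE where the label is a scored stage; defaults to
#'   `labels >= 0`.
#' @export
masked_cross_entropy <- function(probs, labels, mask = NULL) {
  if (is.matrix(probs)) probs <- array(probs, c(1, dim(probs)))
  labels <- matrix(as.integer(labels), dim(probs)[1], dim(probs)[2])
  if (is.null(mask)) mask <- labels >= 0L
  idx <- which(mask, arr.ind = TRUE)
  if (!nrow(idx)) {
    warning("all epochs masked; loss is 0")
    return(0)
  }
  p <- probs[cbind(idx, labels[idx] + 1L)]
  mean(-log(pmax(p, 1e-12)))
}

# Gradient of the masked mean cross-entropy at the softmax input.
ce_logit_grad <- function(probs, labels, mask) {
  d <- dim(probs)
  dZ <- probs
  idx <- which(mask, arr.ind = TRUE)
  n <- nrow(idx)
  dZ[cbind(idx, labels[idx] + 1L)] <- dZ[cbind(idx, labels[idx] + 1L)] - 1
  for (k in seq_len(d[3])) dZ[, , k] <- dZ[, , k] * mask
  dZ / max(n, 1)
}

# ---- Adam over the nested parameter tree --------------------------------

# Trainable-leaf selection mirrors count_params(): conv W/b and the
# normalization affines of the active mode.
norm_grad_names <- function(mode) switch(mode,
  vanilla = c("gamma", "beta"),
  ccbn = c("gamma_g", "beta_g"),
  sabn = c("gamma_sa", "beta_sa", "gamma_g", "beta_g"))

adam_step <- function(params, grads, state, cfg, t) {
  lr_t <- cfg$lr * sqrt(1 - cfg$beta2^t) / (1 - cfg$beta1^t)
  rec <- function(p, g, s) {
    if (is.numeric(g)) {
      if (is.null(s)) s <- list(m = g * 0, v = g * 0)
      s$m <- cfg$beta1 * s$m + (1 - cfg$beta1) * g
      s$v <- cfg$beta2 * s$v + (1 - cfg$beta2) * g * g
      p <- p - lr_t * s$m / (sqrt(s$v) + cfg$eps)
      return(list(p = p, s = s))
    }
    if (is.null(s)) s <- vector("list", length(g))
    for (nm in names(g)) {
      r <- rec(p[[nm]], g[[nm]], s[[nm]])
      p[[nm]] <- r$p
      if (is.null(names(s))) names(s) <- names(g)
      s[[nm]] <- r$s
    }
    # unnamed list levels (enc/dec block lists)
    if (is.null(names(g))) for (i2 in seq_along(g)) {
      r <- rec(p[[i2]], g[[i2]], s[[i2]])
      p[[i2]] <- r$p
      s[[i2]] <- r$s
    }
    list(p = p, s = s)
  }
  rec(params, grads, state)
}

#' Pooled macro F1 over a set of recordings
#'
#' The cheap staging metric used for validation during training: each
#' recording is staged with a single fixed recommended derivation pair
#' (the first EEG and first EOG of the table), predictions and labels are
#' pooled across recordings, and the unweighted (macro) F1 is returned on
#' the `[0, 1]` scale.
#'
#' @param model a `psg_model`.
#' @param recordings list/cohort of preprocessed recordings.
#' @param condition_fn optional recording -> condition index function.
#' @param table recommended-derivation table override.
#' @export
pooled_macro_f1 <- function(model, recordings, condition_fn = NULL,
                            table = aasm_derivation_table()) {
  yt <- integer(0); yp <- integer(0)
  for (rec in recordings) {
    derivs <- split_by_modality(recommended_derivations(rec$electrodes, table))
    comb <- list(eeg = derivs$eeg[[1]], eog = derivs$eog[[1]])
    X <- cbind(derive_signal(rec, comb$eeg), derive_signal(rec, comb$eog))
    g <- if (!is.null(condition_fn)) as.integer(condition_fn(rec))
         else if (model$config$norm_mode != "vanilla") 1L else NULL
    pr <- forward(model, X, g)
    labs <- unclass(rec$hypnogram)
    keep <- labs >= 0
    yt <- c(yt, labs[keep])
    yp <- c(yp, max.col(pr)[keep] - 1L)
  }
  stage_f1(yt, yp)$aggregate / 100
}

#' Fit a stager by masked cross-entropy with Adam and early stopping
#'
#' Each iteration draws `batches_per_iteration` batches from the training
#' cohort through the hierarchical sampler, takes one Adam step per batch,
#' then evaluates macro F1 on the validation recordings (single fixed
#' recommended derivation per recording, pooled across epochs). The best
#' validation checkpoint is kept — on exact ties the later model is
#' retained, since it has seen more data — and training stops early after
#' `patience` iterations without strict improvement. Non-finite losses abort with the
#' state flagged as diverged.
#'
#' @param model a `psg_model`.
#' @param cohort training [psg_cohort()] (preprocessed, at the model's
#'   sampling rate).
#' @param validation non-empty list/cohort of validation recordings.
#' @param config a [train_config()].
#' @param sampler a [sampler_config()].
#' @param condition_fn optional recording -> condition index function for
#'   ccbn/sabn models; also used at validation time.
#' @return a `train_state`: the best model, history data frame
#'   (`iteration`, `loss`, `val_f1`, `best_f1`), iteration counts and stop
#'   reason.
#' @export
fit <- function(model, cohort, validation, config = train_config(),
                sampler = sampler_config(), condition_fn = NULL) {
  if (!length(validation)) stop("validation set must be non-empty")
  state <- NULL
  best <- -Inf
  best_model <- model
  best_iter <- 0L
  wait <- 0L
  hist <- list()
  t_step <- 0L
  reason <- "max_iterations"
  for (it in seq_len(config$max_iterations)) {
    losses <- numeric(config$batches_per_iteration)
    for (bi in seq_len(config$batches_per_iteration)) {
      bseed <- derive_seed(config$seed, 10000L * it + bi)
      batch <- make_batch(cohort, sampler, condition_fn, seed = bseed)
      fwd <- net_forward(model, batch$X,
                         if (model$config$norm_mode == "vanilla") NULL else batch$g,
                         training = TRUE)
      model <- fwd$model
      loss <- masked_cross_entropy(fwd$probs, batch$y, batch$mask)
      if (!is.finite(loss)) {
        model$iteration <- it
        return(structure(list(model = best_model, last_model = model,
                              history = do.call(rbind, hist),
                              best_val_f1 = best, best_iteration = best_iter,
                              iterations = it, reason = "diverged"),
                         class = "train_state"))
      }
      losses[bi] <- loss
      dZ <- ce_logit_grad(fwd$probs, batch$y, batch$mask)
      grads <- net_backward(model, fwd$cache, dZ)
      t_step <- t_step + 1L
      upd <- adam_step(model$params, grads, state, config, t_step)
      model$params <- upd$p
      state <- upd$s
    }
    vf1 <- pooled_macro_f1(model, validation, condition_fn)
    if (vf1 > best) {
      best <- vf1
      best_model <- model
      best_iter <- it
      wait <- 0L
    } else {
      # a tie refreshes the checkpoint (the later of two equally good
      # models has seen more data) but neither resets patience nor counts
      # as an improvement
      if (vf1 == best) best_model <- model
      wait <- wait + 1L
    }
    hist[[it]] <- data.frame(iteration = it, loss = mean(losses),
                             val_f1 = vf1, best_f1 = best)
    if (wait >= config$patience) {
      reason <- "early_stop"
      break
    }
  }
  best_model$iteration <- best_iter
  structure(list(model = best_model, last_model = model,
                 history = do.call(rbind, hist), best_val_f1 = best,
                 best_iteration = best_iter, iterations = length(hist),
                 reason = reason),
            class = "train_state")
}

#' @export
print.train_state <- function(x, ...) {
  cat("<train_state> ", x$iterations, " iterations (", x$reason,
      "), best val F1 ", sprintf("%.3f", x$best_val_f1),
      " at iteration ", x$best_iteration, "\n", sep = "")
  invisible(x)
}

#' Fine-tune a pretrained stager on a target domain
#'
#' All parameters stay trainable (no freezing); a smaller learning rate is
#' the default. Optionally converts the normalization family first (e.g.
#' vanilla to sandwich normalization for group-conditioned fine-tuning):
#' the existing affine parameters are duplicated into every group and the
#' sandwich affine starts at the identity, so pre-fine-tuning predictions
#' match the pretrained model for every condition index.
#'
#' @param pretrained a `train_state` or `psg_model`.
#' @param cohort,validation target-domain data as in [fit()].
#' @param config a [train_config()]; default uses `lr = 1e-6`.
#' @param norm_mode optional target normalization mode (`"ccbn"`/`"sabn"`).
#' @param G condition-group count when converting.
#' @param sampler,condition_fn as in [fit()].
#' @export
fine_tune <- function(pretrained, cohort, validation,
                      config = train_config(lr = 1e-6),
                      norm_mode = NULL, G = NULL,
                      sampler = sampler_config(), condition_fn = NULL) {
  model <- if (inherits(pretrained, "train_state")) pretrained$model
           else pretrained
  stopifnot(inherits(model, "psg_model"))
  if (!is.null(norm_mode) && norm_mode != model$config$norm_mode)
    model <- convert_norm_mode(model, norm_mode, G %||% model$config$G)
  fit(model, cohort, validation, config, sampler, condition_fn)
}
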