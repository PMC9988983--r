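#' Whole-recording inference with majority-vote ensembling
#'
#' Runs the model over every realizable EEG x EOG derivation combination of
#' the recording and combines the per-combination argmax votes into a final
#' per-epoch label by majority vote. Ties are broken by the higher mean
#' predicted probability across combinations, then by the lower stage
#' index. Masked epochs keep their votes here; metric functions drop them.
#'
#' @param model a `psg_model` at the recording's sampling rate.
#' @param recording a preprocessed [psg_recording()].
#' @param derivation_mode `"recommended"` or `"atypical"`.
#' @param n_atypical c(EEG, EOG) counts drawn in atypical mode.
#' @param seed seed for atypical derivation draws.
#' @param g condition index for conditional models.
#' @param table recommended-derivation table override.
#' @return list with `probs` (combinations x epochs x K array), `votes`
#'   (combinations x epochs), `labels` (ensembled per-epoch stage codes)
#'   and `combinations`.
#' @export
predict_recording <- function(model, recording,
                              derivation_mode = c("recommended", "atypical"),
                              n_atypical = c(2L, 2L), seed = NULL, g = NULL,
                              table = aasm_derivation_table()) {
  derivation_mode <- match.arg(derivation_mode)
  if (recording$fs != model$config$fs)
    stop("recording sampling rate differs from the model's")
  derivs <- if (derivation_mode == "recommended") {
    recommended_derivations(recording$electrodes, table)
  } else {
    atypical_derivations(recording$electrodes, n_atypical[1], n_atypical[2],
                         seed = seed)
  }
  sp <- split_by_modality(derivs)
  combos <- enumerate_combinations(sp$eeg, sp$eog)
  ne <- n_epochs(recording)
  K <- model$config$K
  if (model$config$norm_mode != "vanilla" && is.null(g)) g <- 1L
  probs <- array(NA_real_, c(length(combos), ne, K))
  for (ci in seq_along(combos)) {
    cb <- combos[[ci]]
    X <- cbind(derive_signal(recording, cb$eeg),
               derive_signal(recording, cb$eog))
    probs[ci, , ] <- forward(model, X, g)
  }
  votes <- apply(probs, c(1, 2), which.max) - 1L   # combos x epochs
  dim(votes) <- c(length(combos), ne)
  labels <- majority_vote(votes, probs)
  list(probs = probs, votes = votes, labels = labels, combinations = combos)
}

#' Majority vote over per-combination stage votes
#'
#' @param votes combinations x epochs integer matrix of stage codes.
#' @param probs optional combinations x epochs x K probability array used
#'   to break ties (higher mean probability, then lower stage index).
#' @return integer vector of per-epoch winning stage codes.
#' @export
majority_vote <- function(votes, probs = NULL) {
  ne <- ncol(votes)
  out <- integer(ne)
  for (ep in seq_len(ne)) {
    v <- votes[, ep]
    tab <- table(v)
    winners <- as.integer(names(tab)[tab == max(tab)])
    if (length(winners) > 1 && !is.null(probs)) {
      mp <- apply(probs[, ep, , drop = FALSE], 3, mean)
      winners <- winners[order(-mp[winners + 1L], winners)]
    } else winners <- sort(winners)
    out[ep] <- winners[1]
  }
  out
}

#' Per-stage and aggregate F1 score
#'
#' Per-class F1 is `2TP / (2TP + FP + FN)`. The unweighted (macro)
#' aggregate averages over classes; the weighted aggregate weights by the
#' number of true instances per class. By default only classes present in
#' the truth or the prediction enter the average (`classes = "present"`),
#' so a short recording missing a stage is not zero-penalized; set
#' `classes = "all"` for fixed five-class averaging. Masked positions
#' (`y_true == -1`) are dropped first.
#'
#' @param y_true,y_pred integer stage codes of equal length.
#' @param weighting `"unweighted"` or `"weighted"`.
#' @param classes `"present"` or `"all"`.
#' @return list with `per_class` (named F1 vector on \[0, 1\], NA where a
#'   class is absent) and `aggregate` (percent).
#' @export
stage_f1 <- function(y_true, y_pred,
                     weighting = c("unweighted", "weighted"),
                     classes = c("present", "all")) {
  weighting <- match.arg(weighting)
  classes <- match.arg(classes)
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  keep <- y_true >= 0
  y_true <- y_true[keep]; y_pred <- y_pred[keep]
  if (!length(y_true)) stop("no scored epochs")
  per <- rep(NA_real_, 5)
  names(per) <- stage_levels()
  support <- numeric(5)
  for (k in 0:4) {
    tp <- sum(y_true == k & y_pred == k)
    fp <- sum(y_true != k & y_pred == k)
    fn <- sum(y_true == k & y_pred != k)
    support[k + 1] <- tp + fn
    if (tp + fp + fn > 0) per[k + 1] <- 2 * tp / (2 * tp + fp + fn)
  }
  use <- if (classes == "present") which(!is.na(per)) else 1:5
  vals <- per[use]
  vals[is.na(vals)] <- 0
  agg <- if (weighting == "unweighted") mean(vals)
         else {
           w <- support[use]
           if (sum(w) == 0) 0 else sum(vals * w) / sum(w)
         }
  list(per_class = per, aggregate = 100 * agg)
}

#' Cohen's kappa
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with the expected
#' agreement from the marginal products. Masked positions are dropped. If
#' both sequences are constant and equal (`p_e = 1`) the conventional
#' value 1 is returned with a message.
#'
#' @param y_true,y_pred integer stage codes of equal length.
#' @export
cohens_kappa <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  keep <- y_true >= 0
  y_true <- y_true[keep]; y_pred <- y_pred[keep]
  if (!length(y_true)) stop("no scored epochs")
  lev <- sort(unique(c(y_true, y_pred)))
  tab <- table(factor(y_true, lev), factor(y_pred, lev))
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (abs(1 - pe) < 1e-12) {
    message("degenerate kappa (both raters constant); returning 1")
    return(1)
  }
  (po - pe) / (1 - pe)
}

#' Evaluate a model on a cohort, per recording
#'
#' Computes majority-vote predictions and per-recording metrics
#' (unweighted and weighted F1 %, Cohen's kappa, per-stage F1), then
#' aggregates across recordings as mean and population standard deviation.
#' Recordings failing prediction are recorded as failures and excluded.
#'
#' @param model a `psg_model`.
#' @param recordings a [psg_cohort()] or list of recordings.
#' @param derivation_mode,seed,condition_fn,table forwarded to
#'   [predict_recording()]; `condition_fn` maps a recording to its
#'   condition index.
#' @return list of class `psg_eval` with `per_recording` and `summary`
#'   data frames and a `failures` character vector.
#' @export
evaluate_cohort <- function(model, recordings,
                            derivation_mode = c("recommended", "atypical"),
                            seed = NULL, condition_fn = NULL,
                            table = aasm_derivation_table()) {
  derivation_mode <- match.arg(derivation_mode)
  if (!length(recordings)) stop("empty cohort")
  rows <- list()
  failures <- character(0)
  for (ri in seq_along(recordings)) {
    rec <- recordings[[ri]]
    res <- tryCatch({
      g <- if (is.null(condition_fn)) NULL else as.integer(condition_fn(rec))
      pr <- predict_recording(model, rec, derivation_mode,
                              seed = derive_seed(seed %||% 0L, ri), g = g,
                              table = table)
      yt <- unclass(rec$hypnogram)
      uf <- stage_f1(yt, pr$labels, "unweighted")
      wf <- stage_f1(yt, pr$labels, "weighted")
      pc <- uf$per_class
      data.frame(recording_id = rec$recording_id,
                 dataset_id = rec$dataset_id,
                 uf1 = uf$aggregate, wf1 = wf$aggregate,
                 kappa = cohens_kappa(yt, pr$labels),
                 f1_W = pc["W"], f1_N1 = pc["N1"], f1_N2 = pc["N2"],
                 f1_N3 = pc["N3"], f1_REM = pc["REM"],
                 row.names = NULL)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning("recording ", rec$recording_id, " failed: ",
              conditionMessage(res))
      failures <- c(failures, rec$recording_id)
    } else rows[[length(rows) + 1L]] <- res
  }
  per <- do.call(rbind, rows)
  metr <- c("uf1", "wf1", "kappa")
  summary <- data.frame(metric = metr,
                        mean = vapply(metr, function(m) mean(per[[m]]), 0),
                        sd = vapply(metr, function(m) pop_sd(per[[m]]), 0),
                        row.names = NULL)
  structure(list(per_recording = per, summary = summary,
                 failures = failures, derivation_mode = derivation_mode),
            class = "psg_eval")
}

#' @export
print.psg_eval <- function(x, ...) {
  cat("<psg_eval> ", nrow(x$per_recording), " recordings (",
      x$derivation_mode, " derivations)\n", sep = "")
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-6s %6.2f +/- %.2f\n", s$metric[i], s$mean[i], s$sd[i]))
  invisible(x)
}

#' Paired t-test across recordings
#'
#' Paired t statistic on the per-recording differences `scores_b -
#' scores_a`; `"one_sided_greater"` tests whether `scores_b` exceeds
#' `scores_a`. Zero-variance differences yield a flagged degenerate result
#' (p-value NA), never a silent 0.
#'
#' @param scores_a,scores_b equal-length paired score vectors (>= 2).
#' @param alternative `"two_sided"` or `"one_sided_greater"`.
#' @return list with `statistic`, `df`, `p_value`, `mean_diff`,
#'   `degenerate`.
#' @export
paired_test <- function(scores_a, scores_b,
                        alternative = c("two_sided", "one_sided_greater")) {
  alternative <- match.arg(alternative)
  if (length(scores_a) != length(scores_b) || length(scores_a) < 2)
    stop("paired scores of equal length >= 2 required")
  d <- scores_b - scores_a
  if (sd(d) < 1e-15) {
    return(list(statistic = NA_real_, df = length(d) - 1,
                p_value = NA_real_, mean_diff = mean(d), degenerate = TRUE))
  }
  alt <- if (alternative == "two_sided") "two.sided" else "greater"
  tt <- stats::t.test(scores_b, scores_a, paired = TRUE, alternative = alt)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_diff = mean(d), degenerate = FALSE)
}
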