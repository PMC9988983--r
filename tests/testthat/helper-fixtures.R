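# Shared fixtures, generated in code at load time. Small sizes keep the
# suite fast; the 32 Hz rate still resolves spindles (13 Hz) and alpha.

FIX_FS <- 32

fixture_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cs <- cohort_spec(list(list(name = "A", n_subjects = 3, n_epochs = 60),
                             list(name = "B", n_subjects = 3, n_epochs = 60)),
                        fs = FIX_FS, seed = 101)
      cache <<- preprocess_cohort(generate_cohort(cs),
                                  prep_config(target_fs = FIX_FS))
    }
    cache
  }
})

fixture_recording <- function() fixture_cohort()[[1]]

tiny_model <- function(depth = 3, norm_mode = "vanilla", G = 1, seed = 1,
                       base_filters = 3) {
  build_model(model_config(depth = depth, base_filters = base_filters,
                           kernel_size = 5, fs = FIX_FS,
                           norm_mode = norm_mode, G = G), seed = seed)
}

# Independent brute-force F1: straightforward per-class loops, no shared
# code with stage_f1().
brute_f1 <- function(y_true, y_pred, weighted = FALSE) {
  keep <- y_true >= 0
  y_true <- y_true[keep]; y_pred <- y_pred[keep]
  f1s <- c(); ws <- c()
  for (k in 0:4) {
    if (!any(y_true == k) && !any(y_pred == k)) next
    tp <- 0; fp <- 0; fn <- 0
    for (i in seq_along(y_true)) {
      if (y_true[i] == k && y_pred[i] == k) tp <- tp + 1
      if (y_true[i] != k && y_pred[i] == k) fp <- fp + 1
      if (y_true[i] == k && y_pred[i] != k) fn <- fn + 1
    }
    f1s <- c(f1s, if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn))
    ws <- c(ws, sum(y_true == k))
  }
  if (weighted) 100 * sum(f1s * ws) / sum(ws) else 100 * mean(f1s)
}

# Independent kappa from the explicit contingency table formula.
brute_kappa <- function(y_true, y_pred) {
  keep <- y_true >= 0
  y_true <- y_true[keep]; y_pred <- y_pred[keep]
  n <- length(y_true)
  po <- sum(y_true == y_pred) / n
  pe <- 0
  for (k in unique(c(y_true, y_pred)))
    pe <- pe + (sum(y_true == k) / n) * (sum(y_pred == k) / n)
  (po - pe) / (1 - pe)
}

# Welch-style band power oracle via stats::spec.pgram (independent of the
# package's fft-based bandpower).
oracle_bandpower <- function(x, fs, f_lo, f_hi) {
  sp <- stats::spec.pgram(stats::ts(x, frequency = fs), taper = 0,
                          detrend = FALSE, plot = FALSE)
  sum(sp$spec[sp$freq >= f_lo & sp$freq <= f_hi])
}
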