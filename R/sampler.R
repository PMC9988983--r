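#' Augmentation parameters
#'
#' Gaussian-noise augmentation: with probability `event_prob` per batch
#' element, a contiguous fraction of the segment (log-uniform in
#' `[frac_min, frac_max]`) is replaced by draws from a normal law with mean
#' equal to the element's overall signal mean and variance `noise_var`;
#' independently, with probability `whole_channel_prob` at most one channel
#' is entirely replaced by such noise.
#'
#' @param event_prob per-element probability of a partial replacement.
#' @param frac_min,frac_max bounds of the log-uniform replaced fraction.
#' @param noise_var variance of the replacement noise.
#' @param whole_channel_prob probability of a whole-channel replacement.
#' @export
augment_params <- function(event_prob = 0.1, frac_min = 0.001,
                           frac_max = 0.33, noise_var = 0.01,
                           whole_channel_prob = 0.1) {
  stopifnot(event_prob >= 0, event_prob <= 1, whole_channel_prob >= 0,
            whole_channel_prob <= 1, frac_min > 0, frac_min < frac_max,
            frac_max <= 1, noise_var >= 0)
  structure(list(event_prob = event_prob, frac_min = frac_min,
                 frac_max = frac_max, noise_var = noise_var,
                 whole_channel_prob = whole_channel_prob),
            class = "augment_params")
}

#' Sampler configuration
#'
#' Controls the hierarchical training sampler: dataset mixture weight
#' `alpha` (P(D) = alpha * uniform + (1 - alpha) * size-proportional),
#' segment length `L` in 30-s epochs, derivation mode, augmentation and
#' batch size.
#'
#' @param alpha dataset mixture weight in `[0, 1]`.
#' @param L segment length in epochs.
#' @param derivation_mode `"recommended"` (uniform over the AASM table) or
#'   `"atypical"` (fresh random pairs per sample).
#' @param augment an [augment_params()] or `NULL` to disable.
#' @param batch_size elements per batch.
#' @export
sampler_config <- function(alpha = 0.5, L = 35,
                           derivation_mode = c("recommended", "atypical"),
                           augment = augment_params(), batch_size = 64) {
  stopifnot(alpha >= 0, alpha <= 1, L >= 1, batch_size >= 1)
  structure(list(alpha = alpha, L = as.integer(L),
                 derivation_mode = match.arg(derivation_mode),
                 augment = augment, batch_size = as.integer(batch_size)),
            class = "sampler_config")
}

#' Dataset selection probabilities
#'
#' `P(D) = alpha * P1(D) + (1 - alpha) * P2(D)` with `P1` uniform over
#' datasets and `P2` proportional to dataset size.
#'
#' @param dataset_sizes positive recording counts per dataset.
#' @param alpha mixture weight.
#' @export
dataset_probabilities <- function(dataset_sizes, alpha = 0.5) {
  if (!length(dataset_sizes)) stop("at least one dataset required")
  if (any(dataset_sizes <= 0)) stop("dataset sizes must be positive")
  alpha / length(dataset_sizes) +
    (1 - alpha) * dataset_sizes / sum(dataset_sizes)
}

#' @rdname dataset_probabilities
#' @param seed integer seed or `NULL`.
#' @return `sample_dataset` returns a single dataset index.
#' @export
sample_dataset <- function(dataset_sizes, alpha = 0.5, seed = NULL) {
  p <- dataset_probabilities(dataset_sizes, alpha)
  with_seed(seed, sample.int(length(p), 1L, prob = p))
}

#' Class-balanced segment sampling
#'
#' First a stage is sampled uniformly among the stages present in the
#' recording, then an epoch of that stage uniformly, and finally the anchor
#' epoch is shifted to a uniform position within the `L`-epoch window (the
#' window start is clamped so the window lies fully inside the recording).
#'
#' @param recording a [psg_recording()] with at least `L` scored epochs.
#' @param L window length in epochs.
#' @param seed integer seed or `NULL`.
#' @return list with `epoch_start` (1-based), `anchor_class` (stage code)
#'   and `anchor_epoch`.
#' @export
sample_segment <- function(recording, L, seed = NULL) {
  labs <- unclass(recording$hypnogram)
  ne <- length(labs)
  L <- as.integer(L)
  if (ne < L) stop("recording shorter than L epochs")
  scored <- which(labs >= 0L)
  if (!length(scored)) stop("recording contains only masked epochs")
  with_seed(seed, {
    present <- sort(unique(labs[scored]))
    cls <- present[sample.int(length(present), 1L)]
    cand <- which(labs == cls)
    anchor <- cand[sample.int(length(cand), 1L)]
    offset <- sample.int(L, 1L) - 1L
    start <- min(max(anchor - offset, 1L), ne - L + 1L)
    list(epoch_start = start, anchor_class = cls, anchor_epoch = anchor)
  })
}

#' Apply Gaussian-noise augmentation to one segment
#'
#' @param X time-by-channel numeric matrix (one batch element).
#' @param params an [augment_params()].
#' @param seed integer seed or `NULL`.
#' @return the augmented matrix; untouched samples are bit-identical.
#' @export
apply_augmentation <- function(X, params = augment_params(), seed = NULL) {
  stopifnot(is.matrix(X), all(is.finite(X)))
  with_seed(seed, {
    mu <- mean(X)
    sdv <- sqrt(params$noise_var)
    T <- nrow(X)
    if (runif(1) < params$event_prob) {
      f <- exp(runif(1, log(params$frac_min), log(params$frac_max)))
      len <- max(1L, min(T, round(f * T)))
      a <- sample.int(T - len + 1L, 1L)
      X[a:(a + len - 1L), ] <- rnorm(len * ncol(X), mu, sdv)
    }
    if (runif(1) < params$whole_channel_prob) {
      ch <- sample.int(ncol(X), 1L)
      X[, ch] <- rnorm(T, mu, sdv)
    }
    X
  })
}

#' Assemble a training batch
#'
#' Composes the hierarchical sampler: dataset by the alpha-mixture law,
#' recording uniformly within the dataset, one EEG and one EOG derivation
#' (uniform over the recommended table, or freshly random pairs in atypical
#' mode), class-balanced segment placement, then augmentation. The
#' condition index `g` is filled by `condition_fn(recording)` (e.g. an age
#' group) or 1.
#'
#' @param cohort a [psg_cohort()]; all recordings at a common sampling rate.
#' @param config a [sampler_config()].
#' @param condition_fn function of a recording returning an integer
#'   condition index (1-based), or `NULL`.
#' @param seed integer seed or `NULL`.
#' @param table recommended-derivation table override.
#' @return a list of class `psg_batch` with `X` (batch x time x 2 array,
#'   EEG then EOG channel), `y` (batch x L integer labels, -1 masked),
#'   `mask`, `g` and a `meta` data frame logging the sampled tuples.
#' @export
make_batch <- function(cohort, config = sampler_config(),
                       condition_fn = NULL, seed = NULL,
                       table = aasm_derivation_table()) {
  stopifnot(inherits(cohort, "psg_cohort"))
  fs <- unique(vapply(cohort, `[[`, 0, "fs"))
  if (length(fs) != 1) stop("all recordings must share one sampling rate")
  i <- as.integer(30 * fs)
  L <- config$L
  ds <- cohort_dataset_ids(cohort)
  dnames <- unique(ds)
  sizes <- vapply(dnames, function(d) sum(ds == d), 0L)
  B <- config$batch_size
  X <- array(0, c(B, L * i, 2L))
  y <- matrix(MASK_CODE, B, L)
  g <- integer(B)
  meta <- vector("list", B)
  with_seed(seed, {
    for (b in seq_len(B)) {
      di <- sample_dataset(sizes, config$alpha)
      members <- which(ds == dnames[di])
      rec <- cohort[[members[sample.int(length(members), 1L)]]]
      if (config$derivation_mode == "recommended") {
        sp <- split_by_modality(recommended_derivations(rec$electrodes, table))
        de <- sp$eeg[[sample.int(length(sp$eeg), 1L)]]
        do <- sp$eog[[sample.int(length(sp$eog), 1L)]]
      } else {
        sp <- split_by_modality(atypical_derivations(rec$electrodes, 1L, 1L))
        de <- sp$eeg[[1]]; do <- sp$eog[[1]]
      }
      seg <- sample_segment(rec, L)
      idx <- ((seg$epoch_start - 1L) * i + 1L):((seg$epoch_start + L - 1L) * i)
      Xb <- cbind(derive_signal(rec, de)[idx], derive_signal(rec, do)[idx])
      if (!is.null(config$augment))
        Xb <- apply_augmentation(Xb, config$augment)
      X[b, , ] <- Xb
      y[b, ] <- unclass(rec$hypnogram)[seg$epoch_start:(seg$epoch_start + L - 1L)]
      g[b] <- if (is.null(condition_fn)) 1L else as.integer(condition_fn(rec))
      meta[[b]] <- data.frame(dataset = rec$dataset_id,
                              recording = rec$recording_id,
                              eeg = format(de), eog = format(do),
                              epoch_start = seg$epoch_start,
                              anchor_class = seg$anchor_class)
    }
  })
  structure(list(X = X, y = y, mask = y != MASK_CODE, g = g, fs = fs,
                 meta = do.call(rbind, meta)),
            class = "psg_batch")
}
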