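#' Default referential electrode set
#'
#' Six scalp EEG electrodes, two mastoids and two EOG electrodes. Mastoids
#' carry attenuated copies of the same-side scalp activity plus independent
#' noise, so that both recommended and atypical derivations remain
#' informative about sleep stage.
#' @export
default_electrodes <- function() {
  c("F3", "F4", "C3", "C4", "O1", "O2", "M1", "M2", "E1", "E2")
}

#' Stationary-targeted stage transition matrix
#'
#' Builds a row-stochastic first-order transition matrix whose stationary
#' distribution equals `stationary`: each row is
#' `persistence * e_i + (1 - persistence) * stationary`, i.e. stages persist
#' across epochs (sleep stages come in bouts) and otherwise renew from the
#' stationary law.
#'
#' @param stationary probability vector over (W, N1, N2, N3, REM).
#' @param persistence probability of self-renewal mass added to the
#'   diagonal; higher values give longer stage bouts.
#' @return 5 x 5 row-stochastic matrix.
#' @export
stage_transition_matrix <- function(stationary = c(W = 0.15, N1 = 0.10,
                                                   N2 = 0.40, N3 = 0.15,
                                                   REM = 0.20),
                                    persistence = 0.85) {
  stopifnot(length(stationary) == 5, all(stationary >= 0))
  stationary <- stationary / sum(stationary)
  P <- persistence * diag(5) +
    (1 - persistence) * matrix(stationary, 5, 5, byrow = TRUE)
  dimnames(P) <- list(stage_levels(), stage_levels())
  P
}

#' Age-dependent stage priors
#'
#' Children show substantially more REM (and more N3) sleep than adults,
#' while elderly subjects show more wake after sleep onset and less deep
#' sleep. These priors drive the stationary distribution of the hypnogram
#' Markov chain for a subject of the given age.
#'
#' @param age age in years.
#' @return named probability vector over the five stages.
#' @export
age_stage_prior <- function(age) {
  if (is.null(age) || is.na(age)) age <- 40
  if (age < 13)      c(W = 0.10, N1 = 0.05, N2 = 0.35, N3 = 0.20, REM = 0.30)
  else if (age < 60) c(W = 0.15, N1 = 0.10, N2 = 0.40, N3 = 0.15, REM = 0.20)
  else               c(W = 0.25, N1 = 0.15, N2 = 0.35, N3 = 0.10, REM = 0.15)
}

# Delta (slow-wave) amplitude declines with age; children show large slow
# waves. Multiplies the N3 delta RMS.
age_delta_scale <- function(age) {
  if (is.null(age) || is.na(age)) return(1)
  if (age < 13) 1.3 else if (age < 60) 1 else 0.7
}

#' Generate a hypnogram as a first-order Markov chain
#'
#' @param n_epochs number of 30-second epochs (>= 0).
#' @param transition 5 x 5 row-stochastic transition matrix over
#'   (W, N1, N2, N3, REM).
#' @param initial initial stage distribution; defaults to the stationary
#'   distribution of `transition`.
#' @param mask_prob probability that an epoch is replaced by the mask
#'   sentinel (emulating MOVEMENT/UNKNOWN scores).
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @return a [stage_sequence()].
#' @export
generate_hypnogram <- function(n_epochs, transition = stage_transition_matrix(),
                               initial = NULL, mask_prob = 0, seed = NULL) {
  if (n_epochs < 0) stop("n_epochs must be >= 0")
  assert_prob_matrix(transition, "transition")
  if (is.null(initial)) initial <- stationary_distribution(transition)
  stopifnot(length(initial) == 5, all(initial >= -1e-12))
  initial <- pmax(initial, 0); initial <- initial / sum(initial)
  with_seed(seed, {
    labs <- integer(n_epochs)
    if (n_epochs > 0) {
      s <- sample.int(5L, 1L, prob = initial)
      labs[1] <- s
      if (n_epochs > 1) for (t in 2:n_epochs) {
        s <- sample.int(5L, 1L, prob = transition[s, ])
        labs[t] <- s
      }
    }
    labs <- labs - 1L
    if (mask_prob > 0 && n_epochs > 0) {
      m <- runif(n_epochs) < mask_prob
      labs[m] <- MASK_CODE
    }
    stage_sequence(labs)
  })
}

#' Stationary distribution of a stochastic matrix
#'
#' Left eigenvector of the transition matrix for eigenvalue 1, normalized to
#' a probability vector.
#' @param transition row-stochastic square matrix.
#' @export
stationary_distribution <- function(transition) {
  assert_prob_matrix(transition, "transition")
  e <- eigen(t(transition))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v <- v / sum(v)
  stats::setNames(pmax(v, 0) / sum(pmax(v, 0)), rownames(transition))
}

#' Signal-generator parameters
#'
#' Defines the per-stage spectral content of the synthetic EEG/EOG signals:
#' a pink-noise floor everywhere, alpha (8-12 Hz) in wake, theta (4-7 Hz) in
#' N1 and REM, delta (0.5-4 Hz) rising from N2 to N3, 13 Hz spindle packets
#' at Poisson times in N2, and large slow EOG deflections in wake and REM.
#' Amplitudes are in arbitrary units (the preprocessing rescales them away);
#' their ratios were chosen so that stages are separable from bandpower at
#' desk scale.
#'
#' @param noise_rms RMS of the 1/f noise floor on every electrode.
#' @param mastoid_mix attenuation of the same-side scalp average carried by
#'   the mastoids.
#' @param spindle_rate expected spindle packets per 30 s N2 epoch.
#' @export
default_gen_params <- function(noise_rms = 10, mastoid_mix = 0.2,
                               spindle_rate = 3) {
  list(
    noise_rms = noise_rms,
    mastoid_mix = mastoid_mix,
    # per-stage EEG band components: list of c(f_lo, f_hi, rms)
    eeg_bands = list(
      W   = list(c(8, 12, 12)),
      N1  = list(c(4, 7, 8)),
      N2  = list(c(0.5, 4, 8)),
      N3  = list(c(0.5, 4, 25)),
      REM = list(c(4, 7, 8))
    ),
    spindle = list(freq = 13, rate = spindle_rate, dur_s = 1, rms = 14),
    # slow, large EOG deflections (blinks / rapid eye movements)
    eog_bands = list(
      W   = list(c(0.3, 2, 30)),
      REM = list(c(0.3, 2, 36))
    )
  )
}

# Band-limited Gaussian noise via FFT masking, scaled to a target RMS.
band_noise <- function(n, fs, f_lo, f_hi, rms) {
  if (n == 0) return(numeric(0))
  x <- rnorm(n)
  f <- (seq_len(n) - 1) / n * fs
  f <- pmin(f, fs - f)                       # two-sided frequency axis
  keep <- f >= f_lo & f <= f_hi
  if (!any(keep)) keep[which.min(abs(f - (f_lo + f_hi) / 2))] <- TRUE
  X <- fft(x); X[!keep] <- 0
  y <- Re(fft(X, inverse = TRUE)) / n
  s <- sqrt(mean(y^2))
  if (s > 0) y * (rms / s) else y
}

# 1/f amplitude noise floor.
pink_noise <- function(n, fs, rms) {
  if (n == 0) return(numeric(0))
  x <- rnorm(n)
  f <- (seq_len(n) - 1) / n * fs
  f <- pmin(f, fs - f)
  amp <- 1 / sqrt(pmax(f, fs / n))
  amp[1] <- 0
  X <- fft(x) * amp
  y <- Re(fft(X, inverse = TRUE)) / n
  y * (rms / sqrt(mean(y^2)))
}

# Gaussian-windowed spindle packets at Poisson times within one epoch.
spindle_burst <- function(n, fs, sp) {
  y <- numeric(n)
  k <- rpois(1, sp$rate)
  if (k == 0) return(y)
  half <- round(sp$dur_s * fs / 2)
  tt <- seq(-half, half) / fs
  win <- exp(-0.5 * (tt / (sp$dur_s / 4))^2)
  for (j in seq_len(k)) {
    c0 <- sample.int(n, 1)
    phase <- runif(1, 0, 2 * pi)
    pkt <- win * sin(2 * pi * sp$freq * tt + phase)
    pkt <- pkt * (sp$rms / sqrt(mean(pkt^2)))
    idx <- (c0 - half):(c0 + half)
    ok <- idx >= 1 & idx <= n
    y[idx[ok]] <- y[idx[ok]] + pkt[ok]
  }
  y
}

#' Synthesize a multi-channel PSG recording for a hypnogram
#'
#' Builds per-electrode referential signals whose spectral content follows
#' the stage sequence: each scored epoch receives the stage's band
#' components (independent realizations per electrode, so derivations do
#' not cancel), masked epochs carry the noise floor only, mastoids carry an
#' attenuated copy of the same-side scalp average plus independent noise,
#' and EOG electrodes carry slow deflections in W and REM. Optional
#' center effects (gain, low-pass filtering) are applied last.
#'
#' @param hypnogram a [stage_sequence()].
#' @param electrodes electrode labels; see [default_electrodes()].
#' @param gen_params see [default_gen_params()].
#' @param fs sampling rate in Hz.
#' @param seed integer seed or `NULL`.
#' @param age subject age in years (scales slow-wave amplitude), or `NULL`.
#' @param center_params list with `gain` (> 0) and optional `lowpass` (Hz).
#' @param ... metadata forwarded to [psg_recording()].
#' @return a [psg_recording()].
#' @export
synthesize_recording <- function(hypnogram, electrodes = default_electrodes(),
                                 gen_params = default_gen_params(), fs = 128,
                                 seed = NULL, age = NULL,
                                 center_params = NULL, ...) {
  if (!length(electrodes)) stop("empty electrode list")
  if (fs <= 0) stop("fs must be positive")
  if (!inherits(hypnogram, "stage_sequence"))
    hypnogram <- stage_sequence(hypnogram)
  ne <- length(hypnogram)
  i <- as.integer(30 * fs)
  n <- ne * i
  eog <- intersect(electrodes, c("E1", "E2"))
  mast <- intersect(electrodes, c("M1", "M2"))
  scalp <- setdiff(electrodes, c(eog, mast))
  dscale <- age_delta_scale(age)
  with_seed(seed, {
    sig <- matrix(0, length(electrodes), n,
                  dimnames = list(electrodes, NULL))
    for (el in electrodes) sig[el, ] <- pink_noise(n, fs, gen_params$noise_rms)
    add_epoch <- function(el, ep, comp) {
      a <- (ep - 1L) * i + 1L
      sig[el, a:(a + i - 1L)] <<- sig[el, a:(a + i - 1L)] + comp
    }
    labs <- unclass(hypnogram)
    for (ep in seq_len(ne)) {
      s <- labs[ep]
      if (s == MASK_CODE) next
      sname <- stage_levels()[s + 1L]
      for (el in scalp) {
        for (bd in gen_params$eeg_bands[[sname]] %||% list()) {
          rms <- bd[3] * if (sname == "N3") dscale else 1
          add_epoch(el, ep, band_noise(i, fs, bd[1], bd[2], rms))
        }
        if (sname == "N2")
          add_epoch(el, ep, spindle_burst(i, fs, gen_params$spindle))
      }
      for (el in eog) {
        for (bd in gen_params$eog_bands[[sname]] %||% list())
          add_epoch(el, ep, band_noise(i, fs, bd[1], bd[2], bd[3]))
      }
    }
    # mastoids: attenuated same-side scalp average + independent noise
    side <- list(M1 = c("F3", "C3", "O1"), M2 = c("F4", "C4", "O2"))
    for (m in mast) {
      nb <- intersect(side[[m]], scalp)
      if (!length(nb)) nb <- scalp
      if (length(nb))
        sig[m, ] <- sig[m, ] +
          gen_params$mastoid_mix * colMeans(sig[nb, , drop = FALSE])
    }
    if (!is.null(center_params)) {
      gain <- center_params$gain %||% 1
      if (gain <= 0) stop("center gain must be positive")
      if (!is.null(center_params$lowpass)) {
        bf <- signal::butter(2, min(center_params$lowpass / (fs / 2), 0.99))
        for (r in seq_len(nrow(sig)))
          sig[r, ] <- signal::filtfilt(bf, sig[r, ])
      }
      sig <- sig * gain
    }
    psg_recording(sig, fs, electrodes, hypnogram, age = age,
                  center_params = center_params, ...)
  })
}

#' Cohort specification for the synthetic generator
#'
#' Describes a multi-dataset (multi-center) study: per dataset the number of
#' subjects, recordings per subject, epochs per recording, an age range and
#' center effects (hardware gain/filter, scorer confusion matrix).
#'
#' @param datasets list of per-dataset lists; each may contain `name`,
#'   `n_subjects`, `n_recordings` (per subject), `n_epochs` (scalar or
#'   range), `age_range` (years), `transition` (5 x 5; default derived from
#'   the drawn age via [age_stage_prior()]), `gain`, `lowpass`,
#'   `scorer_confusion` (5 x 5 row-stochastic), `mask_prob`.
#' @param fs sampling rate in Hz.
#' @param electrodes electrode labels.
#' @param gen_params see [default_gen_params()].
#' @param seed integer seed for the whole cohort.
#' @export
cohort_spec <- function(datasets, fs = 128,
                        electrodes = default_electrodes(),
                        gen_params = default_gen_params(), seed = 1L) {
  if (!length(datasets)) stop("at least one dataset required")
  for (d in datasets) {
    if ((d$n_subjects %||% 0) < 1) stop("zero subjects in a dataset")
    if (!is.null(d$transition)) assert_prob_matrix(d$transition, "transition")
    if (!is.null(d$scorer_confusion))
      assert_prob_matrix(d$scorer_confusion, "scorer_confusion")
    if ((d$gain %||% 1) <= 0) stop("center gains must be > 0")
  }
  structure(list(datasets = datasets, fs = fs, electrodes = electrodes,
                 gen_params = gen_params, seed = seed),
            class = "cohort_spec")
}

#' Uniform scorer-confusion matrix
#'
#' With probability `error` the stored label of a scored epoch is replaced
#' by one of the other four stages uniformly; emulates inter-scorer
#' disagreement.
#' @param error off-diagonal mass per row.
#' @export
scorer_confusion_matrix <- function(error = 0.2) {
  stopifnot(error >= 0, error <= 1)
  P <- matrix(error / 4, 5, 5); diag(P) <- 1 - error
  dimnames(P) <- list(stage_levels(), stage_levels())
  P
}

apply_scorer_noise <- function(labels, confusion) {
  labs <- unclass(labels)
  out <- labs
  for (t in seq_along(labs)) {
    if (labs[t] == MASK_CODE) next
    out[t] <- sample.int(5L, 1L, prob = confusion[labs[t] + 1L, ]) - 1L
  }
  stage_sequence(out)
}

#' Generate a seeded synthetic PSG cohort
#'
#' Realizes a [cohort_spec()]: per dataset and subject, draws an age,
#' simulates a hypnogram from the (age-adjusted) transition matrix,
#' synthesizes the signals with the dataset's center effects, and optionally
#' corrupts the stored labels with the scorer confusion matrix (the latent
#' labels are retained in `latent_hypnogram` for diagnostics). Identical
#' spec and seed give an identical cohort.
#'
#' @param spec a [cohort_spec()].
#' @return a [psg_cohort()].
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  recs <- list()
  k <- 0L
  for (di in seq_along(spec$datasets)) {
    d <- spec$datasets[[di]]
    dname <- d$name %||% paste0("D", di)
    for (si in seq_len(d$n_subjects)) {
      sid <- sprintf("%s_S%02d", dname, si)
      sseed <- derive_seed(spec$seed, 1000L * di + si)
      age <- with_seed(sseed, {
        ar <- d$age_range %||% c(25, 60)
        if (length(ar) == 1) ar else round(runif(1, ar[1], ar[2]), 1)
      })
      trans <- d$transition %||%
        stage_transition_matrix(age_stage_prior(age))
      for (ri in seq_len(d$n_recordings %||% 1L)) {
        k <- k + 1L
        rseed <- derive_seed(sseed, ri)
        nep <- d$n_epochs %||% 80L
        hyp <- with_seed(rseed, {
          if (length(nep) > 1) nep <- sample(nep[1]:nep[2], 1)
          generate_hypnogram(nep, trans, mask_prob = d$mask_prob %||% 0)
        })
        cp <- list(gain = d$gain %||% 1, lowpass = d$lowpass,
                   scorer_confusion = d$scorer_confusion)
        rec <- synthesize_recording(
          hyp, spec$electrodes, spec$gen_params, spec$fs,
          seed = derive_seed(rseed, 7L), age = age, center_params = cp,
          subject_id = sid, family_id = d$family_of %||% sid,
          dataset_id = dname, center_id = dname,
          recording_id = sprintf("%s_r%d", sid, ri))
        if (!is.null(d$scorer_confusion)) {
          rec$latent_hypnogram <- rec$hypnogram
          rec$hypnogram <- with_seed(derive_seed(rseed, 13L),
            apply_scorer_noise(rec$latent_hypnogram, d$scorer_confusion))
        }
        recs[[k]] <- rec
      }
    }
  }
  psg_cohort(recs)
}

#' Log-bandpower features of 30-second epochs
#'
#' Per-epoch, per-channel log power in the canonical EEG bands (delta
#' 0.5-4, theta 4-7, alpha 8-12, sigma 12-14 Hz) plus the slow EOG band
#' (0.3-2 Hz), computed from the periodogram. These features drive the
#' nearest-centroid separability diagnostic and are a useful sanity check
#' that a generated cohort carries stage information.
#'
#' @param signals channel-by-sample matrix covering whole epochs.
#' @param fs sampling rate in Hz.
#' @return matrix: epochs x (channels * bands) of log10 band powers.
#' @export
bandpower_features <- function(signals, fs) {
  bands <- list(delta = c(0.5, 4), theta = c(4, 7), alpha = c(8, 12),
                sigma = c(12, 14), slow = c(0.3, 2))
  i <- as.integer(30 * fs)
  ne <- ncol(signals) %/% i
  out <- matrix(NA_real_, ne, nrow(signals) * length(bands))
  cn <- as.vector(outer(names(bands), rownames(signals) %||%
                          paste0("ch", seq_len(nrow(signals))),
                        function(b, c) paste(c, b, sep = ".")))
  colnames(out) <- cn
  f <- (seq_len(i) - 1) / i * fs
  keepers <- lapply(bands, function(b) f >= b[1] & f < b[2] & f <= fs / 2)
  for (ep in seq_len(ne)) {
    seg <- signals[, ((ep - 1) * i + 1):(ep * i), drop = FALSE]
    col <- 0L
    for (ch in seq_len(nrow(signals))) {
      px <- Mod(fft(seg[ch, ]))^2 / i
      for (b in seq_along(bands)) {
        col <- col + 1L
        out[ep, col] <- log10(sum(px[keepers[[b]]]) + 1e-12)
      }
    }
  }
  out
}

#' Nearest-centroid stage classification from bandpower
#'
#' Fits per-stage centroids of standardized [bandpower_features()] on one
#' set of epochs and classifies another; used as the package's separability
#' diagnostic (a generated recording should be stage-classifiable from
#' bandpower alone well above chance).
#'
#' @param train_x,train_y feature matrix and integer stage labels (0-4).
#' @param test_x feature matrix to classify.
#' @return integer vector of predicted stage codes.
#' @export
nearest_centroid_stages <- function(train_x, train_y, test_x) {
  mu <- colMeans(train_x); sdv <- apply(train_x, 2, sd); sdv[sdv == 0] <- 1
  zs <- function(m) sweep(sweep(m, 2, mu), 2, sdv, "/")
  trz <- zs(train_x); tez <- zs(test_x)
  stages <- sort(unique(train_y))
  cent <- t(vapply(stages, function(s) colMeans(trz[train_y == s, , drop = FALSE]),
                   numeric(ncol(trz))))
  d2 <- vapply(seq_along(stages), function(j)
    rowSums(sweep(tez, 2, cent[j, ])^2), numeric(nrow(tez)))
  stages[max.col(-d2)]
}
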