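#' Preprocessing configuration
#'
#' @param target_fs target sampling rate in Hz (128 by convention).
#' @param clip_k clipping bound in multiples of the IQR after scaling.
#' @param iqr_type quartile interpolation rule passed to
#'   [stats::quantile()]; type 7 (linear interpolation) is the fixed
#'   default so results are exactly reproducible.
#' @export
prep_config <- function(target_fs = 128, clip_k = 20, iqr_type = 7) {
  stopifnot(target_fs > 0, clip_k > 0)
  structure(list(target_fs = target_fs, clip_k = clip_k,
                 iqr_type = iqr_type), class = "prep_config")
}

#' Resample a channel to a new sampling rate
#'
#' Rational-ratio polyphase resampling: the signal is upsampled by zero
#' stuffing, low-pass filtered with a zero-phase (delay-compensated)
#' Kaiser-window FIR at the tighter of the two Nyquist limits, and
#' decimated. Output length is `round(n * fs_out / fs_in)`.
#'
#' @param x numeric signal vector.
#' @param fs_in,fs_out sampling rates in Hz (> 0).
#' @export
resample_channel <- function(x, fs_in, fs_out) {
  if (fs_in <= 0 || fs_out <= 0) stop("sampling rates must be positive")
  if (!length(x)) stop("empty signal")
  if (fs_in == fs_out) return(x)
  # rational ratio: scale to integers, reduce by gcd
  s <- 1e6
  a <- round(fs_out * s); b <- round(fs_in * s)
  g <- function(u, v) if (v == 0) u else Recall(v, u %% v)
  d <- g(a, b)
  p <- a / d; q <- b / d
  n <- length(x)
  up <- numeric(n * p)
  up[seq(1, n * p, by = p)] <- x
  # Kaiser-window low-pass at 1/max(p,q) of the upsampled Nyquist
  fc <- 1 / max(p, q)
  M <- 10 * max(p, q)                 # half-length: 10 zero crossings
  m <- (-M):M
  h <- fc * ifelse(m == 0, 1, sin(pi * fc * m) / (pi * fc * m))
  beta <- 7.8562                      # ~80 dB sidelobe attenuation
  w <- besselI(beta * sqrt(pmax(1 - (m / M)^2, 0)), 0) / besselI(beta, 0)
  h <- h * w
  h <- h / sum(h) * p                 # unit DC gain after zero stuffing
  # centered (zero-phase) FIR convolution via FFT
  y <- stats::convolve(up, rev(h), type = "open")[(M + 1):(M + n * p)]
  y <- y[seq(1, n * p, by = q)]
  n_out <- round(n * fs_out / fs_in)
  if (length(y) >= n_out) y[seq_len(n_out)]
  else c(y, rep(y[length(y)], n_out - length(y)))
}

#' Robust per-channel scaling with clipping
#'
#' Centers a channel at median 0 and scales it to inter-quartile range 1,
#' then clips absolute values above `clip_k` (so outputs lie in
#' `[-clip_k, clip_k]`). Constant-like channels (IQR ~ 0) are centered only,
#' with a warning.
#'
#' @param x numeric channel.
#' @param config a [prep_config()].
#' @export
robust_scale <- function(x, config = prep_config()) {
  if (!length(x)) stop("empty channel")
  med <- stats::median(x)
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE,
                       type = config$iqr_type)
  iqr <- q[2] - q[1]
  if (iqr <= .Machine$double.eps * max(1, abs(med))) {
    warning("IQR is zero; channel centered but not scaled")
    return(x - med)
  }
  y <- (x - med) / iqr
  pmin(pmax(y, -config$clip_k), config$clip_k)
}

#' Trim signals to the scored hypnogram range
#'
#' Drops samples before `hypnogram_start_epoch` and after the last scored
#' epoch so that `n_samples == 30 * fs * length(hypnogram)`.
#'
#' @param recording a [psg_recording()].
#' @export
trim_to_hypnogram <- function(recording) {
  i <- epoch_samples_of(recording)
  start <- recording$hypnogram_start_epoch
  need <- (start + length(recording$hypnogram)) * i
  if (ncol(recording$signals) < need)
    stop("hypnogram extends beyond the recorded signal")
  a <- start * i + 1L
  recording$signals <-
    recording$signals[, a:(a + length(recording$hypnogram) * i - 1L),
                      drop = FALSE]
  recording$hypnogram_start_epoch <- 0L
  recording
}

#' Preprocess a recording
#'
#' The standard chain: resample every channel to `target_fs`, trim the
#' signals to the scored hypnogram, and robust-scale each channel
#' (median 0, IQR 1, clipped at `clip_k`). No band-pass filtering is
#' applied. Scaling is per channel and per recording.
#'
#' @param recording a [psg_recording()].
#' @param config a [prep_config()].
#' @return the preprocessed [psg_recording()].
#' @export
preprocess_recording <- function(recording, config = prep_config()) {
  if (recording$fs != config$target_fs) {
    sig <- t(apply(recording$signals, 1, resample_channel,
                   fs_in = recording$fs, fs_out = config$target_fs))
    rownames(sig) <- recording$electrodes
    recording$signals <- sig
    recording$fs <- config$target_fs
  }
  recording <- trim_to_hypnogram(recording)
  for (r in seq_len(nrow(recording$signals)))
    recording$signals[r, ] <- robust_scale(recording$signals[r, ], config)
  recording
}

#' @rdname preprocess_recording
#' @param cohort a [psg_cohort()].
#' @export
preprocess_cohort <- function(cohort, config = prep_config()) {
  psg_cohort(lapply(cohort, preprocess_recording, config = config))
}
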