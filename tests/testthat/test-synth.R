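test_that("hypnogram generation follows the Markov model", {
  # absorbing chain: identity transition from a fixed start stays put
  hyp <- generate_hypnogram(10, diag(5), initial = c(0, 0, 1, 0, 0), seed = 1)
  expect_equal(as.integer(hyp), rep(2L, 10))
  expect_length(generate_hypnogram(0, seed = 1), 0)

  # ergodic chain: empirical frequencies match the eigenvector stationary
  # distribution within 3 standard errors
  P <- stage_transition_matrix(c(0.2, 0.1, 0.35, 0.15, 0.2), 0.6)
  pi_hat <- stationary_distribution(P)
  n <- 1e5
  hyp <- generate_hypnogram(n, P, seed = 7)
  freq <- tabulate(unclass(hyp) + 1L, 5) / n
  # the chain is autocorrelated (persistence 0.6): inflate the iid
  # standard error by sqrt((1 + rho) / (1 - rho)) = 2
  se <- 2 * sqrt(pi_hat * (1 - pi_hat) / n)
  expect_true(all(abs(freq - pi_hat) < 3 * se + 1e-12))

  expect_error(generate_hypnogram(5, matrix(1, 5, 5)), "sum to 1")
  expect_identical(unclass(generate_hypnogram(50, P, seed = 3)),
                   unclass(generate_hypnogram(50, P, seed = 3)))
})

test_that("synthesized signals honor the per-stage spectral contract", {
  hyp <- stage_sequence(c(rep(3L, 20), rep(0L, 20)))   # 20 N3 then 20 W
  rec <- synthesize_recording(hyp, fs = FIX_FS, seed = 5)
  expect_equal(ncol(rec$signals), 40 * 30 * FIX_FS)
  i <- 30 * FIX_FS
  eeg <- setdiff(rec$electrodes, c("M1", "M2", "E1", "E2"))
  for (el in eeg) {
    x <- rec$signals[el, ]
    d_n3 <- mean(vapply(1:20, function(ep)
      oracle_bandpower(x[((ep - 1) * i + 1):(ep * i)], FIX_FS, 0.5, 4), 0))
    d_w <- mean(vapply(21:40, function(ep)
      oracle_bandpower(x[((ep - 1) * i + 1):(ep * i)], FIX_FS, 0.5, 4), 0))
    expect_gt(d_n3, d_w)
  }
  # alpha band dominates in W relative to N3 on EEG
  x <- rec$signals["C3", ]
  a_w <- mean(vapply(21:40, function(ep)
    oracle_bandpower(x[((ep - 1) * i + 1):(ep * i)], FIX_FS, 8, 12), 0))
  a_n3 <- mean(vapply(1:20, function(ep)
    oracle_bandpower(x[((ep - 1) * i + 1):(ep * i)], FIX_FS, 8, 12), 0))
  expect_gt(a_w, a_n3)

  # determinism and length arithmetic
  rec2 <- synthesize_recording(hyp, fs = FIX_FS, seed = 5)
  expect_identical(rec$signals, rec2$signals)
  rec3 <- synthesize_recording(stage_sequence(rep(2L, 4)), fs = 128, seed = 1)
  expect_equal(ncol(rec3$signals), 4 * 30 * 128)
  expect_error(synthesize_recording(hyp, electrodes = character(0)), "empty")
})

test_that("cohort generation applies center gain and age effects", {
  # dataset sizes and tags
  cs <- cohort_spec(list(list(name = "A", n_subjects = 3),
                         list(name = "B", n_subjects = 3)),
                    fs = FIX_FS, seed = 2)
  co <- generate_cohort(cs)
  expect_length(co, 6)
  expect_equal(sum(cohort_dataset_ids(co) == "A"), 3)

  # center B gain = 2x center A, identical otherwise -> RMS ratio ~ 2
  mk <- function(gain, seed) {
    cs <- cohort_spec(list(list(name = "X", n_subjects = 10, n_epochs = 20,
                                gain = gain,
                                transition = stage_transition_matrix())),
                      fs = FIX_FS, seed = seed)
    generate_cohort(cs)
  }
  ca <- mk(1, 77); cb <- mk(2, 77)
  rms <- function(co) mean(vapply(co, function(r) sqrt(mean(r$signals^2)), 0))
  expect_gt(rms(cb) / rms(ca), 1.9)
  expect_lt(rms(cb) / rms(ca), 2.1)

  # children cohorts carry more REM than elderly cohorts
  mk_age <- function(ages, seed) {
    cs <- cohort_spec(list(list(name = "G", n_subjects = 20, n_epochs = 40,
                                age_range = ages)),
                      fs = FIX_FS, seed = seed)
    generate_cohort(cs)
  }
  remfrac <- function(co) mean(vapply(co, function(r)
    mean(unclass(r$hypnogram) == 4L), 0))
  expect_gt(remfrac(mk_age(c(2, 8), 31)), remfrac(mk_age(c(65, 80), 31)))

  expect_error(cohort_spec(list(list(n_subjects = 0))), "zero subjects")
  expect_error(cohort_spec(list(list(n_subjects = 2, gain = -1))), "gain")
})

test_that("identical spec and seed reproduce the cohort exactly", {
  cs <- cohort_spec(list(list(name = "A", n_subjects = 2, n_epochs = 15)),
                    fs = FIX_FS, seed = 42)
  expect_identical(generate_cohort(cs), generate_cohort(cs))
})

test_that("scorer noise matches the confusion matrix off-diagonal mass", {
  err <- 0.25
  cs <- cohort_spec(list(list(name = "A", n_subjects = 10, n_epochs = 60,
                              scorer_confusion = scorer_confusion_matrix(err))),
                    fs = FIX_FS, seed = 13)
  co <- generate_cohort(cs)
  mism <- unlist(lapply(co, function(r) {
    lat <- unclass(r$latent_hypnogram)
    sto <- unclass(r$hypnogram)
    (lat != sto)[lat >= 0]
  }))
  n <- length(mism)
  se <- sqrt(err * (1 - err) / n)
  expect_lt(abs(mean(mism) - err), 3 * se)
})

test_that("generated recordings are stage-separable from bandpower", {
  rec <- fixture_recording()
  labs <- unclass(rec$hypnogram)
  feats <- bandpower_features(rec$signals, rec$fs)
  keep <- labs >= 0
  idx <- which(keep)
  tr <- idx[seq(1, length(idx), 2)]
  te <- idx[seq(2, length(idx), 2)]
  pred <- nearest_centroid_stages(feats[tr, ], labs[tr], feats[te, , drop = FALSE])
  expect_gt(mean(pred == labs[te]), 0.8)
})

test_that("EDF and hypnogram CSV round-trip a recording", {
  hyp <- generate_hypnogram(6, seed = 3, mask_prob = 0.2)
  rec <- synthesize_recording(hyp, fs = FIX_FS, seed = 3)
  f <- tempfile(fileext = ".edf")
  write_edf(rec, f)
  back <- read_edf(f)
  expect_equal(back$fs, FIX_FS)
  expect_identical(rownames(back$signals), rec$electrodes)
  # 16-bit quantization over the physical range
  tol <- max(abs(range(rec$signals))) / 32767 * 2.1
  expect_lt(max(abs(back$signals - rec$signals)), tol)

  g <- tempfile(fileext = ".csv")
  write_hypnogram_csv(hyp, g)
  expect_identical(unclass(read_hypnogram_csv(g)), unclass(hyp))

  h <- tempfile(fileext = ".rds")
  write_psg_container(rec, h)
  expect_identical(read_psg_container(h), rec)
  unlink(c(f, g, h))
})
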