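test_that("dataset sampling follows the alpha-mixture law", {
  expect_equal(dataset_probabilities(c(100, 300), alpha = 0.5),
               c(0.375, 0.625))
  expect_equal(dataset_probabilities(c(10, 99, 1), alpha = 1),
               rep(1 / 3, 3))
  expect_equal(sample_dataset(5, seed = 1), 1)
  expect_error(sample_dataset(integer(0)), "at least one")

  # empirical frequencies at 1e5 draws within 3 SE of P(D)
  p <- dataset_probabilities(c(100, 300), 0.5)
  n <- 1e5
  draws <- psgres:::with_seed(42, vapply(seq_len(n), function(i)
    sample_dataset(c(100, 300), 0.5), 0L))
  freq <- tabulate(draws, 2) / n
  se <- sqrt(p * (1 - p) / n)
  expect_true(all(abs(freq - p) < 3 * se))
  # chi-square goodness of fit is not rejected at 0.001
  expect_gt(stats::chisq.test(tabulate(draws, 2), p = p)$p.value, 0.001)
})

test_that("segment sampling is class-balanced and in-bounds", {
  rec <- fixture_recording()
  L <- 6
  ne <- length(rec$hypnogram)
  labs <- unclass(rec$hypnogram)
  present <- sort(unique(labs[labs >= 0]))
  draws <- lapply(1:2000, function(i) sample_segment(rec, L, seed = i))
  starts <- vapply(draws, `[[`, 0L, "epoch_start")
  expect_true(all(starts >= 1 & starts <= ne - L + 1))
  cls <- vapply(draws, `[[`, 0L, "anchor_class")
  freq <- table(factor(cls, present)) / length(cls)
  p <- 1 / length(present)
  expect_true(all(abs(freq - p) < 3 * sqrt(p * (1 - p) / length(cls))))
  # anchor epoch always carries the anchor class
  for (d in draws[1:50])
    expect_equal(labs[d$anchor_epoch], d$anchor_class)

  # single-class recording always anchors that class
  rec_n2 <- synthesize_recording(stage_sequence(rep(2L, 10)), fs = FIX_FS,
                                 seed = 2)
  expect_equal(sample_segment(rec_n2, 4, seed = 1)$anchor_class, 2)

  expect_error(sample_segment(rec, ne + 1), "shorter")
  rec_masked <- synthesize_recording(stage_sequence(rep(-1L, 10)),
                                     fs = FIX_FS, seed = 1)
  expect_error(sample_segment(rec_masked, 4), "masked")
})

test_that("augmentation replaces spans with the configured noise law", {
  X <- matrix(rnorm(2000), 1000, 2)
  # seed yielding no events (event draws above the probabilities)
  none <- augment_params(event_prob = 0, whole_channel_prob = 0)
  expect_identical(apply_augmentation(X, none, seed = 1), X)

  # forced events: replaced fraction within the log-uniform bounds and
  # replacement variance near noise_var
  always <- augment_params(event_prob = 1, whole_channel_prob = 0)
  fracs <- numeric(300); repl <- c()
  for (i in 1:300) {
    Y <- apply_augmentation(X, always, seed = i)
    changed <- which(rowSums(Y != X) > 0)
    fracs[i] <- length(changed) / nrow(X)
    # contiguity of the replaced span
    expect_equal(changed, seq(min(changed), max(changed)))
    repl <- c(repl, Y[changed, ])
  }
  expect_true(all(fracs >= 0.001 - 1e-9 & fracs <= 0.33 + 1 / nrow(X)))
  # moment check: sd of replacements ~ sqrt(0.01), mean ~ mean(X)
  expect_lt(abs(sd(repl) - 0.1), 3 * 0.1 / sqrt(2 * length(repl)) + 0.002)
  expect_lt(abs(mean(repl) - mean(X)), 3 * 0.1 / sqrt(length(repl)) + 1e-3)

  # whole-channel replacement touches exactly one channel
  chan <- augment_params(event_prob = 0, whole_channel_prob = 1)
  Y <- apply_augmentation(X, chan, seed = 4)
  touched <- which(colSums(Y != X) > 0)
  expect_length(touched, 1)
  expect_true(all(Y[, touched] != X[, touched]))
})

test_that("batches compose the hierarchical sampler", {
  cohort <- fixture_cohort()
  cfg <- sampler_config(L = 4, batch_size = 5)
  b <- make_batch(cohort, cfg, seed = 11)
  i <- 30 * FIX_FS
  expect_equal(dim(b$X), c(5, 4 * i, 2))
  expect_equal(dim(b$y), c(5, 4))
  expect_identical(b$mask, b$y != -1L)
  expect_true(all(b$y %in% c(-1L, 0:4)))
  expect_equal(b$g, rep(1L, 5))

  # determinism / decorrelation
  b2 <- make_batch(cohort, cfg, seed = 11)
  expect_identical(b$X, b2$X)
  b3 <- make_batch(cohort, cfg, seed = 12)
  expect_false(identical(b$X, b3$X))

  # single-recording cohort: every row drawn from it
  solo <- cohort[1]
  bs <- make_batch(solo, cfg, seed = 3)
  expect_true(all(bs$meta$recording == solo[[1]]$recording_id))

  # labels in the batch match the recording's hypnogram at the window
  rec_by_id <- setNames(unclass(cohort),
                        vapply(cohort, `[[`, "", "recording_id"))
  for (r in 1:5) {
    rec <- rec_by_id[[b$meta$recording[r]]]
    s <- b$meta$epoch_start[r]
    expect_equal(b$y[r, ], unclass(rec$hypnogram)[s:(s + 3)])
  }

  # atypical mode redraws random derivations
  cfga <- sampler_config(L = 4, batch_size = 8,
                         derivation_mode = "atypical")
  ba <- make_batch(cohort, cfga, seed = 5)
  expect_gt(length(unique(ba$meta$eeg)), 1)
})

test_that("recording selection within a dataset is uniform", {
  cohort <- fixture_cohort()[1:2]     # two recordings, same dataset
  cfg <- sampler_config(L = 4, batch_size = 4)
  picks <- unlist(lapply(1:400, function(i)
    make_batch(cohort, cfg, seed = i)$meta$recording))
  freq <- table(picks) / length(picks)
  expect_lt(max(abs(freq - 0.5)), 3 * sqrt(0.25 / length(picks)))
})
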