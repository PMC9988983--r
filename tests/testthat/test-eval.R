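test_that("stage F1 matches hand-computed and brute-force values", {
  # W W N2 N2 REM vs W N2 N2 N2 REM
  yt <- c(0, 0, 2, 2, 4); yp <- c(0, 2, 2, 2, 4)
  r <- stage_f1(yt, yp)
  expect_equal(unname(r$per_class[c("W", "N2", "REM")]),
               c(2 / 3, 0.8, 1))
  expect_equal(r$aggregate, 100 * mean(c(2 / 3, 0.8, 1)), tolerance = 1e-10)

  expect_equal(stage_f1(yt, yt)$aggregate, 100)
  expect_equal(stage_f1(c(0, 0, 0), c(2, 2, 2))$aggregate, 0)

  # masked positions are dropped before scoring
  expect_equal(stage_f1(c(-1, yt), c(3, yp))$aggregate, r$aggregate)

  # brute-force cross-check on random label pairs
  set.seed(21)
  for (rep in 1:200) {
    n <- sample(10:60, 1)
    yt <- sample(c(-1L, 0:4), n, TRUE)
    yp <- sample(0:4, n, TRUE)
    if (!any(yt >= 0)) next
    expect_equal(stage_f1(yt, yp)$aggregate, brute_f1(yt, yp),
                 tolerance = 1e-12)
    expect_equal(stage_f1(yt, yp, "weighted")$aggregate,
                 brute_f1(yt, yp, weighted = TRUE), tolerance = 1e-12)
  }
})

test_that("weighted F1 dominates unweighted when rare classes score worst", {
  # construct predictions that are perfect on the abundant class and wrong
  # on the rare ones
  yt <- c(rep(2, 80), rep(1, 10), rep(4, 10))
  yp <- c(rep(2, 80), rep(4, 10), rep(1, 10))
  expect_gt(stage_f1(yt, yp, "weighted")$aggregate,
            stage_f1(yt, yp, "unweighted")$aggregate)
})

test_that("metrics are invariant to permuting pairs in unison", {
  set.seed(5)
  yt <- sample(0:4, 100, TRUE); yp <- sample(0:4, 100, TRUE)
  p <- sample(100)
  expect_equal(stage_f1(yt, yp)$aggregate, stage_f1(yt[p], yp[p])$aggregate)
  expect_equal(cohens_kappa(yt, yp), cohens_kappa(yt[p], yp[p]))
})

test_that("Cohen's kappa matches its definition and chance behavior", {
  expect_equal(cohens_kappa(c(0, 1, 2, 3), c(0, 1, 2, 3)), 1)
  # p_o = 0.5, p_e = 0.5 -> kappa 0
  expect_equal(cohens_kappa(c(0, 0, 2, 2), c(0, 2, 0, 2)), 0)
  # independent uniform labels: kappa near 0
  set.seed(8)
  yt <- sample(0:4, 1e5, TRUE); yp <- sample(0:4, 1e5, TRUE)
  expect_lt(abs(cohens_kappa(yt, yp)), 0.02)
  expect_message(k <- cohens_kappa(rep(2, 5), rep(2, 5)), "degenerate")
  expect_equal(k, 1)
  # cross-check against e1071's implementation on random tables
  skip_if_not_installed("e1071")
  for (rep in 1:100) {
    yt <- sample(0:4, 50, TRUE); yp <- sample(0:4, 50, TRUE)
    tab <- table(factor(yt, 0:4), factor(yp, 0:4))
    expect_equal(cohens_kappa(yt, yp),
                 e1071::classAgreement(tab)$kappa, tolerance = 1e-10)
  }
})

test_that("majority vote equals a brute-force per-epoch mode", {
  set.seed(3)
  for (rep in 1:20) {
    nc <- sample(1:5, 1); ne <- 100
    votes <- matrix(sample(0:4, nc * ne, TRUE), nc, ne)
    got <- majority_vote(votes)
    for (ep in 1:ne) {
      tab <- table(votes[, ep])
      best <- as.integer(names(tab)[tab == max(tab)])
      expect_true(got[ep] %in% best)
      expect_equal(got[ep], min(best))   # no probs: ties to lowest index
    }
  }
  # tie broken by higher mean probability
  votes <- matrix(c(0L, 2L), 2, 1)
  probs <- array(0.1, c(2, 1, 5))
  probs[, 1, 3] <- c(0.5, 0.6)   # N2 has the higher mean probability
  expect_equal(majority_vote(votes, probs), 2L)
  probs[, 1, 1] <- c(0.9, 0.9)   # now W does
  expect_equal(majority_vote(votes, probs), 0L)
})

test_that("recording prediction ensembles all combinations", {
  rec <- fixture_recording()
  m <- tiny_model(seed = 2)
  m$params$seg$conv_o$W[] <- rnorm(length(m$params$seg$conv_o$W), 0, 0.5)
  res <- predict_recording(m, rec, "recommended")
  expect_length(res$combinations, 12)   # 6 EEG x 2 EOG
  expect_equal(dim(res$votes), c(12, length(rec$hypnogram)))
  expect_true(all(res$labels %in% 0:4))
  # single combination: ensemble equals that combination's argmax
  tab <- aasm_derivation_table()[c(2, 7)]
  res1 <- predict_recording(m, rec, "recommended", table = tab)
  expect_length(res1$combinations, 1)
  expect_equal(res1$labels, res1$votes[1, ])
})

test_that("cohort evaluation aggregates with the population sd", {
  rec <- fixture_recording()
  m <- tiny_model(seed = 2)
  ev <- evaluate_cohort(m, list(rec, rec))
  expect_equal(ev$summary$sd, rep(0, 3))
  # mean 70, sd 10 for per-recording scores 60 and 80
  expect_equal(mean(c(60, 80)), 70)
  expect_equal(psgres:::pop_sd(c(60, 80)), 10)
  # an oracle that predicts the stored labels scores 100 with kappa 1
  yt <- unclass(rec$hypnogram)
  expect_equal(stage_f1(yt, yt)$aggregate, 100)
})

test_that("paired tests flag degeneracy and respect sidedness", {
  a <- c(70, 72, 75, 71)
  expect_true(paired_test(a, a)$degenerate)
  expect_true(is.na(paired_test(a, a)$p_value))

  set.seed(12)
  a <- rnorm(100, 70, 5)
  b <- a + 1 + rnorm(100, 0, 0.1)
  expect_lt(paired_test(a, b, "one_sided_greater")$p_value, 1e-10)
  # two-sided p is symmetric in the arguments
  expect_equal(paired_test(a, b)$p_value, paired_test(b, a)$p_value)
  # cross-check against stats::t.test
  x <- rnorm(20); y <- rnorm(20, 0.3)
  expect_equal(paired_test(x, y)$p_value,
               stats::t.test(y, x, paired = TRUE)$p.value)
})
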