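test_that("age groups follow the seven- and two-group schemes", {
  s7 <- age_group_scheme(7)
  expect_equal(s7$labels[assign_age_group(2, s7)], "B")
  expect_equal(s7$labels[assign_age_group(3.9, s7)], "B")
  expect_equal(s7$labels[assign_age_group(4, s7)], "C")
  expect_equal(s7$labels[assign_age_group(12, s7)], "C")
  expect_equal(s7$labels[assign_age_group(13, s7)], "A")
  expect_equal(s7$labels[assign_age_group(19, s7)], "YA")
  expect_equal(s7$labels[assign_age_group(45, s7)], "MA")
  expect_equal(s7$labels[assign_age_group(65, s7)], "E")
  expect_equal(s7$labels[assign_age_group(70, s7)], "OE")
  expect_equal(s7$labels[assign_age_group(91, s7)], "OE")
  s2 <- age_group_scheme(2)
  expect_equal(s2$labels[assign_age_group(5, s2)], "G1")    # B u C
  expect_equal(s2$labels[assign_age_group(12.5, s2)], "G1")
  expect_equal(s2$labels[assign_age_group(30, s2)], "G2")
  expect_error(assign_age_group(NA, s7), "missing")
  expect_error(age_group_scheme(5), "G = 7 or G = 2")
})

test_that("cohort splits respect grouping and target fractions", {
  # 100 single-recording subjects split exactly 75/10/15
  recs <- lapply(1:100, function(i)
    psg_recording(matrix(0, 1, 30 * 4), fs = 4, electrodes = "C4",
                  hypnogram = stage_sequence(2L),
                  subject_id = sprintf("S%03d", i)))
  sp <- split_cohort(recs, c(0.75, 0.10, 0.15), seed = 1)
  expect_equal(lengths(sp), c(train = 75, val = 10, test = 15))

  # same seed reproduces the assignment
  sp2 <- split_cohort(recs, c(0.75, 0.10, 0.15), seed = 1)
  expect_identical(lapply(sp, function(co) vapply(co, `[[`, "", "subject_id")),
                   lapply(sp2, function(co) vapply(co, `[[`, "", "subject_id")))

  # a subject with several recordings never straddles splits
  recs2 <- unlist(lapply(1:10, function(i) lapply(1:2, function(r)
    psg_recording(matrix(0, 1, 30 * 4), fs = 4, electrodes = "C4",
                  hypnogram = stage_sequence(2L),
                  subject_id = sprintf("S%02d", i),
                  recording_id = sprintf("S%02d_r%d", i, r)))),
    recursive = FALSE)
  sp3 <- split_cohort(recs2, c(0.6, 0.2, 0.2), seed = 2)
  for (part in sp3) {
    ids <- vapply(part, `[[`, "", "subject_id")
    for (id in unique(ids)) expect_equal(sum(ids == id), 2)
  }
  expect_error(split_cohort(recs[1:2], c(0.5, 0.25, 0.25)), "fewer groups")
  expect_error(split_cohort(recs, c(0.7, 0.2, 0.2)), "sum to 1")
})

test_that("group caps bound validation and test membership", {
  recs <- lapply(1:40, function(i)
    psg_recording(matrix(0, 1, 30 * 4), fs = 4, electrodes = "C4",
                  hypnogram = stage_sequence(2L),
                  subject_id = sprintf("S%02d", i)))
  sp <- split_cohort(recs, c(0.5, 0.25, 0.25), seed = 3,
                     max_val_groups = 3, max_test_groups = 4)
  expect_lte(length(sp$val), 3)
  expect_lte(length(sp$test), 4)
  expect_equal(sum(lengths(sp)), 40)
})

test_that("a null-difference configuration yields matching twin metrics", {
  # with both 'centers' identical, the derivation-resilience report format
  # is exercised end to end at micro scale
  rep1 <- run_experiment("i", experiment_spec(
    "i", replicates = 1, seed = 5, n_subjects = 4, n_epochs = 14,
    max_iterations = 2, batches_per_iteration = 2, L = 1, batch_size = 4,
    base_filters = 3, fractions = c(0.5, 0.25, 0.25)))
  expect_s3_class(rep1, "psgres_report")
  expect_true(all(c("f1_recommended", "f1_atypical") %in%
                    names(rep1$per_recording)))
  expect_true(is.numeric(rep1$tests$recommended_vs_atypical$p_value) ||
                rep1$tests$recommended_vs_atypical$degenerate)
  expect_identical(rep1$seeds,
                   psgres:::derive_seed(5, 101L))
  d <- tempfile()
  write_report(rep1, d)
  expect_true(file.exists(file.path(d, "per_recording.csv")))
  expect_true(file.exists(file.path(d, "config.yaml")))
  cfg <- yaml::read_yaml(file.path(d, "config.yaml"))
  expect_equal(cfg$kind, "i")
  expect_equal(cfg$seeds, rep1$seeds)
  unlink(d, recursive = TRUE)
})

test_that("age-conditioning workflow compares FT, FT-I and FT-SaBN", {
  rep3 <- run_experiment("iii", experiment_spec(
    "iii", replicates = 1, seed = 11, n_subjects = 4, n_epochs = 14,
    max_iterations = 2, ft_iterations = 1, batches_per_iteration = 2,
    L = 1, batch_size = 4, base_filters = 3, age_scheme_G = 2,
    fractions = c(0.5, 0.25, 0.25)))
  expect_s3_class(rep3, "psgres_report")
  expect_true(all(c("f1_ft", "f1_sabn", "f1_fti") %in%
                    names(rep3$per_recording)))
  expect_true(all(rep3$per_recording$group %in% c("G1", "G2")))
  # the conditioned model carries exactly G extra affine sets
  expect_gt(rep3$tests$param_surplus, 0)
})

test_that("sandwich fine-tuning surplus equals G extra affine sets", {
  m <- tiny_model(depth = 2, seed = 1)
  n_affine <- 0
  walk <- function(x) {
    if (is.list(x) && !is.null(x$run_mean))
      n_affine <<- n_affine + 2 * length(x$gamma)
    else if (is.list(x) && is.null(x$W)) for (e in x) walk(e)
  }
  walk(m$params)
  for (G in c(2, 7)) {
    ms <- convert_norm_mode(m, "sabn", G)
    expect_equal(count_params(ms) - count_params(m), G * n_affine)
  }
})
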