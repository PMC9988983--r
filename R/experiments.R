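#' Age-group schemes
#'
#' The seven-group scheme: B Babies (0-3), C Children (4-12), A Adolescents
#' (13-18), YA Young Adults (19-39), MA Middle-aged adults (40-59),
#' E Elderly (60-69), OE Old Elderly (>= 70 years). The two-group scheme
#' merges B and C into G1 and the rest into G2.
#'
#' @param G group count, 7 or 2.
#' @export
age_group_scheme <- function(G = 7) {
  if (G == 7) {
    structure(list(G = 7L, breaks = c(0, 4, 13, 19, 40, 60, 70),
                   labels = c("B", "C", "A", "YA", "MA", "E", "OE")),
              class = "age_group_scheme")
  } else if (G == 2) {
    structure(list(G = 2L, breaks = c(0, 13),
                   labels = c("G1", "G2")), class = "age_group_scheme")
  } else stop("built-in schemes have G = 7 or G = 2")
}

#' Assign an age to its group index
#'
#' @param age age in years (>= 0); missing ages are an error (exclude the
#'   recording upstream).
#' @param scheme an [age_group_scheme()].
#' @return 1-based group index.
#' @export
assign_age_group <- function(age, scheme = age_group_scheme(7)) {
  if (is.null(age) || any(is.na(age))) stop("age is missing")
  if (any(age < 0)) stop("age must be >= 0")
  findInterval(age, scheme$breaks)
}

#' Grouped train/validation/test split
#'
#' Splits recordings into train/validation/test so that no subject (or
#' family) straddles two splits. Target recording counts follow the
#' fractions by largest remainder; groups are shuffled under the seed and
#' greedily assigned to the split with the largest remaining deficit.
#' Optional subject caps bound the validation and test splits.
#'
#' @param recordings a [psg_cohort()] or list of recordings.
#' @param fractions length-3 (train, val, test), summing to 1.
#' @param group_key `"subject"` or `"family"`.
#' @param seed integer seed.
#' @param max_val_groups,max_test_groups optional caps on the number of
#'   groups (subjects/families) in the validation / test split.
#' @return named list of three [psg_cohort()]s (`train`, `val`, `test`).
#' @export
split_cohort <- function(recordings, fractions = c(0.75, 0.10, 0.15),
                         group_key = c("subject", "family"), seed = NULL,
                         max_val_groups = NULL, max_test_groups = NULL) {
  group_key <- match.arg(group_key)
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  if (!length(recordings)) stop("empty cohort")
  key <- vapply(recordings, `[[`, "",
                if (group_key == "subject") "subject_id" else "family_id")
  groups <- split(seq_along(recordings), key)
  if (length(groups) < 3) stop("fewer groups than splits")
  n <- length(recordings)
  raw <- fractions * n
  target <- floor(raw)
  rem <- order(raw - target, decreasing = TRUE)
  for (j in seq_len(n - sum(target))) target[rem[j]] <- target[rem[j]] + 1
  caps <- c(Inf, max_val_groups %||% Inf, max_test_groups %||% Inf)
  assigned <- vector("list", 3)
  gcount <- c(0, 0, 0)
  sizes <- c(0, 0, 0)
  ord <- with_seed(seed, sample(seq_along(groups)))
  for (gi in ord) {
    need <- target - sizes
    need[gcount >= caps] <- -Inf
    pick <- which.max(need)
    assigned[[pick]] <- c(assigned[[pick]], groups[[gi]])
    sizes[pick] <- sizes[pick] + length(groups[[gi]])
    gcount[pick] <- gcount[pick] + 1
  }
  out <- lapply(assigned, function(ix) psg_cohort(unclass(recordings)[sort(ix)]))
  names(out) <- c("train", "val", "test")
  out
}

# condition function factory: age group index of a recording
age_condition_fn <- function(scheme) {
  function(rec) assign_age_group(rec$age, scheme)
}

exp_model_config <- function(spec) {
  model_config(depth = spec$depth %||% 3, base_filters = spec$base_filters %||% 4,
               kernel_size = spec$kernel_size %||% 9, fs = spec$fs %||% 32,
               norm_mode = "vanilla")
}

exp_train_config <- function(spec, seed) {
  train_config(lr = spec$lr %||% 3e-3,
               patience = spec$patience %||% 8,
               max_iterations = spec$max_iterations %||% 30,
               batches_per_iteration = spec$batches_per_iteration %||% 6,
               seed = seed)
}

exp_sampler_config <- function(spec, mode = "recommended") {
  aug <- if (isFALSE(spec$augment)) NULL
         else spec$augment %||% augment_params()
  sampler_config(alpha = spec$alpha %||% 0.5, L = spec$L %||% 2,
                 derivation_mode = mode, augment = aug,
                 batch_size = spec$batch_size %||% 8)
}

#' Desk-scale experiment specification
#'
#' Collects the synthetic cohort, model and training parameters for
#' [run_experiment()]. Defaults target minutes of CPU: a depth-3 model at
#' 32 Hz, 1-2-epoch training segments, small cohorts of 40-80-epoch
#' recordings. Any field can be overridden.
#'
#' @param kind experiment kind, `"i"`, `"ii"` or `"iii"`.
#' @param replicates number of seeded replicates.
#' @param seed master seed.
#' @param ... overrides (e.g. `n_subjects`, `n_epochs`, `max_iterations`,
#'   `gain_shift`, `scorer_error`, `age_scheme_G`).
#' @export
experiment_spec <- function(kind = c("i", "ii", "iii"), replicates = 3,
                            seed = 1L, ...) {
  kind <- match.arg(kind)
  spec <- list(kind = kind, replicates = replicates, seed = seed,
               fs = 32, L = 2, depth = 3, base_filters = 4,
               n_subjects = 5, n_epochs = 60)
  dots <- list(...)
  if (length(dots)) spec <- utils::modifyList(spec, dots, keep.null = TRUE)
  structure(spec, class = "experiment_spec")
}

#' Run a desk-scale resilience experiment
#'
#' Three synthetic analogues of the resilience questions:
#' \describe{
#'   \item{kind "i" (derivation resilience)}{trains twin models on
#'     recommended vs atypical derivations of the same cohorts and compares
#'     per-recording test F1 with a two-sided paired t-test.}
#'   \item{kind "ii" (center generalization)}{trains from scratch (S) on
#'     the target center, pretrains on the source centers and evaluates the
#'     direct transfer (DT) on the target test set, then fine-tunes (FT)
#'     the pretrained model on the target center; reports the DT/S/FT
#'     comparison per replicate.}
#'   \item{kind "iii" (age conditioning)}{pretrains a pooled model, then
#'     fine-tunes it pooled (FT), per age group (FT-I) and
#'     group-conditioned via sandwich normalization (FT-SaBN), and reports
#'     per-group test F1 with one-sided paired t-tests against FT.}
#' }
#' Every report embeds the resolved spec and all derived seeds.
#'
#' @param kind `"i"`, `"ii"` or `"iii"`.
#' @param spec an [experiment_spec()]; built from `...` if omitted.
#' @param ... forwarded to [experiment_spec()] when `spec` is missing.
#' @return a list of class `psgres_report`.
#' @export
run_experiment <- function(kind = c("i", "ii", "iii"), spec = NULL, ...) {
  kind <- match.arg(kind)
  if (is.null(spec)) spec <- experiment_spec(kind, ...)
  spec$kind <- kind
  switch(kind,
         i = run_experiment_i(spec),
         ii = run_experiment_ii(spec),
         iii = run_experiment_iii(spec))
}

exp_cohort <- function(spec, seed, datasets) {
  cs <- cohort_spec(datasets, fs = spec$fs, seed = seed)
  preprocess_cohort(generate_cohort(cs),
                    prep_config(target_fs = spec$fs))
}

run_experiment_i <- function(spec) {
  pairs <- list()
  seeds <- integer(0)
  for (r in seq_len(spec$replicates)) {
    rs <- derive_seed(spec$seed, 100L + r)
    seeds <- c(seeds, rs)
    cohort <- exp_cohort(spec, rs, list(
      list(name = "A", n_subjects = spec$n_subjects, n_epochs = spec$n_epochs),
      list(name = "B", n_subjects = spec$n_subjects, n_epochs = spec$n_epochs)))
    sp <- split_cohort(cohort, spec$fractions %||% c(0.75, 0.10, 0.15),
                       seed = derive_seed(rs, 1))
    mseed <- derive_seed(rs, 2)
    tc <- exp_train_config(spec, derive_seed(rs, 3))
    st_rec <- fit(build_model(exp_model_config(spec), mseed),
                  sp$train, sp$val, tc, exp_sampler_config(spec, "recommended"))
    st_aty <- fit(build_model(exp_model_config(spec), mseed),
                  sp$train, sp$val, tc, exp_sampler_config(spec, "atypical"))
    ev_rec <- evaluate_cohort(st_rec$model, sp$test, "recommended")
    ev_aty <- evaluate_cohort(st_aty$model, sp$test, "atypical",
                              seed = derive_seed(rs, 4))
    pairs[[r]] <- data.frame(replicate = r,
                             recording_id = ev_rec$per_recording$recording_id,
                             f1_recommended = ev_rec$per_recording$uf1,
                             f1_atypical = ev_aty$per_recording$uf1)
  }
  per <- do.call(rbind, pairs)
  test <- if (nrow(per) >= 2) {
    paired_test(per$f1_recommended, per$f1_atypical, "two_sided")
  } else list(statistic = NA_real_, df = NA_real_, p_value = NA_real_,
              mean_diff = NA_real_, degenerate = TRUE)
  summary <- data.frame(
    mode = c("recommended", "atypical"),
    mean_f1 = c(mean(per$f1_recommended), mean(per$f1_atypical)),
    sd_f1 = c(pop_sd(per$f1_recommended), pop_sd(per$f1_atypical)))
  new_report("i", spec, seeds, per, summary,
             tests = list(recommended_vs_atypical = test))
}

run_experiment_ii <- function(spec) {
  rows <- list()
  seeds <- integer(0)
  workflows <- spec$workflows %||% c("S", "DT", "FT")
  for (r in seq_len(spec$replicates)) {
    rs <- derive_seed(spec$seed, 200L + r)
    seeds <- c(seeds, rs)
    shift_conf <- scorer_confusion_matrix(spec$scorer_error %||% 0.35)
    # target center: clean; source centers: gain/filter/scorer-noise shifted
    target <- list(name = "target", n_subjects = spec$n_subjects + 2,
                   n_epochs = spec$n_epochs)
    sources <- list(
      list(name = "src1", n_subjects = spec$n_subjects,
           n_epochs = spec$n_epochs, gain = spec$gain_shift %||% 4,
           lowpass = spec$source_lowpass %||% 8,
           scorer_confusion = shift_conf),
      list(name = "src2", n_subjects = spec$n_subjects,
           n_epochs = spec$n_epochs, gain = spec$gain_shift %||% 4,
           lowpass = spec$source_lowpass %||% 8,
           scorer_confusion = shift_conf))
    cohort <- exp_cohort(spec, rs, c(list(target), sources))
    ds <- cohort_dataset_ids(cohort)
    fr <- spec$fractions %||% c(0.75, 0.10, 0.15)
    tgt <- split_cohort(cohort[ds == "target"], fr, seed = derive_seed(rs, 1))
    src <- split_cohort(cohort[ds != "target"], fr, seed = derive_seed(rs, 2))
    mseed <- derive_seed(rs, 3)
    tc <- exp_train_config(spec, derive_seed(rs, 4))
    sc <- exp_sampler_config(spec)
    f1 <- c(S = NA_real_, DT = NA_real_, FT = NA_real_)
    st_pre <- NULL
    if (any(c("DT", "FT") %in% workflows)) {
      st_pre <- fit(build_model(exp_model_config(spec), mseed),
                    src$train, src$val, tc, sc)
      if ("DT" %in% workflows)
        f1["DT"] <- evaluate_cohort(st_pre$model, tgt$test)$summary$mean[1]
    }
    if ("S" %in% workflows) {
      st_s <- fit(build_model(exp_model_config(spec), derive_seed(mseed, 1)),
                  tgt$train, tgt$val, tc, sc)
      f1["S"] <- evaluate_cohort(st_s$model, tgt$test)$summary$mean[1]
    }
    if ("FT" %in% workflows) {
      ft_cfg <- exp_train_config(spec, derive_seed(rs, 5))
      ft_cfg$lr <- spec$ft_lr %||% (ft_cfg$lr / 10)
      st_ft <- fine_tune(st_pre, tgt$train, tgt$val, ft_cfg, sampler = sc)
      f1["FT"] <- evaluate_cohort(st_ft$model, tgt$test)$summary$mean[1]
    }
    rows[[r]] <- data.frame(replicate = r, workflow = names(f1),
                            test_f1 = unname(f1), row.names = NULL)
  }
  per <- do.call(rbind, rows)
  per <- per[!is.na(per$test_f1), ]
  summary <- do.call(rbind, lapply(split(per, per$workflow), function(d)
    data.frame(workflow = d$workflow[1], mean_f1 = mean(d$test_f1),
               sd_f1 = pop_sd(d$test_f1))))
  tests <- list()
  if (all(c("S", "DT") %in% per$workflow)) {
    s <- per$test_f1[per$workflow == "S"]
    dt <- per$test_f1[per$workflow == "DT"]
    tests$dt_below_s_fraction <- mean(dt < s)
    if (length(s) >= 2) tests$s_vs_dt <- paired_test(dt, s, "one_sided_greater")
  }
  new_report("ii", spec, seeds, per, summary, tests)
}

run_experiment_iii <- function(spec) {
  scheme <- age_group_scheme(spec$age_scheme_G %||% 2)
  cfn <- age_condition_fn(scheme)
  rows <- list()
  seeds <- integer(0)
  extra <- list()
  for (r in seq_len(spec$replicates)) {
    rs <- derive_seed(spec$seed, 300L + r)
    seeds <- c(seeds, rs)
    young <- list(name = "young", n_subjects = spec$n_subjects + 1,
                  n_epochs = spec$n_epochs, age_range = c(2, 10))
    adult <- list(name = "adult", n_subjects = spec$n_subjects + 1,
                  n_epochs = spec$n_epochs, age_range = c(30, 65))
    if (isTRUE(spec$null_age_effect)) {
      young$age_range <- c(30, 65)
      young$name <- "young"
    }
    cohort <- exp_cohort(spec, rs, list(young, adult))
    sp <- split_cohort(cohort, spec$fractions %||% c(0.75, 0.10, 0.15),
                       seed = derive_seed(rs, 1))
    tc <- exp_train_config(spec, derive_seed(rs, 2))
    sc <- exp_sampler_config(spec)
    pre <- fit(build_model(exp_model_config(spec), derive_seed(rs, 3)),
               sp$train, sp$val, tc, sc)
    ft_cfg <- exp_train_config(spec, derive_seed(rs, 4))
    ft_cfg$lr <- spec$ft_lr %||% (ft_cfg$lr / 10)
    ft_cfg$max_iterations <- spec$ft_iterations %||% 10
    st_ft <- fine_tune(pre, sp$train, sp$val, ft_cfg, sampler = sc)
    st_sabn <- fine_tune(pre, sp$train, sp$val, ft_cfg,
                         norm_mode = "sabn", G = scheme$G, sampler = sc,
                         condition_fn = cfn)
    groups <- vapply(sp$test, function(rec) cfn(rec), 0L)
    ev_ft <- evaluate_cohort(st_ft$model, sp$test)
    ev_sabn <- evaluate_cohort(st_sabn$model, sp$test, condition_fn = cfn)
    # FT-I: one independent fine-tune per group
    fi_rows <- list()
    for (gi in sort(unique(groups))) {
      tr_g <- Filter(function(rec) cfn(rec) == gi, unclass(sp$train))
      va_g <- Filter(function(rec) cfn(rec) == gi, unclass(sp$val))
      te_g <- sp$test[groups == gi]
      if (!length(tr_g) || !length(va_g) || !length(te_g)) next
      st_g <- fine_tune(pre, psg_cohort(tr_g), va_g, ft_cfg, sampler = sc)
      ev_g <- evaluate_cohort(st_g$model, te_g)
      fi_rows[[length(fi_rows) + 1L]] <-
        data.frame(recording_id = ev_g$per_recording$recording_id,
                   f1_fti = ev_g$per_recording$uf1)
    }
    fti <- do.call(rbind, fi_rows)
    df <- data.frame(replicate = r,
                     recording_id = ev_ft$per_recording$recording_id,
                     group = scheme$labels[groups],
                     f1_ft = ev_ft$per_recording$uf1,
                     f1_sabn = ev_sabn$per_recording$uf1)
    df <- merge(df, fti, by = "recording_id", all.x = TRUE)
    rows[[r]] <- df
    extra$param_surplus <- count_params(st_sabn$model) - count_params(st_ft$model)
  }
  per <- do.call(rbind, rows)
  tests <- list(
    sabn_vs_ft = paired_test(per$f1_ft, per$f1_sabn, "one_sided_greater"),
    fti_vs_ft = if (!anyNA(per$f1_fti))
      paired_test(per$f1_ft, per$f1_fti, "one_sided_greater") else NULL,
    param_surplus = extra$param_surplus)
  summary <- do.call(rbind, lapply(split(per, per$group), function(d)
    data.frame(group = d$group[1], n = nrow(d),
               mean_f1_ft = mean(d$f1_ft), mean_f1_fti = mean(d$f1_fti),
               mean_f1_sabn = mean(d$f1_sabn))))
  new_report("iii", spec, seeds, per, summary, tests)
}

new_report <- function(kind, spec, seeds, per_recording, summary, tests) {
  structure(list(kind = kind, spec = unclass(spec), seeds = seeds,
                 per_recording = per_recording, summary = summary,
                 tests = tests),
            class = "psgres_report")
}

#' @export
print.psgres_report <- function(x, ...) {
  cat("<psgres_report> experiment (", x$kind, "), ",
      length(x$seeds), " replicate(s)\n", sep = "")
  print(x$summary, row.names = FALSE)
  for (nm in names(x$tests)) {
    t <- x$tests[[nm]]
    if (is.list(t) && !is.null(t$p_value))
      cat(sprintf("  %s: p = %.4g (mean diff %.2f)\n", nm, t$p_value,
                  t$mean_diff))
    else if (is.numeric(t)) cat(sprintf("  %s: %s\n", nm, format(t)))
  }
  invisible(x)
}

#' Serialize an experiment report to a directory
#'
#' Writes the per-recording metrics CSV, the summary CSV, a human-readable
#' summary and the resolved configuration (YAML) with all seeds.
#'
#' @param report a `psgres_report`.
#' @param dir output directory (created if needed).
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$per_recording,
                   file.path(dir, "per_recording.csv"), row.names = FALSE)
  utils::write.csv(report$summary, file.path(dir, "summary.csv"),
                   row.names = FALSE)
  cfg <- report$spec
  cfg$seeds <- report$seeds
  cfg <- lapply(cfg, function(x) if (is.matrix(x)) as.vector(x) else x)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  con <- file(file.path(dir, "summary.txt"), "w")
  sink(con)
  print(report)
  sink()
  close(con)
  invisible(dir)
}
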