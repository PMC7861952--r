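test_that("signal sets round-trip through delimited text", {
  ds <- simulate_emg_dataset(
    emg_sim_spec(n_subjects = 1, n_classes = 2, n_channels = 2,
                 n_repetitions = 2, trial_duration = 0.1,
                 rest_duration = 0.05, seed = 8))
  dir <- withr::local_tempdir()
  write_signal_set(ds, dir)
  back <- read_signal_set(dir)
  expect_length(back$trials, length(ds$trials))
  expect_equal(back$sampling_rate, ds$sampling_rate)
  for (i in seq_along(ds$trials)) {
    expect_equal(back$trials[[i]]$signal, ds$trials[[i]]$signal,
                 tolerance = 1e-12)
    expect_equal(back$trials[[i]]$class, ds$trials[[i]]$class)
    expect_equal(back$trials[[i]]$subject, ds$trials[[i]]$subject)
  }
})

test_that("feature tables round-trip with discrete flags and metadata", {
  ft <- make_toy_multiclass(5, 3, 4, 2, discrete_cols = 4, n_subjects = 2,
                            seed = 13)
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(ft, path)
  back <- read_feature_table(path)
  expect_equal(back$x, ft$x, ignore_attr = TRUE)
  expect_equal(as.character(back$y), as.character(ft$y))
  expect_identical(back$discrete, ft$discrete)
  expect_equal(back$subject, ft$subject)
})

test_that("threefold CV assigns exactly two of six repetitions per test fold", {
  ds <- simulate_emg_dataset(
    emg_sim_spec(n_subjects = 2, n_classes = 3, n_channels = 1,
                 n_repetitions = 6, trial_duration = 0.05,
                 rest_duration = 0.05, seed = 5))
  plan <- make_cv_folds(ds, n_folds = 3, seed = 17)
  meta <- data.frame(
    id = vapply(ds$trials, `[[`, 0, "trial_id"),
    subject = vapply(ds$trials, `[[`, 0, "subject"),
    class = vapply(ds$trials, `[[`, 0, "class"))
  for (fold in plan$folds) {
    test_meta <- meta[meta$id %in% fold$test, ]
    expect_true(all(table(test_meta$subject, test_meta$class) == 2))
    expect_equal(length(fold$train) / length(fold$test), 2)  # 2:1 split
  }
})

test_that("CV folds partition the trials", {
  ft <- make_toy_multiclass(9, 3, 4, 1, n_subjects = 3, seed = 2)
  plan <- make_cv_folds(ft, n_folds = 3, seed = 1)
  tests <- lapply(plan$folds, `[[`, "test")
  expect_setequal(unlist(tests), ft$trial_id)          # union covers all
  for (i in 1:2) for (j in (i + 1):3) {
    expect_length(intersect(tests[[i]], tests[[j]]), 0) # pairwise disjoint
  }
  for (fold in plan$folds) {
    expect_setequal(c(fold$train, fold$test), ft$trial_id)
  }
})

test_that("CV fold construction validates its inputs", {
  ft <- make_toy_multiclass(4, 2, 3, 1, seed = 1)
  expect_error(make_cv_folds(ft, n_folds = 1), "n_folds")
  expect_error(make_cv_folds(ft, n_folds = 5), "class")  # group too small
})

test_that("overall accuracy is the unweighted mean of per-subject accuracies", {
  # two subjects at 0.8 and 1.0
  rep1 <- subject_average(c("a", "a", "b", "a", "b", "a", "a", "b", "a", "b"),
                          c("a", "b", "b", "a", "b", "a", "a", "b", "a", "b"),
                          rep(c("s1", "s2"), each = 5))
  expect_equal(unname(rep1$per_subject["s1"]), 0.8)
  expect_equal(unname(rep1$per_subject["s2"]), 1.0)
  expect_equal(rep1$overall, 0.9)

  # all correct
  rep2 <- subject_average(c("a", "b"), c("a", "b"), c("s1", "s2"))
  expect_equal(rep2$overall, 1.0)

  # unequal trial counts: 10 trials at 1.0, 90 trials at 0.5 -> 0.75 (not
  # the pooled 0.55): subjects count equally
  pred <- c(rep("a", 10), rep(c("a", "b"), 45))
  truth <- c(rep("a", 10), rep("a", 90))
  subj <- c(rep("s1", 10), rep("s2", 90))
  rep3 <- subject_average(pred, truth, subj)
  expect_equal(rep3$overall, 0.75)
})

test_that("subject averaging ignores trial order", {
  set.seed(31)
  pred <- sample(c("a", "b"), 60, TRUE)
  truth <- sample(c("a", "b"), 60, TRUE)
  subj <- sample(c("s1", "s2", "s3"), 60, TRUE)
  base <- subject_average(pred, truth, subj)
  perm <- sample(60)
  shuf <- subject_average(pred[perm], truth[perm], subj[perm])
  expect_equal(shuf$overall, base$overall)
  expect_equal(shuf$per_subject, base$per_subject)
})
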