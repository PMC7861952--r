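#' Write a labeled signal set as delimited text
#'
#' One CSV per trial (columns = channels, rows = samples) plus a
#' `manifest.csv` recording subject, class, repetition, force level, active
#' sample count, sampling rate and relative file path.
#'
#' @param dataset a `labeled_signal_set`.
#' @param dir output directory (created if absent).
#' @export
write_signal_set <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- lapply(dataset$trials, function(tr) {
    fn <- sprintf("trial_%04d.csv", tr$trial_id)
    utils::write.csv(as.data.frame(t(tr$signal)),
                     file.path(dir, fn), row.names = FALSE)
    data.frame(trial_id = tr$trial_id, subject = tr$subject,
               class = tr$class, repetition = tr$repetition,
               force = tr$force, active_samples = tr$active_samples,
               sampling_rate = dataset$sampling_rate, path = fn)
  })
  utils::write.csv(do.call(rbind, rows), file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a labeled signal set written by [write_signal_set()]
#'
#' @param dir directory containing `manifest.csv` and the per-trial CSVs.
#' @return a `labeled_signal_set`.
#' @export
read_signal_set <- function(dir) {
  man <- utils::read.csv(file.path(dir, "manifest.csv"))
  check_that(length(unique(man$sampling_rate)) == 1,
             "all trials must share one sampling rate")
  trials <- lapply(seq_len(nrow(man)), function(i) {
    sig <- t(as.matrix(utils::read.csv(file.path(dir, man$path[i]))))
    dimnames(sig) <- NULL
    list(signal = sig, subject = man$subject[i], class = man$class[i],
         repetition = man$repetition[i], force = man$force[i],
         active_samples = man$active_samples[i], trial_id = man$trial_id[i])
  })
  nch <- vapply(trials, function(tr) nrow(tr$signal), 0L)
  check_that(length(unique(nch)) == 1,
             "all trials must share one channel count")
  structure(list(trials = trials, sampling_rate = man$sampling_rate[1],
                 classes = sort(unique(man$class)), spec = NULL),
            class = "labeled_signal_set")
}

## per-trial grouping metadata for either container
trial_meta <- function(dataset) {
  if (inherits(dataset, "labeled_signal_set")) {
    data.frame(
      id = vapply(dataset$trials, `[[`, 0, "trial_id"),
      subject = vapply(dataset$trials, `[[`, 0, "subject"),
      class = vapply(dataset$trials, `[[`, 0, "class")
    )
  } else if (inherits(dataset, "feature_table")) {
    data.frame(
      id = if (!is.null(dataset$trial_id)) dataset$trial_id
           else seq_len(nrow(dataset$x)),
      subject = if (!is.null(dataset$subject)) dataset$subject else 1L,
      class = as.character(dataset$y)
    )
  } else stop("unsupported dataset type", call. = FALSE)
}

#' Build a stratified k-fold cross-validation plan
#'
#' Trials are partitioned into `n_folds` folds, stratified within each
#' (subject, class) group: each group's trials are shuffled by the seed and
#' dealt round-robin, so with six repetitions and three folds every fold's
#' test set holds exactly two repetitions per group. Each fold uses one part
#' for testing and the remaining parts for training (a 2:1 train:test ratio
#' at three folds). Splitting is by trial, never by analysis window, so the
#' heavily correlated windows of one trial can never straddle the split.
#'
#' @param dataset a `labeled_signal_set` or `feature_table`.
#' @param n_folds number of folds (default 3).
#' @param seed integer seed for the within-group shuffle.
#' @return a `cv_plan`: list of folds, each with `train` and `test` trial-id
#'   vectors.
#' @export
make_cv_folds <- function(dataset, n_folds = 3, seed = 1L) {
  check_that(n_folds >= 2, "n_folds must be >= 2")
  meta <- trial_meta(dataset)
  set.seed(seed)
  fold_of <- integer(nrow(meta))
  for (g in split(seq_len(nrow(meta)),
                  interaction(meta$subject, meta$class, drop = TRUE))) {
    if (length(g) < n_folds) {
      stop(sprintf(
        "group (subject=%s, class=%s) has %d trials; need at least %d",
        meta$subject[g[1]], meta$class[g[1]], length(g), n_folds),
        call. = FALSE)
    }
    fold_of[sample(g)] <- rep_len(seq_len(n_folds), length(g))
  }
  folds <- lapply(seq_len(n_folds), function(k) {
    list(train = meta$id[fold_of != k], test = meta$id[fold_of == k])
  })
  structure(list(folds = folds, n_folds = n_folds, seed = seed,
                 trial_ids = meta$id),
            class = "cv_plan")
}

#' @export
print.cv_plan <- function(x, ...) {
  cat(sprintf("CV plan: %d folds over %d trials\n", x$n_folds,
              length(x$trial_ids)))
  for (k in seq_along(x$folds)) {
    cat(sprintf("  fold %d: %d train / %d test\n", k,
                length(x$folds[[k]]$train), length(x$folds[[k]]$test)))
  }
  invisible(x)
}

#' Per-subject-averaged accuracy report
#'
#' Accuracy is computed within each subject (correct / total for that
#' subject) and the overall accuracy is the unweighted mean of the
#' per-subject accuracies — subjects count equally regardless of how many
#' trials each contributed. Per-class accuracies (recall of each true
#' class) are reported alongside.
#'
#' @param predictions predicted labels.
#' @param truth true labels, same length.
#' @param subject subject identifier per prediction.
#' @param split_name label for the report (e.g. "train" or "test").
#' @return an `accuracy_report` with `per_subject`, `overall`, `per_class`
#'   and `split` fields.
#' @export
subject_average <- function(predictions, truth, subject,
                            split_name = "test") {
  check_that(length(predictions) == length(truth) &&
               length(truth) == length(subject),
             "predictions, truth and subject must have equal lengths")
  keep <- !is.na(subject)
  if (any(!keep)) {
    warning("excluding ", sum(!keep), " predictions with missing subject id")
  }
  predictions <- as.character(predictions)[keep]
  truth <- as.character(truth)[keep]
  subject <- subject[keep]
  correct <- predictions == truth
  per_subject <- tapply(correct, subject, mean)
  per_class <- tapply(correct, truth, mean)
  structure(list(per_subject = per_subject,
                 overall = mean(per_subject),
                 per_class = per_class,
                 split = split_name,
                 n = length(truth)),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("%s accuracy: %.2f%% (unweighted mean over %d subjects, %d trials)\n",
              x$split, 100 * x$overall, length(x$per_subject), x$n))
  cat("  per subject:",
      paste(sprintf("%s=%.2f", names(x$per_subject), x$per_subject),
            collapse = "  "), "\n")
  cat("  per class:  ",
      paste(sprintf("%s=%.2f", names(x$per_class), x$per_class),
            collapse = "  "), "\n")
  invisible(x)
}
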