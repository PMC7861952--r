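#' Pipeline configuration
#'
#' Bundles the stage settings for [run_pipeline()]. Two profiles scale the
#' expensive knobs: `"paper"` carries the full-scale constants
#' (augmentation factor 1000, hidden sizes 1200/900, 1024-point DFT) and
#' `"test"` shrinks them (factor 10, hidden 40/20, 256-point DFT, fewer
#' epochs) so a complete cross-validated run finishes in seconds to
#' minutes on one CPU. Any field can be overridden explicitly.
#'
#' @param profile `"test"` or `"paper"`.
#' @param spectrogram a [spectrogram_spec()] (ignored for feature-table
#'   input).
#' @param augmentation_factor virtual rows per original row.
#' @param hidden_sizes autoencoder layer sizes.
#' @param ae_epochs,ae_learning_rate autoencoder optimizer settings.
#' @param l2_weight,sparsity_weight,sparsity_proportion,encoder_transfer
#'   autoencoder penalties and transfer.
#' @param elm_hidden ELM hidden-unit count.
#' @param elm_ridge ELM ridge coefficient.
#' @param svm_cost SVM box constraint.
#' @param softmax_l2 softmax weight decay.
#' @param n_folds cross-validation folds (default 3).
#' @param inner_val_fraction fraction of each training fold held out (per
#'   subject x class stratum) for variant selection and per-class fusion
#'   accuracies (default 0.25).
#' @param seed master seed; every stochastic stage derives its own seed
#'   from it via [derive_seed()].
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(profile = c("test", "paper"),
                            spectrogram = NULL,
                            augmentation_factor = NULL,
                            hidden_sizes = NULL,
                            ae_epochs = NULL, ae_learning_rate = 0.05,
                            l2_weight = 0.001, sparsity_weight = 4,
                            sparsity_proportion = 0.05,
                            encoder_transfer = "linear",
                            elm_hidden = NULL, elm_ridge = 1e-4,
                            svm_cost = 1, softmax_l2 = 1e-4,
                            n_folds = 3, inner_val_fraction = 0.25,
                            seed = 1L) {
  profile <- match.arg(profile)
  if (is.null(spectrogram)) {
    # test profile shrinks the analysis window with the DFT so 2000 Hz
    # signals still fit (window length in samples must not exceed n_fft)
    spectrogram <- if (profile == "paper") {
      spectrogram_spec(window_ms = 200, increment_ms = 50, n_fft = 1024)
    } else {
      spectrogram_spec(window_ms = 100, increment_ms = 50, n_fft = 256)
    }
  }
  defaults <- if (profile == "paper") {
    list(aug = 1000L, hidden = c(1200L, 900L), epochs = 200L,
         elm_hidden = 500L)
  } else {
    list(aug = 10L, hidden = c(40L, 20L), epochs = 40L,
         elm_hidden = 100L)
  }
  structure(list(
    profile = profile,
    spectrogram = spectrogram,
    augmentation_factor = if (is.null(augmentation_factor)) defaults$aug
                          else as.integer(augmentation_factor),
    hidden_sizes = if (is.null(hidden_sizes)) defaults$hidden
                   else as.integer(hidden_sizes),
    ae_epochs = if (is.null(ae_epochs)) defaults$epochs
                else as.integer(ae_epochs),
    ae_learning_rate = ae_learning_rate,
    l2_weight = l2_weight, sparsity_weight = sparsity_weight,
    sparsity_proportion = sparsity_proportion,
    encoder_transfer = encoder_transfer,
    elm_hidden = if (is.null(elm_hidden)) defaults$elm_hidden
                 else as.integer(elm_hidden),
    elm_ridge = elm_ridge, svm_cost = svm_cost, softmax_l2 = softmax_l2,
    n_folds = as.integer(n_folds),
    inner_val_fraction = inner_val_fraction,
    seed = as.integer(seed)
  ), class = "pipeline_config")
}

## stage indices for seed derivation, recorded in the run report
.stage_ids <- c(cv = 1L, inner_split = 2L, augment_inner = 3L,
                augment_full = 4L, autoencoder = 5L, elm = 6L)

## standardize continuous columns only; sd-0 columns get scale 1
fit_standardizer <- function(ft) {
  center <- colMeans(ft$x)
  scale <- apply(ft$x, 2L, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  center[ft$discrete] <- 0
  scale[ft$discrete] <- 1
  list(center = center, scale = scale)
}

apply_standardizer <- function(std, ft) {
  ft$x <- sweep(sweep(ft$x, 2L, std$center, `-`), 2L, std$scale, `/`)
  ft
}

## stratified inner split: per (subject, class) stratum of the training
## rows, hold out ~frac (at least 1, at most size-2) rows for selection
inner_split <- function(ft, frac, seed) {
  set.seed(seed)
  meta <- interaction(
    if (is.null(ft$subject)) rep(1L, nrow(ft$x)) else ft$subject,
    ft$y, drop = TRUE)
  val <- integer(0)
  for (g in split(seq_len(nrow(ft$x)), meta)) {
    n_val <- max(1L, min(length(g) - 2L, round(frac * length(g))))
    if (length(g) >= 3L) val <- c(val, sample(g, n_val))
  }
  if (!length(val)) {
    # strata too small to spare rows: select on training predictions
    return(list(train = seq_len(nrow(ft$x)), val = seq_len(nrow(ft$x))))
  }
  list(train = setdiff(seq_len(nrow(ft$x)), val), val = val)
}

## train the three-family bank on encoded training data, choose the best
## variant per family on the encoded validation data
train_bank <- function(Xtr, ytr, Xval, yval, config, seed) {
  elms <- list()
  for (i in seq_along(elm_activations)) {
    elms[[elm_activations[i]]] <-
      train_elm(Xtr, ytr, config$elm_hidden, elm_activations[i],
                ridge = config$elm_ridge, seed = derive_seed(seed, i))
  }
  svms <- list()
  for (k in svm_kernels) {
    svms[[k]] <- train_svm(Xtr, ytr, k, cost = config$svm_cost)
  }
  sl <- list(softmax = train_softmax(Xtr, ytr, l2 = config$softmax_l2))
  list(ELM = select_best_variant(elms, Xval, yval),
       SVM = select_best_variant(svms, Xval, yval),
       SL = select_best_variant(sl, Xval, yval))
}

bank_scores <- function(models, X) {
  lapply(models, function(m) predict(m, X, type = "prob"))
}

#' Run the full cross-validated pipeline
#'
#' Orchestrates the stage order raw signal -> spectrogram ->
#' standardization -> Gaussian virtual-sample augmentation -> tensor view
#' -> stacked sparse autoencoder -> classifier bank -> per-class fusion,
#' under stratified k-fold cross-validation. All data-dependent fitting
#' (standardization statistics, class Gaussians, autoencoder weights,
#' classifiers, fusion table) happens on the training portion of each fold
#' only; a per-stage log of the trial ids each fitting stage saw is kept so
#' the no-leakage property is checkable. Feature-table input skips the
#' spectrogram stage.
#'
#' Within each training fold, a stratified selection split (25% by
#' default) is held out: candidate variants are trained on the remainder
#' (augmented), the best variant per family and the per-class fusion
#' assignments are chosen on the held-out part, and the chosen variants are
#' then retrained on the full augmented training fold.
#'
#' @param dataset a `labeled_signal_set` or `feature_table`.
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, reports (JSON), the
#'   fusion tables and the seed log are written there.
#' @return an object of class `semg_pipeline` with train/test
#'   `accuracy_report`s, per-fold artifacts and the fit log.
#' @export
run_pipeline <- function(dataset, config = pipeline_config(),
                         out_dir = NULL) {
  master <- config$seed
  ft_all <- if (inherits(dataset, "labeled_signal_set")) {
    extract_spectrogram_features(dataset, config$spectrogram)
  } else if (inherits(dataset, "feature_table")) {
    dataset
  } else stop("dataset must be a labeled_signal_set or feature_table",
              call. = FALSE)
  if (is.null(ft_all$trial_id)) ft_all$trial_id <- seq_len(nrow(ft_all$x))
  if (is.null(ft_all$subject)) ft_all$subject <- rep(1L, nrow(ft_all$x))

  plan <- make_cv_folds(ft_all, config$n_folds,
                        seed = derive_seed(master, .stage_ids[["cv"]]))
  folds_out <- vector("list", config$n_folds)
  pooled <- list(test = NULL, train = NULL)

  for (k in seq_len(config$n_folds)) {
    tr_idx <- which(ft_all$trial_id %in% plan$folds[[k]]$train)
    te_idx <- which(ft_all$trial_id %in% plan$folds[[k]]$test)
    tr <- ft_rows(ft_all, tr_idx)
    te <- ft_rows(ft_all, te_idx)
    fit_ids <- tr$trial_id                 # every fitting stage sees these only
    fit_log <- list()

    std <- fit_standardizer(tr)
    fit_log$standardizer <- fit_ids
    tr_s <- apply_standardizer(std, tr)
    te_s <- apply_standardizer(std, te)

    spl <- inner_split(tr_s, config$inner_val_fraction,
                       derive_seed(master, .stage_ids[["inner_split"]], k))
    inner_tr <- ft_rows(tr_s, spl$train)
    inner_val <- ft_rows(tr_s, spl$val)

    aug_inner <- augment_training_set(
      inner_tr, augmentation_spec(config$augmentation_factor, TRUE,
        derive_seed(master, .stage_ids[["augment_inner"]], k)))
    aug_full <- augment_training_set(
      tr_s, augmentation_spec(config$augmentation_factor, TRUE,
        derive_seed(master, .stage_ids[["augment_full"]], k)))
    fit_log$class_gaussian <- fit_ids

    ae_spec <- autoencoder_spec(
      hidden_sizes = config$hidden_sizes, l2_weight = config$l2_weight,
      sparsity_weight = config$sparsity_weight,
      sparsity_proportion = config$sparsity_proportion,
      encoder_transfer = config$encoder_transfer,
      max_epochs = config$ae_epochs,
      learning_rate = config$ae_learning_rate,
      seed = derive_seed(master, .stage_ids[["autoencoder"]], k))
    stack <- train_encoder_stack(aug_full$x, ae_spec)
    fit_log$autoencoder <- fit_ids

    enc <- function(ftab) encode_stack(stack, ftab$x)
    sel <- train_bank(enc(aug_inner), aug_inner$y,
                      enc(inner_val), inner_val$y, config,
                      derive_seed(master, .stage_ids[["elm"]], k))
    classes <- levels(droplevels(tr$y))
    acc_tables <- lapply(sel, function(s) {
      per_class_accuracy(predict(s$model, enc(inner_val)), inner_val$y,
                         classes = classes)
    })
    fusion <- select_local_classifiers(
      acc_tables, variants = lapply(sel, `[[`, "variant"))

    # retrain the chosen variants on the full augmented training fold
    finals <- list(
      ELM = train_elm(enc(aug_full), aug_full$y, config$elm_hidden,
                      sel$ELM$variant, ridge = config$elm_ridge,
                      seed = derive_seed(master, .stage_ids[["elm"]],
                                         k + 100L)),
      SVM = train_svm(enc(aug_full), aug_full$y, sel$SVM$variant,
                      cost = config$svm_cost),
      SL = train_softmax(enc(aug_full), aug_full$y, l2 = config$softmax_l2))
    fit_log$classifiers <- fit_ids

    pred_split <- function(ftab) {
      fuse_predict(fusion, bank_scores(finals, enc(ftab)))
    }
    te_pred <- pred_split(te_s)
    tr_pred <- pred_split(tr_s)

    pooled$test <- rbind(pooled$test, data.frame(
      pred = as.character(te_pred), truth = as.character(te$y),
      subject = te$subject, trial_id = te$trial_id, fold = k))
    pooled$train <- rbind(pooled$train, data.frame(
      pred = as.character(tr_pred), truth = as.character(tr$y),
      subject = tr$subject, trial_id = tr$trial_id, fold = k))

    folds_out[[k]] <- list(fusion = fusion, variants = lapply(sel, `[[`,
                                                              "variant"),
                           standardizer = std, encoder = stack,
                           models = finals, fit_log = fit_log,
                           test_ids = te$trial_id)
  }

  report_test <- subject_average(pooled$test$pred, pooled$test$truth,
                                 pooled$test$subject, "test")
  report_train <- subject_average(pooled$train$pred, pooled$train$truth,
                                  pooled$train$subject, "train")
  res <- structure(list(
    config = config, plan = plan, folds = folds_out,
    report = list(train = report_train, test = report_test),
    predictions = pooled,
    seeds = list(master = master, stages = .stage_ids)
  ), class = "semg_pipeline")

  if (!is.null(out_dir)) write_pipeline_artifacts(res, out_dir)
  res
}

write_pipeline_artifacts <- function(res, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  rep <- lapply(res$report, function(r) {
    list(split = r$split, overall = r$overall,
         per_subject = as.list(r$per_subject),
         per_class = as.list(r$per_class), n = r$n)
  })
  jsonlite::write_json(
    list(reports = rep,
         seeds = list(master = res$seeds$master,
                      stages = as.list(res$seeds$stages)),
         profile = res$config$profile),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  for (k in seq_along(res$folds)) {
    utils::write.csv(as.data.frame(res$folds[[k]]$fusion),
                     file.path(out_dir, sprintf("fusion_fold%d.csv", k)),
                     row.names = FALSE)
  }
  utils::write.csv(res$predictions$test,
                   file.path(out_dir, "test_predictions.csv"),
                   row.names = FALSE)
  invisible(out_dir)
}

#' @export
print.semg_pipeline <- function(x, ...) {
  cat(sprintf("sEMG classification pipeline (%s profile, %d-fold CV, seed %d)\n",
              x$config$profile, x$config$n_folds, x$seeds$master))
  cat(sprintf("  train accuracy: %.2f%%   test accuracy: %.2f%%\n",
              100 * x$report$train$overall, 100 * x$report$test$overall))
  invisible(x)
}

#' @export
summary.semg_pipeline <- function(object, ...) {
  print(object)
  cat("\n")
  print(object$report$train)
  print(object$report$test)
  cat("\nFold fusion assignments:\n")
  for (k in seq_along(object$folds)) {
    f <- object$folds[[k]]$fusion
    cat(sprintf("  fold %d: %s\n", k,
                paste(sprintf("%s->%s[%s]", f$class, f$classifier,
                              f$variant), collapse = "  ")))
  }
  invisible(object)
}

#' Predict with a fitted pipeline
#'
#' Applies the first fold's fitted stages (standardizer, encoder stack,
#' final classifier bank and fusion table) to new data.
#'
#' @param object a `semg_pipeline`.
#' @param newdata a `labeled_signal_set` or `feature_table` (or bare
#'   numeric matrix of features on the pre-encoding scale).
#' @param fold which fold's artifacts to use (default 1).
#' @param ... unused.
#' @return factor of predicted class labels.
#' @export
predict.semg_pipeline <- function(object, newdata, fold = 1, ...) {
  art <- object$folds[[fold]]
  ftab <- if (inherits(newdata, "labeled_signal_set")) {
    extract_spectrogram_features(newdata, object$config$spectrogram)
  } else if (inherits(newdata, "feature_table")) {
    newdata
  } else {
    feature_table(as.matrix(newdata),
                  rep(object$folds[[fold]]$fusion$class[1],
                      nrow(as.matrix(newdata))))
  }
  ftab <- apply_standardizer(art$standardizer, ftab)
  enc <- encode_stack(art$encoder, ftab$x)
  fuse_predict(art$fusion, bank_scores(art$models, enc))
}
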