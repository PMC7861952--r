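#' Virtual-sample augmentation settings
#'
#' Controls class-conditional Gaussian virtual-sample generation: each
#' original training row is "reiterated" `replication_factor` times by
#' drawing that many virtual rows from its class's fitted Gaussian. The
#' full-scale setting is 1000 replications; test profiles use far smaller
#' factors.
#'
#' @param replication_factor virtual rows generated per original row
#'   (default 1000).
#' @param include_originals keep the original rows alongside the virtual
#'   ones (default `TRUE`).
#' @param seed integer seed.
#' @return an object of class `augmentation_spec`.
#' @export
augmentation_spec <- function(replication_factor = 1000,
                              include_originals = TRUE, seed = 1L) {
  check_that(replication_factor >= 0, "replication_factor must be >= 0")
  structure(list(replication_factor = as.integer(replication_factor),
                 include_originals = isTRUE(include_originals),
                 seed = as.integer(seed)),
            class = "augmentation_spec")
}

#' Fit per-class, per-feature Gaussians
#'
#' For every class c and continuous feature j, the model stores the sample
#' mean mu[c, j] and sample standard deviation eta[c, j] (denominator
#' N - 1) of that feature within that class. Discrete features are not
#' modeled as Gaussians: they get eta = 0 and mu = the within-class mode,
#' the degenerate N(mu, 0) that keeps generated rows consistent with the
#' discrete codes seen in training.
#'
#' @param train a `feature_table`.
#' @return a `class_gaussian_model` with matrices `mu` and `eta`
#'   (class x feature), the `discrete` flags, and the class levels.
#' @export
fit_class_gaussian <- function(train) {
  check_that(inherits(train, "feature_table"),
             "train must be a feature_table")
  classes <- levels(droplevels(train$y))
  k <- ncol(train$x)
  mu <- matrix(0, length(classes), k,
               dimnames = list(classes, colnames(train$x)))
  eta <- mu
  for (ci in seq_along(classes)) {
    rows <- train$x[train$y == classes[ci], , drop = FALSE]
    if (nrow(rows) < 2 && any(!train$discrete)) {
      stop(sprintf(
        paste0("class '%s' has %d row(s); the sample standard deviation ",
               "needs at least 2 — supply more rows or mark features ",
               "discrete"), classes[ci], nrow(rows)), call. = FALSE)
    }
    mu[ci, ] <- colMeans(rows)
    eta[ci, ] <- apply(rows, 2L, stats::sd)
    for (j in which(train$discrete)) {
      vals <- rows[, j]
      tab <- table(vals)
      mu[ci, j] <- as.numeric(names(tab)[which.max(tab)])  # class mode
      eta[ci, j] <- 0
    }
  }
  structure(list(mu = mu, eta = eta, discrete = train$discrete,
                 classes = classes, feature_count = k,
                 continuous_count = sum(!train$discrete)),
            class = "class_gaussian_model")
}

#' @export
print.class_gaussian_model <- function(x, ...) {
  cat(sprintf(
    "Class-conditional Gaussian model: %d classes, %d features (%d continuous, %d discrete)\n",
    length(x$classes), x$feature_count, x$continuous_count,
    x$feature_count - x$continuous_count))
  invisible(x)
}

#' Generate virtual samples for one class
#'
#' Draws `m` rows: continuous feature j is drawn independently from
#' Normal(mu[c, j], eta[c, j]^2); discrete feature j is set to the stored
#' class mode exactly (the eta^2 = 0 degenerate draw). Deterministic given
#' the seed.
#'
#' @param model a `class_gaussian_model`.
#' @param class_label the class to generate for.
#' @param m number of virtual rows (>= 0).
#' @param seed integer seed.
#' @return a `feature_table` of `m` rows labeled `class_label`.
#' @export
generate_virtual_samples <- function(model, class_label, m, seed = 1L) {
  ci <- match(as.character(class_label), model$classes)
  if (is.na(ci)) {
    stop(sprintf("unknown class '%s' (model has: %s)", class_label,
                 paste(model$classes, collapse = ", ")), call. = FALSE)
  }
  check_that(m >= 0, "m must be >= 0")
  set.seed(seed)
  k <- model$feature_count
  x <- matrix(0, m, k, dimnames = list(NULL, colnames(model$mu)))
  if (m > 0) {
    for (j in seq_len(k)) {
      x[, j] <- if (model$discrete[j]) rep(model$mu[ci, j], m)
                else stats::rnorm(m, model$mu[ci, j], model$eta[ci, j])
    }
  }
  feature_table(x, factor(rep(as.character(class_label), m),
                          levels = model$classes),
                model$discrete)
}

#' Augment a training set with class-conditional virtual samples
#'
#' Fits the class Gaussians on `train` and generates
#' `replication_factor x N_c` virtual rows for each class c with N_c
#' original rows, then merges them with the originals (when
#' `include_originals`). For a balanced input of N rows the output holds
#' `N * (1 + R)` rows. Intended for training folds only — augmenting test
#' data would corrupt evaluation; the pipeline enforces this.
#'
#' @param train a `feature_table` of original training rows.
#' @param spec an [augmentation_spec()].
#' @return a `feature_table`; virtual rows carry `NA` subject/trial ids so
#'   the originals remain identifiable.
#' @export
augment_training_set <- function(train, spec = augmentation_spec()) {
  model <- fit_class_gaussian(train)
  r <- spec$replication_factor
  if (r == 0L) {
    return(if (spec$include_originals) train else ft_rows(train, integer(0)))
  }
  parts <- list()
  for (ci in seq_along(model$classes)) {
    n_c <- sum(train$y == model$classes[ci])
    vt <- generate_virtual_samples(model, model$classes[ci], r * n_c,
                                   seed = derive_seed(spec$seed, ci))
    vt$y <- factor(as.character(vt$y), levels = levels(train$y))
    parts[[ci]] <- vt
  }
  virt <- Reduce(ft_rbind, parts)
  if (spec$include_originals) ft_rbind(train, virt) else virt
}
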