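#' ELM activation functions
#'
#' The five hidden-unit activations used by the extreme learning machine
#' bank: sine, triangular basis `max(0, 1 - |z|)`, radial basis
#' `exp(-z^2)`, logistic, and hard limit `1[z >= 0]`.
#'
#' @format character vector of activation names.
#' @export
elm_activations <- c("sine", "tribas", "radbas", "logistic", "hardlim")

elm_activation_fun <- function(name) {
  switch(name,
    sine = sin,
    tribas = function(z) pmax(1 - abs(z), 0),   # z first so dims survive
    radbas = function(z) exp(-z^2),
    logistic = function(z) 1 / (1 + exp(-z)),
    hardlim = function(z) (z >= 0) * 1,
    stop(sprintf("unknown ELM activation '%s'", name), call. = FALSE))
}

#' Train an extreme learning machine
#'
#' Single-hidden-layer network with random fixed input weights: `W` and
#' `b` are drawn Uniform(-1, 1) from the seed, the hidden matrix is
#' `G = activation(X W' + b)`, and the output weights solve the
#' (ridge-regularized) least-squares system against one-hot class targets.
#' With `ridge = 0` the minimum-norm solution is taken via the
#' Moore-Penrose pseudoinverse of `G`, so with at least as many hidden
#' units as distinct training points the machine interpolates the training
#' labels.
#'
#' @param X feature matrix (rows = samples).
#' @param y class labels.
#' @param hidden number of hidden units H (>= 1).
#' @param activation one of [elm_activations].
#' @param ridge ridge coefficient (default 1e-6; 0 = pseudoinverse).
#' @param seed integer seed for the random input weights.
#' @return an `elm` model.
#' @export
train_elm <- function(X, y, hidden, activation = "sine", ridge = 1e-6,
                      seed = 1L) {
  X <- as.matrix(X)
  y <- factor(y)
  check_that(hidden >= 1, "hidden must be >= 1")
  check_that(nlevels(y) >= 2, "need at least 2 classes")
  act <- elm_activation_fun(activation)
  set.seed(seed)
  d <- ncol(X)
  W <- matrix(stats::runif(hidden * d, -1, 1), hidden, d)
  b <- stats::runif(hidden, -1, 1)
  G <- act(sweep(X %*% t(W), 2L, b, `+`))
  Yh <- stats::model.matrix(~ y - 1)             # one-hot targets
  B <- if (ridge > 0) {
    solve(crossprod(G) + ridge * diag(hidden), crossprod(G, Yh))
  } else {
    MASS::ginv(G) %*% Yh
  }
  structure(list(W = W, b = b, B = B, activation = activation,
                 classes = levels(y), hidden = hidden, ridge = ridge,
                 seed = seed),
            class = "elm")
}

#' @export
print.elm <- function(x, ...) {
  cat(sprintf("ELM: %d hidden units, %s activation, %d classes\n",
              x$hidden, x$activation, length(x$classes)))
  invisible(x)
}

elm_raw_scores <- function(object, X) {
  act <- elm_activation_fun(object$activation)
  G <- act(sweep(as.matrix(X) %*% t(object$W), 2L, object$b, `+`))
  S <- G %*% object$B
  colnames(S) <- object$classes
  S
}

#' @export
predict.elm <- function(object, newdata,
                        type = c("class", "score", "prob"), ...) {
  type <- match.arg(type)
  S <- elm_raw_scores(object, newdata)
  switch(type,
    class = factor(object$classes[argmax_first(S)], levels = object$classes),
    score = S,
    prob = row_softmax(S))
}

#' The six SVM kernel variants
#'
#' Linear, quadratic, cubic, and three Gaussian kernels whose scales follow
#' the convention the fine/medium/coarse names come from:
#' `sqrt(d)/4`, `sqrt(d)` and `4*sqrt(d)` with `d` the feature count.
#'
#' @format character vector of kernel names.
#' @export
svm_kernels <- c("linear", "quadratic", "cubic",
                 "fine-gaussian", "medium-gaussian", "coarse-gaussian")

svm_kernel_params <- function(kernel, d) {
  switch(kernel,
    "linear" = list(kernel = "linear"),
    "quadratic" = list(kernel = "polynomial", degree = 2, gamma = 1,
                       coef0 = 1),
    "cubic" = list(kernel = "polynomial", degree = 3, gamma = 1, coef0 = 1),
    "fine-gaussian" = list(kernel = "radial", gamma = 1 / (sqrt(d) / 4)^2),
    "medium-gaussian" = list(kernel = "radial", gamma = 1 / sqrt(d)^2),
    "coarse-gaussian" = list(kernel = "radial", gamma = 1 / (4 * sqrt(d))^2),
    stop(sprintf("unknown SVM kernel '%s'", kernel), call. = FALSE))
}

#' Train a multiclass soft-margin SVM
#'
#' Wraps a one-vs-one multiclass SVM with one of the six named kernels.
#' Class scores are obtained by summing each class's signed one-vs-one
#' decision values and softmax-normalizing the sums, giving a
#' deterministic, row-normalized score table comparable across
#' classifiers.
#'
#' @param X feature matrix.
#' @param y class labels (>= 2 classes present).
#' @param kernel one of [svm_kernels].
#' @param cost box constraint (default 1).
#' @return an `svm_variant` model.
#' @export
train_svm <- function(X, y, kernel = "linear", cost = 1) {
  X <- as.matrix(X)
  y <- droplevels(factor(y))
  check_that(nlevels(y) >= 2, "need at least 2 classes")
  pars <- svm_kernel_params(kernel, ncol(X))
  fit <- do.call(e1071::svm, c(list(x = X, y = y, cost = cost,
                                    scale = FALSE), pars))
  structure(list(fit = fit, kernel = kernel, classes = levels(y)),
            class = "svm_variant")
}

#' @export
print.svm_variant <- function(x, ...) {
  cat(sprintf("SVM: %s kernel, %d classes, %d support vectors\n",
              x$kernel, length(x$classes), x$fit$tot.nSV))
  invisible(x)
}

#' @export
predict.svm_variant <- function(object, newdata,
                                type = c("class", "prob"), ...) {
  type <- match.arg(type)
  p <- stats::predict(object$fit, as.matrix(newdata),
                      decision.values = TRUE)
  if (type == "class") {
    return(factor(as.character(p), levels = object$classes))
  }
  dec <- attr(p, "decision.values")
  cls <- object$classes
  S <- matrix(0, nrow(as.matrix(newdata)), length(cls),
              dimnames = list(NULL, cls))
  for (cn in colnames(dec)) {
    pair <- strsplit(cn, "/", fixed = TRUE)[[1]]
    S[, pair[1]] <- S[, pair[1]] + dec[, cn]
    S[, pair[2]] <- S[, pair[2]] - dec[, cn]
  }
  row_softmax(S)
}

#' Train a softmax (multinomial logistic) classifier
#'
#' The "SL" head: a multinomial logistic model on the encoded features,
#' fitted with weight decay `l2`, exposing class probabilities that sum to
#' one per row.
#'
#' @param X feature matrix.
#' @param y class labels.
#' @param l2 weight-decay coefficient (default 1e-4).
#' @param maxit optimizer iteration cap (default 200).
#' @return a `softmax_classifier`.
#' @export
train_softmax <- function(X, y, l2 = 1e-4, maxit = 200) {
  X <- as.matrix(X)
  check_that(all(is.finite(X)), "X must be finite")
  y <- droplevels(factor(y))
  check_that(nlevels(y) >= 2, "need at least 2 classes")
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  df <- data.frame(.y = y, X)
  fit <- nnet::multinom(.y ~ ., data = df, decay = l2, maxit = maxit,
                        trace = FALSE,
                        MaxNWts = max(10000L, (ncol(X) + 2L) * nlevels(y) * 2L))
  structure(list(fit = fit, classes = levels(y),
                 feature_names = names(df)[-1L]),
            class = "softmax_classifier")
}

#' @export
print.softmax_classifier <- function(x, ...) {
  cat(sprintf("Softmax layer: %d classes on %d features\n",
              length(x$classes), length(x$feature_names)))
  invisible(x)
}

#' @export
predict.softmax_classifier <- function(object, newdata,
                                       type = c("class", "prob"), ...) {
  type <- match.arg(type)
  nd <- as.data.frame(as.matrix(newdata))
  names(nd) <- object$feature_names
  if (type == "class") {
    p <- stats::predict(object$fit, nd, type = "class")
    return(factor(as.character(p), levels = object$classes))
  }
  pr <- stats::predict(object$fit, nd, type = "probs")
  if (is.null(dim(pr))) {                 # binary: vector of P(class 2)
    pr <- cbind(1 - pr, pr)
  }
  pr <- as.matrix(pr)
  colnames(pr) <- object$classes
  pr
}
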