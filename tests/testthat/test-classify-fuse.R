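test_that("an ELM with H >= N and no ridge interpolates XOR", {
  X <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  y <- c("a", "b", "b", "a")
  m <- train_elm(X, y, hidden = 10, activation = "logistic", ridge = 0,
                 seed = 4)
  expect_equal(as.character(predict(m, X)), y)
})

test_that("ELM output weights match an independent svd pseudoinverse", {
  set.seed(15)
  X <- matrix(rnorm(12 * 3), 12, 3)
  y <- rep(c("a", "b", "c"), 4)
  m <- train_elm(X, y, hidden = 20, activation = "sine", ridge = 0, seed = 7)
  act <- sin
  G <- act(sweep(X %*% t(m$W), 2L, m$b, `+`))
  Y <- stats::model.matrix(~ factor(y) - 1)
  B_oracle <- svd_pinv(G) %*% Y
  expect_equal(unname(m$B), unname(B_oracle), tolerance = 1e-8)
})

test_that("ELM separates far-apart blobs on held-out data", {
  ft <- make_toy_multiclass(40, 2, 4, separation = 10, seed = 18)
  tr <- seq(1, 80, by = 2); te <- seq(2, 80, by = 2)
  m <- train_elm(ft$x[tr, ], ft$y[tr], hidden = 50, activation = "sine",
                 ridge = 1e-4, seed = 3)
  acc <- mean(predict(m, ft$x[te, ]) == ft$y[te])
  expect_gte(acc, 0.95)
})

test_that("ELM training is seed-deterministic and validates inputs", {
  X <- matrix(rnorm(20), 10, 2)
  y <- rep(c("a", "b"), 5)
  a <- train_elm(X, y, 8, "radbas", seed = 5)
  b <- train_elm(X, y, 8, "radbas", seed = 5)
  expect_identical(a$B, b$B)
  expect_error(train_elm(X, y, 0), "hidden")
  expect_error(train_elm(X, rep("a", 10), 5), "classes")
})

test_that("ELM probability scores are row-normalized", {
  ft <- make_toy_multiclass(10, 3, 4, 3, seed = 2)
  m <- train_elm(ft$x, ft$y, 30, "tribas", seed = 1)
  p <- predict(m, ft$x, type = "prob")
  expect_equal(rowSums(p), rep(1, 30), tolerance = 1e-9)
})

test_that("linear SVM separates linearly separable data exactly", {
  ft <- make_toy_multiclass(15, 2, 3, separation = 8, seed = 3)
  m <- train_svm(ft$x, ft$y, "linear")
  expect_equal(mean(predict(m, ft$x) == ft$y), 1.0)
})

concentric_circles <- function(n, seed) {
  set.seed(seed)
  r <- rep(c(1, 3), each = n)
  th <- runif(2 * n, 0, 2 * pi)
  list(x = cbind(r * cos(th), r * sin(th)) + matrix(rnorm(4 * n, 0, 0.1),
                                                    2 * n, 2),
       y = rep(c("inner", "outer"), each = n))
}

test_that("Gaussian and polynomial kernels solve radially separable data", {
  cc <- concentric_circles(60, 8)
  lin <- train_svm(cc$x, cc$y, "linear")
  expect_lte(mean(predict(lin, cc$x) == cc$y), 0.7)
  fine <- train_svm(cc$x, cc$y, "fine-gaussian")
  expect_gte(mean(predict(fine, cc$x) == cc$y), 0.9)
  quad <- train_svm(cc$x, cc$y, "quadratic")  # separable by a conic
  expect_equal(mean(predict(quad, cc$x) == cc$y), 1.0)
})

test_that("SVM scores are row-normalized and the class argmax is coherent", {
  ft <- make_toy_multiclass(12, 3, 4, separation = 8, seed = 5)
  m <- train_svm(ft$x, ft$y, "medium-gaussian")
  p <- predict(m, ft$x, type = "prob")
  expect_equal(rowSums(p), rep(1, 36), tolerance = 1e-9)
  expect_equal(colnames(p), m$classes)
  expect_error(train_svm(ft$x, rep("a", 36), "linear"), "classes")
})

test_that("softmax probabilities normalize, separate blobs, and shrink", {
  ft <- make_toy_multiclass(20, 3, 4, separation = 10, seed = 6)
  m <- train_softmax(ft$x, ft$y, l2 = 1e-4)
  p <- predict(m, ft$x, type = "prob")
  expect_equal(unname(rowSums(p)), rep(1, 60), tolerance = 1e-9)
  expect_gte(mean(predict(m, ft$x) == ft$y), 0.95)
  # total shrinkage: probabilities collapse to 1/n_classes
  m0 <- train_softmax(ft$x, ft$y, l2 = 1e8)
  p0 <- predict(m0, ft$x, type = "prob")
  expect_equal(unname(as.vector(p0)), rep(1 / 3, 180), tolerance = 1e-3)
  expect_error(train_softmax(matrix(c(1, NaN), 1, 2), "a"), "finite")
})

test_that("variant selection takes the accuracy argmax, first on ties", {
  X <- matrix(0, 20, 1)
  truth <- rep(c("a", "b"), 10)
  flip <- function(lab, k) { lab[seq_len(k)] <- "z"; lab }  # k wrong labels
  cand <- list(v1 = mock_classifier(flip(truth, 4)),   # accuracy 0.80
               v2 = mock_classifier(flip(truth, 2)),   # accuracy 0.90
               v3 = mock_classifier(flip(truth, 3)))   # accuracy 0.85
  sel <- select_best_variant(cand, X, truth)
  expect_equal(sel$variant, "v2")
  expect_equal(unname(sel$accuracies), c(0.80, 0.90, 0.85))

  one <- select_best_variant(cand["v1"], X, truth)
  expect_equal(one$variant, "v1")

  tied <- select_best_variant(list(p = cand$v2, q = cand$v2), X, truth)
  expect_equal(tied$variant, "p")          # first declared wins ties
  expect_error(select_best_variant(list(), X, truth), "candidate")
})

test_that("per-class accuracy is the recall of each true class", {
  out <- per_class_accuracy(c("a", "b", "b", "b"), c("a", "a", "b", "b"))
  expect_equal(out, c(a = 0.5, b = 1.0))
  expect_equal(per_class_accuracy(c("a", "b"), c("a", "b")),
               c(a = 1, b = 1))
  expect_warning(per_class_accuracy("a", "a", classes = c("a", "b")),
                 "absent")
})

test_that("per-class accuracy matches a confusion-matrix oracle", {
  set.seed(23)
  for (rep in 1:5) {
    truth <- sample(c("x", "y", "z"), 40, TRUE)
    pred <- sample(c("x", "y", "z"), 40, TRUE)
    cm <- table(factor(truth, c("x", "y", "z")),
                factor(pred, c("x", "y", "z")))
    oracle <- diag(cm) / rowSums(cm)
    got <- per_class_accuracy(pred, truth)
    expect_equal(got[names(oracle)], oracle, ignore_attr = TRUE,
                 tolerance = 1e-12)
  }
})

test_that("local-classifier selection is an argmax with fixed-priority ties", {
  tab <- select_local_classifiers(list(
    ELM = c(`1` = 0.9, `2` = 0.5),
    SVM = c(`1` = 0.6, `2` = 0.8)))
  expect_equal(tab$classifier, c("ELM", "SVM"))
  expect_equal(tab$accuracy, c(0.9, 0.8))

  only <- select_local_classifiers(list(SL = c(a = 0.4, b = 0.7)))
  expect_true(all(only$classifier == "SL"))

  tied <- select_local_classifiers(list(ELM = c(a = 0.5, b = 0.5),
                                        SVM = c(a = 0.5, b = 0.5),
                                        SL = c(a = 0.5, b = 0.5)))
  expect_true(all(tied$classifier == "ELM"))   # declaration-order priority

  expect_error(select_local_classifiers(list(ELM = c(a = 1),
                                             SVM = c(b = 1))),
               "class set")
})

test_that("selected per-class accuracy equals the column-wise max, exhaustively", {
  grid <- seq(0, 1, by = 0.25)
  for (a1 in grid) for (a2 in grid) for (b1 in grid) for (b2 in grid) {
    tab <- select_local_classifiers(list(C1 = c(k1 = a1, k2 = a2),
                                         C2 = c(k1 = b1, k2 = b2)))
    expect_equal(tab$accuracy, c(max(a1, b1), max(a2, b2)))
    expect_equal(tab$classifier,
                 c(if (a1 >= b1) "C1" else "C2",
                   if (a2 >= b2) "C1" else "C2"))
  }
})

test_that("fusion reduces to the owning classifier and gates per class", {
  # all classes owned by one classifier -> that classifier's argmax
  sA <- matrix(c(0.7, 0.3, 0.2, 0.8, 0.5, 0.5), 3, 2, byrow = TRUE,
               dimnames = list(NULL, c("k1", "k2")))
  sB <- matrix(c(0.1, 0.9, 0.9, 0.1, 0.6, 0.4), 3, 2, byrow = TRUE,
               dimnames = list(NULL, c("k1", "k2")))
  own_all <- select_local_classifiers(list(A = c(k1 = 0.9, k2 = 0.9),
                                           B = c(k1 = 0.1, k2 = 0.1)))
  expect_equal(as.character(fuse_predict(own_all, list(A = sA))),
               c("k1", "k2", "k1"))       # ties -> lowest class index

  # split ownership: class k1 from A, class k2 from B; enumerate patterns
  fus <- select_local_classifiers(list(A = c(k1 = 0.9, k2 = 0.2),
                                       B = c(k1 = 0.3, k2 = 0.8)))
  fused <- fuse_predict(fus, list(A = sA, B = sB))
  hand <- character(3)
  for (i in 1:3) hand[i] <- if (sA[i, "k1"] >= sB[i, "k2"]) "k1" else "k2"
  expect_equal(as.character(fused), hand)

  expect_error(fuse_predict(fus, list(A = sA)), "missing score tables")
})

test_that("fused accuracy is at least the worst single classifier's", {
  set.seed(40)
  truth <- sample(c("k1", "k2"), 50, TRUE)
  mk <- function(acc) {
    s <- matrix(0.5, 50, 2, dimnames = list(NULL, c("k1", "k2")))
    hit <- runif(50) < acc
    lab <- ifelse(hit, truth, ifelse(truth == "k1", "k2", "k1"))
    s[cbind(1:50, match(lab, c("k1", "k2")))] <- 0.9
    s[cbind(1:50, 3 - match(lab, c("k1", "k2")))] <- 0.1
    s
  }
  sA <- mk(0.9); sB <- mk(0.6)
  accs <- function(s) per_class_accuracy(colnames(s)[max.col(s)], truth)
  fus <- select_local_classifiers(list(A = accs(sA), B = accs(sB)))
  fused <- fuse_predict(fus, list(A = sA, B = sB))
  acc_f <- mean(fused == truth)
  acc_each <- c(mean(colnames(sA)[max.col(sA)] == truth),
                mean(colnames(sB)[max.col(sB)] == truth))
  expect_gte(acc_f, min(acc_each))
})
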