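test_that("class Gaussians store sample mean and N-1 standard deviation", {
  ft <- feature_table(matrix(c(2, 4, 10, 10), 2, 2), c("a", "a"))
  m <- fit_class_gaussian(ft)
  expect_equal(unname(m$mu["a", 1]), 3)
  expect_equal(unname(m$eta["a", 1]), sqrt(2))   # two-point sample sd
  expect_equal(unname(m$eta["a", 2]), 0)
  expect_true(all(m$eta >= 0))
})

test_that("discrete features get eta = 0 and mu = the class mode", {
  x <- cbind(rnorm(5), c(3, 3, 3, 2, 3))
  ft <- feature_table(x, rep("a", 5), discrete = c(FALSE, TRUE))
  m <- fit_class_gaussian(ft)
  expect_equal(unname(m$mu["a", 2]), 3)
  expect_equal(unname(m$eta["a", 2]), 0)
  expect_equal(m$continuous_count, 1)
  expect_equal(m$feature_count, 2)
})

test_that("a single-row class is rejected with actionable advice", {
  ft <- feature_table(matrix(rnorm(3), 1, 3), "a")
  expect_error(fit_class_gaussian(ft), "at least 2")
})

test_that("degenerate Gaussians generate identical rows; m = 0 keeps schema", {
  ft <- feature_table(matrix(rep(c(1, 2), each = 3), 3, 2), rep("a", 3),
                      discrete = c(TRUE, TRUE))
  m <- fit_class_gaussian(ft)
  v <- generate_virtual_samples(m, "a", 5, seed = 2)
  expect_equal(nrow(v$x), 5)
  expect_true(all(v$x[, 1] == 1) && all(v$x[, 2] == 2))

  v0 <- generate_virtual_samples(m, "a", 0, seed = 2)
  expect_equal(nrow(v0$x), 0)
  expect_equal(ncol(v0$x), 2)
  expect_identical(v0$discrete, m$discrete)
  expect_error(generate_virtual_samples(m, "zz", 1), "unknown class")
})

test_that("virtual samples recover the fitted moments at the 3/sqrt(m) rate", {
  set.seed(44)
  ft <- make_toy_multiclass(30, 3, 5, separation = 4, seed = 44)
  model <- fit_class_gaussian(ft)
  m <- 100000
  for (cl in model$classes) {
    v <- generate_virtual_samples(model, cl, m, seed = derive_seed(44, 1))
    tol <- 3 / sqrt(m)
    mu_err <- abs(colMeans(v$x) - model$mu[cl, ]) /
      pmax(model$eta[cl, ], 1e-12)       # error in units of eta
    expect_true(all(mu_err < tol))
    sd_err <- abs(apply(v$x, 2L, sd) - model$eta[cl, ]) /
      pmax(model$eta[cl, ], 1e-12)
    expect_true(all(sd_err < tol))
  }
})

test_that("generation is deterministic given the seed", {
  ft <- make_toy_multiclass(10, 2, 3, 2, seed = 3)
  m <- fit_class_gaussian(ft)
  a <- generate_virtual_samples(m, "c1", 50, seed = 9)
  b <- generate_virtual_samples(m, "c1", 50, seed = 9)
  expect_identical(a$x, b$x)
})

test_that("reiterating 1000 times turns 12 training rows into 12012", {
  ft <- make_toy_multiclass(4, 3, 3, separation = 3, seed = 5)  # 12 rows
  out <- augment_training_set(ft, augmentation_spec(1000, TRUE, seed = 6))
  expect_equal(nrow(out$x), 12 + 12000)
  expect_identical(levels(out$y), levels(ft$y))    # label set preserved
  expect_true(all(table(out$y) == 4 * (1 + 1000))) # per-class bookkeeping
})

test_that("replication factor 0 returns the input unchanged", {
  ft <- make_toy_multiclass(5, 2, 3, 2, seed = 1)
  out <- augment_training_set(ft, augmentation_spec(0, TRUE, seed = 1))
  expect_identical(out$x, ft$x)
  expect_identical(out$y, ft$y)
})

test_that("per-class virtual counts scale with each class's original count", {
  # unbalanced 3-class table: 4, 6 and 8 rows
  ft <- make_toy_multiclass(8, 3, 3, separation = 3, seed = 9)
  keep <- c(1:4, 9:14, 17:24)
  ft <- ft_rows(ft, keep)
  out <- augment_training_set(ft, augmentation_spec(10, FALSE, seed = 2))
  expect_equal(unname(table(out$y)[c("c1", "c2", "c3")]),
               10 * c(4, 6, 8), ignore_attr = TRUE)
})

test_that("virtual discrete values never leave the observed class codes", {
  ft <- make_toy_multiclass(12, 3, 4, separation = 2, discrete_cols = c(2, 4),
                            seed = 21)
  out <- augment_training_set(ft, augmentation_spec(20, FALSE, seed = 3))
  for (cl in levels(ft$y)) {
    seen2 <- unique(ft$x[ft$y == cl, 2])
    seen4 <- unique(ft$x[ft$y == cl, 4])
    expect_true(all(out$x[out$y == cl, 2] %in% seen2))
    expect_true(all(out$x[out$y == cl, 4] %in% seen4))
  }
})
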