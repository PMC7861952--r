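# Shared fixtures, memoised so expensive cross-validated runs are computed
# once per test session and reused by the module and acceptance tests.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# separable 3-class toy benchmark: 60 rows, separation 10
toy_table <- function() {
  memo("toy_table",
       make_toy_multiclass(20, 3, 8, separation = 10, n_subjects = 2,
                           seed = 7))
}

toy_run <- function() {
  memo("toy_run", run_pipeline(toy_table(), pipeline_config("test", seed = 42)))
}

toy_run_repeat <- function() {
  memo("toy_run_repeat",
       run_pipeline(toy_table(), pipeline_config("test", seed = 42)))
}

# small simulated-EMG study: 2 subjects, 3 classes, 2 channels, 6 reps
emg_dataset <- function() {
  memo("emg_dataset", simulate_emg_dataset(
    emg_sim_spec(n_subjects = 2, n_classes = 3, n_channels = 2,
                 n_repetitions = 6, seed = 11)))
}

emg_run <- function() {
  memo("emg_run", run_pipeline(emg_dataset(), pipeline_config("test", seed = 5)))
}

# mock classifier with canned predictions, for selection/fusion tests
mock_classifier <- function(labels) {
  structure(list(labels = labels), class = "mock_classifier")
}

predict.mock_classifier <- function(object, newdata, ...) {
  object$labels[seq_len(nrow(as.matrix(newdata)))]
}

# registered so predict() dispatches inside package functions too
registerS3method("predict", "mock_classifier", predict.mock_classifier)

# brute-force DFT of one frame: literal O(N^2) sum, independent of fft()
brute_dft <- function(x, n_fft) {
  x <- c(x, rep(0, n_fft - length(x)))
  vapply(0:(n_fft %/% 2), function(k) {
    sum(x * exp(-2i * pi * k * (seq_along(x) - 1) / n_fft))
  }, complex(1))
}

# svd-based Moore-Penrose pseudoinverse, written out as the oracle
svd_pinv <- function(M, tol = 1e-10) {
  s <- svd(M)
  keep <- s$d > tol * max(s$d)
  s$v[, keep, drop = FALSE] %*%
    diag(1 / s$d[keep], sum(keep)) %*% t(s$u[, keep, drop = FALSE])
}

# activation definitions written out independently of the package internals
elm_activation_fun_local <- function(name) {
  switch(name,
         sine = function(z) sin(z),
         radbas = function(z) exp(-z^2),
         logistic = function(z) 1 / (1 + exp(-z)))
}

row_softmax_local <- function(m) {
  e <- exp(m - apply(m, 1, max))
  e / rowSums(e)
}
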