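#' Derive a stage seed from a master seed
#'
#' The pipeline fans one master seed out to its stages through a fixed
#' affine-mod scheme, so any stage can be re-run in isolation with the seed
#' recorded in the run report. The result is always a valid 32-bit integer
#' seed.
#'
#' @param master integer master seed.
#' @param stage integer stage index (0-based; each pipeline stage has a fixed
#'   index recorded in the run report).
#' @param fold integer fold index (0 for fold-independent stages).
#' @return an integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, stage, fold = 0L) {
  m <- 2147483647                       # 2^31 - 1 (prime)
  s <- (as.numeric(master) %% m) * 48271 + as.numeric(stage) * 10007 +
    as.numeric(fold) * 101
  as.integer(s %% m)
}

## internal validation helper: stop with the offending condition named
check_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

## softmax by row, numerically stable
row_softmax <- function(m) {
  m <- as.matrix(m)
  m <- m - apply(m, 1L, max)
  e <- exp(m)
  e / rowSums(e)
}

## argmax over columns with ties broken by the first (lowest-index) column
argmax_first <- function(m) max.col(as.matrix(m), ties.method = "first")
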