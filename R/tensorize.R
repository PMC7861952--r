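#' Multiway feature tensor
#'
#' A named-axis view of a feature vector or array (e.g. a spectrogram as
#' channel x frequency x time). Flattening and mode unfolding use a fixed,
#' documented element order — row-major, last axis fastest — so serialized
#' tensors are portable across implementations.
#'
#' @param data numeric array (or vector for 1-way tensors).
#' @param axis_names character vector naming each axis, unique.
#' @return an object of class `feature_tensor` with fields `data`,
#'   `axis_names`, `shape`.
#' @export
feature_tensor <- function(data, axis_names) {
  if (is.null(dim(data))) dim(data) <- length(data)
  dim(data) <- as.integer(unname(dim(data)))   # strip axis-size names
  check_that(length(axis_names) == length(dim(data)),
             "one axis name per array dimension required")
  check_that(!anyDuplicated(axis_names), "axis names must be unique")
  structure(list(data = data, axis_names = as.character(axis_names),
                 shape = dim(data)),
            class = "feature_tensor")
}

#' @export
print.feature_tensor <- function(x, ...) {
  cat("Feature tensor:",
      paste(sprintf("%s=%d", x$axis_names, x$shape), collapse = " x "), "\n")
  invisible(x)
}

#' Reshape a flat feature row into a tensor
#'
#' Lossless inverse of [flatten_tensor()]: the vector is interpreted in
#' row-major (last-axis-fastest) order over the requested axes.
#'
#' @param row numeric vector.
#' @param axis_sizes named integer vector, e.g. `c(channel = 2, time = 3)`;
#'   its product must equal `length(row)`.
#' @return a `feature_tensor`.
#' @export
tensorize_features <- function(row, axis_sizes) {
  if (prod(axis_sizes) != length(row)) {
    stop(sprintf("size mismatch: expected %d elements (product of axes), got %d",
                 prod(axis_sizes), length(row)), call. = FALSE)
  }
  k <- length(axis_sizes)
  arr <- if (k == 1L) array(row, axis_sizes)
         else aperm(array(row, rev(axis_sizes)), k:1)
  feature_tensor(arr, names(axis_sizes))
}

#' Flatten a tensor to a feature row
#'
#' Row-major (last-axis-fastest) order; exact inverse of
#' [tensorize_features()].
#'
#' @param t a `feature_tensor`.
#' @return numeric vector of length `prod(t$shape)`.
#' @export
flatten_tensor <- function(t) {
  k <- length(t$shape)
  if (k == 1L) as.vector(t$data) else as.vector(aperm(t$data, k:1))
}

#' Mode-n unfolding of a tensor
#'
#' Returns the matrix whose rows are indexed by the chosen axis and whose
#' columns run over the remaining axes in their original order with the
#' last remaining axis fastest.
#'
#' @param t a `feature_tensor`.
#' @param axis axis name or index.
#' @return a matrix of dimension `shape[axis] x prod(shape[-axis])`.
#' @export
unfold_mode <- function(t, axis) {
  n <- resolve_axis(t, axis)
  others <- setdiff(seq_along(t$shape), n)
  if (!length(others)) return(matrix(as.vector(t$data), ncol = 1L))
  ap <- aperm(t$data, c(rev(others), n))
  t(matrix(as.vector(ap), ncol = t$shape[n]))
}

#' Fold a mode-n unfolding back into a tensor
#'
#' Exact inverse of [unfold_mode()] given the original axis layout.
#'
#' @param m matrix produced by [unfold_mode()].
#' @param axis_sizes named sizes of the original tensor, in original order.
#' @param axis the axis that was unfolded (name or index).
#' @return a `feature_tensor` with the original layout.
#' @export
fold_mode <- function(m, axis_sizes, axis) {
  tmp <- feature_tensor(array(0, axis_sizes), names(axis_sizes))
  n <- resolve_axis(tmp, axis)
  others <- setdiff(seq_along(axis_sizes), n)
  if (!length(others)) {
    return(feature_tensor(array(as.vector(m), axis_sizes),
                          names(axis_sizes)))
  }
  ap <- array(as.vector(t(m)), c(rev(axis_sizes[others]), axis_sizes[n]))
  inv <- order(c(rev(others), n))
  feature_tensor(aperm(ap, inv), names(axis_sizes))
}

resolve_axis <- function(t, axis) {
  if (is.character(axis)) {
    n <- match(axis, t$axis_names)
    if (is.na(n)) {
      stop(sprintf("unknown axis '%s' (have: %s)", axis,
                   paste(t$axis_names, collapse = ", ")), call. = FALSE)
    }
    n
  } else {
    check_that(axis >= 1 && axis <= length(t$shape), "axis index out of range")
    as.integer(axis)
  }
}

#' Coordinate transformation with Jacobian
#'
#' A smooth map between two N-dimensional coordinate systems together with
#' its NxN Jacobian (the matrix of first-order partial derivatives). If no
#' analytic Jacobian is supplied, a central-difference approximation is
#' used. Transforms compose: see [compose_transforms()].
#'
#' @param forward function `R^N -> R^N`.
#' @param jacobian function returning the NxN Jacobian at a point, or
#'   `NULL` for numerical differentiation.
#' @param dim dimension N.
#' @return an object of class `coordinate_transform`.
#' @export
coordinate_transform <- function(forward, jacobian = NULL, dim) {
  if (is.null(jacobian)) {
    jacobian <- function(x) numerical_jacobian(forward, x)
  }
  structure(list(forward = forward, jacobian = jacobian,
                 dim = as.integer(dim)),
            class = "coordinate_transform")
}

#' Affine coordinate transformation
#'
#' `T(x) = A x + b`; the Jacobian is the constant matrix `A`.
#'
#' @param A square matrix.
#' @param b offset vector (default zero).
#' @return a `coordinate_transform`.
#' @export
affine_transform <- function(A, b = rep(0, nrow(A))) {
  A <- as.matrix(A)
  check_that(nrow(A) == ncol(A), "A must be square")
  check_that(length(b) == nrow(A), "b must match dim(A)")
  force(A); force(b)
  coordinate_transform(function(x) as.vector(A %*% x + b),
                       function(x) A, nrow(A))
}

#' Identity transform in N dimensions
#'
#' The default pipeline transform: tensorization is then a pure
#' axis-structured view of the features, with [coordinate_transform()]
#' available as the extension point for non-trivial coordinate changes.
#'
#' @param dim dimension N.
#' @return a `coordinate_transform`.
#' @export
identity_transform <- function(dim) {
  affine_transform(diag(dim))
}

#' Compose two coordinate transformations
#'
#' The composite applies `t1` then `t2` (`T3 = T2 T1`); by the chain rule
#' its Jacobian at `x` is `J2(T1(x)) %*% J1(x)`, so for affine maps the
#' composite Jacobian determinant is the product of the factors'.
#'
#' @param t1,t2 `coordinate_transform` objects of equal dimension.
#' @return the composite `coordinate_transform`.
#' @export
compose_transforms <- function(t1, t2) {
  check_that(t1$dim == t2$dim,
             sprintf("dimension mismatch: %d vs %d", t1$dim, t2$dim))
  force(t1); force(t2)
  coordinate_transform(
    forward = function(x) t2$forward(t1$forward(x)),
    jacobian = function(x) t2$jacobian(t1$forward(x)) %*% t1$jacobian(x),
    dim = t1$dim
  )
}

#' Central-difference numerical Jacobian
#'
#' @param f function `R^N -> R^N`.
#' @param x point of evaluation.
#' @param h step size (default `1e-6 * (1 + |x|)` per coordinate).
#' @return the NxN Jacobian approximation.
#' @export
numerical_jacobian <- function(f, x, h = NULL) {
  n <- length(x)
  if (is.null(h)) h <- 1e-6 * (1 + abs(x))
  h <- rep_len(h, n)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    e <- numeric(n); e[j] <- h[j]
    J[, j] <- (f(x + e) - f(x - e)) / (2 * h[j])
  }
  J
}
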