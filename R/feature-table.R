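#' Construct a labeled feature table
#'
#' The common currency between the pipeline stages: a numeric matrix of
#' feature rows, a class label per row, and a per-column flag marking
#' discrete (integer-coded) columns, plus optional per-row metadata used by
#' the cross-validation protocol (subject and trial identifiers).
#'
#' @param x numeric matrix (rows = samples, columns = features).
#' @param y class labels, one per row (coerced to factor).
#' @param discrete logical vector, one flag per column; `NULL` means all
#'   continuous.
#' @param subject optional per-row subject identifiers.
#' @param trial_id optional per-row trial identifiers (used by the leakage
#'   guard in the pipeline).
#' @return an object of class `feature_table`.
#' @export
feature_table <- function(x, y, discrete = NULL, subject = NULL,
                          trial_id = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- factor(y)
  check_that(nrow(x) == length(y), "nrow(x) must equal length(y)")
  if (is.null(discrete)) discrete <- rep(FALSE, ncol(x))
  check_that(length(discrete) == ncol(x),
             "discrete flags must have one entry per feature column")
  if (!is.null(subject)) {
    check_that(length(subject) == nrow(x), "one subject id per row required")
  }
  if (!is.null(trial_id)) {
    check_that(length(trial_id) == nrow(x), "one trial id per row required")
  }
  if (is.null(colnames(x)) && ncol(x) > 0) {
    colnames(x) <- paste0("f", seq_len(ncol(x)))
  }
  structure(
    list(x = x, y = y, discrete = as.logical(discrete),
         subject = subject, trial_id = trial_id),
    class = "feature_table"
  )
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("Feature table: %d rows x %d features, %d classes",
              nrow(x$x), ncol(x$x), nlevels(x$y)))
  if (any(x$discrete)) cat(sprintf(" (%d discrete columns)", sum(x$discrete)))
  cat("\n")
  cat("  classes:", paste(levels(x$y), collapse = ", "), "\n")
  if (!is.null(x$subject)) {
    cat("  subjects:", paste(unique(x$subject), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$x)

#' Subset rows of a feature table
#'
#' @param ft a `feature_table`.
#' @param i row index vector.
#' @return a `feature_table` with the selected rows.
#' @export
ft_rows <- function(ft, i) {
  feature_table(ft$x[i, , drop = FALSE], ft$y[i], ft$discrete,
                subject = if (!is.null(ft$subject)) ft$subject[i],
                trial_id = if (!is.null(ft$trial_id)) ft$trial_id[i])
}

#' Bind two feature tables row-wise
#'
#' Schemas (column count and discrete flags) must agree; the class-label set
#' is the union of levels.
#'
#' @param a,b `feature_table` objects.
#' @return the combined `feature_table`.
#' @export
ft_rbind <- function(a, b) {
  check_that(ncol(a$x) == ncol(b$x), "feature tables have different widths")
  check_that(identical(a$discrete, b$discrete),
             "feature tables have different discrete flags")
  sub <- if (!is.null(a$subject) || !is.null(b$subject)) {
    c(if (is.null(a$subject)) rep(NA, nrow(a$x)) else a$subject,
      if (is.null(b$subject)) rep(NA, nrow(b$x)) else b$subject)
  }
  tid <- if (!is.null(a$trial_id) || !is.null(b$trial_id)) {
    c(if (is.null(a$trial_id)) rep(NA, nrow(a$x)) else a$trial_id,
      if (is.null(b$trial_id)) rep(NA, nrow(b$x)) else b$trial_id)
  }
  feature_table(rbind(a$x, b$x),
                factor(c(as.character(a$y), as.character(b$y)),
                       levels = union(levels(a$y), levels(b$y))),
                a$discrete, subject = sub, trial_id = tid)
}

#' Write a feature table as delimited text
#'
#' One header row; feature columns first, then `class` and optional
#' `subject` / `trial_id` columns. Discrete flags travel in a sidecar JSON
#' file `<path>.meta.json`.
#'
#' @param ft a `feature_table`.
#' @param path output file path (CSV).
#' @export
write_feature_table <- function(ft, path) {
  df <- as.data.frame(ft$x)
  df$class <- as.character(ft$y)
  if (!is.null(ft$subject)) df$subject <- ft$subject
  if (!is.null(ft$trial_id)) df$trial_id <- ft$trial_id
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(discrete = as.logical(ft$discrete),
               classes = levels(ft$y))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path CSV path.
#' @return a `feature_table`.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  meta_path <- paste0(path, ".meta.json")
  special <- intersect(c("class", "subject", "trial_id"), names(df))
  feat <- setdiff(names(df), special)
  discrete <- NULL
  lev <- NULL
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    discrete <- meta$discrete
    lev <- meta$classes
  }
  y <- if (is.null(lev)) factor(df$class) else factor(df$class, levels = lev)
  feature_table(as.matrix(df[feat]), y, discrete,
                subject = if ("subject" %in% special) df$subject,
                trial_id = if ("trial_id" %in% special) df$trial_id)
}

#' Flag discrete feature columns by inspection
#'
#' Default heuristic: a column is discrete when every value is integral and
#' it has at most `max_levels` distinct values. Explicit flags always win.
#'
#' @param ft a `feature_table`.
#' @param max_levels distinct-count ceiling for the heuristic (default 10).
#' @return the table with updated `discrete` flags.
#' @export
detect_discrete <- function(ft, max_levels = 10) {
  flags <- apply(ft$x, 2L, function(col) {
    all(is.finite(col)) && all(col == round(col)) &&
      length(unique(col)) <= max_levels
  })
  ft$discrete <- as.logical(flags)
  ft
}
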