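#' Per-class accuracy (recall of each true class)
#'
#' For each class c present in `truth`: correct predictions among rows with
#' `truth == c`, divided by the count of such rows. Classes absent from
#' `truth` are excluded with a warning.
#'
#' @param predictions predicted labels.
#' @param truth true labels, same length.
#' @param classes the full class set to report over (default: classes seen
#'   in `truth`).
#' @return a named numeric vector, one fraction per class.
#' @export
per_class_accuracy <- function(predictions, truth, classes = NULL) {
  check_that(length(predictions) == length(truth),
             "predictions and truth must have equal lengths")
  predictions <- as.character(predictions)
  truth <- as.character(truth)
  if (is.null(classes)) classes <- sort(unique(truth))
  missing <- setdiff(classes, unique(truth))
  if (length(missing)) {
    warning("classes absent from truth excluded: ",
            paste(missing, collapse = ", "))
    classes <- setdiff(classes, missing)
  }
  out <- vapply(classes, function(cl) {
    idx <- truth == cl
    mean(predictions[idx] == cl)
  }, 0)
  names(out) <- classes
  out
}

#' Select the best variant within a classifier family
#'
#' Evaluates each candidate model's accuracy on a validation split and
#' returns the one with the highest accuracy; ties go to the earliest
#' candidate in the declared order.
#'
#' @param candidates named list of fitted models, each supporting
#'   `predict(model, X)` returning class labels.
#' @param X_val,y_val validation features and labels.
#' @return list with `model`, `variant` (its name) and `accuracies` over
#'   all candidates.
#' @export
select_best_variant <- function(candidates, X_val, y_val) {
  check_that(length(candidates) >= 1, "need at least one candidate")
  acc <- vapply(candidates, function(m) {
    mean(as.character(predict(m, X_val)) == as.character(y_val))
  }, 0)
  best <- which.max(acc)                 # first maximum on ties
  list(model = candidates[[best]], variant = names(candidates)[best],
       accuracies = acc)
}

#' Build the per-class fusion table
#'
#' Assigns every class to the classifier with the highest per-class
#' accuracy for it; ties are broken by the declared priority — the order of
#' `acc_tables` (ELM before SVM before SL in the standard bank).
#'
#' @param acc_tables named list of per-class accuracy vectors (one per
#'   classifier), all covering the same class set.
#' @param variants optional named list mapping classifier id to the variant
#'   id chosen within its family (recorded in the table).
#' @return a `fusion_table`: data frame with `class`, `classifier`,
#'   `variant`, `accuracy`, plus the full selection matrix as attribute
#'   `selection`.
#' @export
select_local_classifiers <- function(acc_tables, variants = NULL) {
  check_that(length(acc_tables) >= 1, "need at least one accuracy table")
  classes <- names(acc_tables[[1]])
  for (nm in names(acc_tables)) {
    if (!identical(sort(names(acc_tables[[nm]])), sort(classes))) {
      stop(sprintf("classifier '%s' covers a different class set", nm),
           call. = FALSE)
    }
  }
  sel <- do.call(rbind, lapply(acc_tables, function(a) a[classes]))
  winner <- apply(sel, 2L, which.max)    # first maximum = declared priority
  tab <- data.frame(
    class = classes,
    classifier = names(acc_tables)[winner],
    variant = if (is.null(variants)) NA_character_
              else unlist(variants)[names(acc_tables)[winner]],
    accuracy = sel[cbind(winner, seq_along(classes))],
    row.names = NULL
  )
  structure(tab, selection = sel, class = c("fusion_table", "data.frame"))
}

#' @export
print.fusion_table <- function(x, ...) {
  cat("Per-class fusion table:\n")
  print.data.frame(x)
  invisible(x)
}

#' Fused prediction through the per-class gate
#'
#' Each class's score column is taken from the classifier that owns the
#' class in the fusion table; the prediction is the argmax over these gated
#' scores, ties resolved to the lowest class index. When one classifier
#' owns every class this reduces exactly to that classifier's own argmax
#' prediction. Score tables must be row-normalized (each row sums to 1) so
#' scores are comparable across classifiers.
#'
#' @param fusion a `fusion_table`.
#' @param score_tables named list of n x n_classes score matrices, one per
#'   classifier appearing in the table, columns named by class.
#' @return factor of fused predictions (levels = the fusion classes).
#' @export
fuse_predict <- function(fusion, score_tables) {
  classes <- fusion$class
  need <- unique(fusion$classifier)
  miss <- setdiff(need, names(score_tables))
  if (length(miss)) {
    stop("missing score tables for: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(score_tables[[need[1]]])
  fused <- matrix(0, n, length(classes), dimnames = list(NULL, classes))
  for (i in seq_along(classes)) {
    st <- score_tables[[fusion$classifier[i]]]
    check_that(classes[i] %in% colnames(st),
               sprintf("score table for %s lacks class %s",
                       fusion$classifier[i], classes[i]))
    fused[, i] <- st[, classes[i]]
  }
  factor(classes[argmax_first(fused)], levels = classes)
}
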