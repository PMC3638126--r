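#' Round half-up to one decimal
#'
#' All printed percentages in this package use half-up rounding to one
#' decimal (so 1.25 prints as 1.3), matching the convention of the
#' confusion-table metrics.
#'
#' @param x Numeric vector.
#' @return `x` rounded half-up to one decimal place.
#' @export
round1 <- function(x) floor(x * 10 + 0.5) / 10

#' Build a confusion matrix
#'
#' Rows are actual classes, columns predicted classes, in the supplied
#' order.
#'
#' @param truth,predicted Equal-length label vectors.
#' @param classes Ordered class labels; every label in `truth`/`predicted`
#'   must appear here.
#' @return An integer matrix of class `confusion_matrix` with `classes` as
#'   row and column names.
#' @export
#' @examples
#' cm <- build_confusion(c("h", "s", "h"), c("h", "s", "h"), c("h", "s"))
#' pooled_accuracy(cm)
build_confusion <- function(truth, predicted,
                            classes = sort(unique(c(truth, predicted)))) {
  if (length(truth) != length(predicted)) {
    abort("`truth` and `predicted` must have equal length.")
  }
  unknown <- setdiff(unique(c(truth, predicted)), classes)
  if (length(unknown)) {
    abort(sprintf("Unknown label(s): %s", paste(unknown, collapse = ", ")))
  }
  m <- table(factor(truth, levels = classes),
             factor(predicted, levels = classes))
  m <- matrix(as.integer(m), nrow = length(classes),
              dimnames = list(actual = classes, predicted = classes))
  new_confusion(m)
}

new_confusion <- function(m) {
  if (nrow(m) != ncol(m)) abort("Confusion matrix must be square.")
  if (any(m < 0)) abort("Confusion counts must be non-negative.")
  structure(m, class = c("confusion_matrix", "matrix"))
}

#' Coerce a plain count matrix to a confusion matrix
#'
#' @param m Square matrix of counts with class dimnames.
#' @return A `confusion_matrix`.
#' @export
as_confusion <- function(m) {
  m <- as.matrix(m)
  storage.mode(m) <- "integer"
  if (is.null(rownames(m))) abort("Count matrix needs class dimnames.")
  new_confusion(m)
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> actual x predicted\n")
  print(unclass(x))
  invisible(x)
}

#' @export
tidy.confusion_matrix <- function(x, ...) {
  df <- as.data.frame(as.table(unclass(x)), stringsAsFactors = FALSE)
  names(df) <- c("actual", "predicted", "n")
  as_tibble(df)
}

#' Per-class error percentages
#'
#' For each actual class, the percentage of its samples not on the
#' diagonal, rounded half-up to one decimal.
#'
#' @param cm A `confusion_matrix`; every row sum must be positive.
#' @return A tibble with columns `class`, `error_pct`.
#' @export
per_class_error <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  rs <- rowSums(cm)
  if (any(rs == 0)) {
    abort(sprintf("No samples of class: %s",
                  paste(rownames(cm)[rs == 0], collapse = ", ")))
  }
  err <- 100 * (rs - diag(cm)) / rs
  tibble(class = rownames(cm), error_pct = unname(round1(err)))
}

per_class_error_raw <- function(cm) {
  rs <- rowSums(cm)
  100 * (rs - diag(cm)) / rs
}

#' Average error (unweighted mean of per-class errors)
#'
#' The unweighted mean of the unrounded per-class error rates, rounded
#' half-up to one decimal. This is the "average error" convention of the
#' bundled confusion tables: classes contribute equally regardless of their
#' sample counts, which differs from the pooled off-diagonal rate when row
#' sums are unequal.
#'
#' @param cm A `confusion_matrix`.
#' @return A single percentage.
#' @export
average_error <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  rs <- rowSums(cm)
  if (any(rs == 0)) {
    abort(sprintf("No samples of class: %s",
                  paste(rownames(cm)[rs == 0], collapse = ", ")))
  }
  round1(mean(per_class_error_raw(cm)))
}

#' Headline accuracy from the average error
#'
#' `100 - average_error(cm)`: the accuracy reading that pairs with the
#' unweighted average error.
#'
#' @param cm A `confusion_matrix`.
#' @return A single percentage.
#' @export
headline_accuracy <- function(cm) 100 - average_error(cm)

#' Pooled accuracy
#'
#' `100 * trace / total`, rounded half-up to one decimal: the fraction of
#' all samples classified correctly.
#'
#' @param cm A `confusion_matrix` with a positive total count.
#' @return A single percentage.
#' @export
pooled_accuracy <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- sum(cm)
  if (total == 0) abort("Confusion matrix is all zero.")
  round1(100 * sum(diag(cm)) / total)
}

#' Pairwise accuracy between two classes
#'
#' Counts only the direct cross-confusions between classes `a` and `b` as
#' errors: `100 * (n_a + n_b - cm[a,b] - cm[b,a]) / (n_a + n_b)`.
#'
#' @param cm A `confusion_matrix`.
#' @param a,b Two distinct class labels present in `cm`.
#' @return A single percentage, one decimal.
#' @export
pairwise_accuracy <- function(cm, a, b) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (identical(a, b)) abort("Need two distinct classes.")
  miss <- setdiff(c(a, b), rownames(cm))
  if (length(miss)) abort(sprintf("Class not in matrix: %s",
                                  paste(miss, collapse = ", ")))
  na <- sum(cm[a, ])
  nb <- sum(cm[b, ])
  round1(100 * (na + nb - cm[a, b] - cm[b, a]) / (na + nb))
}

#' Write / read a confusion matrix CSV
#'
#' Layout mirrors the printed tables: header row of predicted classes, first
#' column the actual class, last column the per-class error percentage. The
#' reader ignores the error column and rebuilds it from the counts.
#'
#' @param cm A `confusion_matrix`.
#' @param path CSV path.
#' @return `write_confusion_csv`: `path` invisibly; `read_confusion_csv`:
#'   a `confusion_matrix`.
#' @export
write_confusion_csv <- function(cm, path) {
  stopifnot(inherits(cm, "confusion_matrix"))
  df <- data.frame(category = rownames(cm), unclass(cm),
                   error = sprintf("%.1f%%", per_class_error(cm)$error_pct),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_confusion_csv
#' @export
read_confusion_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  classes <- df[[1]]
  count_cols <- intersect(names(df)[-1], classes)
  if (length(count_cols) != length(classes)) {
    abort("Confusion CSV must have one count column per actual class.")
  }
  m <- as.matrix(df[, classes])
  rownames(m) <- classes
  as_confusion(m)
}

#' Bundled benchmark confusion tables
#'
#' Returns one of the three confusion matrices shipped with the package:
#' `"human"` (seven listeners on four emotions, 70 samples each), or the
#' classifier's `"offline"` / `"live"` happy/sad-by-gender tables.
#'
#' @param which `"human"`, `"offline"` or `"live"`.
#' @return A `confusion_matrix`.
#' @export
#' @examples
#' pooled_accuracy(paper_confusion("human"))
paper_confusion <- function(which = c("human", "offline", "live")) {
  which <- match.arg(which)
  fname <- switch(which,
    human = "confusion_human.csv",
    offline = "confusion_offline.csv",
    live = "confusion_live.csv"
  )
  read_confusion_csv(system.file("extdata", fname, package = "vnresp",
                                 mustWork = TRUE))
}
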