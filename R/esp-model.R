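#' Stratified train/test split
#'
#' Splits rows into train and test sets with the requested training
#' fraction inside every class, under a fixed seed.
#'
#' @param data Data frame with a label column.
#' @param train_frac Training fraction in (0, 1).
#' @param seed Integer seed.
#' @param label_col Name of the class column.
#' @return `data` with an added `split` column (`"train"` / `"test"`).
#' @export
esp_split <- function(data, train_frac = 0.5, seed = 1, label_col = "label") {
  if (train_frac <= 0 || train_frac >= 1) abort("`train_frac` must be in (0, 1).")
  set.seed(seed)
  split <- rep("test", nrow(data))
  for (cl in unique(data[[label_col]])) {
    idx <- which(data[[label_col]] == cl)
    n_train <- max(1L, round(train_frac * length(idx)))
    split[sample(idx, n_train)] <- "train"
  }
  data$split <- split
  data
}

#' Train the RBF-kernel emotion classifier
#'
#' Fits per-feature scaling on the training vectors (see [fit_scaling()]),
#' then trains a support vector machine with a radial-basis-function kernel
#' on the scaled features via the libsvm solver. The fitted support set,
#' kernel parameters and scaling are extracted into a self-contained model
#' object whose decision function the package evaluates itself (one-vs-one
#' voting), so a model saved as JSON reproduces predictions exactly.
#'
#' @param data Data frame of labeled feature vectors.
#' @param label_col Name of the class column.
#' @param feature_cols Feature column names.
#' @param gamma RBF kernel width (default `1/length(feature_cols)`).
#' @param cost Margin penalty C (default 1).
#' @param train_frac Training fraction recorded in the manifest (metadata
#'   only; the caller does the splitting).
#' @param seed Integer seed recorded in the manifest.
#' @return An object of class `esp_model`.
#' @export
esp_train <- function(data, label_col = "label",
                      feature_cols = esp_feature_cols,
                      gamma = 1 / length(feature_cols), cost = 1,
                      train_frac = NA_real_, seed = NA_integer_) {
  y <- factor(data[[label_col]])
  if (nlevels(y) < 2) abort("Need at least 2 classes to train.")
  if (any(table(y) < 2)) abort("Need at least 2 samples per class.")
  scaling <- fit_scaling(data, feature_cols)
  xs <- as.matrix(apply_scaling(data, scaling)[, feature_cols])
  fit <- e1071::svm(xs, y, scale = FALSE, kernel = "radial",
                    gamma = gamma, cost = cost)
  model <- list(
    version = 1L,
    classes = levels(y),
    feature_cols = feature_cols,
    gamma = gamma,
    cost = cost,
    sv = unname(as.matrix(fit$SV)),
    coefs = unname(as.matrix(fit$coefs)),
    rho = as.numeric(fit$rho),
    n_sv = as.integer(fit$nSV),
    label_order = as.integer(fit$labels),
    scaling = list(feature = scaling$feature, low = scaling$low,
                   high = scaling$high),
    manifest = list(
      n_train = nrow(data), train_frac = train_frac, seed = seed,
      ids = if ("file" %in% names(data)) data$file else NULL
    )
  )
  class(model) <- "esp_model"
  model
}

#' @export
print.esp_model <- function(x, ...) {
  cat(sprintf(
    "<esp_model: RBF SVM, %d classes (%s), %d support vectors, gamma=%.3g, cost=%.3g>\n",
    length(x$classes), paste(x$classes, collapse = "/"),
    nrow(x$sv), x$gamma, x$cost
  ))
  invisible(x)
}

# one-vs-one RBF decision: votes and pairwise decision values, libsvm layout
svm_decision <- function(model, xs) {
  k <- length(model$classes)
  n_sv <- model$n_sv
  start <- c(0L, cumsum(n_sv))
  kern <- exp(-model$gamma *
                outer(rowSums(model$sv^2), rowSums(xs^2), "+") -
                model$gamma * (-2) * tcrossprod(model$sv, xs))
  n_pairs <- k * (k - 1) / 2
  dec <- matrix(0, nrow(xs), n_pairs)
  votes <- matrix(0L, nrow(xs), k)
  p <- 0L
  pair_names <- character(n_pairs)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      p <- p + 1L
      si <- start[i] + seq_len(n_sv[i])
      sj <- start[j] + seq_len(n_sv[j])
      d <- colSums(model$coefs[si, j - 1, drop = TRUE] * kern[si, , drop = FALSE]) +
        colSums(model$coefs[sj, i, drop = TRUE] * kern[sj, , drop = FALSE]) -
        model$rho[p]
      dec[, p] <- d
      win <- ifelse(d > 0, i, j)
      for (cls in c(i, j)) {
        votes[, cls] <- votes[, cls] + as.integer(win == cls)
      }
      li <- model$classes[model$label_order[i]]
      lj <- model$classes[model$label_order[j]]
      pair_names[p] <- paste0(li, "/", lj)
    }
  }
  colnames(dec) <- pair_names
  winner <- apply(votes, 1, which.max)  # first max, as libsvm does
  list(label = model$classes[model$label_order[winner]], decision = dec)
}

#' Classify feature vectors
#'
#' Applies the model's stored scaling and evaluates the one-vs-one RBF
#' decision rule, returning exactly one label per row.
#'
#' @param model An `esp_model`.
#' @param newdata Data frame containing the model's feature columns
#'   (unscaled).
#' @return `newdata` with added columns `.pred` (label) and `.decision`
#'   (first pairwise decision value; the signed margin for two-class
#'   models).
#' @export
esp_classify <- function(model, newdata) {
  stopifnot(inherits(model, "esp_model"))
  miss <- setdiff(model$feature_cols, names(newdata))
  if (length(miss)) {
    abort(sprintf("Feature mismatch: missing column(s) %s",
                  paste(miss, collapse = ", ")))
  }
  scaling <- structure(
    tibble(feature = model$scaling$feature, low = model$scaling$low,
           high = model$scaling$high),
    class = c("esp_scaling", class(tibble()))
  )
  xs <- as.matrix(apply_scaling(newdata, scaling)[, model$feature_cols])
  res <- svm_decision(model, xs)
  newdata$.pred <- res$label
  newdata$.decision <- res$decision[, 1]
  newdata
}

#' Save / load an emotion model as self-describing JSON
#'
#' The JSON file carries the kernel parameters, support set, scaling and
#' training manifest plus a format version; a save/load round trip yields
#' identical predictions on any vector.
#'
#' @param model An `esp_model`.
#' @param path File path.
#' @return `save_model`: `path` invisibly. `load_model`: the restored
#'   `esp_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "esp_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) {
                    abort(sprintf("Cannot parse model file: %s", conditionMessage(e)))
                  })
  required <- c("version", "classes", "feature_cols", "gamma", "cost", "sv",
                "coefs", "rho", "n_sv", "label_order", "scaling")
  miss <- setdiff(required, names(obj))
  if (length(miss)) {
    abort(sprintf("Model file schema mismatch: missing field(s) %s",
                  paste(miss, collapse = ", ")))
  }
  if (!identical(as.integer(obj$version), 1L)) {
    abort(sprintf("Unsupported model format version: %s", obj$version))
  }
  obj$sv <- as.matrix(obj$sv)
  obj$coefs <- as.matrix(obj$coefs)
  obj$n_sv <- as.integer(obj$n_sv)
  obj$label_order <- as.integer(obj$label_order)
  class(obj) <- "esp_model"
  obj
}

#' Small grid search over RBF hyperparameters
#'
#' Optional helper (off the default path): k-fold cross-validated accuracy
#' over a gamma/cost grid.
#'
#' @param data Labeled feature data frame.
#' @param gammas,costs Numeric grids.
#' @param folds Number of cross-validation folds.
#' @param seed Integer seed for fold assignment.
#' @inheritParams esp_train
#' @return Tibble of `gamma`, `cost`, `accuracy`, sorted best-first.
#' @export
esp_tune <- function(data, gammas = c(0.05, 0.2, 1), costs = c(0.5, 1, 4),
                     folds = 5, seed = 1, label_col = "label",
                     feature_cols = esp_feature_cols) {
  set.seed(seed)
  fold <- sample(rep_len(seq_len(folds), nrow(data)))
  grid <- expand.grid(gamma = gammas, cost = costs)
  acc <- vapply(seq_len(nrow(grid)), function(g) {
    correct <- 0L
    for (f in seq_len(folds)) {
      tr <- data[fold != f, ]
      te <- data[fold == f, ]
      if (length(unique(tr[[label_col]])) < 2 || nrow(te) == 0) next
      m <- esp_train(tr, label_col, feature_cols,
                     gamma = grid$gamma[g], cost = grid$cost[g])
      pred <- esp_classify(m, te)$.pred
      correct <- correct + sum(pred == te[[label_col]])
    }
    correct / nrow(data)
  }, numeric(1))
  out <- tibble(gamma = grid$gamma, cost = grid$cost, accuracy = acc)
  arrange(out, dplyr::desc(.data$accuracy))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.esp_model <- function(x, ...) {
  tibble(class = x$classes[x$label_order], n_support = x$n_sv)
}

#' @export
glance.esp_model <- function(x, ...) {
  tibble(
    n_classes = length(x$classes), n_support = sum(x$n_sv),
    gamma = x$gamma, cost = x$cost,
    n_train = x$manifest$n_train %||% NA_integer_,
    train_frac = x$manifest$train_frac %||% NA_real_
  )
}
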