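#' Labeled feature dataset
#'
#' The central in-memory container of the package: a feature matrix with one
#' column per sample (so `X` is d x n), integer class labels `y` in
#' `1..K`, and a logical mask marking samples that have been corrupted by
#' [inject_noise()]. The column-per-sample orientation follows the usual
#' subspace-learning convention `X = [x1, ..., xn]`; delimited tables on disk
#' are row-per-sample and transposed on read.
#'
#' @param X numeric matrix, features in rows, samples in columns.
#' @param y integer vector of class labels, length `ncol(X)`, values in
#'   `1..K` with every class present.
#' @param K number of classes; defaults to `max(y)`.
#' @param noise_mask logical vector of length `ncol(X)`; `TRUE` marks a
#'   noise-corrupted sample. Defaults to all-`FALSE` (clean data).
#' @return An object of class `labeled_dataset`: a list with elements `X`,
#'   `y`, `K`, `noise_mask`.
#' @examples
#' d <- labeled_dataset(matrix(rnorm(20), 4, 5), c(1, 1, 2, 2, 1))
#' d
#' @export
labeled_dataset <- function(X, y, K = max(y), noise_mask = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (anyNA(X) || any(!is.finite(X))) {
    stop("labeled_dataset: X contains missing or non-finite values")
  }
  if (length(y) != ncol(X)) {
    stop(sprintf(
      "labeled_dataset: length(y) = %d but ncol(X) = %d",
      length(y), ncol(X)
    ))
  }
  if (any(y != round(y))) stop("labeled_dataset: labels must be integers")
  y <- as.integer(y)
  K <- as.integer(K)
  if (K < 1L || any(y < 1L) || any(y > K)) {
    stop("labeled_dataset: labels must lie in 1..K")
  }
  missing_cls <- setdiff(seq_len(K), unique(y))
  if (length(missing_cls) > 0L) {
    stop(
      "labeled_dataset: classes absent from y: ",
      paste(missing_cls, collapse = ", "),
      " (labels must be contiguous 1..K; remap before constructing)"
    )
  }
  if (is.null(noise_mask)) noise_mask <- rep(FALSE, ncol(X))
  if (!is.logical(noise_mask) || length(noise_mask) != ncol(X)) {
    stop("labeled_dataset: noise_mask must be logical of length ncol(X)")
  }
  structure(
    list(X = X, y = y, K = K, noise_mask = noise_mask),
    class = "labeled_dataset"
  )
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf(
    "Labeled dataset: %d features x %d samples, %d classes\n",
    nrow(x$X), ncol(x$X), x$K
  ))
  tab <- table(factor(x$y, levels = seq_len(x$K)))
  cat("  samples per class:", paste(as.integer(tab), collapse = ", "), "\n")
  if (any(x$noise_mask)) {
    cat(sprintf(
      "  %d/%d samples marked noise-corrupted\n",
      sum(x$noise_mask), ncol(x$X)
    ))
  }
  invisible(x)
}

#' Subset a labeled dataset by sample index
#'
#' Keeps the feature rows, selects sample columns. Labels are not remapped:
#' the subset must still contain every class (this is checked), so use it for
#' train/test splits of stratified designs.
#'
#' @param data a [labeled_dataset()].
#' @param idx integer vector of sample (column) indices.
#' @return A `labeled_dataset` with the selected samples.
#' @export
subset_samples <- function(data, idx) {
  stopifnot(inherits(data, "labeled_dataset"))
  labeled_dataset(
    data$X[, idx, drop = FALSE], data$y[idx],
    K = data$K, noise_mask = data$noise_mask[idx]
  )
}

#' Stratified train/test split
#'
#' Splits sample indices class by class, assigning `prop` of each class to the
#' training set (rounded, at least one sample per class on each side).
#' Deterministic given `seed`.
#'
#' @param y integer class labels.
#' @param prop proportion of each class assigned to training (default 0.5,
#'   a balanced 50/50 split).
#' @param seed integer seed controlling the within-class shuffle.
#' @return A list with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(y, prop = 0.5, seed = 1L) {
  stopifnot(prop > 0, prop < 1)
  train <- integer(0)
  with_local_seed(seed, {
    for (cls in sort(unique(y))) {
      idx <- which(y == cls)
      n_tr <- min(max(1L, round(prop * length(idx))), length(idx) - 1L)
      train <- c(train, sample(idx)[seq_len(n_tr)])
    }
  })
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(y), train))
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      suppressWarnings(rm(".Random.seed", envir = globalenv())),
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}
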