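#' Confusion matrix of integer-labelled predictions
#'
#' @param y_true,y_pred integer labels in `1..K`, equal length.
#' @param K number of classes.
#' @return K x K integer matrix; entry `(i, j)` counts samples with true
#'   class `i` predicted as class `j`.
#' @export
confusion_matrix <- function(y_true, y_pred, K) {
  if (length(y_true) != length(y_pred)) {
    stop("confusion_matrix: label vectors differ in length")
  }
  if (any(c(y_true, y_pred) < 1L) || any(c(y_true, y_pred) > K)) {
    stop("confusion_matrix: labels outside 1..K")
  }
  M <- matrix(0L, K, K)
  for (i in seq_along(y_true)) {
    M[y_true[i], y_pred[i]] <- M[y_true[i], y_pred[i]] + 1L
  }
  M
}

#' Specificity, sensitivity and accuracy from a confusion matrix
#'
#' For a binary task (`K = 2`) the positive class is class 2 by convention —
#' in the epilepsy protocol that is the seizure set — so sensitivity is
#' `TP/(TP+FN)` of class 2 and specificity is `TN/(TN+FP)` of class 1. For
#' `K > 2` each class is scored one-vs-rest and the aggregate values are
#' unweighted macro averages. Accuracy is always `trace/n`. Rates with a
#' zero denominator are reported as `NA` (undefined, not 0) and flagged.
#'
#' @param M confusion matrix from [confusion_matrix()].
#' @return A list with `accuracy`, `sensitivity`, `specificity` (aggregate,
#'   proportions in `[0, 1]`), `per_class` (data frame of one-vs-rest rates),
#'   `undefined_rates` (logical flag) and the matrix itself.
#' @examples
#' M <- confusion_matrix(c(1, 1, 2), c(1, 2, 2), K = 2)
#' classification_rates(M)$accuracy
#' @export
classification_rates <- function(M) {
  stopifnot(is.matrix(M), nrow(M) == ncol(M))
  K <- nrow(M)
  n <- sum(M)
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- numeric(K)
  spec <- numeric(K)
  for (cls in seq_len(K)) {
    tp <- M[cls, cls]
    fn <- sum(M[cls, -cls])
    fp <- sum(M[-cls, cls])
    tn <- n - tp - fn - fp
    sens[cls] <- safe_div(tp, tp + fn)
    spec[cls] <- safe_div(tn, tn + fp)
  }
  per_class <- data.frame(
    class = seq_len(K),
    sensitivity = sens, specificity = spec
  )
  if (K == 2L) {
    agg_sens <- sens[2L] # positive class = class 2
    agg_spec <- spec[2L] # = TN rate of class 1
  } else {
    agg_sens <- mean(sens, na.rm = FALSE)
    agg_spec <- mean(spec, na.rm = FALSE)
  }
  list(
    accuracy = safe_div(sum(diag(M)), n),
    sensitivity = agg_sens,
    specificity = agg_spec,
    per_class = per_class,
    undefined_rates = anyNA(c(sens, spec)),
    confusion = M
  )
}

#' Task descriptor: relabelling of source groups into task classes
#'
#' The benchmark protocols define tasks by collapsing source groups: the
#' binary epilepsy task maps groups A-D to class 1 (non-seizure) and E to
#' class 2 (seizure, the positive class); the three-class task maps A-B to
#' 1 (normal), C-D to 2 (interictal), E to 3 (ictal).
#'
#' @param name short task name.
#' @param map integer vector: `map[g]` is the task class of source class `g`.
#' @return A `task_spec` object.
#' @export
task_spec <- function(name, map) {
  map <- as.integer(map)
  K <- max(map)
  if (!all(seq_len(K) %in% map)) {
    stop("task_spec: mapped classes must be contiguous 1..K")
  }
  structure(list(name = name, map = map, K = K), class = "task_spec")
}

#' Built-in tasks for a K-group source
#'
#' `"binary"`: last group vs all others (positive class 2); `"threeclass"`
#' (5 source groups): \{1,2\} / \{3,4\} / \{5\}; for a 3-group source it is the
#' identity. `"identity"`: no relabelling.
#'
#' @param name one of `"binary"`, `"threeclass"`, `"identity"`.
#' @param K_source number of source groups.
#' @return A [task_spec()].
#' @export
builtin_task <- function(name = c("binary", "threeclass", "identity"),
                         K_source = 5L) {
  name <- match.arg(name)
  switch(name,
    binary = task_spec(
      "binary",
      c(rep(1L, K_source - 1L), 2L)
    ),
    threeclass = {
      if (K_source == 5L) {
        task_spec("threeclass", c(1L, 1L, 2L, 2L, 3L))
      } else if (K_source == 3L) {
        task_spec("threeclass", 1:3)
      } else {
        stop("builtin_task: threeclass task needs 3 or 5 source groups")
      }
    },
    identity = task_spec("identity", seq_len(K_source))
  )
}

apply_task <- function(data, task) {
  stopifnot(inherits(task, "task_spec"))
  if (max(data$y) > length(task$map)) {
    stop("apply_task: data has more classes than the task map covers")
  }
  labeled_dataset(data$X, task$map[data$y],
    K = task$K,
    noise_mask = data$noise_mask
  )
}

#' Run a noise-robustness classification experiment
#'
#' Replicates the noisy-EEG benchmark protocol on any data source: for every
#' cell of a noise grid and every repeat, the pipeline is
#' load/generate -> segment -> relabel by task -> inject noise ->
#' stratified 50/50 split -> fit -> evaluate on the held-out half. Noise is
#' injected before splitting (corruption hits train and test alike, as in
#' the benchmark). One result row is emitted per (grid cell, repeat), plus a
#' mean row per grid cell (`rep = NA`).
#'
#' @param source a [labeled_dataset()], a [synth_spec()] (traces are
#'   generated and segmented into 3 blocks), or a directory path containing
#'   one Bonn-format subdirectory per group.
#' @param task a [task_spec()], or `NULL` for no relabelling.
#' @param noise_grid data frame with columns `q` (sample fraction) and `v`
#'   (variance fraction); default the benchmark's six cells
#'   (20/50% x 5/10/15%). Use `data.frame(q = 0, v = 0)` for a clean run.
#' @param classifier `"nrlrl"` (default) or `"alssvm"` (the plain classifier
#'   on raw features, the natural baseline).
#' @param classifier_args named list of extra arguments passed to the
#'   classifier ([nrlrl()] or [alssvm()]).
#' @param repeats number of repeated splits per grid cell.
#' @param split_prop training proportion of the stratified split.
#' @param seed master seed; cell/repeat seeds are derived deterministically.
#' @return A data frame with columns `task`, `q`, `v`, `rep`, `seed`,
#'   `specificity`, `sensitivity`, `accuracy`. Mean rows have `rep = NA`.
#' @export
run_experiment <- function(source, task = NULL,
                           noise_grid = default_noise_grid(),
                           classifier = c("nrlrl", "alssvm"),
                           classifier_args = list(),
                           repeats = 1L, split_prop = 0.5, seed = 1L) {
  classifier <- match.arg(classifier)
  base <- load_experiment_source(source)
  if (!is.null(task)) base <- apply_task(base, task)
  task_name <- if (is.null(task)) "generic" else task$name
  stopifnot(all(c("q", "v") %in% names(noise_grid)))

  rows <- list()
  for (g in seq_len(nrow(noise_grid))) {
    q <- noise_grid$q[g]
    v <- noise_grid$v[g]
    cell <- list()
    for (r in seq_len(repeats)) {
      # distinct, reproducible seed per (cell, repeat); kept < 2^31
      run_seed <- (as.integer(seed) + 7919L * g + 104729L * r) %% 2147483587L
      noisy <- if (q > 0 && v > 0) {
        inject_noise(base, noise_spec(q, v, seed = run_seed))
      } else {
        base
      }
      sp <- stratified_split(noisy$y, prop = split_prop, seed = run_seed)
      train <- subset_samples(noisy, sp$train)
      test <- subset_samples(noisy, sp$test)
      pred <- switch(classifier,
        nrlrl = {
          fit <- do.call(nrlrl, c(list(data = train, seed = run_seed),
            classifier_args
          ))
          predict(fit, test$X)
        },
        alssvm = {
          fit <- do.call(alssvm, c(list(codes = train$X, y = train$y),
            classifier_args
          ))
          predict(fit, test$X)
        }
      )
      rates <- classification_rates(
        confusion_matrix(test$y, pred, base$K)
      )
      row <- data.frame(
        task = task_name, q = q, v = v, rep = r, seed = run_seed,
        specificity = rates$specificity,
        sensitivity = rates$sensitivity,
        accuracy = rates$accuracy
      )
      cell[[r]] <- row
    }
    cell_df <- do.call(rbind, cell)
    mean_row <- data.frame(
      task = task_name, q = q, v = v, rep = NA_integer_, seed = NA_integer_,
      specificity = mean(cell_df$specificity),
      sensitivity = mean(cell_df$sensitivity),
      accuracy = mean(cell_df$accuracy)
    )
    rows[[g]] <- rbind(cell_df, mean_row)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' The benchmark noise grid
#'
#' The six corruption settings of the noisy-EEG benchmark: 20% and 50% of
#' samples corrupted, at noise variance 5, 10 and 15% of the per-sample
#' feature variance.
#'
#' @return A 6-row data frame with columns `q` and `v`.
#' @export
default_noise_grid <- function() {
  expand.grid(v = c(0.05, 0.10, 0.15), q = c(0.20, 0.50))[, c("q", "v")]
}

load_experiment_source <- function(source) {
  if (inherits(source, "labeled_dataset")) {
    return(source)
  }
  if (inherits(source, "synth_spec")) {
    return(segment_traces(generate_traces(source), blocks_per_trace = 3L))
  }
  if (is.character(source) && length(source) == 1L && dir.exists(source)) {
    groups <- sort(list.dirs(source, recursive = FALSE, full.names = FALSE))
    if (length(groups) == 0L) {
      stop("run_experiment: no group subdirectories under ", source)
    }
    traces <- unlist(
      lapply(groups, function(g) {
        read_bonn_group(file.path(source, g), group_label = g)
      }),
      recursive = FALSE
    )
    return(segment_traces(traces, blocks_per_trace = 3L))
  }
  stop("run_experiment: unrecognised data source")
}

#' Hyperparameter grid search for NRLRL
#'
#' Evaluates held-out accuracy over a grid of hyperparameter settings using
#' repeated stratified splits, one row per setting. The default grids follow
#' the benchmark protocol: regularisation weights over `2^(-5..3)`,
#' neighbour counts `3..11`, dictionary sizes `40..320` (capped at `n`).
#'
#' @param data a [labeled_dataset()].
#' @param grid data frame of settings; column names must be [nrlrl()]
#'   argument names (e.g. `lambda`, `gamma`, `eta`, `k`, `m`, `p`).
#' @param repeats repeated splits per setting.
#' @param split_prop training proportion.
#' @param seed master seed.
#' @param fixed_args named list of [nrlrl()] arguments held fixed.
#' @return `grid` with an appended `accuracy` column (mean over repeats).
#' @export
nrlrl_grid_search <- function(data, grid, repeats = 3L, split_prop = 0.5,
                              seed = 1L, fixed_args = list()) {
  acc <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    accs <- numeric(repeats)
    for (r in seq_len(repeats)) {
      run_seed <- (as.integer(seed) + 31L * i + 1009L * r) %% 2147483587L
      sp <- stratified_split(data$y, prop = split_prop, seed = run_seed)
      train <- subset_samples(data, sp$train)
      test <- subset_samples(data, sp$test)
      args <- c(
        list(data = train, seed = run_seed),
        as.list(grid[i, , drop = FALSE]), fixed_args
      )
      fit <- do.call(nrlrl, args)
      accs[r] <- mean(predict(fit, test$X) == test$y)
    }
    acc[i] <- mean(accs)
  }
  cbind(grid, accuracy = acc)
}

#' The benchmark regularisation grid
#'
#' @return Numeric vector `2^(-5), ..., 2^3`.
#' @export
default_reg_grid <- function() 2^seq(-5, 3)
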