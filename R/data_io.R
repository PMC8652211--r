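#' Read a directory of Bonn-format EEG traces
#'
#' Bonn-format files are plain ASCII, one numeric amplitude per line, one file
#' per single-channel trace (the public epilepsy set has 4,097 samples per
#' file, 100 files per group, groups A-E). Files are read in lexicographic
#' filename order so the result does not depend on filesystem enumeration.
#'
#' @param directory path to a directory of trace files.
#' @param group_label label attached to every trace read (e.g. `"A"`).
#' @param pattern optional filename regexp passed to [list.files()].
#' @return A list of `raw_trace` objects, each a list with `samples`
#'   (numeric vector), `group_label`, and `source_id` (the filename).
#' @seealso [segment_traces()] to turn traces into a [labeled_dataset()].
#' @export
read_bonn_group <- function(directory, group_label, pattern = NULL) {
  if (!dir.exists(directory)) {
    stop("read_bonn_group: no such directory: ", directory)
  }
  files <- sort(list.files(directory, pattern = pattern, full.names = FALSE))
  files <- files[!dir.exists(file.path(directory, files))]
  if (length(files) == 0L) {
    stop("read_bonn_group: no files found in ", directory)
  }
  lapply(files, function(fn) {
    path <- file.path(directory, fn)
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    vals <- suppressWarnings(as.numeric(lines))
    if (anyNA(vals)) {
      bad <- which(is.na(vals))[1L]
      stop(sprintf(
        "read_bonn_group: non-numeric value %s at line %d of %s",
        dQuote(trimws(lines[bad])), bad, path
      ))
    }
    raw_trace(vals, group_label, source_id = fn)
  })
}

#' Construct a raw single-channel trace
#'
#' @param samples numeric vector of amplitudes; all finite, length at least 3.
#' @param group_label class/group identifier (kept as given).
#' @param source_id provenance string (filename or generator tag).
#' @return A `raw_trace` object.
#' @export
raw_trace <- function(samples, group_label, source_id = "") {
  samples <- as.numeric(samples)
  if (length(samples) < 3L) {
    stop("raw_trace: trace must have at least 3 samples")
  }
  if (any(!is.finite(samples))) {
    stop("raw_trace: non-finite sample values")
  }
  structure(
    list(
      samples = samples, group_label = group_label,
      source_id = as.character(source_id)
    ),
    class = "raw_trace"
  )
}

#' Write traces as a Bonn-format directory tree
#'
#' Inverse of [read_bonn_group()]: one ASCII file per trace (one value per
#' line), grouped into one subdirectory per `group_label`. Lets synthetic
#' traces flow through the identical I/O path as downloaded data.
#'
#' @param traces list of `raw_trace` objects.
#' @param directory output root; subdirectories named by group label are
#'   created as needed.
#' @param digits significant digits written (default 6).
#' @return Invisibly, the vector of files written.
#' @export
write_bonn_group <- function(traces, directory, digits = 6) {
  written <- character(0)
  counter <- list()
  for (tr in traces) {
    grp <- as.character(tr$group_label)
    sub <- file.path(directory, grp)
    if (!dir.exists(sub)) dir.create(sub, recursive = TRUE)
    counter[[grp]] <- (counter[[grp]] %||% 0L) + 1L
    fn <- if (nzchar(tr$source_id)) {
      tr$source_id
    } else {
      sprintf("%s%03d.txt", grp, counter[[grp]])
    }
    path <- file.path(sub, fn)
    writeLines(formatC(tr$samples, digits = digits, format = "g"), path)
    written <- c(written, path)
  }
  invisible(written)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Segment traces into fixed-width feature blocks
#'
#' Each trace is cut into `blocks_per_trace` consecutive non-overlapping
#' blocks of width `floor(length / blocks_per_trace)`, taken from the start of
#' the trace; trailing remainder samples are discarded. Every block becomes
#' one sample column of the resulting dataset. With the Bonn protocol
#' (4,097-point traces, 3 blocks) this yields 1,365 features per sample and
#' 300 samples per 100-trace group, each block covering roughly 8 s of signal.
#'
#' @param traces list of `raw_trace` objects, all of the same length.
#' @param blocks_per_trace number of blocks per trace (default 3).
#' @param label_map named vector mapping `group_label` values to integer
#'   class labels `1..K`. If `NULL`, group labels are mapped to `1..K` in
#'   sorted order of their unique values.
#' @return A [labeled_dataset()] with `d = floor(trace_length / blocks)`
#'   features and `n = length(traces) * blocks_per_trace` samples.
#' @export
segment_traces <- function(traces, blocks_per_trace = 3L, label_map = NULL) {
  stopifnot(length(traces) > 0L, blocks_per_trace >= 1L)
  lens <- vapply(traces, function(tr) length(tr$samples), integer(1))
  if (length(unique(lens)) != 1L) {
    stop(
      "segment_traces: traces have unequal lengths (",
      paste(unique(lens), collapse = ", "),
      "); block width must be uniform across the dataset"
    )
  }
  width <- lens[1L] %/% as.integer(blocks_per_trace)
  if (width < 1L) {
    stop("segment_traces: traces too short for ", blocks_per_trace, " blocks")
  }
  groups <- vapply(traces, function(tr) as.character(tr$group_label), "")
  if (is.null(label_map)) {
    lv <- sort(unique(groups))
    label_map <- stats::setNames(seq_along(lv), lv)
  }
  unknown <- setdiff(unique(groups), names(label_map))
  if (length(unknown) > 0L) {
    stop(
      "segment_traces: group labels missing from label_map: ",
      paste(unknown, collapse = ", ")
    )
  }
  n <- length(traces) * blocks_per_trace
  X <- matrix(0, nrow = width, ncol = n)
  y <- integer(n)
  col <- 0L
  for (i in seq_along(traces)) {
    s <- traces[[i]]$samples
    for (b in seq_len(blocks_per_trace)) {
      col <- col + 1L
      X[, col] <- s[((b - 1L) * width + 1L):(b * width)]
      y[col] <- label_map[[groups[i]]]
    }
  }
  labeled_dataset(X, y, K = max(label_map))
}

#' Specification of sample-wise Gaussian noise corruption
#'
#' Describes the corruption protocol used in noise-robustness benchmarks:
#' a fraction `q` of samples is selected uniformly at random and white
#' Gaussian noise is added to every feature of each selected sample. The
#' noise variance for a sample equals `v` times that sample's empirical
#' feature variance, so `noise_spec(0.2, 0.10)` reads "20% of samples
#' corrupted, noise variance 10% of the sample's features' variance".
#'
#' @param sample_fraction proportion `q` of samples to corrupt, in `[0, 1]`.
#' @param variance_fraction proportion `v >= 0`: noise variance relative to
#'   the per-sample feature variance.
#' @param seed integer seed for selection and noise draws.
#' @return A `noise_spec` object.
#' @export
noise_spec <- function(sample_fraction, variance_fraction, seed = 1L) {
  if (sample_fraction < 0 || sample_fraction > 1) {
    stop("noise_spec: sample_fraction must be in [0, 1]")
  }
  if (variance_fraction < 0) {
    stop("noise_spec: variance_fraction must be >= 0")
  }
  structure(
    list(
      sample_fraction = sample_fraction,
      variance_fraction = variance_fraction,
      seed = as.integer(seed)
    ),
    class = "noise_spec"
  )
}

#' Inject Gaussian white noise into a fraction of samples
#'
#' Selects exactly `round(q * n)` sample columns uniformly at random (without
#' replacement, under `spec$seed`) and adds i.i.d. zero-mean Gaussian noise to
#' each, with variance `v` times the column's empirical feature variance.
#' Unselected columns are returned bit-for-bit unchanged, and the input object
#' is not modified.
#'
#' @param data a [labeled_dataset()].
#' @param spec a [noise_spec()].
#' @param stratify if `TRUE`, the corrupted fraction is drawn per class
#'   rather than globally (default `FALSE`, plain uniform selection).
#' @return A new `labeled_dataset` with `noise_mask` marking corrupted
#'   columns (combined by OR with any pre-existing mask).
#' @export
inject_noise <- function(data, spec, stratify = FALSE) {
  stopifnot(inherits(data, "labeled_dataset"), inherits(spec, "noise_spec"))
  n <- ncol(data$X)
  q <- spec$sample_fraction
  v <- spec$variance_fraction
  if (q == 0 || v == 0) {
    out <- data
    if (q > 0) {
      with_local_seed(spec$seed, {
        sel <- pick_noise_columns(data$y, n, q, stratify)
      })
      out$noise_mask <- out$noise_mask | (seq_len(n) %in% sel)
    }
    return(out)
  }
  X <- data$X
  with_local_seed(spec$seed, {
    sel <- pick_noise_columns(data$y, n, q, stratify)
    for (j in sel) {
      sd_j <- sqrt(v * stats::var(X[, j]))
      X[, j] <- X[, j] + stats::rnorm(nrow(X), mean = 0, sd = sd_j)
    }
  })
  labeled_dataset(
    X, data$y,
    K = data$K,
    noise_mask = data$noise_mask | (seq_len(n) %in% sel)
  )
}

pick_noise_columns <- function(y, n, q, stratify) {
  if (!stratify) {
    return(sample(n, size = round(q * n)))
  }
  unlist(lapply(sort(unique(y)), function(cls) {
    idx <- which(y == cls)
    sample(idx, size = round(q * length(idx)))
  }), use.names = FALSE)
}

#' Read / write a labeled dataset as a delimited table
#'
#' On disk the table is row-per-sample: one row per sample, features in the
#' first `d` columns and the integer class label in the last column. The
#' delimiter (comma or tab) and an optional header row are auto-detected on
#' read. In memory the matrix is transposed to the package's column-per-sample
#' orientation.
#'
#' @param path file path.
#' @param remap if `TRUE`, arbitrary integer label values are remapped to
#'   contiguous `1..K` in sorted order; if `FALSE` (default) labels outside a
#'   contiguous `1..K` range are an error.
#' @return `read_dataset_table` returns a [labeled_dataset()];
#'   `write_dataset_table` returns the path invisibly.
#' @export
read_dataset_table <- function(path, remap = FALSE) {
  if (!file.exists(path)) stop("read_dataset_table: no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("read_dataset_table: empty file: ", path)
  sep <- if (grepl("\t", lines[1L])) "\t" else ","
  fields <- strsplit(lines, sep, fixed = TRUE)
  widths <- lengths(fields)
  if (length(unique(widths)) != 1L) {
    bad <- which(widths != widths[1L])[1L]
    stop(sprintf(
      "read_dataset_table: ragged row %d in %s (%d fields, expected %d)",
      bad, path, widths[bad], widths[1L]
    ))
  }
  first <- suppressWarnings(as.numeric(fields[[1L]]))
  has_header <- anyNA(first)
  rows <- fields[if (has_header) -1L else seq_along(fields)]
  if (length(rows) == 0L) stop("read_dataset_table: no data rows in ", path)
  num <- vapply(
    rows, function(f) suppressWarnings(as.numeric(f)),
    numeric(widths[1L])
  )
  num <- matrix(num, nrow = widths[1L]) # columns = samples already
  if (anyNA(num)) {
    bad <- which(apply(num, 2L, anyNA))[1L] + if (has_header) 1L else 0L
    stop(sprintf(
      "read_dataset_table: non-numeric feature value at data row %d of %s",
      bad, path
    ))
  }
  d <- widths[1L] - 1L
  if (d < 1L) stop("read_dataset_table: need at least one feature column")
  X <- num[seq_len(d), , drop = FALSE]
  ylab <- num[d + 1L, ]
  if (any(ylab != round(ylab))) {
    stop("read_dataset_table: label column must be integer")
  }
  ylab <- as.integer(ylab)
  uy <- sort(unique(ylab))
  if (remap) {
    ylab <- match(ylab, uy)
  } else if (!identical(uy, seq_len(max(uy))) || min(uy) < 1L) {
    stop(
      "read_dataset_table: labels {", paste(uy, collapse = ", "),
      "} are not contiguous 1..K; pass remap = TRUE to remap them"
    )
  }
  labeled_dataset(X, ylab)
}

#' @rdname read_dataset_table
#' @param data a [labeled_dataset()] to write.
#' @param sep field separator, `","` (default) or `"\t"`.
#' @param header write a header row (`f1..fd, label`)? Default `TRUE`.
#' @export
write_dataset_table <- function(path, data, sep = ",", header = TRUE) {
  stopifnot(inherits(data, "labeled_dataset"))
  d <- nrow(data$X)
  con <- file(path, "w")
  on.exit(close(con))
  if (header) {
    writeLines(
      paste(c(sprintf("f%d", seq_len(d)), "label"), collapse = sep), con
    )
  }
  rows <- apply(
    rbind(data$X, data$y), 2L,
    function(col) {
      paste(
        c(
          formatC(col[seq_len(d)], digits = 17, format = "g"),
          as.integer(col[d + 1L])
        ),
        collapse = sep
      )
    }
  )
  writeLines(rows, con)
  invisible(path)
}
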