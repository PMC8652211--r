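#' Specification for synthetic Bonn-like trace generation
#'
#' Describes a multi-class family of single-channel traces. Each trace of
#' class `c` is a sum of class-specific sinusoids (frequencies in cycles per
#' trace, each with an independent uniform random phase per trace), an AR(1)
#' noise process and white Gaussian noise. Classes therefore differ in
#' spectral content and amplitude, loosely mimicking the normal / interictal
#' / ictal contrast of the Bonn epilepsy groups: the "ictal" class has much
#' larger amplitude and slower dominant rhythm.
#'
#' The default parameters generate K = 3 classes, 10 traces per class,
#' 4,097 points per trace, so segmentation into 3 blocks yields the package's
#' standard desk-scale fixture: n = 90 samples with d = 1,365 features.
#'
#' @param n_classes number of classes K (>= 2).
#' @param traces_per_class traces generated per class.
#' @param trace_length samples per trace (default 4,097, the Bonn length).
#' @param class_params list of length `n_classes`; each element a list with
#'   `coh_freqs`/`coh_amps` (phase-locked characteristic rhythms, the
#'   class's deterministic waveform template), `freqs`/`amps` (random-phase
#'   oscillators providing within-class variability; cycles per trace),
#'   `baseline` (constant offset level, emulating electrode-dependent
#'   recording offsets), `ar` (AR(1) coefficient, |ar| < 1), `ar_sd` (AR
#'   innovation s.d.), and `sd` (white-noise s.d.). `NULL` selects built-in
#'   defaults.
#' @param seed integer seed; the generator is fully deterministic given it.
#' @return A `synth_spec` object.
#' @export
synth_spec <- function(n_classes = 3L, traces_per_class = 10L,
                       trace_length = 4097L, class_params = NULL,
                       seed = 1L) {
  n_classes <- as.integer(n_classes)
  stopifnot(n_classes >= 2L, traces_per_class >= 1L, trace_length >= 3L)
  if (is.null(class_params)) {
    class_params <- default_class_params(n_classes)
  }
  if (length(class_params) != n_classes) {
    stop("synth_spec: class_params must have one entry per class")
  }
  for (cp in class_params) {
    stopifnot(
      length(cp$freqs) == length(cp$amps),
      length(cp$coh_freqs %||% numeric(0)) ==
        length(cp$coh_amps %||% numeric(0)),
      all(cp$amps >= 0), all((cp$coh_amps %||% 0) >= 0),
      cp$ar_sd >= 0, cp$sd >= 0, abs(cp$ar) < 1
    )
  }
  structure(
    list(
      n_classes = n_classes, traces_per_class = as.integer(traces_per_class),
      trace_length = as.integer(trace_length), class_params = class_params,
      seed = as.integer(seed)
    ),
    class = "synth_spec"
  )
}

# Built-in class profiles. Frequencies are cycles per trace; at the Bonn
# sampling of 4,097 points / 23.6 s, 236 cycles/trace ~ 10 Hz. Class 1 is
# alpha/beta-dominated low amplitude ("normal"), class 2 slower theta-band
# with stronger AR structure ("interictal"), class 3 high-amplitude delta/
# theta rhythm ("ictal"). The classes also differ in baseline level, as the
# real groups do (surface vs. intracranial electrodes record at different
# offsets and gains); the baseline is what keeps the classes identifiable
# by affine codes once random phases scramble the oscillatory components.
# Extra classes beyond 3 interpolate frequencies and baselines.
default_class_params <- function(K) {
  base <- list(
    list(
      coh_freqs = 236, coh_amps = 1.0,
      freqs = c(420, 310), amps = c(0.6, 0.4), baseline = 0,
      ar = 0.30, ar_sd = 0.4, sd = 0.30
    ),
    list(
      coh_freqs = 120, coh_amps = 1.4,
      freqs = c(190, 150), amps = c(0.9, 0.6), baseline = 3,
      ar = 0.60, ar_sd = 0.5, sd = 0.35
    ),
    list(
      coh_freqs = 70, coh_amps = 4.0,
      freqs = c(140, 95), amps = c(2.2, 1.4), baseline = -6,
      ar = 0.50, ar_sd = 0.8, sd = 0.50
    )
  )
  if (K <= 3L) {
    return(base[seq_len(K)])
  }
  extra <- lapply(seq_len(K - 3L), function(i) {
    list(
      coh_freqs = 36 + 11 * i, coh_amps = 1.5,
      freqs = c(70 + 37 * i, 300 + 23 * i), amps = c(1.0 + 0.5 * i, 0.8),
      baseline = 6 + 3 * i, ar = 0.4, ar_sd = 0.5, sd = 0.4
    )
  })
  c(base, extra)
}

#' Generate synthetic Bonn-like traces
#'
#' @param spec a [synth_spec()].
#' @return A list of `raw_trace` objects (`traces_per_class` per class, in
#'   class order), with `group_label` set to the class index as character and
#'   `source_id` of the form `"synth_c<class>_t<trace>"`.
#' @examples
#' traces <- generate_traces(synth_spec(seed = 7))
#' data <- segment_traces(traces, blocks_per_trace = 3)
#' data
#' @export
generate_traces <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  len <- spec$trace_length
  tt <- seq_len(len) / len
  out <- vector("list", spec$n_classes * spec$traces_per_class)
  with_local_seed(spec$seed, {
    idx <- 0L
    for (cls in seq_len(spec$n_classes)) {
      cp <- spec$class_params[[cls]]
      for (tr in seq_len(spec$traces_per_class)) {
        sig <- rep(cp$baseline %||% 0, len)
        for (s in seq_along(cp$coh_freqs %||% numeric(0))) {
          # phase-locked characteristic rhythm: identical across traces of
          # the class, the class's deterministic waveform template
          sig <- sig + cp$coh_amps[s] * sin(2 * pi * cp$coh_freqs[s] * tt)
        }
        for (s in seq_along(cp$freqs)) {
          phase <- stats::runif(1, 0, 2 * pi)
          sig <- sig + cp$amps[s] * sin(2 * pi * cp$freqs[s] * tt + phase)
        }
        if (cp$ar_sd > 0) {
          innov <- stats::rnorm(len, sd = cp$ar_sd)
          sig <- sig + stats::filter(
            innov,
            filter = cp$ar, method = "recursive"
          )
        }
        if (cp$sd > 0) sig <- sig + stats::rnorm(len, sd = cp$sd)
        idx <- idx + 1L
        out[[idx]] <- raw_trace(
          as.numeric(sig),
          group_label = as.character(cls),
          source_id = sprintf("synth_c%d_t%03d", cls, tr)
        )
      }
    }
  })
  out
}

#' Default synthetic desk-scale fixture
#'
#' Convenience wrapper: generates the default K = 3 trace family and segments
#' it into three blocks, yielding the 1,365 x 90 dataset used throughout the
#' package's tests and examples.
#'
#' @param seed integer seed.
#' @param ... passed through to [synth_spec()].
#' @return A [labeled_dataset()].
#' @export
synthetic_fixture <- function(seed = 1L, ...) {
  segment_traces(generate_traces(synth_spec(seed = seed, ...)),
    blocks_per_trace = 3L
  )
}

#' Generate labeled Gaussian blob data
#'
#' Class `c` is drawn from a spherical unit-variance Gaussian centred at
#' `separation * e_c` (the c-th canonical basis direction). A fast, fully
#' controlled input for unit tests of the graph, classifier and ADMM modules:
#' `separation = 0` gives indistinguishable classes, large `separation`
#' linearly separable ones.
#'
#' @param K number of classes (requires `K <= d`).
#' @param n_per_class samples per class.
#' @param d feature dimension.
#' @param separation nonnegative distance scale between class means.
#' @param seed integer seed.
#' @return A [labeled_dataset()] with `n = K * n_per_class` samples.
#' @export
generate_gaussian_blobs <- function(K, n_per_class, d, separation,
                                    seed = 1L) {
  stopifnot(K >= 2L, K <= d, n_per_class >= 1L, separation >= 0)
  n <- K * n_per_class
  with_local_seed(seed, {
    X <- matrix(stats::rnorm(d * n), nrow = d, ncol = n)
  })
  y <- rep(seq_len(K), each = n_per_class)
  for (cls in seq_len(K)) {
    X[cls, y == cls] <- X[cls, y == cls] + separation
  }
  labeled_dataset(X, y, K = K)
}
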