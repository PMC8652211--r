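#' Squared pinball (expectile) loss
#'
#' The asymmetric squared loss applied to the margin residual
#' `u = y (w'c + b) - 1`. With the default `"violation"` branch, weight `p`
#' falls on margin violations (`u < 0`) and `1 - p` on the over-correct side
#' (`u >= 0`): at `p` near 1 the loss approaches the squared hinge, while
#' the light `1 - p` weight stops samples far on the correct side from
#' dragging the hyperplane — the expectile mechanism that makes the
#' classifier insensitive to feature noise around the boundary. At
#' `p = 0.5` both branches reduce to half the ordinary squared loss, the
#' symmetric LS-SVM case.
#'
#' @param u numeric vector of margin residuals.
#' @param p expectile parameter, strictly inside (0, 1).
#' @param branch `"violation"` (default) applies weight `p` to `u < 0`;
#'   `"overshoot"` applies `p` to `u >= 0` instead (the mirrored convention
#'   that appears in some statements of the loss; with `p` near 1 it
#'   down-weights violations so strongly that the regularised fit can
#'   collapse to a constant classifier — kept for comparison only).
#' @return Elementwise loss values.
#' @export
pinball_sq_loss <- function(u, p, branch = c("violation", "overshoot")) {
  check_p(p)
  branch <- match.arg(branch)
  w <- pinball_weights(u, p, branch)
  w * u^2
}

check_p <- function(p) {
  if (!is.numeric(p) || length(p) != 1L || p <= 0 || p >= 1) {
    stop("expectile parameter p must lie strictly inside (0, 1)")
  }
}

# Branch weights for residual vector u.
pinball_weights <- function(u, p, branch = "violation") {
  heavy <- if (branch == "overshoot") u >= 0 else u < 0
  ifelse(heavy, p, 1 - p)
}

#' Fit a binary asymmetric least-squares SVM
#'
#' Minimises `0.5 ||w||^2 + (alpha/2) sum_i pinball_sq(u_i)` with
#' `u_i = y_i (w'c_i + b) - 1`, by iteratively reweighted least squares
#' (IRLS): each pass freezes the branch weight (`p` or `1 - p`) of every
#' sample at the sign of its current residual and solves the resulting
#' regularised weighted least-squares problem in closed form. The objective
#' is convex and piecewise quadratic, so once the sign pattern stabilises the
#' iterate is the global optimum.
#'
#' @param codes numeric matrix, one column per sample (m x n).
#' @param y labels in `{-1, +1}` (or any two values coercible to them via
#'   `sign`), both classes present.
#' @param p expectile parameter in (0, 1).
#' @param alpha loss regularisation weight, `> 0`.
#' @param branch loss branch convention, see [pinball_sq_loss()].
#' @param max_iters maximum IRLS passes (default 100).
#' @return A list with `w` (length m), `b` (scalar), `objective`,
#'   `iterations`, and `converged`.
#' @export
alssvm_fit_binary <- function(codes, y, p = 0.95, alpha = 1,
                              branch = "violation", max_iters = 100L) {
  codes <- as.matrix(codes)
  check_p(p)
  stopifnot(alpha > 0, length(y) == ncol(codes))
  y <- as.numeric(y)
  if (!all(y %in% c(-1, 1))) {
    stop("alssvm_fit_binary: labels must be -1/+1")
  }
  if (length(unique(y)) < 2L) {
    stop("alssvm_fit_binary: both classes must be present")
  }
  m <- nrow(codes)
  n <- ncol(codes)
  Z <- rbind(codes, rep(1, n)) # (m+1) x n, last row carries the bias
  J0 <- diag(c(rep(1, m), 0)) # no penalty on b
  beta <- rep(0, m + 1L)
  obj_of <- function(beta) {
    u <- y * drop(crossprod(Z, beta)) - 1
    0.5 * sum(beta[seq_len(m)]^2) +
      (alpha / 2) * sum(pinball_sq_loss(u, p, branch))
  }
  solve_weighted <- function(s) {
    # minimiser of 0.5||w||^2 + (alpha/2) sum s_i (z_i'beta - y_i)^2
    A <- J0 + alpha * (Z %*% (s * t(Z)))
    rhs <- alpha * drop(Z %*% (s * y))
    solve_sym(A, rhs)
  }
  u <- y * drop(crossprod(Z, beta)) - 1
  signs <- u >= 0
  best <- list(beta = beta, obj = obj_of(beta))
  obj_trace <- numeric(0)
  converged <- FALSE
  iters <- 0L
  repeat {
    iters <- iters + 1L
    s <- pinball_weights(u, p, branch)
    beta <- solve_weighted(s)
    u <- y * drop(crossprod(Z, beta)) - 1
    ob <- obj_of(beta)
    obj_trace <- c(obj_trace, ob)
    if (ob < best$obj) best <- list(beta = beta, obj = ob)
    new_signs <- u >= 0
    if (identical(new_signs, signs) && iters > 1L) {
      converged <- TRUE
      break
    }
    signs <- new_signs
    if (p == 0.5 || iters >= max_iters) {
      # symmetric loss: the single weighted solve is already optimal
      converged <- p == 0.5
      break
    }
  }
  if (!converged) {
    warning("alssvm_fit_binary: sign pattern not stable after ",
      max_iters, " passes; returning best iterate",
      call. = FALSE
    )
    beta <- best$beta
  }
  list(
    w = beta[seq_len(m)], b = beta[m + 1L],
    objective = obj_of(beta), iterations = iters, converged = converged,
    obj_trace = obj_trace
  )
}

# Solve a symmetric system with a ridge fallback scaled to the diagonal
# magnitude (raw-feature problems can make the normal equations nearly
# rank-deficient at machine precision).
solve_sym <- function(A, rhs) {
  out <- tryCatch(solve(A, rhs), error = function(e) NULL)
  if (is.null(out)) {
    scale <- max(mean(abs(diag(A))), 1)
    for (eps in c(1e-12, 1e-10, 1e-8, 1e-6) * scale) {
      out <- tryCatch(solve(A + eps * diag(nrow(A)), rhs),
        error = function(e) NULL
      )
      if (!is.null(out)) {
        warning(sprintf(
          "singular system; ridge-perturbed diagonal by %.1g", eps
        ), call. = FALSE)
        break
      }
    }
    if (is.null(out)) stop("solve_sym: system irreparably singular")
  }
  out
}

#' Fit a multi-class asymmetric least-squares SVM
#'
#' One-vs-rest wrapper around [alssvm_fit_binary()]: class `k` is coded `+1`
#' against all others `-1`, yielding one hyperplane `(w_k, b_k)` per class.
#'
#' @param codes numeric matrix, one column per sample (m x n).
#' @param y integer class labels in `1..K`, every class present.
#' @param p expectile parameter in (0, 1); default 0.95.
#' @param alpha loss regularisation weight; default 1.
#' @param branch loss branch convention, see [pinball_sq_loss()].
#' @param max_iters maximum IRLS passes per binary fit.
#' @return An object of class `alssvm`: list with `W` (m x K matrix of
#'   weight vectors), `b` (length K), `p`, `alpha`, `K`, `branch`, and
#'   per-class fit diagnostics in `fits`.
#' @examples
#' d <- generate_gaussian_blobs(K = 3, n_per_class = 15, d = 5,
#'                              separation = 6, seed = 2)
#' model <- alssvm(d$X, d$y)
#' mean(predict(model, d$X) == d$y)
#' @export
alssvm <- function(codes, y, p = 0.95, alpha = 1,
                   branch = "violation", max_iters = 100L) {
  codes <- as.matrix(codes)
  y <- as.integer(y)
  K <- max(y)
  if (K < 2L || !all(seq_len(K) %in% y)) {
    stop("alssvm: labels must be contiguous 1..K with K >= 2")
  }
  fits <- lapply(seq_len(K), function(cls) {
    yk <- ifelse(y == cls, 1, -1)
    alssvm_fit_binary(codes, yk,
      p = p, alpha = alpha,
      branch = branch, max_iters = max_iters
    )
  })
  structure(
    list(
      W = vapply(fits, `[[`, numeric(nrow(codes)), "w"),
      b = vapply(fits, `[[`, numeric(1), "b"),
      p = p, alpha = alpha, K = K, branch = branch, fits = fits
    ),
    class = "alssvm"
  )
}

#' Predict class labels from an aLS-SVM model
#'
#' Assigns each sample to `argmax_k (w_k' c + b_k)`; exact score ties go to
#' the lowest class index.
#'
#' @param object an `alssvm` model.
#' @param codes matrix of samples to classify, one column each, with the
#'   model's code dimension.
#' @param ... unused.
#' @return Integer labels in `1..K`.
#' @export
predict.alssvm <- function(object, codes, ...) {
  codes <- as.matrix(codes)
  if (nrow(codes) != nrow(object$W)) {
    stop(sprintf(
      "predict.alssvm: code dimension %d does not match model dimension %d",
      nrow(codes), nrow(object$W)
    ))
  }
  scores <- crossprod(object$W, codes) + object$b # K x q
  apply(scores, 2L, which.max)
}

#' @export
print.alssvm <- function(x, ...) {
  cat(sprintf(
    "aLS-SVM: %d classes, code dimension %d, p = %.3g, alpha = %.3g\n",
    x$K, nrow(x$W), x$p, x$alpha
  ))
  invisible(x)
}

# Total multi-class classifier term of the learning objective:
# sum_k [ sum_i pinball_sq(u_{k,i}) + alpha ||w_k||^2 ].
alssvm_term <- function(model, codes, y) {
  total <- 0
  for (cls in seq_len(model$K)) {
    yk <- ifelse(y == cls, 1, -1)
    u <- yk * drop(crossprod(codes, model$W[, cls]) + model$b[cls]) - 1
    total <- total + sum(pinball_sq_loss(u, model$p, model$branch)) +
      model$alpha * sum(model$W[, cls]^2)
  }
  total
}
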