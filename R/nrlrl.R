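#' Column-wise l2,1 proximal operator
#'
#' Applies the shrinkage `g -> max(0, 1 - tau/||g||) g` to every column of
#' `G`: columns with Euclidean norm at most `tau` are set exactly to zero,
#' larger columns are shortened by `tau`. This is the exact minimiser of
#' `tau * ||e|| + 0.5 ||e - g||^2` per column, i.e. the proximal operator of
#' the l2,1 norm, which models sample-wise (whole-column) corruption.
#'
#' @param G numeric matrix.
#' @param tau nonnegative threshold.
#' @return Matrix of the same shape as `G`.
#' @export
prox_l21 <- function(G, tau) {
  stopifnot(tau >= 0)
  G <- as.matrix(G)
  nrm <- sqrt(colSums(G^2))
  scale <- ifelse(nrm > tau, (nrm - tau) / nrm, 0)
  sweep(G, 2L, scale, `*`)
}

# l2,1 norm: sum of column Euclidean norms.
norm_l21 <- function(E) sum(sqrt(colSums(as.matrix(E)^2)))

# --- C-step machinery -------------------------------------------------------
#
# The augmented Lagrangian restricted to C (classifier weights frozen at the
# current residual-sign pattern) is quadratic:
#
#   Tr(C H C') + gamma * sum_{k,i} s_ki (w_k'c_i + b_k - y_ki)^2
#   - Tr(theta' A C) + delta' (C'1 - 1) + (mu/2)(||X - AC - E||_F^2
#   + ||1'C - 1'||^2),   H = eta * L_eff + I.
#
# Its stationarity condition is the linear system
#
#   2 C H + mu (A'A + 11') C + 2 gamma [Q_i c_i]_i = R,
#   Q_i = sum_k s_ki w_k w_k',
#   R   = A'theta - 1 delta' + mu A'(X - E) + mu 11' + 2 gamma [r_i]_i,
#   r_i = sum_k s_ki w_k (y_ki - b_k).
#
# The locality operator couples the columns of C, so the system is solved
# jointly: the Sylvester part (first two terms) diagonalises in the
# eigenbases of P0 = A'A + 11' and G0 = 2H, and the per-column classifier
# blocks - rank K each - are folded in by a Woodbury correction whose
# capacitance system has size K*n. A dense solve of the full (m*n) x (m*n)
# vectorised system is retained as the reference path.

cstep_context <- function(A, H) {
  m <- ncol(A)
  P0 <- crossprod(A) + matrix(1, m, m)
  G0 <- 2 * H
  eP <- eigen(P0, symmetric = TRUE)
  eG <- eigen(G0, symmetric = TRUE)
  list(
    A = A, H = H, P0 = P0, G0 = G0,
    U = eP$vectors, lam0 = eP$values,
    V = eG$vectors, psi = eG$values
  )
}

# Solve the Sylvester part: mu*P0 %*% C + C %*% G0 = Z.
cstep_sylvester_solve <- function(Z, ctx, mu) {
  D <- outer(mu * ctx$lam0, ctx$psi, `+`)
  small <- abs(D) < 1e-10
  if (any(small)) {
    warning("C-step: near-singular spectrum; ridge-perturbing by 1e-10",
      call. = FALSE
    )
    D[small] <- 1e-10
  }
  Zt <- crossprod(ctx$U, Z) %*% ctx$V
  ctx$U %*% (Zt / D) %*% t(ctx$V)
}

# RHS of the stationarity system.
cstep_rhs <- function(ctx, X, E, theta, delta, mu, W, b, S, Yk, gamma) {
  m <- ncol(ctx$A)
  R <- crossprod(ctx$A, theta) - outer(rep(1, m), delta) +
    mu * crossprod(ctx$A, X - E) + mu
  if (gamma > 0 && !is.null(W) && any(W != 0)) {
    R <- R + 2 * gamma * (W %*% (S * (Yk - b)))
  }
  R
}

# Joint stationarity solve, Sylvester + Woodbury path.
cstep_solve_woodbury <- function(ctx, R, mu, W, b, S, gamma) {
  R1 <- cstep_sylvester_solve(R, ctx, mu)
  if (gamma == 0 || is.null(W) || all(W == 0)) {
    return(R1)
  }
  K <- ncol(W)
  n <- ncol(R)
  D <- outer(mu * ctx$lam0, ctx$psi, `+`)
  D[abs(D) < 1e-10] <- 1e-10
  invD <- 1 / D
  Wt <- crossprod(ctx$U, W) # m x K, atoms in eigenbasis of P0
  Kn <- K * n
  Cap <- matrix(0, Kn, Kn)
  for (k in seq_len(K)) {
    for (l in seq_len(k)) {
      g <- colSums(invD * (Wt[, k] * Wt[, l])) # length n over G0-eigenbasis
      blk <- ctx$V %*% (g * t(ctx$V))
      Cap[seq(k, Kn, by = K), seq(l, Kn, by = K)] <- blk
      if (l != k) Cap[seq(l, Kn, by = K), seq(k, Kn, by = K)] <- blk
    }
  }
  diag(Cap) <- diag(Cap) + 1 / (2 * gamma * as.vector(S))
  u_rhs <- as.vector(crossprod(W, R1)) # Uhat' Msyl^{-1} r, (i,k) k-fastest
  z <- solve_sym(Cap, u_rhs)
  R1 - cstep_sylvester_solve(W %*% matrix(z, nrow = K), ctx, mu)
}

# Reference path: dense solve of the vectorised system.
cstep_solve_direct <- function(ctx, R, mu, W, b, S, gamma) {
  m <- nrow(R)
  n <- ncol(R)
  M <- kronecker(ctx$G0, diag(m)) + kronecker(diag(n), mu * ctx$P0)
  if (gamma > 0 && !is.null(W) && any(W != 0)) {
    for (i in seq_len(n)) {
      idx <- ((i - 1L) * m + 1L):(i * m)
      M[idx, idx] <- M[idx, idx] + 2 * gamma * (W %*% (S[, i] * t(W)))
    }
  }
  matrix(solve_sym(M, as.vector(R)), m, n)
}

# Single-column closed form (n = 1): the joint system collapses to one
# m x m solve, mirroring the per-column update formula.
cstep_solve_single <- function(ctx, R, mu, W, b, S, gamma) {
  stopifnot(ncol(R) == 1L)
  m <- nrow(R)
  M <- 2 * ctx$H[1L, 1L] * diag(m) + mu * ctx$P0
  if (gamma > 0 && !is.null(W) && any(W != 0)) {
    M <- M + 2 * gamma * (W %*% (S[, 1L] * t(W)))
  }
  matrix(solve_sym(M, as.vector(R)), m, 1L)
}

# Gradient of the frozen-weights augmented Lagrangian at C (for the
# stationarity contract: its norm should be ~0 at the returned C). The
# classifier contribution 2*gamma*[Q_i c_i - r_i] is written in the folded
# form W (S * (W'C + b - Yk)); the remaining RHS is the gamma = 0 part.
cstep_gradient <- function(C, ctx, X, E, theta, delta, mu, W, b, S, Yk,
                           gamma) {
  G <- 2 * (C %*% ctx$H) + mu * (ctx$P0 %*% C)
  if (gamma > 0 && !is.null(W) && any(W != 0)) {
    G <- G + 2 * gamma * (W %*% (S * (crossprod(W, C) + b - Yk)))
  }
  G - cstep_rhs(ctx, X, E, theta, delta, mu,
    W = NULL, b = b, S = S, Yk = Yk, gamma = 0
  )
}

# Dual ascent on the multipliers plus penalty growth. With exact primal
# feasibility (X = AC + E and unit column sums) the multipliers are
# unchanged.
admm_update_multipliers <- function(theta, delta, mu, X, A, C, E,
                                    rho = 1.1, mu_max = 1e6) {
  Rp <- X - A %*% C - E
  cs <- colSums(C) - 1
  list(
    theta = theta + mu * Rp,
    delta = delta + mu * cs,
    mu = min(rho * mu, mu_max),
    primal_X = norm(Rp, "F"),
    primal_sum = sqrt(sum(cs^2))
  )
}

# Value of the augmented Lagrangian with frozen classifier branch weights
# (the quadratic the C-step solves, plus the l2,1 term the E-step solves).
# Used by the monotonicity tests.
admm_auglag <- function(C, E, theta, delta, mu, X, A, lambda, gamma,
                        W, b, S, Yk, H) {
  cls <- if (!is.null(W) && any(W != 0)) {
    sum(S * (crossprod(W, C) + b - Yk)^2)
  } else {
    sum(S * (0 + b - Yk)^2)
  }
  Rp <- X - A %*% C - E
  cs <- colSums(C) - 1
  lambda * norm_l21(E) + gamma * cls + sum((C %*% H) * C) +
    sum(theta * Rp) + sum(delta * cs) +
    (mu / 2) * (sum(Rp^2) + sum(cs^2))
}

# Frozen branch weights s_ki for the C-step majorisation.
cstep_weights <- function(C, W, b, Yk, p, branch, scheme) {
  if (scheme == "symmetric" || is.null(W)) {
    return(matrix(1, nrow(Yk), ncol(Yk)))
  }
  u <- Yk * (crossprod(W, C) + b) - 1
  matrix(pinball_weights(u, p, branch), nrow(Yk), ncol(Yk))
}

# +1/-1 one-vs-rest label matrix, K x n.
ovr_labels <- function(y, K) {
  Yk <- matrix(-1, K, length(y))
  Yk[cbind(y, seq_along(y))] <- 1
  Yk
}

#' NRLRL objective value
#'
#' Evaluates the (unaugmented) learning objective
#' `lambda ||E||_2,1 + gamma L(C, W, b) + Tr(C (eta L_eff + I) C')`, where
#' `L(C, W, b)` is the multi-class squared-pinball classifier term plus the
#' `alpha ||w_k||^2` ridge penalties.
#'
#' @param C code matrix (m x n).
#' @param E error matrix (d x n).
#' @param svm an `alssvm` model holding `W`, `b`, `p`, `alpha`.
#' @param y training labels `1..K`.
#' @param lambda weight of the column-sparse error term.
#' @param gamma weight of the classifier term.
#' @param M_loc the matrix `eta * L_eff + I` (n x n).
#' @return Scalar objective value.
#' @export
nrlrl_objective <- function(C, E, svm, y, lambda, gamma, M_loc) {
  stopifnot(
    ncol(C) == ncol(E), ncol(C) == length(y),
    nrow(M_loc) == ncol(C)
  )
  lambda * norm_l21(E) + gamma * alssvm_term(svm, C, y) +
    sum((C %*% M_loc) * C)
}

# --- main fitting routine ---------------------------------------------------

#' Fit a noise-robust low-rank learning (NRLRL) classifier
#'
#' Jointly learns, by ADMM, (i) a low-rank (Frobenius-relaxed) affine coding
#' `X = A C + E` of the training samples over a dictionary `A` of training
#' atoms, with a column-sparse (l2,1) error matrix `E` absorbing corrupted
#' samples, (ii) a supervised locality structure keeping same-class codes
#' close and different-class codes apart, and (iii) a multi-class asymmetric
#' least-squares SVM on the codes. Classification of new samples encodes them
#' over the dictionary ([nrlrl_encode()]) and applies the learned SVM.
#'
#' Each ADMM iteration performs: the joint C-step (exact stationarity solve
#' of the coupled quadratic subproblem with classifier branch weights frozen
#' at the current residual signs), the E-step (column-wise l2,1 proximal
#' shrinkage), the classifier refit, and the dual/multiplier updates with
#' penalty growth `mu <- min(rho mu, mu_max)`.
#'
#' @param data a [labeled_dataset()] of training samples.
#' @param m dictionary size (default 240, capped at `n`); atoms are a
#'   class-stratified uniform subsample of training columns, drawn under
#'   `seed`. Ignored when `dictionary` is given.
#' @param k,t neighbour count and heat-kernel bandwidth for [build_graph()].
#' @param lambda weight of the l2,1 error term.
#' @param gamma weight of the classifier term.
#' @param eta weight of the locality term.
#' @param alpha ridge weight inside the classifier term.
#' @param p expectile parameter of the squared pinball loss, in (0, 1).
#' @param locality_sign sign convention for the locality matrix, see
#'   [locality_matrix()].
#' @param c_step_weights `"expectile"` (default) freezes the asymmetric
#'   branch weights in the C-step; `"symmetric"` drops them (plain squared
#'   loss in the C-subproblem).
#' @param branch pinball branch convention, see [pinball_sq_loss()].
#' @param dictionary optional explicit dictionary matrix (d x m); overrides
#'   the subsampling.
#' @param encode_ridge test-time encoding regulariser epsilon (> 0).
#' @param mu,rho,mu_max initial penalty, growth factor, and cap.
#' @param tol convergence tolerance: stop when both primal residuals fall
#'   below `tol * ||X||_F`.
#' @param max_iters maximum ADMM iterations.
#' @param seed seed for the dictionary subsample (the only randomness).
#' @param c_step_method `"woodbury"` (default; eigenbasis Sylvester solve
#'   with low-rank classifier correction) or `"direct"` (dense vectorised
#'   solve, exact but only viable for small `m * n`).
#' @param svm_max_iters IRLS pass cap per classifier refit.
#' @return An object of class `nrlrl`; see Details.
#' @details The returned model contains `dictionary` (`A`, `atom_indices`),
#'   the trained `svm`, final `C`, `E`, multipliers `theta`/`delta`, the
#'   resolved graph bandwidth, convergence flags, and a per-iteration
#'   `history` data frame (primal residuals, objective, `mu`). Serialised
#'   models carry `format_version` for forward compatibility.
#' @examples
#' d <- generate_gaussian_blobs(K = 2, n_per_class = 20, d = 10,
#'                              separation = 8, seed = 1)
#' fit <- nrlrl(d, m = 10, k = 3, max_iters = 60)
#' mean(predict(fit, d$X) == d$y)
#' @export
nrlrl <- function(data, m = 240L, k = 7L, t = "auto",
                  lambda = 1, gamma = 1, eta = 1, alpha = 1, p = 0.95,
                  locality_sign = "discriminative",
                  c_step_weights = c("expectile", "symmetric"),
                  branch = "violation", dictionary = NULL,
                  encode_ridge = 1e-3, mu = 0.1, rho = 1.1, mu_max = 1e6,
                  tol = 1e-4, max_iters = 300L, seed = 1L,
                  c_step_method = c("woodbury", "direct"),
                  svm_max_iters = 100L) {
  stopifnot(inherits(data, "labeled_dataset"))
  c_step_weights <- match.arg(c_step_weights)
  c_step_method <- match.arg(c_step_method)
  stopifnot(
    lambda > 0, gamma > 0, eta >= 0, alpha > 0,
    encode_ridge > 0, mu > 0, rho >= 1, tol > 0
  )
  check_p(p)
  X <- data$X
  y <- data$y
  K <- data$K
  n <- ncol(X)
  d <- nrow(X)

  if (is.null(dictionary)) {
    m <- min(as.integer(m), n)
    if (m < K) stop("nrlrl: dictionary size m must be at least K")
    atom_indices <- stratified_atoms(y, m, seed)
    A <- X[, atom_indices, drop = FALSE]
  } else {
    A <- as.matrix(dictionary)
    if (nrow(A) != d) stop("nrlrl: dictionary row dimension must equal d")
    m <- ncol(A)
    atom_indices <- NULL
  }

  if (m > d) {
    warning(
      "nrlrl: dictionary is overcomplete (m = ", m, " atoms > d = ", d,
      " features); codes are underdetermined and training codes can drift",
      " away from what the test-time encoder reproduces. Prefer m <= d.",
      call. = FALSE
    )
  }

  graph <- build_graph(data, k = k, t = t)
  L_eff <- locality_matrix(graph, locality_sign)
  # The between-class (repulsive) part can make eta*L_eff + I indefinite,
  # turning the coupled C-subproblem into a saddle problem whose solution
  # spreads codes without bound along negative-curvature directions. Shift
  # by the smallest eigenvalue so the subproblem stays convex: the shift
  # adds only a uniform ridge c*||C||_F^2 and leaves the relative
  # pull/push geometry of the locality term untouched.
  locality_shift <- 0
  if (eta > 0) {
    lam_min <- min(eigen(eta * L_eff, symmetric = TRUE,
      only.values = TRUE
    )$values)
    locality_shift <- max(0, -lam_min)
  }
  H <- eta * L_eff + (1 + locality_shift) * diag(n)
  ctx <- cstep_context(A, H)
  M_loc <- H

  Yk <- ovr_labels(y, K)
  C <- matrix(1 / m, m, n) # feasible: columns sum to 1
  E <- matrix(0, d, n)
  theta <- matrix(0, d, n)
  delta <- rep(0, n)
  W <- NULL
  b <- rep(0, K)
  svm <- NULL

  normX <- norm(X, "F")
  hist_rows <- vector("list", max_iters)
  converged <- FALSE
  r1_init <- NA_real_
  iter <- 0L

  solve_c <- switch(c_step_method,
    woodbury = cstep_solve_woodbury,
    direct = cstep_solve_direct
  )

  for (iter in seq_len(max_iters)) {
    S <- cstep_weights(C, W, b, Yk, p, branch, c_step_weights)
    R <- cstep_rhs(ctx, X, E, theta, delta, mu, W, b, S, Yk, gamma)
    C <- solve_c(ctx, R, mu, W, b, S, gamma)

    E <- prox_l21(X - A %*% C + theta / mu, lambda / mu)

    svm <- alssvm(C, y,
      p = p, alpha = alpha, branch = branch,
      max_iters = svm_max_iters
    )
    W <- svm$W
    b <- svm$b

    upd <- admm_update_multipliers(theta, delta, mu, X, A, C, E,
      rho = rho, mu_max = mu_max
    )
    theta <- upd$theta
    delta <- upd$delta
    mu <- upd$mu
    r1 <- upd$primal_X
    r2 <- upd$primal_sum
    obj <- nrlrl_objective(C, E, svm, y, lambda, gamma, M_loc)
    hist_rows[[iter]] <- c(
      iter = iter, primal_X = r1, primal_sum = r2,
      objective = obj, mu = mu
    )
    if (iter == 1L) r1_init <- max(r1, .Machine$double.eps)
    if (r1 > 1e3 * r1_init) {
      stop(sprintf(
        "nrlrl: ADMM diverged at iteration %d (residual %.3g vs initial %.3g)",
        iter, r1, r1_init
      ))
    }
    # each residual is compared with the norm of its constraint target:
    # ||X||_F for the reconstruction, ||1_n|| = sqrt(n) for the column sums
    if (r1 <= tol * normX && r2 <= tol * sqrt(n)) {
      converged <- TRUE
      break
    }
  }

  history <- as.data.frame(do.call(rbind, hist_rows[seq_len(iter)]))
  train_pred <- predict(svm, C)
  model <- structure(
    list(
      dictionary = list(A = A, atom_indices = atom_indices),
      graph_params = list(k = graph$k, t = graph$t),
      hyperparams = list(
        lambda = lambda, gamma = gamma, eta = eta,
        alpha = alpha, p = p
      ),
      locality_sign = locality_sign, locality_shift = locality_shift,
      c_step_weights = c_step_weights,
      branch = branch, svm = svm, C = C, E = E,
      theta = theta, delta = delta, mu = mu,
      encode_ridge = encode_ridge, history = history,
      converged = converged, iterations = iter,
      train_accuracy = mean(train_pred == y),
      y = y, K = K, format_version = "nrlrl-model-1"
    ),
    class = "nrlrl"
  )
  model
}

# Class-stratified uniform subsample of m column indices, seeded.
stratified_atoms <- function(y, m, seed) {
  n <- length(y)
  classes <- sort(unique(y))
  counts <- vapply(classes, function(cls) sum(y == cls), integer(1))
  quota <- floor(m * counts / n)
  quota <- pmax(quota, 1L)
  # distribute the remainder by largest fractional part, deterministically
  while (sum(quota) < m) {
    frac <- m * counts / n - quota
    quota[which.max(frac)] <- quota[which.max(frac)] + 1L
  }
  while (sum(quota) > m) {
    over <- which(quota > 1L)
    frac <- m * counts / n - quota
    j <- over[which.min(frac[over])]
    quota[j] <- quota[j] - 1L
  }
  idx <- integer(0)
  with_local_seed(seed, {
    for (ci in seq_along(classes)) {
      pool <- which(y == classes[ci])
      idx <- c(idx, sort(sample(pool, quota[ci])))
    }
  })
  sort(idx)
}

#' Encode new samples over a trained dictionary
#'
#' Each new column `x` is coded by the equality-constrained ridge problem
#' `min_c ||x - A c||^2 + eps ||c||^2 subject to 1'c = 1`, solved exactly
#' through its KKT system (one factorisation, shared across columns). The
#' affine constraint matches the column-sum constraint imposed during
#' training, so training and test codes live on the same affine slice.
#'
#' @param model a fitted `nrlrl` model.
#' @param X_new matrix of new samples, one column each (d x q).
#' @return An m x q matrix of codes; every column sums to 1.
#' @export
nrlrl_encode <- function(model, X_new) {
  stopifnot(inherits(model, "nrlrl"))
  X_new <- as.matrix(X_new)
  A <- model$dictionary$A
  if (nrow(X_new) != nrow(A)) {
    stop(sprintf(
      "nrlrl_encode: feature dimension %d does not match dictionary %d",
      nrow(X_new), nrow(A)
    ))
  }
  m <- ncol(A)
  eps <- model$encode_ridge
  KKT <- rbind(
    cbind(2 * (crossprod(A) + eps * diag(m)), rep(1, m)),
    c(rep(1, m), 0)
  )
  rhs <- rbind(2 * crossprod(A, X_new), rep(1, ncol(X_new)))
  sol <- solve_sym(KKT, rhs)
  sol[seq_len(m), , drop = FALSE]
}

#' Predict class labels with a fitted NRLRL model
#'
#' Encodes the new samples over the training dictionary and applies the
#' jointly learned aLS-SVM to the codes.
#'
#' @param object a fitted `nrlrl` model.
#' @param X_new matrix of samples to classify, one column each.
#' @param ... unused.
#' @return Integer labels in `1..K`.
#' @export
predict.nrlrl <- function(object, X_new, ...) {
  predict(object$svm, nrlrl_encode(object, X_new))
}

#' @export
print.nrlrl <- function(x, ...) {
  hp <- x$hyperparams
  cat(sprintf(
    "NRLRL model: %d classes, dictionary %d x %d\n",
    x$K, nrow(x$dictionary$A), ncol(x$dictionary$A)
  ))
  cat(sprintf(
    "  lambda = %.3g, gamma = %.3g, eta = %.3g, alpha = %.3g, p = %.3g\n",
    hp$lambda, hp$gamma, hp$eta, hp$alpha, hp$p
  ))
  cat(sprintf(
    "  ADMM: %d iterations, %sconverged; training accuracy %.3f\n",
    x$iterations, if (x$converged) "" else "NOT ", x$train_accuracy
  ))
  invisible(x)
}

#' Save / load a fitted NRLRL model
#'
#' Serialises the complete model (all matrices and configuration) as a
#' single-file archive via R's native RDS format. The object carries a
#' `format_version` field (`"nrlrl-model-1"`) checked on load.
#'
#' @param model a fitted `nrlrl` model.
#' @param path file path (conventionally `.rds`).
#' @return `save_nrlrl` returns `path` invisibly; `load_nrlrl` returns the
#'   model.
#' @export
save_nrlrl <- function(model, path) {
  stopifnot(inherits(model, "nrlrl"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_nrlrl
#' @export
load_nrlrl <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "nrlrl") ||
    !identical(model$format_version, "nrlrl-model-1")) {
    stop("load_nrlrl: not a recognised nrlrl model archive")
  }
  model
}
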