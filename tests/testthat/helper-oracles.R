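# Independent oracles and small fixture builders shared across test files.

# Epigraph QP formulation of the binary aLS-SVM, solved by kernlab's
# interior-point QP solver: variables x = (w, b, xi, zeta),
#   min 0.5||w||^2 + (alpha/2)(p xi'xi + (1-p) zeta'zeta)
#   s.t. y_i (w'c_i + b) - 1 = xi_i - zeta_i,  xi, zeta >= 0.
# At the optimum xi = max(u, 0), zeta = max(-u, 0), recovering the squared
# pinball loss. Returns the objective value at the QP solution.
alssvm_qp_oracle <- function(C, y, p, alpha) {
  m <- nrow(C)
  n <- ncol(C)
  # xi carries the u > 0 (over-correct) part, zeta the u < 0 (violation)
  # part; the default branch puts weight p on violations
  H <- diag(c(rep(1, m), 1e-8, rep(alpha * (1 - p), n), rep(alpha * p, n)))
  cc <- rep(0, m + 1 + 2 * n)
  A <- cbind(t(C) * y, y, -diag(n), diag(n))
  big <- 100
  sv <- kernlab::ipop(cc, H, A, rep(1, n),
    l = c(rep(-big, m + 1), rep(0, 2 * n)),
    u = rep(big, m + 1 + 2 * n), r = rep(0, n),
    sigf = 9, maxiter = 200
  )
  x <- kernlab::primal(sv)
  w <- x[seq_len(m)]
  b <- x[m + 1]
  u <- y * (drop(crossprod(C, w)) + b) - 1
  0.5 * sum(w^2) + (alpha / 2) * sum(pinball_sq_loss(u, p))
}

# Second, solver-independent check: quasi-Newton descent on the smooth
# convex objective from a cold start.
alssvm_bfgs_oracle <- function(C, y, p, alpha) {
  m <- nrow(C)
  fn <- function(th) {
    w <- th[seq_len(m)]
    u <- y * (drop(crossprod(C, w)) + th[m + 1]) - 1
    0.5 * sum(w^2) + (alpha / 2) * sum(pinball_sq_loss(u, p))
  }
  gr <- function(th) {
    w <- th[seq_len(m)]
    u <- y * (drop(crossprod(C, w)) + th[m + 1]) - 1
    s <- ifelse(u < 0, p, 1 - p) # weight p on violations (default branch)
    c(w + alpha * drop(C %*% (s * u * y)), alpha * sum(s * u * y))
  }
  stats::optim(rep(0, m + 1), fn, gr,
    method = "BFGS",
    control = list(maxit = 5000, reltol = 1e-15)
  )$value
}

# Scalar brute-force minimiser of the per-column l2,1 proximal problem
# tau*||e|| + 0.5*||e - g||^2, searching over the scaling e = s*g.
# Golden-section search is refined by one exact parabolic step (away from
# s = 0 the objective is a perfect quadratic in s), then compared against
# the kink at s = 0.
prox_column_oracle <- function(g, tau) {
  f <- function(s) tau * sqrt(sum((s * g)^2)) + 0.5 * sum((s * g - g)^2)
  s0 <- stats::optimize(f, c(-0.5, 1.5), tol = 1e-10)$minimum
  h <- 1e-4
  if (s0 > 2 * h) {
    fm <- f(s0 - h)
    f0 <- f(s0)
    fp <- f(s0 + h)
    denom <- fm - 2 * f0 + fp
    if (denom > 0) s0 <- s0 - h * (fp - fm) / (2 * denom)
  }
  if (f(0) <= f(s0)) s0 <- 0
  s0 * g
}

# Random small ADMM C-step instance (shapes follow the stationarity
# contract checks).
random_cstep_instance <- function(seed, d = 8, m = 5, n = 12, K = 2,
                                  eta = 0.5) {
  set.seed(seed)
  X <- matrix(rnorm(d * n), d, n)
  A <- matrix(rnorm(d * m), d, m)
  y <- rep(seq_len(K), length.out = n)
  data <- labeled_dataset(X, y[order(y)])
  gr <- build_graph(data, k = 3)
  H <- eta * locality_matrix(gr) + diag(n)
  list(
    X = data$X, A = A, y = data$y, K = K,
    H = H, ctx = nrlrl:::cstep_context(A, H),
    E = 0.1 * matrix(rnorm(d * n), d, n),
    theta = 0.1 * matrix(rnorm(d * n), d, n),
    delta = 0.1 * rnorm(n),
    W = matrix(rnorm(m * K), m, K),
    b = rnorm(K),
    Yk = nrlrl:::ovr_labels(data$y, K),
    mu = runif(1, 0.2, 2),
    gamma = runif(1, 0.3, 2)
  )
}

# Paired noisy-blob train/test split used by the robustness comparisons.
# Conditions are the package's frozen desk-scale study design: K = 3,
# d = 60 (keeping the dictionary strongly undercomplete), 20 samples per
# class, class separation 3.
noisy_blob_split <- function(sd, q, v) {
  base <- generate_gaussian_blobs(
    K = 3, n_per_class = 20, d = 60,
    separation = 3, seed = sd
  )
  noisy <- if (q > 0) {
    inject_noise(base, noise_spec(q, v, seed = sd + 500L))
  } else {
    base
  }
  sp <- stratified_split(noisy$y, prop = 0.5, seed = sd + 900L)
  list(
    train = subset_samples(noisy, sp$train),
    test = subset_samples(noisy, sp$test)
  )
}
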