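test_that("l2,1 proximal operator shrinks columns exactly", {
  # direct formula case: column (3,4), tau = 1 -> (2.4, 3.2)
  expect_equal(prox_l21(cbind(c(3, 4)), 1), cbind(c(2.4, 3.2)))
  # zero branch: column norm below the threshold vanishes entirely
  expect_equal(prox_l21(cbind(c(0.3, 0.4)), 1), cbind(c(0, 0)))
  # scalar brute-force oracle over the scaling factor, 20 random columns
  set.seed(30)
  for (rep in 1:20) {
    g <- stats::rnorm(sample(2:10, 1), sd = 2)
    tau <- stats::runif(1, 0, 3)
    expect_equal(drop(prox_l21(cbind(g), tau)), prox_column_oracle(g, tau),
      tolerance = 1e-8
    )
  }
})

test_that("objective evaluates in closed form and scales linearly", {
  set.seed(31)
  m <- 4
  n <- 10
  d <- 6
  K <- 2
  y <- rep(1:2, each = 5)
  zero_svm <- structure(
    list(
      W = matrix(0, m, K), b = rep(0, K), p = 0.9, alpha = 1,
      K = K, branch = "violation"
    ),
    class = "alssvm"
  )
  # E = 0, C = 0, W = 0, b = 0: every margin residual is u = -1, a
  # violation, so with the default branch each sample contributes weight p
  # and the objective is gamma * K * n * p
  obj <- nrlrl_objective(
    C = matrix(0, m, n), E = matrix(0, d, n),
    svm = zero_svm, y = y, lambda = 2, gamma = 3, M_loc = diag(n)
  )
  expect_equal(obj, 3 * K * n * 0.9)

  # doubling lambda doubles exactly the error-term contribution
  E <- matrix(stats::rnorm(d * n), d, n)
  C <- matrix(stats::rnorm(m * n), m, n)
  o1 <- nrlrl_objective(C, E, zero_svm, y, 1, 3, diag(n))
  o2 <- nrlrl_objective(C, E, zero_svm, y, 2, 3, diag(n))
  expect_equal(o2 - o1, sum(sqrt(colSums(E^2))), tolerance = 1e-12)

  # independent term-by-term re-evaluation on a random instance
  W <- matrix(stats::rnorm(m * K), m, K)
  b <- stats::rnorm(K)
  svm <- structure(
    list(W = W, b = b, p = 0.8, alpha = 0.7, K = K, branch = "violation"),
    class = "alssvm"
  )
  M <- crossprod(matrix(stats::rnorm(n * n), n, n)) / n
  lambda <- 1.3
  gamma <- 0.6
  expected <- lambda * sum(sqrt(colSums(E^2)))
  for (k in 1:K) {
    yk <- ifelse(y == k, 1, -1)
    u <- yk * (drop(crossprod(C, W[, k])) + b[k]) - 1
    lo <- ifelse(u < 0, 0.8 * u^2, 0.2 * u^2) # p on violations
    expected <- expected + gamma * (sum(lo) + 0.7 * sum(W[, k]^2))
  }
  expected <- expected + sum(diag(C %*% M %*% t(C)))
  expect_equal(nrlrl_objective(C, E, svm, y, lambda, gamma, M), expected,
    tolerance = 1e-12
  )
})

test_that("C-step satisfies the joint stationarity condition", {
  for (seed in 1:10) {
    inst <- random_cstep_instance(seed)
    C0 <- matrix(stats::rnorm(5 * 12), 5, 12)
    S <- nrlrl:::cstep_weights(
      C0, inst$W, inst$b, inst$Yk, 0.95,
      "violation", "expectile"
    )
    R <- nrlrl:::cstep_rhs(
      inst$ctx, inst$X, inst$E, inst$theta, inst$delta,
      inst$mu, inst$W, inst$b, S, inst$Yk, inst$gamma
    )
    C <- nrlrl:::cstep_solve_woodbury(
      inst$ctx, R, inst$mu, inst$W, inst$b,
      S, inst$gamma
    )
    G <- nrlrl:::cstep_gradient(
      C, inst$ctx, inst$X, inst$E, inst$theta,
      inst$delta, inst$mu, inst$W, inst$b, S, inst$Yk, inst$gamma
    )
    expect_lt(norm(G, "F"), 1e-8 * (1 + norm(R, "F")))
    # the low-rank-corrected path agrees with the dense reference solve
    C_direct <- nrlrl:::cstep_solve_direct(
      inst$ctx, R, inst$mu, inst$W,
      inst$b, S, inst$gamma
    )
    expect_equal(C, C_direct, tolerance = 1e-9)
  }
})

test_that("single-column C-step matches the joint solve at n = 1", {
  set.seed(33)
  d <- 6
  m <- 4
  K <- 2
  A <- matrix(stats::rnorm(d * m), d, m)
  H <- matrix(1.3, 1, 1)
  ctx <- nrlrl:::cstep_context(A, H)
  W <- matrix(stats::rnorm(m * K), m, K)
  b <- stats::rnorm(K)
  S <- matrix(c(0.95, 0.05), K, 1)
  R <- matrix(stats::rnorm(m), m, 1)
  joint <- nrlrl:::cstep_solve_woodbury(ctx, R, 0.8, W, b, S, 1.1)
  single <- nrlrl:::cstep_solve_single(ctx, R, 0.8, W, b, S, 1.1)
  expect_equal(joint, single, tolerance = 1e-10)
})

test_that("C-step reduces to constrained least squares when decoupled", {
  # eta = 0, gamma = 0, E = 0, multipliers 0, huge mu: the stationarity
  # system becomes the KKT/normal system of the joint least-squares fit
  # A C ~ X with soft unit column sums; oracle solves it directly.
  set.seed(34)
  d <- 5
  m <- 4
  n <- 8
  A <- matrix(stats::rnorm(d * m), d, m)
  X <- matrix(stats::rnorm(d * n), d, n)
  H <- diag(n) # eta = 0
  ctx <- nrlrl:::cstep_context(A, H)
  mu <- 1e8
  R <- nrlrl:::cstep_rhs(
    ctx, X, matrix(0, d, n), matrix(0, d, n),
    rep(0, n), mu, NULL, 0, NULL, NULL, 0
  )
  C <- nrlrl:::cstep_solve_woodbury(ctx, R, mu, NULL, 0, NULL, 0)
  oracle <- solve(
    crossprod(A) + matrix(1, m, m),
    crossprod(A, X) + 1
  )
  expect_equal(C, oracle, tolerance = 1e-6)
})

test_that("E-step zero branch follows the threshold rule", {
  # columns with ||g|| <= lambda/mu are zeroed, others shrunk by lambda/mu
  g1 <- c(0.1, 0.1)
  g2 <- c(5, 0)
  E <- prox_l21(cbind(g1, g2), tau = 1)
  expect_equal(E[, 1], c(0, 0))
  expect_equal(E[, 2], c(4, 0))
})

test_that("multiplier update is a no-op at exact feasibility and caps mu", {
  set.seed(35)
  d <- 5
  m <- 3
  n <- 6
  A <- matrix(stats::rnorm(d * m), d, m)
  C <- matrix(stats::rnorm(m * n), m, n)
  C <- sweep(C, 2, colSums(C), `/`) # unit column sums
  E <- matrix(stats::rnorm(d * n), d, n)
  X <- A %*% C + E
  theta <- matrix(stats::rnorm(d * n), d, n)
  delta <- stats::rnorm(n)
  upd <- nrlrl:::admm_update_multipliers(theta, delta, 2, X, A, C, E)
  expect_equal(upd$theta, theta, tolerance = 1e-12)
  expect_equal(upd$delta, delta, tolerance = 1e-12)
  expect_equal(upd$mu, 2.2)
  # penalty growth respects the cap
  upd2 <- nrlrl:::admm_update_multipliers(
    theta, delta, 9.9e5, X, A, C, E,
    rho = 1.1, mu_max = 1e6
  )
  expect_equal(upd2$mu, 1e6)
})

test_that("augmented Lagrangian is non-increasing across C and E steps", {
  # with the convexity shift the frozen-weights C-subproblem is strictly
  # convex, so its exact stationarity solve can only lower the value; the
  # E-step is an exact proximal minimisation
  blob <- generate_gaussian_blobs(
    K = 2, n_per_class = 8, d = 10,
    separation = 3, seed = 4
  )
  n <- 16
  m <- 8
  idx <- nrlrl:::stratified_atoms(blob$y, m, 1)
  A <- blob$X[, idx]
  gr <- build_graph(blob, k = 3)
  lam_min <- min(eigen(locality_matrix(gr), symmetric = TRUE,
    only.values = TRUE
  )$values)
  H <- locality_matrix(gr) + (1 + max(0, -lam_min)) * diag(n)
  ctx <- nrlrl:::cstep_context(A, H)
  Yk <- nrlrl:::ovr_labels(blob$y, 2)
  X <- blob$X
  C <- matrix(1 / m, m, n)
  E <- matrix(0, nrow(X), n)
  theta <- matrix(0, nrow(X), n)
  delta <- rep(0, n)
  mu <- 0.5
  gamma <- 1
  lambda <- 1
  W <- matrix(stats::rnorm(m * 2, sd = 0.3), m, 2)
  b <- c(0.1, -0.1)
  val <- function(C, E, S) {
    nrlrl:::admm_auglag(
      C, E, theta, delta, mu, X, A, lambda, gamma,
      W, b, S, Yk, H
    )
  }
  for (it in 1:5) {
    S <- nrlrl:::cstep_weights(C, W, b, Yk, 0.95, "violation", "expectile")
    v0 <- val(C, E, S)
    R <- nrlrl:::cstep_rhs(ctx, X, E, theta, delta, mu, W, b, S, Yk, gamma)
    C <- nrlrl:::cstep_solve_woodbury(ctx, R, mu, W, b, S, gamma)
    v1 <- val(C, E, S)
    expect_lte(v1, v0 + 1e-8 * (1 + abs(v0)))
    E <- prox_l21(X - A %*% C + theta / mu, lambda / mu)
    v2 <- val(C, E, S)
    expect_lte(v2, v1 + 1e-8 * (1 + abs(v1)))
    upd <- nrlrl:::admm_update_multipliers(theta, delta, mu, X, A, C, E)
    theta <- upd$theta
    delta <- upd$delta
    mu <- upd$mu
  }
})

test_that("classifier refit never increases the learning objective", {
  set.seed(36)
  m <- 5
  n <- 14
  d <- 7
  y <- rep(1:2, each = 7)
  C <- matrix(stats::rnorm(m * n), m, n)
  E <- matrix(stats::rnorm(d * n), d, n) * 0.2
  M <- diag(n)
  stale <- structure(
    list(
      W = matrix(stats::rnorm(m * 2), m, 2), b = stats::rnorm(2),
      p = 0.95, alpha = 1, K = 2, branch = "violation"
    ),
    class = "alssvm"
  )
  refit <- alssvm(C, y, p = 0.95, alpha = 1)
  o_stale <- nrlrl_objective(C, E, stale, y, 1, 1, M)
  o_refit <- nrlrl_objective(C, E, refit, y, 1, 1, M)
  expect_lte(o_refit, o_stale + 1e-10)
  # refitting with unchanged codes is deterministic
  refit2 <- alssvm(C, y, p = 0.95, alpha = 1)
  expect_identical(refit$W, refit2$W)
})

test_that("fitting is deterministic and solves clean separable problems", {
  for (sd in 0:2) {
    blob <- generate_gaussian_blobs(
      K = 2, n_per_class = 10, d = 25,
      separation = 10, seed = sd
    )
    fit <- nrlrl(blob, m = 10, k = 3, max_iters = 200, seed = sd)
    expect_equal(fit$train_accuracy, 1)
  }
  blob <- generate_gaussian_blobs(
    K = 2, n_per_class = 10, d = 25,
    separation = 10, seed = 1
  )
  f1 <- nrlrl(blob, m = 10, k = 3, max_iters = 50, seed = 7)
  f2 <- nrlrl(blob, m = 10, k = 3, max_iters = 50, seed = 7)
  expect_identical(f1$C, f2$C)
  expect_identical(f1$svm$W, f2$svm$W)
  expect_identical(f1$dictionary$atom_indices, f2$dictionary$atom_indices)
})

test_that("encoding satisfies its constraint and recovers atom indicators", {
  blob <- generate_gaussian_blobs(
    K = 2, n_per_class = 10, d = 25,
    separation = 5, seed = 2
  )
  fit <- nrlrl(blob, m = 8, k = 3, max_iters = 60)
  codes <- nrlrl_encode(fit, blob$X)
  # every code lies on the affine slice
  expect_lt(max(abs(colSums(codes) - 1)), 1e-10)
  # KKT residual of the solve
  A <- fit$dictionary$A
  eps <- fit$encode_ridge
  x <- blob$X[, 3, drop = FALSE]
  cc <- nrlrl_encode(fit, x)
  resid <- 2 * (crossprod(A) + eps * diag(8)) %*% cc - 2 * crossprod(A, x)
  # the stationarity residual must be a multiple of the all-ones vector
  # (the constraint's normal); remove it and expect zero
  resid <- resid - mean(resid)
  expect_lt(max(abs(resid)), 1e-8)

  # a dictionary atom encodes to (approximately) its own indicator
  fit$encode_ridge <- 1e-8
  atom1 <- A[, 1, drop = FALSE]
  code1 <- nrlrl_encode(fit, atom1)
  expect_lt(max(abs(code1[-1])), 1e-3)
  expect_equal(code1[1], 1, tolerance = 1e-3)

  expect_error(nrlrl_encode(fit, matrix(0, 3, 1)), "dimension")
})

test_that("prediction is consistent between batch and single samples", {
  blob <- generate_gaussian_blobs(
    K = 3, n_per_class = 8, d = 30,
    separation = 6, seed = 5
  )
  fit <- nrlrl(blob, m = 9, k = 3, max_iters = 80)
  preds <- predict(fit, blob$X)
  expect_true(all(preds %in% 1:3))
  one_by_one <- vapply(
    seq_len(ncol(blob$X)),
    function(j) predict(fit, blob$X[, j, drop = FALSE]), 1L
  )
  expect_equal(preds, one_by_one)
  # encode-vs-trained-codes discrepancy costs at most one sample
  expect_gte(
    sum(preds == blob$y),
    sum(fit$train_accuracy * ncol(blob$X)) - 1
  )
})

test_that("models survive a save/load round trip", {
  blob <- generate_gaussian_blobs(
    K = 2, n_per_class = 6, d = 15,
    separation = 6, seed = 6
  )
  fit <- nrlrl(blob, m = 6, k = 3, max_iters = 40)
  path <- withr::local_tempfile(fileext = ".rds")
  save_nrlrl(fit, path)
  back <- load_nrlrl(path)
  expect_identical(back$C, fit$C)
  expect_equal(predict(back, blob$X), predict(fit, blob$X))
  bad <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(a = 1), bad)
  expect_error(load_nrlrl(bad), "not a recognised")
})

test_that("fit validates hyperparameters and dictionary shapes", {
  blob <- generate_gaussian_blobs(
    K = 2, n_per_class = 6, d = 10,
    separation = 4, seed = 1
  )
  expect_error(nrlrl(blob, p = 1.2), "strictly inside")
  expect_error(nrlrl(blob, lambda = 0))
  expect_error(nrlrl(blob, m = 1), "at least K")
  expect_error(nrlrl(blob, dictionary = matrix(0, 3, 5)), "row dimension")
  expect_warning(
    nrlrl(blob, m = 12, k = 3, max_iters = 5),
    "overcomplete"
  )
})

test_that("NRLRL matches or beats the raw-feature classifier on corrupted traces", {
  # corrupted at noise(20%, 10%) on the structured trace family the model
  # targets: dictionary coding with column-sparse error absorption should
  # at least match a plain aLS-SVM on raw features, averaged over seeds.
  # (On isotropic blobs the raw linear classifier is already the Bayes
  # shape and dictionary compression can only lose; see the vignette's
  # limitations section.)
  accs <- vapply(1:5, function(sd) {
    data <- synthetic_fixture(seed = sd)
    noisy <- inject_noise(data, noise_spec(0.2, 0.10, seed = sd + 500L))
    sp <- stratified_split(noisy$y, 0.5, seed = sd + 900L)
    tr <- subset_samples(noisy, sp$train)
    te <- subset_samples(noisy, sp$test)
    fit <- nrlrl(tr, m = 45, k = 7, max_iters = 200, seed = sd)
    raw <- alssvm(tr$X, tr$y, p = 0.95)
    c(
      nrlrl = mean(predict(fit, te$X) == te$y),
      raw = mean(predict(raw, te$X) == te$y)
    )
  }, c(nrlrl = 0, raw = 0))
  expect_gte(mean(accs["nrlrl", ]), mean(accs["raw", ]))
})
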