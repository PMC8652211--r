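#' Supervised k-nearest-neighbour locality graph
#'
#' Builds the label-aware neighbourhood structure used by the locality
#' preservation term. Two samples are neighbours if either is among the
#' other's k nearest (Euclidean) neighbours — the symmetric "or" rule. The
#' within-class matrix holds heat-kernel weights
#' `exp(-||xi - xj||^2 / t)` for same-label neighbour pairs; the
#' between-class matrix holds the negated weights for different-label
#' neighbour pairs. Both have zero diagonals and are symmetric by
#' construction.
#'
#' `t = "auto"` sets the bandwidth to the mean squared distance over all
#' neighbour pairs, a scale-free self-tuning choice.
#'
#' @param data a [labeled_dataset()].
#' @param k neighbour count, `1 <= k < n`.
#' @param t heat-kernel bandwidth (squared-distance units), a positive
#'   number or `"auto"` (default).
#' @return A `neighbor_graph` object: list with `B_within`, `B_between`
#'   (n x n), `L` (the combined locality operator from
#'   [build_locality_operator()]), `L_within_lap` and `L_between_lap`
#'   (degree-minus-adjacency Laplacians of the within weights and of the
#'   magnitudes of the between weights), `k`, and the resolved `t`.
#' @details Distance ties in the k-NN ranking are broken by lower sample
#'   index, making the graph deterministic. Duplicate points are allowed
#'   (distance 0, weight 1).
#' @export
build_graph <- function(data, k = 7L, t = "auto") {
  stopifnot(inherits(data, "labeled_dataset"))
  n <- ncol(data$X)
  k <- as.integer(k)
  if (k < 1L || k >= n) {
    stop(sprintf("build_graph: need 1 <= k < n, got k = %d, n = %d", k, n))
  }
  d2 <- unname(as.matrix(stats::dist(t(data$X))))^2
  # nn[i, j] = TRUE iff x_i is among the k nearest neighbours of x_j
  nn <- matrix(FALSE, n, n)
  for (j in seq_len(n)) {
    ord <- order(d2[, j], seq_len(n))
    ord <- ord[ord != j]
    nn[ord[seq_len(k)], j] <- TRUE
  }
  nb <- nn | t(nn)
  if (identical(t, "auto")) {
    t <- mean(d2[nb])
    if (!is.finite(t) || t <= 0) t <- 1
  }
  if (!is.numeric(t) || t <= 0) stop("build_graph: t must be positive")
  Wt <- exp(-d2 / t) * nb
  same <- outer(data$y, data$y, `==`)
  B_within <- Wt * same
  B_between <- -Wt * !same
  diag(B_within) <- 0
  diag(B_between) <- 0
  L <- build_locality_operator(B_within, B_between)
  structure(
    list(
      B_within = B_within, B_between = B_between, L = L,
      L_within_lap = graph_laplacian(B_within),
      L_between_lap = graph_laplacian(-B_between),
      k = k, t = t
    ),
    class = "neighbor_graph"
  )
}

# Degree-minus-adjacency Laplacian of a nonnegative symmetric adjacency.
graph_laplacian <- function(B) {
  diag(rowSums(B)) - B
}

#' Combined locality operator
#'
#' Assembles `L = L_between - L_within` from the two signed weight matrices,
#' where each `L` is the degree-minus-adjacency operator of its weight matrix
#' (`L_within = D_within - B_within`, `D[i,i] = sum_j B[i,j]`, likewise for
#' the between matrix with its negative weights). The defining contract,
#' exercised directly by the test suite, is the quadratic-form identity
#'
#' \deqn{\tfrac12 \sum_{ij} \|c_i - c_j\|^2 (B^{w}_{ij} - B^{b}_{ij})
#'       = \mathrm{Tr}(C\,(-L)\,C^\top)}
#'
#' for any code matrix `C` whose columns are the per-sample codes.
#'
#' @param B_within symmetric nonnegative matrix, zero diagonal.
#' @param B_between symmetric nonpositive matrix, zero diagonal.
#' @return The n x n symmetric matrix `L`.
#' @export
build_locality_operator <- function(B_within, B_between) {
  check_locality_input(B_within, "B_within")
  check_locality_input(B_between, "B_between")
  (diag(rowSums(B_between)) - B_between) -
    (diag(rowSums(B_within)) - B_within)
}

check_locality_input <- function(B, name) {
  if (!isSymmetric(unname(B), tol = 1e-10)) {
    stop("build_locality_operator: ", name, " must be symmetric")
  }
  if (any(abs(diag(B)) > 0)) {
    stop("build_locality_operator: ", name, " must have zero diagonal")
  }
}

#' Effective locality matrix for the learning objective
#'
#' The locality penalty added to the objective is `eta * Tr(C L_eff C^T)`.
#' With `sign = "discriminative"` (default), `L_eff` is the within-class
#' Laplacian minus the between-class Laplacian, so minimising the trace pulls
#' same-class codes together *and* pushes different-class codes apart —
#' the stated classification principle of within-class compactness and
#' between-class separation. `sign = "printed"` uses the operator `L` exactly
#' as assembled by [build_locality_operator()], whose minimisation rewards
#' spread of both kinds of pairs; it is retained for comparison.
#'
#' @param graph a `neighbor_graph` from [build_graph()].
#' @param sign `"discriminative"` (default) or `"printed"`.
#' @return An n x n symmetric matrix.
#' @export
locality_matrix <- function(graph, sign = c("discriminative", "printed")) {
  stopifnot(inherits(graph, "neighbor_graph"))
  sign <- match.arg(sign)
  switch(sign,
    discriminative = graph$L_within_lap - graph$L_between_lap,
    printed = graph$L
  )
}

#' @export
print.neighbor_graph <- function(x, ...) {
  n <- nrow(x$B_within)
  cat(sprintf(
    "Supervised k-NN graph: n = %d, k = %d, bandwidth t = %.4g\n",
    n, x$k, x$t
  ))
  cat(sprintf(
    "  within-class edges: %d, between-class edges: %d\n",
    sum(x$B_within > 0) / 2, sum(x$B_between < 0) / 2
  ))
  invisible(x)
}
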