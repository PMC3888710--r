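#' Build the uniform transition matrix of the random walk
#'
#' From an augmented network, builds the row-stochastic matrix M of the
#' walk in which a walker at node i steps to each out-neighbor with equal
#' probability: `M[i, j] = 1 / outdeg(i)` if the edge i -> j exists and 0
#' otherwise. Rows and columns follow the augmented ordering
#' `[S, proteins, T]`. Every node of an augmented network has out-degree
#' at least one, so no row is degenerate.
#'
#' @param aug an [augment()]ed network.
#' @return A `transition_matrix`: a numeric matrix with node labels as
#'   dimnames and class `c("transition_matrix", "matrix", "array")`.
#' @examples
#' M <- build_transition(augment(directed_network(c("A", "B", "C"),
#'                                                cbind("B", "C"))))
#' M["B", ]   # 1/3 to each of S, C, T
#' @export
build_transition <- function(aug) {
  stopifnot(inherits(aug, "augmented_network"))
  ord <- aug$ordering
  n <- length(ord)
  M <- matrix(0, n, n, dimnames = list(ord, ord))
  for (v in ord) {
    nb <- aug$out_neighbors[[v]]
    M[v, nb] <- 1 / length(nb)
  }
  class(M) <- c("transition_matrix", class(matrix()))
  M
}

as_transition_matrix <- function(M, tol = 1e-9) {
  M <- as.matrix(M)
  if (nrow(M) != ncol(M)) stop_io("transition matrix must be square")
  if (any(M < 0)) stop_io("transition matrix has negative entries")
  rs <- rowSums(M)
  if (any(abs(rs - 1) > tol))
    stop_method("row(s) %s do not sum to 1",
                paste(which(abs(rs - 1) > tol), collapse = ", "))
  class(M) <- c("transition_matrix", class(matrix()))
  M
}

#' Load a transition matrix from a CSV file
#'
#' Reads a square row-stochastic matrix for a pre-augmented network,
#' ordering `[S, proteins, T]`. Matrices transcribed from print are
#' typically rounded (4 decimals), so each row whose sum deviates from 1
#' by at most `renorm_tol` is renormalized; a larger deviation, a zero
#' row, a negative entry, or a non-square array is an error.
#'
#' @param path CSV file; a header row of node labels is auto-detected (a
#'   first field that does not parse as a number).
#' @param renorm_tol maximum allowed absolute deviation of a row sum from
#'   1 before renormalization is refused (default `1e-3`, sized for
#'   4-decimal rounding of up to nine entries per row).
#' @return A `transition_matrix` with exact row sums of 1.
#' @examples
#' M <- load_transition(system.file("extdata", "p53_regulators_matrix.csv",
#'                                  package = "walkrank"))
#' dim(M)
#' @export
load_transition <- function(path, renorm_tol = 1e-3) {
  if (!file.exists(path)) stop_io("matrix file not found: %s", path)
  first <- strsplit(readLines(path, n = 1L), ",")[[1]]
  has_header <- suppressWarnings(anyNA(as.numeric(first[nzchar(first)])))
  raw <- utils::read.csv(path, header = has_header, check.names = FALSE)
  labeled <- has_header && is.character(raw[[1]])
  if (labeled) {
    labs <- raw[[1]]
    raw <- raw[, -1L, drop = FALSE]
  }
  M <- as.matrix(raw)
  if (!is.numeric(M)) stop_io("non-numeric entries in %s", path)
  if (nrow(M) != ncol(M))
    stop_io("matrix in %s is not square (%d x %d)", path, nrow(M), ncol(M))
  if (any(M < 0)) stop_io("negative entries in %s", path)
  if (labeled) dimnames(M) <- list(labs, labs)
  else if (has_header) dimnames(M) <- list(colnames(raw), colnames(raw))
  else {
    labs <- paste0("v", seq_len(nrow(M)))
    dimnames(M) <- list(labs, labs)
  }
  rs <- rowSums(M)
  bad <- abs(rs - 1) > renorm_tol
  if (any(bad))
    stop_method(
      "row(s) %s of %s sum to %s; outside the +/- %g renormalization band",
      paste(which(bad), collapse = ", "), path,
      paste(signif(rs[bad], 6), collapse = ", "), renorm_tol)
  M <- M / rs
  class(M) <- c("transition_matrix", class(matrix()))
  M
}

gcd2 <- function(a, b) if (b == 0L) a else gcd2(b, a %% b)

support_igraph <- function(M) {
  igraph::graph_from_adjacency_matrix((unclass(M) > 0) * 1L,
                                      mode = "directed")
}

#' Verify the convergence conditions of the walk
#'
#' A unique stationary distribution that the walk converges to from any
#' start exists iff the support graph of the transition matrix is
#' irreducible (strongly connected) and aperiodic (the greatest common
#' divisor of all directed cycle lengths is 1). Augmentation guarantees
#' both: for any node A the cycle A -> T -> S -> A has length 3, and any
#' protein edge A -> B closes a cycle A -> B -> T -> S -> A of length 4,
#' so the gcd is 1.
#'
#' Strong connectivity is decided by igraph's strongly-connected-component
#' computation. The period is computed by the BFS-level method: label the
#' nodes with breadth-first levels from an arbitrary root, then take the
#' gcd over all edges u -> v of `level(u) + 1 - level(v)`.
#'
#' @param M a `transition_matrix` (or any nonnegative square matrix; its
#'   support is taken as the directed graph).
#' @return An `ergodicity_report`: list with `strongly_connected`
#'   (logical), `period` (integer; 0 if not strongly connected, where the
#'   period is undefined), and `is_ergodic` (`strongly_connected` and
#'   `period == 1`).
#' @examples
#' toy <- build_transition(augment(directed_network(c("A", "B", "C"),
#'                                                  cbind("B", "C"))))
#' check_ergodicity(toy)
#' @export
check_ergodicity <- function(M) {
  g <- support_igraph(M)
  strong <- igraph::components(g, mode = "strong")$no == 1L
  period <- 0L
  if (strong) {
    lev <- as.integer(igraph::bfs(g, root = 1, dist = TRUE)$dist)
    el <- igraph::as_edgelist(g, names = FALSE)
    d <- lev[el[, 1L]] + 1L - lev[el[, 2L]]
    period <- 0L
    for (x in abs(d)) period <- gcd2(max(period, x), min(period, x))
    if (period == 0L) period <- 1L  # single node, self-transition only
  }
  structure(list(strongly_connected = strong, period = period,
                 is_ergodic = strong && period == 1L),
            class = "ergodicity_report")
}

#' @export
print.ergodicity_report <- function(x, ...) {
  cat(sprintf("strongly connected: %s; period: %s; ergodic: %s\n",
              if (x$strongly_connected) "yes" else "no",
              if (x$strongly_connected) x$period else "undefined",
              if (x$is_ergodic) "yes" else "no"))
  invisible(x)
}

new_stationary <- function(p, M, scaling, method) {
  canon <- p / sum(p)
  resid <- max(abs(canon %*% unclass(M) - canon))
  p <- switch(scaling,
              "sum-one"          = canon,
              "unit-euclidean"   = p / sqrt(sum(p^2)),
              "initial-node-one" = p / p[1L],
              stop_io("unknown scaling '%s'", scaling))
  names(p) <- rownames(M)
  structure(list(p = p, scaling = scaling, residual = resid,
                 method = method),
            class = "stationary_distribution")
}

#' @export
print.stationary_distribution <- function(x, digits = 4, ...) {
  cat(sprintf("stationary distribution (%s, %s scaling, residual %.2e)\n",
              x$method, x$scaling, x$residual))
  print(round(x$p, digits))
  invisible(x)
}

#' Rescale a stationary distribution
#'
#' The stationary solution of `P M = P` is defined up to a positive
#' factor; this switches between the supported normalizations.
#'
#' @param P a `stationary_distribution`.
#' @param scaling `"sum-one"` (probabilities, the canonical internal
#'   form), `"unit-euclidean"` (unit 2-norm), or `"initial-node-one"`
#'   (first entry 1).
#' @return A rescaled `stationary_distribution`.
#' @export
rescale <- function(P, scaling = c("sum-one", "unit-euclidean",
                                   "initial-node-one")) {
  stopifnot(inherits(P, "stationary_distribution"))
  scaling <- match.arg(scaling)
  p <- switch(scaling,
              "sum-one"          = P$p / sum(P$p),
              "unit-euclidean"   = P$p / sqrt(sum(P$p^2)),
              "initial-node-one" = P$p / P$p[1L])
  structure(list(p = p, scaling = scaling, residual = P$residual,
                 method = P$method),
            class = "stationary_distribution")
}

#' Solve the stationary distribution directly
#'
#' Solves `P M = P` as the null space of the transposed matrix `t(M) - I`:
#' the eigenvector of `t(M)` for eigenvalue 1. For an ergodic chain the
#' eigenvalue 1 is simple and the Perron-Frobenius theorem guarantees an
#' eigenvector with entries of one sign, so the vector is sign-fixed to
#' nonnegative and rescaled to the requested convention.
#'
#' @param M a `transition_matrix`.
#' @param scaling output normalization, see [rescale()].
#' @param check verify ergodicity first (default). Set `FALSE` to bypass
#'   the check for externally loaded matrices known to be ergodic.
#' @return A `stationary_distribution`: list with `p` (named vector),
#'   `scaling`, `residual` (max-norm of `P M - P` for the sum-one
#'   vector), and `method`.
#' @examples
#' toy <- build_transition(augment(directed_network(c("A", "B", "C"),
#'                                                  cbind("B", "C"))))
#' stationary_direct(toy, scaling = "initial-node-one")$p
#' # S = 1, A = 1/3, B = 1/3, C = 4/9, T = 1/2
#' @export
stationary_direct <- function(M, scaling = c("sum-one", "unit-euclidean",
                                             "initial-node-one"),
                              check = TRUE) {
  M <- as_transition_matrix(M)
  scaling <- match.arg(scaling)
  if (check) {
    erg <- check_ergodicity(M)
    if (!erg$is_ergodic)
      stop_method(paste0("chain is not ergodic (strongly connected: %s, ",
                         "period: %d); no unique stationary distribution"),
                  erg$strongly_connected, erg$period)
  }
  e <- eigen(t(unclass(M)))
  ix <- which(abs(e$values - 1) < 1e-6)
  if (length(ix) != 1L)
    stop_method("eigenspace at eigenvalue 1 has dimension %d (expected 1)",
                length(ix))
  p <- Re(e$vectors[, ix])
  p <- p * sign(sum(p))
  if (any(p < -1e-8))
    stop_method("stationary eigenvector is not one-signed; degenerate input")
  p[p < 0] <- 0
  new_stationary(p, M, scaling, "direct")
}

#' Approximate the stationary distribution by power iteration
#'
#' Iterates the state-distribution update `P_{t+1} = P_t M` from the
#' uniform distribution until the max-norm change drops below `tol`. For
#' an ergodic chain the limit is the unique stationary distribution
#' whatever the start; this serves as an independent cross-check of
#' [stationary_direct()]. A periodic chain oscillates and is reported as
#' non-convergence.
#'
#' @inheritParams stationary_direct
#' @param tol convergence threshold on the max-norm step change.
#' @param max_iter iteration cap; exceeding it raises a method error.
#' @param start optional starting distribution (defaults to uniform).
#' @return A `stationary_distribution` (sum-one iterate rescaled to the
#'   requested convention).
#' @export
stationary_power <- function(M, tol = 1e-12, max_iter = 1e6,
                             scaling = c("sum-one", "unit-euclidean",
                                         "initial-node-one"),
                             check = TRUE, start = NULL) {
  M <- as_transition_matrix(M)
  scaling <- match.arg(scaling)
  if (tol <= 0) stop_io("tol must be positive")
  if (check) {
    erg <- check_ergodicity(M)
    if (!erg$is_ergodic)
      stop_method("chain is not ergodic; power iteration would not converge")
  }
  n <- nrow(M)
  p <- if (is.null(start)) rep(1 / n, n) else start / sum(start)
  Mu <- unclass(M)
  for (it in seq_len(max_iter)) {
    p_new <- as.vector(p %*% Mu)
    if (max(abs(p_new - p)) < tol) {
      return(new_stationary(p_new, M, scaling, "power"))
    }
    p <- p_new
  }
  stop_method(
    "power iteration did not converge in %d iterations (tol %g); %s",
    max_iter, tol, "the chain may be periodic or tol too tight")
}
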