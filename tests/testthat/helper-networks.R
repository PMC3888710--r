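# Shared builders and independent oracles.

toy_net <- function() directed_network(c("A", "B", "C"), cbind("B", "C"))

toy_matrix <- function() build_transition(augment(toy_net()))

# Exact transition matrix of the augmented toy network, assembled from the
# uniform rule by hand (order S, A, B, C, T).
toy_matrix_expected <- function() {
  m <- rbind(c(0, 1/3, 1/3, 1/3, 0),
             c(1/2, 0, 0, 0, 1/2),
             c(1/3, 0, 0, 1/3, 1/3),
             c(1/2, 0, 0, 0, 1/2),
             c(1, 0, 0, 0, 0))
  dimnames(m) <- list(c("S", "A", "B", "C", "T"),
                      c("S", "A", "B", "C", "T"))
  m
}

# Row-stochastic matrix of a pure 2-cycle (period 2, no augmentation).
cycle2_matrix <- function() {
  m <- rbind(c(0, 1), c(1, 0))
  dimnames(m) <- list(c("u", "v"), c("u", "v"))
  m
}

# Brute-force period oracle: gcd of all cycle lengths up to Lmax, detected
# through positive diagonal entries of powers of the adjacency matrix.
brute_period <- function(adj, Lmax = 2L * nrow(adj)) {
  gcd <- function(a, b) if (b == 0) a else gcd(b, a %% b)
  P <- diag(nrow(adj))
  lens <- integer(0)
  for (l in seq_len(Lmax)) {
    P <- P %*% adj
    if (any(diag(P) > 0)) lens <- c(lens, l)
  }
  if (!length(lens)) return(0L)
  Reduce(gcd, lens)
}

# Independent stationary-distribution oracle: solve the balance equations
# t(M) p = p with the sum-to-one constraint as an overdetermined linear
# system (no eigendecomposition involved).
stationary_linear_oracle <- function(M) {
  n <- nrow(M)
  A <- rbind(t(unclass(M)) - diag(n), rep(1, n))
  p <- qr.solve(A, c(rep(0, n), 1))
  stats::setNames(p, rownames(M))
}

# Random networks re-augmented for property loops; guarantees n >= 1.
random_augmented <- function(n, p, seed) {
  augment(random_network(n, p, seed))
}
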