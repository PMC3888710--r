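#' Simulate the random walk on an augmented network
#'
#' Runs the walker process directly: starting at the initial node S, at
#' each step the walker moves to a uniformly chosen out-neighbor. Visit
#' counts estimate the stationary distribution independently of the
#' analytic solvers, making the simulator an implementation-independent
#' oracle. The start at S is counted as a visit, so counts sum to
#' `steps + 1` and empirical frequencies divide by `steps + 1` (the
#' standard occupancy estimator); with `burn_in = B` the first `B`
#' visits are discarded and counts sum to `steps + 1 - B`.
#'
#' @param aug an [augment()]ed network.
#' @param steps number of steps to take (`>= 1`).
#' @param seed integer seed; the run is reproducible and leaves the
#'   caller's RNG state untouched.
#' @param burn_in number of initial visits to discard (default 0; the
#'   chain mixes fast at typical sizes).
#' @return A `walk_result`: list with `visit_counts` (named integer
#'   vector over the augmented ordering), `steps`, `burn_in`, `seed`,
#'   and `empirical_frequencies` (counts / total visits, summing to 1).
#' @examples
#' aug <- augment(directed_network(c("A", "B", "C"), cbind("B", "C")))
#' simulate_walk(aug, steps = 1000, seed = 42)$empirical_frequencies
#' @export
simulate_walk <- function(aug, steps, seed, burn_in = 0L) {
  stopifnot(inherits(aug, "augmented_network"))
  if (!is.numeric(steps) || length(steps) != 1L || steps < 1 ||
      steps != round(steps))
    stop_io("steps must be a positive integer")
  if (burn_in < 0 || burn_in > steps)
    stop_io("burn_in must be in [0, steps]")
  ord <- aug$ordering
  n <- length(ord)
  idx <- stats::setNames(seq_len(n), ord)
  nbrs <- lapply(ord, function(v) unname(idx[aug$out_neighbors[[v]]]))
  deg <- lengths(nbrs)
  visits <- integer(n)
  u <- with_seed(seed, stats::runif(steps))
  cur <- 1L                       # start at S
  visits[cur] <- 1L
  for (t in seq_len(steps)) {
    cur <- nbrs[[cur]][1L + floor(u[t] * deg[cur])]
    visits[cur] <- visits[cur] + 1L
  }
  if (burn_in > 0L) {
    # replay the first burn_in visits and subtract them
    drop <- integer(n)
    cur <- 1L
    drop[cur] <- 1L
    t <- 0L
    while (sum(drop) < burn_in && t < steps) {
      t <- t + 1L
      cur <- nbrs[[cur]][1L + floor(u[t] * deg[cur])]
      drop[cur] <- drop[cur] + 1L
    }
    visits <- visits - drop
  }
  total <- sum(visits)
  structure(list(visit_counts = stats::setNames(visits, ord),
                 steps = as.integer(steps), burn_in = as.integer(burn_in),
                 seed = seed,
                 empirical_frequencies = stats::setNames(visits / total,
                                                         ord)),
            class = "walk_result")
}

#' @export
print.walk_result <- function(x, ...) {
  cat(sprintf("random walk: %d step(s), seed %s\n", x$steps,
              format(x$seed)))
  print(round(x$empirical_frequencies, 4))
  invisible(x)
}

#' Compare empirical visit frequencies with the analytic distribution
#'
#' Summarizes the divergence between the Monte Carlo occupancy estimate
#' and the analytic stationary distribution: maximum absolute deviation,
#' total variation distance, and per-node z-scores using the binomial
#' standard error `sqrt(p (1 - p) / steps)` (an approximation that
#' ignores the walk's serial dependence).
#'
#' @param analytic a `stationary_distribution` over the same ordering
#'   (rescaled internally to sum-one).
#' @param empirical a [simulate_walk()] result.
#' @return A `walk_divergence` list: `max_abs_deviation`,
#'   `total_variation`, and `per_node` (data frame of analytic and
#'   empirical probabilities, deviation and z-score).
#' @export
compare_empirical <- function(analytic, empirical) {
  stopifnot(inherits(analytic, "stationary_distribution"),
            inherits(empirical, "walk_result"))
  p <- rescale(analytic, "sum-one")$p
  q <- empirical$empirical_frequencies
  if (!identical(names(p), names(q)))
    stop_io("node orderings differ between analytic and empirical inputs")
  dev <- q - p
  se <- sqrt(p * (1 - p) / empirical$steps)
  structure(list(max_abs_deviation = max(abs(dev)),
                 total_variation = sum(abs(dev)) / 2,
                 per_node = data.frame(node = names(p),
                                       analytic = unname(p),
                                       empirical = unname(q),
                                       deviation = unname(dev),
                                       z = unname(dev / se),
                                       row.names = NULL,
                                       stringsAsFactors = FALSE)),
            class = "walk_divergence")
}

#' @export
print.walk_divergence <- function(x, ...) {
  cat(sprintf("max |deviation| %.4g; total variation %.4g\n",
              x$max_abs_deviation, x$total_variation))
  print(x$per_node, digits = 4)
  invisible(x)
}
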