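#' Per-protein influence scores from a stationary distribution
#'
#' Drops the first and last entries of the stationary vector (the
#' artificial initial node S and transition node T), and divides the
#' remaining protein entries by their sum N. The resulting vector X sums
#' to 1 and its entries are read as the percentage of each protein's
#' individual interaction with the hub (p53/MDM2) that is effective
#' within the network. Because the operation renormalizes, the result is
#' identical for any input scaling of the stationary vector.
#'
#' @param P a `stationary_distribution` (any scaling), or a bare numeric
#'   vector ordered `[S, proteins, T]`.
#' @param ordering optional node ordering if `P` is an unnamed vector.
#' @return An `influence_scores` object: list with `scores` (named vector
#'   in `(0, 1)` summing to 1), `norm_constant` (the divisor N),
#'   `baseline` (`1/n`), and `ranking` (protein labels by descending
#'   score, ties stable in input order).
#' @examples
#' toy <- build_transition(augment(directed_network(c("A", "B", "C"),
#'                                                  cbind("B", "C"))))
#' influence_scores(stationary_direct(toy))$scores  # 0.3 0.3 0.4
#' @export
influence_scores <- function(P, ordering = NULL) {
  p <- if (inherits(P, "stationary_distribution")) P$p
       else stats::setNames(as.numeric(P), names(P))
  if (!is.null(ordering)) {
    if (length(ordering) != length(p))
      stop_io("ordering length %d does not match vector length %d",
              length(ordering), length(p))
    names(p) <- ordering
  }
  n_all <- length(p)
  if (n_all < 3L)
    stop_method("need at least 3 entries (S, one protein, T); got %d", n_all)
  inner <- p[2:(n_all - 1L)]
  N <- sum(inner)
  x <- inner / N
  labels <- names(x)
  if (is.null(labels)) labels <- paste0("p", seq_along(x))
  names(x) <- labels
  # rank on 12 significant digits so solver noise at machine precision does
  # not break the stable input-order tie-break
  structure(list(scores = x, norm_constant = N, baseline = 1 / length(x),
                 ranking = labels[order(-signif(x, 12))]),
            class = "influence_scores")
}

#' @export
print.influence_scores <- function(x, ...) {
  cat(sprintf("influence scores for %d protein(s) (baseline %.2f%%)\n",
              length(x$scores), 100 * x$baseline))
  for (nm in names(x$scores))
    cat(sprintf("  %-10s %6.2f%%  (%.4f)\n", nm, 100 * x$scores[[nm]],
                x$scores[[nm]]))
  invisible(x)
}

#' Compare influence scores to the uniform baseline
#'
#' In a network with no protein-protein edges every protein scores
#' exactly `1/n`; the ratio of a protein's score to this uniform baseline
#' measures how much the network amplifies or damps its individual
#' interaction with the hub.
#'
#' @param X an [influence_scores()] object.
#' @return A data frame with one row per protein: `protein`, `score`,
#'   `percent` (score * 100), `baseline`, `ratio` (score / baseline),
#'   `above_baseline`, and `rank` (1 = highest score, ties stable in
#'   input order).
#' @examples
#' toy <- build_transition(augment(directed_network(c("A", "B", "C"),
#'                                                  cbind("B", "C"))))
#' compare_to_baseline(influence_scores(stationary_direct(toy)))
#' @export
compare_to_baseline <- function(X) {
  stopifnot(inherits(X, "influence_scores"))
  s <- X$scores
  rank <- match(names(s), X$ranking)
  data.frame(protein = names(s), score = unname(s),
             percent = unname(100 * s), baseline = X$baseline,
             ratio = unname(s / X$baseline),
             above_baseline = unname(s > X$baseline),
             rank = rank, row.names = NULL,
             stringsAsFactors = FALSE)
}

# Full pipeline on a plain network: validate -> augment -> transition ->
# stationary -> influence scores.
score_network <- function(net, method = c("direct", "power"), ...) {
  method <- match.arg(method)
  M <- build_transition(augment(net))
  P <- if (method == "direct") stationary_direct(M, ...)
       else stationary_power(M, ...)
  influence_scores(P)
}

#' Two-stage group-then-rescore procedure
#'
#' For networks too large to study whole, proteins are first partitioned
#' into functional groups. Stage 1 scores each group's induced
#' subnetwork independently (each augmented with its own S and T); stage
#' 2 takes the `k` highest-scoring proteins of every group, induces their
#' joint subnetwork from the original edges, and scores that network.
#' Edges between selected proteins are taken from the original network,
#' not re-derived.
#'
#' @param net the full [directed_network()].
#' @param groups named list mapping group label to a character vector of
#'   protein labels; groups may overlap but must be non-empty subsets of
#'   the network's nodes.
#' @param k number of top-scoring proteins to carry forward from each
#'   group; clamped to the group size with a warning.
#' @return A `hierarchical_scores` object: list with `stage1` (named list
#'   of per-group [influence_scores()]), `selected` (named list of the
#'   proteins carried forward), and `stage2` (the final
#'   [influence_scores()] on the selected proteins' joint subnetwork).
#' @export
hierarchical_score <- function(net, groups, k) {
  stopifnot(inherits(net, "directed_network"))
  if (!is.list(groups) || is.null(names(groups)) || !length(groups))
    stop_io("groups must be a non-empty named list of protein vectors")
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != round(k))
    stop_io("k must be a positive integer")
  stage1 <- list()
  selected <- list()
  for (g in names(groups)) {
    members <- unique(as.character(groups[[g]]))
    if (!length(members)) stop_method("group '%s' is empty", g)
    sub <- induce_subnetwork(net, members)
    sc <- score_network(sub)
    kk <- k
    if (kk > length(members)) {
      warning(sprintf("k = %d exceeds size of group '%s' (%d); clamped",
                      k, g, length(members)), call. = FALSE)
      kk <- length(members)
    }
    stage1[[g]] <- sc
    selected[[g]] <- sc$ranking[seq_len(kk)]
  }
  chosen <- net$nodes[net$nodes %in% unique(unlist(selected))]
  stage2 <- score_network(induce_subnetwork(net, chosen))
  structure(list(stage1 = stage1, selected = selected, stage2 = stage2),
            class = "hierarchical_scores")
}

#' @export
print.hierarchical_scores <- function(x, ...) {
  cat(sprintf("hierarchical scoring: %d group(s) -> %d selected protein(s)\n",
              length(x$stage1), length(x$stage2$scores)))
  for (g in names(x$selected))
    cat(sprintf("  %s: selected %s\n", g,
                paste(x$selected[[g]], collapse = ", ")))
  cat("stage-2 scores:\n")
  print(x$stage2)
  invisible(x)
}
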