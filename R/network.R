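#' @keywords internal
"_PACKAGE"

# Condition helpers: method errors (exit code 1 at the CLI) vs I/O and
# configuration errors (exit code 2).
stop_method <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("walkrank_method_error", "walkrank_error")))
}

stop_io <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("walkrank_io_error", "walkrank_error")))
}

#' Construct and validate a directed protein network
#'
#' Builds the canonical directed-network object from node labels and a list
#' of directed edges. Each node represents a protein and each directed edge
#' a protein-protein interaction. Validation enforces the invariants the
#' random-walk model relies on: unique non-empty labels, no self-loops, no
#' reference to undeclared nodes, and no collision with the reserved labels
#' of the artificial initial and transition nodes.
#'
#' Duplicate directed edges are collapsed to a single edge with a warning:
#' the walk assigns equal probability to each distinct out-edge, so edge
#' multiplicity carries no meaning in this model.
#'
#' @param nodes character vector of unique node labels, in the order that
#'   defines the matrix ordering downstream.
#' @param edges directed edges: a two-column matrix or data frame
#'   (source, target), or `NULL` for an edgeless network.
#' @param reserved labels reserved for the artificial nodes prepended and
#'   appended by [augment()]; defaults to `c("S", "T")`. Override if a
#'   protein is literally named S or T.
#' @return An object of class `directed_network` with elements `nodes`
#'   (character) and `edges` (two-column character matrix).
#' @examples
#' net <- directed_network(c("A", "B", "C"), cbind("B", "C"))
#' net
#' @seealso [augment()], [read_network()], [random_network()]
#' @export
directed_network <- function(nodes, edges = NULL, reserved = c("S", "T")) {
  nodes <- as.character(nodes)
  if (length(nodes) < 1L)
    stop_method("network must contain at least one node")
  if (anyNA(nodes) || any(!nzchar(nodes)))
    stop_method("node labels must be non-empty strings")
  if (anyDuplicated(nodes))
    stop_method("duplicate node label(s): %s",
                paste(unique(nodes[duplicated(nodes)]), collapse = ", "))
  hit <- intersect(nodes, reserved)
  if (length(hit))
    stop_method("node label(s) collide with reserved artificial labels: %s",
                paste(hit, collapse = ", "))

  if (is.null(edges) || NROW(edges) == 0L) {
    em <- matrix(character(0), ncol = 2L,
                 dimnames = list(NULL, c("source", "target")))
  } else {
    em <- as.matrix(edges)
    if (ncol(em) != 2L)
      stop_io("edges must have two columns (source, target)")
    storage.mode(em) <- "character"
    colnames(em) <- c("source", "target")
    unknown <- setdiff(c(em), nodes)
    if (length(unknown))
      stop_method("edge endpoint(s) not in node set: %s",
                  paste(unknown, collapse = ", "))
    loops <- em[, 1L] == em[, 2L]
    if (any(loops))
      stop_method("self-loop(s) not allowed: %s",
                  paste(unique(em[loops, 1L]), collapse = ", "))
    key <- paste(em[, 1L], em[, 2L], sep = "\r")
    if (anyDuplicated(key)) {
      warning(sprintf("collapsed %d duplicate directed edge(s)",
                      sum(duplicated(key))), call. = FALSE)
      em <- em[!duplicated(key), , drop = FALSE]
    }
  }
  structure(list(nodes = nodes, edges = em, reserved = reserved),
            class = "directed_network")
}

#' @export
print.directed_network <- function(x, ...) {
  cat(sprintf("directed_network: %d node(s), %d directed edge(s)\n",
              length(x$nodes), nrow(x$edges)))
  cat("nodes:", paste(x$nodes, collapse = ", "), "\n")
  if (nrow(x$edges))
    cat("edges:", paste(x$edges[, 1L], x$edges[, 2L], sep = "->",
                        collapse = ", "), "\n")
  invisible(x)
}

# Ordered out-neighbor list over the given node ordering.
out_neighbor_list <- function(nodes, edges) {
  out <- stats::setNames(vector("list", length(nodes)), nodes)
  for (v in nodes) out[[v]] <- character(0)
  if (nrow(edges))
    for (i in seq_len(nrow(edges)))
      out[[edges[i, 1L]]] <- c(out[[edges[i, 1L]]], unname(edges[i, 2L]))
  out
}

#' Augment a network with the initial node S and transition node T
#'
#' Adds the two artificial nodes that make the random walk ergodic and give
#' it its restart semantics. The initial node S gains a directed edge to
#' every protein node (restart: influence entering the network from external
#' proteins); every protein node gains directed edges to S and to T; and T
#' has a single directed edge back to S (the walk exiting to external
#' proteins). S has no edge to T. The node ordering of the augmented
#' network is `[S, proteins in input order, T]`.
#'
#' @param net a [directed_network()].
#' @return An object of class `augmented_network` with elements `base` (the
#'   input network), `ordering` (character vector `[S, proteins, T]`), and
#'   `out_neighbors` (named list of ordered out-neighbor vectors).
#' @examples
#' aug <- augment(directed_network(c("A", "B", "C"), cbind("B", "C")))
#' aug$out_neighbors$B   # S, C, T
#' @export
augment <- function(net) {
  stopifnot(inherits(net, "directed_network"))
  s <- net$reserved[1L]
  t <- net$reserved[2L]
  ordering <- c(s, net$nodes, t)
  base_out <- out_neighbor_list(net$nodes, net$edges)
  out <- stats::setNames(vector("list", length(ordering)), ordering)
  out[[s]] <- net$nodes
  for (v in net$nodes) out[[v]] <- c(s, base_out[[v]], t)
  out[[t]] <- s
  structure(list(base = net, ordering = ordering, out_neighbors = out,
                 s_label = s, t_label = t),
            class = "augmented_network")
}

#' @export
print.augmented_network <- function(x, ...) {
  cat(sprintf("augmented_network: %d node(s) [%s, %d protein(s), %s]\n",
              length(x$ordering), x$s_label, length(x$base$nodes),
              x$t_label))
  invisible(x)
}

#' Describe the on-disk format of a network file
#'
#' @param format one of `"edge-list"` (one source/target pair per line),
#'   `"sif"` (Cytoscape-style `source relation target...` lines; the
#'   relation is ignored, a single token declares an isolated node), or
#'   `"adjacency"` (square 0/1 CSV with a label header row and column).
#' @param delimiter field separator for edge-list files (default tab).
#' @param header whether the first line of an edge-list file is a header.
#' @param undirected if `TRUE`, each listed pair is expanded into both
#'   directed edges. The model's walk is directed, so the default is
#'   directed input.
#' @return A `network_dialect` list used by [read_network()] and
#'   [write_network()].
#' @export
network_dialect <- function(format = c("edge-list", "sif", "adjacency"),
                            delimiter = "\t", header = FALSE,
                            undirected = FALSE) {
  format <- match.arg(format)
  structure(list(format = format, delimiter = delimiter,
                 header = isTRUE(header), undirected = isTRUE(undirected)),
            class = "network_dialect")
}

#' Read a directed network from a file
#'
#' Node order is first-appearance order: nodes declared in `nodes` (or the
#' sidecar node-list file) first, then edge endpoints in the order they are
#' encountered. A node-list sidecar is the only way to declare isolated
#' nodes in edge-list format.
#'
#' @param path path to the network file.
#' @param dialect a [network_dialect()].
#' @param nodes optional character vector of node labels, or a path to a
#'   sidecar file with one label per line, declaring nodes (including
#'   isolated ones) ahead of the edge list.
#' @param reserved reserved artificial labels, see [directed_network()].
#' @return A [directed_network()].
#' @examples
#' f <- tempfile(); writeLines("B\tC", f)
#' read_network(f, nodes = c("A", "B", "C"))
#' @export
read_network <- function(path, dialect = network_dialect(), nodes = NULL,
                         reserved = c("S", "T")) {
  if (!file.exists(path)) stop_io("network file not found: %s", path)
  if (!is.null(nodes) && length(nodes) == 1L && file.exists(nodes))
    nodes <- readLines(nodes, warn = FALSE)
  nodes <- setdiff(trimws(as.character(nodes)), "")

  if (dialect$format == "adjacency") {
    m <- utils::read.csv(path, row.names = 1L, check.names = FALSE)
    m <- as.matrix(m)
    if (nrow(m) != ncol(m) || !identical(rownames(m), colnames(m)))
      stop_io("adjacency file is not square with matching labels: %s", path)
    idx <- which(m != 0, arr.ind = TRUE)
    em <- cbind(rownames(m)[idx[, 1L]], colnames(m)[idx[, 2L]])
    em <- em[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
    labels <- unique(c(nodes, rownames(m)))
    return(directed_network(labels, em, reserved = reserved))
  }

  lines <- readLines(path, warn = FALSE)
  if (dialect$header && length(lines)) lines <- lines[-1L]
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  lineno <- which(keep) + if (dialect$header) 1L else 0L
  lines <- lines[keep]
  if (!length(lines) && !length(nodes))
    stop_io("empty network file: %s", path)

  src <- character(0); dst <- character(0); appear <- character(0)
  for (i in seq_along(lines)) {
    tok <- strsplit(lines[i],
                    if (dialect$format == "sif") "\t| +" else dialect$delimiter)[[1]]
    tok <- tok[nzchar(tok)]
    if (dialect$format == "sif") {
      if (length(tok) == 1L) { appear <- c(appear, tok); next }
      if (length(tok) == 2L)
        stop_io("malformed SIF line %d in %s: need source, relation, target(s)",
                lineno[i], path)
      src <- c(src, rep(tok[1L], length(tok) - 2L))
      dst <- c(dst, tok[-(1:2)])
      appear <- c(appear, tok[1L], tok[-(1:2)])
    } else {
      if (length(tok) != 2L)
        stop_io("malformed line %d in %s: expected 2 fields, got %d",
                lineno[i], path, length(tok))
      src <- c(src, tok[1L]); dst <- c(dst, tok[2L])
      appear <- c(appear, tok)
    }
  }
  if (dialect$undirected && length(src)) {
    src0 <- src
    src <- c(src, dst); dst <- c(dst, src0)
  }
  labels <- unique(c(nodes, appear))
  em <- if (length(src)) cbind(src, dst) else NULL
  directed_network(labels, em, reserved = reserved)
}

#' Write a directed network to a file
#'
#' Inverse of [read_network()] for each dialect; reading the written file
#' back yields an identical network.
#'
#' @inheritParams read_network
#' @param net a [directed_network()].
#' @param nodes_path optional path for an edge-list node sidecar (needed to
#'   round-trip isolated nodes).
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, dialect = network_dialect(),
                          nodes_path = NULL) {
  stopifnot(inherits(net, "directed_network"))
  if (dialect$format == "adjacency") {
    n <- length(net$nodes)
    m <- matrix(0L, n, n, dimnames = list(net$nodes, net$nodes))
    if (nrow(net$edges)) m[net$edges] <- 1L
    utils::write.csv(as.data.frame(m), path)
  } else if (dialect$format == "sif") {
    deg <- table(factor(c(net$edges), levels = net$nodes))
    iso <- net$nodes[deg == 0L]
    lines <- c(if (nrow(net$edges))
                 paste(net$edges[, 1L], "interacts", net$edges[, 2L],
                       sep = "\t"),
               iso)
    writeLines(lines, path)
    if (!is.null(nodes_path)) writeLines(net$nodes, nodes_path)
  } else {
    writeLines(paste(net$edges[, 1L], net$edges[, 2L],
                     sep = dialect$delimiter), path)
    if (!is.null(nodes_path)) writeLines(net$nodes, nodes_path)
  }
  invisible(path)
}

# Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate a seeded directed Erdos-Renyi network
#'
#' Each ordered pair of distinct nodes is included as a directed edge
#' independently with probability `edge_prob`. Used as the input generator
#' for property-style testing of the scoring pipeline; reproducible for a
#' fixed seed and side-effect free on the caller's RNG state.
#'
#' @param n number of nodes (`>= 1`); labels are `n1, n2, ...`.
#' @param edge_prob edge inclusion probability in `[0, 1]`.
#' @param seed integer seed.
#' @param labels optional custom node labels of length `n`.
#' @return A [directed_network()].
#' @examples
#' random_network(5, 0.3, seed = 7)
#' @export
random_network <- function(n, edge_prob, seed, labels = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    stop_io("n must be a positive integer")
  if (!is.numeric(edge_prob) || edge_prob < 0 || edge_prob > 1)
    stop_io("edge_prob must be in [0, 1]")
  if (is.null(labels)) labels <- paste0("n", seq_len(n))
  stopifnot(length(labels) == n)
  pairs <- expand.grid(target = seq_len(n), source = seq_len(n))
  pairs <- pairs[pairs$source != pairs$target, c("source", "target")]
  pairs <- pairs[order(pairs$source, pairs$target), ]
  keep <- with_seed(seed, stats::runif(nrow(pairs)) < edge_prob)
  em <- if (any(keep))
    cbind(labels[pairs$source[keep]], labels[pairs$target[keep]]) else NULL
  directed_network(labels, em)
}

# Induced subnetwork: keep `keep_nodes` (in original order) and the edges
# whose endpoints both survive.
induce_subnetwork <- function(net, keep_nodes) {
  stopifnot(inherits(net, "directed_network"))
  unknown <- setdiff(keep_nodes, net$nodes)
  if (length(unknown))
    stop_method("cannot induce subnetwork: unknown node(s) %s",
                paste(unknown, collapse = ", "))
  nodes <- net$nodes[net$nodes %in% keep_nodes]
  sel <- net$edges[, 1L] %in% nodes & net$edges[, 2L] %in% nodes
  em <- net$edges[sel, , drop = FALSE]
  directed_network(nodes, if (nrow(em)) em else NULL,
                   reserved = net$reserved)
}
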