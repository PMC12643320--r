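#' Stimulus graphs for graph serial reaction time tasks
#'
#' The task presents a sequence of stimuli generated by a random walk on a
#' 15-node, 4-regular undirected graph from one of three families: a modular
#' graph (3 clusters of 5 nodes joined in a ring), a ring lattice, or a
#' uniformly sampled connected 4-regular random graph. Matched degree across
#' families means one-step transition probabilities are identical (all 1/4),
#' so any behavioral difference between edge types must reflect multi-step
#' structure.
#'
#' @param n_nodes integer number of nodes; the constructors below fix it
#'   at 15.
#' @param adjacency symmetric binary adjacency matrix with zero diagonal.
#' @param cluster_of optional integer vector of cluster labels per node
#'   (modular graph only).
#' @return An object of class `sr_graph`: a list with elements `n_nodes`,
#'   `adjacency`, `cluster_of` and `family`.
#' @name sr_graph
NULL

new_sr_graph <- function(adjacency, cluster_of = NULL, family = "custom") {
  n <- nrow(adjacency)
  g <- structure(
    list(n_nodes = n, adjacency = adjacency, cluster_of = cluster_of,
         family = family),
    class = "sr_graph")
  validate_sr_graph(g)
}

validate_sr_graph <- function(g) {
  A <- g$adjacency
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  if (!all(A %in% c(0, 1))) stop("adjacency must be binary")
  if (!isTRUE(all.equal(A, t(A)))) stop("adjacency must be symmetric")
  if (any(diag(A) != 0)) stop("self-loops are not allowed")
  if (!is_connected_adjacency(A)) stop("graph must be connected")
  if (!is.null(g$cluster_of) && length(g$cluster_of) != g$n_nodes)
    stop("cluster_of must have one label per node")
  g
}

is_connected_adjacency <- function(A) {
  n <- nrow(A)
  seen <- logical(n)
  stack <- 1L
  seen[1L] <- TRUE
  while (length(stack)) {
    v <- stack[[1L]]
    stack <- stack[-1L]
    nb <- which(A[v, ] > 0 & !seen)
    seen[nb] <- TRUE
    stack <- c(stack, nb)
  }
  all(seen)
}

#' @export
print.sr_graph <- function(x, ...) {
  cat(sprintf("<sr_graph> %s: %d nodes, %d edges, degrees %s\n",
              x$family, x$n_nodes, sum(x$adjacency) / 2,
              paste(unique(rowSums(x$adjacency)), collapse = "/")))
  if (!is.null(x$cluster_of))
    cat("  clusters:", paste(table(x$cluster_of), collapse = "+"), "\n")
  invisible(x)
}

#' Construct the modular graph (3 clusters of 5 nodes)
#'
#' Each cluster is a 5-clique minus the edge between its two boundary nodes;
#' each boundary node carries exactly one cross-cluster edge to a boundary
#' node of the adjacent cluster, so the clusters form a ring and every node
#' has degree 4. Cross-cluster transitions therefore have the same one-step
#' probability (1/4) as within-cluster ones, while multi-step (SR)
#' predictions differ.
#'
#' @return An [sr_graph] with `cluster_of` labels 1..3.
#' @export
make_modular_graph <- function() {
  n <- 15L
  A <- matrix(0L, n, n)
  cluster_of <- rep(1:3, each = 5L)
  for (c in 0:2) {
    nodes <- 5L * c + 1:5
    A[nodes, nodes] <- 1L
    diag(A)[nodes] <- 0L
    # boundary nodes (first and last of the cluster) are not connected
    A[nodes[1L], nodes[5L]] <- A[nodes[5L], nodes[1L]] <- 0L
  }
  # ring of clusters via boundary-boundary edges
  A[5L, 6L] <- A[6L, 5L] <- 1L
  A[10L, 11L] <- A[11L, 10L] <- 1L
  A[15L, 1L] <- A[1L, 15L] <- 1L
  new_sr_graph(A, cluster_of = cluster_of, family = "modular")
}

#' Construct the ring lattice graph
#'
#' 15 nodes on a ring, each connected to its neighbors at circular distance
#' 1 and 2 (4-regular, vertex-transitive).
#'
#' @return An [sr_graph].
#' @export
make_lattice_graph <- function() {
  n <- 15L
  A <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    for (d in c(1L, 2L)) {
      j <- (i - 1L + d) %% n + 1L
      A[i, j] <- A[j, i] <- 1L
    }
  }
  new_sr_graph(A, family = "lattice")
}

#' Sample a connected 4-regular random graph
#'
#' Draws simple 4-regular graphs on 15 nodes (via [igraph::sample_k_regular])
#' and rejects until a connected one is found. Deterministic given `seed`.
#'
#' @param seed integer seed.
#' @param max_attempts rejection budget before signaling a sampler defect.
#' @return An [sr_graph].
#' @export
make_random_graph <- function(seed, max_attempts = 200L) {
  with_seed(seed, {
    for (i in seq_len(max_attempts)) {
      ig <- igraph::sample_k_regular(15L, 4L)
      if (igraph::is_connected(ig)) {
        A <- as.matrix(igraph::as_adjacency_matrix(ig, sparse = FALSE))
        storage.mode(A) <- "integer"
        dimnames(A) <- NULL
        return(new_sr_graph(A, family = "random"))
      }
    }
    stop("failed to sample a connected 4-regular graph after ",
         max_attempts, " attempts")
  })
}

#' Generate a random-walk stimulus sequence
#'
#' The start node is uniform over all nodes (the stationary distribution of
#' any regular graph); each subsequent node is uniform over the neighbors of
#' its predecessor.
#'
#' @param graph an [sr_graph].
#' @param n_trials walk length (>= 1).
#' @param seed integer seed; the walk is deterministic given it.
#' @param stage stage label (1 or 2) carried on the walk.
#' @return An object of class `sr_walk`: list with `nodes` (1-based),
#'   `graph`, `stage`, `rng_seed`.
#' @export
random_walk <- function(graph, n_trials, seed, stage = 1L) {
  stopifnot(inherits(graph, "sr_graph"), n_trials >= 1)
  nbrs <- apply(graph$adjacency > 0, 1L, which, simplify = FALSE)
  nodes <- with_seed(seed, {
    out <- integer(n_trials)
    out[1L] <- sample.int(graph$n_nodes, 1L)
    for (t in seq_len(n_trials - 1L)) {
      nb <- nbrs[[out[t]]]
      out[t + 1L] <- nb[sample.int(length(nb), 1L)]
    }
    out
  })
  structure(list(nodes = nodes, graph = graph, stage = as.integer(stage),
                 rng_seed = as.integer(seed)),
            class = "sr_walk")
}

#' @export
print.sr_walk <- function(x, ...) {
  cat(sprintf("<sr_walk> %d trials on %s graph (stage %d, seed %d)\n",
              length(x$nodes), x$graph$family, x$stage, x$rng_seed))
  invisible(x)
}

#' True one-step transition matrix of a graph
#'
#' Row i is the adjacency row divided by the degree of i: the kernel of the
#' random walk used to generate stimulus sequences.
#'
#' @param graph an [sr_graph].
#' @return Row-stochastic n x n matrix.
#' @export
transition_matrix <- function(graph) {
  deg <- rowSums(graph$adjacency)
  if (any(deg == 0)) stop("graph has a zero-degree node")
  graph$adjacency / deg
}

#' Empirical transition matrix of a walk
#'
#' Entry (i, j) is the observed count of i -> j transitions divided by the
#' count of transitions out of i. A node that never occurs as a predecessor
#' gets a uniform row (with a warning), so the result is always
#' row-stochastic.
#'
#' @param walk an [sr_walk], or a plain integer node sequence (1-based).
#' @param n_nodes number of nodes (taken from the walk's graph if present).
#' @return Row-stochastic n x n matrix.
#' @export
empirical_transition_matrix <- function(walk, n_nodes = NULL) {
  nodes <- if (inherits(walk, "sr_walk")) walk$nodes else as.integer(walk)
  n <- n_nodes %||% (if (inherits(walk, "sr_walk")) walk$graph$n_nodes
                     else max(nodes))
  Tn <- matrix(0, n, n)
  if (length(nodes) >= 2L) {
    from <- nodes[-length(nodes)]
    to <- nodes[-1L]
    for (k in seq_along(from)) Tn[from[k], to[k]] <- Tn[from[k], to[k]] + 1
  }
  out <- rowSums(Tn)
  never <- out == 0
  if (any(never)) {
    warning(sum(never), " node(s) never occurred as a predecessor; ",
            "their rows are set uniform")
    Tn[never, ] <- 1 / n
    out[never] <- 1
  }
  Tn / out
}

#' Write / read a graph as an edge-list TSV
#'
#' Plain `u<TAB>v` edge list (1-based, each undirected edge once, u < v) with
#' an optional JSON sidecar holding cluster labels.
#'
#' @param graph an [sr_graph].
#' @param path output TSV path; the sidecar (if any) is `<path>.json`.
#' @return `write_graph_tsv` returns `path` invisibly; `read_graph_tsv`
#'   returns an [sr_graph].
#' @export
write_graph_tsv <- function(graph, path) {
  idx <- which(graph$adjacency > 0 & upper.tri(graph$adjacency), arr.ind = TRUE)
  el <- data.frame(u = idx[, 1L], v = idx[, 2L])
  el <- el[order(el$u, el$v), ]
  utils::write.table(el, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(graph$cluster_of)) {
    jsonlite::write_json(
      list(family = graph$family, cluster_of = graph$cluster_of),
      paste0(path, ".json"), auto_unbox = TRUE)
  }
  invisible(path)
}

#' @rdname write_graph_tsv
#' @export
read_graph_tsv <- function(path) {
  el <- utils::read.table(path, sep = "\t", col.names = c("u", "v"))
  n <- max(el$u, el$v)
  A <- matrix(0L, n, n)
  for (k in seq_len(nrow(el))) {
    A[el$u[k], el$v[k]] <- 1L
    A[el$v[k], el$u[k]] <- 1L
  }
  cl <- NULL
  fam <- "custom"
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    cl <- meta$cluster_of
    fam <- meta$family %||% "custom"
  }
  new_sr_graph(A, cluster_of = cl, family = fam)
}
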