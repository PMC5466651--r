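# Seeded random network generator. Stands in for external network simulators
# in property tests: a random rooted binary tree on the requested taxa plus
# uniformly chosen acyclicity-preserving reticulation edges.

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a seeded random rooted phylogenetic network
#'
#' Builds a random rooted binary tree on taxa `1..n_leaves` by repeatedly
#' joining two uniformly chosen subtree roots, then adds `n_reticulations`
#' extra edges chosen uniformly among pairs (u, v) with `depth(u) < depth(v)`,
#' `u` internal, and no existing u->v edge — a choice that keeps the graph
#' acyclic and single-rooted. Optionally inserts pass-through nodes
#' (in-degree 1, out-degree 1) on random edges, the inputs the reduction step
#' must suppress.
#'
#' @param n_leaves number of taxa (>= 1).
#' @param n_reticulations number of extra cross edges (>= 0).
#' @param seed integer seed; the same configuration yields a bit-identical
#'   network. `NULL` uses (and advances) the session RNG.
#' @param max_extra_depth insert `0..max_extra_depth` pass-through nodes
#'   (count drawn uniformly) on randomly chosen edges. Default 0.
#' @param name optional network name.
#' @return a validated [phylo_network].
#' @examples
#' net <- random_network(5, n_reticulations = 1, seed = 42)
#' net
#' @export
random_network <- function(n_leaves, n_reticulations = 0, seed = NULL,
                           max_extra_depth = 0, name = NULL) {
  if (n_leaves < 1) stop_usage("n_leaves must be >= 1")
  if (n_reticulations < 0) stop_usage("n_reticulations must be >= 0")
  with_seed(seed, {
    leaves <- paste0("t", seq_len(n_leaves))
    labels <- stats::setNames(as.character(seq_len(n_leaves)), leaves)
    edges <- matrix(character(0), ncol = 2)
    active <- leaves
    vi <- 0L
    while (length(active) > 1) {
      pick <- sample.int(length(active), 2)
      vi <- vi + 1L
      v <- paste0("v", vi)
      edges <- rbind(edges, c(v, active[pick[1]]), c(v, active[pick[2]]))
      active <- c(active[-pick], v)
    }
    nodes <- unique(c(leaves, as.vector(t(edges))))

    for (r in seq_len(n_reticulations)) {
      depth <- edge_depths(nodes, edges)
      outdeg <- tabulate_degree(edges[, 1], nodes)
      existing <- if (nrow(edges)) paste(edges[, 1], edges[, 2], sep = "\x1f")
                  else character(0)
      cand_from <- nodes[outdeg >= 1]
      cand <- list()
      for (u in cand_from) {
        vs <- nodes[depth[nodes] > depth[[u]]]
        vs <- vs[!(paste(u, vs, sep = "\x1f") %in% existing)]
        for (v in vs) cand[[length(cand) + 1L]] <- c(u, v)
      }
      if (length(cand) == 0)
        stop_generation(sprintf(
          "no legal reticulation edge available (placed %d of %d)",
          r - 1L, n_reticulations))
      pick <- cand[[sample.int(length(cand), 1)]]
      edges <- rbind(edges, pick)
    }

    if (max_extra_depth > 0 && nrow(edges) > 0) {
      extra <- sample.int(max_extra_depth + 1L, 1) - 1L
      ui <- 0L
      for (j in seq_len(extra)) {
        ei <- sample.int(nrow(edges), 1)
        p <- edges[ei, 1]; c <- edges[ei, 2]
        ui <- ui + 1L
        w <- paste0("u", ui)
        edges <- rbind(edges[-ei, , drop = FALSE], c(p, w), c(w, c))
        nodes <- c(nodes, w)
      }
    }
    phylo_network(edges, labels, nodes = nodes, name = name)
  })
}

# longest-path depths from the (unique) in-degree-0 node, on raw edge data
edge_depths <- function(nodes, edges) {
  ord <- topological_order(nodes, edges)
  parents <- split_edges(edges, nodes, by = "child")
  depth <- stats::setNames(integer(length(nodes)), nodes)
  for (v in ord) {
    pa <- parents[[v]]
    if (length(pa) > 0) depth[[v]] <- 1L + max(depth[pa])
  }
  depth
}
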