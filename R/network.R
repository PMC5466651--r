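#' Construct and validate a rooted phylogenetic network
#'
#' A rooted phylogenetic network is a directed acyclic graph with a single
#' root (the unique in-degree-0 node) in which every node is reachable from
#' the root and the out-degree-0 nodes (leaves) are bijectively labelled by a
#' taxon set. Nodes of in-degree 1 and out-degree 1 are permitted on input
#' (the reduction step removes them); parallel edges are not.
#'
#' @param edges two-column character matrix or data.frame of directed edges
#'   (parent, child). May have zero rows for a one-node network.
#' @param leaf_labels named character vector mapping leaf node ids to taxon
#'   names.
#' @param nodes optional character vector of node ids; defaults to the ids
#'   appearing in `edges` and `leaf_labels`. Supplying extra ids triggers a
#'   disconnected-node error, which is the point of the argument.
#' @param name optional display name.
#'
#' @return An object of class `phylo_network` with components `nodes`,
#'   `edges` (2-column character matrix), `labels` (named character vector)
#'   and `name`.
#'
#' @examples
#' net <- phylo_network(rbind(c("r", "a"), c("r", "b")),
#'                      c(a = "1", b = "2"))
#' net
#' @export
phylo_network <- function(edges, leaf_labels, nodes = NULL, name = NULL) {
  edges <- as_edge_matrix(edges)
  leaf_labels <- as_label_vector(leaf_labels)
  if (is.null(nodes)) {
    nodes <- unique(c(as.vector(t(edges)), names(leaf_labels)))
  } else {
    nodes <- as.character(nodes)
  }
  nodes <- sort(unique(nodes), method = "radix")
  net <- structure(
    list(nodes = nodes, edges = edges, labels = leaf_labels, name = name),
    class = "phylo_network"
  )
  validate_network(net)
}

as_edge_matrix <- function(edges) {
  if (is.null(edges) || (is.matrix(edges) && nrow(edges) == 0) ||
      (is.data.frame(edges) && nrow(edges) == 0) || length(edges) == 0) {
    return(matrix(character(0), ncol = 2,
                  dimnames = list(NULL, c("parent", "child"))))
  }
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  if (is.vector(edges) && length(edges) == 2) edges <- matrix(edges, ncol = 2)
  storage.mode(edges) <- "character"
  if (ncol(edges) != 2) stop_parse("edge table must have two columns")
  colnames(edges) <- c("parent", "child")
  edges
}

as_label_vector <- function(leaf_labels) {
  if (length(leaf_labels) == 0) return(structure(character(0), names = character(0)))
  lab <- as.character(leaf_labels)
  names(lab) <- names(leaf_labels)
  if (is.null(names(lab)) || any(names(lab) == ""))
    stop_label("leaf labels must be a named vector (node id -> taxon)")
  lab
}

#' Validate a phylogenetic network object
#'
#' Checks every structural invariant: acyclicity, a single root, full
#' reachability from the root, no parallel edges, and the label bijection
#' (every leaf labelled, no internal node labelled, labels pairwise
#' distinct).
#'
#' @param net object of class `phylo_network` (or a bare list with the same
#'   fields).
#' @return `net`, invisibly classed, if valid; otherwise signals a condition
#'   of class `pkd_cycle_error`, `pkd_multiroot_error`, `pkd_label_error` or
#'   `pkd_disconnected_error`.
#' @export
validate_network <- function(net) {
  nodes <- net$nodes
  edges <- net$edges
  labels <- net$labels
  if (length(nodes) == 0) stop_disconnected("network has no nodes")
  if (anyDuplicated(nodes)) stop_parse("duplicate node ids")
  mentioned <- unique(c(as.vector(t(edges)), names(labels)))
  if (!all(mentioned %in% nodes))
    stop_parse(paste("edge or label refers to unknown node:",
                     paste(setdiff(mentioned, nodes), collapse = ", ")))
  if (nrow(edges) > 0) {
    key <- paste(edges[, 1], edges[, 2], sep = "\x1f")
    if (anyDuplicated(key)) stop_parse("parallel edges are not allowed")
    if (any(edges[, 1] == edges[, 2])) stop_cycle("self-loop edge")
  }

  indeg <- tabulate_degree(edges[, 2], nodes)
  outdeg <- tabulate_degree(edges[, 1], nodes)

  ord <- topological_order(nodes, edges, indeg)
  if (is.null(ord)) stop_cycle("edge relation contains a directed cycle")

  # Root candidates: in-degree-0 nodes that start edges (or the single node of
  # a one-node network). An isolated extra node is a connectivity defect, not
  # a competing root.
  roots <- nodes[indeg == 0 & (outdeg > 0 | length(nodes) == 1)]
  if (length(roots) != 1)
    stop_multiroot(sprintf("network must have exactly one root, found %d (%s)",
                           length(roots), paste(roots, collapse = ", ")))

  # reachability from the root
  reach <- reachable_from(roots, nodes, edges)
  if (!all(nodes %in% reach))
    stop_disconnected(paste("nodes unreachable from the root:",
                            paste(setdiff(nodes, reach), collapse = ", ")))

  leaves <- nodes[outdeg == 0]
  unlabelled <- setdiff(leaves, names(labels))
  if (length(unlabelled) > 0)
    stop_label(paste("unlabelled leaves:", paste(unlabelled, collapse = ", ")))
  internal_labelled <- setdiff(names(labels), leaves)
  if (length(internal_labelled) > 0)
    stop_label(paste("labels on non-leaf nodes:",
                     paste(internal_labelled, collapse = ", ")))
  if (anyDuplicated(labels))
    stop_label(paste("duplicate taxon labels:",
                     paste(unique(labels[duplicated(labels)]), collapse = ", ")))
  class(net) <- "phylo_network"
  net
}

tabulate_degree <- function(ends, nodes) {
  if (length(ends) == 0) return(stats::setNames(integer(length(nodes)), nodes))
  tab <- table(factor(ends, levels = nodes))
  stats::setNames(as.integer(tab), nodes)
}

topological_order <- function(nodes, edges, indeg = NULL) {
  if (is.null(indeg)) indeg <- tabulate_degree(edges[, 2], nodes)
  children <- split_edges(edges, nodes, by = "parent")
  queue <- nodes[indeg == 0]
  out <- character(0)
  deg <- indeg
  while (length(queue) > 0) {
    v <- queue[[1]]; queue <- queue[-1]
    out <- c(out, v)
    for (c in children[[v]]) {
      deg[[c]] <- deg[[c]] - 1L
      if (deg[[c]] == 0L) queue <- c(queue, c)
    }
  }
  if (length(out) != length(nodes)) NULL else out
}

split_edges <- function(edges, nodes, by = c("parent", "child")) {
  by <- match.arg(by)
  res <- stats::setNames(vector("list", length(nodes)), nodes)
  for (i in seq_along(res)) res[[i]] <- character(0)
  if (nrow(edges) > 0) {
    from <- if (by == "parent") edges[, 1] else edges[, 2]
    to <- if (by == "parent") edges[, 2] else edges[, 1]
    sp <- split(to, factor(from, levels = nodes))
    for (n in names(sp)) res[[n]] <- as.character(sp[[n]])
  }
  res
}

reachable_from <- function(start, nodes, edges) {
  children <- split_edges(edges, nodes, by = "parent")
  seen <- stats::setNames(logical(length(nodes)), nodes)
  stack <- start
  while (length(stack) > 0) {
    v <- stack[[length(stack)]]; stack <- stack[-length(stack)]
    if (seen[[v]]) next
    seen[[v]] <- TRUE
    stack <- c(stack, children[[v]][!seen[children[[v]]]])
  }
  nodes[seen]
}

#' Structural index of a network
#'
#' Computes, by longest-path dynamic programming over a topological order,
#' the height of every node (length of a longest directed path to a leaf) and
#' its depth (length of a longest directed path from the root), together with
#' parent/child adjacency and the degree-based node categories: in-degree 0
#' is the root, in-degree <= 1 a tree node, in-degree >= 2 a reticulate node,
#' out-degree 0 a leaf, out-degree >= 1 an internal node. The categories are
#' not mutually exclusive (a reticulate node may be a leaf).
#'
#' @param net validated `phylo_network`.
#' @return list with named components `children`, `parents` (lists of child /
#'   parent id vectors), `height`, `depth` (named integers), `indeg`,
#'   `outdeg`, `root`, `leaves`, and `category` (named list of category
#'   character vectors per node).
#' @export
network_index <- function(net) {
  nodes <- net$nodes
  edges <- net$edges
  children <- split_edges(edges, nodes, by = "parent")
  parents <- split_edges(edges, nodes, by = "child")
  indeg <- lengths(parents)
  outdeg <- lengths(children)
  ord <- topological_order(nodes, edges)

  height <- stats::setNames(integer(length(nodes)), nodes)
  for (v in rev(ord)) {
    ch <- children[[v]]
    if (length(ch) > 0) height[[v]] <- 1L + max(height[ch])
  }
  depth <- stats::setNames(integer(length(nodes)), nodes)
  for (v in ord) {
    pa <- parents[[v]]
    if (length(pa) > 0) depth[[v]] <- 1L + max(depth[pa])
  }

  category <- lapply(nodes, function(v) {
    cats <- character(0)
    if (indeg[[v]] == 0) cats <- c(cats, "root")
    if (indeg[[v]] <= 1) cats <- c(cats, "tree")
    if (indeg[[v]] >= 2) cats <- c(cats, "reticulate")
    if (outdeg[[v]] == 0) cats <- c(cats, "leaf")
    if (outdeg[[v]] >= 1) cats <- c(cats, "internal")
    cats
  })
  names(category) <- nodes

  list(children = children, parents = parents,
       height = height, depth = depth,
       indeg = indeg, outdeg = outdeg,
       root = nodes[indeg == 0], leaves = nodes[outdeg == 0],
       topo = ord, category = category)
}

#' @export
print.phylo_network <- function(x, ...) {
  idx <- network_index(x)
  cat(sprintf("Rooted phylogenetic network%s\n",
              if (!is.null(x$name)) paste0(" '", x$name, "'") else ""))
  cat(sprintf("  %d nodes, %d edges, %d leaves, %d reticulate node(s)\n",
              length(x$nodes), nrow(x$edges), length(idx$leaves),
              sum(idx$indeg >= 2)))
  cat(sprintf("  taxa: {%s}\n",
              paste(sort(unname(x$labels), method = "radix"), collapse = ", ")))
  invisible(x)
}

#' Number of nodes of a network
#' @param net a `phylo_network`.
#' @return integer node count.
#' @export
n_nodes <- function(net) length(net$nodes)

#' Taxon set of a network
#' @param net a `phylo_network`.
#' @return sorted character vector of taxon labels.
#' @export
taxa <- function(net) sort(unname(net$labels), method = "radix")

#' Rename the nodes of a network
#'
#' Applies a bijection to node ids, keeping the topology and the taxon
#' labels. Useful for testing isomorphism invariance.
#'
#' @param net a `phylo_network`.
#' @param map named character vector, `map[old id] = new id`; ids absent from
#'   `map` are kept.
#' @return the renamed `phylo_network`.
#' @export
rename_nodes <- function(net, map) {
  tr <- function(x) ifelse(x %in% names(map), unname(map[x]), x)
  edges <- net$edges
  if (nrow(edges) > 0) {
    edges <- cbind(parent = tr(edges[, 1]), child = tr(edges[, 2]))
  }
  labels <- net$labels
  names(labels) <- tr(names(labels))
  phylo_network(edges, labels, nodes = tr(net$nodes), name = net$name)
}
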