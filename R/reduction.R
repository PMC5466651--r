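# kth-order reduction: a network is kth-order reduced iff every node is
# kth-order equivalent only with itself and no node has in-degree 1 and
# out-degree 1. reduce_network() drives an arbitrary input to that fixpoint.

#' Is a network kth-order reduced?
#'
#' True iff the order-k partition of the network (single-network scope) is
#' discrete — every node equivalent only with itself — and the network has no
#' node of in-degree 1 and out-degree 1. Because order k+1 refines order k, a
#' network reduced at order k is reduced at every higher order.
#'
#' @param net a validated [phylo_network].
#' @param k order, positive integer.
#' @return logical.
#' @export
is_kth_order_reduced <- function(net, k) {
  k <- check_order(k)
  idx <- network_index(net)
  if (any(idx$indeg == 1 & idx$outdeg == 1)) return(FALSE)
  chain <- equivalence_chain(disjoint_union(net), k)
  is_discrete(chain[[k]])
}

#' Suppress in-degree-1/out-degree-1 nodes
#'
#' Repeatedly removes every node with exactly one parent and one child,
#' connecting the parent to the child; a contraction that would duplicate an
#' existing edge collapses onto it. Runs to a fixpoint (contractions can
#' create new unary nodes).
#'
#' @param net a validated [phylo_network].
#' @return the suppressed [phylo_network].
#' @export
suppress_unary <- function(net) {
  suppress_unary_tracked(net)$net
}

suppress_unary_tracked <- function(net) {
  edges <- net$edges
  nodes <- net$nodes
  removed <- character(0)
  repeat {
    indeg <- tabulate_degree(edges[, 2], nodes)
    outdeg <- tabulate_degree(edges[, 1], nodes)
    unary <- nodes[indeg == 1 & outdeg == 1]
    if (length(unary) == 0) break
    v <- sort(unary, method = "radix")[[1]]
    p <- edges[edges[, 2] == v, 1]
    c <- edges[edges[, 1] == v, 2]
    edges <- edges[edges[, 1] != v & edges[, 2] != v, , drop = FALSE]
    if (!any(edges[, 1] == p & edges[, 2] == c))
      edges <- rbind(edges, c(p, c))
    nodes <- setdiff(nodes, v)
    removed <- c(removed, v)
  }
  net2 <- phylo_network(edges, net$labels, nodes = nodes, name = net$name)
  list(net = net2, removed = removed)
}

#' Reduce a network at order k
#'
#' Iterates to a fixpoint: (1) compute the order-k partition of the current
#' network; (2) merge every non-singleton class onto one representative (the
#' lexicographically least node id), redirecting all incident edges and
#' collapsing duplicates; (3) suppress in-degree-1/out-degree-1 nodes. Nodes
#' of one class share a height, so no merge can create a cycle, and
#' within-network equivalent leaves would share a taxon label, which the
#' label bijection forbids — so leaves are never merged and the taxon set is
#' preserved.
#'
#' @param net a validated [phylo_network].
#' @param k order, positive integer.
#' @return an object of class `reduction_report` with fields `input_size`,
#'   `output` (the reduced [phylo_network]), `merged_classes` (list, per
#'   pass, of merged node-id sets), `suppressed` (list, per pass, of removed
#'   unary node ids), `passes` and `k`.
#' @export
reduce_network <- function(net, k) {
  k <- check_order(k)
  current <- net
  merged_classes <- list()
  suppressed <- list()
  passes <- 0L
  repeat {
    passes <- passes + 1L
    if (passes > length(net$nodes) + 1L)
      stop(pkd_error("pkd_reduction_diverged",
                     "reduction failed to reach a fixpoint")) # defensive
    changed <- FALSE

    chain <- equivalence_chain(disjoint_union(current), k)
    p <- unclass(chain[[k]])
    groups <- split(names(p), p)
    groups <- groups[lengths(groups) > 1]
    pass_merges <- list()
    if (length(groups) > 0) {
      changed <- TRUE
      rep_of <- stats::setNames(current$nodes, current$nodes)
      for (g in groups) {
        ids <- sort(current$nodes[match(g, node_key(1, current$nodes))],
                    method = "radix")
        rep_of[ids] <- ids[[1]]
        pass_merges[[length(pass_merges) + 1L]] <- ids
      }
      edges <- current$edges
      if (nrow(edges) > 0) {
        edges <- cbind(parent = unname(rep_of[edges[, 1]]),
                       child = unname(rep_of[edges[, 2]]))
        edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE] # defensive
        edges <- edges[!duplicated(paste(edges[, 1], edges[, 2], sep = "\x1f")),
                       , drop = FALSE]
      }
      keep <- unique(unname(rep_of))
      labels <- current$labels[names(current$labels) %in% keep]
      current <- phylo_network(edges, labels, nodes = keep, name = current$name)
    }
    merged_classes[[passes]] <- pass_merges

    sup <- suppress_unary_tracked(current)
    suppressed[[passes]] <- sup$removed
    if (length(sup$removed) > 0) changed <- TRUE
    current <- sup$net

    if (!changed) break
  }
  structure(
    list(input_size = length(net$nodes), output = current,
         merged_classes = merged_classes, suppressed = suppressed,
         passes = passes, k = k),
    class = "reduction_report"
  )
}

#' @export
print.reduction_report <- function(x, ...) {
  cat(sprintf("Order-%d reduction: %d -> %d nodes in %d pass(es)\n",
              x$k, x$input_size, length(x$output$nodes), x$passes))
  merged <- unlist(lapply(x$merged_classes, function(m)
    vapply(m, paste, "", collapse = ",")))
  if (length(merged) > 0)
    cat("  merged classes:", paste(sprintf("{%s}", merged), collapse = " "), "\n")
  sup <- unlist(x$suppressed)
  if (length(sup) > 0)
    cat("  suppressed unary nodes:", paste(sup, collapse = ", "), "\n")
  invisible(x)
}
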