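# kth-order node equivalence.
#
# The relation chain alternates direction: order 1 and every odd order look at
# children (anchored at taxon labels), every even order looks at parents
# (anchored at the root). Children/parent lists are unordered, so "there is a
# pairing u_i ~ v_i" is equality of the multisets of neighbour class ids,
# which is valid because each order is an equivalence relation. The fast path
# is signature-based partition refinement; naive_equivalent() is the direct
# recursive reading of the definitions, kept as an independent oracle.

node_key <- function(origin, id) paste0(origin, "\x1f", id)

#' Combine one or two networks into a node universe
#'
#' The universe is the disjoint union of the node sets: nodes are tagged with
#' their origin network and never merged, even when the two networks share
#' taxon labels. Cross-network label identity is consumed only by the order-1
#' base case of the equivalence relations.
#'
#' @param net1 a validated [phylo_network].
#' @param net2 optional second network; omit for single-network scope.
#' @return an object of class `network_universe`.
#' @export
disjoint_union <- function(net1, net2 = NULL) {
  nets <- if (is.null(net2)) list(net1) else list(net1, net2)
  keys <- character(0)
  origin <- integer(0); id <- character(0)
  children <- list(); parents <- list()
  height <- integer(0); depth <- integer(0)
  label <- character(0); is_root <- logical(0); is_leaf <- logical(0)

  for (o in seq_along(nets)) {
    net <- nets[[o]]
    idx <- network_index(net)
    k <- node_key(o, net$nodes)
    keys <- c(keys, k)
    origin <- c(origin, rep(o, length(k)))
    id <- c(id, net$nodes)
    children <- c(children, stats::setNames(
      lapply(net$nodes, function(v) node_key(o, idx$children[[v]])), k))
    parents <- c(parents, stats::setNames(
      lapply(net$nodes, function(v) node_key(o, idx$parents[[v]])), k))
    height <- c(height, stats::setNames(idx$height[net$nodes], k))
    depth <- c(depth, stats::setNames(idx$depth[net$nodes], k))
    lab <- rep(NA_character_, length(k))
    lv <- net$nodes %in% idx$leaves
    lab[lv] <- unname(net$labels[net$nodes[lv]])
    label <- c(label, stats::setNames(lab, k))
    is_root <- c(is_root, stats::setNames(net$nodes == idx$root, k))
    is_leaf <- c(is_leaf, stats::setNames(lv, k))
  }
  names(origin) <- keys; names(id) <- keys
  structure(
    list(nets = nets, keys = keys, origin = origin, id = id,
         children = children, parents = parents,
         height = height, depth = depth, label = label,
         is_root = is_root, is_leaf = is_leaf,
         scope = if (length(nets) == 1) "one-network" else "two-network"),
    class = "network_universe"
  )
}

new_partition <- function(class_of, order, scope) {
  structure(class_of, order = order, scope = scope, class = "node_partition")
}

#' @export
print.node_partition <- function(x, ...) {
  cat(sprintf("Order-%d node partition (%s scope): %d nodes, %d classes\n",
              attr(x, "order"), attr(x, "scope"), length(x),
              length(unique(unclass(x)))))
  invisible(x)
}

assign_classes <- function(u, process_order, sig_fun) {
  class_of <- stats::setNames(integer(length(u$keys)), u$keys)
  sigs <- new.env(parent = emptyenv(), hash = TRUE)
  next_id <- 0L
  for (key in process_order) {
    s <- sig_fun(key, class_of)
    hit <- sigs[[s]]
    if (is.null(hit)) {
      next_id <- next_id + 1L
      sigs[[s]] <- next_id
      hit <- next_id
    }
    class_of[[key]] <- hit
  }
  class_of
}

#' First-order equivalence partition
#'
#' Nodes are processed in increasing height. Leaves are grouped by taxon
#' label; an internal node's signature is the multiset of its children's
#' order-1 class ids.
#'
#' @param universe a [disjoint_union()] universe.
#' @return a `node_partition`: named integer vector of class ids over the
#'   tagged node keys, with attributes `order` and `scope`.
#' @export
partition_order1 <- function(universe) {
  u <- universe
  ord <- u$keys[order(u$height[u$keys], u$keys, method = "radix")]
  class_of <- assign_classes(u, ord, function(key, class_of) {
    if (u$is_leaf[[key]]) {
      paste0("L\x1f", u$label[[key]])
    } else {
      paste0("I\x1f", paste(sort(class_of[u$children[[key]]]), collapse = ","))
    }
  })
  new_partition(class_of, 1L, u$scope)
}

#' Refine a partition to the next order
#'
#' Even target orders compare parent class multisets, processing nodes in
#' increasing depth (the roots, which have no parents, anchor the recursion:
#' a root pairs only with a root). Odd target orders (>= 3) compare child
#' class multisets, processing in increasing height (leaves anchor via their
#' labels). Each signature includes the previous-order class, so every order
#' refines the one before it.
#'
#' @param prev `node_partition` of order k-1.
#' @param universe the universe `prev` was computed on.
#' @return a `node_partition` of order k.
#' @export
refine_step <- function(prev, universe) {
  u <- universe
  k <- attr(prev, "order") + 1L
  if (k %% 2L == 0L) {
    ord <- u$keys[order(u$depth[u$keys], u$keys, method = "radix")]
    class_of <- assign_classes(u, ord, function(key, class_of) {
      if (u$is_root[[key]]) {
        paste0(prev[[key]], "\x1fR")
      } else {
        paste0(prev[[key]], "\x1fP",
               paste(sort(class_of[u$parents[[key]]]), collapse = ","))
      }
    })
  } else {
    ord <- u$keys[order(u$height[u$keys], u$keys, method = "radix")]
    class_of <- assign_classes(u, ord, function(key, class_of) {
      if (u$is_leaf[[key]]) {
        paste0(prev[[key]], "\x1fL", u$label[[key]])
      } else {
        paste0(prev[[key]], "\x1fC",
               paste(sort(class_of[u$children[[key]]]), collapse = ","))
      }
    })
  }
  new_partition(class_of, k, u$scope)
}

is_discrete <- function(partition) !anyDuplicated(unclass(partition))

#' Equivalence chain of orders 1..k
#'
#' Runs [partition_order1()] followed by k-1 [refine_step()]s. Once a
#' partition is discrete (all singletons) the remaining orders reuse it,
#' since refinement can never coarsen.
#'
#' @param universe a [disjoint_union()] universe.
#' @param k maximum order, a positive integer.
#' @return list of `node_partition`s, element i having order i.
#' @export
equivalence_chain <- function(universe, k) {
  k <- check_order(k)
  chain <- vector("list", k)
  chain[[1]] <- partition_order1(universe)
  if (k == 1) return(chain)
  for (i in 2:k) {
    prev <- chain[[i - 1]]
    if (is_discrete(prev)) {
      p <- prev
      attr(p, "order") <- i
      chain[[i]] <- p
    } else {
      chain[[i]] <- refine_step(prev, universe)
    }
  }
  chain
}

check_order <- function(k) {
  if (length(k) != 1 || is.na(k) || k < 1 || k != as.integer(k))
    stop_usage("order k must be a positive integer (the chain starts at 1)")
  as.integer(k)
}

#' Are two nodes in the same class of a partition?
#'
#' @param partition a `node_partition`.
#' @param u,v node ids.
#' @param origin_u,origin_v origin network (1 or 2) of each node; both
#'   default to 1.
#' @return logical.
#' @export
same_class <- function(partition, u, v, origin_u = 1, origin_v = 1) {
  ku <- node_key(origin_u, u); kv <- node_key(origin_v, v)
  if (!ku %in% names(partition)) stop_usage(sprintf("unknown node '%s'", u))
  if (!kv %in% names(partition)) stop_usage(sprintf("unknown node '%s'", v))
  partition[[ku]] == partition[[kv]]
}

#' Partition chain as a table
#'
#' Long-format export of an equivalence chain, one row per node, one column
#' of class ids per order — the debugging TSV surface.
#'
#' @param chain result of [equivalence_chain()].
#' @param universe the universe the chain was computed on.
#' @return data.frame with columns `origin`, `node`, `order_1` .. `order_k`.
#' @export
partition_table <- function(chain, universe) {
  u <- universe
  out <- data.frame(origin = unname(u$origin[u$keys]),
                    node = unname(u$id[u$keys]),
                    stringsAsFactors = FALSE)
  for (i in seq_along(chain))
    out[[paste0("order_", i)]] <- unname(unclass(chain[[i]])[u$keys])
  out[order(out$origin, out$node, method = "radix"), , drop = FALSE]
}

# ---- naive oracle ----------------------------------------------------------

#' Naive recursive kth-order equivalence (test oracle)
#'
#' Direct memoized recursion on the definitions: degree check first, base
#' cases for labelled leaves (odd orders) and the root (even orders), then an
#' exhaustive search for a bijection between children (odd) or parents (even)
#' under which matched nodes are equivalent. Exponential in the worst case;
#' guarded by a size bound. This deliberately does not share code with the
#' partition-refinement path.
#'
#' @param universe a [disjoint_union()] universe.
#' @param u,v node ids.
#' @param k order, positive integer.
#' @param origin_u,origin_v origin network of `u` and `v` (default: 1, and 2
#'   when the universe holds two networks).
#' @param max_nodes refuse universes whose largest member network exceeds
#'   this node count (default 16).
#' @param memo optional environment reused across calls on the same universe.
#' @return logical: are `u` and `v` kth-order equivalent?
#' @export
naive_equivalent <- function(universe, u, v, k,
                             origin_u = 1,
                             origin_v = if (universe$scope == "two-network") 2 else 1,
                             max_nodes = 16,
                             memo = NULL) {
  k <- check_order(k)
  if (max(vapply(universe$nets, n_nodes, 0L)) > max_nodes)
    stop_size(sprintf("naive oracle limited to networks of <= %d nodes", max_nodes))
  if (is.null(memo)) memo <- new.env(parent = emptyenv(), hash = TRUE)
  ku <- node_key(origin_u, u); kv <- node_key(origin_v, v)
  if (!ku %in% universe$keys) stop_usage(sprintf("unknown node '%s'", u))
  if (!kv %in% universe$keys) stop_usage(sprintf("unknown node '%s'", v))
  naive_rec(universe, ku, kv, k, memo)
}

naive_rec <- function(u, ku, kv, k, memo) {
  mk <- paste0(ku, "\x1e", kv, "\x1e", k)
  hit <- memo[[mk]]
  if (!is.null(hit)) return(hit)
  res <- naive_compute(u, ku, kv, k, memo)
  memo[[mk]] <- res
  memo[[paste0(kv, "\x1e", ku, "\x1e", k)]] <- res
  res
}

naive_compute <- function(u, ku, kv, k, memo) {
  ch_u <- u$children[[ku]]; ch_v <- u$children[[kv]]
  pa_u <- u$parents[[ku]]; pa_v <- u$parents[[kv]]
  if (k == 1L) {
    if (u$is_leaf[[ku]] || u$is_leaf[[kv]]) {
      return(u$is_leaf[[ku]] && u$is_leaf[[kv]] &&
               u$label[[ku]] == u$label[[kv]])
    }
    if (length(ch_u) != length(ch_v)) return(FALSE)
    return(has_matching(u, ch_u, ch_v, 1L, memo))
  }
  if (!naive_rec(u, ku, kv, k - 1L, memo)) return(FALSE)
  if (k %% 2L == 0L) {
    if (u$is_root[[ku]] || u$is_root[[kv]])
      return(u$is_root[[ku]] && u$is_root[[kv]])
    if (length(pa_u) != length(pa_v)) return(FALSE)
    has_matching(u, pa_u, pa_v, k, memo)
  } else {
    if (u$is_leaf[[ku]] || u$is_leaf[[kv]]) {
      return(u$is_leaf[[ku]] && u$is_leaf[[kv]] &&
               u$label[[ku]] == u$label[[kv]])
    }
    if (length(ch_u) != length(ch_v)) return(FALSE)
    has_matching(u, ch_u, ch_v, k, memo)
  }
}

# exhaustive search for a perfect matching between as and bs such that
# matched nodes are kth-order equivalent
has_matching <- function(u, as, bs, k, memo) {
  l <- length(as)
  if (l == 0) return(TRUE) # not reachable through the definitions (l >= 1)
  ok <- matrix(FALSE, l, l)
  for (i in seq_len(l))
    for (j in seq_len(l))
      ok[i, j] <- naive_rec(u, as[[i]], bs[[j]], k, memo)
  try_match <- function(i, used) {
    if (i > l) return(TRUE)
    for (j in seq_len(l)) {
      if (!used[j] && ok[i, j]) {
        used[j] <- TRUE
        if (try_match(i + 1L, used)) return(TRUE)
        used[j] <- FALSE
      }
    }
    FALSE
  }
  try_match(1L, logical(l))
}
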