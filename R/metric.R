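# The kth-distance between two rooted phylogenetic networks:
#
#   d_k(N1, N2) = 1/(k (n1 + n2)) * sum_{i=1..k} S_i
#   S_i = sum_{v in L^i(N1)} max(0, e^i(v) - e^i(v'))
#       + sum_{u in L^i(N2)} max(0, e^i(u) - e^i(u'))
#
# where L^i(N) holds one representative per order-i class of N, e^i(v) is the
# within-network class size, and v' is the representative of the other
# network that is ith-order equivalent to v (e^i of a missing partner is 0).
# The partner is unique when it exists: cross-equivalence transfers within
# classes, so pairing is at most one-to-one. All sums are integers; the
# distance is kept as an exact rational alongside its float rendering.

#' Per-order class tables for a pair of networks
#'
#' Runs one joint equivalence chain over the disjoint union and tabulates,
#' per order i and per network, the unique representatives L^i, the
#' within-network class sizes e^i, and the pairing between representatives
#' that share a joint class. Representatives are the lexicographically least
#' node id of each class per network; the distance is invariant to this
#' choice, since only class sizes enter the formula.
#'
#' @param net1,net2 validated [phylo_network]s.
#' @param k maximum order, a positive integer.
#' @return list of `k` class tables; element i is a list with `order` and two
#'   data.frames `n1`, `n2` having columns `rep`, `e`, `partner`
#'   (representative id in the other network, or `NA`) and `e_partner`
#'   (0 when unpaired).
#' @export
class_tables <- function(net1, net2, k) {
  k <- check_order(k)
  uni <- disjoint_union(net1, net2)
  chain <- equivalence_chain(uni, k)
  lapply(seq_len(k), function(i) {
    p <- unclass(chain[[i]])
    groups <- split(names(p), p)
    per_class <- lapply(groups, function(g) {
      o <- uni$origin[g]
      ids1 <- sort(uni$id[g[o == 1]], method = "radix")
      ids2 <- sort(uni$id[g[o == 2]], method = "radix")
      list(rep1 = if (length(ids1)) ids1[[1]] else NA_character_, e1 = length(ids1),
           rep2 = if (length(ids2)) ids2[[1]] else NA_character_, e2 = length(ids2))
    })
    tab <- function(side) {
      own_rep <- if (side == 1) "rep1" else "rep2"
      own_e <- if (side == 1) "e1" else "e2"
      oth_rep <- if (side == 1) "rep2" else "rep1"
      oth_e <- if (side == 1) "e2" else "e1"
      rows <- Filter(function(cl) cl[[own_e]] > 0, per_class)
      df <- data.frame(
        rep = vapply(rows, `[[`, "", own_rep),
        e = vapply(rows, `[[`, 0L, own_e),
        partner = vapply(rows, `[[`, "", oth_rep),
        e_partner = vapply(rows, `[[`, 0L, oth_e),
        stringsAsFactors = FALSE
      )
      df <- df[order(df$rep, method = "radix"), , drop = FALSE]
      rownames(df) <- NULL
      df
    }
    list(order = i, n1 = tab(1), n2 = tab(2))
  })
}

order_sum <- function(table_i) {
  sum(pmax(0L, table_i$n1$e - table_i$n1$e_partner)) +
    sum(pmax(0L, table_i$n2$e - table_i$n2$e_partner))
}

#' The kth-distance between two networks
#'
#' Computes the normalized sum, over orders 1..k, of the one-sided class-size
#' discordances between the two networks. The value lies in \[0, 1\] and is a
#' metric on the space of kth-order reduced networks; the networks themselves
#' need not be reduced for the value to be defined. Order 1 reproduces the
#' m-distance construction and order 2 the d_e-distance construction.
#'
#' @param net1,net2 validated [phylo_network]s; taxon sets may differ.
#' @param k order, a positive integer.
#' @return an object of class `kth_distance`: list with `k`, `n1`, `n2`,
#'   `per_order_sum` (integer vector S_1..S_k), `numerator`/`denominator`
#'   (the exact reduced rational), `distance` (its float value) and `tables`
#'   (the [class_tables()] result).
#' @examples
#' a <- parse_enewick("((1,2),3);")
#' b <- parse_enewick("((1,3),2);")
#' kth_distance(a, b, 3)
#' @export
kth_distance <- function(net1, net2, k) {
  k <- check_order(k)
  tabs <- class_tables(net1, net2, k)
  s <- vapply(tabs, order_sum, 0)
  n1 <- n_nodes(net1); n2 <- n_nodes(net2)
  num <- sum(s)
  den <- k * (n1 + n2)
  g <- int_gcd(num, den)
  structure(
    list(k = k, n1 = n1, n2 = n2,
         per_order_sum = stats::setNames(as.integer(s), paste0("S", seq_len(k))),
         numerator = num / g, denominator = den / g,
         distance = num / den, tables = tabs),
    class = "kth_distance"
  )
}

int_gcd <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) { t <- a %% b; a <- b; b <- t }
  if (a == 0) 1 else a
}

#' Format a kth-distance as an exact fraction string
#' @param d a `kth_distance` object.
#' @return character like `"16/21"` (or `"0"`, `"1"`).
#' @export
distance_fraction <- function(d) {
  if (d$numerator == 0) return("0")
  if (d$numerator == d$denominator) return("1")
  sprintf("%d/%d", d$numerator, d$denominator)
}

#' @export
print.kth_distance <- function(x, ...) {
  cat(sprintf("kth-distance (k = %d) between networks of %d and %d nodes\n",
              x$k, x$n1, x$n2))
  cat(sprintf("  per-order sums: %s\n",
              paste(sprintf("S%d=%d", seq_len(x$k), x$per_order_sum),
                    collapse = ", ")))
  cat(sprintf("  d_%d = %s = %.6g\n", x$k, distance_fraction(x), x$distance))
  invisible(x)
}

#' JSON report of a kth-distance
#' @param d a `kth_distance` object.
#' @return single JSON string.
#' @export
distance_json <- function(d) {
  jsonlite::toJSON(
    list(k = d$k, n1 = d$n1, n2 = d$n2,
         per_order_sum = unname(as.list(d$per_order_sum)),
         distance_rational = distance_fraction(d),
         distance_float = d$distance),
    auto_unbox = TRUE, digits = NA
  )
}

# ---- brute-force isomorphism ----------------------------------------------

#' Brute-force network isomorphism (small instances)
#'
#' Backtracking search for a bijection between node sets that preserves edges
#' in both directions and taxon labels, pruned by height, depth, degree and
#' label invariants. Used to verify that distance zero coincides with
#' isomorphism on kth-order reduced networks.
#'
#' @param net1,net2 validated [phylo_network]s.
#' @param max_nodes refuse networks larger than this (default 16).
#' @return logical.
#' @export
brute_force_isomorphic <- function(net1, net2, max_nodes = 16) {
  if (max(n_nodes(net1), n_nodes(net2)) > max_nodes)
    stop_size(sprintf("isomorphism oracle limited to <= %d nodes", max_nodes))
  if (n_nodes(net1) != n_nodes(net2)) return(FALSE)
  if (nrow(net1$edges) != nrow(net2$edges)) return(FALSE)
  i1 <- network_index(net1); i2 <- network_index(net2)

  inv <- function(net, idx) {
    vapply(net$nodes, function(v) {
      paste(idx$height[[v]], idx$depth[[v]], idx$indeg[[v]], idx$outdeg[[v]],
            if (v %in% names(net$labels)) net$labels[[v]] else "",
            sep = "\x1f")
    }, "")
  }
  sig1 <- inv(net1, i1); sig2 <- inv(net2, i2)
  if (!identical(sort(unname(sig1), method = "radix"),
                 sort(unname(sig2), method = "radix"))) return(FALSE)

  cands <- lapply(net1$nodes, function(v) net2$nodes[sig2 == sig1[[v]]])
  names(cands) <- net1$nodes
  ord <- net1$nodes[order(lengths(cands), net1$nodes, method = "radix")]

  edge_set <- function(net) {
    e <- net$edges
    if (nrow(e) == 0) character(0) else paste(e[, 1], e[, 2], sep = "\x1f")
  }
  e1 <- edge_set(net1); e2 <- edge_set(net2)
  has1 <- function(a, b) paste(a, b, sep = "\x1f") %in% e1
  has2 <- function(a, b) paste(a, b, sep = "\x1f") %in% e2

  assign_map <- new.env(parent = emptyenv())
  used <- new.env(parent = emptyenv())

  search <- function(i) {
    if (i > length(ord)) return(TRUE)
    v <- ord[[i]]
    for (w in cands[[v]]) {
      if (!is.null(used[[w]])) next
      ok <- TRUE
      for (x in ord[seq_len(i - 1L)]) {
        fx <- assign_map[[x]]
        if (has1(v, x) != has2(w, fx) || has1(x, v) != has2(fx, w)) {
          ok <- FALSE; break
        }
      }
      if (ok) {
        assign_map[[v]] <- w; used[[w]] <- TRUE
        if (search(i + 1L)) return(TRUE)
        rm(list = v, envir = assign_map); rm(list = w, envir = used)
      }
    }
    FALSE
  }
  search(1L)
}
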