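# Shared fixtures and independent oracles. Oracles here must stay independent
# of the code paths they check: heights/depths by exhaustive path enumeration,
# and the distance recomputed from the naive definitional recursion only.

fixture_net <- function(name) load_fixture(name)$network

net_el <- function(text, name = NULL) parse_edgelist(text, name = name)

chain1 <- function(net, k) equivalence_chain(disjoint_union(net), k)

# a small feasible random network; keeps reticulation count achievable
rnet <- function(seed, leaves = NULL, retics = NULL, ...) {
  set.seed(seed * 7919L)
  if (is.null(leaves)) leaves <- sample(3:6, 1)
  if (is.null(retics)) retics <- sample(0:2, 1)
  random_network(leaves, retics, seed = seed, ...)
}

# a feasible small configuration (a 2-leaf cherry admits no reticulation)
small_cfg <- function() {
  leaves <- sample(2:4, 1)
  list(leaves = leaves, retics = if (leaves >= 3) sample(0:1, 1) else 0L)
}

# full partition-vs-oracle agreement over every node pair of a universe;
# returns TRUE or a string describing the first disagreement
oracle_agrees <- function(uni, chain, orders) {
  memo <- new.env(parent = emptyenv())
  keys <- uni$keys
  for (k in orders) {
    p <- unclass(chain[[k]])
    for (i in seq_along(keys)) {
      for (j in seq(i, length(keys))) {
        fast <- p[[keys[i]]] == p[[keys[j]]]
        slow <- naive_equivalent(uni, uni$id[[keys[i]]], uni$id[[keys[j]]], k,
                                 origin_u = uni$origin[[keys[i]]],
                                 origin_v = uni$origin[[keys[j]]],
                                 memo = memo)
        if (!identical(fast, slow))
          return(sprintf("k=%d %s~%s: refinement %s, oracle %s",
                         k, keys[i], keys[j], fast, slow))
      }
    }
  }
  TRUE
}

# exhaustive enumeration of all directed path lengths starting (or ending) at v
path_lengths_down <- function(children, v) {
  if (length(children[[v]]) == 0) return(0L)
  unlist(lapply(children[[v]], function(c) 1L + path_lengths_down(children, c)))
}
path_lengths_up <- function(parents, v) {
  if (length(parents[[v]]) == 0) return(0L)
  unlist(lapply(parents[[v]], function(p) 1L + path_lengths_up(parents, p)))
}

# distance recomputed from scratch with the naive oracle only (no shared code
# with class_tables/kth_distance beyond the universe container)
oracle_distance <- function(n1, n2, k) {
  uni <- disjoint_union(n1, n2)
  memo <- new.env(parent = emptyenv())
  nv <- function(u, v, ou, ov, i)
    naive_equivalent(uni, u, v, i, origin_u = ou, origin_v = ov, memo = memo)
  s <- integer(k)
  for (i in seq_len(k)) {
    side_sum <- function(own, oth, o_own, o_oth) {
      reps <- character(0)
      for (u in own) {
        if (!any(vapply(reps, function(r) nv(u, r, o_own, o_own, i), TRUE)))
          reps <- c(reps, u)
      }
      total <- 0L
      for (r in reps) {
        e <- sum(vapply(own, function(v) nv(r, v, o_own, o_own, i), TRUE))
        partner <- oth[vapply(oth, function(w) nv(r, w, o_own, o_oth, i), TRUE)]
        ep <- if (length(partner) == 0) 0L
              else sum(vapply(oth, function(v) nv(partner[[1]], v, o_oth, o_oth, i), TRUE))
        total <- total + max(0L, e - ep)
      }
      total
    }
    s[i] <- side_sum(n1$nodes, n2$nodes, 1, 2) + side_sum(n2$nodes, n1$nodes, 2, 1)
  }
  list(per_order_sum = s,
       numerator = sum(s), denominator = k * (n_nodes(n1) + n_nodes(n2)))
}

# exact rational comparison helpers (integer arithmetic, no floats)
frac_equal <- function(d, num, den) {
  d$numerator * den == num * d$denominator
}
triangle_holds_exactly <- function(dab, dbc, dac) {
  # a/b + c/d >= e/f  <=>  (a*d + c*b) * f >= e * b * d, all terms small ints
  lhs <- (dab$numerator * dbc$denominator + dbc$numerator * dab$denominator) *
    dac$denominator
  rhs <- dac$numerator * dab$denominator * dbc$denominator
  lhs >= rhs
}
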