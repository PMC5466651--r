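# kth-order equivalence: base cases, worked-example facts, chain properties,
# agreement between partition refinement and the naive definitional oracle.

test_that("order-1 base cases: labels anchor leaves within and across networks", {
  cherry <- net_el("edge r a\nedge r b\nleaf a 1\nleaf b 2")
  p <- partition_order1(disjoint_union(cherry))
  expect_false(same_class(p, "a", "b"))

  one1 <- phylo_network(NULL, c(x = "1"))
  one2 <- phylo_network(NULL, c(y = "1"))
  p <- partition_order1(disjoint_union(one1, one2))
  expect_true(same_class(p, "x", "y", 1, 2))
  one3 <- phylo_network(NULL, c(z = "2"))
  p <- partition_order1(disjoint_union(one1, one3))
  expect_false(same_class(p, "x", "z", 1, 2))
})

test_that("the single-node network satisfies both anchors (leaf at odd, root at even orders)", {
  one1 <- phylo_network(NULL, c(x = "1"))
  one2 <- phylo_network(NULL, c(y = "1"))
  chain <- equivalence_chain(disjoint_union(one1, one2), 4)
  for (k in 1:4) expect_true(same_class(chain[[k]], "x", "y", 1, 2))
})

test_that("worked-example equivalences hold in the first figure network", {
  n1 <- fixture_net("fig1_n1")
  chain <- chain1(n1, 4)
  # order 1: exactly the documented nontrivial pairs
  expect_true(same_class(chain[[1]], "C", "E"))
  expect_true(same_class(chain[[1]], "D", "F"))
  expect_true(same_class(chain[[1]], "H", "J"))
  expect_identical(length(unique(unclass(chain[[1]]))), n_nodes(n1) - 3L)
  # order 2: only H,J survive together
  expect_true(same_class(chain[[2]], "H", "J"))
  expect_false(same_class(chain[[2]], "C", "E"))
  expect_false(same_class(chain[[2]], "D", "F"))
  # order >= 3: discrete
  expect_true(!anyDuplicated(unclass(chain[[3]])))
  expect_true(!anyDuplicated(unclass(chain[[4]])))
})

test_that("a root-to-leaf path network is discrete at every order (height separation)", {
  path <- net_el("edge r a\nedge a b\nedge b c\nleaf c 1")
  chain <- chain1(path, 4)
  for (k in 1:4)
    expect_identical(length(unique(unclass(chain[[k]]))), 4L)
})

test_that("each order refines the previous one and classes are height/depth homogeneous", {
  for (s in 1:10) {
    uni <- disjoint_union(rnet(s), rnet(s + 50))
    chain <- equivalence_chain(uni, 5)
    for (k in 2:5) {
      pk <- unclass(chain[[k]]); pk1 <- unclass(chain[[k - 1]])
      # same class at order k implies same class at order k-1
      expect_true(all(tapply(pk1, pk, function(x) length(unique(x))) == 1L))
    }
    for (k in 1:5) {
      pk <- unclass(chain[[k]])
      expect_true(all(tapply(uni$height[names(pk)], pk,
                             function(x) length(unique(x))) == 1L))
      if (k >= 2)
        expect_true(all(tapply(uni$depth[names(pk)], pk,
                               function(x) length(unique(x))) == 1L))
      # a class never mixes leaves and non-leaves, nor two taxon labels
      expect_true(all(tapply(uni$is_leaf[names(pk)], pk,
                             function(x) length(unique(x))) == 1L))
      labs <- uni$label[names(pk)]
      expect_true(all(tapply(labs, pk, function(x)
        length(unique(x[!is.na(x)])) <= 1L)))
    }
  }
})

test_that("two copies of one network are equivalent node-by-node at every order", {
  for (s in c(4, 9)) {
    net <- rnet(s, leaves = 4, retics = 1)
    copy <- rename_nodes(net, stats::setNames(paste0("c_", net$nodes), net$nodes))
    chain <- equivalence_chain(disjoint_union(net, copy), 4)
    for (k in 1:4)
      for (v in net$nodes)
        expect_true(same_class(chain[[k]], v, paste0("c_", v), 1, 2))
  }
})

test_that("leaves, the root and height-1 nodes stay self-equivalent in the chain", {
  for (s in 1:6) {
    net <- rnet(s)
    idx <- network_index(net)
    chain <- chain1(net, 5)
    keep <- net$nodes[idx$height <= 1 | idx$indeg == 0]
    # self-equivalence is class membership of the node itself: always true;
    # the substantive claim is that these nodes never drop out of the chain,
    # i.e. every order assigns them a class
    for (k in 1:5)
      expect_true(all(paste0("1\x1f", keep) %in% names(chain[[k]])))
  }
})

test_that("non-equivalence persists: once separated, never rejoined", {
  for (s in 1:8) {
    uni <- disjoint_union(rnet(s), rnet(s + 31))
    chain <- equivalence_chain(uni, 5)
    for (k in 2:5) {
      pk <- unclass(chain[[k]]); pk1 <- unclass(chain[[k - 1]])
      sep_before <- outer(pk1, pk1, "!=")
      sep_after <- outer(pk, pk, "!=")
      expect_true(all(sep_after[sep_before]))
    }
  }
})

test_that("odd-order equivalence from shared children (common-neighbour structure)", {
  # three internal nodes with the same two (reticulate) leaf children: all
  # mutually equivalent at every order, because children and parents coincide
  net <- net_el(paste(
    "edge r p1", "edge r p2", "edge r p3",
    "edge p1 a", "edge p1 b", "edge p2 a", "edge p2 b", "edge p3 a", "edge p3 b",
    "leaf a 1", "leaf b 2", sep = "\n"))
  chain <- chain1(net, 5)
  for (k in 1:5) {
    expect_true(same_class(chain[[k]], "p1", "p2"))
    expect_true(same_class(chain[[k]], "p2", "p3"))
  }
})

test_that("even-order equivalence needs shared parents when parents are distinguishable", {
  # A and B share children {1,2}; A's parents are {X,Y}, B's are {X,W}, and
  # Y,W are distinguishable by their extra leaves: so A =1= B but not =2=
  net <- net_el(paste(
    "edge r X", "edge r Y", "edge r W",
    "edge X A", "edge X B", "edge Y A", "edge Y l3", "edge W B", "edge W l4",
    "edge A 1", "edge A 2", "edge B 1", "edge B 2",
    "leaf 1 1", "leaf 2 2", "leaf l3 3", "leaf l4 4", sep = "\n"))
  chain <- chain1(net, 3)
  expect_true(same_class(chain[[1]], "A", "B"))
  expect_false(same_class(chain[[2]], "A", "B"))
  expect_false(same_class(chain[[3]], "A", "B"))
  # the shared-parent variant keeps A and B together at every order
  fig7 <- fixture_net("fig7_n")
  chain <- chain1(fig7, 4)
  for (k in 1:4) expect_true(same_class(chain[[k]], "A", "B"))
})

test_that("cross-network equivalence transfers: u1~v1, u2~v2 gives u1~u2 iff v1~v2", {
  # checked on the naive oracle, which decides each pair independently and so
  # could in principle violate the transfer property the fast path builds in
  for (s in 1:10) {
    n1 <- rnet(s, leaves = 3, retics = sample(0:1, 1))
    n2 <- rnet(s + 77, leaves = 3, retics = sample(0:1, 1))
    uni <- disjoint_union(n1, n2)
    memo <- new.env(parent = emptyenv())
    nv <- function(u, v, ou, ov, k)
      naive_equivalent(uni, u, v, k, origin_u = ou, origin_v = ov, memo = memo)
    for (k in 1:3) {
      cross <- list()
      for (u in n1$nodes)
        for (v in n2$nodes)
          if (nv(u, v, 1, 2, k)) cross[[length(cross) + 1L]] <- c(u, v)
      if (length(cross) < 2) next
      for (a in seq_along(cross)) {
        for (b in seq_along(cross)) {
          u1 <- cross[[a]][1]; v1 <- cross[[a]][2]
          u2 <- cross[[b]][1]; v2 <- cross[[b]][2]
          expect_identical(nv(u1, u2, 1, 1, k), nv(v1, v2, 2, 2, k),
                           label = sprintf("transfer seed %d k=%d", s, k))
        }
      }
    }
  }
})

test_that("partition refinement agrees with the naive definitional oracle", {
  for (s in 1:40) {
    set.seed(s)
    c1 <- small_cfg(); c2 <- small_cfg()
    n1 <- random_network(c1$leaves, c1$retics, seed = s)
    n2 <- random_network(c2$leaves, c2$retics, seed = s + 1000)
    uni <- disjoint_union(n1, n2)
    chain <- equivalence_chain(uni, 5)
    expect_true(isTRUE(oracle_agrees(uni, chain, c(1, 2, 3, 5))),
                label = sprintf("oracle agreement, seed %d", s))
  }
})

test_that("naive oracle guards its size bound and k validation", {
  big <- random_network(12, 0, seed = 1)
  uni <- disjoint_union(big)
  expect_error(naive_equivalent(uni, "t1", "t2", 1, max_nodes = 10),
               class = "pkd_size_error")
  expect_error(equivalence_chain(uni, 0), class = "pkd_usage_error")
})
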