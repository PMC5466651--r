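# The kth-distance: worked examples, exact arithmetic, metric properties,
# and recomputation through the naive oracle.

test_that("the 13/15-node figure pair has distance 16/21 at k = 3", {
  n1 <- fixture_net("fig2_n1"); n2 <- fixture_net("fig2_n2")
  d <- kth_distance(n1, n2, 3)
  expect_identical(unname(d$per_order_sum), c(8L, 28L, 28L))
  expect_true(frac_equal(d, 16, 21))
  expect_identical(distance_fraction(d), "16/21")
})

test_that("the unequal-taxon-set figure pair also has distance 16/21 at k = 3", {
  n1 <- fixture_net("fig3_n1"); n2 <- fixture_net("fig3_n2")
  expect_false(setequal(taxa(n1), taxa(n2)))
  d <- kth_distance(n1, n2, 3)
  expect_identical(unname(d$per_order_sum), c(8L, 28L, 28L))
  expect_true(frac_equal(d, 16, 21))
})

test_that("the first figure pair is indistinguishable at orders 1 and 2", {
  n1 <- fixture_net("fig1_n1"); n2 <- fixture_net("fig1_n2")
  expect_true(frac_equal(kth_distance(n1, n2, 1), 0, 1))
  expect_true(frac_equal(kth_distance(n1, n2, 2), 0, 1))
  d3 <- kth_distance(n1, n2, 3)
  expect_identical(unname(d3$per_order_sum[1:2]), c(0L, 0L))
  expect_gt(d3$distance, 0)
})

test_that("distance to self is 0 and class tables balance", {
  for (s in c(2, 5, 8)) {
    net <- rnet(s)
    for (k in 1:3) {
      d <- kth_distance(net, net, k)
      expect_identical(d$numerator, 0)
      # identical inputs: every representative paired with equal counts
      for (t in d$tables) {
        expect_true(all(!is.na(t$n1$partner)))
        expect_identical(t$n1$e, t$n1$e_partner)
      }
    }
  }
})

test_that("count conservation: class sizes per network sum to the node count", {
  for (s in 1:15) {
    n1 <- rnet(s); n2 <- rnet(s + 500)
    tabs <- class_tables(n1, n2, 3)
    for (t in tabs) {
      expect_identical(sum(t$n1$e), n_nodes(n1))
      expect_identical(sum(t$n2$e), n_nodes(n2))
      # pairing is one-to-one where present
      pt <- t$n1$partner[!is.na(t$n1$partner)]
      expect_false(anyDuplicated(pt) > 0)
    }
  }
})

test_that("per-order discordance sums are non-decreasing and within [0, n1+n2]", {
  for (s in 1:15) {
    n1 <- rnet(s); n2 <- rnet(s + 250)
    d <- kth_distance(n1, n2, 4)
    s_i <- unname(d$per_order_sum)
    expect_true(all(diff(s_i) >= 0))
    expect_true(all(s_i >= 0 & s_i <= d$n1 + d$n2))
    expect_gte(d$distance, 0); expect_lte(d$distance, 1)
  }
})

test_that("symmetry holds exactly", {
  for (s in 1:10) {
    n1 <- rnet(s); n2 <- rnet(s + 123)
    for (k in 1:3) {
      a <- kth_distance(n1, n2, k); b <- kth_distance(n2, n1, k)
      expect_identical(a$numerator, b$numerator)
      expect_identical(a$denominator, b$denominator)
    }
  }
})

test_that("the distance is invariant to node renaming (representative choice)", {
  for (s in c(3, 7)) {
    n1 <- rnet(s); n2 <- rnet(s + 321)
    ren <- rename_nodes(n1, stats::setNames(paste0("zz", rev(seq_along(n1$nodes))),
                                            n1$nodes))
    a <- kth_distance(n1, n2, 3); b <- kth_distance(ren, n2, 3)
    expect_identical(a$per_order_sum, b$per_order_sum)
    expect_identical(a$numerator, b$numerator)
  }
})

test_that("kth_distance matches a from-scratch recomputation through the naive oracle", {
  for (s in 1:12) {
    set.seed(s)
    c1 <- small_cfg(); c2 <- small_cfg()
    n1 <- random_network(c1$leaves, c1$retics, seed = s)
    n2 <- random_network(c2$leaves, c2$retics, seed = s + 2000)
    k <- sample(1:3, 1)
    d <- kth_distance(n1, n2, k)
    o <- oracle_distance(n1, n2, k)
    expect_identical(unname(d$per_order_sum), o$per_order_sum,
                     label = sprintf("seed %d k=%d", s, k))
    expect_true(d$numerator * o$denominator == o$numerator * d$denominator)
  }
})

test_that("distance zero on reduced networks coincides with isomorphism", {
  hits <- 0L
  for (s in 1:25) {
    n1 <- reduce_network(rnet(s, leaves = 4), 2)$output
    n2 <- if (s %% 2 == 0) {
      rename_nodes(n1, stats::setNames(paste0("w", seq_along(n1$nodes)), n1$nodes))
    } else {
      reduce_network(rnet(s + 400, leaves = 4), 2)$output
    }
    d0 <- kth_distance(n1, n2, 2)$numerator == 0
    iso <- brute_force_isomorphic(n1, n2)
    expect_identical(d0, iso, label = sprintf("seed %d", s))
    if (d0) hits <- hits + 1L
  }
  expect_gte(hits, 10L) # the renamed copies guarantee both outcomes occur
})

test_that("distance zero forces equal sizes and fully paired equal counts (all orders)", {
  net <- rnet(6, leaves = 5, retics = 1)
  copy <- rename_nodes(net, stats::setNames(paste0("c", seq_along(net$nodes)),
                                            net$nodes))
  d <- kth_distance(net, copy, 3)
  expect_identical(d$numerator, 0)
  expect_identical(d$n1, d$n2)
  for (t in d$tables) {
    expect_true(all(!is.na(t$n1$partner)) && all(!is.na(t$n2$partner)))
    expect_identical(t$n1$e, t$n1$e_partner)
    expect_identical(t$n2$e, t$n2$e_partner)
  }
})

test_that("isomorphism oracle: renaming invariance, figure pair, size guard", {
  net <- rnet(5, leaves = 4, retics = 1)
  ren <- rename_nodes(net, stats::setNames(paste0("q", seq_along(net$nodes)),
                                           net$nodes))
  expect_true(brute_force_isomorphic(net, ren))
  expect_false(brute_force_isomorphic(fixture_net("fig1_n1"),
                                      fixture_net("fig1_n2")))
  expect_false(brute_force_isomorphic(
    net_el("edge r a\nedge r b\nleaf a 1\nleaf b 2"),
    net_el("edge r a\nedge r b\nleaf a 1\nleaf b 3")))
  expect_error(brute_force_isomorphic(random_network(12, 0, seed = 3),
                                      random_network(12, 0, seed = 4),
                                      max_nodes = 10),
               class = "pkd_size_error")
})

test_that("order k = 0 is rejected", {
  net <- rnet(1)
  expect_error(kth_distance(net, net, 0), class = "pkd_usage_error")
})
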