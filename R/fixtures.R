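# Figure fixtures. The published figures are not machine-readable, so the
# networks shipped under inst/extdata are synthetic reconstructions pinned by
# the checkable facts the accompanying text states about them; load_fixture()
# re-evaluates every fact on load and refuses a fixture that drifts.

fixture_names <- c("fig1_n1", "fig1_n2", "fig2_n1", "fig2_n2",
                   "fig3_n1", "fig3_n2", "fig7_n")

fixture_path <- function(name) {
  f <- system.file("extdata", paste0("synthetic-", name, ".edges"),
                   package = "knetdist")
  if (!nzchar(f)) stop_usage(sprintf("unknown fixture '%s'", name))
  f
}

read_fixture_network <- function(name) {
  read_network(fixture_path(name), name = name)
}

#' Load a figure fixture network with self-verification
#'
#' Returns one of the transcribed figure networks and re-checks, at load
#' time, every documented fact that pins the transcription (equivalence
#' pairs, node counts, taxon sets, named unpaired order-1 representatives,
#' non-isomorphism of figure pairs). A failing fact raises a
#' `pkd_fixture_error` naming it. The shipped topologies are synthetic
#' reconstructions: the facts, not the drawings, are the contract.
#'
#' @param name one of `fig1_n1`, `fig1_n2`, `fig2_n1`, `fig2_n2`, `fig3_n1`,
#'   `fig3_n2`, `fig7_n`.
#' @return object of class `network_fixture`: list with `name`, `network`,
#'   and `documented_facts` (character vector of the facts verified).
#' @export
load_fixture <- function(name) {
  if (!name %in% fixture_names)
    stop_usage(sprintf("unknown fixture '%s' (known: %s)", name,
                       paste(fixture_names, collapse = ", ")))
  net <- read_fixture_network(name)
  facts <- switch(substr(name, 1, 4),
                  fig1 = check_fig1_facts(),
                  fig2 = check_fig2_facts(),
                  fig3 = check_fig3_facts(),
                  fig7 = check_fig7_facts())
  structure(list(name = name, network = net, documented_facts = facts),
            class = "network_fixture")
}

#' @export
print.network_fixture <- function(x, ...) {
  cat(sprintf("Fixture '%s' (%d documented facts verified)\n",
              x$name, length(x$documented_facts)))
  print(x$network)
  invisible(x)
}

fact <- function(ok, description) {
  if (!isTRUE(ok))
    stop_fixture(sprintf("fixture fact failed: %s", description))
  description
}

unpaired_reps <- function(tab) sort(tab$rep[is.na(tab$partner)], method = "radix")

check_fig1_facts <- function() {
  n1 <- read_fixture_network("fig1_n1")
  n2 <- read_fixture_network("fig1_n2")
  chain <- equivalence_chain(disjoint_union(n1), 3)
  facts <- c(
    fact(same_class(chain[[1]], "C", "E"), "fig1_n1: C =1= E"),
    fact(same_class(chain[[1]], "D", "F"), "fig1_n1: D =1= F"),
    fact(same_class(chain[[1]], "H", "J"), "fig1_n1: H =1= J"),
    fact(same_class(chain[[2]], "H", "J"), "fig1_n1: H =2= J"),
    fact(!same_class(chain[[2]], "C", "E") && !same_class(chain[[2]], "D", "F"),
         "fig1_n1: only H,J remain equivalent at order 2"),
    fact(is_discrete(chain[[3]]),
         "fig1_n1: every order-3 class is a singleton")
  )
  chain2 <- equivalence_chain(disjoint_union(n2), 3)
  facts <- c(facts,
    fact(is_discrete(chain2[[3]]),
         "fig1_n2: every order-3 class is a singleton"),
    fact(!brute_force_isomorphic(n1, n2), "fig1 pair is not isomorphic")
  )
  facts
}

check_fig2_facts <- function() {
  n1 <- read_fixture_network("fig2_n1")
  n2 <- read_fixture_network("fig2_n2")
  tabs <- class_tables(n1, n2, 1)
  c(
    fact(n_nodes(n1) == 13, "fig2_n1 has 13 nodes"),
    fact(n_nodes(n2) == 15, "fig2_n2 has 15 nodes"),
    fact(identical(taxa(n1), as.character(1:6)), "fig2_n1 is on taxa {1..6}"),
    fact(identical(taxa(n2), as.character(1:6)), "fig2_n2 is on taxa {1..6}"),
    fact(identical(unpaired_reps(tabs[[1]]$n1), c("B", "F", "R")),
         "fig2: exactly R, B, F of the 13-node network lack an order-1 partner"),
    fact(identical(unpaired_reps(tabs[[1]]$n2), c("B", "E", "F", "K", "R")),
         "fig2: exactly R, B, E, F, K of the 15-node network lack an order-1 partner"),
    fact(all(tabs[[1]]$n1$e == 1) && all(tabs[[1]]$n2$e == 1),
         "fig2: all order-1 classes are singletons within each network")
  )
}

check_fig3_facts <- function() {
  n1 <- read_fixture_network("fig3_n1")
  n2 <- read_fixture_network("fig3_n2")
  tabs <- class_tables(n1, n2, 1)
  c(
    fact(identical(taxa(n1), as.character(1:5)), "fig3_n1 is on taxa {1..5}"),
    fact(identical(taxa(n2), as.character(1:6)), "fig3_n2 is on taxa {1..6}"),
    fact(n_nodes(n1) == 13 && n_nodes(n2) == 15, "fig3 pair has 13 and 15 nodes"),
    fact(identical(unpaired_reps(tabs[[1]]$n1), c("B", "F", "R")),
         "fig3: exactly R, B, F of the smaller network lack an order-1 partner"),
    fact(identical(unpaired_reps(tabs[[1]]$n2), c("6", "B", "F", "H", "R")),
         "fig3: exactly R, B, F, H and leaf 6 of the larger network lack an order-1 partner")
  )
}

check_fig7_facts <- function() {
  n <- read_fixture_network("fig7_n")
  chain <- equivalence_chain(disjoint_union(n), 4)
  facts <- character(0)
  for (k in 1:4) {
    facts <- c(facts, fact(same_class(chain[[k]], "A", "B"),
                           sprintf("fig7: A =%d= B", k)))
  }
  c(facts,
    fact(!is_kth_order_reduced(n, 4),
         "fig7: the network is not kth-order reduced"))
}
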