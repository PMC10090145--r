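contact_net <- function(t, pairs, horizon = NULL) {
  temporal_hypergraph(
    tibble::tibble(t = t, nodes = lapply(pairs, as.character)), horizon = horizon
  )
}

test_that("simultaneous contact triangles promote to one order-3 event", {
  net <- contact_net(c(0L, 0L, 0L), list(c("i", "j"), c("j", "k"), c("i", "k")))
  prom <- promote_cliques(net)
  ev <- hg_events(prom)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$order, 3L)
  expect_equal(ev$nodes, "i,j,k")
})

test_that("promotion keeps isolated contacts and splits overlapping structures", {
  one <- promote_cliques(contact_net(0L, list(c("a", "b"))))
  expect_equal(hg_events(one)$order, 2L)
  # triangle abc plus pendant edge cd: events {a,b,c} and {c,d}
  net <- contact_net(rep(0L, 4), list(c("a", "b"), c("b", "c"), c("a", "c"), c("c", "d")))
  ev <- hg_events(promote_cliques(net))
  expect_setequal(ev$nodes, c("a,b,c", "c,d"))
})

test_that("promoted events per step form an antichain covering the contacts", {
  for (s in 1:20) {
    set.seed(s)
    n <- 12L
    m <- sample(4:20, 1)
    pairs <- replicate(m, sample.int(n, 2), simplify = FALSE)
    t <- sample.int(3L, m, replace = TRUE) - 1L
    net <- contact_net(t, pairs)
    prom <- promote_cliques(net)
    evp <- hg_events(prom, labels = FALSE)
    evc <- hg_events(net, labels = FALSE)
    for (tt in unique(evc$t)) {
      sets <- strsplit(evp$nodes[evp$t == tt], "-")
      # antichain: no event's node set contained in another's at the same step
      if (length(sets) > 1L) {
        for (i in seq_along(sets)) for (j in seq_along(sets)) {
          if (i != j) expect_false(all(sets[[i]] %in% sets[[j]]))
        }
      }
      # 2-subset union equals the step's contact edge set
      cover <- unique(unlist(lapply(sets, function(v) {
        apply(utils::combn(sort(as.integer(v)), 2), 2, paste, collapse = "-")
      })))
      orig <- unique(evc$nodes[evc$t == tt])
      expect_setequal(cover, orig)
    }
  }
})

test_that("missing-link completion fills exactly the single absent edge of near-cliques", {
  # K4 minus one edge
  k4m <- contact_net(rep(0L, 5), list(c("a", "b"), c("a", "c"), c("a", "d"),
                                      c("b", "c"), c("b", "d")))
  res <- complete_missing_links(k4m)
  expect_equal(res$n_added, 1L)
  ev <- hg_events(promote_cliques(res$network))
  expect_equal(ev$order, 4L)
  # triangle minus an edge (d = 3): below the size threshold, nothing added
  tri <- contact_net(c(0L, 0L), list(c("a", "b"), c("b", "c")))
  expect_equal(complete_missing_links(tri)$n_added, 0L)
  # K5 minus one edge: one edge added (the 5-clique's), not its 4-subsets'
  vs <- c("a", "b", "c", "d", "e")
  all_pairs <- utils::combn(vs, 2, simplify = FALSE)
  drop <- which(vapply(all_pairs, function(p) identical(p, c("a", "b")), logical(1)))
  k5m <- contact_net(rep(0L, 9), all_pairs[-drop])
  res5 <- complete_missing_links(k5m)
  expect_equal(res5$n_added, 1L)
  expect_equal(sort(node_labels(k5m)[unlist(res5$added[, c("u", "v")])]), c("a", "b"))
  expect_equal(hg_events(promote_cliques(res5$network))$order, 5L)
})

test_that("completion never shrinks the largest promotable event", {
  for (s in 1:10) {
    set.seed(s)
    n <- 10L
    pairs <- replicate(sample(5:15, 1), sample.int(n, 2), simplify = FALSE)
    net <- contact_net(rep(0L, length(pairs)), pairs)
    before <- max(hg_events(promote_cliques(net))$order)
    after <- max(hg_events(promote_cliques(complete_missing_links(net)$network))$order)
    expect_gte(after, before)
  }
})

test_that("largest-component restriction drops minority components deterministically", {
  # components {a,b,c} (triangle) and {x,y}
  net <- contact_net(c(0L, 0L, 1L, 2L),
                     list(c("a", "b"), c("b", "c"), c("a", "c"), c("x", "y")))
  res <- restrict_to_lcc(net)
  expect_equal(sort(node_labels(res$network)), c("a", "b", "c"))
  expect_equal(res$report$nodes_removed, 2L)
  expect_equal(res$report$events_removed, 1L)
  # connected network unchanged
  conn <- contact_net(0:1, list(c("a", "b"), c("b", "c")))
  expect_equal(event_multiset(restrict_to_lcc(conn)$network), event_multiset(conn))
  # tie between equal components: smallest original node id wins
  tie <- contact_net(c(0L, 1L), list(c("p", "q"), c("r", "s")))
  res2 <- restrict_to_lcc(tie)
  expect_true(res2$report$tie_broken)
  expect_equal(sort(node_labels(res2$network)), c("p", "q"))
  # component labelling oracle on random instances
  for (s in 1:5) {
    rnet <- random_small_net(s, n = 15, m = 8)
    D <- fw_distances(aggregate_pairwise(rnet)$edges, n_nodes(rnet))
    comp_sizes <- table(apply(is.finite(D), 1, function(r) min(which(r))))
    keep_n <- max(comp_sizes)
    expect_equal(n_nodes(restrict_to_lcc(rnet)$network), as.integer(keep_n))
  }
})

test_that("inactivity gaps above threshold are excised with times reindexed", {
  net <- temporal_hypergraph(tibble::tibble(
    t = c(0L, 1L, 2L, 5000L, 5001L),
    nodes = list(c("a", "b"), c("a", "b"), c("c", "d"), c("a", "b"), c("c", "d"))
  ), horizon = 5002L)
  res <- remove_inactivity_gaps(net, gap_rule("fixed", 1000))
  expect_equal(sort(unique(res$network$events$t)), 0:4)
  expect_equal(res$summary$steps_removed, 4997L)
  expect_equal(res$summary$T_after, res$summary$T_before - res$summary$steps_removed)
  expect_equal(nrow(res$network$events), nrow(net$events))
  # below threshold: identity
  res2 <- remove_inactivity_gaps(net, gap_rule("fixed", 6000))
  expect_equal(res2$network$events, net$events)
  expect_equal(nrow(res2$report), 0L)
  # event count invariant under any rule
  for (meth in list(gap_rule("tukey", 3), gap_rule("quantile", 0.9), gap_rule("fixed", 2))) {
    expect_equal(nrow(remove_inactivity_gaps(net, meth)$network$events), nrow(net$events))
  }
})

test_that("gap removal preserves inter-event times not spanning a removed gap", {
  net <- temporal_hypergraph(tibble::tibble(
    t = c(2L, 4L, 300L, 303L),
    nodes = list(c("a", "b"), c("a", "b"), c("c", "d"), c("c", "d"))
  ), horizon = 304L)
  res <- remove_inactivity_gaps(net, gap_rule("fixed", 100))
  tt <- sort(res$network$events$t)
  expect_equal(diff(tt), c(2L, 1L, 3L))  # local spacings intact, big gap gone
})
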