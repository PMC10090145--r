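test_that("degree and strength count hyperlinks and events per node and order", {
  net <- temporal_hypergraph(tibble::tibble(
    t = c(0L, 4L, 1L),
    nodes = list(c("i", "j", "k"), c("i", "j", "k"), c("i", "j"))
  ))
  tab <- degree_strength(net)
  get <- function(node, order, col) {
    r <- tab[tab$node == node & tab$order == order, ][[col]]
    if (length(r) == 0L) 0L else r
  }
  expect_equal(get("i", 3, "degree"), 1L)
  expect_equal(get("i", 3, "strength"), 2L)
  expect_equal(get("i", 2, "degree"), 1L)
  expect_equal(get("i", 2, "strength"), 1L)
  expect_equal(get("k", 2, "degree"), 0L)
})

test_that("sum identities hold on generated and randomized instances", {
  for (s in 1:4) {
    net <- generate_uncorrelated(n_nodes = 30L, horizon = 200L, n_pairs = 20L,
                                 n_triples = 10L, n_quads = 4L,
                                 weight_dispersion = "poisson", seed = s)
    variants <- list(net, randomize_h1(net, 3, s), randomize_h2(net, 3, s),
                     randomize_h3(net, 2, s))
    for (v in variants) {
      tab <- degree_strength(v)
      cen <- order_census(v)
      for (i in seq_len(nrow(cen))) {
        d <- cen$order[i]
        expect_equal(sum(tab$degree[tab$order == d]), d * cen$n_hyperlinks[i])
        expect_equal(sum(tab$strength[tab$order == d]), d * cen$n_events[i])
      }
      expect_true(all(tab$strength >= tab$degree))
    }
  }
})

test_that("degrees survive all null models; strengths redistribute only under H2", {
  net <- generate_uncorrelated(n_nodes = 40L, horizon = 300L, n_pairs = 30L,
                               n_triples = 15L, weight_dispersion = "poisson",
                               seed = 9)
  tab0 <- degree_strength(net)
  deg0 <- tab0[, c("node_id", "order", "degree")]
  h2_changed <- FALSE
  for (s in 1:5) {
    for (m in c("H1", "H2", "H3")) {
      r <- randomize_events(net, 3, seed = 50 + s, model = m)
      tab <- degree_strength(r)
      expect_equal(tab[, c("node_id", "order", "degree")], deg0)
      if (m %in% c("H1", "H3")) {
        expect_equal(tab, tab0)  # strengths invariant too
      } else if (!identical(tab$strength, tab0$strength)) {
        h2_changed <- TRUE
      }
    }
  }
  expect_true(h2_changed)
})

test_that("omega is the mean activation count of hyperlinks of an order", {
  net <- temporal_hypergraph(tibble::tibble(
    t = c(0L, 1L, 2L, 3L, 4L, 5L),
    nodes = list(c("a", "b"), c("a", "b"), c("a", "b"), c("a", "c"),
                 c("a", "c"), c("b", "c"))
  ))
  expect_equal(omega(net, 2), 2)
  expect_error(omega(net, 3), "no hyperlinks")
  for (s in 1:5) {
    rnet <- random_small_net(s)
    for (d in order_census(rnet)$order) {
      H <- aggregate_hypergraph(rnet)
      expect_equal(omega(rnet, d), mean(H$weight[H$order == d]))
    }
  }
})

test_that("cross-order relation matches a brute-force binning oracle", {
  set.seed(21)
  tab <- tibble::tibble(
    node = as.character(rep(1:100, 2)), node_id = rep(1:100, 2),
    order = rep(c(2L, 3L), each = 100),
    degree = c(sample.int(40, 100, replace = TRUE), sample.int(12, 100, replace = TRUE)),
    strength = 0L
  )
  curve <- cross_order_relation(tab, 2, 3, which = "degree", bins = 30)
  x <- tab$degree[tab$order == 2]
  y <- tab$degree[tab$order == 3]
  xn <- x / max(x); yn <- y / max(y)
  edges <- exp(seq(log(min(xn)), log(1), length.out = 31))
  idx <- findInterval(xn, edges, left.open = TRUE)
  idx[xn <= edges[1]] <- 1L
  idx <- pmin(idx, 30L)
  for (b in sort(unique(idx))) {
    row <- curve[curve$bin == b, ]
    expect_equal(nrow(row), 1L)
    expect_equal(row$y_mean, mean(yn[idx == b]))
    expect_equal(row$n, sum(idx == b))
  }
  expect_equal(sum(curve$n), 100L)
})

test_that("degenerate and proportional tables give single-bin and diagonal curves", {
  tab <- tibble::tibble(node = as.character(rep(1:10, 2)), node_id = rep(1:10, 2),
                        order = rep(c(2L, 3L), each = 10),
                        degree = c(rep(4L, 10), rep(6L, 10)), strength = 0L)
  curve <- cross_order_relation(tab, 2, 3, "degree")
  expect_equal(nrow(curve), 1L)
  expect_equal(curve$x_mean, 1)
  expect_equal(curve$y_mean, 1)
  # exact proportionality: normalized curve on the diagonal
  tab2 <- tab
  tab2$degree <- c(1:10, 2L * (1:10))
  curve2 <- cross_order_relation(tab2, 2, 3, "degree")
  expect_equal(curve2$y_mean, curve2$x_mean, tolerance = 1e-12)
})

test_that("strength-vs-degree lies on the diagonal when all weights are equal", {
  net <- generate_uncorrelated(n_nodes = 40L, horizon = 500L, n_pairs = 40L,
                               n_triples = 0L, events_per_pair = 3L,
                               weight_dispersion = "fixed", backbone = FALSE,
                               seed = 2)
  sv <- strength_vs_degree(net, 2)
  expect_equal(sv$y_mean, sv$x_mean, tolerance = 1e-12)
})

test_that("cross-order relation is invariant under node relabeling", {
  net <- random_small_net(17, n = 20, m = 40)
  tab <- degree_strength(net)
  perm <- sample(n_nodes(net))
  tab2 <- tab
  tab2$node_id <- perm[tab$node_id]
  cen <- order_census(net)
  if (nrow(cen) >= 2L) {
    c1 <- cross_order_relation(tab, cen$order[1], cen$order[2], "degree")
    c2 <- cross_order_relation(tab2, cen$order[1], cen$order[2], "degree")
    expect_equal(c1, c2, ignore_attr = TRUE)
  }
})
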