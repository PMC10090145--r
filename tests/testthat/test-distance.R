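test_that("event distance is zero on the same hyperlink, one on shared nodes", {
  net <- temporal_hypergraph(tibble::tibble(
    t = c(0L, 5L), nodes = list(c("i", "j", "k"), c("i", "m", "n"))
  ))
  G <- aggregate_pairwise(net)
  hl <- hyperlinks(net)
  expect_equal(event_distance(hl$nodes[[1]], hl$nodes[[2]], G), 1)
  expect_equal(event_distance(hl$nodes[[1]], hl$nodes[[1]], G), 0)
})

test_that("event distance on a path graph is one plus the minimal hop count", {
  net <- temporal_hypergraph(tibble::tibble(
    t = 0:3, nodes = list(c("a", "b"), c("b", "c"), c("c", "d"), c("d", "e"))
  ))
  G <- aggregate_pairwise(net)
  expect_equal(event_distance(c(1L, 2L), c(4L, 5L), G), 3)  # min delta = 2
})

test_that("event distance matches the Floyd-Warshall brute-force oracle", {
  for (s in 1:15) {
    net <- random_small_net(s)
    G <- aggregate_pairwise(net)
    D <- fw_distances(G$edges, n_nodes(net))
    hl <- hyperlinks(net)
    k <- min(nrow(hl), 8L)
    idx <- seq_len(k)
    for (i in idx) for (j in idx) {
      got <- event_distance(hl$nodes[[i]], hl$nodes[[j]], G)
      want <- brute_event_distance(hl$nodes[[i]], hl$nodes[[j]], D)
      expect_equal(got, want)
      expect_equal(got, event_distance(hl$nodes[[j]], hl$nodes[[i]], G))  # symmetry
    }
  }
})

test_that("exact distance curve equals exhaustive pair enumeration on toy nets", {
  for (s in c(2, 9)) {
    net <- random_small_net(s, n = 12, m = 12)
    cen <- order_census(net)
    d <- cen$order[which.max(cen$n_events)]
    grid <- c(1L, 3L, 10L, 60L)
    for (kind in c("cross_order", "same_order")) {
      n_d <- cen$n_events[cen$order == d]
      if (kind == "cross_order" && nrow(cen) < 2L) next
      if (kind == "same_order" && n_d < 2L) next
      got <- distance_curve(net, d, kind = kind, grid = grid)
      want <- brute_distance_curve(net, d, kind, grid)
      expect_equal(got$n_pairs, want$n_pairs)
      expect_equal(got$mean_dist, want$mean_dist, tolerance = 1e-12)
      expect_equal(got$normalized, want$normalized, tolerance = 1e-12)
    }
  }
})

test_that("normalized curve is exactly 1 beyond the maximal temporal distance", {
  net <- random_small_net(4, n = 10, m = 20)
  d <- order_census(net)$order[1]
  cv <- distance_curve(net, d, grid = c(1L, net$horizon + 1L))
  expect_equal(cv$normalized[2], 1)
  expect_equal(cv$n_pairs[2], attr(cv, "total_pairs"))
})

test_that("curves are invariant under node relabeling and event reordering", {
  net <- random_small_net(6, n = 10, m = 15)
  ev <- hg_events(net)
  set.seed(1)
  perm <- sample(letters, n_nodes(net))
  relab <- vapply(strsplit(ev$nodes, ","), function(x) {
    paste(perm[match(x, node_labels(net))], collapse = ",")
  }, character(1))
  net2 <- temporal_hypergraph(tibble::tibble(t = ev$t, nodes = relab)[sample(nrow(ev)), ],
                              horizon = net$horizon)
  d <- order_census(net)$order[1]
  g <- c(1L, 5L, 20L, 60L)
  expect_equal(distance_curve(net, d, grid = g)$normalized,
               distance_curve(net2, d, grid = g)$normalized)
})

test_that("sampled estimator agrees with the exact curve within 3 standard errors", {
  net <- random_small_net(13, n = 15, m = 40)
  d <- order_census(net)$order[which.max(order_census(net)$n_events)]
  grid <- c(2L, 10L, 60L)
  exact <- distance_curve(net, d, grid = grid, estimator = "exact")
  samp <- distance_curve(net, d, grid = grid, estimator = "sampled",
                         sample_size = 2e4, seed = 5)
  ok <- !is.na(samp$normalized) & !is.na(exact$normalized) & samp$n_pairs > 1
  expect_true(all(abs(samp$normalized[ok] - exact$normalized[ok]) <=
                    3 * samp$se[ok] + 1e-9))
})

fake_curve <- function(dt, y, n = 100L) {
  out <- tibble::tibble(dt_steps = dt, n_pairs = rep(n, length(dt)),
                        mean_dist = y * 2, normalized = y, se = NA_real_)
  attr(out, "kind") <- "cross_order"
  attr(out, "d") <- 3
  class(out) <- c("hg_distance_curve", class(out))
  out
}

test_that("slope fit recovers exact lines, constants, and V-shapes", {
  dt <- as.integer(round(10^seq(0, 3, length.out = 20)))
  dt <- unique(dt)
  lin <- fake_curve(dt, 0.5 + 0.1 * log10(dt))
  f <- fit_increasing_slope(lin)
  expect_equal(f$m, 0.1, tolerance = 1e-9)
  expect_equal(fit_increasing_slope(lin, weights = "none")$m, 0.1, tolerance = 1e-9)
  cst <- fake_curve(dt, rep(0.7, length(dt)))
  expect_equal(fit_increasing_slope(cst)$m, 0)
  # V-shape: decreasing, then linear with slope 0.2 from the minimum
  brk <- 8L
  y <- c(seq(1, 0.4, length.out = brk),
         0.4 + 0.2 * (log10(dt[(brk + 1):length(dt)]) - log10(dt[brk])))
  v <- fake_curve(dt, y)
  fv <- fit_increasing_slope(v)
  expect_equal(fv$m, 0.2, tolerance = 1e-9)
  expect_equal(fv$fit_range[1], which.min(y))
  # tidy/glance accessors
  expect_equal(glance(fv)$m, fv$m)
  expect_equal(tidy(fv)$estimate[2], fv$m)
})

test_that("slope fit needs 3 defined points and flags short increasing parts", {
  dt <- c(1L, 10L, 100L, 1000L)
  short <- fake_curve(dt, c(NA, NA, 0.5, 0.6))
  expect_error(fit_increasing_slope(short), "3 defined")
  # minimum at the second-to-last point -> too few points, full-curve fallback
  dec <- fake_curve(dt, c(0.9, 0.8, 0.5, 0.6))
  f <- fit_increasing_slope(dec)
  expect_true(f$flagged)
  expect_equal(f$fit_range, c(1L, 4L))
})
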