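# Independent oracles and tiny fixture builders shared across tests.
# Oracles deliberately avoid the code paths (and graph library) they check.

# Floyd-Warshall all-pairs hop counts from an edge tibble (u, v), n nodes.
fw_distances <- function(edges, n) {
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  if (nrow(edges) > 0L) {
    D[cbind(edges$u, edges$v)] <- 1
    D[cbind(edges$v, edges$u)] <- 1
  }
  for (k in seq_len(n)) {
    D <- pmin(D, outer(D[, k], D[k, ], "+"))
  }
  D
}

# Brute-force event distance from a precomputed distance matrix.
brute_event_distance <- function(n1, n2, D) {
  n1 <- sort(n1); n2 <- sort(n2)
  if (identical(n1, n2)) return(0)
  best <- Inf
  for (u in n1) for (v in n2) best <- min(best, D[u, v])
  best + 1
}

# Build a network from a plain tibble of (t, ids list) over n labelled nodes.
net_from_ids <- function(t, ids, n, horizon = NULL) {
  temporal_hypergraph(
    tibble::tibble(t = t, nodes = lapply(ids, function(v) as.character(v))),
    horizon = horizon
  )
}

# Random small network: n nodes "1".."n", m events of order 2..4.
random_small_net <- function(seed, n = NULL, m = NULL) {
  set.seed(seed)
  n <- n %||% sample(5:30, 1)
  m <- m %||% sample(5:60, 1)
  ids <- lapply(seq_len(m), function(i) sample.int(n, sample(2:min(4, n), 1)))
  t <- sample.int(50L, m, replace = TRUE) - 1L
  net <- temporal_hypergraph(
    tibble::tibble(t = t, nodes = lapply(ids, as.character)),
    horizon = 50L
  )
  net
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force O(|E|^2) conditional distance-delay curve.
brute_distance_curve <- function(net, d, kind, grid, G = aggregate_pairwise(net)) {
  ev <- hg_events(net, labels = FALSE)
  hl <- hyperlinks(net)
  nodes_of <- function(h) hl$nodes[[match(h, hl$hid)]]
  A <- ev[ev$order == d, , drop = FALSE]
  B <- if (kind == "cross_order") ev[ev$order != d, , drop = FALSE] else A
  eta <- c(); td <- c()
  if (kind == "cross_order") {
    for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B))) {
      eta <- c(eta, event_distance(nodes_of(A$hid[i]), nodes_of(B$hid[j]), G))
      td <- c(td, abs(A$t[i] - B$t[j]))
    }
  } else {
    for (i in seq_len(nrow(A) - 1L)) for (j in (i + 1L):nrow(A)) {
      eta <- c(eta, event_distance(nodes_of(A$hid[i]), nodes_of(A$hid[j]), G))
      td <- c(td, abs(A$t[i] - A$t[j]))
    }
  }
  uncond <- mean(eta)
  tibble::tibble(
    dt_steps = grid,
    n_pairs = vapply(grid, function(g) sum(td < g), integer(1)),
    mean_dist = vapply(grid, function(g) if (any(td < g)) mean(eta[td < g]) else NA_real_, numeric(1)),
    normalized = vapply(grid, function(g) if (any(td < g)) mean(eta[td < g]) / uncond else NA_real_, numeric(1))
  )
}

# Brute-force left-to-right train scan over an activity table (t, count):
# walk steps in order, opening a new train whenever the gap since the last
# active step exceeds delta_t.
brute_trains <- function(activity, delta_t, center_times = integer()) {
  activity <- activity[order(activity$t), , drop = FALSE]
  if (nrow(activity) == 0L) {
    return(tibble::tibble(start = integer(), end = integer(), size = integer(),
                          center_active = logical()))
  }
  start <- activity$t[1L]; last <- activity$t[1L]; size <- activity$count[1L]
  out <- NULL
  if (nrow(activity) > 1L) {
    for (i in 2:nrow(activity)) {
      if (activity$t[i] - last > delta_t) {
        out <- rbind(out, c(start, last, size))
        start <- activity$t[i]; size <- 0L
      }
      size <- size + activity$count[i]
      last <- activity$t[i]
    }
  }
  out <- rbind(out, c(start, last, size))
  tibble::tibble(
    start = out[, 1L], end = out[, 2L], size = out[, 3L],
    center_active = vapply(seq_len(nrow(out)), function(i) {
      any(center_times >= out[i, 1L] & center_times <= out[i, 2L])
    }, logical(1))
  )
}

# Serialized event multiset for exact-equality comparisons.
event_multiset <- function(net) {
  ev <- hg_events(net, labels = TRUE)
  sort(paste(ev$t, vapply(strsplit(ev$nodes, ","), function(x) paste(sort(x), collapse = ","),
                          character(1))))
}

# Per-hyperlink weights keyed by label-sorted node set.
weight_map <- function(net) {
  H <- aggregate_hypergraph(net)
  keys <- vapply(H$nodes, function(v) paste(sort(node_labels(net)[v]), collapse = ","), character(1))
  stats::setNames(H$weight, keys)[order(keys)]
}

# Multiset of activity series (as strings) of order-d hyperlinks.
series_multiset <- function(net, d) {
  H <- aggregate_hypergraph(net)
  hids <- H$hid[H$order == d]
  hl <- hyperlinks(net)
  sort(vapply(hids, function(h) {
    paste(activity_series(net, hl$nodes[[match(h, hl$hid)]]), collapse = ",")
  }, character(1)))
}

# Events of all orders except d, serialized (for bit-identity checks).
other_order_events <- function(net, d) {
  ev <- hg_events(net, labels = TRUE)
  ev <- ev[ev$order != d, , drop = FALSE]
  sort(paste(ev$t, vapply(strsplit(ev$nodes, ","), function(x) paste(sort(x), collapse = ","),
                          character(1))))
}
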