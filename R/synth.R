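#' Seeded generators for higher-order temporal networks
#'
#' Three generators emulating the regularities of empirical higher-order
#' contact data at desk scale, used throughout the test suite in place of
#' real recordings:
#'
#' * `generate_uncorrelated()` — the negative control matching the world of
#'   the null models: hyperlinks drawn on a ring lattice (or uniformly),
#'   activation times i.i.d. uniform per hyperlink (or bursty), no coupling
#'   between temporal and topological location of events.
#' * `generate_coupled()` — the positive control: order-3 anchor events
#'   each spawn, with probability `p_coupling`, a pairwise event on one of
#'   their own 2-subsets after a short geometric lag, planting the
#'   "close in time implies close in topology" signature.
#' * `generate_contact_sequence()` — an order-2 contact stream with known
#'   planted cliques and near-cliques (one edge missing) at known steps,
#'   with a ground-truth manifest, for exercising clique promotion and
#'   missing-link completion.
#'
#' Nodes sit on a ring; a hyperlink is sampled by picking a center node and
#' `d - 1` distinct companions within `radius` ring positions, which gives
#' the aggregated graph the non-trivial hop-count structure the distance
#' statistics need (`locality = "uniform"` drops this). A backbone of all
#' `n_nodes` consecutive ring pairs (one activation each, uniform times)
#' keeps the aggregated graph connected. All output is bit-reproducible
#' from `seed`.
#'
#' @param n_nodes Number of nodes on the ring.
#' @param horizon Number of time steps `T`.
#' @param n_pairs Number of order-2 hyperlinks beyond the backbone.
#' @param n_triples Number of order-3 hyperlinks.
#' @param n_quads Number of order-4 hyperlinks (uncorrelated generator).
#' @param events_per_pair,events_per_triple,events_per_quad Activations per
#'   hyperlink of the respective order.
#' @param weight_dispersion `"fixed"` (every hyperlink exactly the stated
#'   count) or `"poisson"` (1 + Poisson with the stated mean - 1), the
#'   latter giving the heterogeneous weights needed to distinguish the H2
#'   and H3 null models.
#' @param bursty If `TRUE`, per-hyperlink activation times are laid out as
#'   bursts: inter-event gaps drawn from a truncated discrete power law
#'   (exponent `burst_alpha`) instead of i.i.d. uniform placement.
#' @param burst_alpha Power-law exponent of the bursty gap law (> 1).
#' @param locality `"ring"` or `"uniform"` hyperlink placement.
#' @param radius Ring neighborhood radius for `locality = "ring"`.
#' @param backbone Include the ring backbone pairs (default `TRUE`).
#' @param seed Integer seed (mandatory).
#' @return A `temporal_hypergraph`. `generate_coupled()` attaches a
#'   `spawns` attribute (tibble of anchor/spawn ground truth);
#'   `generate_contact_sequence()` attaches a `manifest` attribute (tibble
#'   `t`, `kind`, `size`, `nodes`).
#' @export
generate_uncorrelated <- function(n_nodes = 300L, horizon = 5000L,
                                  n_pairs = 150L, n_triples = 60L,
                                  n_quads = 0L,
                                  events_per_pair = 4L, events_per_triple = 5L,
                                  events_per_quad = 3L,
                                  weight_dispersion = c("fixed", "poisson"),
                                  bursty = FALSE, burst_alpha = 2.2,
                                  locality = c("ring", "uniform"), radius = 5L,
                                  backbone = TRUE, seed) {
  weight_dispersion <- match.arg(weight_dispersion)
  locality <- match.arg(locality)
  restore <- local_seed_expr(seed)
  on.exit(restore(), add = TRUE)

  bb <- if (backbone) ring_backbone(n_nodes) else list()
  pairs <- sample_hyperlinks(n_nodes, d = 2L, count = n_pairs, locality, radius,
                             taken = bb)
  triples <- sample_hyperlinks(n_nodes, d = 3L, count = n_triples, locality, radius)
  quads <- sample_hyperlinks(n_nodes, d = 4L, count = n_quads, locality, radius)
  place <- function(sets, mean_w) {
    if (length(sets) == 0L) return(list(nodes = list(), t = integer()))
    w <- draw_weights(length(sets), mean_w, weight_dispersion)
    times <- lapply(w, function(k) {
      if (bursty) bursty_times(k, horizon, burst_alpha) else
        sample.int(horizon, k) - 1L
    })
    list(nodes = rep(sets, lengths(times)),
         t = unlist(times, use.names = FALSE))
  }
  bb_ev <- if (backbone) {
    list(nodes = bb, t = sample.int(horizon, length(bb), replace = TRUE) - 1L)
  } else list(nodes = list(), t = integer())
  p2 <- place(pairs, events_per_pair)
  p3 <- place(triples, events_per_triple)
  p4 <- place(quads, events_per_quad)
  new_temporal_hypergraph(
    labels = as.character(seq_len(n_nodes)),
    node_sets = c(bb_ev$nodes, p2$nodes, p3$nodes, p4$nodes),
    times = c(bb_ev$t, p2$t, p3$t, p4$t),
    horizon = as.integer(horizon), dt = 1, dt_unit = "s",
    contact_type = "synthetic-uncorrelated"
  )
}

#' @param p_coupling Probability that an order-3 anchor event spawns a
#'   pairwise event on one of its 2-subsets.
#' @param lag_scale Mean of the geometric spawn lag (steps, `>= 1`).
#' @rdname generate_uncorrelated
#' @export
generate_coupled <- function(n_nodes = 300L, horizon = 5000L,
                             n_pairs = 150L, n_triples = 60L,
                             events_per_pair = 4L, events_per_triple = 5L,
                             p_coupling = 0.8, lag_scale = 5,
                             weight_dispersion = c("fixed", "poisson"),
                             bursty = FALSE, burst_alpha = 2.2,
                             locality = c("ring", "uniform"), radius = 5L,
                             backbone = TRUE, seed) {
  weight_dispersion <- match.arg(weight_dispersion)
  locality <- match.arg(locality)
  stopifnot(p_coupling >= 0, p_coupling <= 1, lag_scale >= 1)
  restore <- local_seed_expr(seed)
  on.exit(restore(), add = TRUE)

  bb <- if (backbone) ring_backbone(n_nodes) else list()
  pairs <- sample_hyperlinks(n_nodes, d = 2L, count = n_pairs, locality, radius,
                             taken = bb)
  triples <- sample_hyperlinks(n_nodes, d = 3L, count = n_triples, locality, radius)

  w3 <- draw_weights(length(triples), events_per_triple, weight_dispersion)
  anchor_nodes <- rep(triples, w3)
  anchor_t <- unlist(lapply(w3, function(k) {
    if (bursty) bursty_times(k, horizon, burst_alpha) else sample.int(horizon, k) - 1L
  }), use.names = FALSE)

  spawn <- stats::runif(length(anchor_t)) < p_coupling
  lag <- 1L + stats::rgeom(length(anchor_t), prob = 1 / lag_scale)
  sub_pick <- sample.int(3L, length(anchor_t), replace = TRUE)
  spawn_nodes <- purrr::map2(anchor_nodes, sub_pick, function(v, k) sort(v[-k]))
  spawn_t <- anchor_t + lag
  keep <- spawn & spawn_t < horizon
  spawns <- tibble::tibble(
    anchor_key = vapply(anchor_nodes[keep], paste, character(1), collapse = "-"),
    anchor_t = anchor_t[keep],
    spawn_key = vapply(spawn_nodes[keep], paste, character(1), collapse = "-"),
    spawn_t = spawn_t[keep]
  )

  w2 <- draw_weights(length(pairs), events_per_pair, weight_dispersion)
  bg_nodes <- rep(pairs, w2)
  bg_t <- unlist(lapply(w2, function(k) {
    if (bursty) bursty_times(k, horizon, burst_alpha) else sample.int(horizon, k) - 1L
  }), use.names = FALSE)
  bb_t <- if (backbone) sample.int(horizon, length(bb), replace = TRUE) - 1L else integer()

  out <- new_temporal_hypergraph(
    labels = as.character(seq_len(n_nodes)),
    node_sets = c(bb, bg_nodes, spawn_nodes[keep], anchor_nodes),
    times = c(bb_t, bg_t, spawn_t[keep], anchor_t),
    horizon = as.integer(horizon), dt = 1, dt_unit = "s",
    contact_type = "synthetic-coupled"
  )
  attr(out, "spawns") <- spawns
  out
}

#' @param n_steps Number of active steps at which structures are planted.
#' @param units_per_step Planted structures per step (node-disjoint).
#' @param sizes Candidate clique sizes (near-cliques use sizes `>= 4`).
#' @param p_near Probability a planted unit of size `>= 4` is a near-clique
#'   (complete minus one edge) rather than a full clique.
#' @rdname generate_uncorrelated
#' @export
generate_contact_sequence <- function(n_nodes = 30L, n_steps = 8L,
                                      units_per_step = 2L, sizes = 2:5,
                                      p_near = 0.35, seed) {
  restore <- local_seed_expr(seed)
  on.exit(restore(), add = TRUE)
  stopifnot(max(sizes) * units_per_step <= n_nodes)
  steps <- sort(sample.int(10L * n_steps, n_steps) - 1L)
  man_t <- integer(); man_kind <- character(); man_size <- integer()
  man_nodes <- character()
  cs_nodes <- list(); cs_t <- integer()
  for (tt in steps) {
    pool <- sample.int(n_nodes)
    used <- 0L
    for (u in seq_len(units_per_step)) {
      sz <- sample(sizes, 1L)
      vs <- sort(pool[(used + 1L):(used + sz)])
      used <- used + sz
      near <- sz >= 4L && stats::runif(1) < p_near
      edges <- utils::combn(vs, 2L, simplify = FALSE)
      if (near) edges <- edges[-sample.int(length(edges), 1L)]
      cs_nodes <- c(cs_nodes, edges)
      cs_t <- c(cs_t, rep.int(tt, length(edges)))
      man_t <- c(man_t, tt)
      man_kind <- c(man_kind, if (near) "near_clique" else "clique")
      man_size <- c(man_size, sz)
      man_nodes <- c(man_nodes, paste(vs, collapse = "-"))
    }
  }
  out <- new_temporal_hypergraph(
    labels = as.character(seq_len(n_nodes)),
    node_sets = cs_nodes, times = cs_t,
    horizon = max(steps) + 1L, dt = 1, dt_unit = "s",
    contact_type = "synthetic-contacts"
  )
  attr(out, "manifest") <- tibble::tibble(
    t = man_t, kind = man_kind, size = man_size, nodes = man_nodes
  )
  out
}

ring_backbone <- function(n) {
  lapply(seq_len(n), function(i) sort(c(i, i %% n + 1L)))
}

# Sample `count` distinct hyperlinks of order d, avoiding keys in `taken`.
sample_hyperlinks <- function(n, d, count, locality, radius, taken = list()) {
  if (count == 0L) return(list())
  if (locality == "uniform" && choose(n, d) < count + length(taken)) {
    stop("requested hyperlink count exceeds distinct combinations")
  }
  seen <- vapply(taken, paste, character(1), collapse = "-")
  out <- vector("list", count)
  got <- 0L
  tries <- 0L
  while (got < count) {
    tries <- tries + 1L
    if (tries > 200L * count) stop("could not sample enough distinct hyperlinks")
    vs <- if (locality == "ring") {
      c0 <- sample.int(n, 1L)
      off <- sample(c(-radius:-1L, 1L:radius), d - 1L)
      sort(unique(c(c0, (c0 + off - 1L) %% n + 1L)))
    } else {
      sort(sample.int(n, d))
    }
    if (length(vs) != d) next
    key <- paste(vs, collapse = "-")
    if (key %in% seen) next
    seen <- c(seen, key)
    got <- got + 1L
    out[[got]] <- vs
  }
  out
}

draw_weights <- function(k, mean_w, dispersion) {
  if (k == 0L) return(integer())
  if (dispersion == "fixed") return(rep.int(as.integer(mean_w), k))
  1L + stats::rpois(k, lambda = mean_w - 1)
}

# k activation steps forming bursts: heavy-tailed gaps, resampled until the
# span fits inside the horizon.
bursty_times <- function(k, horizon, alpha) {
  if (k == 1L) return(sample.int(horizon, 1L) - 1L)
  for (i in seq_len(200L)) {
    gaps <- pmax(1L, floor(stats::runif(k - 1L)^(-1 / (alpha - 1))))
    gaps <- pmin(gaps, max(1L, horizon %/% 10L))
    span <- sum(gaps)
    if (span < horizon) {
      start <- sample.int(horizon - span, 1L) - 1L
      return(start + cumsum(c(0L, gaps)))
    }
  }
  sort(sample.int(horizon, k) - 1L)
}
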