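#' Promote simultaneous contact cliques to higher-order events
#'
#' Group interactions measured as pairwise contacts appear as cliques of
#' simultaneous contacts: an interaction among `d` people is recorded as the
#' `choose(d, 2)` dyadic contacts at the same step. This operation
#' reconstructs the higher-order events: at each time step, the graph of
#' contacts active at that step is decomposed into its maximal cliques, and
#' each maximal clique of size `d` becomes one order-`d` event. Sub-cliques
#' are ignored, so three simultaneous contacts forming a triangle become a
#' single order-3 event and no order-2 event. A contact that belongs to two
#' overlapping maximal cliques contributes to both events.
#'
#' @param net A `temporal_hypergraph` whose events are all order 2.
#' @return A `temporal_hypergraph` with promoted events (same node table,
#'   horizon and metadata).
#' @export
promote_cliques <- function(net) {
  hl <- net$hyperlinks
  if (any(hl$order != 2L)) stop("promote_cliques() requires an order-2-only network")
  if (nrow(net$events) == 0L) return(net)
  ev <- net$events
  uv <- do.call(rbind, hl$nodes[match(ev$hid, hl$hid)])
  out_nodes <- list()
  out_t <- integer()
  for (tt in sort(unique(ev$t))) {
    sel <- ev$t == tt
    cl <- step_maximal_cliques(uv[sel, , drop = FALSE])
    out_nodes <- c(out_nodes, cl)
    out_t <- c(out_t, rep.int(tt, length(cl)))
  }
  new_temporal_hypergraph(
    labels = net$labels, node_sets = out_nodes, times = out_t,
    horizon = net$horizon, dt = net$dt, dt_unit = net$dt_unit,
    contact_type = net$contact_type
  )
}

# Maximal cliques (size >= 2, sorted id vectors) of the graph given by an
# edge matrix over dense node ids.
step_maximal_cliques <- function(edge_mat) {
  nodes <- sort(unique(as.vector(edge_mat)))
  g <- igraph::graph_from_edgelist(
    matrix(match(edge_mat, nodes), ncol = 2L), directed = FALSE
  )
  cl <- igraph::max_cliques(g, min = 2L)
  lapply(cl, function(idx) sort(nodes[as.integer(idx)]))
}

#' Add single missing links of near-complete simultaneous cliques
#'
#' Measured contact data can be incomplete: if one of the `choose(d, 2)`
#' contacts of a genuine order-`d` group interaction was missed, clique
#' promotion splits the group into two order `d - 1` events. This robustness
#' variant scans each time step for induced subgraphs on `d >= 4` nodes that
#' are a complete graph minus exactly one edge and adds that edge as a
#' contact at that step. Only maximal near-cliques trigger an addition (a
#' near-clique contained in a larger one at the same step is ignored), and a
#' single pass is applied per step — added edges do not cascade. The result
#' is ready for [promote_cliques()].
#'
#' @param net A `temporal_hypergraph` whose events are all order 2.
#' @return A list: `network` (the completed order-2 network), `added`
#'   (tibble of added contacts: `t`, `u`, `v` dense ids), `n_added`.
#' @export
complete_missing_links <- function(net) {
  hl <- net$hyperlinks
  if (any(hl$order != 2L)) stop("complete_missing_links() requires an order-2-only network")
  ev <- net$events
  add_t <- integer(); add_u <- integer(); add_v <- integer()
  if (nrow(ev) > 0L) {
    uv <- do.call(rbind, hl$nodes[match(ev$hid, hl$hid)])
    for (tt in sort(unique(ev$t))) {
      m <- uv[ev$t == tt, , drop = FALSE]
      miss <- step_missing_links(m)
      if (nrow(miss) > 0L) {
        add_t <- c(add_t, rep.int(tt, nrow(miss)))
        add_u <- c(add_u, miss[, 1L]); add_v <- c(add_v, miss[, 2L])
      }
    }
  }
  all_nodes <- c(lapply(seq_len(nrow(ev)), function(i) {
    hl$nodes[[match(ev$hid[i], hl$hid)]]
  }), purrr::map2(add_u, add_v, c))
  all_t <- c(ev$t, add_t)
  out <- new_temporal_hypergraph(
    labels = net$labels, node_sets = all_nodes, times = all_t,
    horizon = net$horizon, dt = net$dt, dt_unit = net$dt_unit,
    contact_type = net$contact_type
  )
  list(
    network = out,
    added = tibble::tibble(t = add_t, u = add_u, v = add_v),
    n_added = length(add_t)
  )
}

# Missing edges (u, v) of maximal near-cliques of size >= 4 in the step
# graph given as an edge matrix. A near-clique missing edge (u, v) is
# {u, v} + a clique of >= 2 common neighbours of u and v; any such clique
# (in particular a maximal one) witnesses a near-clique of size >= 4.
step_missing_links <- function(edge_mat) {
  nodes <- sort(unique(as.vector(edge_mat)))
  n <- length(nodes)
  A <- matrix(FALSE, n, n)
  e <- cbind(match(edge_mat[, 1L], nodes), match(edge_mat[, 2L], nodes))
  A[e] <- TRUE
  A[e[, c(2L, 1L)]] <- TRUE
  out <- NULL
  if (n >= 4L) {
    cn <- crossprod(A)  # common-neighbour counts
    cand <- which(!A & cn >= 2L & upper.tri(cn), arr.ind = TRUE)
    for (r in seq_len(nrow(cand))) {
      u <- cand[r, 1L]; v <- cand[r, 2L]
      nb <- which(A[u, ] & A[v, ])
      if (any(A[nb, nb])) out <- rbind(out, c(nodes[u], nodes[v]))
    }
  }
  if (is.null(out)) matrix(integer(), ncol = 2L) else out
}

#' Restrict a network to the largest connected component
#'
#' Removes nodes outside the largest connected component of the pairwise
#' aggregated graph, together with every event touching them, and
#' re-densifies the node table. Ties between equal-size components are
#' broken deterministically towards the component containing the smallest
#' original node id.
#'
#' @param net A `temporal_hypergraph`.
#' @return A list: `network` (restricted net) and `report` (one-row tibble
#'   with `nodes_removed`, `events_removed`, `tie_broken`).
#' @export
restrict_to_lcc <- function(net) {
  if (length(net$labels) == 0L) {
    return(list(network = net,
                report = tibble::tibble(nodes_removed = 0L, events_removed = 0L,
                                        tie_broken = FALSE)))
  }
  G <- aggregate_pairwise(net)
  comp <- igraph::components(G$graph)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  tie <- length(best) > 1L
  if (tie) {
    min_id <- vapply(best, function(cc) min(which(comp$membership == cc)), integer(1))
    best <- best[which.min(min_id)]
  } else {
    best <- best[1L]
  }
  keep <- which(comp$membership == best)
  if (length(keep) == length(net$labels)) {
    return(list(network = net,
                report = tibble::tibble(nodes_removed = 0L, events_removed = 0L,
                                        tie_broken = tie)))
  }
  hl <- net$hyperlinks
  hid_keep <- hl$hid[vapply(hl$nodes, function(v) all(v %in% keep), logical(1))]
  ev <- net$events[net$events$hid %in% hid_keep, , drop = FALSE]
  remap <- match(seq_along(net$labels), keep)  # old id -> new id (NA if dropped)
  idx <- match(ev$hid, hl$hid)
  node_sets <- lapply(hl$nodes[idx], function(v) sort(remap[v]))
  out <- new_temporal_hypergraph(
    labels = net$labels[keep], node_sets = node_sets, times = ev$t,
    horizon = net$horizon, dt = net$dt, dt_unit = net$dt_unit,
    contact_type = net$contact_type
  )
  list(
    network = out,
    report = tibble::tibble(
      nodes_removed = length(net$labels) - length(keep),
      events_removed = nrow(net$events) - nrow(ev),
      tie_broken = tie
    )
  )
}

#' Inactivity-gap removal rule
#'
#' Long periods with no event anywhere in the network (nights, weekends)
#' show up as outlying zero-activity runs in the network-wide activity
#' series. A `gap_rule` decides which runs count as outliers:
#' `tukey` removes runs longer than `Q3 + parameter * IQR` of the run-length
#' distribution (default fence multiplier 3), `quantile` removes runs above
#' the `parameter` quantile, and `fixed` removes runs longer than
#' `parameter` steps.
#'
#' @param method One of `"tukey"`, `"quantile"`, `"fixed"`.
#' @param parameter Fence multiplier, quantile in (0, 1), or absolute
#'   threshold in steps.
#' @return A `gap_rule` object.
#' @export
gap_rule <- function(method = c("tukey", "quantile", "fixed"), parameter = 3) {
  method <- match.arg(method)
  stopifnot(is.numeric(parameter), length(parameter) == 1L, parameter > 0)
  if (method == "quantile") stopifnot(parameter < 1)
  structure(list(method = method, parameter = parameter), class = "gap_rule")
}

#' Remove long network-wide inactivity gaps
#'
#' Computes the network-wide activity series (events per step), finds the
#' maximal runs of zero-activity steps between active steps, and deletes the
#' runs flagged as outliers by `rule`, shifting later timestamps left by the
#' deleted length. The event multiset size and all inter-event times not
#' spanning a removed gap are preserved. An inactivity run before the first
#' event is subject to the same rule (the threshold itself is computed from
#' internal runs only, matching the inter-event-time reading of the
#' outlier criterion).
#'
#' @param net A `temporal_hypergraph`.
#' @param rule A [gap_rule()]; default `gap_rule("tukey", 3)`.
#' @param collapse_to Steps a removed gap is collapsed to: 0 (default,
#'   removed entirely) or 1.
#' @return A list: `network` and `report` (tibble with `gap_start`,
#'   `gap_length` per removed gap) plus attributes-free summary columns via
#'   `summary`: a one-row tibble `n_gaps`, `steps_removed`, `T_before`,
#'   `T_after`.
#' @export
remove_inactivity_gaps <- function(net, rule = gap_rule("tukey", 3),
                                   collapse_to = 0L) {
  stopifnot(inherits(rule, "gap_rule"), collapse_to %in% c(0L, 1L))
  ev <- net$events
  T_before <- net$horizon
  empty_report <- tibble::tibble(gap_start = integer(), gap_length = integer())
  if (nrow(ev) == 0L) {
    return(list(network = net, report = empty_report,
                summary = tibble::tibble(n_gaps = 0L, steps_removed = 0L,
                                         T_before = T_before, T_after = T_before)))
  }
  active <- sort(unique(ev$t))
  # zero runs between consecutive active steps (+ leading run before first)
  runs <- tibble::tibble(
    gap_start = c(0L, utils::head(active, -1L) + 1L),
    gap_length = c(active[1L], diff(active) - 1L)
  )
  runs <- runs[runs$gap_length > 0L, , drop = FALSE]
  internal <- runs$gap_start > 0L
  thr <- gap_threshold(runs$gap_length[internal], rule)
  remove <- runs[runs$gap_length > thr, , drop = FALSE]
  remove$collapsed_to <- ifelse(remove$gap_start == 0L, 0L, collapse_to)
  if (nrow(remove) == 0L) {
    return(list(network = net, report = empty_report,
                summary = tibble::tibble(n_gaps = 0L, steps_removed = 0L,
                                         T_before = T_before, T_after = T_before)))
  }
  # shift each event left by the total removed length of gaps before it
  removed_len <- remove$gap_length - remove$collapsed_to
  shift_at <- remove$gap_start  # times >= gap_start + gap_length shift left
  new_t <- ev$t
  for (k in seq_len(nrow(remove))) {
    new_t <- new_t - ifelse(ev$t >= shift_at[k] + remove$gap_length[k], removed_len[k], 0L)
  }
  steps_removed <- sum(removed_len)
  out <- net
  out$events <- dplyr::arrange(tibble::tibble(t = new_t, hid = ev$hid), .data$t, .data$hid)
  out$horizon <- T_before - steps_removed
  # trailing inactivity: keep horizon bookkeeping consistent with invariants
  list(
    network = out,
    report = remove[, c("gap_start", "gap_length")],
    summary = tibble::tibble(n_gaps = nrow(remove), steps_removed = steps_removed,
                             T_before = T_before, T_after = T_before - steps_removed)
  )
}

gap_threshold <- function(lengths, rule) {
  if (length(lengths) == 0L) return(Inf)
  switch(rule$method,
    tukey = {
      q <- stats::quantile(lengths, c(0.25, 0.75), names = FALSE, type = 7)
      q[2L] + rule$parameter * (q[2L] - q[1L])
    },
    quantile = stats::quantile(lengths, rule$parameter, names = FALSE, type = 7),
    fixed = rule$parameter
  )
}
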