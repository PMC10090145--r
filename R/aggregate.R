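#' Pairwise time-aggregated network
#'
#' Projects a temporal hypergraph onto the unweighted static graph `G` used
#' for node-to-node hop counts: nodes `u`, `v` are linked iff they co-occur
#' in at least one event of any order (each event's node set becomes a
#' clique). For pairwise contact data this is exactly the classical
#' aggregated contact graph; for intrinsically higher-order data it is the
#' co-membership projection.
#'
#' @param net A `temporal_hypergraph`.
#' @return A `pairwise_graph`: list with `n` (node count), `labels`,
#'   `edges` (tibble `u`, `v` of dense ids with `u < v`), and `graph`
#'   (the equivalent igraph object, used for shortest paths and components).
#' @export
aggregate_pairwise <- function(net) {
  hl <- net$hyperlinks
  if (nrow(hl) == 0L) {
    ed <- tibble::tibble(u = integer(), v = integer())
  } else {
    pairs <- purrr::map(hl$nodes, function(v) {
      if (length(v) == 2L) return(matrix(v, ncol = 2L))
      t(utils::combn(v, 2L))
    })
    m <- do.call(rbind, pairs)
    ed <- tibble::tibble(u = m[, 1L], v = m[, 2L])
    ed <- dplyr::distinct(ed)
    ed <- dplyr::arrange(ed, .data$u, .data$v)
  }
  g <- igraph::make_empty_graph(n = length(net$labels), directed = FALSE)
  if (nrow(ed) > 0L) {
    g <- igraph::add_edges(g, rbind(ed$u, ed$v))
  }
  structure(
    list(n = length(net$labels), labels = net$labels, edges = ed, graph = g),
    class = "pairwise_graph"
  )
}

#' @export
print.pairwise_graph <- function(x, ...) {
  cat("<pairwise_graph> ", x$n, " nodes, ", nrow(x$edges), " links\n", sep = "")
  invisible(x)
}

#' Weighted higher-order time-aggregated hypergraph
#'
#' The static hypergraph `H`: one entry per hyperlink activated at least
#' once, weighted by its activation count. Weights sum to the total number
#' of events.
#'
#' @param net A `temporal_hypergraph`.
#' @return A tibble of class `aggregated_hypergraph` with columns `hid`,
#'   `order`, `nodes` (list of dense ids), `key`, `weight`.
#' @export
aggregate_hypergraph <- function(net) {
  w <- dplyr::count(net$events, .data$hid, name = "weight")
  out <- dplyr::left_join(net$hyperlinks, w, by = "hid")
  out$weight[is.na(out$weight)] <- 0L
  out <- out[out$weight > 0L, , drop = FALSE]
  class(out) <- c("aggregated_hypergraph", class(out))
  out
}

#' Hop counts on the pairwise aggregated graph
#'
#' Breadth-first-search shortest-path lengths (number of links) between
#' nodes of `G`; unreachable pairs are `Inf`.
#'
#' @param G A `pairwise_graph` from [aggregate_pairwise()].
#' @param sources,targets Dense node ids (default: all nodes).
#' @return Numeric matrix of hop counts, `length(sources)` x
#'   `length(targets)`, with dimnames the ids.
#' @export
node_distances <- function(G, sources = NULL, targets = NULL) {
  sources <- sources %||% seq_len(G$n)
  targets <- targets %||% seq_len(G$n)
  m <- igraph::distances(G$graph, v = sources, to = targets, algorithm = "unweighted")
  dimnames(m) <- list(sources, targets)
  m
}
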