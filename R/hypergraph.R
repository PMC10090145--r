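#' Temporal hypergraph objects
#'
#' A temporal hypergraph records a node set together with timestamped
#' hyperevents: activations `(h, t)` of a hyperlink `h` (a set of `d >= 2`
#' nodes, its *order*) at a discrete time step `t` on a clock of `horizon`
#' steps of duration `dt` native time units each. Pairwise contact data are
#' the special case where every event has order 2.
#'
#' Internally nodes carry dense integer ids `1..n` in first-appearance order
#' of their external labels; hyperlink identity is the sorted id tuple (set
#' semantics, no multiplicity), and the `(hyperlink, t)` event multiset
#' contains no duplicates.
#'
#' @param events A data frame with columns `t` (non-negative integer time
#'   steps) and `nodes` (a list column of character label vectors, or a
#'   character column of comma-separated labels). Each node set must have at
#'   least two distinct labels.
#' @param horizon Total number of time steps `T`; events must satisfy
#'   `t < horizon`. Defaults to `max(t) + 1` (0 for an empty event table).
#' @param dt Duration of one time step in native units (default 1).
#' @param dt_unit Native time unit, e.g. `"s"` or `"d"`.
#' @param contact_type Free-text provenance tag (e.g. `"physical"`).
#'
#' @return An object of class `temporal_hypergraph`: a list with elements
#'   `labels` (external node labels, position = dense id), `hyperlinks`
#'   (tibble: `hid`, `order`, `nodes` list of sorted dense ids, `key`),
#'   `events` (tibble: `t`, `hid`), `horizon`, `dt`, `dt_unit`,
#'   `contact_type`.
#'
#' @examples
#' net <- temporal_hypergraph(
#'   tibble::tibble(t = c(0L, 0L, 3L), nodes = list(c("a", "b"), c("a", "b", "c"), c("a", "b")))
#' )
#' order_census(net)
#' @export
temporal_hypergraph <- function(events, horizon = NULL, dt = 1, dt_unit = "s",
                                contact_type = NA_character_) {
  stopifnot(is.data.frame(events))
  if (nrow(events) == 0L) {
    return(new_temporal_hypergraph(
      labels = character(), horizon = as.integer(horizon %||% 0L),
      node_sets = list(), times = integer(),
      dt = dt, dt_unit = dt_unit, contact_type = contact_type
    ))
  }
  stopifnot(all(c("t", "nodes") %in% names(events)))
  node_sets <- events$nodes
  if (is.character(node_sets)) node_sets <- strsplit(node_sets, ",", fixed = TRUE)
  node_sets <- lapply(node_sets, as.character)
  t <- as.integer(events$t)
  if (anyNA(t) || any(t < 0L)) stop("event times must be non-negative integers")
  bad <- vapply(node_sets, function(x) length(x) < 2L || anyDuplicated(x) > 0L, logical(1))
  if (any(bad)) {
    stop("event node sets must contain >= 2 distinct labels (rows: ",
         paste(utils::head(which(bad), 5L), collapse = ", "), ")")
  }
  labels <- unique(unlist(node_sets, use.names = FALSE))
  ids <- lapply(node_sets, function(x) sort(match(x, labels)))
  new_temporal_hypergraph(
    labels = labels,
    node_sets = ids, times = t,
    horizon = as.integer(horizon %||% (max(t) + 1L)),
    dt = dt, dt_unit = dt_unit, contact_type = contact_type
  )
}

# Internal constructor from dense-id node sets (already sorted) + times.
# Collapses duplicate (hyperlink, t) records silently (binary activity).
new_temporal_hypergraph <- function(labels, node_sets, times, horizon,
                                    dt = 1, dt_unit = "s",
                                    contact_type = NA_character_) {
  stopifnot(length(node_sets) == length(times))
  keys <- vapply(node_sets, paste, character(1), collapse = "-")
  ukeys <- unique(keys)
  hid <- match(keys, ukeys)
  unodes <- node_sets[!duplicated(keys)]
  hyperlinks <- tibble::tibble(
    hid = seq_along(ukeys),
    order = lengths(unodes),
    nodes = unodes,
    key = ukeys
  )
  ev <- tibble::tibble(t = as.integer(times), hid = hid)
  dup <- duplicated(ev)
  if (any(dup)) ev <- ev[!dup, , drop = FALSE]
  ev <- dplyr::arrange(ev, .data$t, .data$hid)
  horizon <- as.integer(horizon)
  if (nrow(ev) > 0L && max(ev$t) >= horizon) {
    stop("event time >= horizon (T = ", horizon, ")")
  }
  structure(
    list(
      labels = labels, hyperlinks = hyperlinks, events = ev,
      horizon = horizon, dt = dt, dt_unit = dt_unit,
      contact_type = contact_type, n_duplicates_dropped = sum(dup)
    ),
    class = "temporal_hypergraph"
  )
}

# Rebuild a network keeping node table / metadata, replacing events given as
# (hid, t) against the existing hyperlink table.
hg_replace_events <- function(net, t, hid) {
  keep <- hid %in% net$hyperlinks$hid
  stopifnot(all(keep))
  used <- sort(unique(hid))
  hl <- net$hyperlinks[net$hyperlinks$hid %in% used, , drop = FALSE]
  # re-densify hyperlink ids
  new_hid <- match(hid, hl$hid)
  hl$hid <- seq_len(nrow(hl))
  ev <- tibble::tibble(t = as.integer(t), hid = new_hid)
  ev <- ev[!duplicated(ev), , drop = FALSE]
  ev <- dplyr::arrange(ev, .data$t, .data$hid)
  out <- net
  out$hyperlinks <- hl
  out$events <- ev
  out
}

#' @export
print.temporal_hypergraph <- function(x, ...) {
  cen <- order_census(x)
  cat("<temporal_hypergraph>\n")
  cat("  nodes:      ", length(x$labels), "\n", sep = "")
  cat("  hyperlinks: ", nrow(x$hyperlinks), "\n", sep = "")
  cat("  events:     ", nrow(x$events), "\n", sep = "")
  cat("  horizon:    ", x$horizon, " steps of ", x$dt, " ", x$dt_unit, "\n", sep = "")
  if (nrow(cen) > 0L) {
    cat("  orders:     ",
        paste(sprintf("d=%d (%d links, %d events)", cen$order, cen$n_hyperlinks, cen$n_events),
              collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Number of nodes / node labels of a temporal hypergraph
#' @param net A `temporal_hypergraph`.
#' @return `n_nodes()`: integer count. `node_labels()`: character vector of
#'   external labels ordered by dense id.
#' @export
n_nodes <- function(net) length(net$labels)

#' @rdname n_nodes
#' @export
node_labels <- function(net) net$labels

#' Events of a temporal hypergraph as a tibble
#'
#' @param net A `temporal_hypergraph`.
#' @param labels If `TRUE`, render node sets as comma-joined external labels;
#'   otherwise as hyphen-joined dense ids.
#' @return A tibble with one row per event: `t`, `order`, `hid`, `nodes`.
#' @export
hg_events <- function(net, labels = TRUE) {
  hl <- net$hyperlinks
  idx <- match(net$events$hid, hl$hid)
  nodes <- if (labels) {
    vapply(hl$nodes[idx], function(v) paste(net$labels[v], collapse = ","), character(1))
  } else {
    hl$key[idx]
  }
  tibble::tibble(t = net$events$t, order = hl$order[idx], hid = net$events$hid, nodes = nodes)
}

#' @rdname hg_events
#' @method as_tibble temporal_hypergraph
#' @export
as_tibble.temporal_hypergraph <- function(x, ...) hg_events(x)

#' Hyperlink table of a temporal hypergraph
#' @param net A `temporal_hypergraph`.
#' @return Tibble with `hid`, `order`, `nodes` (list of dense ids), `key`.
#' @export
hyperlinks <- function(net) net$hyperlinks

#' Binary activity series of one hyperlink
#'
#' The activity series of a hyperlink is the strictly increasing collection
#' of time steps at which it is active (binary semantics: a step is active
#' or not, duplicates never occur).
#'
#' @param net A `temporal_hypergraph`.
#' @param nodes Node labels (character vector) or dense ids (integer vector)
#'   identifying the hyperlink as a set.
#' @return Sorted integer vector of activation steps; empty if the hyperlink
#'   never occurs.
#' @export
activity_series <- function(net, nodes) {
  ids <- if (is.character(nodes)) match(nodes, net$labels) else as.integer(nodes)
  if (anyNA(ids)) return(integer())
  key <- paste(sort(ids), collapse = "-")
  hid <- net$hyperlinks$hid[match(key, net$hyperlinks$key)]
  if (is.na(hid)) return(integer())
  sort(net$events$t[net$events$hid == hid])
}

#' Census of hyperlinks and events by order
#'
#' @param net A `temporal_hypergraph`.
#' @return Tibble with one row per order present: `order`, `n_hyperlinks`
#'   (distinct hyperlinks of that order), `n_events` (activations). Column
#'   sums equal the total hyperlink and event counts.
#' @export
order_census <- function(net) {
  if (nrow(net$events) == 0L) {
    return(tibble::tibble(order = integer(), n_hyperlinks = integer(), n_events = integer()))
  }
  hl <- net$hyperlinks
  ev_order <- hl$order[match(net$events$hid, hl$hid)]
  links <- dplyr::count(hl, .data$order, name = "n_hyperlinks")
  evs <- dplyr::count(tibble::tibble(order = ev_order), .data$order, name = "n_events")
  dplyr::arrange(dplyr::left_join(links, evs, by = "order"), .data$order)
}

#' Basic descriptives of a temporal hypergraph
#'
#' One-row summary in the conventional form used to describe empirical
#' higher-order evolving networks: node, hyperlink and event counts, the
#' observation window length in steps, and the step duration.
#'
#' @param net A `temporal_hypergraph`.
#' @return One-row tibble: `n_nodes`, `n_hyperlinks`, `n_events`, `T`,
#'   `dt`, `dt_unit`, `contact_type`.
#' @export
hg_descriptives <- function(net) {
  tibble::tibble(
    n_nodes = length(net$labels),
    n_hyperlinks = nrow(net$hyperlinks),
    n_events = nrow(net$events),
    T = net$horizon,
    dt = net$dt,
    dt_unit = net$dt_unit,
    contact_type = net$contact_type
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
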