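#' Egonetwork of a hyperlink
#'
#' The topological neighborhood of an order-`d` hyperlink `h` in the
#' aggregated hypergraph: `h` itself plus every hyperlink of order strictly
#' lower than `d` sharing at least one node with it. Equal-order or
#' higher-order neighbours are not members. For `d = 2` there are no
#' lower-order hyperlinks, so the egonetwork is the singleton center.
#'
#' @param H An `aggregated_hypergraph` from [aggregate_hypergraph()].
#' @param center The center hyperlink: its `hid`, or an integer vector of
#'   dense node ids identifying it as a set.
#' @return A tibble of class `hg_egonetwork`: the member rows of `H`
#'   (center first) plus a logical `is_center` column; attribute
#'   `center_hid`.
#' @export
build_egonetwork <- function(H, center) {
  if (length(center) == 1L && center %in% H$hid) {
    chid <- as.integer(center)
  } else {
    key <- paste(sort(as.integer(center)), collapse = "-")
    chid <- H$hid[match(key, H$key)]
    if (is.na(chid)) stop("center hyperlink not present in the aggregated hypergraph")
  }
  crow <- H[H$hid == chid, , drop = FALSE]
  cnodes <- crow$nodes[[1L]]
  d <- crow$order
  lower <- H[H$order < d, , drop = FALSE]
  shares <- vapply(lower$nodes, function(v) any(v %in% cnodes), logical(1))
  out <- dplyr::bind_rows(crow, lower[shares, , drop = FALSE])
  out$is_center <- c(TRUE, rep(FALSE, sum(shares)))
  attr(out, "center_hid") <- chid
  class(out) <- c("hg_egonetwork", class(out))
  out
}

#' Aggregated activity series of an egonetwork
#'
#' The pointwise sum of the binary activity series of the member
#' hyperlinks: for each time step with activity, how many member hyperlinks
#' are active. Total mass equals the sum of member weights.
#'
#' @param net A `temporal_hypergraph`.
#' @param ego An `hg_egonetwork` from [build_egonetwork()].
#' @return A tibble: `t`, `count` (only steps with `count >= 1`).
#' @export
ego_activity <- function(net, ego) {
  ev <- net$events[net$events$hid %in% ego$hid, , drop = FALSE]
  if (nrow(ev) == 0L) return(tibble::tibble(t = integer(), count = integer()))
  dplyr::count(ev, .data$t, name = "count")
}

#' Detect event trains in an activity series
#'
#' A train is a maximal sequence of consecutive events whose inter-event
#' times are shorter than or equal to `delta_t` and that is separated from
#' other events by a gap larger than `delta_t`. Inter-event times are
#' measured between consecutive active steps; simultaneous events at one
#' step contribute to a train's size, not to its gaps. The size of a train
#' is the number of events it contains (summed activity over its span).
#'
#' @param activity A tibble with columns `t` and `count` (as from
#'   [ego_activity()]), or an integer vector of active steps (unit counts).
#' @param delta_t Reference temporal interval in steps (`>= 1`); a gap of
#'   exactly `delta_t` still joins.
#' @param center_times Integer vector of activation steps of the center
#'   hyperlink, used to flag center-active trains.
#' @return A tibble: `start`, `end`, `size`, `center_active` (TRUE iff a
#'   center activation falls inside `[start, end]`).
#' @export
detect_trains <- function(activity, delta_t, center_times = integer()) {
  stopifnot(delta_t >= 1)
  if (is.atomic(activity)) {
    activity <- dplyr::count(tibble::tibble(t = as.integer(activity)),
                             .data$t, name = "count")
  }
  if (nrow(activity) == 0L) {
    return(tibble::tibble(start = integer(), end = integer(),
                          size = integer(), center_active = logical()))
  }
  activity <- dplyr::arrange(activity, .data$t)
  gaps <- diff(activity$t)
  grp <- cumsum(c(1L, as.integer(gaps > delta_t)))
  out <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(t = activity$t, count = activity$count, grp = grp),
                    .data$grp),
    start = min(.data$t), end = max(.data$t), size = sum(.data$count),
    .groups = "drop"
  )
  tibble::tibble(
    start = out$start, end = out$end, size = out$size,
    center_active = vapply(seq_len(nrow(out)), function(i) {
      any(center_times >= out$start[i] & center_times <= out$end[i])
    }, logical(1))
  )
}

#' Center-active train size distribution
#'
#' Pools the event trains detected in the aggregated activity series of the
#' egonetworks centered at *each* order-`d` hyperlink, keeps the trains in
#' which the center hyperlink is activated at least once, and reports their
#' empirical size distribution and mean. Trains from overlapping
#' egonetworks are pooled without deduplication (one series, and hence one
#' train set, per center). A mean size exceeding the one measured on the
#' order-`d` null models signals temporal clustering of local events around
#' the center's activations.
#'
#' @param net A `temporal_hypergraph`.
#' @param d Center order (at least one order-`d` hyperlink required).
#' @param delta_t Train-joining interval in steps (see [detect_trains()]).
#' @return A tibble of class `hg_train_dist`: `size`, `n`, `prob`.
#'   Attributes: `d`, `delta_t`, `mean_size`, `n_trains`, and `trains`
#'   (the pooled per-train records with their center `hid`).
#' @export
train_size_distribution <- function(net, d, delta_t) {
  H <- aggregate_hypergraph(net)
  centers <- H$hid[H$order == d]
  if (length(centers) == 0L) stop("no hyperlinks of order ", d)
  series_of <- split(net$events$t, net$events$hid)
  pooled <- purrr::map_dfr(centers, function(ch) {
    ego <- build_egonetwork(H, ch)
    act <- ego_activity(net, ego)
    tr <- detect_trains(act, delta_t,
                        center_times = series_of[[as.character(ch)]] %||% integer())
    if (nrow(tr) > 0L) tr$center <- ch
    tr
  })
  keep <- pooled[pooled$center_active, , drop = FALSE]
  if (nrow(keep) == 0L) {
    out <- tibble::tibble(size = integer(), n = integer(), prob = numeric())
    warning("no center-active trains at delta_t = ", delta_t)
    mean_size <- NA_real_
  } else {
    out <- dplyr::count(keep, size = .data$size)
    out$prob <- out$n / sum(out$n)
    mean_size <- mean(keep$size)
  }
  attr(out, "d") <- d
  attr(out, "delta_t") <- delta_t
  attr(out, "mean_size") <- mean_size
  attr(out, "n_trains") <- nrow(keep)
  attr(out, "trains") <- pooled
  class(out) <- c("hg_train_dist", class(out))
  out
}

#' Mean center-active train size
#' @param dist An `hg_train_dist` from [train_size_distribution()].
#' @return The mean size (numeric scalar, possibly `NA`).
#' @export
mean_train_size <- function(dist) attr(dist, "mean_size")
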