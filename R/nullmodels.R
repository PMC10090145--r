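#' Order-targeted randomized reference models
#'
#' Three null models that randomize the events of one chosen order `d` while
#' leaving events of every other order untouched. All three preserve the
#' node set, the unweighted aggregated hypergraph `H` (hence also the
#' pairwise aggregated graph `G`), and the distribution of the temporal
#' distance of two random order-`d` events:
#'
#' * **H1** — timestamp reshuffle: the multiset of order-`d` timestamps is
#'   randomly permuted across order-`d` events, keeping each event's
#'   hyperlink. Per-hyperlink activation counts are preserved, but
#'   within-hyperlink temporal structure (burstiness) is destroyed. Should a
#'   permutation land two identical `(h, t)` records, it is repaired by
#'   random transpositions; in the (pathological) case where no collision-free
#'   permutation is found the input is returned with a warning.
#' * **H2** — activity-series swap: the activity series of the order-`d`
#'   hyperlinks are reassigned by one uniform random permutation (the
#'   stationary distribution of iterated random series swaps). Each series
#'   survives intact — the order-`d` inter-event time distribution is
#'   preserved — but becomes independent of its topological location, and
#'   hyperlink weights redistribute.
#' * **H3** — weight-matched series swap: as H2, but series are permuted only
#'   within groups of order-`d` hyperlinks having equal total activations,
#'   so every hyperlink keeps its weight exactly. When all order-`d` weights
#'   are distinct the model is the identity.
#'
#' @param net A `temporal_hypergraph`.
#' @param d Target order (`>= 2`).
#' @param seed Integer seed; every realization is reproducible from it.
#' @param model One of `"H1"`, `"H2"`, `"H3"` (for `randomize_events()`).
#' @return A randomized `temporal_hypergraph`.
#' @export
randomize_events <- function(net, d, seed, model = c("H1", "H2", "H3")) {
  model <- match.arg(model)
  switch(model,
    H1 = randomize_h1(net, d, seed),
    H2 = randomize_h2(net, d, seed),
    H3 = randomize_h3(net, d, seed)
  )
}

#' @rdname randomize_events
#' @export
randomize_h1 <- function(net, d, seed) {
  restore <- local_seed_expr(seed)
  on.exit(restore(), add = TRUE)
  ord <- net$hyperlinks$order[match(net$events$hid, net$hyperlinks$hid)]
  idx <- which(ord == d)
  if (length(idx) < 2L) return(net)
  hid_d <- net$events$hid[idx]
  t_new <- sample(net$events$t[idx])
  # repair (h, t) collisions by random transpositions
  max_tries <- 100L * length(idx)
  tries <- 0L
  repeat {
    dup <- which(duplicated(paste(hid_d, t_new)) |
                   duplicated(paste(hid_d, t_new), fromLast = TRUE))
    if (length(dup) == 0L) break
    tries <- tries + 1L
    if (tries > max_tries) {
      warning("H1: no collision-free timestamp permutation found; returning input")
      return(net)
    }
    a <- dup[sample.int(length(dup), 1L)]
    b <- sample.int(length(idx), 1L)
    tmp <- t_new[a]; t_new[a] <- t_new[b]; t_new[b] <- tmp
  }
  out <- net
  t_all <- net$events$t
  t_all[idx] <- t_new
  out$events <- dplyr::arrange(tibble::tibble(t = t_all, hid = net$events$hid),
                               .data$t, .data$hid)
  out
}

#' @rdname randomize_events
#' @export
randomize_h2 <- function(net, d, seed) {
  restore <- local_seed_expr(seed)
  on.exit(restore(), add = TRUE)
  permute_series(net, d, function(hids) sample(hids))
}

#' @rdname randomize_events
#' @export
randomize_h3 <- function(net, d, seed) {
  restore <- local_seed_expr(seed)
  on.exit(restore(), add = TRUE)
  w <- dplyr::count(net$events, .data$hid, name = "weight")
  permute_series(net, d, function(hids) {
    ws <- w$weight[match(hids, w$hid)]
    out <- hids
    for (g in unique(ws)) {
      grp <- which(ws == g)
      if (length(grp) > 1L) out[grp] <- hids[grp][sample.int(length(grp))]
    }
    out
  })
}

# Reassign activity series among order-d hyperlinks via `perm_fun`, which
# maps the vector of order-d hids to a permutation of it (hid i receives
# the series of perm[i]).
permute_series <- function(net, d, perm_fun) {
  hl <- net$hyperlinks
  hids <- hl$hid[hl$order == d]
  hids <- hids[hids %in% net$events$hid]
  if (length(hids) < 2L) return(net)
  donor <- perm_fun(hids)       # hids[i] takes the series of donor[i]
  series_of <- split(net$events$t, net$events$hid)
  ord_ev <- hl$order[match(net$events$hid, hl$hid)]
  keep <- net$events[ord_ev != d, , drop = FALSE]
  new_t <- unlist(series_of[as.character(donor)], use.names = FALSE)
  new_hid <- rep(hids, lengths(series_of[as.character(donor)]))
  out <- net
  out$events <- dplyr::arrange(
    tibble::tibble(t = c(keep$t, new_t), hid = c(keep$hid, new_hid)),
    .data$t, .data$hid
  )
  out
}
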