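#' Topological distance between two events
#'
#' The topological distance between two events is the distance between
#' their hyperlinks on the unweighted pairwise aggregated graph `G`: zero
#' when the two events activate the same hyperlink, otherwise one plus the
#' minimum hop count between a component node of the first and a component
#' node of the second. Two different hyperlinks sharing a node are at
#' distance 1. The temporal location of the events plays no role.
#'
#' @param e1,e2 Events given as integer vectors of dense node ids, or lists
#'   with a `nodes` element (the time component, if present, is ignored).
#' @param G A `pairwise_graph` from [aggregate_pairwise()] of the full
#'   network (all orders).
#' @return A non-negative number; `Inf` if every node pair is unreachable.
#' @export
event_distance <- function(e1, e2, G) {
  n1 <- sort(as.integer(if (is.list(e1)) e1$nodes else e1))
  n2 <- sort(as.integer(if (is.list(e2)) e2$nodes else e2))
  if (identical(n1, n2)) return(0)
  min(node_distances(G, n1, n2)) + 1
}

# Hyperlink-to-hyperlink event distances: rows = node-set list `a`,
# cols = node-set list `b`; 0 where the sorted sets coincide.
hyperlink_distance_matrix <- function(G, a, b) {
  used <- sort(unique(c(unlist(a), unlist(b))))
  D <- node_distances(G, used, used)
  pos <- function(v) match(v, used)
  col_min <- function(m) {  # row-wise minimum of a matrix
    do.call(pmin, lapply(seq_len(ncol(m)), function(j) m[, j]))
  }
  # bmin[u, jb]: min hop count from used node u to any node of b[[jb]]
  bmin <- vapply(b, function(v) col_min(D[, pos(v), drop = FALSE]),
                 numeric(length(used)))
  bmin <- matrix(bmin, nrow = length(used))
  res <- vapply(a, function(v) {
    col_min(t(bmin[pos(v), , drop = FALSE])) + 1
  }, numeric(length(b)))
  M <- if (length(b) == 1L) matrix(res, ncol = 1L) else t(res)
  ka <- vapply(a, paste, character(1), collapse = "-")
  kb <- vapply(b, paste, character(1), collapse = "-")
  M[outer(ka, kb, "==")] <- 0
  M
}

#' Conditional distance-delay curve
#'
#' For a chosen order `d`, measures how topologically close events are,
#' given that they occur within a temporal delay `Delta t` of each other.
#' With `kind = "cross_order"` the pair population is (order-`d` event,
#' event of any other order); with `kind = "same_order"` it is the unordered
#' pairs of distinct order-`d` events (pairs of events on the same hyperlink
#' contribute distance 0). For every grid value the curve reports the mean
#' topological distance over pairs whose delay is strictly smaller than
#' `Delta t`, and that mean normalized by the unconditional mean over the
#' whole pair population — so the normalized curve tends to 1 as
#' `Delta t` grows beyond the largest delay. Values below 1 at short delays
#' mean events close in time are also close in topology.
#'
#' The exact estimator enumerates every pair; above `max_exact_pairs` pairs
#' (or on request) a seeded uniform sample of pairs is used instead and
#' per-point standard errors are reported.
#'
#' @param net A `temporal_hypergraph`.
#' @param d Event order whose temporal-topological correlation is probed.
#' @param kind `"cross_order"` or `"same_order"`.
#' @param grid Increasing positive delays in steps; default 50
#'   log-spaced integers from 1 to the horizon (deduplicated).
#' @param estimator `"auto"` (exact below `max_exact_pairs`), `"exact"`, or
#'   `"sampled"`.
#' @param sample_size Number of pairs drawn by the sampled estimator.
#' @param seed Seed for the sampled estimator (mandatory there).
#' @param max_exact_pairs Pair-count switch point for `"auto"`.
#' @param G Pairwise aggregated graph; defaults to
#'   `aggregate_pairwise(net)` of the full network. Null-model realizations
#'   preserve `G`, so one graph can be shared across comparisons.
#' @return A tibble of class `hg_distance_curve`: `dt_steps`, `n_pairs`
#'   (pairs with delay < `dt_steps`), `mean_dist`, `normalized`, `se`
#'   (NA for the exact estimator). Attributes: `kind`, `d`,
#'   `unconditional_mean`, `estimator`, `total_pairs`, `horizon`.
#' @export
distance_curve <- function(net, d, kind = c("cross_order", "same_order"),
                           grid = NULL, estimator = c("auto", "exact", "sampled"),
                           sample_size = 1e6, seed = NULL,
                           max_exact_pairs = 2e7, G = NULL) {
  kind <- match.arg(kind)
  estimator <- match.arg(estimator)
  ev <- hg_events(net, labels = FALSE)
  A <- ev[ev$order == d, , drop = FALSE]
  B <- if (kind == "cross_order") ev[ev$order != d, , drop = FALSE] else A
  if (nrow(A) == 0L) stop("no events of order ", d)
  if (kind == "cross_order" && nrow(B) == 0L) stop("no events of order != ", d)
  if (kind == "same_order" && nrow(A) < 2L) stop("need >= 2 events of order ", d)
  G <- G %||% aggregate_pairwise(net)
  grid <- grid %||% default_delay_grid(net$horizon)
  stopifnot(all(grid > 0), !is.unsorted(grid, strictly = TRUE))

  hla <- unique(A$hid)
  hlb <- unique(B$hid)
  sets <- net$hyperlinks$nodes[match(c(hla, hlb), net$hyperlinks$hid)]
  M <- hyperlink_distance_matrix(G, sets[seq_along(hla)],
                                 sets[-seq_along(hla)])
  ai <- match(A$hid, hla)
  bi <- match(B$hid, hlb)
  total_pairs <- if (kind == "cross_order") {
    as.numeric(nrow(A)) * nrow(B)
  } else {
    as.numeric(nrow(A)) * (nrow(A) - 1) / 2
  }
  if (estimator == "auto") {
    estimator <- if (total_pairs <= max_exact_pairs) "exact" else "sampled"
  }

  if (estimator == "exact") {
    eta <- M[ai, bi, drop = FALSE]
    td <- abs(outer(A$t, B$t, "-"))
    if (kind == "same_order") {
      sel <- upper.tri(eta)
      eta <- eta[sel]
      td <- td[sel]
    } else {
      eta <- as.vector(eta)
      td <- as.vector(td)
    }
  } else {
    if (is.null(seed)) stop("sampled estimator requires a seed")
    withr_seed <- local_seed_expr(seed)
    on.exit(withr_seed(), add = TRUE)
    S <- as.integer(sample_size)
    if (kind == "cross_order") {
      i <- sample.int(nrow(A), S, replace = TRUE)
      j <- sample.int(nrow(B), S, replace = TRUE)
    } else {
      i <- sample.int(nrow(A), S, replace = TRUE)
      j <- sample.int(nrow(A) - 1L, S, replace = TRUE)
      j <- ifelse(j >= i, j + 1L, j)  # uniform over ordered distinct pairs
    }
    eta <- M[cbind(ai[i], bi[j])]
    td <- abs(A$t[i] - B$t[j])
  }
  bad <- !is.finite(eta)
  n_unreachable <- sum(bad)
  if (n_unreachable > 0L) {
    warning(n_unreachable, " unreachable event pair(s) dropped; ",
            "consider restrict_to_lcc()")
    eta <- eta[!bad]
    td <- td[!bad]
  }
  ord <- order(td)
  td <- td[ord]
  eta <- eta[ord]
  csum <- cumsum(eta)
  csq <- cumsum(eta^2)
  uncond <- mean(eta)
  counts <- findInterval(grid - 1e-9, td)  # pairs with delay < grid value
  mean_dist <- ifelse(counts > 0L, csum[pmax(counts, 1L)] / counts, NA_real_)
  se <- rep(NA_real_, length(grid))
  if (estimator == "sampled") {
    varr <- ifelse(counts > 1L,
                   (csq[pmax(counts, 1L)] - counts * mean_dist^2) / (counts - 1L),
                   NA_real_)
    se <- sqrt(pmax(varr, 0) / counts) / uncond
  }
  out <- tibble::tibble(
    dt_steps = grid,
    n_pairs = counts,
    mean_dist = mean_dist,
    normalized = mean_dist / uncond,
    se = se
  )
  attr(out, "kind") <- kind
  attr(out, "d") <- d
  attr(out, "unconditional_mean") <- uncond
  attr(out, "estimator") <- estimator
  attr(out, "total_pairs") <- total_pairs
  attr(out, "horizon") <- net$horizon
  class(out) <- c("hg_distance_curve", class(out))
  out
}

default_delay_grid <- function(horizon) {
  if (horizon <= 1L) return(1L)
  unique(as.integer(round(10^seq(0, log10(horizon), length.out = 50L))))
}

#' Slope of the increasing part of a distance-delay curve
#'
#' Summarizes the strength of temporal-topological correlation as the slope
#' `m` of the normalized curve against `log10(Delta t)` (units: change per
#' decade of delay), fitted over the increasing part: from the minimum of
#' the normalized curve (ties broken towards the largest delay) to the last
#' defined grid point. The fit is least squares, weighted by the pair count
#' behind each grid point (low-count points at short delays carry
#' proportionally less information); `weights = "none"` gives ordinary
#' least squares. If fewer than 3 defined points remain after the minimum,
#' the whole curve is fitted and the result flagged.
#'
#' @param curve An `hg_distance_curve` with at least 3 defined points.
#' @param weights `"pairs"` (default) or `"none"`.
#' @return An object of class `hg_slope_fit`: list with `m`, `intercept`,
#'   `fit_range` (first and last grid index used), `r2`, `flagged`, and the
#'   curve metadata. [generics::tidy()] and [generics::glance()] methods
#'   return it in broom style.
#' @export
fit_increasing_slope <- function(curve, weights = c("pairs", "none")) {
  weights <- match.arg(weights)
  ok <- which(!is.na(curve$normalized) & curve$n_pairs > 0L)
  if (length(ok) < 3L) stop("need at least 3 defined grid points")
  y_ok <- curve$normalized[ok]
  i_min_rel <- max(which(y_ok == min(y_ok)))  # ties -> largest index
  range_idx <- ok[ok >= ok[i_min_rel]]
  flagged <- FALSE
  if (length(range_idx) < 3L) {
    range_idx <- ok
    flagged <- TRUE
  }
  x <- log10(curve$dt_steps[range_idx])
  y <- curve$normalized[range_idx]
  w <- if (weights == "pairs") as.numeric(curve$n_pairs[range_idx]) else NULL
  fit <- if (is.null(w)) stats::lm(y ~ x) else stats::lm(y ~ x, weights = w)
  sm <- suppressWarnings(summary(fit))  # perfect fits are legitimate here
  structure(
    list(
      m = unname(stats::coef(fit)[2L]),
      intercept = unname(stats::coef(fit)[1L]),
      fit_range = c(min(range_idx), max(range_idx)),
      r2 = sm$r.squared,
      se_m = unname(sm$coefficients[2L, 2L]),
      flagged = flagged,
      weights = weights,
      kind = attr(curve, "kind"),
      d = attr(curve, "d")
    ),
    class = "hg_slope_fit"
  )
}

#' @export
print.hg_slope_fit <- function(x, ...) {
  cat("<hg_slope_fit> m = ", signif(x$m, 4), " per decade (r2 = ",
      signif(x$r2, 3), ", grid points ", x$fit_range[1L], "..",
      x$fit_range[2L], if (x$flagged) ", flagged: full-curve fit" else "",
      ")\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy hg_slope_fit
#' @export
tidy.hg_slope_fit <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "log10_dt"),
    estimate = c(x$intercept, x$m),
    std.error = c(NA_real_, x$se_m)
  )
}

#' @method glance hg_slope_fit
#' @export
glance.hg_slope_fit <- function(x, ...) {
  tibble::tibble(
    m = x$m, intercept = x$intercept, r2 = x$r2, se_m = x$se_m,
    fit_from = x$fit_range[1L], fit_to = x$fit_range[2L],
    flagged = x$flagged, kind = x$kind %||% NA_character_,
    d = x$d %||% NA_integer_
  )
}

# Seed randomness locally, restoring the caller's RNG state on exit.
local_seed_expr <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}
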