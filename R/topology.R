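#' Per-node degree and strength by order
#'
#' The `d`-degree `k_d(v)` of a node is the number of distinct order-`d`
#' hyperlinks it belongs to in the aggregated hypergraph; the `d`-strength
#' `s_d(v)` is the number of order-`d` events it is involved in, i.e. the
#' sum of the weights of its order-`d` hyperlinks. Only (node, order)
#' combinations with positive degree are listed; absence means zero. The
#' table satisfies, for every order, `sum(degree) = d * |L_d|` and
#' `sum(strength) = d * |E_d|`.
#'
#' @param net A `temporal_hypergraph`.
#' @return A tibble of class `hg_degree_strength`: `node` (label),
#'   `node_id`, `order`, `degree`, `strength`.
#' @export
degree_strength <- function(net) {
  H <- aggregate_hypergraph(net)
  if (nrow(H) == 0L) {
    out <- tibble::tibble(node = character(), node_id = integer(),
                          order = integer(), degree = integer(),
                          strength = integer())
  } else {
    long <- tibble::tibble(
      node_id = unlist(H$nodes),
      order = rep(H$order, H$order),
      weight = rep(H$weight, H$order)
    )
    out <- dplyr::summarise(
      dplyr::group_by(long, .data$node_id, .data$order),
      degree = dplyr::n(), strength = sum(.data$weight), .groups = "drop"
    )
    out <- dplyr::arrange(out, .data$node_id, .data$order)
    out <- dplyr::mutate(out, node = net$labels[.data$node_id], .before = 1L)
  }
  class(out) <- c("hg_degree_strength", class(out))
  out
}

#' Mean activations per hyperlink of a given order
#'
#' `omega_d = |E_d| / |L_d|`: the average number of activations of an
#' order-`d` hyperlink. It is the constant of the approximately linear
#' relation `s_d(v) ~ omega_d * k_d(v)` between a node's `d`-strength and
#' `d`-degree.
#'
#' @param net A `temporal_hypergraph`.
#' @param d Order with at least one hyperlink.
#' @return A positive number.
#' @export
omega <- function(net, d) {
  cen <- order_census(net)
  row <- cen[cen$order == d, , drop = FALSE]
  if (nrow(row) == 0L) stop("no hyperlinks of order ", d)
  row$n_events / row$n_hyperlinks
}

#' Cross-order degree (or strength) relation curve
#'
#' Compares a node's order-`d` and order-`d2` participation: restricted to
#' nodes where both quantities are non-zero, each axis is normalized by its
#' maximum over that restricted set, and the x axis is split into 30
#' logarithmic bins; each bin reports the mean normalized y. A curve lying
#' on the diagonal `y = x` indicates proportional participation across the
#' two orders. A Spearman rank correlation over the restricted node set is
#' attached as a scalar summary of the (in)dependence.
#'
#' @param table An `hg_degree_strength` table from [degree_strength()].
#' @param d,d2 The two orders compared (x axis: `d`; y axis: `d2`).
#' @param which `"degree"` or `"strength"`.
#' @param bins Number of bins (default 30).
#' @return A tibble of class `hg_binned_curve`: `bin`, `x_lo`, `x_hi`,
#'   `x_mid` (geometric mid), `x_mean`, `y_mean`, `n`. Empty bins are
#'   omitted. Attributes: `which`, `d`, `d2`, `scale = "log"`, `spearman`,
#'   `n_nodes`.
#' @export
cross_order_relation <- function(table, d, d2, which = c("degree", "strength"),
                                 bins = 30L) {
  which <- match.arg(which)
  xt <- table[table$order == d, c("node_id", which)]
  yt <- table[table$order == d2, c("node_id", which)]
  names(xt)[2L] <- "x"
  names(yt)[2L] <- "y"
  xy <- dplyr::inner_join(xt, yt, by = "node_id")
  xy <- xy[xy$x > 0 & xy$y > 0, , drop = FALSE]
  if (nrow(xy) == 0L) {
    out <- empty_binned_curve()
  } else {
    xn <- xy$x / max(xy$x)
    yn <- xy$y / max(xy$y)
    out <- bin_curve(xn, yn, bins = bins, scale = "log")
  }
  attr(out, "which") <- which
  attr(out, "d") <- d
  attr(out, "d2") <- d2
  attr(out, "scale") <- "log"
  attr(out, "spearman") <- if (nrow(xy) >= 3L) {
    suppressWarnings(stats::cor(xy$x, xy$y, method = "spearman"))
  } else NA_real_
  attr(out, "n_nodes") <- nrow(xy)
  class(out) <- c("hg_binned_curve", class(out))
  out
}

#' Strength versus degree at one order
#'
#' Bins nodes by their `d`-degree (30 linear bins) and reports the mean
#' `d`-strength normalized by `omega_d`. Under proportional activity the
#' curve lies on the reference diagonal `y = x`; it does so exactly when
#' every order-`d` hyperlink has the same number of activations, and in
#' expectation under the H2 null model.
#'
#' @param net A `temporal_hypergraph`.
#' @param d Order with at least one hyperlink.
#' @param bins Number of linear bins (default 30).
#' @param table Optional precomputed [degree_strength()] table.
#' @return A tibble of class `hg_binned_curve` as in
#'   [cross_order_relation()], with `x` the raw degree and `y_mean` the
#'   mean of `strength / omega_d`. Attribute `omega` holds `omega_d`.
#' @export
strength_vs_degree <- function(net, d, bins = 30L, table = NULL) {
  table <- table %||% degree_strength(net)
  sub <- table[table$order == d, , drop = FALSE]
  om <- omega(net, d)
  if (nrow(sub) == 0L) {
    out <- empty_binned_curve()
  } else {
    out <- bin_curve(sub$degree, sub$strength / om, bins = bins, scale = "linear")
  }
  attr(out, "which") <- "strength_vs_degree"
  attr(out, "d") <- d
  attr(out, "scale") <- "linear"
  attr(out, "omega") <- om
  attr(out, "n_nodes") <- nrow(sub)
  class(out) <- c("hg_binned_curve", class(out))
  out
}

empty_binned_curve <- function() {
  tibble::tibble(bin = integer(), x_lo = numeric(), x_hi = numeric(),
                 x_mid = numeric(), x_mean = numeric(), y_mean = numeric(),
                 n = integer())
}

# Bin y by x into `bins` log- or linear-spaced bins spanning the data.
# Intervals are (lo, hi]; a point on an edge joins the left (lower) bin;
# the lowest edge is inclusive.
bin_curve <- function(x, y, bins = 30L, scale = c("log", "linear")) {
  scale <- match.arg(scale)
  stopifnot(length(x) == length(y), all(x > 0 | scale == "linear"))
  lo <- min(x)
  hi <- max(x)
  if (lo == hi) {
    return(tibble::tibble(bin = 1L, x_lo = lo, x_hi = hi, x_mid = lo,
                          x_mean = lo, y_mean = mean(y), n = length(y)))
  }
  edges <- if (scale == "log") {
    exp(seq(log(lo), log(hi), length.out = bins + 1L))
  } else {
    seq(lo, hi, length.out = bins + 1L)
  }
  edges[1L] <- lo
  edges[bins + 1L] <- hi
  idx <- findInterval(x, edges, left.open = TRUE, rightmost.closed = FALSE)
  idx[x <= edges[1L]] <- 1L  # lowest edge inclusive
  idx <- pmin(idx, bins)
  df <- tibble::tibble(bin = idx, x = x, y = y)
  out <- dplyr::summarise(
    dplyr::group_by(df, .data$bin),
    x_mean = mean(.data$x), y_mean = mean(.data$y), n = dplyr::n(),
    .groups = "drop"
  )
  out <- dplyr::arrange(out, .data$bin)
  mid <- if (scale == "log") sqrt(edges[-1L] * edges[-(bins + 1L)]) else
    (edges[-1L] + edges[-(bins + 1L)]) / 2
  tibble::tibble(
    bin = out$bin,
    x_lo = edges[out$bin],
    x_hi = edges[out$bin + 1L],
    x_mid = mid[out$bin],
    x_mean = out$x_mean,
    y_mean = out$y_mean,
    n = out$n
  )
}
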