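#' End-to-end temporal-topological characterization
#'
#' Runs the full analysis battery on a higher-order temporal network: order
#' census and descriptives; for each requested order, the conditional
#' distance-delay curve with its increasing-part slope for the observed
#' network and for each realization of each requested null model;
#' degree/strength tables, cross-order and strength-degree curves; and the
#' center-active train-size summary. Null-model statistics are reported per
#' realization so means and spreads over realizations can be formed
#' downstream.
#'
#' @param net A `temporal_hypergraph`.
#' @param orders Event orders to analyze (default 3).
#' @param null_models Subset of `c("H1", "H2", "H3")`.
#' @param realizations Independent null realizations per model (default 10).
#' @param seed Integer seed; realization `r` of model `m` uses a seed
#'   derived deterministically from it.
#' @param kind Curve population, as in [distance_curve()].
#' @param grid Delay grid (default as in [distance_curve()]).
#' @param delta_t Train-joining intervals in steps (default `c(60, 120)`).
#' @param out_dir Optional directory: when given, every table is also
#'   written as TSV (floats with 6 significant digits) and the summary as
#'   JSON-free TSV logs.
#' @return A list: `descriptives`, `census`, `degree_strength`, `omega`
#'   (tibble order/omega), `slopes` (tibble: order, network, realization,
#'   m, r2, flagged), `curves` (named list of `hg_distance_curve`),
#'   `trains` (tibble: order, network, realization, delta_t, mean_size,
#'   n_trains), `cross_order` (list of binned curves).
#' @export
run_characterize <- function(net, orders = 3L,
                             null_models = c("H1", "H2", "H3"),
                             realizations = 10L, seed = 1L,
                             kind = "cross_order", grid = NULL,
                             delta_t = c(60L, 120L), out_dir = NULL) {
  stopifnot(all(null_models %in% c("H1", "H2", "H3")))
  G <- aggregate_pairwise(net)
  ds <- degree_strength(net)
  cen <- order_census(net)
  omega_tbl <- dplyr::mutate(cen, omega = .data$n_events / .data$n_hyperlinks)

  slopes <- list(); curves <- list(); trains <- list()
  for (d in orders) {
    cv <- distance_curve(net, d, kind = kind, grid = grid, G = G)
    curves[[paste0("d", d, "_observed")]] <- cv
    sf <- glance(fit_increasing_slope(cv))
    slopes[[length(slopes) + 1L]] <- dplyr::mutate(
      sf, order = d, network = "observed", realization = NA_integer_, .before = 1L)
    for (dt_tr in delta_t) {
      td <- train_size_distribution(net, d, dt_tr)
      trains[[length(trains) + 1L]] <- tibble::tibble(
        order = d, network = "observed", realization = NA_integer_,
        delta_t = dt_tr, mean_size = mean_train_size(td),
        n_trains = attr(td, "n_trains"))
    }
    for (mdl in null_models) {
      for (r in seq_len(realizations)) {
        sd_r <- derive_seed(seed, d, match(mdl, c("H1", "H2", "H3")), r)
        rnet <- randomize_events(net, d, seed = sd_r, model = mdl)
        cvr <- distance_curve(rnet, d, kind = kind, grid = grid, G = G)
        sfr <- glance(fit_increasing_slope(cvr))
        slopes[[length(slopes) + 1L]] <- dplyr::mutate(
          sfr, order = d, network = .env$mdl, realization = r, .before = 1L)
        for (dt_tr in delta_t) {
          tdr <- train_size_distribution(rnet, d, dt_tr)
          trains[[length(trains) + 1L]] <- tibble::tibble(
            order = d, network = mdl, realization = r, delta_t = dt_tr,
            mean_size = mean_train_size(tdr), n_trains = attr(tdr, "n_trains"))
        }
      }
    }
  }
  cross <- list()
  present <- sort(cen$order)
  for (i in seq_along(present)) {
    for (j in seq_along(present)) {
      if (i < j) {
        key <- paste0("k", present[j], "_vs_k", present[i])
        cross[[key]] <- cross_order_relation(ds, present[i], present[j], "degree")
      }
    }
  }
  for (d in intersect(orders, present)) {
    cross[[paste0("s_vs_k_d", d)]] <- strength_vs_degree(net, d, table = ds)
  }
  out <- list(
    descriptives = hg_descriptives(net),
    census = cen,
    degree_strength = ds,
    omega = omega_tbl[, c("order", "omega")],
    slopes = dplyr::bind_rows(slopes),
    curves = curves,
    trains = dplyr::bind_rows(trains),
    cross_order = cross
  )
  if (!is.null(out_dir)) write_characterization(out, out_dir)
  out
}

# Deterministic sub-seed, kept within 32-bit integer range.
derive_seed <- function(seed, ...) {
  v <- as.numeric(c(seed, ...))
  as.integer(sum(v * 31^(seq_along(v) - 1)) %% 2147483647)
}

write_characterization <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) write_tsv6(df, file.path(out_dir, paste0(name, ".tsv")))
  wr(res$descriptives, "descriptives")
  wr(res$census, "census")
  wr(res$degree_strength, "degree_strength")
  wr(res$omega, "omega")
  wr(res$slopes, "slopes")
  wr(res$trains, "trains")
  for (nm in names(res$curves)) wr(res$curves[[nm]], paste0("curve_", nm))
  for (nm in names(res$cross_order)) wr(res$cross_order[[nm]], paste0("curve_", nm))
  invisible(out_dir)
}

#' Write a tibble as TSV with 6-significant-digit floats
#' @param df A data frame (list columns are dropped).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv6 <- function(df, path) {
  df <- df[, !vapply(df, is.list, logical(1)), drop = FALSE]
  df <- dplyr::mutate(df, dplyr::across(dplyr::where(is.double), ~ signif(.x, 6)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
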