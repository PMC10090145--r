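#' Read a pairwise contact list ("tij" dialect)
#'
#' Parses whitespace-separated lines `t i j`: an integer timestamp followed
#' by two node labels, the format in which face-to-face contact data are
#' commonly distributed (e.g. SocioPatterns). Lines starting with `#` are
#' comments; columns beyond the first three are ignored. Raw timestamps are
#' rescaled to a dense 0-based step clock: divided by `dt` (inferred as the
#' gcd of distinct inter-record differences when not supplied) and shifted so
#' the first step is 0. Duplicate records collapse to one event; self-loop
#' lines (`i == j`) are dropped with a warning.
#'
#' @param path Path to the contact file.
#' @param dt Step duration in native units; `NULL` (default) infers it.
#' @param dt_unit Native time unit of the raw timestamps (default `"s"`).
#' @param contact_type Free-text provenance tag.
#' @return A `temporal_hypergraph` whose events are all order 2.
#' @export
read_contact_list <- function(path, dt = NULL, dt_unit = "s",
                              contact_type = "physical") {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(temporal_hypergraph(tibble::tibble(t = integer(), nodes = list()),
                               horizon = 0L, dt = dt %||% 1, dt_unit = dt_unit,
                               contact_type = contact_type))
  }
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("malformed contact line (need 't i j') at line ",
         lineno[which(nf < 3L)[1]])
  }
  t_raw <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 1L)))
  if (anyNA(t_raw)) {
    stop("non-numeric timestamp at line ", lineno[which(is.na(t_raw))[1]])
  }
  i <- vapply(fields, `[[`, character(1), 2L)
  j <- vapply(fields, `[[`, character(1), 3L)
  self <- i == j
  if (any(self)) {
    warning(sum(self), " self-loop contact line(s) dropped (first at line ",
            lineno[which(self)[1]], ")")
    t_raw <- t_raw[!self]; i <- i[!self]; j <- j[!self]
  }
  if (length(t_raw) == 0L) {
    return(temporal_hypergraph(tibble::tibble(t = integer(), nodes = list()),
                               horizon = 0L, dt = dt %||% 1, dt_unit = dt_unit,
                               contact_type = contact_type))
  }
  sc <- rescale_times(t_raw, dt)
  temporal_hypergraph(
    tibble::tibble(t = sc$t, nodes = purrr::map2(i, j, c)),
    dt = sc$dt, dt_unit = dt_unit, contact_type = contact_type
  )
}

#' Read / write a hyperevent list
#'
#' The native serialization of a temporal hypergraph: one event per line,
#' `t<TAB>label1,label2,...` with at least two distinct labels per line.
#' The writer emits events sorted by time then lexicographic node tuple, so
#' output is byte-stable; `read_hyperevent_list()` then reproduces the event
#' multiset exactly (node table in first-appearance order). Set
#' `rescale = TRUE` (or pass `dt`) to apply the contact-reader clock
#' normalization (gcd rescaling and shift-to-zero) to raw timestamps
#' instead of taking times as written.
#'
#' @param path File path.
#' @param dt Step duration; with `rescale = TRUE` and `dt = NULL` the step is
#'   inferred as the gcd of inter-record differences.
#' @param rescale Apply clock normalization (default `FALSE`: times are
#'   already steps).
#' @param dt_unit,contact_type Metadata, as in [read_contact_list()].
#' @return `read_hyperevent_list()`: a `temporal_hypergraph`.
#' @export
read_hyperevent_list <- function(path, dt = NULL, rescale = !is.null(dt),
                                 dt_unit = "s", contact_type = NA_character_) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(temporal_hypergraph(tibble::tibble(t = integer(), nodes = list()),
                               horizon = 0L, dt = dt %||% 1, dt_unit = dt_unit,
                               contact_type = contact_type))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2L)) {
    stop("malformed hyperevent line (need 't<TAB>labels') at line ",
         lineno[which(lengths(parts) != 2L)[1]])
  }
  t_raw <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 1L)))
  if (anyNA(t_raw)) {
    stop("non-numeric timestamp at line ", lineno[which(is.na(t_raw))[1]])
  }
  node_sets <- strsplit(vapply(parts, `[[`, character(1), 2L), ",", fixed = TRUE)
  bad <- vapply(node_sets, function(x) length(x) < 2L || anyDuplicated(x) > 0L, logical(1))
  if (any(bad)) {
    stop("hyperevent with < 2 or repeated labels at line ", lineno[which(bad)[1]])
  }
  t_step <- if (rescale) rescale_times(t_raw, dt)$t else as.integer(t_raw)
  step <- if (rescale) rescale_times(t_raw, dt)$dt else (dt %||% 1)
  temporal_hypergraph(
    tibble::tibble(t = t_step, nodes = node_sets),
    dt = step, dt_unit = dt_unit, contact_type = contact_type
  )
}

#' @param net A `temporal_hypergraph` to serialize.
#' @rdname read_hyperevent_list
#' @return `write_hyperevent_list()`: `path`, invisibly.
#' @export
write_hyperevent_list <- function(net, path) {
  ev <- hg_events(net, labels = TRUE)
  # canonical rendering: labels sorted lexicographically within each tuple
  ev$nodes <- vapply(strsplit(ev$nodes, ",", fixed = TRUE),
                     function(x) paste(sort(x, method = "radix"), collapse = ","),
                     character(1))
  ev <- ev[order(ev$t, ev$nodes, method = "radix"), , drop = FALSE]
  writeLines(sprintf("%d\t%s", ev$t, ev$nodes), path)
  invisible(path)
}

# Normalize raw timestamps to 0-based integer steps.
rescale_times <- function(t_raw, dt = NULL) {
  if (is.null(dt)) {
    ts <- sort(unique(t_raw))
    d <- diff(ts)
    dt <- if (length(d) == 0L) 1 else Reduce(gcd2, d)
    if (dt <= 0) dt <- 1
  }
  list(t = as.integer(round((t_raw - min(t_raw)) / dt)), dt = dt)
}

gcd2 <- function(a, b) {
  while (b > 1e-9) {
    r <- a %% b
    a <- b
    b <- r
  }
  a
}
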