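#' Discretize a network's growth into evolutionary events
#'
#' Each distinct relative age present among the (dated) nodes is one event;
#' the network grows as a step function over events. The snapshot at event
#' `k` is the subnetwork induced by every node with `age_nd` less than or
#' equal to the event's age; a link first appears at the age of its younger
#' endpoint, so snapshots are nested and the last snapshot is the full
#' (dated) network. Undated nodes are excluded with a message.
#'
#' @param net An [ef_bipartite()] network or an `ef_projection`, ages set.
#' @return An object of class `ef_events`: the source `network`, an
#'   `events` tibble (`event`, `nd`, `n_new_nodes`, `n_nodes`, `n_links`)
#'   and a list `snapshots` of subnetworks, one per event.
#' @examples
#' out <- synth_ef(synth_config(seed = 1))
#' net <- transfer_loop_ages(out$network, out$ages)
#' ev <- build_events(net)
#' ev$events
#' @export
build_events <- function(net) {
  UseMethod("build_events")
}

#' @export
build_events.ef_bipartite <- function(net) {
  undated <- sum(is.na(net$loops$age_nd)) + sum(is.na(net$domains$age_nd))
  if (undated == nrow(net$loops) + nrow(net$domains)) {
    abort("No dated nodes: set ages before building events.")
  }
  if (undated > 0) {
    inform(sprintf("Excluding %d undated node(s) from the event series.",
                   undated))
  }
  all_ages <- c(net$loops$age_nd, net$domains$age_nd)
  nds <- sort(unique(all_ages[!is.na(all_ages)]))
  snapshots <- lapply(nds, function(t) bipartite_snapshot(net, t))
  finish_events(net, nds, all_ages, snapshots,
                vapply(snapshots, function(s) nrow(s$edges), numeric(1)),
                vapply(snapshots, function(s) nrow(s$loops) + nrow(s$domains),
                       numeric(1)))
}

#' @export
build_events.ef_projection <- function(net) {
  all_ages <- net$nodes$age_nd
  if (all(is.na(all_ages))) abort("No dated nodes: set ages before building events.")
  nds <- sort(unique(all_ages[!is.na(all_ages)]))
  snapshots <- lapply(nds, function(t) projection_snapshot(net, t))
  finish_events(net, nds, all_ages, snapshots,
                vapply(snapshots, function(s) nrow(s$arcs), numeric(1)),
                vapply(snapshots, function(s) nrow(s$nodes), numeric(1)))
}

finish_events <- function(net, nds, all_ages, snapshots, n_links, n_nodes) {
  ages_ok <- all_ages[!is.na(all_ages)]
  structure(list(
    network = net,
    events = tibble(
      event = seq_along(nds),
      nd = nds,
      n_new_nodes = vapply(nds, function(t) sum(ages_ok == t), numeric(1)),
      n_nodes = n_nodes,
      n_links = n_links
    ),
    snapshots = snapshots
  ), class = "ef_events")
}

bipartite_snapshot <- function(net, t) {
  loops <- filter(net$loops, !is.na(.data$age_nd), .data$age_nd <= t)
  domains <- filter(net$domains, !is.na(.data$age_nd), .data$age_nd <= t)
  edges <- filter(net$edges, .data$loop_id %in% loops$loop_id,
                  .data$sf_id %in% domains$sf_id)
  structure(list(loops = loops, domains = domains, edges = edges),
            class = "ef_bipartite")
}

projection_snapshot <- function(p, t) {
  nodes <- filter(p$nodes, !is.na(.data$age_nd), .data$age_nd <= t)
  arcs <- filter(p$arcs, .data$from %in% nodes$id, .data$to %in% nodes$id)
  new_projection(p$mode, nodes, arcs)
}

#' @export
print.ef_events <- function(x, ...) {
  cat(sprintf("<ef_events> %d events over nd [%.3g, %.3g] on a %s\n",
              nrow(x$events), min(x$events$nd), max(x$events$nd),
              class(x$network)[1]))
  invisible(x)
}

#' Chronological accumulation of connections by partner age bin
#'
#' Coarse-grains the timeline into `n_bins` equal-width age bins and, for
#' every node of a projection, counts its arc partners per bin of the
#' *partner's* age, split by direction: outgoing partners appear later in
#' evolution (the node donates), incoming partners appear earlier (the node
#' accepts). Bins are half-open `[l, r)` with the last bin closed; bin 1 is
#' the oldest.
#'
#' @param p An `ef_projection` with ages set.
#' @param n_bins Number of equal-width bins over `[0, 1]`; default 10.
#' @return A tibble `id`, `age_nd`, `direction` (`"out"`/`"in"`), `bin`,
#'   `count`, with zero-count combinations omitted.
#' @export
accumulation_bins <- function(p, n_bins = 10) {
  stopifnot(inherits(p, "ef_projection"))
  if (n_bins < 1) abort("`n_bins` must be >= 1.")
  if (nrow(p$arcs) == 0) {
    return(tibble(id = character(), age_nd = numeric(),
                  direction = character(), bin = integer(), count = integer()))
  }
  age <- setNames(p$nodes$age_nd, p$nodes$id)
  bin_of <- function(nd) pmin(floor(nd * n_bins) + 1L, n_bins)
  bind_rows(
    p$arcs |>
      mutate(id = .data$from, partner = .data$to, direction = "out"),
    p$arcs |>
      mutate(id = .data$to, partner = .data$from, direction = "in")
  ) |>
    mutate(bin = unname(bin_of(age[.data$partner])),
           age_nd = unname(age[.data$id])) |>
    count(.data$id, .data$age_nd, .data$direction, .data$bin, name = "count") |>
    arrange(.data$id, .data$direction, .data$bin)
}

#' Normalized mean degree along an event series
#'
#' At each event, the snapshot's mean degree divided by its maximum degree
#' (0 when the maximum is 0) — a scale-independent reference curve for the
#' per-event statistics. Degrees are cumulative (links accumulated up to the
#' event) and, for projections, weighted by arc weight unless
#' `weighted = FALSE`.
#'
#' @param series An `ef_events` object.
#' @param which `"all"`, `"in"` or `"out"` (`"in"`/`"out"` only for
#'   projections).
#' @param weighted Use arc weights (projections only)? Default `TRUE`.
#' @return A tibble `event`, `nd`, `value`.
#' @export
normalized_mean_degree <- function(series, which = c("all", "in", "out"),
                                   weighted = TRUE) {
  stopifnot(inherits(series, "ef_events"))
  which <- match.arg(which)
  vals <- purrr::map_dbl(series$snapshots, function(s) {
    deg <- snapshot_degrees(s, which, weighted)
    if (length(deg) == 0 || max(deg) == 0) 0 else mean(deg) / max(deg)
  })
  tibble(event = series$events$event, nd = series$events$nd, value = vals)
}

snapshot_degrees <- function(s, which = "all", weighted = TRUE,
                             side = NULL) {
  if (inherits(s, "ef_bipartite")) {
    if (which != "all") abort("Bipartite networks have no arc directions.")
    if (is.null(side)) {
      c(bipartite_degrees(s, "loop"), bipartite_degrees(s, "domain"))
    } else {
      bipartite_degrees(s, side)
    }
  } else {
    w <- if (weighted) s$arcs$weight else rep(1, nrow(s$arcs))
    out <- setNames(rep(0, nrow(s$nodes)), s$nodes$id)
    inn <- out
    if (nrow(s$arcs)) {
      a <- tapply(w, s$arcs$from, sum)
      out[names(a)] <- a
      b <- tapply(w, s$arcs$to, sum)
      inn[names(b)] <- b
    }
    switch(which, all = out + inn, `in` = inn, out = out)
  }
}
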