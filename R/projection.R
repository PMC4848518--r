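new_projection <- function(mode, nodes, arcs) {
  structure(list(mode = mode, nodes = as_tibble(nodes), arcs = as_tibble(arcs)),
            class = "ef_projection")
}

#' @export
print.ef_projection <- function(x, ...) {
  cat(sprintf("<ef_projection mode=%s> %d nodes, %d arcs (density %.4g)\n",
              x$mode, nrow(x$nodes), nrow(x$arcs),
              directed_density(x)))
  invisible(x)
}

#' Time-directed unimodal projection of a bipartite network
#'
#' Projects the bipartite network onto one node class. Two loops are linked
#' when they are embedded in at least one common domain (they combine in the
#' same structural scaffold); two domains are linked when they embody at
#' least one common loop motif. Each link becomes a single arc directed from
#' the strictly older node to the younger one, weighted by the number of
#' shared counterpart nodes. For contemporary (equal-aged) endpoints the
#' direction is drawn uniformly at random under the current RNG state, or
#' lexicographically by id when `tiebreak = "lexicographic"`.
#'
#' @param net An [ef_bipartite()] network with all node ages set.
#' @param mode `"loop"` or `"domain"`: which node class to keep.
#' @param tiebreak `"seed"` (random, reproducible under [set.seed()]) or
#'   `"lexicographic"` (deterministic).
#' @return An `ef_projection`: node tibble (`id`, `age_nd`, `age_gy`) and arc
#'   tibble (`from`, `to`, `weight`).
#' @examples
#' out <- synth_ef(synth_config(seed = 1))
#' net <- transfer_loop_ages(out$network, out$ages)
#' project(net, "loop", tiebreak = "lexicographic")
#' @export
project <- function(net, mode = c("loop", "domain"),
                    tiebreak = c("seed", "lexicographic")) {
  stopifnot(inherits(net, "ef_bipartite"))
  mode <- match.arg(mode)
  tiebreak <- match.arg(tiebreak)

  if (mode == "loop") {
    nodes <- net$loops |> rename(id = "loop_id")
    own <- "loop_id"; counterpart <- "sf_id"
  } else {
    nodes <- net$domains |> rename(id = "sf_id")
    own <- "sf_id"; counterpart <- "loop_id"
  }
  connected <- unique(net$edges[[own]])
  if (any(is.na(nodes$age_nd[nodes$id %in% connected]))) {
    abort("All connected node ages must be set before projecting.")
  }

  e <- net$edges
  pairs <- inner_join(
    e |> select(u = dplyr::all_of(own), c = dplyr::all_of(counterpart)),
    e |> select(v = dplyr::all_of(own), c = dplyr::all_of(counterpart)),
    by = "c", relationship = "many-to-many"
  ) |>
    filter(.data$u < .data$v) |>
    count(.data$u, .data$v, name = "weight")

  age <- setNames(nodes$age_nd, nodes$id)
  au <- age[pairs$u]; av <- age[pairs$v]
  older_first <- au < av
  ties <- au == av
  if (any(ties)) {
    if (tiebreak == "seed") {
      older_first[ties] <- runif(sum(ties)) < 0.5
    } else {
      older_first[ties] <- TRUE  # u < v already lexicographic
    }
  }
  arcs <- tibble(
    from = unname(ifelse(older_first, pairs$u, pairs$v)),
    to = unname(ifelse(older_first, pairs$v, pairs$u)),
    weight = pairs$weight
  )
  new_projection(mode, nodes, arcs)
}

#' Density of a directed projection
#'
#' Arcs divided by ordered node pairs, `|arcs| / (n (n - 1))`.
#'
#' @param p An `ef_projection`.
#' @return A single number.
#' @export
directed_density <- function(p) {
  stopifnot(inherits(p, "ef_projection"))
  n <- nrow(p$nodes)
  if (n < 2) return(NA_real_)
  nrow(p$arcs) / (n * (n - 1))
}

#' Source/sink profile of a projection
#'
#' Weighted out- and indegree per node (sums of arc weights), plus a
#' donor/acceptor classification: a node is a donor (source) when its
#' weighted outdegree exceeds its weighted indegree — it lends its motif or
#' scaffold to younger nodes — an acceptor (sink) in the reverse case, and
#' balanced otherwise. Unweighted arc counts are also reported, since the
#' two degree conventions differ.
#'
#' @param p An `ef_projection`.
#' @return A tibble with one row per node: `id`, `age_nd`, `outdegree`,
#'   `indegree` (weighted), `out_arcs`, `in_arcs`, `role`.
#' @export
source_sink_profile <- function(p) {
  stopifnot(inherits(p, "ef_projection"))
  wout <- p$arcs |> group_by(id = .data$from) |>
    summarise(outdegree = sum(.data$weight), out_arcs = n())
  win <- p$arcs |> group_by(id = .data$to) |>
    summarise(indegree = sum(.data$weight), in_arcs = n())
  p$nodes |>
    select("id", "age_nd") |>
    left_join(wout, by = "id") |>
    left_join(win, by = "id") |>
    mutate(dplyr::across(c("outdegree", "indegree", "out_arcs", "in_arcs"),
                         ~ tidyr::replace_na(.x, 0))) |>
    mutate(role = dplyr::case_when(
      .data$outdegree > .data$indegree ~ "donor",
      .data$outdegree < .data$indegree ~ "acceptor",
      TRUE ~ "balanced"
    ))
}
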