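#' Construct an elementary functionome (EF) bipartite network
#'
#' An EF network is an undirected, unweighted bipartite graph whose two node
#' classes are loop prototypes (ancestral 25-30 residue functional sequence
#' motifs, identified by numeric string labels) and SCOP superfamily domains
#' (identified by concise classification strings such as `"c.37.1"`). An edge
#' records the embedding of a loop motif in a domain's structural scaffold.
#' Nodes optionally carry a relative evolutionary age `age_nd` on a 0 (oldest)
#' to 1 (present) scale.
#'
#' @param edges Data frame with character columns `loop_id` and `sf_id`, one
#'   row per association. Duplicate rows are collapsed to a single edge.
#' @param loops Optional data frame with columns `loop_id` and (optionally)
#'   `age_nd`. Loops absent from `edges` are kept as isolated nodes.
#' @param domains Optional data frame with columns `sf_id` and (optionally)
#'   `age_nd`. Domains absent from `edges` are kept as isolated nodes.
#' @param strict If `TRUE`, malformed SCOP identifiers abort; otherwise the
#'   offending rows are dropped with a warning.
#'
#' @return An object of class `ef_bipartite`: a list with tibbles `loops`
#'   (`loop_id`, `age_nd`, `age_gy`), `domains` (`sf_id`, `age_nd`, `age_gy`)
#'   and `edges` (`loop_id`, `sf_id`).
#' @examples
#' net <- ef_bipartite(data.frame(
#'   loop_id = c("7", "6488", "7"),
#'   sf_id   = c("c.37.1", "c.37.1", "c.2.1")
#' ))
#' net
#' @export
ef_bipartite <- function(edges, loops = NULL, domains = NULL, strict = FALSE) {
  stopifnot(is.data.frame(edges))
  if (!all(c("loop_id", "sf_id") %in% names(edges))) {
    abort("`edges` must have columns `loop_id` and `sf_id`.")
  }
  edges <- tibble(
    loop_id = as.character(edges$loop_id),
    sf_id   = as.character(edges$sf_id)
  )

  bad <- !is_valid_sf_id(edges$sf_id)
  if (any(bad)) {
    if (strict) {
      abort(paste0(
        "Malformed SCOP superfamily id(s): ",
        paste(unique(edges$sf_id[bad]), collapse = ", ")
      ))
    }
    warn(sprintf("Dropping %d row(s) with malformed SCOP superfamily ids.",
                 sum(bad)))
    edges <- edges[!bad, ]
  }

  n_raw <- nrow(edges)
  edges <- distinct(edges)
  n_dup <- n_raw - nrow(edges)
  if (n_dup > 0) {
    inform(sprintf("Collapsed %d duplicate association(s).", n_dup))
  }

  loops <- normalize_node_table(loops, "loop_id", edges$loop_id)
  domains <- normalize_node_table(domains, "sf_id", edges$sf_id)
  if (any(!is_valid_sf_id(domains$sf_id))) {
    abort("Malformed SCOP superfamily id in `domains`.")
  }

  out <- structure(
    list(loops = loops, domains = domains, edges = edges),
    class = "ef_bipartite"
  )
  validate_ef_bipartite(out)
}

normalize_node_table <- function(tbl, id_col, ids_in_edges) {
  if (is.null(tbl)) {
    tbl <- tibble(!!id_col := unique(ids_in_edges))
  } else {
    stopifnot(is.data.frame(tbl), id_col %in% names(tbl))
    tbl <- as_tibble(tbl)
    tbl[[id_col]] <- as.character(tbl[[id_col]])
    missing <- setdiff(unique(ids_in_edges), tbl[[id_col]])
    if (length(missing)) {
      abort(sprintf("Edge endpoint(s) absent from node table: %s",
                    paste(head(missing, 5), collapse = ", ")))
    }
  }
  if (!"age_nd" %in% names(tbl)) tbl$age_nd <- NA_real_
  if (!"age_gy" %in% names(tbl)) tbl$age_gy <- NA_real_
  tbl[, c(id_col, "age_nd", "age_gy")]
}

validate_ef_bipartite <- function(net) {
  stopifnot(inherits(net, "ef_bipartite"))
  if (anyDuplicated(net$loops$loop_id)) abort("Duplicate loop ids.")
  if (anyDuplicated(net$domains$sf_id)) abort("Duplicate domain ids.")
  if (anyDuplicated(paste(net$edges$loop_id, net$edges$sf_id))) {
    abort("Duplicate edges.")
  }
  ages <- c(net$loops$age_nd, net$domains$age_nd)
  ages <- ages[!is.na(ages)]
  if (length(ages) && (min(ages) < 0 || max(ages) > 1)) {
    abort("Node ages must lie in [0, 1].")
  }
  net
}

#' @export
print.ef_bipartite <- function(x, ...) {
  cat(sprintf(
    "<ef_bipartite> %d loops, %d domains, %d edges (density %.4g)\n",
    nrow(x$loops), nrow(x$domains), nrow(x$edges),
    if (nrow(x$loops) && nrow(x$domains))
      nrow(x$edges) / (nrow(x$loops) * nrow(x$domains)) else NA_real_
  ))
  aged <- sum(!is.na(x$domains$age_nd))
  cat(sprintf("  domain ages set: %d/%d; loop ages set: %d/%d\n",
              aged, nrow(x$domains),
              sum(!is.na(x$loops$age_nd)), nrow(x$loops)))
  invisible(x)
}

#' Network density of a bipartite network
#'
#' The ratio of realized to possible loop-domain edges,
#' `|E| / (n_loops * n_domains)`.
#'
#' @param net An [ef_bipartite()] network.
#' @return A single number in `[0, 1]`.
#' @examples
#' net <- synth_ef(synth_config(seed = 1))$network
#' ef_density(net) # 134 / (38 * 82)
#' @export
ef_density <- function(net) {
  stopifnot(inherits(net, "ef_bipartite"))
  n1 <- nrow(net$loops)
  n2 <- nrow(net$domains)
  if (n1 == 0 || n2 == 0) abort("Density undefined: one node class is empty.")
  nrow(net$edges) / (n1 * n2)
}

#' Mean node degree of a bipartite network
#'
#' Mean number of edges per node over the union of both node classes,
#' `2E / (n_loops + n_domains)`, with its standard error (and standard
#' deviation) across nodes.
#'
#' @param net An [ef_bipartite()] network.
#' @return A one-row tibble with columns `mean`, `se`, `sd`, `n_nodes`.
#' @export
mean_degree <- function(net) {
  stopifnot(inherits(net, "ef_bipartite"))
  deg <- c(bipartite_degrees(net, "loop"), bipartite_degrees(net, "domain"))
  if (length(deg) == 0) abort("Network has no nodes.")
  tibble(
    mean = mean(deg),
    se = stats::sd(deg) / sqrt(length(deg)),
    sd = stats::sd(deg),
    n_nodes = length(deg)
  )
}

bipartite_degrees <- function(net, side = c("loop", "domain")) {
  side <- match.arg(side)
  if (side == "loop") {
    setNames(
      tabulate(factor(net$edges$loop_id, levels = net$loops$loop_id),
               nbins = nrow(net$loops)),
      net$loops$loop_id
    )
  } else {
    setNames(
      tabulate(factor(net$edges$sf_id, levels = net$domains$sf_id),
               nbins = nrow(net$domains)),
      net$domains$sf_id
    )
  }
}

#' Convert an EF network or projection to an igraph graph
#'
#' Bipartite networks become undirected bipartite graphs (vertex attribute
#' `type`: `FALSE` for loops, `TRUE` for domains); projections become directed
#' weighted graphs. Ages travel as vertex attributes `age_nd` and `age_gy`.
#'
#' @param x An `ef_bipartite` or `ef_projection` object.
#' @return An [igraph::graph] object.
#' @export
as_igraph <- function(x) UseMethod("as_igraph")

#' @export
as_igraph.ef_bipartite <- function(x) {
  verts <- bind_rows(
    tibble(name = x$loops$loop_id, type = FALSE,
           age_nd = x$loops$age_nd, age_gy = x$loops$age_gy),
    tibble(name = x$domains$sf_id, type = TRUE,
           age_nd = x$domains$age_nd, age_gy = x$domains$age_gy)
  )
  igraph::graph_from_data_frame(
    d = tibble(from = x$edges$loop_id, to = x$edges$sf_id),
    directed = FALSE, vertices = verts
  )
}

#' @export
as_igraph.ef_projection <- function(x) {
  igraph::graph_from_data_frame(
    d = x$arcs[, c("from", "to", "weight")],
    directed = TRUE,
    vertices = tibble(name = x$nodes$id, age_nd = x$nodes$age_nd,
                      age_gy = x$nodes$age_gy)
  )
}
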