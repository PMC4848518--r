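#' Weighted adjacency matrix over all nodes
#'
#' Bipartite networks yield the full symmetric 0/1 adjacency over loops and
#' domains; projections are symmetrized (the Newman-Girvan index is defined
#' on undirected weights) with arc weights kept.
#' @noRd
ef_adjacency <- function(net) {
  if (inherits(net, "ef_bipartite")) {
    ids <- c(net$loops$loop_id, net$domains$sf_id)
    A <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    if (nrow(net$edges)) {
      i <- match(net$edges$loop_id, ids)
      j <- match(net$edges$sf_id, ids)
      A[cbind(i, j)] <- 1
      A[cbind(j, i)] <- 1
    }
    A
  } else if (inherits(net, "ef_projection")) {
    ids <- net$nodes$id
    A <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    if (nrow(net$arcs)) {
      i <- match(net$arcs$from, ids)
      j <- match(net$arcs$to, ids)
      A[cbind(i, j)] <- A[cbind(i, j)] + net$arcs$weight
      A[cbind(j, i)] <- A[cbind(j, i)] + net$arcs$weight
    }
    A
  } else {
    abort("Unsupported network class.")
  }
}

ef_node_ids <- function(net) {
  if (inherits(net, "ef_bipartite")) c(net$loops$loop_id, net$domains$sf_id)
  else net$nodes$id
}

ef_node_ages <- function(net) {
  if (inherits(net, "ef_bipartite")) {
    setNames(c(net$loops$age_nd, net$domains$age_nd), ef_node_ids(net))
  } else {
    setNames(net$nodes$age_nd, net$nodes$id)
  }
}

check_partition <- function(net, partition) {
  ids <- ef_node_ids(net)
  part <- unclass(partition)
  if (is.null(names(part))) abort("`partition` must be named by node id.")
  uncovered <- setdiff(ids, names(part))
  if (length(uncovered)) {
    abort(sprintf("Partition does not cover node(s): %s",
                  paste(head(uncovered, 5), collapse = ", ")))
  }
  part[ids]
}

#' Newman-Girvan modularity of a network under a partition
#'
#' Evaluates `Q = 1/(2m) * sum_ij (A_ij - k_i k_j / (2m)) delta(c_i, c_j)`
#' with `m` the total edge weight, `A` the (symmetrized) weighted adjacency,
#' `k` the weighted degrees and `delta` the Kronecker delta on community
#' labels. Positive values indicate assortative mixing (connectivity within
#' communities), negative values disassortative mixing across them;
#' the index ranges over `[-1, 1]`.
#'
#' @param net An [ef_bipartite()] network or `ef_projection`.
#' @param partition Named vector of community labels covering every node
#'   (see [age_partition()], [detect_communities()]).
#' @return A single number in `[-1, 1]`.
#' @export
ng_modularity <- function(net, partition) {
  A <- ef_adjacency(net)
  part <- check_partition(net, partition)
  k <- rowSums(A)
  two_m <- sum(A)
  if (two_m == 0) return(0)
  S <- outer(part, part, "==")
  sum((A - outer(k, k) / two_m) * S) / two_m
}

#' Community quality index (VQ)
#'
#' The community-quality sum over communities of the within-community edge
#' fraction minus the squared degree fraction, `sum_i (e_ii - a_i^2)`, with
#' `e_ii = sum_{v,w in c_i} A_vw / (2m)` and `a_i = k_i / (2m)`. On any
#' network this equals the Newman-Girvan modularity of the same partition;
#' it is computed here by independent community-block summation. (Printed
#' statements of this sum sometimes index it over pairs `i < j` of
#' communities; the `e`/`a` definitions and the 0-1 range only cohere under
#' the diagonal-block reading, which is the one implemented.)
#'
#' @inheritParams ng_modularity
#' @return A single number.
#' @export
quality_index <- function(net, partition) {
  A <- ef_adjacency(net)
  part <- check_partition(net, partition)
  two_m <- sum(A)
  if (two_m == 0) return(0)
  comms <- unique(part)
  vals <- vapply(comms, function(cc) {
    inside <- part == cc
    e_ii <- sum(A[inside, inside, drop = FALSE]) / two_m
    a_i <- sum(rowSums(A)[inside]) / two_m
    e_ii - a_i^2
  }, numeric(1))
  sum(vals)
}

#' Average clustering coefficient
#'
#' The mean over nodes of the ratio of triangles to connected triples in the
#' simplified (undirected, unweighted) graph; nodes with fewer than two
#' neighbours contribute 0. Bipartite graphs contain no triangles, so the
#' coefficient is only meaningful for unipartite graphs (projections) and
#' calling it on a bipartite network is an error.
#'
#' @param net An `ef_projection` or an [igraph::graph] object.
#' @return A number in `[0, 1]`.
#' @export
clustering_coefficient <- function(net) {
  if (inherits(net, "ef_bipartite")) {
    abort("The clustering coefficient is only meaningful for unipartite graphs; project the network first.")
  }
  g <- if (inherits(net, "ef_projection")) as_igraph(net) else net
  stopifnot(igraph::is_igraph(g))
  g <- igraph::as_undirected(igraph::simplify(g), mode = "collapse")
  if (igraph::vcount(g) == 0) return(NA_real_)
  loc <- igraph::transitivity(g, type = "local", isolates = "zero")
  mean(loc)
}

#' Regression of the clustering coefficient on network size and age
#'
#' For a growing projection, the per-event clustering coefficient `C` is
#' regressed (OLS on log-log scale) against snapshot size `N` and against
#' snapshot age `nd`; the slopes are the scaling exponents `C ~ N^b` and
#' `C ~ nd^b`. Scale-free growth drives `C` down as `N^-0.75`, whereas
#' exponents near zero indicate size-independent (hierarchically modular)
#' clustering. Events with `C = 0`, `N = 0` or `nd = 0` are excluded from
#' the respective regression (their count is reported).
#'
#' @param series An `ef_events` object over a projection.
#' @return A one-row tibble: `exponent_N`, `exponent_nd`, `n_used_N`,
#'   `n_used_nd`, `n_dropped_N`, `n_dropped_nd`, `ok`.
#' @export
c_regressions <- function(series) {
  stopifnot(inherits(series, "ef_events"))
  if (!inherits(series$network, "ef_projection")) {
    abort("C regressions are defined on projection event series.")
  }
  C <- purrr::map_dbl(series$snapshots, clustering_coefficient)
  N <- series$events$n_nodes
  nd <- series$events$nd

  fit_exponent <- function(y, x) {
    keep <- y > 0 & x > 0 & !is.na(y)
    if (sum(keep) < 3) return(list(b = NA_real_, n = sum(keep)))
    list(b = unname(coef(lm(log(y[keep]) ~ log(x[keep])))[2]), n = sum(keep))
  }
  fN <- fit_exponent(C, N)
  fnd <- fit_exponent(C, nd)
  tibble(
    exponent_N = fN$b, exponent_nd = fnd$b,
    n_used_N = fN$n, n_used_nd = fnd$n,
    n_dropped_N = length(C) - fN$n, n_dropped_nd = length(C) - fnd$n,
    ok = !is.na(fN$b) && !is.na(fnd$b)
  )
}

#' Partition of a network's nodes by age (event membership)
#'
#' Groups nodes by their distinct `age_nd` value, so each community is one
#' evolutionary event. Links joining equal-aged nodes are intra-event links.
#' Undated nodes (necessarily isolated, since connected nodes inherit ages)
#' are pooled into one extra community; having degree 0 they contribute
#' nothing to any modularity index.
#'
#' @param net An [ef_bipartite()] network or `ef_projection` with ages set
#'   on all connected nodes.
#' @return An `ef_partition`: named integer vector of event indices.
#' @export
age_partition <- function(net) {
  ages <- ef_node_ages(net)
  lev <- sort(unique(ages[!is.na(ages)]))
  labels <- match(ages, lev)
  if (anyNA(labels)) {
    A <- ef_adjacency(net)
    if (any(rowSums(A)[is.na(labels)] > 0)) {
      abort("Undated node with links: set ages before partitioning by age.")
    }
    labels[is.na(labels)] <- length(lev) + 1L
  }
  structure(setNames(labels, names(ages)),
            class = "ef_partition", method = "age")
}

#' Detect communities in a network
#'
#' Community detection on the simplified undirected weighted graph:
#' `"fgc"` is fast-greedy hierarchical agglomeration (modularity
#' maximization with a merge dendrogram), `"wtc"` is the walktrap
#' random-walk method (walk length 4 by default), and `"vos"` is
#' similarity-based modularity maximization (multilevel/Louvain) scored by
#' the [quality_index()] — a stand-in for layout-coupled VOS clustering, so
#' exact community counts from VOS runs are not expected to reproduce.
#' Connected components are handled independently by all three methods.
#'
#' @param net An [ef_bipartite()] network, `ef_projection`, or igraph graph.
#' @param method `"fgc"`, `"wtc"` or `"vos"`.
#' @param walk_steps Walk length for `"wtc"`; default 4.
#' @param seed Optional RNG seed, making `"vos"` deterministic.
#' @return An `ef_partition` (named integer labels) with attributes
#'   `method`, `quality` (the [quality_index()] of the partition),
#'   `n_communities`, and for `"fgc"` the merge matrix `merges`.
#' @export
detect_communities <- function(net, method = c("fgc", "wtc", "vos"),
                               walk_steps = 4, seed = NULL) {
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  g0 <- if (igraph::is_igraph(net)) net else as_igraph(net)
  g <- igraph::as_undirected(g0, mode = "collapse", edge.attr.comb = "sum")
  g <- igraph::simplify(g, edge.attr.comb = "sum")
  comm <- switch(
    method,
    fgc = igraph::cluster_fast_greedy(g, weights = igraph::E(g)$weight),
    wtc = igraph::cluster_walktrap(g, steps = walk_steps,
                                   weights = igraph::E(g)$weight),
    vos = igraph::cluster_louvain(g, weights = igraph::E(g)$weight)
  )
  memb <- setNames(as.integer(igraph::membership(comm)),
                   igraph::V(g)$name)
  part <- structure(memb, class = "ef_partition", method = method,
                    n_communities = length(unique(memb)))
  if (!igraph::is_igraph(net)) {
    attr(part, "quality") <- quality_index(net, part)
  } else {
    attr(part, "quality") <- igraph::modularity(comm)
  }
  if (method == "fgc") attr(part, "merges") <- igraph::merges(comm)
  part
}

#' @export
print.ef_partition <- function(x, ...) {
  cat(sprintf("<ef_partition method=%s> %d nodes, %d communities",
              attr(x, "method") %||% "custom", length(x),
              length(unique(unclass(x)))))
  q <- attr(x, "quality")
  if (!is.null(q)) cat(sprintf(", quality %.3f", q))
  cat("\n")
  invisible(x)
}

#' Clustering ratio
#'
#' The number of communities of a partition divided by the number of
#' connected (non-isolated) nodes; ranges over (0, 1] and decreases as
#' communities agglomerate.
#'
#' @param net An [ef_bipartite()] network or `ef_projection`.
#' @param partition An `ef_partition` or named label vector.
#' @return A single number, `NA` when no node is connected.
#' @export
clustering_ratio <- function(net, partition) {
  part <- check_partition(net, partition)
  A <- ef_adjacency(net)
  connected <- rowSums(A) > 0
  if (!any(connected)) return(NA_real_)
  length(unique(part[connected])) / sum(connected)
}

#' Scaled pairwise modularity matrix and Ward dendrogram
#'
#' Builds the matrix with elements `(A_ij - k_i k_j / (2m)) * M_nd`, where
#' `M_nd` is a network-level modularity index at the chosen event, then
#' hierarchically clusters its rows with Ward's minimum-variance method on
#' squared Euclidean distances. Rows and columns are ordered by ascending
#' node age for rendering.
#'
#' @param net An [ef_bipartite()] network or `ef_projection` (a snapshot at
#'   the event of interest).
#' @param m_nd The network's modularity index at this event (e.g. the
#'   per-event Newman-Girvan index under the age partition).
#' @return An object of class `ef_heatmap`: list with `matrix` (age-ordered),
#'   `dendrogram` (an [stats::hclust] tree) and `m_nd`.
#' @export
heatmap_matrix <- function(net, m_nd) {
  A <- ef_adjacency(net)
  k <- rowSums(A)
  two_m <- sum(A)
  B <- if (two_m == 0) A * 0 else (A - outer(k, k) / two_m) * m_nd
  ages <- ef_node_ages(net)
  ord <- order(ages, names(ages))
  B <- B[ord, ord, drop = FALSE]
  dendro <- if (nrow(B) >= 2) {
    hclust(dist(B)^2, method = "ward.D")
  } else NULL
  structure(list(matrix = B, dendrogram = dendro, m_nd = m_nd),
            class = "ef_heatmap")
}

#' Per-event Newman-Girvan modularity under the age partition
#'
#' For every snapshot of a growing network, the NG index with nodes
#' partitioned by their event (distinct age value). Positive values mean
#' links concentrate within events (age-assortative growth); negative
#' values mean links cross events (recruitment of older material).
#'
#' @param series An `ef_events` object.
#' @return A tibble `event`, `nd`, `ng_age`.
#' @export
ng_age_series <- function(series) {
  stopifnot(inherits(series, "ef_events"))
  vals <- purrr::map_dbl(series$snapshots, function(s) {
    ng_modularity(s, age_partition(s))
  })
  tibble(event = series$events$event, nd = series$events$nd, ng_age = vals)
}

#' The six modularity indices of a network
#'
#' Bundles the package's modularity surface into one row: the quality index
#' VQ under the detected ("vos") partition, the clustering ratio, the
#' average clustering coefficient (projections only; `NA` for bipartite
#' networks, which have no triangles), the fast-greedy community quality,
#' and the Newman-Girvan index under the age, vos, fgc and wtc partitions.
#'
#' @param net An [ef_bipartite()] network or `ef_projection` with ages set.
#' @param seed RNG seed for the detection methods.
#' @param walk_steps Walktrap walk length; default 4.
#' @return A one-row tibble: `vq`, `c_ratio`, `c_avg`, `fgc_q`, `ng_age`,
#'   `ng_vos`, `ng_fgc`, `ng_wtc`, plus community counts
#'   `n_comm_vos`, `n_comm_fgc`, `n_comm_wtc`.
#' @export
modularity_report <- function(net, seed = 1L, walk_steps = 4) {
  p_vos <- detect_communities(net, "vos", seed = seed)
  p_fgc <- detect_communities(net, "fgc")
  p_wtc <- detect_communities(net, "wtc", walk_steps = walk_steps)
  p_age <- age_partition(net)
  tibble(
    vq = quality_index(net, p_vos),
    c_ratio = clustering_ratio(net, p_vos),
    c_avg = if (inherits(net, "ef_projection"))
      clustering_coefficient(net) else NA_real_,
    fgc_q = quality_index(net, p_fgc),
    ng_age = ng_modularity(net, p_age),
    ng_vos = ng_modularity(net, p_vos),
    ng_fgc = ng_modularity(net, p_fgc),
    ng_wtc = ng_modularity(net, p_wtc),
    n_comm_vos = attr(p_vos, "n_communities"),
    n_comm_fgc = attr(p_fgc, "n_communities"),
    n_comm_wtc = attr(p_wtc, "n_communities")
  )
}
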