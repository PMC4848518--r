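#' Configuration for the synthetic EF network generator
#'
#' The generator emulates the statistical structure assumed by the analysis:
#' a sparse, disconnected bipartite graph of loop prototypes and domain
#' superfamilies whose loop degrees are hub-dominated, whose domain ages are
#' concentrated early in the timeline, and which starts from one or more
#' "founder" domains at the origin (`nd = 0`) seeding waves of innovation.
#' Defaults match the dimensions of the archaeal loop-domain mapping the
#' analysis was designed for: 38 loops, 82 domains, 134 associations, two
#' founder waves.
#'
#' @param n_loops,n_domains,n_edges Network dimensions. `n_edges` must not
#'   exceed `n_loops * n_domains`.
#' @param wave_seeds Number of founder domains pinned at `age_nd = 0`.
#' @param attachment_bias Exponent `b >= 0`: each non-seed edge picks its loop
#'   endpoint with probability proportional to `(degree + 1)^b`. `b = 0` is
#'   uniform; `b = 1` (default) is linear preferential attachment.
#' @param age_concentration Shape `a > 0` of the `Beta(1, a)` age density for
#'   non-founder domains; larger values concentrate innovation earlier.
#' @param seed RNG seed; the same seed yields byte-identical output.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_loops = 38, n_domains = 82, n_edges = 134,
                         wave_seeds = 2, attachment_bias = 1,
                         age_concentration = 4, seed = 1L) {
  cfg <- list(
    n_loops = as.integer(n_loops), n_domains = as.integer(n_domains),
    n_edges = as.integer(n_edges), wave_seeds = as.integer(wave_seeds),
    attachment_bias = attachment_bias,
    age_concentration = age_concentration, seed = as.integer(seed)
  )
  stopifnot(cfg$n_loops > 0, cfg$n_domains > 0, cfg$n_edges > 0,
            cfg$wave_seeds >= 0, cfg$wave_seeds <= cfg$n_domains,
            cfg$attachment_bias >= 0, cfg$age_concentration > 0)
  if (cfg$n_edges > cfg$n_loops * cfg$n_domains) {
    abort("Infeasible config: n_edges exceeds n_loops * n_domains.")
  }
  structure(cfg, class = "synth_config")
}

#' Generate a synthetic EF bipartite network with domain ages
#'
#' Domain ages are drawn from a decreasing density on `[0, 1]`
#' (`Beta(1, age_concentration)`), with `wave_seeds` founder domains forced
#' to `nd = 0`. Edges are laid down one at a time in order of the domain
#' timeline: each founder receives a first edge to a fresh loop, then each
#' remaining edge joins a uniformly chosen domain to a loop chosen with
#' probability proportional to `(current degree + 1)^attachment_bias`,
#' producing hub-dominated loop degrees. Exactly `n_edges` distinct edges
#' result; isolated nodes are permitted (the emulated network is
#' disconnected). Loop ages are left unset: they are derived from domain
#' ages through [transfer_loop_ages()], mirroring the causal structure of
#' the analysis.
#'
#' @param config A [synth_config()].
#' @return A list with elements `network` ([ef_bipartite()], domain ages
#'   set) and `ages` (an `ef_age_table` of the domain ages).
#' @examples
#' out <- synth_ef(synth_config(seed = 42))
#' ef_density(out$network)
#' @export
synth_ef <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)

  loop_ids <- as.character(seq_len(config$n_loops) * 7 + 1)  # opaque labels
  sf_ids <- synth_sf_ids(config$n_domains)

  ages <- numeric(config$n_domains)
  n_free <- config$n_domains - config$wave_seeds
  if (n_free > 0) {
    ages[(config$wave_seeds + 1):config$n_domains] <-
      rbeta(n_free, 1, config$age_concentration)
  }
  ord <- order(ages)
  ages <- ages[ord]

  deg <- rep(0L, config$n_loops)
  present <- matrix(FALSE, config$n_loops, config$n_domains)
  el <- matrix(0L, config$n_edges, 2)
  n_e <- 0L

  add_edge <- function(li, di) {
    n_e <<- n_e + 1L
    el[n_e, ] <<- c(li, di)
    present[li, di] <<- TRUE
    deg[li] <<- deg[li] + 1L
  }

  # founders: one fresh loop each, so every wave seed has degree >= 1
  n_seed_edges <- min(config$wave_seeds, config$n_edges, config$n_loops)
  for (i in seq_len(n_seed_edges)) add_edge(i, i)

  loop_idx <- seq_len(config$n_loops)
  while (n_e < config$n_edges) {
    di <- sample.int(config$n_domains, 1)
    w <- (deg + 1)^config$attachment_bias
    li <- sample(loop_idx, 1, prob = w)
    if (!present[li, di]) add_edge(li, di)
  }

  age_tbl <- age_table(tibble(sf_id = sf_ids, age_nd = ages))
  net <- ef_bipartite(
    edges = tibble(loop_id = loop_ids[el[, 1]], sf_id = sf_ids[el[, 2]]),
    loops = tibble(loop_id = loop_ids),
    domains = tibble(sf_id = sf_ids, age_nd = ages)
  )
  list(network = net, ages = age_tbl)
}

synth_sf_ids <- function(n) {
  # plausible-looking SCOP-style identifiers, unique by construction
  cls <- rep(letters[1:7], length.out = n)
  fold <- rep(seq_len(ceiling(n / 7)), each = 7)[seq_len(n)]
  sprintf("%s.%d.%d", cls, fold, (seq_len(n) - 1) %% 3 + 1)
}

#' Generate an ordered set of event ages
#'
#' Produces `n_events` strictly increasing relative ages spanning `[0, 1]`,
#' anchored at 0 (the origin of the timeline).
#'
#' @param n_events Number of distinct events (>= 1).
#' @param span Interval to cover; default `c(0, 1)`.
#' @return Numeric vector of length `n_events`, sorted ascending, first
#'   element `span[1]`.
#' @export
generate_event_ages <- function(n_events, span = c(0, 1)) {
  stopifnot(n_events >= 1, length(span) == 2, span[1] < span[2] || n_events == 1)
  if (n_events == 1) return(span[1])
  seq(span[1], span[2], length.out = n_events)
}
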