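#' Transfer domain ages to loop prototypes
#'
#' Loops have no direct placement on the domain timeline; their ages are
#' inherited from the domains that embed them. Two schemes are supported:
#'
#' * `"oldest"`: the loop is as old as its most ancient associated domain
#'   (minimum neighbour `age_nd`).
#' * `"second_oldest"` (default): the loop's age is the more recent of its
#'   two most ancient associated domains — the second value of the ascending
#'   sort of neighbour ages — or the age of the single associated domain.
#'   This conservative reading dates a loop to when its function is first
#'   transferred between structural scaffolds.
#'
#' Loops with no associations cannot be dated; their age stays `NA` and they
#' are reported via a message.
#'
#' @param net An [ef_bipartite()] network.
#' @param ages An `ef_age_table` (see [age_table()]); every domain that has
#'   at least one edge must be present.
#' @param scheme `"second_oldest"` (default) or `"oldest"`.
#' @param clock An [ef_clock()] used to populate `age_gy`, or `NULL` to skip.
#' @return The network with `age_nd`/`age_gy` set on domains and loops.
#' @examples
#' net <- synth_ef(synth_config(seed = 1))
#' aged <- transfer_loop_ages(net$network, net$ages)
#' head(aged$loops)
#' @export
transfer_loop_ages <- function(net, ages,
                               scheme = c("second_oldest", "oldest"),
                               clock = ef_clock()) {
  stopifnot(inherits(net, "ef_bipartite"))
  scheme <- match.arg(scheme)
  ages <- age_table(ages)

  connected_domains <- unique(net$edges$sf_id)
  missing <- setdiff(connected_domains, ages$sf_id)
  if (length(missing)) {
    abort(sprintf("No age for connected domain(s): %s",
                  paste(head(missing, 5), collapse = ", ")))
  }

  net$domains <- net$domains |>
    select(-"age_nd", -"age_gy") |>
    left_join(ages, by = "sf_id")

  loop_age <- net$edges |>
    left_join(ages, by = "sf_id") |>
    group_by(.data$loop_id) |>
    summarise(age_nd = pick_transfer_age(.data$age_nd, scheme)) |>
    ungroup()

  net$loops <- net$loops |>
    select(-"age_nd", -"age_gy") |>
    left_join(loop_age, by = "loop_id")

  orphans <- net$loops$loop_id[is.na(net$loops$age_nd)]
  if (length(orphans)) {
    inform(sprintf("%d loop(s) with no associations left undated: %s",
                   length(orphans), paste(head(orphans, 5), collapse = ", ")))
  }

  if (!is.null(clock)) {
    net$loops$age_gy <- apply_clock(net$loops$age_nd, clock)
    net$domains$age_gy <- apply_clock(net$domains$age_nd, clock)
  } else {
    net$loops$age_gy <- NA_real_
    net$domains$age_gy <- NA_real_
  }
  validate_ef_bipartite(net)
}

pick_transfer_age <- function(neighbour_ages, scheme) {
  a <- sort(neighbour_ages)
  if (length(a) == 0) return(NA_real_)
  if (scheme == "oldest" || length(a) == 1) a[1] else a[2]
}

#' Per-event loops-per-domain and domains-per-loop ratios
#'
#' At each event of a growing bipartite network, the mean degree of the
#' connected domain nodes (loops per domain) and of the connected loop nodes
#' (domains per loop). Isolated nodes are excluded; an event with no edges
#' yields `NA` ratios (flagged, never zero).
#'
#' @param series An [build_events()] series over an `ef_bipartite` network.
#' @return A tibble with one row per event: `event`, `nd`, `loops_per_domain`,
#'   `domains_per_loop`, `n_edges`.
#' @export
per_partner_ratio_series <- function(series) {
  stopifnot(inherits(series, "ef_events"))
  if (!inherits(series$network, "ef_bipartite")) {
    abort("Partner ratios are defined for bipartite event series.")
  }
  purrr::map2_dfr(series$snapshots, seq_along(series$snapshots), function(s, i) {
    e <- s$edges
    tibble(
      event = i,
      nd = series$events$nd[i],
      loops_per_domain = if (nrow(e)) mean(table(e$sf_id)) else NA_real_,
      domains_per_loop = if (nrow(e)) mean(table(e$loop_id)) else NA_real_,
      n_edges = nrow(e)
    )
  })
}
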