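#' Tidy a power-law fit
#'
#' One row per fitted quantity, broom-style.
#'
#' @param x An `ef_powerlaw_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `alpha`, `ks_stat`, `ks_p`, `loglik`,
#'   `continuous_fit`, `rejected`.
#' @export
tidy.ef_powerlaw_fit <- function(x, ...) {
  tibble(alpha = x$alpha, ks_stat = x$ks_stat, ks_p = x$ks_p,
         loglik = x$loglik, continuous_fit = x$continuous_fit,
         rejected = x$rejected)
}

#' Glance at a power-law fit
#'
#' @param x An `ef_powerlaw_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `n`, `xmin`, `degenerate`, `too_small`.
#' @export
glance.ef_powerlaw_fit <- function(x, ...) {
  tibble(n = x$n, xmin = x$xmin, degenerate = x$degenerate,
         too_small = x$too_small)
}

#' Tidy an event series
#'
#' @param x An `ef_events` object.
#' @param ... Unused.
#' @return The per-event tibble (`event`, `nd`, `n_new_nodes`, `n_nodes`,
#'   `n_links`).
#' @export
tidy.ef_events <- function(x, ...) x$events

#' Tidy a partition
#'
#' @param x An `ef_partition`.
#' @param ... Unused.
#' @return A tibble `id`, `community`.
#' @export
tidy.ef_partition <- function(x, ...) {
  tibble(id = names(x), community = as.integer(unclass(x)))
}

#' @export
glance.ef_partition <- function(x, ...) {
  tibble(method = attr(x, "method") %||% "custom",
         n_communities = length(unique(unclass(x))),
         quality = attr(x, "quality") %||% NA_real_)
}

#' Broom-style generics
#'
#' Re-exported `tidy()`/`glance()` generics (defined here to avoid a hard
#' broom dependency).
#'
#' @param x An object.
#' @param ... Method-specific arguments.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
glance <- function(x, ...) UseMethod("glance")
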