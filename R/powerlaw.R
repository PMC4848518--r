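#' Empirical degree distribution
#'
#' The probability `P(k)` of a node having `k` links — the fraction of nodes
#' with degree `k` — tabulated over the observed degrees. For a bipartite
#' network the distribution is computed separately for the loop or domain
#' portion; for a projection, over weighted (or unweighted) in-, out- or
#' total degree.
#'
#' @param net An [ef_bipartite()] network or `ef_projection`.
#' @param side For bipartite networks: `"loop"` or `"domain"`.
#' @param direction For projections: `"all"`, `"in"` or `"out"`.
#' @param weighted For projections: sum arc weights (default `TRUE`).
#' @return A tibble `k`, `count`, `p` with `sum(p) == 1`.
#' @export
degree_distribution_table <- function(net, side = c("loop", "domain"),
                                      direction = c("all", "in", "out"),
                                      weighted = TRUE) {
  if (inherits(net, "ef_bipartite")) {
    deg <- bipartite_degrees(net, match.arg(side))
  } else if (inherits(net, "ef_projection")) {
    deg <- snapshot_degrees(net, match.arg(direction), weighted)
  } else {
    abort("Unsupported network class.")
  }
  if (length(deg) == 0) abort("Network has no nodes on the requested side.")
  tbl <- as.data.frame(table(deg), stringsAsFactors = FALSE)
  tibble(k = as.numeric(tbl$deg), count = as.integer(tbl$Freq),
         p = tbl$Freq / length(deg))
}

#' Log-log regression estimate of the power-law decay exponent
#'
#' Ordinary least squares of `log P(k)` on `log k` over the support with
#' `k > 0` and `P(k) > 0`. The decay exponent gamma is the negative slope;
#' the coefficient of determination R^2 measures how much of the
#' distribution the linear (i.e. power-law) model captures. High gamma with
#' high R^2 supports preferential-attachment (scale-free) behaviour.
#'
#' @param dist A degree distribution table from
#'   [degree_distribution_table()], or any data frame with columns `k`, `p`.
#' @return A one-row tibble `gamma`, `r2`, `n_support`; `NA`s (flagged via
#'   `ok = FALSE`) when fewer than two support points remain.
#' @export
loglog_regression <- function(dist) {
  stopifnot(is.data.frame(dist), all(c("k", "p") %in% names(dist)))
  d <- dist |> filter(.data$k > 0, .data$p > 0)
  if (nrow(d) < 2) {
    return(tibble(gamma = NA_real_, r2 = NA_real_, n_support = nrow(d),
                  ok = FALSE))
  }
  fit <- lm(log(p) ~ log(k), data = d)
  # two support points fit exactly; summary.lm warns about perfect fits
  r2 <- suppressWarnings(summary(fit)$r.squared)
  tibble(
    gamma = -unname(coef(fit)[2]),
    r2 = r2,
    n_support = nrow(d),
    ok = TRUE
  )
}

#' Maximum-likelihood discrete power-law fit with KS diagnostics
#'
#' Fits `P(X = x) = x^-alpha / zeta(alpha, xmin)` to a degree vector by
#' maximum likelihood (zero degrees are excluded; `xmin` is fixed at 1 by
#' default, fitting the whole degree vector without tail truncation, or
#' chosen by a Clauset-style scan with `xmin = "auto"`). Goodness of fit is
#' summarised by the Kolmogorov-Smirnov distance between the empirical and
#' fitted CDFs and a parametric-bootstrap p-value for the power-law null:
#' the fit is rejected when `ks_p < 0.05` or `ks_stat > 0.10`.
#'
#' @param degrees Integer-like vector of node degrees.
#' @param xmin Lower cut-off of the fitted law (default 1), or `"auto"`.
#' @param bootstrap Number of bootstrap replicates for `ks_p` (default 100);
#'   0 skips the p-value.
#' @param floor Minimum number of nonzero degrees for a meaningful fit.
#' @return An object of class `ef_powerlaw_fit` with fields `alpha`,
#'   `ks_stat`, `ks_p`, `loglik`, `continuous_fit` (is the observed degree
#'   support gap-free?), `rejected`, `degenerate`, `n`, `xmin`.
#' @examples
#' set.seed(1)
#' x <- rplaw(500, alpha = 2.5)
#' fit_power_law(x, bootstrap = 20)
#' @export
fit_power_law <- function(degrees, xmin = 1, bootstrap = 100, floor = 10) {
  x <- as.numeric(degrees)
  x <- x[!is.na(x) & x > 0]
  x <- round(x)
  out <- list(alpha = NA_real_, ks_stat = NA_real_, ks_p = NA_real_,
              loglik = NA_real_, continuous_fit = NA, rejected = NA,
              degenerate = FALSE, n = length(x), xmin = xmin,
              too_small = FALSE)
  class(out) <- "ef_powerlaw_fit"
  if (length(x) < floor) {
    out$too_small <- TRUE
    return(out)
  }
  if (length(unique(x)) == 1) {
    out$degenerate <- TRUE
    return(out)
  }
  if (identical(xmin, "auto")) {
    cand <- sort(unique(x))
    cand <- cand[cand <= quantile(x, 0.9)]
    scans <- lapply(cand, function(xm) plaw_fit_at(x[x >= xm], xm))
    best <- which.min(vapply(scans, function(s) s$ks_stat, numeric(1)))
    fit <- scans[[best]]
    xmin <- cand[best]
    x <- x[x >= xmin]
  } else {
    fit <- plaw_fit_at(x, xmin)
  }
  out$alpha <- fit$alpha
  out$ks_stat <- fit$ks_stat
  out$loglik <- fit$loglik
  out$xmin <- xmin
  ks <- sort(unique(x))
  out$continuous_fit <- all(diff(ks) == 1)
  if (bootstrap > 0) {
    n <- length(x)
    reps <- vapply(seq_len(bootstrap), function(i) {
      sim <- rplaw(n, fit$alpha, xmin)
      plaw_fit_at(sim, xmin)$ks_stat
    }, numeric(1))
    out$ks_p <- mean(reps >= fit$ks_stat)
    out$rejected <- (out$ks_p < 0.05) || (out$ks_stat > 0.10)
  } else {
    out$rejected <- out$ks_stat > 0.10
  }
  out
}

# MLE + KS at a fixed xmin for a vector of degrees >= xmin
plaw_fit_at <- function(x, xmin) {
  n <- length(x)
  slx <- sum(log(x))
  nll <- function(a) n * log(hurwitz_zeta(a, xmin)) + a * slx
  opt <- optimize(nll, c(1.000001, 25))
  alpha <- opt$minimum
  list(alpha = alpha, ks_stat = plaw_ks(x, alpha, xmin),
       loglik = -opt$objective)
}

hurwitz_zeta <- function(a, xmin) {
  if (xmin == 1) return(pracma::zeta(a))
  # zeta(a) minus the first xmin-1 terms
  pracma::zeta(a) - sum(seq_len(xmin - 1)^(-a))
}

# KS distance between the empirical CDF of x and the fitted power-law CDF,
# evaluated at the observed support. Beyond a fixed table the tail mass
# P(X > k) is approximated by Euler-Maclaurin, sum_{j>k} j^-a ~
# (k + 0.5)^(1-a) / (a - 1), which keeps memory bounded for heavy tails.
plaw_ks <- function(x, alpha, xmin) {
  xs <- sort(unique(x))
  n <- length(x)
  ecdf_v <- cumsum(tabulate(match(x, xs), nbins = length(xs))) / n
  z <- hurwitz_zeta(alpha, xmin)
  K0 <- min(max(xs), 100000)
  supp <- xmin:K0
  cdf_tab <- cumsum(supp^(-alpha)) / z
  cdf <- numeric(length(xs))
  small <- xs <= K0
  cdf[small] <- cdf_tab[xs[small] - xmin + 1]
  if (any(!small)) {
    cdf[!small] <- 1 - (xs[!small] + 0.5)^(1 - alpha) / ((alpha - 1) * z)
  }
  max(abs(ecdf_v - cdf))
}

#' Sample from a discrete power law
#'
#' Exact inverse-CDF sampling for `P(X = x) proportional to x^-alpha`,
#' `x >= xmin`, with a continuous Pareto approximation beyond the 10^4-term
#' table (negligible mass for `alpha > 1.2`).
#'
#' @param n Sample size.
#' @param alpha Exponent (> 1).
#' @param xmin Lower cut-off (default 1).
#' @return Numeric vector of `n` integer-valued samples.
#' @export
rplaw <- function(n, alpha, xmin = 1) {
  stopifnot(alpha > 1)
  kmax <- 10000L
  supp <- xmin:(xmin + kmax - 1L)
  z <- hurwitz_zeta(alpha, xmin)
  cdf <- cumsum(supp^(-alpha) / z)
  u <- runif(n)
  idx <- findInterval(u, cdf) + 1L
  out <- as.numeric(supp[pmin(idx, kmax)])
  over <- idx > kmax
  if (any(over)) {
    # continuous Pareto tail conditioned on exceeding the table
    ptail <- 1 - cdf[kmax]
    v <- (u[over] - cdf[kmax]) / ptail
    out[over] <- floor((supp[kmax] + 0.5) * (1 - v)^(-1 / (alpha - 1)))
  }
  out
}

#' @export
print.ef_powerlaw_fit <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat("<ef_powerlaw_fit> degenerate (all degrees equal)\n")
  } else if (isTRUE(x$too_small)) {
    cat(sprintf("<ef_powerlaw_fit> too few nonzero degrees (n = %d)\n", x$n))
  } else {
    cat(sprintf(
      "<ef_powerlaw_fit> alpha = %.3f, KS = %.4f, p = %s, loglik = %.1f, %s\n",
      x$alpha, x$ks_stat,
      if (is.na(x$ks_p)) "NA" else format(x$ks_p),
      x$loglik,
      if (isTRUE(x$rejected)) "power law rejected" else "not rejected"
    ))
  }
  invisible(x)
}

#' Per-event power-law diagnostics along an event series
#'
#' Applies [loglog_regression()] and [fit_power_law()] to the degree vector
#' of every snapshot of a growing network, producing one tidy row per event.
#' Events whose snapshot falls below the size floor are flagged
#' (`fit_ok = FALSE`) rather than dropped.
#'
#' @param series An `ef_events` object.
#' @param side For bipartite series: `"loop"` or `"domain"`.
#' @param direction For projection series: `"all"`, `"in"` or `"out"`.
#' @param weighted Use arc weights for projection degrees (default `TRUE`).
#' @param bootstrap Bootstrap replicates per event for `ks_p`; default 0
#'   (skip the p-value, which dominates run time).
#' @param floor Minimum nonzero degrees for the MLE fit.
#' @return A tibble with one row per event: `event`, `nd`, `n_nodes`,
#'   `gamma`, `r2`, `alpha`, `ks_stat`, `ks_p`, `loglik`, `continuous_fit`,
#'   `rejected`, `fit_ok`.
#' @export
fit_series <- function(series, side = c("loop", "domain"),
                       direction = c("all", "in", "out"), weighted = TRUE,
                       bootstrap = 0, floor = 10) {
  stopifnot(inherits(series, "ef_events"))
  bip <- inherits(series$network, "ef_bipartite")
  side <- match.arg(side)
  direction <- match.arg(direction)
  purrr::map2_dfr(series$snapshots, seq_along(series$snapshots), function(s, i) {
    deg <- if (bip) snapshot_degrees(s, side = side)
           else snapshot_degrees(s, direction, weighted)
    dist <- if (length(deg)) {
      tbl <- as.data.frame(table(deg), stringsAsFactors = FALSE)
      tibble(k = as.numeric(tbl$deg), p = tbl$Freq / length(deg))
    } else tibble(k = numeric(), p = numeric())
    reg <- loglog_regression(dist)
    pl <- fit_power_law(deg, bootstrap = bootstrap, floor = floor)
    tibble(
      event = i, nd = series$events$nd[i], n_nodes = length(deg),
      gamma = reg$gamma, r2 = reg$r2,
      alpha = pl$alpha, ks_stat = pl$ks_stat, ks_p = pl$ks_p,
      loglik = pl$loglik, continuous_fit = pl$continuous_fit,
      rejected = pl$rejected,
      fit_ok = !isTRUE(pl$too_small) && !isTRUE(pl$degenerate)
    )
  })
}

#' Preferential-attachment reference graphs
#'
#' Reference controls for the per-event statistics: a Barabasi-Albert graph
#' grown with one edge per arriving node (a tree, so its clustering
#' coefficient is exactly 0), or an age-dependent variant in which the
#' attachment weight of an existing node is the product of its degree and a
#' power kernel of its age rank (exponent `aging_exp`, default -1: older
#' nodes lose appeal).
#'
#' @param n Number of nodes (>= 2).
#' @param age_dependent Grow the age-dependent variant?
#' @param m Edges added per arriving node; default 1.
#' @param aging_exp Age-kernel exponent for the age-dependent variant.
#' @param seed Optional RNG seed for reproducibility.
#' @return An undirected [igraph::graph] object.
#' @export
reference_barabasi <- function(n, age_dependent = FALSE, m = 1,
                               aging_exp = -1, seed = NULL) {
  stopifnot(n >= 2)
  if (!is.null(seed)) set.seed(seed)
  g <- if (age_dependent) {
    igraph::sample_pa_age(n, pa.exp = 1, aging.exp = aging_exp, m = m,
                          directed = FALSE)
  } else {
    igraph::sample_pa(n, power = 1, m = m, directed = FALSE)
  }
  igraph::simplify(g)
}
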