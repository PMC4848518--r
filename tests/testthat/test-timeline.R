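test_that("one event per distinct age; degenerate cases behave", {
  net <- ef_bipartite(
    data.frame(loop_id = c("L1", "L2"), sf_id = c("a.1.1", "b.1.1")),
    loops = data.frame(loop_id = c("L1", "L2"), age_nd = c(0, 0.2)),
    domains = data.frame(sf_id = c("a.1.1", "b.1.1"), age_nd = c(0, 0.5))
  )
  ev <- build_events(net)
  expect_equal(nrow(ev$events), 3)  # ages {0, 0, 0.2, 0.5}
  expect_equal(ev$events$nd, c(0, 0.2, 0.5))

  single <- ef_bipartite(
    data.frame(loop_id = "L1", sf_id = "a.1.1"),
    loops = data.frame(loop_id = "L1", age_nd = 0.3),
    domains = data.frame(sf_id = "a.1.1", age_nd = 0.3)
  )
  ev1 <- build_events(single)
  expect_equal(nrow(ev1$events), 1)
  expect_equal(nrow(ev1$snapshots[[1]]$edges), 1)
})

test_that("snapshots are nested and the last equals the full network", {
  for (seed in 1:4) {
    net <- rand_bip(10, 12, 30, seed)
    ev <- build_events(net)
    # events never outnumber nodes; equality iff ages all distinct
    n_nodes <- sum(!is.na(c(net$loops$age_nd, net$domains$age_nd)))
    expect_lte(nrow(ev$events), n_nodes)
    for (k in seq_len(nrow(ev$events) - 1)) {
      a <- ev$snapshots[[k]]; b <- ev$snapshots[[k + 1]]
      expect_true(all(a$loops$loop_id %in% b$loops$loop_id))
      expect_true(all(a$domains$sf_id %in% b$domains$sf_id))
      expect_true(all(paste(a$edges$loop_id, a$edges$sf_id) %in%
                        paste(b$edges$loop_id, b$edges$sf_id)))
    }
    last <- ev$snapshots[[nrow(ev$events)]]
    expect_equal(nrow(last$edges), nrow(net$edges))
    # statistics on the final snapshot equal statistics on the full network
    expect_equal(ef_density(last),
                 nrow(net$edges) / (nrow(last$loops) * nrow(last$domains)))
  }
})

test_that("projection event series nest and links appear with their younger endpoint", {
  net <- rand_bip(10, 12, 35, seed = 9)
  p <- project(net, "domain", tiebreak = "lexicographic")
  ev <- build_events(p)
  age <- setNames(p$nodes$age_nd, p$nodes$id)
  for (k in seq_len(nrow(ev$events))) {
    s <- ev$snapshots[[k]]
    t <- ev$events$nd[k]
    # every arc whose younger endpoint is within the horizon is present
    due <- p$arcs[pmax(age[p$arcs$from], age[p$arcs$to]) <= t, ]
    expect_equal(nrow(s$arcs), nrow(due))
  }
})

test_that("accumulation bins follow the bin arithmetic and conserve arcs", {
  p <- efnet:::new_projection(
    "loop",
    nodes = tibble::tibble(id = c("u", "v"), age_nd = c(0.05, 0.55),
                           age_gy = NA_real_),
    arcs = tibble::tibble(from = "u", to = "v", weight = 1)
  )
  b <- accumulation_bins(p, 10)
  expect_equal(b$bin[b$id == "u" & b$direction == "out"], 6L)
  expect_equal(b$bin[b$id == "v" & b$direction == "in"], 1L)

  for (seed in 1:4) {
    p <- rand_projection(12, 40, seed)
    b <- accumulation_bins(p, 10)
    expect_equal(sum(b$count[b$direction == "in"]), nrow(p$arcs))
    expect_equal(sum(b$count[b$direction == "out"]), nrow(p$arcs))
    expect_true(all(b$bin >= 1 & b$bin <= 10))
  }

  # age exactly 1 lands in the last (closed) bin
  p1 <- efnet:::new_projection(
    "loop",
    nodes = tibble::tibble(id = c("u", "v"), age_nd = c(0, 1),
                           age_gy = NA_real_),
    arcs = tibble::tibble(from = "u", to = "v", weight = 1)
  )
  b1 <- accumulation_bins(p1, 10)
  expect_equal(b1$bin[b1$direction == "out"], 10L)

  empty <- efnet:::new_projection(
    "loop", nodes = tibble::tibble(id = "u", age_nd = 0, age_gy = NA_real_),
    arcs = tibble::tibble(from = character(), to = character(),
                          weight = numeric())
  )
  expect_equal(nrow(accumulation_bins(empty, 10)), 0)
  expect_error(accumulation_bins(p1, 0), "n_bins")
})

test_that("normalized mean degree is 1 on regular snapshots and follows the star closed form", {
  # 4-cycle: regular, every event cumulative; last snapshot mean = max
  net <- ef_bipartite(
    data.frame(loop_id = c("L1", "L1", "L2", "L2"),
               sf_id = c("a.1.1", "b.1.1", "a.1.1", "b.1.1")),
    loops = data.frame(loop_id = c("L1", "L2"), age_nd = c(0, 0)),
    domains = data.frame(sf_id = c("a.1.1", "b.1.1"), age_nd = c(0, 0))
  )
  ev <- build_events(net)
  curve <- normalized_mean_degree(ev)
  expect_equal(nrow(curve), nrow(ev$events))
  expect_equal(curve$value[nrow(curve)], 1)

  # bipartite star with n leaves: degrees (n, 1, ..., 1)
  n <- 5
  star <- ef_bipartite(
    data.frame(loop_id = "hub", sf_id = sprintf("a.%d.1", 1:n)),
    loops = data.frame(loop_id = "hub", age_nd = 0),
    domains = data.frame(sf_id = sprintf("a.%d.1", 1:n), age_nd = rep(0, n))
  )
  sev <- build_events(star)
  expect_equal(normalized_mean_degree(sev)$value,
               (2 * n / (n + 1)) / n)
})
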