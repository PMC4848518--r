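test_that("NG modularity matches hand values on canonical small graphs", {
  # two disjoint edges (as a bipartite graph), partition by component
  net <- ef_bipartite(data.frame(loop_id = c("L1", "L2"),
                                 sf_id = c("a.1.1", "b.1.1")))
  by_comp <- setNames(c(1, 2, 1, 2), c("L1", "L2", "a.1.1", "b.1.1"))
  expect_equal(ng_modularity(net, by_comp), 0.5)
  one_comm <- setNames(rep(1, 4), c("L1", "L2", "a.1.1", "b.1.1"))
  expect_equal(ng_modularity(net, one_comm), 0)
  expect_error(ng_modularity(net, by_comp[-1]), "cover")
})

test_that("NG modularity equals the double-loop formula and igraph on random graphs", {
  for (seed in 1:10) {
    net <- rand_bip(sample(4:12, 1), sample(4:12, 1), sample(8:30, 1), seed)
    A <- efnet:::ef_adjacency(net)
    part <- rand_partition(rownames(A), sample(2:4, 1), seed + 100)
    expect_equal(ng_modularity(net, part), brute_ng(A, part[rownames(A)]),
                 tolerance = 1e-12)
    # independent library oracle
    g <- as_igraph(net)
    expect_equal(ng_modularity(net, part),
                 igraph::modularity(g, part[igraph::V(g)$name]),
                 tolerance = 1e-12)
  }
  for (seed in 1:10) {
    p <- rand_projection(sample(5:12, 1), sample(8:25, 1), seed)
    A <- efnet:::ef_adjacency(p)
    part <- rand_partition(p$nodes$id, 3, seed + 200)
    expect_equal(ng_modularity(p, part), brute_ng(A, part[rownames(A)]),
                 tolerance = 1e-12)
  }
})

test_that("the quality index matches block brute force and equals NG", {
  # two disjoint triangles, partitioned by triangle
  ids <- sprintf("n%d", 1:6)
  tri2 <- efnet:::new_projection(
    "loop",
    nodes = tibble::tibble(id = ids, age_nd = seq(0, 1, length.out = 6),
                           age_gy = NA_real_),
    arcs = tibble::tibble(
      from = c("n1", "n2", "n1", "n4", "n5", "n4"),
      to = c("n2", "n3", "n3", "n5", "n6", "n6"),
      weight = 1
    )
  )
  part <- setNames(c(1, 1, 1, 2, 2, 2), ids)
  expect_equal(quality_index(tri2, part), 0.5)
  expect_equal(quality_index(tri2, setNames(rep(1, 6), ids)), 0)

  for (seed in 1:10) {
    net <- rand_bip(sample(4:10, 1), sample(4:10, 1), sample(8:25, 1), seed)
    part <- rand_partition(c(net$loops$loop_id, net$domains$sf_id), 3,
                           seed + 300)
    expect_equal(quality_index(net, part), ng_modularity(net, part),
                 tolerance = 1e-12)
  }
})

test_that("clustering coefficient handles triangles, stars and bipartite input", {
  ids <- c("a", "b", "c")
  tri <- efnet:::new_projection(
    "loop",
    nodes = tibble::tibble(id = ids, age_nd = c(0, 0.5, 1), age_gy = NA_real_),
    arcs = tibble::tibble(from = c("a", "a", "b"), to = c("b", "c", "c"),
                          weight = c(3, 1, 2))
  )
  expect_equal(clustering_coefficient(tri), 1)

  star <- efnet:::new_projection(
    "loop",
    nodes = tibble::tibble(id = c("h", "x", "y", "z"),
                           age_nd = c(0, 1, 1, 1) / 2, age_gy = NA_real_),
    arcs = tibble::tibble(from = "h", to = c("x", "y", "z"), weight = 1)
  )
  expect_equal(clustering_coefficient(star), 0)
  expect_error(clustering_coefficient(toy_net()), "unipartite")
})

test_that("heatmap elements follow the scaled formula exactly", {
  # single edge, M_nd = 1: off-diagonal 1 - (1*1)/2 = 0.5
  one <- ef_bipartite(data.frame(loop_id = "L", sf_id = "a.1.1"),
                      loops = data.frame(loop_id = "L", age_nd = 0),
                      domains = data.frame(sf_id = "a.1.1", age_nd = 0.5))
  hm <- heatmap_matrix(one, m_nd = 1)
  expect_equal(hm$matrix["L", "a.1.1"], 0.5)
  expect_equal(hm$matrix["L", "L"], -0.5)
  expect_equal(unname(heatmap_matrix(one, m_nd = 0)$matrix),
               matrix(0, 2, 2))

  for (seed in 1:6) {
    net <- rand_bip(6, 8, 18, seed)
    m_nd <- 0.7
    hm <- heatmap_matrix(net, m_nd)
    A <- efnet:::ef_adjacency(net)
    k <- rowSums(A)
    # element sum identity, against direct summation
    expect_equal(sum(hm$matrix),
                 (sum(A) - sum(k)^2 / sum(A)) * m_nd, tolerance = 1e-10)
    expect_equal(hm$matrix, t(hm$matrix))
    # rows ordered by ascending age (undated isolates sort last)
    ages <- efnet:::ef_node_ages(net)[rownames(hm$matrix)]
    expect_false(is.unsorted(ages, na.rm = TRUE))
    expect_s3_class(hm$dendrogram, "hclust")
  }
})

test_that("community detection resolves disjoint cliques and improves on one community", {
  ids <- sprintf("n%d", 1:6)
  tri2 <- efnet:::new_projection(
    "loop",
    nodes = tibble::tibble(id = ids, age_nd = seq(0, 1, length.out = 6),
                           age_gy = NA_real_),
    arcs = tibble::tibble(
      from = c("n1", "n2", "n1", "n4", "n5", "n4"),
      to = c("n2", "n3", "n3", "n5", "n6", "n6"),
      weight = 1
    )
  )
  truth <- setNames(c(1, 1, 1, 2, 2, 2), ids)
  for (method in c("fgc", "wtc", "vos")) {
    part <- detect_communities(tri2, method, seed = 1)
    expect_equal(attr(part, "n_communities"), 2)
    # same partition up to label permutation
    expect_equal(length(unique(paste(part, truth))), 2)
    expect_gte(attr(part, "quality"),
               quality_index(tri2, setNames(rep(1, 6), ids)))
  }
  # fgc dendrogram merges n - 1 times on a connected graph
  pm <- detect_communities(tri2, "fgc")
  expect_equal(nrow(attr(pm, "merges")), 4)  # two components of 3 nodes
  expect_equal(clustering_ratio(tri2, truth), 2 / 6)
})

test_that("detected communities never score below the single-community baseline", {
  for (seed in 1:5) {
    net <- rand_bip(8, 10, 25, seed)
    base <- quality_index(
      net, setNames(rep(1, 18), c(net$loops$loop_id, net$domains$sf_id)))
    for (method in c("fgc", "vos")) {
      expect_gte(attr(detect_communities(net, method, seed = seed),
                      "quality"), base)
    }
  }
})

test_that("C regressions recover a constant-C series and reject bipartite input", {
  # growing union of triangles: C = 1 at every event
  ids <- sprintf("n%d", 1:9)
  tri3 <- efnet:::new_projection(
    "loop",
    nodes = tibble::tibble(id = ids,
                           age_nd = rep(c(0.1, 0.4, 0.8), each = 3),
                           age_gy = NA_real_),
    arcs = tibble::tibble(
      from = ids[c(1, 2, 1, 4, 5, 4, 7, 8, 7)],
      to = ids[c(2, 3, 3, 5, 6, 6, 8, 9, 9)],
      weight = 1
    )
  )
  ev <- build_events(tri3)
  r <- c_regressions(ev)
  expect_true(r$ok)
  expect_equal(r$exponent_N, 0, tolerance = 1e-10)  # C constant at 1
  expect_equal(r$exponent_nd, 0, tolerance = 1e-10)
  expect_error(c_regressions(build_events(rand_bip(5, 5, 10, 1))),
               "projection")
})

test_that("the age partition drives NG_age signs as expected", {
  # all links join equal-aged nodes: positive NG_age
  within <- ef_bipartite(
    data.frame(loop_id = c("L1", "L2"), sf_id = c("a.1.1", "b.1.1")),
    loops = data.frame(loop_id = c("L1", "L2"), age_nd = c(0, 0.5)),
    domains = data.frame(sf_id = c("a.1.1", "b.1.1"), age_nd = c(0, 0.5))
  )
  expect_gt(ng_modularity(within, age_partition(within)), 0)

  # every link crosses ages: negative NG_age
  across <- ef_bipartite(
    data.frame(loop_id = c("L1", "L1"), sf_id = c("a.1.1", "b.1.1")),
    loops = data.frame(loop_id = "L1", age_nd = 0),
    domains = data.frame(sf_id = c("a.1.1", "b.1.1"), age_nd = c(0.5, 0.7))
  )
  expect_lt(ng_modularity(across, age_partition(across)), 0)

  net <- rand_bip(8, 10, 24, seed = 6)
  ev <- build_events(net)
  curve <- ng_age_series(ev)
  expect_equal(nrow(curve), nrow(ev$events))
  expect_true(all(curve$ng_age >= -1 & curve$ng_age <= 1))
})

test_that("the modularity report bundles indices within their ranges", {
  out <- synth_ef(synth_config(seed = 2))
  net <- suppressMessages(transfer_loop_ages(out$network, out$ages))
  rep_ef <- modularity_report(net, seed = 2)
  expect_true(rep_ef$vq >= 0 && rep_ef$vq <= 1)
  expect_true(rep_ef$c_ratio > 0 && rep_ef$c_ratio <= 1)
  expect_true(is.na(rep_ef$c_avg))
  expect_true(all(abs(c(rep_ef$ng_age, rep_ef$ng_vos, rep_ef$ng_fgc,
                        rep_ef$ng_wtc)) <= 1))
  set.seed(2)
  p <- project(net, "domain")
  rep_p <- modularity_report(p, seed = 2)
  expect_true(rep_p$c_avg > 0 && rep_p$c_avg <= 1)
})
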