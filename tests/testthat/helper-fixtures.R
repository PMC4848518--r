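# Fixture builders and independent brute-force oracles shared across tests.

# A tiny hand-built network with known ages: two domain "scaffolds" shared
# by overlapping loop sets, plus an isolated loop.
toy_net <- function() {
  ef_bipartite(
    edges = data.frame(
      loop_id = c("7", "6488", "7", "536", "536"),
      sf_id   = c("c.37.1", "c.37.1", "c.2.1", "c.2.1", "a.4.5")
    ),
    loops = data.frame(loop_id = c("7", "6488", "536", "9999")),
    domains = data.frame(sf_id = c("c.37.1", "c.2.1", "a.4.5"))
  )
}

toy_ages <- function() {
  age_table(data.frame(
    sf_id = c("c.37.1", "c.2.1", "a.4.5"),
    age_nd = c(0.0, 0.2, 0.5)
  ))
}

# Random bipartite network with distinct node ages, for property tests.
rand_bip <- function(n1, n2, n_edges, seed) {
  set.seed(seed)
  loops <- as.character(seq_len(n1))
  domains <- sprintf("c.%d.1", seq_len(n2))
  all_pairs <- expand.grid(loop_id = loops, sf_id = domains,
                           stringsAsFactors = FALSE)
  pick <- sample(nrow(all_pairs), min(n_edges, nrow(all_pairs)))
  net <- ef_bipartite(all_pairs[pick, ],
                      loops = data.frame(loop_id = loops),
                      domains = data.frame(sf_id = domains))
  ages <- age_table(data.frame(sf_id = domains,
                               age_nd = round(runif(n2), 6)))
  suppressMessages(transfer_loop_ages(net, ages, clock = NULL))
}

# Random directed weighted projection over nodes with random ages.
rand_projection <- function(n, n_arcs, seed) {
  set.seed(seed)
  ids <- sprintf("n%02d", seq_len(n))
  pairs <- t(combn(ids, 2))
  pick <- sample(nrow(pairs), min(n_arcs, nrow(pairs)))
  flip <- runif(length(pick)) < 0.5
  efnet:::new_projection(
    mode = "loop",
    nodes = tibble::tibble(id = ids, age_nd = round(runif(n), 6),
                           age_gy = NA_real_),
    arcs = tibble::tibble(
      from = ifelse(flip, pairs[pick, 2], pairs[pick, 1]),
      to = ifelse(flip, pairs[pick, 1], pairs[pick, 2]),
      weight = sample(1:4, length(pick), replace = TRUE)
    )
  )
}

# Brute-force unimodal projection: shared-counterpart counts over all pairs.
brute_shared_counts <- function(net, mode) {
  if (mode == "loop") {
    ids <- net$loops$loop_id
    nbr <- function(id) net$edges$sf_id[net$edges$loop_id == id]
  } else {
    ids <- net$domains$sf_id
    nbr <- function(id) net$edges$loop_id[net$edges$sf_id == id]
  }
  out <- list()
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (i < j) {
      w <- length(intersect(nbr(ids[i]), nbr(ids[j])))
      if (w > 0) out[[length(out) + 1]] <-
          data.frame(u = ids[i], v = ids[j], weight = w)
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(u = character(), v = character(), weight = numeric())
}

# Brute-force Newman-Girvan modularity: literal double loop over the formula.
brute_ng <- function(A, labels) {
  two_m <- sum(A)
  if (two_m == 0) return(0)
  k <- rowSums(A)
  q <- 0
  for (i in seq_len(nrow(A))) for (j in seq_len(ncol(A))) {
    if (labels[i] == labels[j]) {
      q <- q + (A[i, j] - k[i] * k[j] / two_m)
    }
  }
  unname(q / two_m)
}

# Membership vector named by node id, random labels.
rand_partition <- function(ids, n_comm, seed) {
  set.seed(seed)
  structure(setNames(sample(seq_len(n_comm), length(ids), replace = TRUE),
                     ids))
}

expect_same_network <- function(a, b) {
  expect_setequal(a$loops$loop_id, b$loops$loop_id)
  expect_setequal(a$domains$sf_id, b$domains$sf_id)
  key <- function(n) sort(paste(n$edges$loop_id, n$edges$sf_id))
  expect_identical(key(a), key(b))
}
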