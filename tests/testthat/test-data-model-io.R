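test_that("association tables collapse duplicates and validate ids", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("loop_id\tsf_id",
               "7\tc.37.1",
               "6488\tc.37.1",
               "7\tc.37.1"), path)
  net <- suppressMessages(read_association_table(path))
  expect_equal(nrow(net$loops), 2)
  expect_equal(nrow(net$domains), 1)
  expect_equal(nrow(net$edges), 2)
  expect_message(read_association_table(path), "1 duplicate")

  # collapsing is idempotent
  net2 <- ef_bipartite(net$edges, loops = net$loops, domains = net$domains)
  expect_same_network(net, net2)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("loop_id\tsf_id", "7\tx37"), bad)
  expect_error(read_association_table(bad, strict = TRUE), "Malformed")
  expect_warning(lax <- read_association_table(bad, strict = FALSE),
                 "malformed")
  expect_equal(nrow(lax$edges), 0)

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("loop_id\tsf_id", empty)
  expect_error(read_association_table(empty), "Empty")
})

test_that("a paper-scale association table yields the expected dimensions", {
  out <- synth_ef(synth_config(seed = 11))
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(out$network$edges, path)
  net <- read_association_table(path)
  expect_equal(nrow(net$edges), 134)
  expect_lte(nrow(net$loops), 38)
  expect_lte(nrow(net$domains), 82)
})

test_that("age tables parse, and reject out-of-range or conflicting rows", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sf_id\tnd", "c.37.1\t0.0", "a.4.5\t0.25"), path)
  ages <- read_age_table(path)
  expect_s3_class(ages, "ef_age_table")
  expect_equal(ages$age_nd[ages$sf_id == "c.37.1"], 0)
  expect_equal(ages$age_nd[ages$sf_id == "a.4.5"], 0.25)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sf_id\tnd", "a.4.5\t1.5"), bad)
  expect_error(read_age_table(bad), "a\\.4\\.5")

  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sf_id\tnd", "c.2.1\t0.1", "c.2.1\t0.2"), dup)
  expect_error(read_age_table(dup), "c\\.2\\.1")

  # exact duplicates are tolerated (not a conflict)
  dup2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sf_id\tnd", "c.2.1\t0.1", "c.2.1\t0.1"), dup2)
  expect_equal(nrow(read_age_table(dup2)), 1)
})

test_that("pajek export uses the two-mode convention and round-trips", {
  net <- toy_net()
  path <- withr::local_tempfile(fileext = ".net")
  write_pajek(net, path)
  lines <- readLines(path)
  expect_equal(lines[1], "*vertices 7 4")  # loops occupy indices 1..n1
  expect_true("*edges" %in% lines)

  back <- read_pajek(path)
  expect_same_network(net, back)

  # a directed projection writes *arcs, with weights intact
  p <- rand_projection(8, 12, seed = 3)
  ppath <- withr::local_tempfile(fileext = ".net")
  write_pajek(p, ppath, partition = setNames(rep(1L, 8), p$nodes$id))
  plines <- readLines(ppath)
  expect_true("*arcs" %in% plines)
  expect_false(any(plines == "*edges"))
  expect_true(file.exists(sub("\\.net$", ".clu", ppath)))

  pback <- read_pajek(ppath)
  expect_setequal(pback$nodes$id, p$nodes$id)
  key <- function(x) sort(paste(x$arcs$from, x$arcs$to, x$arcs$weight))
  expect_identical(key(pback), key(p))
})

test_that("pajek round trip is identity on random 10-node graphs", {
  for (seed in 1:3) {
    net <- rand_bip(5, 5, 12, seed)
    path <- withr::local_tempfile(fileext = ".net")
    write_pajek(net, path)
    expect_same_network(net, read_pajek(path))
  }
})

test_that("graphml round trip preserves node sets, edges and ages", {
  out <- synth_ef(synth_config(n_loops = 8, n_domains = 10, n_edges = 20,
                               seed = 5))
  net <- suppressMessages(transfer_loop_ages(out$network, out$ages))
  path <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(net, path)
  back <- read_graphml(path)
  expect_same_network(net, back)
  ages_in <- setNames(net$domains$age_nd, net$domains$sf_id)
  ages_out <- setNames(back$domains$age_nd, back$domains$sf_id)
  expect_equal(ages_out[names(ages_in)], ages_in, tolerance = 1e-12)

  # a specific attribute value survives
  one <- ef_bipartite(data.frame(loop_id = "1", sf_id = "c.1.1"),
                      domains = data.frame(sf_id = "c.1.1", age_nd = 0.25))
  p1 <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(one, p1)
  expect_equal(read_graphml(p1)$domains$age_nd, 0.25)

  # projections round-trip direction and weight
  p <- rand_projection(9, 14, seed = 8)
  p2 <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(p, p2)
  pback <- read_graphml(p2)
  key <- function(x) sort(paste(x$arcs$from, x$arcs$to, x$arcs$weight))
  expect_identical(key(pback), key(p))
  expect_equal(pback$mode, "loop")
})
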