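#' Read a loop-domain association table
#'
#' Reads a delimited table of loop-prototype / domain-superfamily
#' associations (one row per association) and assembles the bipartite
#' network. Duplicate rows collapse to a single edge; the count of collapsed
#' duplicates is reported. An optional third column of proteome hit counts is
#' tolerated but ignored: associations are unweighted by design.
#'
#' @param path Path to the table.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @param header Does the file carry a header row? Default `TRUE`.
#' @param strict If `TRUE`, a malformed SCOP id aborts; otherwise the row is
#'   dropped with a warning.
#' @return An [ef_bipartite()] network with ages unset.
#' @export
read_association_table <- function(path, dialect = c("tsv", "csv"),
                                   header = TRUE, strict = FALSE) {
  dialect <- match.arg(dialect)
  reader <- if (dialect == "tsv") readr::read_tsv else readr::read_csv
  tbl <- reader(path, col_names = header, show_col_types = FALSE,
                col_types = readr::cols(.default = readr::col_character()))
  if (nrow(tbl) == 0) abort(sprintf("Empty association table: %s", path))
  if (ncol(tbl) < 2) abort("Association table needs >= 2 columns (loop_id, sf_id).")
  edges <- tibble(loop_id = as.character(tbl[[1]]),
                  sf_id = as.character(tbl[[2]]))
  ef_bipartite(edges, strict = strict)
}

#' Read a domain age table
#'
#' Reads a two-column table mapping SCOP superfamily ids to relative ages
#' `nd` in `[0, 1]` (0 = oldest). Conflicting duplicate entries and
#' out-of-range ages are errors.
#'
#' @param path Path to the table.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @param header Does the file carry a header row? Default `TRUE`.
#' @return A tibble with columns `sf_id`, `age_nd` (class `ef_age_table`).
#' @export
read_age_table <- function(path, dialect = c("tsv", "csv"), header = TRUE) {
  dialect <- match.arg(dialect)
  reader <- if (dialect == "tsv") readr::read_tsv else readr::read_csv
  tbl <- reader(path, col_names = header, show_col_types = FALSE,
                col_types = readr::cols(.default = readr::col_character()))
  if (ncol(tbl) < 2) abort("Age table needs 2 columns (sf_id, nd).")
  ages <- tibble(sf_id = as.character(tbl[[1]]),
                 age_nd = as.numeric(tbl[[2]]))
  age_table(ages)
}

#' Build a domain age table from a data frame
#'
#' @param ages Data frame with columns `sf_id` and `age_nd`.
#' @return The validated tibble with class `ef_age_table` prepended.
#' @export
age_table <- function(ages) {
  stopifnot(is.data.frame(ages), all(c("sf_id", "age_nd") %in% names(ages)))
  ages <- as_tibble(ages)[, c("sf_id", "age_nd")]
  bad <- is.na(ages$age_nd) | ages$age_nd < 0 | ages$age_nd > 1
  if (any(bad)) {
    abort(sprintf("Age out of [0, 1] (or unparseable) for: %s",
                  paste(head(ages$sf_id[bad], 5), collapse = ", ")))
  }
  dup <- ages |> distinct() |> count(.data$sf_id) |> filter(n > 1)
  if (nrow(dup)) {
    abort(sprintf("Conflicting duplicate ages for: %s",
                  paste(head(dup$sf_id, 5), collapse = ", ")))
  }
  ages <- distinct(ages)
  class(ages) <- c("ef_age_table", class(ages))
  ages
}

#' Write a network in Pajek format
#'
#' Writes a `.net` file (and, when `partition` is given, a companion `.clu`
#' partition file). Bipartite networks use the Pajek two-mode header
#' `*vertices N n1` with loops occupying vertex indices `1..n1`; projections
#' emit an `*arcs` section with weights.
#'
#' @param net An `ef_bipartite` or `ef_projection` object.
#' @param path Output `.net` path.
#' @param partition Optional named vector (or `ef_partition`) of integer
#'   community labels keyed by node id; written to `<path base>.clu`.
#' @return `path`, invisibly.
#' @export
write_pajek <- function(net, path, partition = NULL) {
  ids <- pajek_vertex_ids(net)
  n <- length(ids)
  if (n == 0) abort("Refusing to write an empty network.")
  lines <- character(0)
  if (inherits(net, "ef_bipartite")) {
    lines <- c(lines, sprintf("*vertices %d %d", n, nrow(net$loops)))
    lines <- c(lines, sprintf('%d "%s"', seq_len(n), ids))
    idx <- setNames(seq_len(n), ids)
    lines <- c(lines, "*edges")
    lines <- c(lines, sprintf("%d %d 1", idx[net$edges$loop_id],
                              idx[net$edges$sf_id]))
  } else {
    lines <- c(lines, sprintf("*vertices %d", n))
    lines <- c(lines, sprintf('%d "%s"', seq_len(n), ids))
    idx <- setNames(seq_len(n), ids)
    lines <- c(lines, "*arcs")
    lines <- c(lines, sprintf("%d %d %d", idx[net$arcs$from], idx[net$arcs$to],
                              as.integer(net$arcs$weight)))
  }
  writeLines(lines, path)
  if (!is.null(partition)) {
    part <- unclass(partition)
    if (is.null(names(part))) abort("`partition` must be named by node id.")
    clu <- c(sprintf("*vertices %d", n), as.character(as.integer(part[ids])))
    writeLines(clu, sub("\\.net$", "", path) |> paste0(".clu"))
  }
  invisible(path)
}

pajek_vertex_ids <- function(net) {
  if (inherits(net, "ef_bipartite")) {
    c(net$loops$loop_id, net$domains$sf_id)
  } else if (inherits(net, "ef_projection")) {
    net$nodes$id
  } else {
    abort("Unsupported network class for Pajek export.")
  }
}

#' Read a network written by [write_pajek()]
#'
#' Two-mode files are returned as `ef_bipartite` (ages unset); one-mode files
#' with an `*arcs` section are returned as `ef_projection` (ages unset, mode
#' unknown).
#'
#' @param path Path to the `.net` file.
#' @return An `ef_bipartite` or bare projection-shaped list.
#' @export
read_pajek <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  hdr <- strsplit(tolower(lines[1]), "\\s+")[[1]]
  if (hdr[1] != "*vertices") abort("Not a Pajek .net file (missing *vertices).")
  n <- as.integer(hdr[2])
  two_mode <- length(hdr) >= 3
  vlines <- lines[2:(1 + n)]
  ids <- sub('^\\s*\\d+\\s+"(.*)".*$', "\\1", vlines)
  rest <- lines[-(1:(1 + n))]
  sec_i <- grep("^\\*", rest)
  section <- tolower(rest[sec_i[1]])
  body <- if (length(rest) > sec_i[1]) rest[(sec_i[1] + 1):length(rest)] else character(0)
  parts <- strsplit(body, "\\s+")
  from <- ids[vapply(parts, function(p) as.integer(p[1]), integer(1))]
  to <- ids[vapply(parts, function(p) as.integer(p[2]), integer(1))]
  w <- vapply(parts, function(p) if (length(p) >= 3) as.numeric(p[3]) else 1,
              numeric(1))
  if (two_mode) {
    n1 <- as.integer(hdr[3])
    ef_bipartite(
      edges = tibble(loop_id = from, sf_id = to),
      loops = tibble(loop_id = ids[seq_len(n1)]),
      domains = tibble(sf_id = ids[seq(n1 + 1, n)])
    )
  } else {
    if (!startsWith(section, "*arcs")) abort("One-mode file without *arcs.")
    new_projection(
      mode = "unknown",
      nodes = tibble(id = ids, age_nd = NA_real_, age_gy = NA_real_),
      arcs = tibble(from = from, to = to, weight = w)
    )
  }
}

#' Write / read GraphML with age annotations
#'
#' Thin wrappers over [igraph::write_graph()] / [igraph::read_graph()] that
#' preserve node ages and, for projections, arc weights and direction.
#'
#' @param net An `ef_bipartite` or `ef_projection` object.
#' @param path Output file path.
#' @return `path` invisibly for the writer; for the reader, an
#'   `ef_bipartite` or `ef_projection` reconstructed from the file.
#' @export
write_graphml <- function(net, path) {
  g <- as_igraph(net)
  if (inherits(net, "ef_projection")) {
    g <- igraph::set_graph_attr(g, "mode", net$mode)
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname write_graphml
#' @export
read_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  vat <- igraph::vertex_attr(g)
  if (!igraph::is_directed(g)) {
    type <- as.logical(vat$type)
    el <- igraph::as_edgelist(g)
    nd <- vat$age_nd %||% rep(NA_real_, length(type))
    gy <- vat$age_gy %||% rep(NA_real_, length(type))
    # graphml NaN round-trips NA
    nd[is.nan(nd)] <- NA_real_
    gy[is.nan(gy)] <- NA_real_
    loop_first <- el[, 1] %in% vat$name[!type]
    ef_bipartite(
      edges = tibble(loop_id = ifelse(loop_first, el[, 1], el[, 2]),
                     sf_id = ifelse(loop_first, el[, 2], el[, 1])),
      loops = tibble(loop_id = vat$name[!type], age_nd = nd[!type],
                     age_gy = gy[!type]),
      domains = tibble(sf_id = vat$name[type], age_nd = nd[type],
                       age_gy = gy[type])
    )
  } else {
    el <- igraph::as_edgelist(g)
    nd <- vat$age_nd %||% rep(NA_real_, length(vat$name))
    nd[is.nan(nd)] <- NA_real_
    gy <- vat$age_gy %||% rep(NA_real_, length(vat$name))
    gy[is.nan(gy)] <- NA_real_
    new_projection(
      mode = igraph::graph_attr(g, "mode") %||% "unknown",
      nodes = tibble(id = vat$name, age_nd = nd, age_gy = gy),
      arcs = tibble(from = el[, 1], to = el[, 2],
                    weight = igraph::edge_attr(g, "weight") %||%
                      rep(1, nrow(el)))
    )
  }
}
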