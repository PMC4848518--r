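#' Waterfall layout coordinates
#'
#' Computes the coordinate table behind a waterfall diagram: nodes are
#' arranged top-down by relative age (`y = age_nd`, origin at the top), and
#' horizontally grouped by community with deterministic within-group
#' ordering by age then id. Glyph dimensions encode connectivity shifted by
#' 10 so 0-degree nodes stay visible (a rendering convention only — never
#' applied in statistics): for projections, width is weighted outdegree + 10
#' and height weighted indegree + 10; for bipartite networks both encode
#' weighted degree.
#'
#' @param net An [ef_bipartite()] network or `ef_projection`, ages set.
#' @param partition Optional `ef_partition` for horizontal grouping; by
#'   default communities are detected with `"fgc"`.
#' @param clock An [ef_clock()] for the secondary Gy axis.
#' @return A tibble: `id`, `class`, `age_nd`, `age_gy`, `community`, `x`,
#'   `y`, `width`, `height`, `event`.
#' @export
waterfall_layout <- function(net, partition = NULL, clock = ef_clock()) {
  ages <- ef_node_ages(net)
  if (any(is.na(ages))) {
    abort("All node ages must be set for a waterfall layout.")
  }
  if (is.null(partition)) partition <- detect_communities(net, "fgc")
  part <- check_partition(net, partition)

  if (inherits(net, "ef_bipartite")) {
    wdeg <- c(bipartite_degrees(net, "loop"), bipartite_degrees(net, "domain"))
    width <- wdeg + 10
    height <- wdeg + 10
    cls <- c(rep("loop", nrow(net$loops)), rep("domain", nrow(net$domains)))
  } else {
    width <- snapshot_degrees(net, "out") + 10
    height <- snapshot_degrees(net, "in") + 10
    cls <- rep(net$mode, nrow(net$nodes))
  }

  lev <- sort(unique(ages))
  tibble(
    id = names(ages), class = cls, age_nd = unname(ages),
    age_gy = apply_clock(unname(ages), clock),
    community = unname(part),
    width = unname(width[names(ages)]),
    height = unname(height[names(ages)]),
    event = match(ages, lev)
  ) |>
    arrange(.data$community, .data$age_nd, .data$id) |>
    mutate(x = dplyr::row_number(), y = .data$age_nd)
}

#' Waterfall diagram of an age-annotated network
#'
#' Renders nodes top-down by age (dual axes: relative `nd` and geological
#' Gy through the molecular clock) with arcs drawn from older to younger
#' nodes, arc width and grey level proportional to weight, and glyph size
#' encoding weighted degree (out/in for projections). The layout is
#' deterministic; the coordinate table is available via
#' [waterfall_layout()] so rendered figures are auditable.
#'
#' @inheritParams waterfall_layout
#' @return A [ggplot2::ggplot] object.
#' @export
plot_waterfall <- function(net, partition = NULL, clock = ef_clock()) {
  lay <- waterfall_layout(net, partition, clock)
  pos <- lay |> select("id", "x", "y")

  seg <- if (inherits(net, "ef_bipartite")) {
    net$edges |>
      mutate(weight = 1) |>
      left_join(pos, by = c(loop_id = "id")) |>
      rename(x0 = "x", y0 = "y") |>
      left_join(pos, by = c(sf_id = "id")) |>
      rename(x1 = "x", y1 = "y")
  } else {
    net$arcs |>
      left_join(pos, by = c(from = "id")) |>
      rename(x0 = "x", y0 = "y") |>
      left_join(pos, by = c(to = "id")) |>
      rename(x1 = "x", y1 = "y")
  }

  gy_breaks <- seq(0, 1, 0.25)
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x1,
                   yend = .data$y1, linewidth = .data$weight,
                   alpha = .data$weight),
      colour = "grey30"
    ) +
    ggplot2::geom_point(
      data = lay,
      ggplot2::aes(x = .data$x, y = .data$y, size = .data$width,
                   fill = factor(.data$event),
                   shape = .data$class),
      colour = "grey20"
    ) +
    ggplot2::scale_shape_manual(
      values = c(loop = 21, domain = 23, unknown = 22)) +
    ggplot2::scale_linewidth(range = c(0.2, 1.5), guide = "none") +
    ggplot2::scale_alpha(range = c(0.25, 0.9), guide = "none") +
    ggplot2::scale_y_reverse(
      name = "relative age (nd)",
      sec.axis = ggplot2::sec_axis(~ apply_clock(., clock),
                                   name = "geological age (Gy)",
                                   breaks = apply_clock(gy_breaks, clock))
    ) +
    ggplot2::scale_fill_viridis_d(guide = "none") +
    ggplot2::labs(x = NULL, size = "weighted degree + 10",
                  shape = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid.major.x = ggplot2::element_blank())
}

#' Stacked bars of chronological connectivity accumulation
#'
#' One bar per node, stacked by the age bin of its partners (10 bins by
#' convention, coloured old-to-young), faceted by arc direction: incoming
#' partners appeared earlier in evolution, outgoing partners later. Stack
#' heights equal the bin counts from [accumulation_bins()].
#'
#' @param bins A tibble from [accumulation_bins()].
#' @param n_bins Number of bins used (for a complete legend); default 10.
#' @return A [ggplot2::ggplot] object.
#' @export
plot_accumulation_bars <- function(bins, n_bins = 10) {
  stopifnot(is.data.frame(bins))
  bins <- bins |>
    mutate(bin = factor(.data$bin, levels = seq_len(n_bins)),
           id = stats::reorder(.data$id, .data$age_nd))
  ggplot2::ggplot(bins,
                  ggplot2::aes(x = .data$id, y = .data$count,
                               fill = .data$bin)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::facet_wrap(~ .data$direction, ncol = 1, scales = "free_y") +
    ggplot2::scale_fill_manual(
      values = grDevices::rainbow(n_bins, end = 0.8),
      drop = FALSE, name = "partner age bin") +
    ggplot2::labs(x = NULL, y = "partners") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       size = 6))
}

#' @export
autoplot.ef_heatmap <- function(object, ...) {
  B <- object$matrix
  df <- as_tibble(as.table(B), .name_repair = ~ c("row", "col", "value"))
  df$row <- factor(df$row, levels = rownames(B))
  df$col <- factor(df$col, levels = colnames(B))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red", midpoint = 0,
                                  name = "scaled\nmodularity") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_text(size = 5),
                   axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' @export
autoplot.ef_events <- function(object, ...) {
  ggplot2::ggplot(object$events,
                  ggplot2::aes(x = .data$nd)) +
    ggplot2::geom_step(ggplot2::aes(y = .data$n_nodes,
                                    colour = "nodes")) +
    ggplot2::geom_step(ggplot2::aes(y = .data$n_links,
                                    colour = "links")) +
    ggplot2::labs(x = "relative age (nd)", y = "count", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
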