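# broom-style tidiers and ggplot2 autoplot methods.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data %||%
NULL

#' Tidy a median-joining network into its edge table
#' @param x An `mj_network`.
#' @param ... Unused.
#' @return Tibble with one row per branch: `from`, `to`, `length`,
#'   `n_labels`, `labels` (list column of changing positions).
#' @export
tidy.mj_network <- function(x, ...) x$edges

#' One-row summary of a median-joining network
#' @param x An `mj_network`.
#' @param ... Unused.
#' @return Tibble: `n_nodes`, `n_observed`, `n_medians`, `n_edges`,
#'   `n_positions`, `spanning_length`, `epsilon`.
#' @export
glance.mj_network <- function(x, ...) {
  tibble::tibble(
    n_nodes = nrow(x$nodes),
    n_observed = sum(!x$nodes$is_median),
    n_medians = sum(x$nodes$is_median),
    n_edges = nrow(x$edges),
    n_positions = length(x$positions),
    spanning_length = x$spanning_length,
    epsilon = x$epsilon
  )
}

#' Tidy a damage spectrum into its 12-change table
#' @param x A `damage_spectrum`.
#' @param ... Unused.
#' @return Tibble with columns `change`, `from`, `to`, `pair`, `raw`,
#'   `scaled`.
#' @export
tidy.damage_spectrum <- function(x, ...) x$table

#' One-row summary of a damage spectrum
#' @param x A `damage_spectrum`.
#' @param ... Unused.
#' @return Tibble: `group_id`, `n_reads`, `type1`, `type2`, `ratio21`,
#'   `type1_raw`, `type2_raw`, `ratio21_raw`.
#' @export
glance.damage_spectrum <- function(x, ...) {
  tibble::tibble(group_id = x$group_id, n_reads = x$n_reads,
                 type1 = x$type1, type2 = x$type2, ratio21 = x$ratio21,
                 type1_raw = x$type1_raw, type2_raw = x$type2_raw,
                 ratio21_raw = x$ratio21_raw)
}

#' Per-group table of a pooled type-ratio summary
#' @param x A `type_ratio_summary` from [type_ratio()].
#' @param ... Unused.
#' @return The per-group tibble.
#' @export
tidy.type_ratio_summary <- function(x, ...) x$per_group

#' Pooled row of a type-ratio summary
#' @param x A `type_ratio_summary` from [type_ratio()].
#' @param ... Unused.
#' @return The one-row pooled tibble.
#' @export
glance.type_ratio_summary <- function(x, ...) x$pooled

#' Plot a median-joining network
#'
#' Observed clusters are drawn as circles scaled by member count, median
#' vectors as small black dots, and branches annotated with the number of
#' mutation labels they carry.
#'
#' @param object An `mj_network`.
#' @param label_edges Annotate branches with their label counts.
#' @param seed Layout seed (Fruchterman-Reingold).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mj_network <- function(object, label_edges = TRUE, seed = 42L, ...) {
  g <- as_igraph(object)
  xy <- withr::with_seed(seed, igraph::layout_with_fr(
    g, weights = igraph::E(g)$weight))
  lay <- tibble::tibble(id = igraph::V(g)$name, x = xy[, 1], y = xy[, 2])
  nodes <- dplyr::left_join(object$nodes, lay, by = "id")
  edges <- dplyr::left_join(
    dplyr::left_join(object$edges, lay, by = c(from = "id")),
    lay, by = c(to = "id"), suffix = c("", "end"))
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$xend, yend = .data$yend),
      colour = "grey40") +
    ggplot2::geom_point(
      data = dplyr::filter(nodes, !.data$is_median),
      ggplot2::aes(x = .data$x, y = .data$y, size = .data$n_members),
      shape = 21, fill = "steelblue", colour = "black") +
    ggplot2::geom_point(
      data = dplyr::filter(nodes, .data$is_median),
      ggplot2::aes(x = .data$x, y = .data$y),
      shape = 16, size = 1.6, colour = "black") +
    ggplot2::geom_text(
      data = dplyr::filter(nodes, !.data$is_median),
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$id),
      vjust = -1.2, size = 3) +
    ggplot2::scale_size_area(max_size = 10, name = "haplotypes") +
    ggplot2::theme_void()
  if (label_edges) {
    p <- p + ggplot2::geom_text(
      data = edges,
      ggplot2::aes(x = (.data$x + .data$xend) / 2,
                   y = (.data$y + .data$yend) / 2,
                   label = .data$n_labels),
      size = 2.8, colour = "grey25")
  }
  p
}

#' Plot a misincorporation spectrum
#'
#' Bar chart of the 12 directed changes (scaled counts), coloured by
#' complementary pair; the type-2 classes C>T/G>A stand out for authentic
#' ancient templates.
#'
#' @param object A `damage_spectrum`.
#' @param scaled Plot scaled (default) or raw counts.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.damage_spectrum <- function(object, scaled = TRUE, ...) {
  col <- if (scaled) "scaled" else "raw"
  ggplot2::ggplot(object$table,
                  ggplot2::aes(x = .data$change, y = .data[[col]],
                               fill = .data$pair)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "directed base change",
                  y = if (scaled) "scaled count" else "raw count",
                  title = paste0(object$group_id, ": type2/type1 = ",
                                 signif(object$ratio21, 3)),
                  fill = "complementary pair") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
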