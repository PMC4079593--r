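# Network annotation: per-position mutation frequencies, hotspot detection,
# inverse-frequency weighting and haplogroup-diagnostic motif inference.

#' Per-position mutation frequencies of a network
#'
#' The frequency of a position is the number of network branches (edges,
#' including those incident to median vectors) whose label set contains it.
#' Positions mutating on several independent branches are homoplasic; the
#' maximal-frequency positions are flagged as hotspot candidates.
#'
#' @param net A [build_mj_network()] result.
#' @return Tibble of class `freq_table` with columns `position`, `freq`,
#'   sorted by decreasing frequency; hotspot positions (all ties at the
#'   maximum) in `attr(, "hotspots")`, retrievable via [hotspots()].
#' @export
mutation_frequencies <- function(net) {
  stopifnot(inherits(net, "mj_network"))
  pos <- unlist(net$edges$labels)
  if (length(pos) == 0L) {
    out <- tibble::tibble(position = character(), freq = integer())
  } else {
    tab <- table(pos)
    out <- tibble::tibble(position = names(tab), freq = as.integer(tab))
    out <- dplyr::arrange(out, dplyr::desc(.data$freq), .data$position)
  }
  class(out) <- c("freq_table", class(out))
  attr(out, "hotspots") <- if (nrow(out) == 0L) character() else
    sort(out$position[out$freq == max(out$freq)])
  out
}

#' Hotspot positions of a frequency table
#' @param ft A [mutation_frequencies()] result.
#' @return Character vector of maximal-frequency positions.
#' @export
hotspots <- function(ft) attr(ft, "hotspots")

#' Inverse-frequency position weights
#'
#' Maps mutation frequencies to integer weights in inverse proportion:
#' `w = clamp(round(scale / freq), 1, 99)`. Positions absent from the table
#' (never observed mutating) receive the full weight `scale`.
#'
#' @param ft A [mutation_frequencies()] result (or tibble with `position`,
#'   `freq`).
#' @param scale Positive integer weight scale (default 10).
#' @param positions Optional character vector of all positions that need a
#'   weight; defaults to the table's own positions.
#' @return Tibble with columns `position`, `weight`.
#' @export
inverse_frequency_weights <- function(ft, scale = 10L, positions = NULL) {
  scale <- as.integer(scale)
  if (is.na(scale) || scale <= 0L) stop("scale must be a positive integer",
                                        call. = FALSE)
  if (is.null(positions)) positions <- ft$position
  f <- stats::setNames(ft$freq, ft$position)[positions]
  w <- ifelse(is.na(f), scale, pmin(pmax(round(scale / f), 1L), 99L))
  tibble::tibble(position = positions, weight = as.integer(w))
}

#' Infer the diagnostic motif of a haplogroup from the network
#'
#' The haplogroup's stem is the minimal edge cut separating its nodes from
#' the rest of the network; each stem position is reported with its
#' network-wide mutation frequency, and the motif is the frequency-1 subset
#' (positions mutating nowhere else, hence diagnostic). The ancestor
#' candidate is the observed node outside the haplogroup adjacent to the
#' cut that lies closest to it. Reticulate structures in which the
#' haplogroup side cannot be cleanly separated (the cut strands foreign
#' observed nodes with the haplogroup, or leaves the haplogroup side
#' disconnected) raise a topology error rather than guessing.
#'
#' @param net A [build_mj_network()] result.
#' @param haplogroup_nodes Character vector of observed node ids forming the
#'   haplogroup.
#' @param ft Optional precomputed [mutation_frequencies()] table.
#' @param haplogroup Name used in the report (default derived from nodes).
#' @return List of class `motif_report`: `haplogroup`, `stem_positions`
#'   (tibble `position`, `freq`), `motif` (character vector),
#'   `ancestor_candidate`, `cut_edges` (tibble).
#' @export
infer_motif <- function(net, haplogroup_nodes, ft = NULL,
                        haplogroup = NULL) {
  stopifnot(inherits(net, "mj_network"))
  haplogroup_nodes <- as.character(haplogroup_nodes)
  obs <- net$nodes$id[!net$nodes$is_median]
  unknown <- setdiff(haplogroup_nodes, obs)
  if (length(unknown) > 0) {
    stop("unknown or non-observed node id(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  rest <- setdiff(obs, haplogroup_nodes)
  if (length(haplogroup_nodes) == 0L || length(rest) == 0L) {
    stop("haplogroup must be a non-empty proper subset of observed nodes",
         call. = FALSE)
  }
  if (is.null(ft)) ft <- mutation_frequencies(net)
  g <- as_igraph(net)
  # minimum edge cut (edge count) separating the haplogroup from the rest;
  # median vectors fall on either side as the cut dictates
  gc <- g
  gc <- igraph::add_vertices(gc, 2, name = c(".src", ".snk"))
  big <- igraph::ecount(g) + length(haplogroup_nodes) + length(rest) + 1
  for (v in haplogroup_nodes) gc <- igraph::add_edges(gc, c(".src", v))
  for (v in rest) gc <- igraph::add_edges(gc, c(".snk", v))
  cap <- c(rep(1, igraph::ecount(g)),
           rep(big, length(haplogroup_nodes) + length(rest)))
  mc <- igraph::min_cut(gc, source = ".src", target = ".snk",
                        capacity = cap, value.only = FALSE)
  if (mc$value >= big) {
    stop("haplogroup is not separable from the rest of the network",
         call. = FALSE)
  }
  side_h <- setdiff(igraph::V(gc)$name[mc$partition1], c(".src", ".snk"))
  side_r <- setdiff(igraph::V(gc)$name[mc$partition2], c(".src", ".snk"))
  if (!all(haplogroup_nodes %in% side_h)) {
    tmp <- side_h; side_h <- side_r; side_r <- tmp
  }
  foreign <- intersect(side_h, rest)
  if (length(foreign) > 0) {
    stop("topology error: minimal cut strands observed node(s) ",
         paste(foreign, collapse = ", "),
         " with the haplogroup; reticulation prevents motif inference",
         call. = FALSE)
  }
  sub_h <- igraph::induced_subgraph(g, side_h)
  if (igraph::components(sub_h)$no != 1L) {
    stop("topology error: haplogroup side of the cut is disconnected",
         call. = FALSE)
  }
  # cut edges in the original network
  eidx <- which(apply(igraph::as_edgelist(g), 1, function(e) {
    (e[1] %in% side_h) != (e[2] %in% side_h)
  }))
  el <- igraph::as_edgelist(g)[eidx, , drop = FALSE]
  lab <- strsplit(igraph::E(g)$labels[eidx], ",", fixed = TRUE)
  cut_edges <- tibble::tibble(
    from = el[, 1], to = el[, 2],
    labels = lapply(lab, function(x) x[nzchar(x)])
  )
  stem <- sort(unique(unlist(cut_edges$labels)))
  fmap <- stats::setNames(ft$freq, ft$position)
  stem_tbl <- tibble::tibble(position = stem,
                             freq = as.integer(fmap[stem]))
  motif <- stem_tbl$position[stem_tbl$freq == 1L]
  # ancestor candidate: observed node on the far side adjacent to the cut,
  # closest (weighted) to the haplogroup side; ties broken lexicographically
  ext_adj <- unique(c(el[el[, 1] %in% side_r, 1], el[el[, 2] %in% side_r, 2]))
  anc <- NA_character_
  if (length(ext_adj) > 0) {
    cand <- ext_adj
    # walk from median adjacents to the nearest observed node if needed
    dmat <- igraph::distances(g, v = cand, to = haplogroup_nodes,
                              weights = igraph::E(g)$weight)
    near <- cand[order(apply(dmat, 1, min), cand)]
    near_obs <- near[near %in% obs]
    if (length(near_obs) > 0) {
      anc <- near_obs[1]
    } else {
      dall <- igraph::distances(g, v = intersect(side_r, obs),
                                to = haplogroup_nodes,
                                weights = igraph::E(g)$weight)
      ord <- order(apply(dall, 1, min), rownames(dall))
      anc <- rownames(dall)[ord][1]
    }
  }
  structure(list(haplogroup = haplogroup %||% paste0(
    "{", paste(haplogroup_nodes, collapse = ","), "}"),
    stem_positions = stem_tbl, motif = motif,
    ancestor_candidate = anc, cut_edges = cut_edges),
    class = "motif_report")
}

#' @export
print.motif_report <- function(x, ...) {
  cat("<motif_report> ", x$haplogroup, ": motif {",
      paste(x$motif, collapse = ", "), "}; stem of ",
      nrow(x$stem_positions), " position(s); ancestor candidate ",
      x$ancestor_candidate, "\n", sep = "")
  invisible(x)
}

#' Shortest-path placement report between two network nodes
#'
#' Reports the shortest weighted path, its total weighted length, the total
#' number of mutation labels along it, and the labels per branch —
#' supporting statements about a haplotype's placement relative to another.
#'
#' @param net A [build_mj_network()] result.
#' @param a,b Node ids.
#' @return List of class `distance_report`: `from`, `to`, `path` (node ids),
#'   `total_length` (weighted), `n_labels`, `edges` (tibble `from`, `to`,
#'   `length`, `labels`).
#' @export
cluster_distance_report <- function(net, a, b) {
  stopifnot(inherits(net, "mj_network"))
  ids <- net$nodes$id
  missing <- setdiff(c(a, b), ids)
  if (length(missing) > 0) {
    stop("unknown node id(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  g <- as_igraph(net)
  sp <- igraph::shortest_paths(g, from = a, to = b,
                               weights = igraph::E(g)$weight,
                               output = "both")
  path_v <- igraph::V(g)$name[sp$vpath[[1]]]
  eids <- sp$epath[[1]]
  lab <- strsplit(igraph::E(g)$labels[eids], ",", fixed = TRUE)
  lab <- lapply(lab, function(x) x[nzchar(x)])
  edges <- tibble::tibble(
    from = path_v[-length(path_v)], to = path_v[-1],
    length = igraph::E(g)$weight[eids],
    labels = lab
  )
  structure(list(from = a, to = b, path = path_v,
                 total_length = sum(edges$length),
                 n_labels = sum(lengths(lab)), edges = edges),
            class = "distance_report")
}

#' @export
print.distance_report <- function(x, ...) {
  cat("<distance_report> ", x$from, " -> ", x$to, ": ",
      length(x$path) - 1L, " branch(es), weighted length ", x$total_length,
      ", ", x$n_labels, " mutation label(s)\n", sep = "")
  invisible(x)
}

#' Two-pass weighted network construction
#'
#' The position weights are defined by inverse mutation frequencies, which
#' themselves require a network: the first pass builds a unit-weight
#' network, reads off the per-position frequencies, maps them to integer
#' weights, and the second pass rebuilds the network under those weights.
#'
#' @param clusters A `hap_clusters` tibble (or state matrix).
#' @param epsilon Relaxation parameter for both passes.
#' @param scale Weight scale for [inverse_frequency_weights()].
#' @return List: `network` (weighted, second pass), `first_pass`,
#'   `frequencies`, `weights`.
#' @export
build_mj_network_weighted <- function(clusters, epsilon = 0L, scale = 10L) {
  first <- build_mj_network(clusters, weights = NULL, epsilon = epsilon)
  ft <- mutation_frequencies(first)
  states <- cluster_states(clusters)
  w <- inverse_frequency_weights(ft, scale = scale,
                                 positions = colnames(states))
  net <- build_mj_network(clusters, weights = w, epsilon = epsilon)
  list(network = net, first_pass = first, frequencies = ft, weights = w)
}

#' Write a frequency table as TSV
#' @param ft A [mutation_frequencies()] result.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_frequency_tsv <- function(ft, path) {
  readr::write_tsv(tibble::as_tibble(ft), path)
  invisible(path)
}

#' Write a motif report as TSV
#' @param report A [infer_motif()] result.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_motif_tsv <- function(report, path) {
  out <- dplyr::mutate(report$stem_positions,
                       haplogroup = report$haplogroup,
                       in_motif = .data$position %in% report$motif,
                       ancestor_candidate = report$ancestor_candidate)
  readr::write_tsv(out, path)
  invisible(path)
}
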