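# Haplotype collapsing and median-joining network construction.
#
# The builder follows the classic median-joining scheme: iterate between a
# minimum spanning network (all links realisable in some minimum spanning
# tree, relaxed by an integer epsilon) and quasi-median generation over
# linked triplets, keeping cost-reducing median vectors, until a fixed
# point; finally prune synthetic nodes that no longer shorten the network.

#' Collapse identical haplotypes over the analysed region
#'
#' Haplotypes identical over the variable columns of the (gap-filtered)
#' alignment are merged into one cluster ("revised haplotype"). Under the
#' default `missing = "permissive"` mode an N matches any base and clusters
#' are formed greedily in input order, back-filling the representative
#' states; `"strict"` requires byte-identical state vectors.
#'
#' @param aln A [hap_alignment()] (gap policy already applied).
#' @param region Optional [ref_interval()] to restrict the columns first.
#' @param missing `"permissive"` (default) or `"strict"`.
#' @return A tibble of class `hap_clusters` with columns `cluster_id` (the
#'   first member's label), `n`, `members` (list column); the per-cluster
#'   state matrix over variable columns is in `attr(, "states")` and the
#'   variable position keys in `attr(, "positions")`.
#' @export
collapse_haplotypes <- function(aln, region = NULL,
                                missing = c("permissive", "strict")) {
  stopifnot(inherits(aln, "hap_alignment"))
  missing <- match.arg(missing)
  if (!is.null(region)) aln <- extract_region(aln, region)
  if (nrow(aln$mat) == 0L) stop("empty alignment", call. = FALSE)
  mat <- aln$mat
  colnames(mat) <- aln$colmap$key
  variable <- apply(mat, 2, function(x) length(unique(x[x != "N"])) >= 2L)
  vm <- mat[, variable, drop = FALSE]
  labels <- rownames(mat)
  reps <- list(); members <- list()
  for (i in seq_along(labels)) {
    v <- vm[i, ]
    placed <- FALSE
    for (k in seq_along(reps)) {
      r <- reps[[k]]
      if (missing == "strict") {
        ok <- all(r == v)
      } else {
        both <- r != "N" & v != "N"
        ok <- all(r[both] == v[both])
      }
      if (ok) {
        r[r == "N"] <- v[r == "N"]
        reps[[k]] <- r
        members[[k]] <- c(members[[k]], labels[i])
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps[[length(reps) + 1L]] <- v
      members[[length(members) + 1L]] <- labels[i]
    }
  }
  ids <- vapply(members, `[[`, "", 1)
  states <- do.call(rbind, reps)
  if (is.null(states)) states <- matrix("", 0, 0)
  rownames(states) <- ids
  colnames(states) <- colnames(vm)
  out <- tibble::tibble(cluster_id = ids,
                        n = lengths(members),
                        members = members)
  class(out) <- c("hap_clusters", class(out))
  attr(out, "states") <- states
  attr(out, "positions") <- colnames(vm)
  attr(out, "n_input") <- length(labels)
  out
}

#' State matrix of a cluster set
#' @param clusters A `hap_clusters` tibble (or a character matrix passed
#'   through unchanged).
#' @return Character matrix, rows = clusters, columns = variable positions.
#' @export
cluster_states <- function(clusters) {
  if (is.matrix(clusters)) return(clusters)
  attr(clusters, "states")
}

#' Weighted Hamming distance between state vectors
#'
#' Missing states (`N`) contribute 0; the indel character `-` is an ordinary
#' fifth state; a weight of 0 removes a column from the comparison.
#'
#' @param a,b Character state vectors of equal length.
#' @param w Numeric weights per column (default all 1).
#' @return Non-negative number (integer-valued for integer weights).
#' @export
#' @examples
#' weighted_distance(c("A", "C"), c("G", "C"))            # 1
#' weighted_distance(c("A", "C"), c("G", "T"), w = c(2, 1))  # 3
weighted_distance <- function(a, b, w = NULL) {
  if (length(a) != length(b)) stop("state vectors differ in length",
                                   call. = FALSE)
  if (is.null(w)) w <- rep(1, length(a))
  stopifnot(length(w) == length(a))
  sum(w[a != b & a != "N" & b != "N"])
}

# pairwise weighted distance matrix over the rows of a state matrix
pairwise_dist <- function(mat, w) {
  n <- nrow(mat)
  D <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (j in seq_len(ncol(mat))) {
    if (w[j] == 0) next
    m <- mat[, j]
    valid <- m != "N"
    dif <- outer(m, m, "!=") & outer(valid, valid, "&")
    D <- D + w[j] * dif
  }
  D
}

# minimax (single-linkage cophenetic) distances: sigma[i,j] is the smallest
# distance level at which i and j fall into one component
minimax_dist <- function(D) {
  n <- nrow(D)
  if (n == 2L) return(D)
  hc <- stats::hclust(stats::as.dist(D), method = "single")
  as.matrix(stats::cophenetic(hc))
}

# feasible links of the epsilon-relaxed minimum spanning network:
# d(u,v) <= sigma(u,v) + epsilon; epsilon = 0 gives the union of all MSTs
msn_links <- function(D, epsilon = 0) {
  sigma <- minimax_dist(D)
  feas <- D <= sigma + epsilon
  diag(feas) <- FALSE
  feas
}

# Prim MST length (deterministic smallest-index tie-break)
mst_length <- function(D) {
  n <- nrow(D)
  if (n < 2L) return(0)
  intree <- rep(FALSE, n)
  intree[1L] <- TRUE
  best <- D[1L, ]
  best[1L] <- Inf
  total <- 0
  for (k in seq_len(n - 1L)) {
    v <- which.min(best)
    total <- total + unname(best[v])
    intree[v] <- TRUE
    upd <- !intree & D[v, ] < best
    best[upd] <- D[v, upd]
    best[intree] <- Inf
  }
  total
}

# quasi-medians of a triplet of state vectors: per column the majority state
# among non-N states; ties expand to all tied states (capped, deterministic)
quasi_medians <- function(a, b, c, max_expand = 64L) {
  m <- length(a)
  opts <- vector("list", m)
  for (j in seq_len(m)) {
    s <- c(a[j], b[j], c[j])
    s <- s[s != "N"]
    if (length(s) == 0L) { opts[[j]] <- "N"; next }
    tab <- table(s)
    top <- sort(names(tab)[tab == max(tab)])
    opts[[j]] <- top
  }
  sizes <- lengths(opts)
  if (prod(sizes) > max_expand) {
    # cap combinatorial blow-up: collapse ties deterministically
    opts <- lapply(opts, `[[`, 1L)
    sizes <- lengths(opts)
  }
  grid <- expand.grid(opts, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(i) as.character(grid[i, ]))
}

#' Build a median-joining haplotype network
#'
#' Implements the median-joining procedure over collapsed haplotype
#' clusters: alternate between the epsilon-relaxed minimum spanning network
#' under the weighted Hamming distance and quasi-median generation for
#' linked triplets, adding minimum-connection-cost median vectors until no
#' new ones arise, then pruning synthetic nodes that do not shorten the
#' network. The result is deterministic for a given input ordering.
#'
#' @param clusters A `hap_clusters` tibble from [collapse_haplotypes()], or a
#'   character state matrix with unique rownames (columns = positions).
#' @param weights `NULL` for unit weights, a named numeric vector, or a
#'   tibble with columns `position`, `weight` covering all variable columns.
#' @param epsilon Non-negative integer relaxation parameter (default 0, the
#'   minimal reproducible network).
#' @param add_medians Set `FALSE` to stop at the minimum spanning network.
#' @param refine_limit Node-count bound below which the exhaustive
#'   refinement phase runs (all-triple quasi-median search with plateau
#'   escapes); above it only the scalable feasible-link search is used.
#'   Default 15.
#' @param max_nodes Safety cap on the node count.
#' @return Object of class `mj_network`: list with `nodes` (tibble `id`,
#'   `is_median`, `n_members`, `members`), `edges` (tibble `from`, `to`,
#'   `length`, `n_labels`, `labels` list column of changing positions),
#'   `states` matrix, `weights`, `epsilon`, `spanning_length`.
#' @export
build_mj_network <- function(clusters, weights = NULL, epsilon = 0L,
                             add_medians = TRUE, refine_limit = 15L,
                             max_nodes = 2000L) {
  states <- cluster_states(clusters)
  if (is.null(states) || nrow(states) < 2L) {
    stop("need at least two distinct haplotype clusters", call. = FALSE)
  }
  if (anyDuplicated(rownames(states))) {
    stop("cluster ids must be unique", call. = FALSE)
  }
  epsilon <- as.integer(epsilon)
  stopifnot(epsilon >= 0L)
  positions <- colnames(states)
  if (is.null(positions)) {
    positions <- as.character(seq_len(ncol(states)))
    colnames(states) <- positions
  }
  w <- resolve_weights(weights, positions)
  obs_ids <- rownames(states)
  mat <- states
  is_median <- rep(FALSE, nrow(mat))
  med_counter <- 0L
  seen <- apply(mat, 1, paste, collapse = "")

  if (add_medians) {
    repeat {
      D <- pairwise_dist(mat, w)
      links <- msn_links(D, epsilon)
      cands <- list()
      n <- nrow(mat)
      for (u in seq_len(n)) {
        nb <- which(links[u, ])
        if (length(nb) < 2L) next
        for (ii in seq_len(length(nb) - 1L)) {
          for (jj in seq.int(ii + 1L, length(nb))) {
            v <- nb[ii]; x <- nb[jj]
            meds <- quasi_medians(mat[u, ], mat[v, ], mat[x, ])
            for (mvec in meds) {
              key <- paste(mvec, collapse = "")
              if (key %in% seen || !is.null(cands[[key]])) next
              lam <- weighted_distance(mvec, mat[u, ], w) +
                weighted_distance(mvec, mat[v, ], w) +
                weighted_distance(mvec, mat[x, ], w)
              cands[[key]] <- lam
            }
          }
        }
      }
      if (length(cands) == 0L) break
      lam <- unlist(cands)
      keep <- names(lam)[lam <= min(lam) + epsilon]
      keep <- sort(keep)
      for (key in keep) {
        if (nrow(mat) >= max_nodes) {
          stop("median-joining node cap (", max_nodes, ") exceeded",
               call. = FALSE)
        }
        med_counter <- med_counter + 1L
        mvec <- strsplit(key, "")[[1]]
        mat <- rbind(mat, mvec)
        rownames(mat)[nrow(mat)] <- paste0("mv", med_counter)
        is_median <- c(is_median, TRUE)
        seen <- c(seen, key)
      }
    }
    st <- prune_medians(mat, is_median, w)
    if (nrow(st$mat) <= refine_limit) {
      st <- refine_medians(st$mat, st$is_median, w, max_nodes = max_nodes)
    }
    mat <- st$mat; is_median <- st$is_median
    # renumber surviving medians for a canonical output
    med_idx <- which(is_median)
    rownames(mat)[med_idx] <- paste0("mv", seq_along(med_idx))
  }

  D <- pairwise_dist(mat, w)
  links <- msn_links(D, epsilon)
  n <- nrow(mat)
  ef <- integer(0); et <- integer(0)
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    if (links[i, j]) { ef <- c(ef, i); et <- c(et, j) }
  }
  labels <- purrr::map2(ef, et, function(i, j) {
    d <- mat[i, ] != mat[j, ] & mat[i, ] != "N" & mat[j, ] != "N"
    positions[d]
  })
  edges <- tibble::tibble(
    from = rownames(mat)[ef], to = rownames(mat)[et],
    length = D[cbind(ef, et)],
    n_labels = lengths(labels), labels = labels
  )
  members <- vector("list", n)
  n_members <- integer(n)
  if (!is.matrix(clusters)) {
    mem_lookup <- stats::setNames(clusters$members, clusters$cluster_id)
    sz_lookup <- stats::setNames(clusters$n, clusters$cluster_id)
  } else {
    mem_lookup <- stats::setNames(as.list(obs_ids), obs_ids)
    sz_lookup <- stats::setNames(rep(1L, length(obs_ids)), obs_ids)
  }
  for (i in seq_len(n)) {
    id <- rownames(mat)[i]
    if (is_median[i]) {
      members[[i]] <- character(0); n_members[i] <- 0L
    } else {
      members[[i]] <- mem_lookup[[id]]; n_members[i] <- sz_lookup[[id]]
    }
  }
  nodes <- tibble::tibble(id = rownames(mat), is_median = is_median,
                          n_members = n_members, members = members)
  structure(list(
    nodes = nodes, edges = edges, states = mat, weights = w,
    epsilon = epsilon, positions = positions,
    spanning_length = mst_length(D)
  ), class = "mj_network")
}

# remove synthetic nodes whose removal does not lengthen the spanning tree
prune_medians <- function(mat, is_median, w) {
  repeat {
    D <- pairwise_dist(mat, w)
    base_len <- mst_length(D)
    removable <- NA_integer_
    for (i in which(is_median)) {
      if (mst_length(D[-i, -i, drop = FALSE]) <= base_len) {
        removable <- i
        break
      }
    }
    if (is.na(removable)) break
    mat <- mat[-removable, , drop = FALSE]
    is_median <- is_median[-removable]
  }
  list(mat = mat, is_median = is_median)
}

# quasi-medians of every triple of current nodes, minus those already present
triple_candidates <- function(mat) {
  n <- nrow(mat)
  if (n < 3L) return(character(0))
  seen <- apply(mat, 1, paste, collapse = "")
  cand <- character(0)
  combs <- utils::combn(n, 3L)
  for (ci in seq_len(ncol(combs))) {
    tr <- combs[, ci]
    for (mv in quasi_medians(mat[tr[1], ], mat[tr[2], ], mat[tr[3], ])) {
      key <- paste(mv, collapse = "")
      if (!(key %in% seen) && !(key %in% cand)) cand <- c(cand, key)
    }
  }
  sort(cand)
}

append_median <- function(mat, is_median, key) {
  mat <- rbind(mat, strsplit(key, "")[[1]])
  rownames(mat)[nrow(mat)] <- paste0(".r", nrow(mat))
  list(mat = mat, is_median = c(is_median, TRUE))
}

# weighted distances from one state vector to every row of a state matrix
dist_vec <- function(mat, v, w) {
  out <- numeric(nrow(mat))
  for (j in which(v != "N" & w != 0)) {
    mj <- mat[, j]
    out <- out + w[j] * (mj != v[j] & mj != "N")
  }
  out
}

# spanning length after appending one node with distance vector dnew
mst_length_plus <- function(D, dnew) {
  mst_length(rbind(cbind(D, dnew), c(dnew, 0)))
}

# strict-improvement greedy: keep adding the single quasi-median (over all
# triples) that most shortens the spanning tree
greedy_medians <- function(mat, is_median, w, max_nodes) {
  repeat {
    D <- pairwise_dist(mat, w)
    base_len <- mst_length(D)
    best_key <- NULL; best_len <- base_len
    for (key in triple_candidates(mat)) {
      l <- mst_length_plus(D, dist_vec(mat, strsplit(key, "")[[1]], w))
      if (l < best_len) { best_len <- l; best_key <- key }
    }
    if (is.null(best_key) || nrow(mat) >= max_nodes) break
    st <- append_median(mat, is_median, best_key)
    mat <- st$mat; is_median <- st$is_median
  }
  list(mat = mat, is_median = is_median)
}

# exhaustive refinement for small node sets: alternate strict-improvement
# greedy and pruning, escaping plateaus by provisionally adding one or two
# near-neutral medians and retrying; deterministic candidate order
refine_medians <- function(mat, is_median, w, max_nodes, slack = 1) {
  st <- greedy_medians(mat, is_median, w, max_nodes)
  st <- prune_medians(st$mat, st$is_median, w)
  near_neutral <- function(state, base_len) {
    cands <- triple_candidates(state$mat)
    if (length(cands) == 0L) return(character(0))
    D <- pairwise_dist(state$mat, w)
    deltas <- vapply(cands, function(key) {
      mst_length_plus(D, dist_vec(state$mat, strsplit(key, "")[[1]], w)) -
        base_len
    }, 0)
    ord <- order(deltas, cands)
    cands[ord][deltas[ord] <= slack]
  }
  settle <- function(state) {
    state <- greedy_medians(state$mat, state$is_median, w, max_nodes)
    prune_medians(state$mat, state$is_median, w)
  }
  repeat {
    base_len <- mst_length(pairwise_dist(st$mat, w))
    improved <- FALSE
    kicks <- near_neutral(st, base_len)
    for (key in kicks) {
      s1 <- append_median(st$mat, st$is_median, key)
      s2 <- settle(s1)
      if (mst_length(pairwise_dist(s2$mat, w)) < base_len) {
        st <- s2; improved <- TRUE
        break
      }
    }
    if (!improved) {
      # depth-2: a pair of neutral medians may be jointly cost-reducing
      for (key in kicks) {
        s1 <- append_median(st$mat, st$is_median, key)
        l1 <- mst_length(pairwise_dist(s1$mat, w))
        for (key2 in near_neutral(s1, l1)) {
          s2 <- settle(append_median(s1$mat, s1$is_median, key2))
          if (mst_length(pairwise_dist(s2$mat, w)) < base_len) {
            st <- s2; improved <- TRUE
            break
          }
        }
        if (improved) break
      }
    }
    if (!improved) break
  }
  st
}

resolve_weights <- function(weights, positions) {
  if (is.null(weights)) {
    return(stats::setNames(rep(1, length(positions)), positions))
  }
  if (is.data.frame(weights)) {
    weights <- stats::setNames(weights$weight, weights$position)
  }
  missing <- setdiff(positions, names(weights))
  if (length(missing) > 0) {
    stop("weights do not cover variable position(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  wv <- as.numeric(weights[positions])
  if (any(wv < 0)) stop("weights must be non-negative", call. = FALSE)
  if (all(wv == 0)) stop("at least one weight must be positive", call. = FALSE)
  stats::setNames(wv, positions)
}

#' @export
print.mj_network <- function(x, ...) {
  cat("<mj_network> ", sum(!x$nodes$is_median), " observed clusters + ",
      sum(x$nodes$is_median), " median vectors; ", nrow(x$edges),
      " links; spanning length ", x$spanning_length,
      " (epsilon = ", x$epsilon, ")\n", sep = "")
  invisible(x)
}

#' Convert a network to an igraph object
#' @param net A [build_mj_network()] result.
#' @return An igraph graph with `is_median`/`size` vertex attributes and
#'   `weight`/`labels` edge attributes.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "mj_network"))
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = net$edges$from, to = net$edges$to,
                   weight = net$edges$length,
                   labels = vapply(net$edges$labels, paste, "", collapse = ","),
                   stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = net$nodes$id,
                          is_median = net$nodes$is_median,
                          size = net$nodes$n_members,
                          stringsAsFactors = FALSE)
  )
  g
}

#' Export a network in GraphML format
#' @param net A [build_mj_network()] result.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_network_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}

#' Write node and edge tables of a network as TSV
#' @param net A [build_mj_network()] result.
#' @param nodes_path,edges_path Output paths.
#' @return Invisibly, `c(nodes_path, edges_path)`.
#' @export
write_network_tsv <- function(net, nodes_path, edges_path) {
  nodes <- dplyr::mutate(net$nodes,
                         members = vapply(.data$members, paste, "",
                                          collapse = ","))
  edges <- dplyr::mutate(net$edges,
                         labels = vapply(.data$labels, paste, "",
                                         collapse = ","))
  readr::write_tsv(nodes, nodes_path)
  readr::write_tsv(edges, edges_path)
  invisible(c(nodes_path, edges_path))
}
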