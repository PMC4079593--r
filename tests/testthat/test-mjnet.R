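test_that("collapsing merges identical haplotypes and partitions the labels", {
  aln <- hap_alignment(c(a = "ACGT", b = "ACGT", c = "AGGT", d = "ATGT"))
  cl <- collapse_haplotypes(aln)
  expect_identical(nrow(cl), 3L)
  expect_identical(sort(cl$n, decreasing = TRUE)[1], 2L)
  expect_identical(sum(cl$n), attr(cl, "n_input"))
  expect_setequal(unlist(cl$members), c("a", "b", "c", "d"))
  # all distinct: one cluster per label
  aln2 <- hap_alignment(c(a = "AC", b = "GC", c = "AT"))
  expect_identical(nrow(collapse_haplotypes(aln2)), 3L)
  empty <- matrix("A", 0, 4, dimnames = list(character(0), NULL))
  expect_error(collapse_haplotypes(hap_alignment(empty)), "empty")
})

test_that("permissive collapsing lets N match any base, strict does not", {
  aln <- hap_alignment(c(a = "ACGT", b = "ANGT", c = "AGGT"))
  perm <- collapse_haplotypes(aln)           # b joins a, backfilled
  expect_identical(nrow(perm), 2L)
  expect_setequal(perm$members[[which(perm$cluster_id == "a")]], c("a", "b"))
  strict <- collapse_haplotypes(aln, missing = "strict")
  expect_identical(nrow(strict), 3L)
})

test_that("weighted Hamming distance honours weights and missing data", {
  expect_identical(weighted_distance(c("A", "C"), c("A", "C")), 0)
  expect_identical(weighted_distance(c("A", "C"), c("G", "T"),
                                     w = c(2, 1)), 3)
  expect_identical(weighted_distance(c("N", "C"), c("G", "C")), 0)
  expect_identical(weighted_distance(c("-", "C"), c("T", "C")), 1)
  expect_identical(weighted_distance(c("A", "C"), c("G", "C"),
                                     w = c(0, 5)), 0)
  expect_error(weighted_distance("A", c("A", "C")), "length")
})

test_that("the three-haplotype star resolves through one median vector", {
  net <- build_mj_network(worked_example_matrix())
  expect_identical(sum(net$nodes$is_median), 1L)
  expect_identical(net$states["mv1", ], c("5" = "A", "7" = "A", "9" = "A"))
  expect_identical(nrow(net$edges), 3L)
  expect_true(all(net$edges$length == 1))
  expect_identical(net$spanning_length, 3)
  # determinism: byte-identical output on rebuild
  net2 <- build_mj_network(worked_example_matrix())
  expect_identical(net$states, net2$states)
  expect_identical(net$edges, net2$edges)
})

test_that("two clusters yield a single edge labelled with their differences", {
  m <- rbind(h1 = c("A", "C", "A"), h2 = c("G", "C", "T"))
  colnames(m) <- c("5", "7", "9")
  net <- build_mj_network(m)
  expect_identical(nrow(net$edges), 1L)
  expect_identical(sum(net$nodes$is_median), 0L)
  expect_setequal(net$edges$labels[[1]], c("5", "9"))
  expect_error(build_mj_network(m[1, , drop = FALSE]), "at least two")
})

test_that("network spanning length matches the exhaustive Steiner oracle", {
  for (s in 1:25) {
    mat <- simulate_genealogy_matrix(s)
    if (nrow(mat) < 2) next
    net <- build_mj_network(mat)
    expect_identical(net$spanning_length, steiner_min_length(mat),
                     info = paste("seed", s))
  }
})

test_that("median vectors only ever shorten the network", {
  for (s in c(3, 15, 27)) {
    mat <- simulate_genealogy_matrix(s)
    if (nrow(mat) < 2) next
    full <- build_mj_network(mat)
    observed_only <- build_mj_network(mat, add_medians = FALSE)
    expect_lte(full$spanning_length, observed_only$spanning_length)
    expect_true(all(mat %in% c("A", "C", "G", "T")))
    # every observed cluster appears exactly once
    expect_setequal(full$nodes$id[!full$nodes$is_median], rownames(mat))
  }
})

test_that("every edge is labelled with exactly the differing positions", {
  for (s in c(2, 8, 14)) {
    sim <- simulate_haplotypes(seed = s, n_haplogroups = 2, star_size = 3,
                               stem_length = 2)
    cl <- collapse_haplotypes(sim$alignment)
    net <- build_mj_network(cl)
    for (i in seq_len(nrow(net$edges))) {
      a <- net$states[net$edges$from[i], ]
      b <- net$states[net$edges$to[i], ]
      expect_setequal(net$edges$labels[[i]],
                      net$positions[a != b & a != "N" & b != "N"])
    }
    # surviving medians are load-bearing: degree >= 3 in the network
    for (mv in net$nodes$id[net$nodes$is_median]) {
      expect_gte(sum(net$edges$from == mv | net$edges$to == mv), 3L)
    }
  }
})

test_that("raising epsilon never removes a feasible link", {
  for (s in c(4, 9, 19)) {
    mat <- simulate_genealogy_matrix(s)
    if (nrow(mat) < 3) next
    edge_keys <- function(net) {
      paste(pmin(net$edges$from, net$edges$to),
            pmax(net$edges$from, net$edges$to))
    }
    e0 <- edge_keys(build_mj_network(mat, add_medians = FALSE, epsilon = 0))
    e1 <- edge_keys(build_mj_network(mat, add_medians = FALSE, epsilon = 1))
    e2 <- edge_keys(build_mj_network(mat, add_medians = FALSE, epsilon = 2))
    expect_true(all(e0 %in% e1))
    expect_true(all(e1 %in% e2))
  }
})

test_that("position weights reshape distances and must cover all columns", {
  m <- rbind(h1 = c("A", "C"), h2 = c("G", "T"))
  colnames(m) <- c("10", "20")
  w <- tibble::tibble(position = c("10", "20"), weight = c(3L, 1L))
  net <- build_mj_network(m, weights = w)
  expect_identical(net$edges$length, 4)
  expect_error(build_mj_network(m, weights = w[1, ]), "cover")
  expect_error(build_mj_network(m, weights = tibble::tibble(
    position = c("10", "20"), weight = c(0L, 0L))), "positive")
})

test_that("the multistate indel character threads through collapse and network", {
  sim <- simulate_haplotypes(seed = 6, n_haplogroups = 2, star_size = 2,
                             stem_length = 2, indel_column = TRUE)
  filtered <- apply_gap_policy(
    sim$alignment,
    exceptions = grep("\\.1$", sim$alignment$colmap$key, value = TRUE))
  cl <- collapse_haplotypes(filtered)
  net <- build_mj_network(cl)
  ins_key <- grep("\\.1$", net$positions, value = TRUE)
  expect_length(ins_key, 1L)
  # the indel column separates haplogroup 1 from the rest on some branch
  expect_true(any(vapply(net$edges$labels, function(l) ins_key %in% l, TRUE)))
})

test_that("network exports write igraph, GraphML and TSV forms", {
  net <- build_mj_network(worked_example_matrix())
  g <- as_igraph(net)
  expect_equal(igraph::vcount(g), 4)
  expect_equal(igraph::ecount(g), 3)
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_network_graphml(net, gml)
  expect_match(readLines(gml, n = 2)[2], "graphml", fixed = TRUE)
  nt <- withr::local_tempfile(fileext = ".tsv")
  et <- withr::local_tempfile(fileext = ".tsv")
  write_network_tsv(net, nt, et)
  expect_identical(nrow(readr::read_tsv(nt, show_col_types = FALSE)), 4L)
  expect_identical(nrow(readr::read_tsv(et, show_col_types = FALSE)), 3L)
})
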