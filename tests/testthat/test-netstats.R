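test_that("mutation frequencies count branches and conserve total labels", {
  m <- rbind(h1 = c("A", "C", "A"), h2 = c("G", "C", "T"))
  colnames(m) <- c("5", "7", "9")
  net <- build_mj_network(m)
  ft <- mutation_frequencies(net)
  expect_identical(ft$freq, c(1L, 1L))
  expect_setequal(ft$position, c("5", "9"))
  # conservation: table total equals total labels over all edges
  sim <- simulate_haplotypes(seed = 12, n_hotspots = 1,
                             hotspot_recurrence = 3)
  net2 <- build_mj_network(collapse_haplotypes(sim$alignment))
  ft2 <- mutation_frequencies(net2)
  expect_identical(sum(ft2$freq), sum(lengths(net2$edges$labels)))
})

test_that("hotspots are the maximal-frequency positions and survive relabelling", {
  sim <- simulate_haplotypes(seed = 31, n_hotspots = 1,
                             hotspot_recurrence = 3)
  cl <- collapse_haplotypes(sim$alignment)
  net <- build_mj_network(cl)
  ft <- mutation_frequencies(net)
  hot <- sim$truth$hotspots$position[1]
  expect_identical(ft$freq[ft$position == hot], 3L)
  expect_identical(hotspots(ft), hot)
  # permutation invariance: shuffling the cluster order leaves them fixed
  states <- cluster_states(cl)
  shuffled <- states[rev(seq_len(nrow(states))), , drop = FALSE]
  ft_shuf <- mutation_frequencies(build_mj_network(shuffled))
  expect_identical(hotspots(ft_shuf), hot)
  expect_identical(dplyr::arrange(tibble::as_tibble(ft), position),
                   dplyr::arrange(tibble::as_tibble(ft_shuf), position))
})

test_that("inverse-frequency weights follow the clamped reciprocal map", {
  ft <- tibble::tibble(position = c("a", "b", "c"), freq = c(1L, 2L, 10L))
  w <- inverse_frequency_weights(ft, scale = 10)
  expect_identical(w$weight, c(10L, 5L, 1L))
  # positions never seen mutating get the full scale
  w2 <- inverse_frequency_weights(ft, scale = 10,
                                  positions = c("a", "zzz"))
  expect_identical(w2$weight[w2$position == "zzz"], 10L)
  # uniform frequencies give uniform weights
  ftu <- tibble::tibble(position = c("a", "b"), freq = c(2L, 2L))
  expect_identical(unique(inverse_frequency_weights(ftu)$weight), 5L)
  # clamping floor at 1 and ceiling at 99
  ftx <- tibble::tibble(position = c("a", "b"), freq = c(1000L, 1L))
  wx <- inverse_frequency_weights(ftx, scale = 99)
  expect_identical(wx$weight, c(1L, 99L))
  expect_error(inverse_frequency_weights(ft, scale = 0), "positive")
})

test_that("two-pass weighting downweights hotspots and keeps stems at full scale", {
  sim <- simulate_haplotypes(seed = 44, n_hotspots = 1,
                             hotspot_recurrence = 3, star_size = 3)
  cl <- collapse_haplotypes(sim$alignment)
  two <- build_mj_network_weighted(cl, scale = 10)
  hot <- sim$truth$hotspots$position[1]
  stems <- unlist(sim$truth$stem_positions)
  w <- stats::setNames(two$weights$weight, two$weights$position)
  expect_lt(w[[hot]], 10L)
  expect_true(all(w[stems] == 10L))
  expect_identical(two$network$epsilon, 0L)
})

test_that("motif inference recovers planted stems exactly", {
  sim <- simulate_haplotypes(seed = 18, n_haplogroups = 3, star_size = 3,
                             stem_length = 2)
  cl <- collapse_haplotypes(sim$alignment)
  net <- build_mj_network(cl)
  lookup <- stats::setNames(rep(cl$cluster_id, cl$n), unlist(cl$members))
  for (hg in c("HG1", "HG2", "HG3")) {
    labs <- sim$truth$groups$label[sim$truth$groups$haplogroup == hg]
    rep <- infer_motif(net, unique(lookup[labs]), haplogroup = hg)
    expect_setequal(rep$motif, sim$truth$stem_positions[[hg]])
    expect_true(all(rep$stem_positions$freq == 1L))
    expect_identical(rep$ancestor_candidate, "ROOT")
  }
})

test_that("recurrent mutations drop out of the motif but stay in the stem listing", {
  # a hotspot recurring on three tip branches: the cut around a carrier
  # tip lists both its private position (freq 1, in the motif) and the
  # hotspot (freq 3, excluded)
  sim <- simulate_haplotypes(seed = 31, n_hotspots = 1,
                             hotspot_recurrence = 3)
  hot <- sim$truth$hotspots$position[1]
  aln <- sim$alignment
  hot_col <- which(aln$colmap$key == hot)
  root_state <- aln$mat["ROOT", hot_col]
  carriers <- rownames(aln$mat)[aln$mat[, hot_col] != root_state]
  carriers <- grep("_T", carriers, value = TRUE)
  expect_length(carriers, 3L)
  net <- build_mj_network(collapse_haplotypes(aln))
  tip <- sort(carriers)[1]
  rep <- infer_motif(net, tip, haplogroup = tip)
  private <- sim$truth$tip_positions[[tip]]
  expect_setequal(rep$stem_positions$position, c(private, hot))
  expect_identical(rep$motif, private)
  expect_identical(
    rep$stem_positions$freq[rep$stem_positions$position == hot], 3L)
  # a haplotype whose every defining mutation recurs elsewhere: empty motif
  m2 <- rbind(
    ROOT = c("A", "A"),
    B1   = c("G", "A"),
    B2   = c("A", "G"),
    B3   = c("G", "G")
  )
  colnames(m2) <- c("1", "2")
  net2 <- build_mj_network(m2)
  rep2 <- infer_motif(net2, "B3", haplogroup = "double")
  expect_length(rep2$motif, 0L)
  expect_setequal(rep2$stem_positions$position, c("1", "2"))
  expect_true(all(rep2$stem_positions$freq == 2L))
})

test_that("motif inference refuses non-separable (reticulate) haplogroups", {
  # a path A - B - C - D: {A, D} cannot be cut off as one connected side
  m <- rbind(
    A = c("A", "A", "A"),
    B = c("G", "A", "A"),
    C = c("G", "C", "A"),
    D = c("G", "C", "T")
  )
  colnames(m) <- c("1", "2", "3")
  net <- build_mj_network(m)
  expect_error(infer_motif(net, c("A", "D")), "topology|strands")
  expect_error(infer_motif(net, c("A", "B", "C", "D")), "proper subset")
  expect_error(infer_motif(net, "nope"), "unknown")
})

test_that("placement reports give path, labels and weighted length", {
  # chain of three unit branches
  m <- rbind(
    w = c("A", "A", "A"),
    x = c("G", "A", "A"),
    y = c("G", "C", "A"),
    z = c("G", "C", "T")
  )
  colnames(m) <- c("1", "2", "3")
  net <- build_mj_network(m)
  rep <- cluster_distance_report(net, "w", "z")
  expect_identical(rep$total_length, 3)
  expect_identical(rep$n_labels, 3L)
  expect_identical(rep$path, c("w", "x", "y", "z"))
  # adjacent nodes report their own edge labels
  adj <- cluster_distance_report(net, "x", "y")
  expect_identical(adj$edges$labels[[1]], "2")
  expect_error(cluster_distance_report(net, "w", "missing"), "unknown")
})

test_that("frequency and motif reports write as TSV", {
  sim <- simulate_haplotypes(seed = 3, n_haplogroups = 2, star_size = 2,
                             stem_length = 2)
  cl <- collapse_haplotypes(sim$alignment)
  net <- build_mj_network(cl)
  ft <- mutation_frequencies(net)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  write_frequency_tsv(ft, f1)
  expect_identical(nrow(readr::read_tsv(f1, show_col_types = FALSE)),
                   nrow(ft))
  lookup <- stats::setNames(rep(cl$cluster_id, cl$n), unlist(cl$members))
  labs <- sim$truth$groups$label[sim$truth$groups$haplogroup == "HG1"]
  mr <- infer_motif(net, unique(lookup[labs]), haplogroup = "HG1")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_motif_tsv(mr, f2)
  tab <- readr::read_tsv(f2, show_col_types = FALSE)
  expect_true(all(tab$in_motif))
})
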