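# Synthetic-data generators with known ground truth: haplogroup-structured
# haplotype alignments (star clusters on multi-mutation stems, optional
# recurrent hotspots and an indel-exception column) and damage-bearing
# amplicon read pools with a closed-form expected type-2/type-1 ratio.

next_base <- function(b) {
  # deterministic derived allele: the next base in A->C->G->T->A order
  stats::setNames(c("C", "G", "T", "A"), c("A", "C", "G", "T"))[b]
}

#' Simulate a haplogroup-structured haplotype alignment
#'
#' Generates a root haplotype plus `n_haplogroups` star clusters: each
#' haplogroup founder differs from the root by `stem_length` private stem
#' mutations, and each of its `star_size` tips differs from the founder by
#' one private tip mutation. Optional hotspots recur on several independent
#' tip branches across haplogroups, and an optional insertion column (an
#' indel kept under the gap-policy exception) joins the first haplogroup's
#' stem. All mutated positions are unique unless marked recurrent, so the
#' default is a perfect phylogeny with exactly known network structure.
#'
#' @param n_haplogroups Number of star clusters (default 3).
#' @param star_size Tips per haplogroup (default 4).
#' @param stem_length Stem mutations separating each founder from the root
#'   (default 3).
#' @param n_hotspots Number of recurrent positions (default 0).
#' @param hotspot_recurrence Branches on which each hotspot recurs
#'   (default 2).
#' @param alignment_length Reference-anchored columns (default 327, the
#'   length of the control-region window analysed in red deer work).
#' @param indel_column Add an insertion column carried (as T) by haplogroup
#'   1 and absent elsewhere (default `FALSE`).
#' @param include_root Include the root haplotype as an observed sequence
#'   (default `TRUE`).
#' @param start_anchor Reference anchor of the first column (default 15573).
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @return List with `alignment` (a [hap_alignment()]; haplogroup tags in
#'   its `meta`) and `truth`: `groups` (tibble `label`, `haplogroup`),
#'   `stem_positions` (named list per haplogroup), `tip_positions`,
#'   `hotspots` (tibble `position`, `recurrence`), `n_mutation_events`,
#'   `root_label`.
#' @export
simulate_haplotypes <- function(n_haplogroups = 3L, star_size = 4L,
                                stem_length = 3L, n_hotspots = 0L,
                                hotspot_recurrence = 2L,
                                alignment_length = 327L,
                                indel_column = FALSE,
                                include_root = TRUE,
                                start_anchor = 15573L, seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  n_haplogroups <- as.integer(n_haplogroups)
  star_size <- as.integer(star_size)
  stem_length <- as.integer(stem_length)
  n_hotspots <- as.integer(n_hotspots)
  stopifnot(n_haplogroups >= 1L, star_size >= 1L, stem_length >= 1L,
            n_hotspots >= 0L, hotspot_recurrence >= 2L)
  n_tips <- n_haplogroups * star_size
  need <- n_haplogroups * stem_length + n_tips + n_hotspots
  if (need > alignment_length) {
    stop("infeasible config: ", need, " mutated positions exceed alignment ",
         "length ", alignment_length, call. = FALSE)
  }
  if (n_hotspots > 0 && hotspot_recurrence > n_haplogroups) {
    # one carrier tip per haplogroup keeps each recurrence on its own branch
    stop("infeasible config: hotspot recurrence exceeds the number of ",
         "haplogroups", call. = FALSE)
  }
  anchors <- start_anchor + seq_len(alignment_length) - 1L
  root <- sample(BASES, alignment_length, replace = TRUE)
  pos_pool <- sample.int(alignment_length, need)
  take <- function(k) {
    out <- pos_pool[seq_len(k)]
    pos_pool <<- pos_pool[-seq_len(k)]
    out
  }
  seqs <- list(); meta_rows <- list()
  stem_positions <- list(); tip_positions <- list()
  groups <- list()
  n_events <- 0L
  if (include_root) {
    seqs[["ROOT"]] <- root
    groups[["ROOT"]] <- "root"
  }
  tip_labels <- character(0)
  for (g in seq_len(n_haplogroups)) {
    hg <- paste0("HG", g)
    stem_idx <- sort(take(stem_length))
    founder <- root
    founder[stem_idx] <- next_base(founder[stem_idx])
    n_events <- n_events + stem_length
    stem_positions[[hg]] <- as.character(anchors[stem_idx])
    flab <- paste0(hg, "_F")
    seqs[[flab]] <- founder
    groups[[flab]] <- hg
    for (t in seq_len(star_size)) {
      tip_idx <- take(1L)
      tip <- founder
      tip[tip_idx] <- next_base(tip[tip_idx])
      n_events <- n_events + 1L
      tlab <- paste0(hg, "_T", t)
      seqs[[tlab]] <- tip
      groups[[tlab]] <- hg
      tip_positions[[tlab]] <- as.character(anchors[tip_idx])
      tip_labels <- c(tip_labels, tlab)
    }
  }
  hot_tbl <- tibble::tibble(position = character(), recurrence = integer())
  if (n_hotspots > 0) {
    for (h in seq_len(n_hotspots)) {
      hidx <- take(1L)
      carrier_groups <- sample(seq_len(n_haplogroups), hotspot_recurrence)
      carriers <- vapply(carrier_groups, function(g) {
        paste0("HG", g, "_T", sample.int(star_size, 1L))
      }, "")
      for (lab in carriers) {
        seqs[[lab]][hidx] <- next_base(root[hidx])
        n_events <- n_events + 1L
      }
      hot_tbl <- dplyr::bind_rows(hot_tbl, tibble::tibble(
        position = as.character(anchors[hidx]),
        recurrence = as.integer(hotspot_recurrence)))
    }
  }
  mat <- do.call(rbind, seqs)
  rownames(mat) <- names(seqs)
  colmap <- tibble::tibble(col = seq_len(alignment_length),
                           anchor = anchors, ins = 0L)
  if (indel_column) {
    # insertion column after the first stem anchor of haplogroup 1,
    # carried as T by every member of that haplogroup
    ins_after <- parse_pos(stem_positions[["HG1"]][1])$anchor
    at <- which(anchors == ins_after)
    ins_state <- ifelse(unlist(groups[rownames(mat)]) == "HG1", "T", "-")
    mat <- cbind(mat[, seq_len(at), drop = FALSE],
                 ins = ins_state,
                 mat[, -seq_len(at), drop = FALSE])
    colmap <- dplyr::bind_rows(
      colmap[seq_len(at), ],
      tibble::tibble(col = 0L, anchor = ins_after, ins = 1L),
      colmap[-seq_len(at), ]
    )
    colmap$col <- seq_len(nrow(colmap))
    colnames(mat) <- NULL
    ins_key <- pos_key(ins_after, 1L)
    stem_positions[["HG1"]] <- c(stem_positions[["HG1"]], ins_key)
    n_events <- n_events + 1L
  }
  meta <- tibble::tibble(label = rownames(mat),
                         haplogroup = unlist(groups[rownames(mat)]),
                         era = "modern")
  aln <- hap_alignment(mat, colmap = colmap, meta = meta)
  truth <- list(
    groups = meta[, c("label", "haplogroup")],
    stem_positions = stem_positions,
    tip_positions = tip_positions,
    hotspots = hot_tbl,
    n_mutation_events = n_events,
    root_label = if (include_root) "ROOT" else NA_character_
  )
  list(alignment = aln, truth = truth)
}

#' Simulate a damage-bearing clonal read group
#'
#' Reads are drawn independently from a template: each site is first masked
#' to N with probability `missing_rate`; otherwise each of the three wrong
#' bases is read with the symmetric polymerase error rate `eps_error`, and
#' C and G sites additionally convert to T and A respectively (the
#' deamination-driven miscoding lesion) with rate `delta_lesion`. The
#' lesion is uniform along the read. The analytic expected type-2/type-1
#' ratio implied by the rates and the template composition is attached as
#' ground truth (see [expected_ratio21()]).
#'
#' @param template Template sequence (string or character vector over
#'   A/C/G/T).
#' @param n_reads Number of reads (default 100).
#' @param delta_lesion Per-site C->T and G->A lesion rate (default 0).
#' @param eps_error Per-site, per-change polymerase error rate (default 0).
#' @param missing_rate Per-site N rate (default 0).
#' @param group_id Group identifier.
#' @param start_anchor Reference anchor of the first template base.
#' @param seed Optional integer seed (RNG state restored afterwards).
#' @return List with `group` (a [clone_group()]) and `truth` (rates,
#'   template composition, `expected_ratio21`).
#' @export
simulate_clone_group <- function(template, n_reads = 100L, delta_lesion = 0,
                                 eps_error = 0, missing_rate = 0,
                                 group_id = "sim1", start_anchor = 1L,
                                 seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  if (length(template) == 1L && nchar(template[1]) > 1L) {
    template <- strsplit(template, "")[[1]]
  }
  template <- toupper(template)
  stopifnot(all(template %in% BASES), n_reads >= 1L)
  if (delta_lesion < 0 || eps_error < 0 || missing_rate < 0 ||
      delta_lesion + 3 * eps_error >= 1 || missing_rate >= 1) {
    stop("invalid rates: need delta, eps, missing in [0,1) with ",
         "delta + 3*eps < 1", call. = FALSE)
  }
  L <- length(template)
  mat <- matrix(template, nrow = n_reads, ncol = L, byrow = TRUE)
  for (j in seq_len(L)) {
    b <- template[j]
    others <- setdiff(BASES, b)
    p <- stats::setNames(rep(eps_error, 3), others)
    if (b == "C") p["T"] <- p["T"] + delta_lesion
    if (b == "G") p["A"] <- p["A"] + delta_lesion
    probs <- c(1 - sum(p), p)
    draw <- sample(c(b, others), n_reads, replace = TRUE, prob = probs)
    mat[, j] <- draw
  }
  if (missing_rate > 0) {
    mask <- matrix(stats::runif(n_reads * L) < missing_rate, n_reads, L)
    mat[mask] <- "N"
  }
  grp <- clone_group(mat, group_id = group_id, start_anchor = start_anchor)
  truth <- list(
    delta_lesion = delta_lesion, eps_error = eps_error,
    missing_rate = missing_rate, n_reads = as.integer(n_reads),
    composition = stats::setNames(
      vapply(BASES, function(b) sum(template == b), 0L), BASES),
    expected_ratio21 = expected_ratio21(template, delta_lesion, eps_error)
  )
  list(group = grp, truth = truth)
}

#' Closed-form expected type-2/type-1 ratio of the read simulator
#'
#' Expected raw counts per directed change are `n_reads * n_origin * rate`;
#' the composition scaling of [scale_spectrum()] is then applied with the
#' template composition, and the scaled type-2/type-1 ratio returned. The
#' ratio is independent of `n_reads` and of the missing-data rate (masking
#' thins all classes equally).
#'
#' @param template Template sequence (string or character vector).
#' @param delta_lesion,eps_error Simulator rates.
#' @return Expected scaled type2/type1 ratio (`NA` when type1 is 0).
#' @export
expected_ratio21 <- function(template, delta_lesion, eps_error) {
  if (length(template) == 1L && nchar(template[1]) > 1L) {
    template <- strsplit(template, "")[[1]]
  }
  comp <- stats::setNames(vapply(BASES, function(b) sum(template == b), 0L),
                          BASES)
  ct <- change_table()
  raw <- stats::setNames(comp[ct$from] * eps_error, ct$change)
  raw["C>T"] <- raw["C>T"] + comp["C"] * delta_lesion
  raw["G>A"] <- raw["G>A"] + comp["G"] * delta_lesion
  scaled <- scale_spectrum(raw, comp)
  t1 <- sum(scaled[TYPE1_CHANGES]); t2 <- sum(scaled[TYPE2_CHANGES])
  if (t1 > 0) t2 / t1 else NA_real_
}

#' Simulate a genealogy-structured haplotype state matrix
#'
#' Small random haplotype sets for stress-testing the network builder:
#' starting from a random root, haplotypes arise by copying a random
#' existing haplotype and mutating one or two sites. Each site has a fixed
#' alternative base toggled with probability `p_toggle` (so recurrent
#' mutation and reversal — homoplasy — occur naturally), otherwise a random
#' third base is introduced. This emulates the copy-and-diverge structure
#' of real haplotype samples, as opposed to uniform random points in
#' sequence space.
#'
#' @param seed Integer seed (RNG state restored afterwards).
#' @param max_haplotypes Target number of distinct haplotypes (default 5;
#'   duplicates are discarded, so fewer may result).
#' @param sites Vector of possible site counts to draw from (default 4:8).
#' @param p_toggle Probability that a mutation toggles between the root
#'   base and the site's fixed alternative (default 0.8).
#' @return Character state matrix with rownames `h1..hk` and site-number
#'   colnames, suitable for [build_mj_network()].
#' @export
simulate_genealogy_matrix <- function(seed, max_haplotypes = 5L,
                                      sites = 4:8, p_toggle = 0.8) {
  withr::local_seed(seed)
  m <- if (length(sites) == 1L) sites else sample(sites, 1)
  k <- if (max_haplotypes <= 3L) max_haplotypes else
    sample(3:max_haplotypes, 1)
  root <- sample(BASES, m, replace = TRUE)
  alt <- vapply(root, function(b) sample(setdiff(BASES, b), 1), "")
  haps <- list(root)
  guard <- 0L
  while (length(haps) < k && guard < 50L) {
    guard <- guard + 1L
    parent <- haps[[sample.int(length(haps), 1)]]
    child <- parent
    for (j in sample.int(m, sample(1:2, 1))) {
      child[j] <- if (stats::runif(1) < p_toggle) {
        if (child[j] == root[j]) alt[j] else root[j]
      } else {
        sample(setdiff(BASES, child[j]), 1)
      }
    }
    if (!any(vapply(haps, identical, TRUE, y = child))) {
      haps[[length(haps) + 1L]] <- child
    }
  }
  mat <- do.call(rbind, haps)
  rownames(mat) <- paste0("h", seq_len(nrow(mat)))
  colnames(mat) <- as.character(seq_len(m))
  mat
}

#' Write a ready-made synthetic fixture bundle
#'
#' Emits an aligned FASTA of simulated haplotypes, per-group read FASTAs
#' from the read simulator, and a JSON ground-truth record, so every
#' pipeline stage can be exercised from files alone.
#'
#' @param dir Output directory (created if needed).
#' @param haplotype_args List of arguments for [simulate_haplotypes()].
#' @param read_args List of arguments for [simulate_clone_group()] (the
#'   template defaults to the simulated root haplotype); `n_groups` of them
#'   are generated with seeds `seed + 1, seed + 2, ...`.
#' @param n_groups Number of clone groups (default 2).
#' @param seed Master seed.
#' @return Invisibly, a list of written paths.
#' @export
write_fixture_bundle <- function(dir, haplotype_args = list(),
                                 read_args = list(), n_groups = 2L,
                                 seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hap <- do.call(simulate_haplotypes,
                 utils::modifyList(list(seed = seed), haplotype_args))
  aln_path <- file.path(dir, "haplotypes.fasta")
  write_alignment_fasta(hap$alignment, aln_path)
  root <- hap$alignment$mat[1, hap$alignment$colmap$ins == 0L]
  read_paths <- character(0)
  read_truth <- list()
  for (k in seq_len(n_groups)) {
    args <- utils::modifyList(
      list(template = paste(root, collapse = ""),
           group_id = paste0("cg", k), seed = seed + k),
      read_args)
    sim <- do.call(simulate_clone_group, args)
    p <- file.path(dir, paste0("reads_cg", k, ".fasta"))
    seqs <- apply(sim$group$mat, 1, paste, collapse = "")
    Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), p, width = 80L)
    read_paths <- c(read_paths, p)
    read_truth[[paste0("cg", k)]] <-
      sim$truth[c("delta_lesion", "eps_error", "missing_rate",
                  "expected_ratio21")]
  }
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(
    list(haplotypes = hap$truth[c("stem_positions", "hotspots",
                                  "n_mutation_events")],
         groups = as.list(stats::setNames(hap$truth$groups$haplogroup,
                                          hap$truth$groups$label)),
         reads = read_truth, seed = seed),
    truth_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(alignment = aln_path, reads = read_paths,
                 truth = truth_path))
}
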