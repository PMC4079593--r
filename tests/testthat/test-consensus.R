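test_that("consensus takes the per-column majority among non-N states", {
  grp <- clone_group(c("AAG", "AAG", "AGG"))
  cons <- build_consensus(grp)
  expect_identical(cons$state, c("A", "A", "G"))
  expect_identical(cons$depth, c(3L, 3L, 3L))
  # N excluded from both the vote and the depth
  grp2 <- clone_group(c("AN", "AN", "GC"))
  cons2 <- build_consensus(grp2)
  expect_identical(cons2$state[1], "A")
  expect_identical(cons2$depth, c(3L, 1L))
  expect_error(clone_group(character(0)), "at least one read")
})

test_that("ties resolve to IUPAC ambiguity or to the reference base", {
  grp <- clone_group(c("AC", "AC", "GC", "GC"))
  expect_identical(build_consensus(grp)$state[1], "R")  # A/G tie
  ref <- circular_reference("r", "GCAA")
  expect_identical(
    build_consensus(grp, tie_rule = "reference", ref = ref)$state[1], "G")
  # reference base outside the tie set falls back to the ambiguity code
  ref2 <- circular_reference("r2", "TCAA")
  expect_identical(
    build_consensus(grp, tie_rule = "reference", ref = ref2)$state[1], "R")
  expect_error(build_consensus(grp, tie_rule = "reference"), "requires")
  # a base outvotes a gap on ties
  grp3 <- clone_group(c("A-", "-C", "AC", "--"))
  expect_identical(build_consensus(grp3)$state, c("A", "C"))
})

test_that("variant calling reproduces reference-anchored records across the origin", {
  ref <- synthetic_reference()
  region2 <- ref_interval(14162, 15301)
  region3 <- ref_interval(15308, 109)   # wraps the origin
  # build a consensus carrying four planted differences, Table-1 style:
  # a substitution beyond the wrap (108), an insertion (15932.1), a
  # deletion (16199) and a plain substitution (16263)
  anchors3 <- c(15308:16357, 1:109)
  cons <- tibble::tibble(anchor = as.integer(anchors3), ins = 0L,
                         state = ref_base(ref, anchors3))
  cons$state[cons$anchor == 108L] <- "G"
  cons$state[cons$anchor == 16263L] <- "G"
  cons$state[cons$anchor == 16199L] <- "-"
  at <- which(cons$anchor == 15932L)
  cons <- dplyr::bind_rows(cons[1:at, ],
                           tibble::tibble(anchor = 15932L, ins = 1L,
                                          state = "C"),
                           cons[-(1:at), ])
  cons$position <- pos_key(cons$anchor, cons$ins)
  # force states at planted substitution sites to actually differ
  stopifnot(ref_base(ref, 108) != "G", ref_base(ref, 16263) != "G")
  v <- call_variants(cons, ref, region = region3)
  expect_identical(nrow(v), 4L)
  expect_setequal(v$position, c("108", "15932.1", "16199", "16263"))
  expect_identical(v$kind[v$position == "15932.1"], "insertion")
  expect_identical(v$obs_state[v$position == "15932.1"], "C")
  expect_identical(v$kind[v$position == "16199"], "deletion")
  expect_identical(v$ref_state[v$position == "16199"],
                   ref_base(ref, 16199))
  expect_identical(v$obs_state[v$position == "108"], "G")
  # round trip: applying the records to the reference reconstructs the
  # consensus over the region
  rebuilt <- apply_variants(ref, v, region3)
  expect_identical(rebuilt$state, cons$state)
  expect_identical(rebuilt$position, cons$position)
})

test_that("a consensus identical to the reference yields no records", {
  ref <- synthetic_reference(L = 500L)
  cons <- tibble::tibble(anchor = 1:100, ins = 0L,
                         state = ref_base(ref, 1:100),
                         position = as.character(1:100))
  expect_identical(nrow(call_variants(cons, ref)), 0L)
})

test_that("substitution records match a direct string-diff oracle", {
  ref <- synthetic_reference(L = 2000L)
  withr::with_seed(5, {
    for (i in 1:10) {
      start <- sample.int(1800, 1)
      anchors <- start:(start + 99L)
      state <- ref_base(ref, anchors)
      nmut <- sample(0:5, 1)
      at <- sample.int(100, nmut)
      for (j in at) {
        state[j] <- sample(setdiff(c("A", "C", "G", "T"), state[j]), 1)
      }
      cons <- tibble::tibble(anchor = as.integer(anchors), ins = 0L,
                             state = state,
                             position = as.character(anchors))
      v <- call_variants(cons, ref)
      expected <- diff_positions(ref_base(ref, anchors), state,
                                 as.character(anchors))
      expect_setequal(v$position, expected)
      expect_true(all(v$kind == "substitution"))
      # substitution count equals the Hamming distance over shared bases
      expect_identical(nrow(v), length(expected))
    }
  })
})

test_that("incompatible ambiguity codes are reported, never coerced", {
  ref <- circular_reference("r", "ACGT")
  cons <- tibble::tibble(anchor = 1:4, ins = 0L,
                         state = c("R", "Y", "G", "T"),
                         position = as.character(1:4))
  # R={A,G} contains ref A at pos 1: silent; Y={C,T} contains C at 2: silent
  v <- call_variants(cons, ref)
  expect_identical(nrow(v), 0L)
  expect_identical(nrow(ambiguous_calls(v)), 0L)
  cons$state[1] <- "Y"  # Y does not contain A
  v2 <- call_variants(cons, ref)
  expect_identical(nrow(v2), 0L)
  expect_identical(ambiguous_calls(v2)$position, "1")
})

test_that("group summaries report read counts, depths and grand means", {
  g1 <- clone_group(matrix("A", nrow = 10, ncol = 50), group_id = "g1")
  g2 <- clone_group(matrix("C", nrow = 20, ncol = 50), group_id = "g2")
  s <- group_summary(list(g1, g2))
  expect_identical(s$n_reads, c(10L, 20L))
  expect_identical(glance_groups(s)$grand_mean_reads, 15)
  # no N or gaps: depth equals the read count
  g3 <- clone_group(matrix("G", nrow = 7, ncol = 100), group_id = "g3")
  expect_identical(group_summary(list(g3))$mean_depth, 7)
  # simulated pool recovers the configured sizes
  sim <- simulate_clone_group(balanced_template(100), n_reads = 37, seed = 2)
  expect_identical(group_summary(list(sim$group))$n_reads, 37L)
})

test_that("variant tables export as TSV and VCF-like records", {
  ref <- circular_reference("toyref", "ACGTACGTAC")
  cons <- tibble::tibble(anchor = 1:10, ins = 0L,
                         state = ref_base(ref, 1:10),
                         position = as.character(1:10))
  cons$state[3] <- "T"
  cons$state[6] <- "-"
  v <- call_variants(cons, ref)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_variant_tsv(v, tsv)
  back <- readr::read_tsv(tsv, show_col_types = FALSE)
  expect_identical(nrow(back), 2L)
  write_variant_vcf(v, ref, vcf)
  lines <- readLines(vcf)
  expect_match(lines[1], "fileformat")
  expect_length(grep("^toyref\t", lines), 2L)
})
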