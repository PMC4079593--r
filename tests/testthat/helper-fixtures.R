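# Shared in-code fixtures.

# the three-haplotype worked example: star with one median AAA, length 3
worked_example_matrix <- function() {
  m <- rbind(GAA = c("G", "A", "A"),
             AGA = c("A", "G", "A"),
             AAG = c("A", "A", "G"))
  colnames(m) <- c("5", "7", "9")
  m
}

# a tiny alignment with a gapped column and an insertion column after 15581
toy_indel_alignment <- function() {
  #               15579 15580 15581 15581.1 15582 16199
  seqs <- c(AA1 = "ACG-TT",
            AD7 = "ACGGTT",
            CC1 = "ACGTT-",
            CC2 = "AGGTT-")
  colmap <- tibble::tibble(col = 1:6,
                           anchor = c(15579L, 15580L, 15581L, 15581L,
                                      15582L, 16199L),
                           ins = c(0L, 0L, 0L, 1L, 0L, 0L))
  hap_alignment(seqs, colmap = colmap)
}

# deterministic synthetic circular reference (content-free stand-in for a
# real mitochondrial genome; only coordinates and diffs matter)
synthetic_reference <- function(L = 16357L, seed = 424242L) {
  withr::with_seed(seed, {
    circular_reference("synthetic_ref",
                       sample(c("A", "C", "G", "T"), L, replace = TRUE))
  })
}

# balanced-composition template for read simulations
balanced_template <- function(L = 328L) {
  paste(rep(c("A", "C", "G", "T"), length.out = L), collapse = "")
}
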