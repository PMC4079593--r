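# Clonal-group consensus building and reference-anchored variant tabulation.

IUPAC_CODES <- c(
  A = "A", C = "C", G = "G", T = "T",
  AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K",
  ACG = "V", ACT = "H", AGT = "D", CGT = "B", ACGT = "N"
)
IUPAC_SETS <- stats::setNames(strsplit(names(IUPAC_CODES), ""),
                              unname(IUPAC_CODES))

iupac_code <- function(bases) {
  IUPAC_CODES[[paste(sort(unique(bases)), collapse = "")]]
}

iupac_set <- function(code) IUPAC_SETS[[code]]

#' Construct a clonal read group
#'
#' A clonal group is the set of sequencing reads deriving from one PCR
#' amplicon, aligned to a common window of the reference and analysed as the
#' clones of that product.
#'
#' @param reads Character vector of equal-length aligned reads over
#'   A/C/G/T/N/-, or a character matrix (rows = reads).
#' @param colmap Optional column map as in [hap_alignment()]; defaults to
#'   anchors `start_anchor, start_anchor + 1, ...` with `ins = 0`.
#' @param group_id Group identifier.
#' @param start_anchor Reference anchor of the first column when no `colmap`
#'   is given (default 1).
#' @return An object of class `clone_group` with fields `group_id`, `mat`,
#'   `colmap`.
#' @export
clone_group <- function(reads, colmap = NULL, group_id = "group1",
                        start_anchor = 1L) {
  if (is.matrix(reads)) {
    mat <- toupper(reads)
  } else {
    if (length(reads) < 1L) stop("a clone group needs at least one read",
                                 call. = FALSE)
    n <- nchar(reads)
    if (length(unique(n)) != 1L) {
      stop("reads must all have equal aligned length", call. = FALSE)
    }
    mat <- do.call(rbind, strsplit(toupper(reads), ""))
  }
  if (nrow(mat) < 1L) stop("a clone group needs at least one read",
                           call. = FALSE)
  bad <- setdiff(unique(as.vector(mat)), ALN_ALPHABET)
  if (length(bad) > 0) {
    stop("reads contain characters outside {A,C,G,T,N,-}: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (is.null(rownames(mat))) {
    rownames(mat) <- paste0(group_id, "_read", seq_len(nrow(mat)))
  }
  nc <- ncol(mat)
  if (is.null(colmap)) {
    colmap <- tibble::tibble(col = seq_len(nc),
                             anchor = as.integer(start_anchor) + seq_len(nc) - 1L,
                             ins = 0L)
  } else {
    colmap <- tibble::as_tibble(colmap)[, c("col", "anchor", "ins")]
    colmap$col <- as.integer(colmap$col)
    colmap$anchor <- as.integer(colmap$anchor)
    colmap$ins <- as.integer(colmap$ins)
  }
  colmap$key <- pos_key(colmap$anchor, colmap$ins)
  structure(list(group_id = group_id, mat = mat, colmap = colmap),
            class = "clone_group")
}

#' @export
print.clone_group <- function(x, ...) {
  cat("<clone_group> ", x$group_id, ": ", nrow(x$mat), " reads x ",
      ncol(x$mat), " columns\n", sep = "")
  invisible(x)
}

#' Majority-rule consensus of a clonal group
#'
#' Per column, the consensus is the majority state among non-N read states
#' ('-' counts as a state, so a gap majority yields a deletion in the
#' consensus). Ties between bases are resolved by `tie_rule`: `"ambiguity"`
#' writes the IUPAC code of the tied bases; `"reference"` writes the
#' reference base when it is among the tied states (falling back to the
#' IUPAC code otherwise). A tie between a base and '-' resolves to the
#' base(s). Depth is the count of non-N states per column.
#'
#' @param group A [clone_group()].
#' @param tie_rule `"ambiguity"` (default) or `"reference"`.
#' @param ref A [circular_reference()], required for `tie_rule = "reference"`.
#' @return A tibble of class `consensus_tbl` with columns `col`, `anchor`,
#'   `ins`, `position`, `state`, `depth`.
#' @export
build_consensus <- function(group, tie_rule = c("ambiguity", "reference"),
                            ref = NULL) {
  stopifnot(inherits(group, "clone_group"))
  tie_rule <- match.arg(tie_rule)
  if (tie_rule == "reference" && is.null(ref)) {
    stop("tie_rule = \"reference\" requires a reference sequence",
         call. = FALSE)
  }
  mat <- group$mat
  states <- c("A", "C", "G", "T", "-")
  counts <- vapply(states, function(s) colSums(mat == s, na.rm = TRUE),
                   numeric(ncol(mat)))
  counts <- matrix(counts, ncol = length(states),
                   dimnames = list(NULL, states))
  depth <- as.integer(rowSums(counts))
  state <- character(ncol(mat))
  for (j in seq_len(ncol(mat))) {
    cj <- counts[j, ]
    if (depth[j] == 0L) { state[j] <- "N"; next }
    top <- names(cj)[cj == max(cj)]
    if (length(top) > 1L && "-" %in% top && length(setdiff(top, "-")) > 0) {
      top <- setdiff(top, "-")  # prefer a base over a gap on ties
    }
    if (length(top) == 1L) {
      state[j] <- top
    } else if (tie_rule == "reference" &&
               group$colmap$ins[j] == 0L &&
               ref_base(ref, group$colmap$anchor[j]) %in% top) {
      state[j] <- ref_base(ref, group$colmap$anchor[j])
    } else if (all(top %in% c("A", "C", "G", "T"))) {
      state[j] <- iupac_code(top)
    } else {
      state[j] <- "-"  # tie among gaps only
    }
  }
  out <- tibble::tibble(
    col = group$colmap$col, anchor = group$colmap$anchor,
    ins = group$colmap$ins, position = group$colmap$key,
    state = state, depth = depth
  )
  class(out) <- c("consensus_tbl", class(out))
  attr(out, "group_id") <- group$group_id
  out
}

#' Tabulate variants of a consensus against the circular reference
#'
#' One record per position where the consensus differs from the reference:
#' substitutions at anchored columns, insertions at insertion columns
#' (named `anchor.k`), deletions where the consensus carries a gap at a
#' reference position. IUPAC ambiguity codes compatible with the reference
#' base produce no record; incompatible ambiguities are never coerced to a
#' substitution but reported in the `"ambiguous"` attribute (see
#' [ambiguous_calls()]).
#'
#' @param consensus A `consensus_tbl` from [build_consensus()], or any tibble
#'   with columns `anchor`, `ins`, `position`, `state`.
#' @param ref A [circular_reference()].
#' @param region Optional [ref_interval()] restricting the calls.
#' @return Tibble with columns `position`, `anchor`, `ins`, `ref_state`,
#'   `obs_state`, `kind` (substitution/insertion/deletion).
#' @export
call_variants <- function(consensus, ref, region = NULL) {
  stopifnot(inherits(ref, "circular_reference"))
  cons <- tibble::as_tibble(consensus)
  if (any(cons$anchor < 1L | cons$anchor > ref$length)) {
    stop("consensus column map exceeds the reference coordinates",
         call. = FALSE)
  }
  if (!is.null(region)) {
    cons <- cons[interval_contains(region, cons$anchor), ]
  }
  recs <- list(); amb <- list()
  for (i in seq_len(nrow(cons))) {
    st <- cons$state[i]
    if (st == "N") next
    if (cons$ins[i] > 0L) {
      if (st == "-") next
      if (st %in% c("A", "C", "G", "T")) {
        recs[[length(recs) + 1L]] <- list(cons$position[i], cons$anchor[i],
                                          cons$ins[i], "-", st, "insertion")
      } else {
        amb[[length(amb) + 1L]] <- list(cons$position[i], st)
      }
      next
    }
    rb <- ref_base(ref, cons$anchor[i])
    if (st == "-") {
      recs[[length(recs) + 1L]] <- list(cons$position[i], cons$anchor[i], 0L,
                                        rb, "-", "deletion")
    } else if (st %in% c("A", "C", "G", "T")) {
      if (st != rb) {
        recs[[length(recs) + 1L]] <- list(cons$position[i], cons$anchor[i], 0L,
                                          rb, st, "substitution")
      }
    } else if (!rb %in% iupac_set(st)) {
      amb[[length(amb) + 1L]] <- list(cons$position[i], st)
    }
  }
  out <- if (length(recs) == 0) {
    tibble::tibble(position = character(), anchor = integer(),
                   ins = integer(), ref_state = character(),
                   obs_state = character(), kind = character())
  } else {
    tibble::tibble(
      position = vapply(recs, `[[`, "", 1),
      anchor = vapply(recs, `[[`, 1L, 2),
      ins = vapply(recs, `[[`, 1L, 3),
      ref_state = vapply(recs, `[[`, "", 4),
      obs_state = vapply(recs, `[[`, "", 5),
      kind = vapply(recs, `[[`, "", 6)
    )
  }
  attr(out, "ambiguous") <- if (length(amb) == 0) {
    tibble::tibble(position = character(), state = character())
  } else {
    tibble::tibble(position = vapply(amb, `[[`, "", 1),
                   state = vapply(amb, `[[`, "", 2))
  }
  out
}

#' Ambiguity list attached to a variant table
#' @param variants Output of [call_variants()].
#' @return Tibble with columns `position`, `state`.
#' @export
ambiguous_calls <- function(variants) {
  a <- attr(variants, "ambiguous")
  if (is.null(a)) tibble::tibble(position = character(), state = character())
  else a
}

#' Reconstruct a consensus by applying variant records to the reference
#'
#' The inverse of [call_variants()]: over `region`, reference bases are
#' copied, substitutions and deletions applied at their anchors, and
#' insertion records expanded into `anchor.k` columns.
#'
#' @param ref A [circular_reference()].
#' @param variants Variant tibble as returned by [call_variants()].
#' @param region A [ref_interval()].
#' @return Tibble with columns `position`, `anchor`, `ins`, `state`.
#' @export
apply_variants <- function(ref, variants, region) {
  stopifnot(inherits(region, "ref_interval"))
  anchors <- if (region$start <= region$end) {
    seq.int(region$start, region$end)
  } else {
    c(seq.int(region$start, ref$length), seq.int(1L, region$end))
  }
  rows <- tibble::tibble(anchor = as.integer(anchors), ins = 0L,
                         state = ref_base(ref, anchors))
  v <- tibble::as_tibble(variants)
  for (i in seq_len(nrow(v))) {
    if (v$kind[i] == "substitution" || v$kind[i] == "deletion") {
      hit <- which(rows$anchor == v$anchor[i] & rows$ins == 0L)
      rows$state[hit] <- v$obs_state[i]
    } else {
      at <- which(rows$anchor == v$anchor[i] & rows$ins == v$ins[i] - 1L)
      ins_row <- tibble::tibble(anchor = v$anchor[i], ins = v$ins[i],
                                state = v$obs_state[i])
      rows <- dplyr::bind_rows(rows[seq_len(at), ], ins_row,
                               rows[-seq_len(at), ])
    }
  }
  rows$position <- pos_key(rows$anchor, rows$ins)
  rows[, c("position", "anchor", "ins", "state")]
}

#' Per-group read counts and coverage depth
#'
#' @param groups A list of [clone_group()] objects.
#' @return Tibble with one row per group (`group_id`, `n_reads`,
#'   `mean_depth`) where depth counts non-N states per column; grand means
#'   over groups are attached via [glance_groups()].
#' @export
group_summary <- function(groups) {
  stopifnot(length(groups) >= 0)
  rows <- purrr::map_dfr(groups, function(g) {
    stopifnot(inherits(g, "clone_group"))
    depth <- colSums(g$mat != "N" & g$mat != "-")
    tibble::tibble(group_id = g$group_id, n_reads = nrow(g$mat),
                   mean_depth = mean(depth))
  })
  attr(rows, "grand") <- tibble::tibble(
    n_groups = nrow(rows),
    grand_mean_reads = mean(rows$n_reads),
    grand_mean_depth = mean(rows$mean_depth)
  )
  rows
}

#' Grand means attached to a [group_summary()] table
#' @param summary Output of [group_summary()].
#' @return One-row tibble: `n_groups`, `grand_mean_reads`, `grand_mean_depth`.
#' @export
glance_groups <- function(summary) attr(summary, "grand")

#' Write a variant table as TSV (reference-position / reference / observed)
#' @param variants Output of [call_variants()].
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_variant_tsv <- function(variants, path) {
  out <- tibble::tibble(
    position = variants$position,
    reference_state = variants$ref_state,
    observed_state = variants$obs_state,
    kind = variants$kind
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' Write variant records in VCF-like form
#'
#' Minimal four-column records (CHROM, POS, REF, ALT) for interoperability;
#' insertions are left-anchored on the preceding reference base and
#' deletions on the deleted base itself.
#'
#' @param variants Output of [call_variants()].
#' @param ref A [circular_reference()] (supplies CHROM and anchor bases).
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_variant_vcf <- function(variants, ref, path) {
  lines <- c("##fileformat=VCFv4.2",
             paste0("##contig=<ID=", ref$id, ",length=", ref$length, ">"),
             "#CHROM\tPOS\tID\tREF\tALT")
  for (i in seq_len(nrow(variants))) {
    anchor <- variants$anchor[i]
    b <- ref_base(ref, anchor)
    fields <- switch(variants$kind[i],
      substitution = c(anchor, variants$ref_state[i], variants$obs_state[i]),
      insertion    = c(anchor, b, paste0(b, variants$obs_state[i])),
      deletion     = c(pos_wrap(anchor - 1L, ref$length),
                       paste0(ref_base(ref, anchor - 1L), variants$ref_state[i]),
                       ref_base(ref, anchor - 1L))
    )
    lines <- c(lines, paste(ref$id, fields[1], ".", fields[2], fields[3],
                            sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}
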