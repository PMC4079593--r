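# Circular reference coordinates, alignment-column mapping, gap policy.

ALN_ALPHABET <- c("A", "C", "G", "T", "N", "-")

#' Format reference positions as position keys
#'
#' A position on the reference is an anchor base (1-based) plus an insertion
#' sub-index: `ins = 0` is the anchored reference base itself, `ins = k >= 1`
#' is the k-th alignment column inserted after that base. Keys render as
#' `"15581"` or `"15581.1"`.
#'
#' @param anchor Integer vector of 1-based anchor positions.
#' @param ins Integer vector of insertion sub-indices (default 0).
#' @return Character vector of position keys.
#' @export
#' @examples
#' pos_key(c(108L, 15581L), c(0L, 1L))
pos_key <- function(anchor, ins = 0L) {
  if (length(ins) == 1L) ins <- rep(ins, length(anchor))
  ifelse(ins > 0L, paste0(anchor, ".", ins), as.character(anchor))
}

#' Parse position keys into anchor and insertion sub-index
#'
#' @param key Character vector of keys such as `"108"` or `"15581.1"`.
#' @return A tibble with columns `key`, `anchor`, `ins`.
#' @export
parse_pos <- function(key) {
  parts <- stringr::str_split_fixed(key, stringr::fixed("."), 2)
  anchor <- suppressWarnings(as.integer(parts[, 1]))
  ins <- suppressWarnings(as.integer(parts[, 2]))
  ins[is.na(ins)] <- 0L
  if (anyNA(anchor)) {
    stop("malformed position key(s): ",
         paste(key[is.na(anchor)], collapse = ", "), call. = FALSE)
  }
  tibble::tibble(key = as.character(key), anchor = anchor, ins = ins)
}

#' Construct a circular reference sequence
#'
#' @param id Sequence identifier.
#' @param bases A single string or character vector over A/C/G/T/N.
#' @return An object of class `circular_reference` with fields `id`, `bases`
#'   (character vector of single bases) and `length`.
#' @export
#' @examples
#' ref <- circular_reference("toy", "ACGTACGT")
#' ref_base(ref, c(1, 8, 9))  # position 9 wraps to 1
circular_reference <- function(id, bases) {
  if (length(bases) == 1L && nchar(bases[1]) > 1L) {
    bases <- strsplit(bases, "")[[1]]
  }
  bases <- toupper(bases)
  bad <- setdiff(unique(bases), c("A", "C", "G", "T", "N"))
  if (length(bad) > 0) {
    stop("reference contains non-ACGTN characters: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(id = id, bases = bases, length = length(bases)),
            class = "circular_reference")
}

#' @export
print.circular_reference <- function(x, ...) {
  cat("<circular_reference> ", x$id, ": ", x$length, " bp\n", sep = "")
  invisible(x)
}

# wrap an arbitrary integer position onto 1..L
pos_wrap <- function(p, L) ((p - 1L) %% L) + 1L

#' Look up reference bases (with circular wrap)
#'
#' @param ref A [circular_reference()].
#' @param anchor Integer positions; values outside 1..length wrap modulo the
#'   reference length.
#' @return Character vector of bases.
#' @export
ref_base <- function(ref, anchor) {
  stopifnot(inherits(ref, "circular_reference"))
  ref$bases[pos_wrap(as.integer(anchor), ref$length)]
}

#' Define a (possibly wrapping) closed interval of reference positions
#'
#' Intervals are closed and 1-based. When `start > end` the interval wraps
#' through the origin of the circular reference, e.g. the amplified stretch
#' spanning positions 15,308-16,357 plus 1-109 is `ref_interval(15308, 109)`.
#'
#' @param start,end Anchor positions (1-based, inclusive).
#' @param circular Whether wrap-through-origin is permitted (default `TRUE`).
#' @return An object of class `ref_interval`.
#' @export
ref_interval <- function(start, end, circular = TRUE) {
  start <- as.integer(start); end <- as.integer(end)
  stopifnot(length(start) == 1L, length(end) == 1L, start >= 1L, end >= 1L)
  if (!circular && start > end) {
    stop("start > end requires a circular interval", call. = FALSE)
  }
  structure(list(start = start, end = end, circular = circular),
            class = "ref_interval")
}

#' @export
print.ref_interval <- function(x, ...) {
  cat("<ref_interval> ", x$start, "-", x$end,
      if (x$start > x$end) " (wraps origin)", "\n", sep = "")
  invisible(x)
}

#' Number of reference positions in a closed interval
#'
#' @param interval A [ref_interval()].
#' @param ref_length Length of the circular reference.
#' @return Integer count of reference positions (insertion columns do not
#'   count; they are alignment artefacts, not reference positions).
#' @export
#' @examples
#' interval_length(ref_interval(14162, 15301), 16357)  # 1140
#' interval_length(ref_interval(15573, 15899), 16357)  # 327
#' interval_length(ref_interval(16350, 5), 16357)      # wraps: 13
interval_length <- function(interval, ref_length) {
  stopifnot(inherits(interval, "ref_interval"))
  ref_length <- as.integer(ref_length)
  s <- interval$start; e <- interval$end
  if (s > ref_length || e > ref_length) {
    stop("interval anchors exceed reference length ", ref_length, call. = FALSE)
  }
  if (s <= e) e - s + 1L else (ref_length - s + 1L) + e
}

# membership of anchors in a (possibly wrapping) interval
interval_contains <- function(interval, anchor) {
  s <- interval$start; e <- interval$end
  if (s <= e) anchor >= s & anchor <= e else anchor >= s | anchor <= e
}

#' Construct a reference-mapped haplotype alignment
#'
#' @param seqs Named character vector of equal-length aligned sequences over
#'   A/C/G/T/N/-, or a character matrix (rows = haplotypes, one character per
#'   cell) with rownames.
#' @param colmap Optional tibble/data frame with columns `col` (1-based
#'   alignment column), `anchor` and `ins` mapping every column to a
#'   reference position. Defaults to anchors 1..n_col with `ins = 0`.
#' @param meta Optional per-haplotype metadata tibble with a `label` column
#'   (e.g. geography, era, haplogroup tag).
#' @return An object of class `hap_alignment`: a list with the character
#'   matrix `mat`, the `colmap` tibble (with derived `key` column) and `meta`.
#' @export
hap_alignment <- function(seqs, colmap = NULL, meta = NULL) {
  if (is.matrix(seqs)) {
    mat <- seqs
  } else {
    if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
      stop("sequences must be uniquely named", call. = FALSE)
    }
    n <- nchar(seqs)
    if (length(unique(n)) != 1L) {
      stop("aligned sequences must all have equal length", call. = FALSE)
    }
    mat <- do.call(rbind, strsplit(toupper(seqs), ""))
    rownames(mat) <- names(seqs)
  }
  if (nrow(mat) > 0L &&
      (is.null(rownames(mat)) || anyDuplicated(rownames(mat)))) {
    stop("alignment rows must be uniquely labelled", call. = FALSE)
  }
  bad <- setdiff(unique(as.vector(mat)), ALN_ALPHABET)
  if (length(bad) > 0) {
    stop("alignment contains characters outside {A,C,G,T,N,-}: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  nc <- ncol(mat)
  if (is.null(colmap)) {
    colmap <- tibble::tibble(col = seq_len(nc), anchor = seq_len(nc), ins = 0L)
  } else {
    colmap <- tibble::as_tibble(colmap)
    stopifnot(all(c("col", "anchor", "ins") %in% names(colmap)))
    colmap <- dplyr::arrange(colmap, .data$col)
    colmap$col <- as.integer(colmap$col)
    colmap$anchor <- as.integer(colmap$anchor)
    colmap$ins <- as.integer(colmap$ins)
    if (!identical(colmap$col, seq_len(nc))) {
      stop("colmap must cover alignment columns 1..", nc, call. = FALSE)
    }
  }
  colmap$key <- pos_key(colmap$anchor, colmap$ins)
  check_colmap_increasing(colmap)
  if (!is.null(meta)) {
    meta <- tibble::as_tibble(meta)
    stopifnot("label" %in% names(meta))
  }
  structure(list(mat = mat, colmap = colmap, meta = meta),
            class = "hap_alignment")
}

# colmap must be strictly increasing in (anchor, ins) order along the chosen
# origin; a single decrease is tolerated for alignments that wrap the origin.
check_colmap_increasing <- function(colmap) {
  ord <- colmap$anchor + colmap$ins / (1 + max(colmap$ins, 1L))
  d <- diff(ord)
  if (any(d == 0)) stop("duplicated reference positions in colmap", call. = FALSE)
  if (sum(d < 0) > 1L) {
    stop("colmap is not increasing in reference-position order ",
         "(more than one wrap point)", call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.hap_alignment <- function(x, ...) {
  cat("<hap_alignment> ", nrow(x$mat), " haplotypes x ", ncol(x$mat),
      " columns (", sum(x$colmap$ins > 0), " insertion columns)\n", sep = "")
  invisible(x)
}

#' @export
dim.hap_alignment <- function(x) dim(x$mat)

#' Labels of a haplotype alignment
#' @param aln A [hap_alignment()].
#' @return Character vector of haplotype labels.
#' @export
aln_labels <- function(aln) rownames(aln$mat)

#' Tidy a haplotype alignment into long format
#' @param x A [hap_alignment()].
#' @param ... Unused.
#' @return Tibble with one row per haplotype x column: `label`, `col`,
#'   `position`, `state`.
#' @export
tidy.hap_alignment <- function(x, ...) {
  tibble::tibble(
    label = rep(rownames(x$mat), times = ncol(x$mat)),
    col = rep(x$colmap$col, each = nrow(x$mat)),
    position = rep(x$colmap$key, each = nrow(x$mat)),
    state = as.vector(x$mat)
  )
}

#' Extract the alignment columns falling in a reference interval
#'
#' Keeps exactly the columns whose reference position lies in the closed
#' interval, including insertion columns anchored inside it; row order,
#' labels and metadata are preserved.
#'
#' @param aln A [hap_alignment()].
#' @param interval A [ref_interval()].
#' @return A `hap_alignment` restricted to the interval.
#' @export
extract_region <- function(aln, interval) {
  stopifnot(inherits(aln, "hap_alignment"), inherits(interval, "ref_interval"))
  keep <- interval_contains(interval, aln$colmap$anchor)
  if (!any(keep)) {
    stop("interval ", interval$start, "-", interval$end,
         " is disjoint from the alignment column map", call. = FALSE)
  }
  subset_alignment(aln, which(keep))
}

subset_alignment <- function(aln, cols) {
  mat <- aln$mat[, cols, drop = FALSE]
  colmap <- aln$colmap[cols, ]
  colmap$col <- seq_len(nrow(colmap))
  hap_alignment(mat, colmap = colmap, meta = aln$meta)
}

#' Remove gapped alignment columns, keeping declared indel characters
#'
#' Every column in which any haplotype carries `-` is removed, unless its
#' position key is listed in `exceptions`; excepted columns are retained as
#' indel characters whose state alphabet is {absent (`-`), A, C, G, T}. `N`
#' is missing data, never grounds for removal. The columns dropped are
#' recorded in the `"dropped"` attribute (a tibble with `ref_position` and
#' `reason`), retrievable via [gap_drop_report()].
#'
#' @param aln A [hap_alignment()].
#' @param exceptions Character vector of position keys (e.g. `"15581.1"`)
#'   exempt from removal.
#' @return The filtered `hap_alignment`.
#' @export
apply_gap_policy <- function(aln, exceptions = character()) {
  stopifnot(inherits(aln, "hap_alignment"))
  exceptions <- as.character(exceptions)
  missing_exc <- setdiff(exceptions, aln$colmap$key)
  if (length(missing_exc) > 0) {
    stop("exception position(s) not present in the alignment: ",
         paste(missing_exc, collapse = ", "), call. = FALSE)
  }
  has_gap <- apply(aln$mat == "-", 2, any)
  drop <- has_gap & !(aln$colmap$key %in% exceptions)
  dropped <- tibble::tibble(
    ref_position = aln$colmap$key[drop],
    reason = ifelse(aln$colmap$ins[drop] > 0, "insertion", "deletion")
  )
  keep <- which(!drop)
  if (length(keep) == 0L) {
    out <- aln
    out$mat <- aln$mat[, 0, drop = FALSE]
    out$colmap <- aln$colmap[0, ]
  } else {
    out <- subset_alignment(aln, keep)
  }
  attr(out, "dropped") <- dropped
  out
}

#' Drop report from [apply_gap_policy()]
#' @param aln A `hap_alignment` returned by [apply_gap_policy()].
#' @return Tibble with columns `ref_position`, `reason`.
#' @export
gap_drop_report <- function(aln) {
  rep <- attr(aln, "dropped")
  if (is.null(rep)) tibble::tibble(ref_position = character(),
                                   reason = character())
  else rep
}

#' Write a gap-policy drop report as TSV
#' @param aln A `hap_alignment` returned by [apply_gap_policy()].
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_drop_report <- function(aln, path) {
  readr::write_tsv(gap_drop_report(aln), path)
  invisible(path)
}

#' Read an aligned FASTA into a reference-mapped alignment
#'
#' The column-to-reference map is supplied either by a reference row inside
#' the FASTA (`ref_label`): its non-gap characters receive successive anchor
#' positions starting at `ref_start` (wrapping at `ref_length` when given)
#' and its gap characters become insertion columns `anchor.k`; or by a
#' sidecar TSV (`colmap_path`) with columns `column_index`, `anchor`,
#' `ins_index`.
#'
#' @param path Aligned FASTA file (gaps as `-`).
#' @param ref_label Label of the in-FASTA reference row, or `NULL`.
#' @param colmap_path Sidecar TSV path, or `NULL`.
#' @param ref_start Anchor of the reference row's first base (default 1).
#' @param ref_length Circular reference length for wrap-around numbering.
#' @param drop_ref Drop the reference row from the returned alignment.
#' @param meta Optional per-haplotype metadata (see [hap_alignment()]).
#' @return A [hap_alignment()].
#' @export
read_alignment_fasta <- function(path, ref_label = NULL, colmap_path = NULL,
                                 ref_start = 1L, ref_length = NULL,
                                 drop_ref = TRUE, meta = NULL) {
  ss <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  colmap <- NULL
  if (!is.null(ref_label)) {
    if (!ref_label %in% names(seqs)) {
      stop("reference row '", ref_label, "' not found in ", path, call. = FALSE)
    }
    refrow <- strsplit(seqs[[ref_label]], "")[[1]]
    colmap <- colmap_from_ref_row(refrow, ref_start = ref_start,
                                  ref_length = ref_length)
    if (drop_ref) seqs <- seqs[names(seqs) != ref_label]
  } else if (!is.null(colmap_path)) {
    cm <- readr::read_tsv(colmap_path, show_col_types = FALSE)
    colmap <- tibble::tibble(col = as.integer(cm$column_index),
                             anchor = as.integer(cm$anchor),
                             ins = as.integer(cm$ins_index))
  }
  hap_alignment(seqs, colmap = colmap, meta = meta)
}

# derive a colmap from an aligned reference row: non-gap chars advance the
# anchor, gap chars are insertion columns after the last emitted anchor
colmap_from_ref_row <- function(refrow, ref_start = 1L, ref_length = NULL) {
  n <- length(refrow)
  anchor <- integer(n); ins <- integer(n)
  cur <- as.integer(ref_start) - 1L
  k <- 0L
  for (i in seq_len(n)) {
    if (refrow[i] == "-") {
      k <- k + 1L
      anchor[i] <- cur; ins[i] <- k
    } else {
      cur <- cur + 1L
      if (!is.null(ref_length) && cur > ref_length) cur <- 1L
      k <- 0L
      anchor[i] <- cur; ins[i] <- 0L
    }
  }
  if (anchor[1] == as.integer(ref_start) - 1L) {
    stop("reference row may not start with a gap column", call. = FALSE)
  }
  tibble::tibble(col = seq_len(n), anchor = anchor, ins = ins)
}

#' Write a haplotype alignment as aligned FASTA
#' @param aln A [hap_alignment()].
#' @param path Output FASTA path.
#' @param ref Optional [circular_reference()]; when given, a reference row is
#'   prepended so the file round-trips through [read_alignment_fasta()].
#' @return The path, invisibly.
#' @export
write_alignment_fasta <- function(aln, path, ref = NULL) {
  seqs <- apply(aln$mat, 1, paste, collapse = "")
  if (!is.null(ref)) {
    refrow <- ifelse(aln$colmap$ins > 0, "-", ref_base(ref, aln$colmap$anchor))
    seqs <- c(stats::setNames(paste(refrow, collapse = ""), ref$id), seqs)
  }
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path, width = 80L)
  invisible(path)
}
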