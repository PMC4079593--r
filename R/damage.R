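# Nucleotide-misincorporation spectra, composition-bias scaling and the
# type-1 / type-2 transition classification used to authenticate ancient
# templates (excess C->T/G->A is the deamination signature).

BASES <- c("A", "C", "G", "T")

# canonical order of the 12 directed base changes
change_table <- function() {
  tb <- expand.grid(to = BASES, from = BASES, stringsAsFactors = FALSE)
  tb <- tb[tb$from != tb$to, c("from", "to")]
  tb <- tb[order(tb$from, tb$to), ]
  tb$change <- paste0(tb$from, ">", tb$to)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  mate <- paste0(comp[tb$from], ">", comp[tb$to])
  tb$pair <- ifelse(tb$change < mate,
                    paste(tb$change, mate, sep = "/"),
                    paste(mate, tb$change, sep = "/"))
  tibble::as_tibble(tb)
}

TYPE1_CHANGES <- c("A>G", "T>C")   # type 1 transitions
TYPE2_CHANGES <- c("C>T", "G>A")   # type 2 transitions (miscoding lesions)

#' Count directed misincorporations of reads against their consensus
#'
#' For every read cell whose state is a base differing from the consensus
#' base at that column, the directed change consensus -> read is counted.
#' Columns where the consensus is not an unambiguous base (gap, N, IUPAC
#' code) and read cells that are N or '-' are skipped: insertions and
#' deletions are excluded from the spectrum.
#'
#' @param group A [clone_group()].
#' @param consensus A `consensus_tbl` from [build_consensus()] on the same
#'   group (or any tibble with a `state` column of matching length).
#' @return Named integer vector of the 12 directed changes (`"A>C"`, ...).
#' @export
count_misincorporations <- function(group, consensus) {
  stopifnot(inherits(group, "clone_group"))
  cons <- consensus$state
  if (length(cons) != ncol(group$mat)) {
    stop("consensus length does not match the group's alignment", call. = FALSE)
  }
  ct <- change_table()
  counts <- stats::setNames(integer(12), ct$change)
  usable <- cons %in% BASES
  mat <- group$mat[, usable, drop = FALSE]
  consb <- cons[usable]
  for (b in BASES) {
    colsel <- consb == b
    if (!any(colsel)) next
    sub <- mat[, colsel, drop = FALSE]
    for (x in setdiff(BASES, b)) {
      counts[paste0(b, ">", x)] <- sum(sub == x)
    }
  }
  counts
}

# composition of the consensus over analysed (unambiguous base) columns
consensus_composition <- function(consensus) {
  st <- consensus$state
  stats::setNames(vapply(BASES, function(b) sum(st == b), 0L), BASES)
}

#' Scale raw misincorporation counts for fragment composition bias
#'
#' Compensates the nucleotide composition of the fragment: with
#' r = (A+T)/(G+C), changes originating from C or G are multiplied by r when
#' G+C is underrepresented; symmetrically, changes originating from A or T
#' are multiplied by (G+C)/(A+T) when A+T is underrepresented. Balanced
#' composition leaves all counts unchanged; scaling is applied only to the
#' underrepresented origin class.
#'
#' @param raw Named vector of the 12 raw counts (as from
#'   [count_misincorporations()]).
#' @param composition Named vector with counts of A, C, G, T in the
#'   fragment's consensus over the analysed columns.
#' @return Named numeric vector of scaled counts.
#' @export
scale_spectrum <- function(raw, composition) {
  ct <- change_table()
  raw <- raw[ct$change]
  at <- sum(composition[c("A", "T")])
  gc <- sum(composition[c("C", "G")])
  scaled <- as.numeric(raw)
  names(scaled) <- ct$change
  origin <- ct$from
  if (gc < at) {
    if (gc == 0) stop("fragment has no G/C bases; composition ratio undefined",
                      call. = FALSE)
    sel <- origin %in% c("C", "G")
    scaled[sel] <- scaled[sel] * (at / gc)
  } else if (at < gc) {
    if (at == 0) stop("fragment has no A/T bases; composition ratio undefined",
                      call. = FALSE)
    sel <- origin %in% c("A", "T")
    scaled[sel] <- scaled[sel] * (gc / at)
  }
  scaled
}

#' Misincorporation spectrum of a clonal group
#'
#' Convenience wrapper: builds (or accepts) the group consensus, counts the
#' 12 directed changes, applies composition scaling, folds the changes into
#' the 6 complementary pairs and classifies type-1 (A>G/T>C) versus type-2
#' (C>T/G>A) transitions.
#'
#' @param group A [clone_group()].
#' @param consensus Optional precomputed `consensus_tbl`.
#' @param tie_rule,ref Passed to [build_consensus()] when `consensus` is
#'   `NULL`.
#' @return Object of class `damage_spectrum`: list with `table` (tibble:
#'   `change`, `from`, `to`, `pair`, `raw`, `scaled`), `composition`,
#'   `type1`, `type2`, `ratio21` (scaled; `NA` when type1 is 0),
#'   `type1_raw`, `type2_raw`, `ratio21_raw`, `group_id`, `n_reads`.
#' @export
damage_spectrum <- function(group, consensus = NULL,
                            tie_rule = "ambiguity", ref = NULL) {
  if (is.null(consensus)) {
    consensus <- build_consensus(group, tie_rule = tie_rule, ref = ref)
  }
  raw <- count_misincorporations(group, consensus)
  comp <- consensus_composition(consensus)
  scaled <- scale_spectrum(raw, comp)
  ct <- change_table()
  tab <- dplyr::mutate(ct, raw = as.integer(raw[.data$change]),
                       scaled = scaled[.data$change])
  type1 <- sum(scaled[TYPE1_CHANGES]); type2 <- sum(scaled[TYPE2_CHANGES])
  type1_raw <- sum(raw[TYPE1_CHANGES]); type2_raw <- sum(raw[TYPE2_CHANGES])
  structure(list(
    table = tab, composition = comp,
    type1 = type1, type2 = type2,
    ratio21 = if (type1 > 0) type2 / type1 else NA_real_,
    type1_raw = type1_raw, type2_raw = type2_raw,
    ratio21_raw = if (type1_raw > 0) type2_raw / type1_raw else NA_real_,
    group_id = group$group_id, n_reads = nrow(group$mat)
  ), class = "damage_spectrum")
}

#' @export
print.damage_spectrum <- function(x, ...) {
  cat("<damage_spectrum> ", x$group_id, ": type1 = ", signif(x$type1, 4),
      ", type2 = ", signif(x$type2, 4), ", type2/type1 = ",
      signif(x$ratio21, 4), "\n", sep = "")
  invisible(x)
}

#' Complementary-pair sums of a spectrum
#' @param spectrum A [damage_spectrum()].
#' @param scaled Use scaled (default) or raw counts.
#' @return Tibble with columns `pair`, `count` (6 rows).
#' @export
pair_sums <- function(spectrum, scaled = TRUE) {
  col <- if (scaled) "scaled" else "raw"
  out <- dplyr::summarise(dplyr::group_by(spectrum$table, .data$pair),
                          count = sum(.data[[col]]), .groups = "drop")
  dplyr::arrange(out, .data$pair)
}

#' Pool type-1/type-2 transition classes across clonal groups
#'
#' Sums the scaled (and raw) type-1 and type-2 classes over all spectra and
#' reports the pooled type2/type1 ratio together with a per-group table.
#'
#' @param spectra A list of [damage_spectrum()] objects (or a single one).
#' @return List of class `type_ratio_summary`: `pooled` (one-row tibble with
#'   `type1`, `type2`, `ratio21`, `type1_raw`, `type2_raw`, `ratio21_raw`,
#'   `ratio_defined`) and `per_group` (one row per spectrum).
#' @export
type_ratio <- function(spectra) {
  if (inherits(spectra, "damage_spectrum")) spectra <- list(spectra)
  stopifnot(length(spectra) >= 1)
  per_group <- purrr::map_dfr(spectra, function(s) {
    tibble::tibble(group_id = s$group_id, n_reads = s$n_reads,
                   type1 = s$type1, type2 = s$type2, ratio21 = s$ratio21,
                   type1_raw = s$type1_raw, type2_raw = s$type2_raw,
                   ratio21_raw = s$ratio21_raw)
  })
  t1 <- sum(per_group$type1); t2 <- sum(per_group$type2)
  t1r <- sum(per_group$type1_raw); t2r <- sum(per_group$type2_raw)
  pooled <- tibble::tibble(
    type1 = t1, type2 = t2,
    ratio21 = if (t1 > 0) t2 / t1 else NA_real_,
    type1_raw = t1r, type2_raw = t2r,
    ratio21_raw = if (t1r > 0) t2r / t1r else NA_real_,
    ratio_defined = t1 > 0
  )
  structure(list(pooled = pooled, per_group = per_group),
            class = "type_ratio_summary")
}

#' @export
print.type_ratio_summary <- function(x, ...) {
  cat("<type_ratio_summary> pooled type2/type1 = ",
      signif(x$pooled$ratio21, 4), " (", nrow(x$per_group), " groups)\n",
      sep = "")
  invisible(x)
}

#' Write per-group and pooled spectra as TSV
#' @param spectra List of [damage_spectrum()] objects.
#' @param path Output TSV (12 changes x groups, plus pair/type summaries).
#' @return The path, invisibly.
#' @export
write_spectra_tsv <- function(spectra, path) {
  if (inherits(spectra, "damage_spectrum")) spectra <- list(spectra)
  long <- purrr::map_dfr(spectra, function(s) {
    dplyr::mutate(s$table, group_id = s$group_id, .before = 1)
  })
  readr::write_tsv(long, path)
  invisible(path)
}
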